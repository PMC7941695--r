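#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an embedding result
#'
#' @param x A `pl_embedding` ([pca_embedding()] / [mds_embedding()]).
#' @param ... Unused.
#' @return Long tibble `unit`, `axis`, `coordinate`.
#' @method tidy pl_embedding
#' @export
tidy.pl_embedding <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"unit", names_to = "axis",
                      values_to = "coordinate")
}

#' @rdname tidy.pl_embedding
#' @return For `glance()`: one row per axis with `eigenvalue` and
#'   `prop_variance`.
#' @method glance pl_embedding
#' @export
glance.pl_embedding <- function(x, ...) {
  eig <- attr(x, "eigenvalues")
  pos <- pmax(eig, 0)
  tibble(axis = seq_along(eig), eigenvalue = eig,
         prop_variance = if (sum(pos) > 0) pos / sum(pos) else rep(0, length(eig)),
         method = attr(x, "method"))
}

#' Tidy an AMOVA result
#'
#' @param x A `pl_amova` ([amova()]).
#' @param ... Unused.
#' @return The variance-decomposition table as a tibble.
#' @method tidy pl_amova
#' @export
tidy.pl_amova <- function(x, ...) x$table

#' @rdname tidy.pl_amova
#' @return For `glance()`: one row with `phi_st`, `p_value`,
#'   `permutations`, `seed`, `n`.
#' @method glance pl_amova
#' @export
glance.pl_amova <- function(x, ...) {
  tibble(phi_st = x$phi_st, p_value = x$p_value,
         permutations = x$permutations, seed = x$seed, n = x$n)
}

#' Tidy a TMRCA estimate
#'
#' @param x A `pl_tmrca` ([rho_tmrca()] / [asd_tmrca()]).
#' @param ... Unused.
#' @return One-row tibble with the estimator, point estimates and
#'   parameters.
#' @method tidy pl_tmrca
#' @export
tidy.pl_tmrca <- function(x, ...) {
  tibble(estimator = x$estimator,
         statistic = if (x$estimator == "rho") x$rho else x$asd,
         t_generations = x$t_generations, t_years = x$t_years,
         se_generations = x$se_generations %||% NA_real_,
         mu = x$mu, generation_time = x$generation_time, n = x$n)
}

#' Tidy a median-joining network
#'
#' @param x An `mj_network`.
#' @param ... Unused.
#' @return Edge list tibble `from`, `to`, `weight`.
#' @method tidy mj_network
#' @export
tidy.mj_network <- function(x, ...) x$edges

#' @rdname tidy.mj_network
#' @method glance mj_network
#' @export
glance.mj_network <- function(x, ...) {
  tibble(n_observed = sum(x$nodes$type == "observed"),
         n_median = sum(x$nodes$type == "median"),
         n_edges = nrow(x$edges),
         total_weight = sum(x$edges$weight),
         epsilon = x$epsilon)
}
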