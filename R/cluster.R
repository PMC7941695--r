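#' Read a sample-to-population assignment file
#'
#' Two-column TSV (`sample`, `population`), header optional.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `sample`, `population`.
#' @export
read_popmap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         header = FALSE)
  if (identical(tolower(as.character(d[1, 1])), "sample")) d <- d[-1, , drop = FALSE]
  tibble(sample = as.character(d[[1]]), population = as.character(d[[2]]))
}

join_popmap <- function(hg, popmap) {
  d <- left_join(hg, popmap, by = "sample")
  drop <- is.na(d$population)
  if (any(drop)) {
    warn(paste0(sum(drop), " classified sample(s) absent from the population ",
                "map were dropped"))
  }
  d[!drop, , drop = FALSE]
}

#' Haplogroup frequency table per population
#'
#' Counts each (optionally depth-simplified) haplogroup within each
#' population and divides by the population sample size, giving the
#' populations-by-haplogroups frequency matrix used for PCA clustering.
#'
#' @param hg Haplogroup assignment tibble ([classify_samples()] / [read_hg()]).
#' @param popmap Tibble `sample`, `population` ([read_popmap()]).
#' @param tree Optional [haplo_tree], required when `level` is given.
#' @param level Optional resolution level at which to simplify haplogroups
#'   first (see [simplify_haplogroup()]).
#' @return A tibble of class `freq_table`: first column `population`, then
#'   one column per haplogroup with frequencies summing to 1 per row;
#'   attribute `n` holds per-population sample counts.
#' @export
haplogroup_frequencies <- function(hg, popmap, tree = NULL, level = NULL) {
  d <- join_popmap(hg, popmap)
  d <- filter(d, .data$status != "unresolved")
  if (!nrow(d)) pl_abort("no mapped, resolved samples", "patriline_empty_input_error")
  if (!is.null(level)) {
    if (is.null(tree)) pl_abort("`tree` is required when `level` is given",
                                "patriline_argument_error")
    d$haplogroup <- simplify_haplogroup(d$haplogroup, level, tree)
  }
  tab <- d |>
    count(.data$population, .data$haplogroup) |>
    group_by(.data$population) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
  sizes <- tab |> group_by(.data$population) |> summarise(n = sum(.data$n))
  wide <- tidyr::pivot_wider(select(tab, "population", "haplogroup", "freq"),
                             names_from = "haplogroup", values_from = "freq",
                             values_fill = 0)
  wide <- arrange(wide, .data$population)
  out <- structure(wide, class = c("freq_table", class(wide)))
  attr(out, "n") <- setNames(sizes$n, sizes$population)
  out
}

freq_matrix <- function(freq) {
  m <- as.matrix(freq[, -1, drop = FALSE])
  rownames(m) <- freq$population
  m
}

#' Principal component embedding of population haplogroup frequencies
#'
#' Column-centres the populations-by-haplogroups frequency matrix and
#' decomposes it; coordinates are the projections of each population on
#' the top-`k` axes and eigenvalues are the variances along them.
#'
#' @param freq A `freq_table` from [haplogroup_frequencies()] (or any
#'   data frame whose first column labels the units).
#' @param k Number of axes to keep (clipped to the matrix rank, with a
#'   warning, if too large).
#' @return An object of class `pl_embedding`: tibble `unit`, `axis1..axisk`,
#'   with attributes `eigenvalues` (all of them, non-increasing) and
#'   `method = "pca"`.
#' @export
pca_embedding <- function(freq, k = 2) {
  m <- freq_matrix(freq)
  if (nrow(m) < 2) pl_abort("need at least 2 populations", "patriline_argument_error")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- p$sdev^2
  kmax <- sum(eig > 1e-12)
  if (k > ncol(p$x)) {
    warn(paste0("k clipped from ", k, " to ", ncol(p$x)))
    k <- ncol(p$x)
  }
  coords <- p$x[, seq_len(k), drop = FALSE]
  out <- as_tibble(coords, .name_repair = ~ paste0("axis", seq_len(k)))
  out <- dplyr::bind_cols(tibble(unit = rownames(m)), out)
  structure(out, class = c("pl_embedding", class(out)),
            eigenvalues = eig, method = "pca", kmax = kmax)
}

#' Pairwise Fst between populations from haplogroup identities
#'
#' Treats haplogroup identity as a single multi-allelic locus and computes,
#' for each pair of populations, `Fst = (H_T - H_S) / H_T` with
#' `H = 1 - sum(p_i^2)`; `H_S` is the unweighted mean within-population
#' gene diversity and `H_T` the gene diversity of the mean frequency
#' vector. Negative estimates are clamped to 0 (the matrix feeds a metric
#' MDS). With `corrected = TRUE` each within-population diversity receives
#' the `n/(n-1)` small-sample factor.
#'
#' @inheritParams haplogroup_frequencies
#' @param corrected Apply the sample-size correction? Default `FALSE`.
#' @return Symmetric matrix (populations x populations) with zero diagonal.
#' @export
pairwise_fst_matrix <- function(hg, popmap, tree = NULL, level = NULL,
                                corrected = FALSE) {
  freq <- haplogroup_frequencies(hg, popmap, tree, level)
  m <- freq_matrix(freq)
  sizes <- attr(freq, "n")[rownames(m)]
  if (nrow(m) < 2) pl_abort("need at least 2 populations", "patriline_argument_error")
  pops <- rownames(m)
  D <- matrix(0, nrow(m), nrow(m), dimnames = list(pops, pops))
  corr <- function(h, n) if (corrected) h * n / (n - 1) else h
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq((i + 1), nrow(m))) {
      p1 <- m[i, ]; p2 <- m[j, ]
      hs <- mean(c(corr(1 - sum(p1^2), sizes[i]), corr(1 - sum(p2^2), sizes[j])))
      pt <- (p1 + p2) / 2
      ht <- 1 - sum(pt^2)
      D[i, j] <- D[j, i] <- if (ht <= 0) 0 else max(0, (ht - hs) / ht)
    }
  }
  D
}

#' Classical (Torgerson) multidimensional scaling embedding
#'
#' Double-centres `-D^2/2` and eigen-decomposes it; coordinates on the
#' top-`k` axes reproduce Euclidean input distances exactly (to numerical
#' precision). Deterministic; no seed involved.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param k Number of axes.
#' @return A `pl_embedding` (see [pca_embedding()]) with `method = "mds"`.
#' @export
mds_embedding <- function(D, k = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    pl_abort("distance matrix must be symmetric", "patriline_validation_error")
  }
  if (any(abs(diag(D)) > 1e-12)) {
    pl_abort("distance matrix must have a zero diagonal",
             "patriline_validation_error")
  }
  n <- nrow(D)
  k <- min(k, n - 1)
  # cmdscale warns when fewer than k eigenvalues are positive; the missing
  # axes are filled with zero coordinates below
  fit <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {  # degenerate (e.g. all-zero) input
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  units <- rownames(D) %||% paste0("unit", seq_len(n))
  out <- as_tibble(pts, .name_repair = ~ paste0("axis", seq_len(k)))
  out <- dplyr::bind_cols(tibble(unit = units), out)
  structure(out, class = c("pl_embedding", class(out)),
            eigenvalues = sort(fit$eig, decreasing = TRUE), method = "mds")
}

#' @export
print.pl_embedding <- function(x, ...) {
  cat("<pl_embedding:", attr(x, "method"), "> ", nrow(x), " units, ",
      ncol(x) - 1, " axes\n", sep = "")
  NextMethod()
}
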