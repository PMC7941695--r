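# ---- median-joining network over Y-STR haplotypes ---------------------------

# L1 (stepwise-mutation-consistent) distance between integer repeat vectors
l1_dist_matrix <- function(V) {
  n <- nrow(V)
  D <- matrix(0, n, n)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    D[i, j] <- D[j, i] <- sum(abs(V[i, ] - V[j, ]))
  }
  D
}

# minimax connection level between all node pairs (max edge weight on the
# MST path), used for the epsilon-relaxed minimum spanning network
minimax_levels <- function(D) {
  n <- nrow(D)
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  lev <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    paths <- igraph::shortest_paths(mst, from = i, to = seq((i + 1), n),
                                    output = "epath",
                                    weights = igraph::E(mst)$weight)$epath
    for (jj in seq_along(paths)) {
      w <- igraph::E(mst)$weight[as.integer(paths[[jj]])]
      lev[i, i + jj] <- lev[i + jj, i] <- max(w)
    }
  }
  lev
}

# epsilon-relaxed minimum spanning network: edge (u,v) present iff its
# weight does not exceed the minimax connection level + epsilon
msn_edges <- function(D, epsilon) {
  lev <- minimax_levels(D)
  n <- nrow(D)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (D[i, j] <= lev[i, j] + epsilon) out <- rbind(out, c(i, j))
  }
  out
}

mst_length <- function(D) {
  g <- igraph::graph_from_adjacency_matrix(unname(D), mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

vec_key <- function(v) paste(v, collapse = ",")

#' Median-joining network of Y-STR haplotypes
#'
#' Builds a haplotype network by the median-joining scheme adapted to
#' integer repeat vectors under the L1 (sum of absolute repeat
#' differences) distance: iteratively, the epsilon-relaxed minimum
#' spanning network over the current node set is computed; locus-wise
#' medians of connected triplets are proposed as intermediate (median)
#' nodes and greedily accepted while they shorten the spanning length;
#' median nodes that end up on a geodesic (degree <= 2) are pruned.
#' Processing orders are lexicographic throughout, so the result is
#' deterministic.
#'
#' @param haps Haplotype table (tibble, `sample` + locus columns); rows
#'   with no-calls are dropped with a warning.
#' @param popmap Optional tibble `sample`, `population` for node population
#'   composition.
#' @param epsilon Weight tolerance of the spanning network (default 0).
#' @param max_medians Cap on added median vectors (default 100).
#' @return Object of class `mj_network`: list with `graph` (igraph),
#'   `nodes` (tibble `id`, `type`, `multiplicity`, `haplotype` list column,
#'   population counts list column), `edges` (tibble `from`, `to`,
#'   `weight`), `epsilon`, `loci`.
#' @export
mj_network <- function(haps, popmap = NULL, epsilon = 0, max_medians = 100) {
  m <- complete_haps(haps)
  loci <- colnames(m)
  key <- apply(m, 1, vec_key)
  uniq <- sort(unique(key))
  V <- do.call(rbind, lapply(strsplit(uniq, ","), as.integer))
  observed <- rep(TRUE, nrow(V))
  mult <- as.integer(table(key)[uniq])
  samples_of <- split(rownames(m), key)[uniq]

  if (nrow(V) >= 3) {
    for (round in seq_len(max_medians)) {
      D <- l1_dist_matrix(V)
      ed <- msn_edges(D, epsilon)
      adj <- matrix(FALSE, nrow(V), nrow(V))
      adj[ed] <- TRUE; adj[ed[, c(2, 1), drop = FALSE]] <- TRUE
      base_len <- mst_length(D)
      have <- new.env(); for (k in apply(V, 1, vec_key)) assign(k, TRUE, have)
      # candidate medians from triplets with at least two connecting edges
      cands <- list()
      n <- nrow(V)
      for (i in seq_len(n - 2)) for (j in seq((i + 1), n - 1)) for (k in seq((j + 1), n)) {
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2) next
        med <- apply(V[c(i, j, k), , drop = FALSE], 2, stats::median)
        mk <- vec_key(med)
        if (!exists(mk, envir = have)) cands[[mk]] <- as.integer(med)
      }
      if (!length(cands)) break
      cands <- cands[order(names(cands))]
      best_gain <- 0; best <- NULL
      for (mk in names(cands)) {
        med <- cands[[mk]]
        dm <- colSums(abs(t(V) - med))
        D2 <- rbind(cbind(D, dm), c(dm, 0))
        gain <- base_len - mst_length(D2)
        if (gain > best_gain + 1e-9) { best_gain <- gain; best <- med }
      }
      if (is.null(best)) break
      V <- rbind(V, best)
      observed <- c(observed, FALSE)
      mult <- c(mult, 0L)
      samples_of <- c(samples_of, list(character(0)))
    }
    # prune median nodes lying on geodesics (degree <= 2 in the final MSN)
    repeat {
      D <- l1_dist_matrix(V)
      ed <- msn_edges(D, epsilon)
      deg <- tabulate(c(ed), nbins = nrow(V))
      drop <- which(!observed & deg <= 2)
      if (!length(drop)) break
      V <- V[-drop, , drop = FALSE]
      observed <- observed[-drop]
      mult <- mult[-drop]
      samples_of <- samples_of[-drop]
    }
  }
  D <- l1_dist_matrix(V)
  ed <- if (nrow(V) >= 2) msn_edges(D, epsilon) else NULL
  ids <- character(nrow(V))
  ids[observed] <- paste0("H", seq_len(sum(observed)))
  if (any(!observed)) ids[!observed] <- paste0("mv", seq_len(sum(!observed)))
  pop_of <- lapply(samples_of, function(ss) {
    if (is.null(popmap) || !length(ss)) return(integer(0))
    table(popmap$population[match(ss, popmap$sample)])
  })
  nodes <- tibble(id = ids, type = ifelse(observed, "observed", "median"),
                  multiplicity = mult,
                  haplotype = lapply(seq_len(nrow(V)), function(i) V[i, ]),
                  samples = samples_of, populations = pop_of)
  edges <- if (is.null(ed)) tibble(from = character(), to = character(),
                                   weight = numeric())
  else tibble(from = ids[ed[, 1]], to = ids[ed[, 2]],
              weight = D[ed]) |> arrange(.data$from, .data$to)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes[, c("id", "type",
                                                          "multiplicity")])
  structure(list(graph = g, nodes = nodes, edges = edges,
                 epsilon = epsilon, loci = loci),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat("<mj_network> ", sum(x$nodes$type == "observed"), " observed + ",
      sum(x$nodes$type == "median"), " median nodes, ", nrow(x$edges),
      " edges, total weight ", sum(x$edges$weight),
      ", epsilon ", x$epsilon, "\n", sep = "")
  invisible(x)
}

#' Export a haplotype network as an fdi project file
#'
#' Writes the network in the text dialect consumed by the Network (Fluxus)
#' software: a taxon block per node (name, deterministic circular layout
#' coordinates, frequency/multiplicity, median flag) and a link block per
#' edge with its mutational-step weight. Byte-stable for identical input.
#'
#' @param net An `mj_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fdi <- function(net, path) {
  n <- nrow(net$nodes)
  angle <- 2 * pi * (seq_len(n) - 1) / n
  x <- round(500 + 400 * cos(angle))
  y <- round(500 + 400 * sin(angle))
  lines <- c(
    "DATA_VERSION;1;",
    paste0("NUMBER_OF_TAXA;", n, ";"),
    vapply(seq_len(n), function(i) {
      paste0("TAXON_NAME;", net$nodes$id[i],
             ";TAXON_X;", x[i], ";TAXON_Y;", y[i],
             ";TAXON_FREQUENCY;", net$nodes$multiplicity[i],
             ";TAXON_IS_MEDIAN;",
             if (net$nodes$type[i] == "median") "T" else "F", ";")
    }, character(1)),
    paste0("NUMBER_OF_LINKS;", nrow(net$edges), ";"),
    vapply(seq_len(nrow(net$edges)), function(i) {
      paste0("LINK_TAXON1;", net$edges$from[i],
             ";LINK_TAXON2;", net$edges$to[i],
             ";LINK_WEIGHT;", net$edges$weight[i], ";")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Parse an fdi file written by [write_fdi()]
#'
#' @param path fdi path.
#' @return List with `nodes` (tibble `id`, `multiplicity`, `is_median`)
#'   and `edges` (tibble `from`, `to`, `weight`).
#' @export
read_fdi <- function(path) {
  lines <- readLines(path)
  tax <- lines[startsWith(lines, "TAXON_NAME;")]
  lnk <- lines[startsWith(lines, "LINK_TAXON1;")]
  field <- function(l, key) {
    parts <- strsplit(l, ";", fixed = TRUE)[[1]]
    parts[which(parts == key) + 1]
  }
  nodes <- bind_rows(lapply(tax, function(l) {
    tibble(id = field(l, "TAXON_NAME"),
           multiplicity = as.integer(field(l, "TAXON_FREQUENCY")),
           is_median = field(l, "TAXON_IS_MEDIAN") == "T")
  }))
  edges <- bind_rows(lapply(lnk, function(l) {
    tibble(from = field(l, "LINK_TAXON1"), to = field(l, "LINK_TAXON2"),
           weight = as.numeric(field(l, "LINK_WEIGHT")))
  }))
  list(nodes = nodes, edges = edges %||% tibble(from = character(),
                                                to = character(),
                                                weight = numeric()))
}

# ---- TMRCA estimators -------------------------------------------------------

#' TMRCA by the rho statistic
#'
#' Rho is the multiplicity-weighted mean number of mutational steps
#' separating each observed haplotype from a designated root (ancestral)
#' haplotype; dividing by the mutation rate gives the age in generations.
#' Steps are measured as shortest-path weights in a haplotype network, or
#' directly as L1 repeat distances when a haplotype table plus ancestral
#' haplotype are supplied.
#'
#' The standard error convention, reported alongside, is
#' `SE(T) = sqrt(rho * sum(w^2)) / mu` with `w` the normalized haplotype
#' weights.
#'
#' @param x An `mj_network`, or a haplotype table (tibble with `sample`
#'   column).
#' @param root Node id of the root haplotype (network input) or a named
#'   integer vector / one-row table giving the ancestral haplotype.
#' @param mu Mutation rate per haplotype per generation.
#' @param generation_time Years per generation (default 30).
#' @return Object of class `pl_tmrca` with fields `estimator = "rho"`,
#'   `rho`, `t_generations`, `t_years`, `se_generations`, `se_years`,
#'   `mu`, `generation_time`, `n`.
#' @export
rho_tmrca <- function(x, root, mu, generation_time = 30) {
  if (inherits(x, "mj_network")) {
    ids <- x$nodes$id
    if (!root %in% ids) pl_abort("root node not found in network",
                                 "patriline_argument_error")
    d_all <- igraph::distances(x$graph, v = root,
                               weights = igraph::E(x$graph)$weight)[1, ]
    obs <- x$nodes$type == "observed"
    d <- d_all[ids[obs]]
    if (any(!is.finite(d))) pl_abort("root is disconnected from some haplotypes",
                                     "patriline_argument_error")
    wts <- x$nodes$multiplicity[obs]
  } else {
    m <- complete_haps(x)
    anc <- root_vector(root, colnames(m))
    d <- apply(m, 1, function(v) sum(abs(v - anc)))
    wts <- rep(1L, length(d))
  }
  w <- wts / sum(wts)
  rho <- sum(w * d)
  se_t <- sqrt(rho * sum(w^2)) / mu
  structure(list(estimator = "rho", rho = rho,
                 t_generations = rho / mu,
                 t_years = rho / mu * generation_time,
                 se_generations = se_t, se_years = se_t * generation_time,
                 mu = mu, generation_time = generation_time,
                 n = sum(wts)),
            class = "pl_tmrca")
}

root_vector <- function(root, loci) {
  if (is.data.frame(root)) {
    root <- unlist(root[, setdiff(names(root), "sample"), drop = FALSE])
  }
  if (is.null(names(root))) {
    stopifnot(length(root) == length(loci))
    names(root) <- loci
  }
  if (!all(loci %in% names(root))) {
    pl_abort("ancestral haplotype does not cover all loci",
             "patriline_argument_error")
  }
  root[loci]
}

#' TMRCA by the average squared difference (ASD)
#'
#' `ASD = mean over samples and loci of (repeat - ancestral repeat)^2`;
#' under symmetric single-step mutation at rate `mu` per locus per
#' generation its expectation is `mu * T`, so `T = ASD / mu` generations.
#'
#' @param haps Haplotype table.
#' @param ancestor Named integer vector (or one-row table) of ancestral
#'   repeat numbers; if `NULL`, the locus-wise modal haplotype is used
#'   with a warning.
#' @param mu Mutation rate per locus per generation.
#' @param generation_time Years per generation (default 30).
#' @return A `pl_tmrca` with fields `estimator = "asd"`, `asd`,
#'   `t_generations`, `t_years`, `mu`, `generation_time`, `n`.
#' @export
asd_tmrca <- function(haps, ancestor = NULL, mu, generation_time = 30) {
  m <- complete_haps(haps)
  if (is.null(ancestor)) {
    warn("no ancestral haplotype supplied: using the locus-wise modal haplotype")
    ancestor <- apply(m, 2, function(v) {
      tb <- sort(table(v), decreasing = TRUE)
      as.integer(names(tb)[1])
    })
  }
  anc <- root_vector(ancestor, colnames(m))
  asd <- mean((t(m) - as.numeric(anc))^2)
  structure(list(estimator = "asd", asd = asd,
                 t_generations = asd / mu,
                 t_years = asd / mu * generation_time,
                 mu = mu, generation_time = generation_time, n = nrow(m)),
            class = "pl_tmrca")
}

#' @export
print.pl_tmrca <- function(x, ...) {
  cat("TMRCA (", x$estimator, "): ",
      format(x$t_generations, digits = 5), " generations = ",
      format(x$t_years, digits = 5), " years (mu = ", x$mu,
      ", generation time = ", x$generation_time, ", n = ", x$n, ")\n",
      sep = "")
  if (!is.null(x$se_generations)) {
    cat("SE: ", format(x$se_generations, digits = 4), " generations ",
        "(convention SE = sqrt(rho * sum(w^2)) / mu)\n", sep = "")
  }
  invisible(x)
}
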