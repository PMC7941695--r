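# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (parent-pointer walks instead of
# haplogroup_path(), direct enumeration instead of the algorithms under test).

# exhaustive best lineage track: for every tree node passing the candidate
# rule, walk parent pointers to compute sum(R)/depth; apply the tie rules
# (max t, max depth, most key-derived on path, lexicographic terminal)
oracle_best_track <- function(scores, parent, root, cutoff, key_only = TRUE) {
  rate <- setNames(scores$rate, scores$haplogroup)
  keyd <- setNames(scores$key_derived, scores$haplogroup)
  nodes <- names(parent)
  pass <- function(h) isTRUE(unname(rate[h]) >= cutoff)
  is_key <- function(h) isTRUE(unname(keyd[h]))
  cands <- Filter(function(h) {
    pass(h) && (!key_only || is_key(h))
  }, nodes)
  if (!length(cands)) return(NULL)
  best <- NULL
  for (h in cands) {
    path <- h
    while (parent[[path[1]]] != root) path <- c(parent[[path[1]]], path)
    r <- length(path)
    t <- sum(vapply(path, pass, logical(1))) / r
    nk <- sum(vapply(path, is_key, logical(1)))
    cand <- list(terminal = h, t = t, r = r, nk = nk)
    if (is.null(best) ||
        t > best$t + 1e-12 ||
        (abs(t - best$t) < 1e-12 && (r > best$r ||
          (r == best$r && (nk > best$nk ||
            (nk == best$nk && h < best$terminal)))))) {
      best <- cand
    }
  }
  best
}

# maximal consecutive copies of a single motif at the start of a window
oracle_run_count <- function(window, motif) {
  w <- nchar(motif)
  q <- 0L
  pos <- 1L
  while (pos + w - 1L <= nchar(window) &&
         substr(window, pos, pos + w - 1L) == motif) {
    q <- q + 1L
    pos <- pos + w
  }
  q
}

# exhaustive small-parsimony score: minimum over all assignments of bases to
# internal nodes, summed over sites (feasible for <= 5 leaves)
oracle_parsimony <- function(phy, seqs) {
  bases <- c("A", "C", "G", "T")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  L <- nchar(seqs[[1]])
  mats <- do.call(rbind, strsplit(seqs[phy$tip.label], ""))
  total <- 0L
  grid <- as.matrix(expand.grid(rep(list(bases), nnode),
                                stringsAsFactors = FALSE))
  for (site in seq_len(L)) {
    tip_state <- mats[, site]
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      state <- c(tip_state, grid[g, ])
      cost <- sum(state[phy$edge[, 1]] != state[phy$edge[, 2]])
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# one-level AMOVA sums of squares via explicit one-hot embedding: the
# mismatch count between haplotypes equals the squared Euclidean distance of
# the per-locus one-hot coordinates scaled by 1/sqrt(2)
oracle_amova_ss <- function(m, labels) {
  enc <- NULL
  for (j in seq_len(ncol(m))) {
    lev <- sort(unique(m[, j]))
    oh <- outer(m[, j], lev, `==`) * 1 / sqrt(2)
    enc <- cbind(enc, oh)
  }
  ssd <- function(rows) {
    if (length(rows) < 2) return(0)
    sub <- enc[rows, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2, ctr)^2)
  }
  ss_total <- ssd(seq_len(nrow(m)))
  ss_within <- sum(vapply(split(seq_len(nrow(m)), labels), ssd, numeric(1)))
  list(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# expected |net displacement| of a +-1 random walk with Poisson(theta) steps
# (series truncated far into the tail); the observable-step rate per locus
# per generation is this divided by the depth
expected_abs_displacement <- function(theta, kmax = 80) {
  ks <- 0:kmax
  e_abs_k <- vapply(ks, function(k) {
    if (k == 0) return(0)
    j <- 0:k
    sum(abs(2 * j - k) * stats::dbinom(j, k, 0.5))
  }, numeric(1))
  sum(stats::dpois(ks, theta) * e_abs_k)
}

# minimum Steiner-augmented MST length over the bounded integer lattice for
# <= 3-locus haplotype sets, allowing up to `max_extra` added lattice points
oracle_steiner_mst <- function(V, max_extra = 1) {
  l1 <- function(a, b) sum(abs(a - b))
  mstlen <- function(pts) {
    n <- nrow(pts)
    if (n < 2) return(0)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      D[i, j] <- D[j, i] <- l1(pts[i, ], pts[j, ])
    }
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
  }
  lattice <- as.matrix(expand.grid(lapply(seq_len(ncol(V)), function(j)
    seq(min(V[, j]), max(V[, j])))))
  best <- mstlen(V)
  if (max_extra >= 1) {
    for (i in seq_len(nrow(lattice))) {
      best <- min(best, mstlen(rbind(V, lattice[i, , drop = FALSE])))
    }
  }
  if (max_extra >= 2 && nrow(lattice) <= 40) {
    for (i in seq_len(nrow(lattice) - 1)) for (j in seq((i + 1), nrow(lattice))) {
      best <- min(best, mstlen(rbind(V, lattice[i, , drop = FALSE],
                                     lattice[j, , drop = FALSE])))
    }
  }
  best
}

# random toy tree as a bare parent map (structure independent of
# make_toy_panel_tree) for classifier oracle tests
random_parent_map <- function(n_nodes, seed) {
  withr::with_seed(seed, {
    nodes <- paste0("N", sprintf("%03d", seq_len(n_nodes)))
    parent <- character(n_nodes)
    names(parent) <- nodes
    parent[1] <- "ROOT"
    for (i in seq_len(n_nodes)[-1]) {
      parent[i] <- nodes[sample.int(i - 1, 1)]
    }
    parent
  })
}
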