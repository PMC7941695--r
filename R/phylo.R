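# ---- internal nested-list tree representation -------------------------------
# leaf: list(label = <sample>); internal: list(label = <haplogroup|"">,
# children = list(...)). Used for polytomy surgery, then serialized back to
# newick / ape phylo.

nl_leaf <- function(label) list(label = label)
nl_node <- function(children, label = "") list(label = label, children = children)
nl_is_leaf <- function(x) is.null(x$children)

nl_to_newick <- function(x) {
  if (nl_is_leaf(x)) return(x$label)
  paste0("(", paste(vapply(x$children, nl_to_newick, character(1)),
                    collapse = ","), ")", x$label)
}

nl_leaves <- function(x) {
  if (nl_is_leaf(x)) return(x$label)
  unlist(lapply(x$children, nl_leaves))
}

# representative leaf of a subtree: alphabetically first, for deterministic
# distance lookups and orderings
nl_rep <- function(x) min(nl_leaves(x))

phylo_to_nl <- function(phy) {
  n_tip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  lab <- function(v) {
    if (v <= n_tip) return(nl_leaf(phy$tip.label[v]))
    nlab <- if (!is.null(phy$node.label)) phy$node.label[v - n_tip] else ""
    nl_node(lapply(kids[[as.character(v)]], lab), label = nlab %||% "")
  }
  lab(n_tip + 1L)
}

nl_to_phylo <- function(x) {
  ape::read.tree(text = paste0(nl_to_newick(x), ";"))
}

# ---- preliminary tree -------------------------------------------------------

#' Preliminary phylogeny from haplogroup assignments
#'
#' First step of the two-step tree construction: each sample is attached as
#' a leaf under its haplogroup's node in the haplogroup tree, then internal
#' nodes with no sample descendants are pruned and unary chains collapsed.
#' Nodes with several samples (or several retained clades) remain
#' polytomies, to be resolved with sequence data by
#' [resolve_polytomies()].
#'
#' @param hg Haplogroup assignment tibble (columns `sample`, `haplogroup`).
#' @param tree A [haplo_tree].
#' @return A rooted `phylo` object; internal node labels are haplogroup
#'   names (where not collapsed away).
#' @export
preliminary_tree <- function(hg, tree) {
  known <- hg$haplogroup %in% c(tree_nodes(tree))
  if (any(!known)) {
    warn(paste0("dropping ", sum(!known), " sample(s) with haplogroups ",
                "absent from the tree: ",
                paste(unique(hg$haplogroup[!known]), collapse = ", ")))
    hg <- hg[known, , drop = FALSE]
  }
  if (nrow(hg) < 2) pl_abort("need at least 2 placeable samples",
                             "patriline_argument_error")
  samples_at <- split(hg$sample, hg$haplogroup)
  build <- function(h) {
    kid_nodes <- lapply(sort(tree_children(tree, h)), build)
    kid_nodes <- kid_nodes[!vapply(kid_nodes, is.null, logical(1))]
    leaves <- lapply(sort(samples_at[[h]] %||% character(0)), nl_leaf)
    items <- c(kid_nodes, leaves)
    if (!length(items)) return(NULL)
    if (length(items) == 1) return(items[[1]])   # collapse unary chain
    nl_node(items, label = if (h == tree$root) "" else h)
  }
  root <- build(tree$root)
  if (is.null(root) || nl_is_leaf(root)) {
    pl_abort("fewer than 2 samples could be placed", "patriline_argument_error")
  }
  nl_to_phylo(root)
}

# ---- polytomy resolution ----------------------------------------------------

# internal Fitch score of a nested tree over representative sequences
nl_fitch <- function(x, seqs) {
  L <- nchar(seqs[[1]])
  splitseqs <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  # Fitch pass: at each node fold the child state sets; every empty
  # intersection costs one substitution
  score <- 0L
  fitch2 <- function(node, site) {
    if (nl_is_leaf(node)) {
      b <- splitseqs[[node$label]][site]
      return(if (b %in% c("A", "C", "G", "T")) b else c("A", "C", "G", "T"))
    }
    sets <- lapply(node$children, fitch2, site = site)
    s <- Reduce(function(a, b) {
      i <- intersect(a, b)
      if (length(i)) i else { score <<- score + 1L; union(a, b) }
    }, sets)
    s
  }
  for (site in seq_len(L)) fitch2(x, site)
  score
}

nl_join <- function(a, b) nl_node(list(a, b))

# caterpillar over items sorted by representative label
nl_caterpillar <- function(items) {
  items <- items[order(vapply(items, nl_rep, character(1)))]
  Reduce(nl_join, items)
}

# binary subtree from hclust merge matrix
hclust_to_nl <- function(hc, items_by_rep) {
  build <- function(i) {
    if (i < 0) items_by_rep[[hc$labels[-i]]]
    else nl_join(build(hc$merge[i, 1]), build(hc$merge[i, 2]))
  }
  build(nrow(hc$merge))
}

resolve_group <- function(items, aln, method, cap_exhaustive = 7) {
  k <- length(items)
  if (k <= 2) return(if (k == 2) nl_join(items[[1]], items[[2]]) else items[[1]])
  reps <- vapply(items, nl_rep, character(1))
  items_by_rep <- setNames(items, reps)
  if (is.null(aln)) return(nl_caterpillar(items))
  seqs <- unclass(aln)[reps]
  D <- ibs_distance(aln, reps)
  if (all(D[upper.tri(D)] == 0)) return(nl_caterpillar(items))  # tie case
  if (method == "upgma" || (method == "ibs" && k == 3)) {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    return(hclust_to_nl(hc, items_by_rep))
  }
  if (method == "ibs") {
    nj <- ape::nj(stats::as.dist(D))
    nj$edge.length[nj$edge.length < 0] <- 0
    # deterministic rooting on the alphabetically first member's edge
    rooted <- ape::root(nj, outgroup = sort(reps)[1], resolve.root = TRUE)
    rooted$edge.length <- NULL
    rooted$node.label <- NULL
    nl <- phylo_to_nl(rooted)
    return(nl_substitute(nl, items_by_rep))
  }
  # maximum parsimony
  if (k <= cap_exhaustive) {
    cands <- phangorn::allTrees(k, rooted = TRUE, tip.label = sort(reps))
    mseq <- do.call(rbind, strsplit(seqs, ""))
    rownames(mseq) <- names(seqs)
    pd <- phangorn::phyDat(mseq, type = "DNA")
    scores <- phangorn::parsimony(cands, pd, method = "fitch")
    # allTrees enumerates deterministically for sorted tip labels, so the
    # first minimum is a stable tie-break
    best <- cands[[which.min(scores)]]
    return(nl_substitute(phylo_to_nl(best), items_by_rep))
  }
  # stepwise addition by representative order
  reps_sorted <- sort(reps)
  cur <- nl_join(nl_leaf(reps_sorted[1]), nl_leaf(reps_sorted[2]))
  for (r in reps_sorted[-(1:2)]) {
    placements <- nl_placements(cur, nl_leaf(r))
    sc <- vapply(placements, nl_fitch, integer(1), seqs = seqs)
    keys <- vapply(placements, function(p) nl_to_newick(p), character(1))
    cur <- placements[[order(sc, keys)[1]]]
  }
  nl_substitute(cur, items_by_rep)
}

# all rooted trees obtained by attaching `leaf` as sister to any subtree
nl_placements <- function(x, leaf) {
  out <- list(nl_join(x, leaf))
  if (!nl_is_leaf(x)) {
    for (i in seq_along(x$children)) {
      subs <- nl_placements(x$children[[i]], leaf)
      for (s in subs[-1]) {
        y <- x; y$children[[i]] <- s; out <- c(out, list(y))
      }
      y <- x; y$children[[i]] <- nl_join(x$children[[i]], leaf)
      out <- c(out, list(y))
    }
  }
  out
}

# replace representative leaves by their original subtrees
nl_substitute <- function(x, items_by_rep) {
  if (nl_is_leaf(x)) return(items_by_rep[[x$label]])
  x$children <- lapply(x$children, nl_substitute, items_by_rep = items_by_rep)
  x
}

#' Resolve polytomies of a preliminary tree into a bifurcating tree
#'
#' Second step of the two-step strategy: every node with more than two
#' children is replaced, in post order, by a bifurcating subtree built from
#' its member clades only, keeping the backbone of the preliminary tree
#' unchanged. Each clade is represented in the subtree search by its
#' alphabetically first sample's aligned sequence.
#'
#' Methods: `"upgma"` — average-linkage clustering on the IBS mismatch
#' distance; `"mp"` — maximum parsimony (exhaustive over all rooted
#' topologies for at most 7 clades, stepwise addition above); `"ibs"` —
#' neighbor-joining on IBS distance, rooted deterministically on the edge
#' of the alphabetically first member. Without an alignment
#' polytomies are broken deterministically into a caterpillar ordered by
#' sample name, with a warning.
#'
#' @param ptree A rooted `phylo` from [preliminary_tree()].
#' @param aln Optional `alignment_block` covering all samples.
#' @param method `"upgma"`, `"mp"` or `"ibs"`.
#' @return A strictly bifurcating rooted `phylo` with the same leaf set.
#' @export
resolve_polytomies <- function(ptree, aln = NULL,
                               method = c("upgma", "mp", "ibs")) {
  method <- match.arg(method)
  if (!is.null(aln)) {
    missing <- setdiff(ptree$tip.label, names(aln))
    if (length(missing)) {
      pl_abort(paste0("alignment lacks sample(s): ",
                      paste(utils::head(missing, 5), collapse = ", ")),
               "patriline_validation_error")
    }
  } else {
    warn("no alignment provided: polytomies broken into caterpillars by sample name")
  }
  resolve <- function(x) {
    if (nl_is_leaf(x)) return(x)
    x$children <- lapply(x$children, resolve)           # post order
    if (length(x$children) <= 2) return(x)
    sub <- resolve_group(x$children, aln, method)
    sub$label <- x$label
    sub
  }
  nl_to_phylo(resolve(phylo_to_nl(ptree)))
}

#' Fitch parsimony score of a tree given an alignment
#'
#' Small-parsimony substitution count summed over alignment sites.
#'
#' @param tree A rooted or unrooted `phylo`; its tips must appear in `aln`.
#' @param aln An `alignment_block`.
#' @return Non-negative integer.
#' @export
parsimony_score <- function(tree, aln) {
  seqs <- unclass(aln)[tree$tip.label]
  if (anyNA(names(seqs))) {
    pl_abort("alignment lacks some tree tips", "patriline_validation_error")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- tree$tip.label
  pd <- phangorn::phyDat(mat, type = "DNA")
  as.integer(phangorn::fitch(tree, pd))
}
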