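hg_of <- function(samples, haplogroups) {
  tibble::tibble(sample = samples, haplogroup = haplogroups)
}

rand_aln <- function(samples, L = 40, seed = 1) {
  withr::with_seed(seed, {
    alignment_block(setNames(vapply(samples, function(s)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)), samples))
  })
}

# clades of a phylo as a set of leaf-label strings
clade_set <- function(phy) {
  ntip <- length(phy$tip.label)
  out <- character(0)
  for (v in (ntip + 1):(ntip + phy$Nnode)) {
    tips <- ape::extract.clade(phy, v)$tip.label
    out <- c(out, paste(sort(tips), collapse = "|"))
  }
  out
}

test_that("preliminary tree mirrors sibling structure of the haplogroup tree", {
  tr <- haplo_tree(c(X = "Y-Adam", A = "X", B = "X", C = "Y-Adam"))
  hg <- hg_of(c("sa", "sb", "sc"), c("A", "B", "C"))
  pt <- preliminary_tree(hg, tr)
  expect_setequal(pt$tip.label, c("sa", "sb", "sc"))
  expect_true(paste(sort(c("sa", "sb")), collapse = "|") %in% clade_set(pt))
  # two samples sharing a haplogroup sit together under that node
  hg2 <- hg_of(c("s1", "s2", "sc"), c("A", "A", "C"))
  pt2 <- preliminary_tree(hg2, tr)
  expect_true("s1|s2" %in% clade_set(pt2))
})

test_that("samples with unknown haplogroups are dropped with a warning", {
  tr <- haplo_tree(c(A = "Y-Adam", B = "Y-Adam"))
  hg <- hg_of(c("s1", "s2", "s3"), c("A", "B", "NOPE"))
  expect_warning(pt <- preliminary_tree(hg, tr), "NOPE")
  expect_setequal(pt$tip.label, c("s1", "s2"))
})

test_that("every preliminary clade is a clade of the haplogroup tree", {
  for (seed in c(201, 202, 203)) {
    toy <- make_toy_panel_tree(depth = 4, branching = 2, markers_per_node = 2,
                               random = TRUE, seed = seed)
    tr <- toy$panel$tree
    nodes <- tree_nodes(tr)
    withr::with_seed(seed + 1000, {
      hgs <- sample(nodes, 30, replace = TRUE)
    })
    hg <- hg_of(sprintf("s%02d", 1:30), hgs)
    pt <- preliminary_tree(hg, tr)
    # map each clade to the haplogroup-tree clade spanned by its samples
    for (cl in clade_set(pt)) {
      tips <- strsplit(cl, "|", fixed = TRUE)[[1]]
      cl_hgs <- unique(hg$haplogroup[hg$sample %in% tips])
      # the MRCA (deepest common ancestor) of these haplogroups must contain
      # no observed haplogroup outside the clade's own samples below it...
      paths <- lapply(cl_hgs, function(h) haplogroup_path(tr, h,
                                                          include_root = TRUE))
      common <- Reduce(intersect, paths)
      mrca <- common[length(common)]
      below <- nodes[vapply(nodes, function(n)
        mrca %in% haplogroup_path(tr, n, include_root = TRUE), logical(1))]
      outside <- setdiff(hg$sample[hg$haplogroup %in% below], tips)
      expect_length(outside, 0)
    }
  }
})

test_that("polytomy of identical sequences becomes a caterpillar in id order", {
  tr <- haplo_tree(c(A = "Y-Adam", B = "Y-Adam"))
  hg <- hg_of(c("s3", "s1", "s2", "sb"), c("A", "A", "A", "B"))
  aln <- alignment_block(setNames(rep("ACGTACGT", 4),
                                  c("s1", "s2", "s3", "sb")))
  pt <- preliminary_tree(hg, tr)
  rt <- resolve_polytomies(pt, aln, "upgma")
  expect_true(ape::is.binary(rt))
  expect_true("s1|s2" %in% clade_set(rt))     # caterpillar (s3,(s2,s1))
  expect_true("s1|s2|s3" %in% clade_set(rt))
})

test_that("UPGMA pairs the two clear pairs and matches exhaustive parsimony", {
  tr <- haplo_tree(c(A = "Y-Adam", B = "Y-Adam"))
  hg <- hg_of(c("w", "x", "y", "z", "out"), c("A", "A", "A", "A", "B"))
  seqs <- c(w = strrep("A", 20),
            x = paste0(strrep("A", 19), "C"),
            y = strrep("T", 20),
            z = paste0(strrep("T", 19), "G"),
            out = paste0(strrep("C", 20)))
  aln <- alignment_block(seqs)
  pt <- preliminary_tree(hg, tr)
  rt <- resolve_polytomies(pt, aln, "upgma")
  cs <- clade_set(rt)
  expect_true("w|x" %in% cs)
  expect_true("y|z" %in% cs)
  # the UPGMA resolution attains the minimum parsimony score over all
  # rooted topologies of the four-leaf polytomy
  cands <- phangorn::allTrees(4, rooted = TRUE, tip.label = c("w", "x", "y", "z"))
  best <- min(vapply(cands, function(tt) parsimony_score(tt, aln), integer(1)))
  sub <- ape::extract.clade(rt, ape::getMRCA(rt, c("w", "x", "y", "z")))
  expect_equal(parsimony_score(sub, aln), best)
})

test_that("resolution preserves backbone clades over many random fixtures", {
  n_fix <- 100
  ok <- 0L
  for (i in seq_len(n_fix)) {
    toy <- make_toy_panel_tree(depth = 3, branching = 2, markers_per_node = 1,
                               random = TRUE, seed = 500 + i)
    tr <- toy$panel$tree
    withr::with_seed(600 + i, {
      hgs <- sample(tree_nodes(tr), 12, replace = TRUE)
    })
    hg <- hg_of(sprintf("s%02d", 1:12), hgs)
    pt <- preliminary_tree(hg, tr)
    aln <- rand_aln(hg$sample, L = 30, seed = 700 + i)
    method <- c("upgma", "mp", "ibs")[1 + i %% 3]
    rt <- suppressWarnings(resolve_polytomies(pt, aln, method))
    ok <- ok + (ape::is.binary(rt) &&
                setequal(rt$tip.label, pt$tip.label) &&
                all(clade_set(pt) %in% clade_set(rt)))
  }
  expect_equal(ok, n_fix)
})

test_that("UPGMA recovers the generating topology from ultrametric distances", {
  # ((a,b),(c,d)) with heights 1 and 3: sequences built to realize it
  seqs <- c(a = paste0(strrep("A", 30), strrep("A", 2)),
            b = paste0(strrep("A", 30), strrep("C", 2)),
            c = paste0(strrep("T", 30), strrep("A", 2)),
            d = paste0(strrep("T", 30), strrep("G", 2)))
  aln <- alignment_block(seqs)
  D <- ibs_distance(aln)
  expect_equal(D["a", "b"], D["c", "d"])  # ultrametric by construction
  tr <- haplo_tree(c(A = "Y-Adam", B = "Y-Adam"))
  hg <- hg_of(c("a", "b", "c", "d", "e"), c("A", "A", "A", "A", "B"))
  aln2 <- alignment_block(c(seqs, e = strrep("G", 32)))
  pt <- preliminary_tree(hg, tr)
  rt <- resolve_polytomies(pt, aln2, "upgma")
  cs <- clade_set(rt)
  expect_true("a|b" %in% cs)
  expect_true("c|d" %in% cs)
})

test_that("without an alignment polytomies break deterministically with a warning", {
  tr <- haplo_tree(c(A = "Y-Adam", B = "Y-Adam"))
  hg <- hg_of(c("s2", "s1", "s3", "sb"), c("A", "A", "A", "B"))
  pt <- preliminary_tree(hg, tr)
  expect_warning(rt1 <- resolve_polytomies(pt), "caterpillar")
  rt2 <- suppressWarnings(resolve_polytomies(pt))
  expect_true(ape::is.binary(rt1))
  expect_identical(ape::write.tree(rt1), ape::write.tree(rt2))
})

test_that("alignment/leaf mismatch is a validation error", {
  tr <- haplo_tree(c(A = "Y-Adam", B = "Y-Adam"))
  hg <- hg_of(c("s1", "s2", "s3"), c("A", "A", "B"))
  pt <- preliminary_tree(hg, tr)
  aln <- alignment_block(c(s1 = "ACGT", s2 = "ACGT"))
  expect_error(resolve_polytomies(pt, aln), class = "patriline_validation_error")
})

test_that("Fitch score matches trivial cases and the exhaustive oracle", {
  t2 <- ape::read.tree(text = "(a,b);")
  aln_same <- alignment_block(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(parsimony_score(t2, aln_same), 0)
  aln_3 <- alignment_block(c(a = "ACGTACGT", b = "TCGAACGA"))
  expect_equal(parsimony_score(t2, aln_3), 3)
  for (seed in c(11, 12, 13, 14)) {
    aln <- rand_aln(letters[1:5], L = 8, seed = seed)
    topo <- withr::with_seed(seed, ape::rtree(5, tip.label = letters[1:5]))
    topo$edge.length <- NULL
    expect_equal(parsimony_score(topo, aln),
                 oracle_parsimony(topo, unclass(aln)))
  }
})

test_that("alignment readers agree across FASTA, PHYLIP and MEGA", {
  seqs <- c(s1 = "ACGTACGTAA", s2 = "ACGTTCGTAA", s3 = "ACTTACGAAA")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  ph <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 3 10", paste(format(names(seqs), width = 12), seqs)), ph)
  mg <- withr::local_tempfile(fileext = ".meg")
  writeLines(c("#mega", "!Title test;",
               rbind(paste0("#", names(seqs)), seqs)), mg)
  a1 <- read_alignment(fa, "fasta")
  a2 <- read_alignment(ph, "phylip")
  a3 <- read_alignment(mg, "mega")
  expect_equal(unclass(a1)[names(seqs)], seqs)
  expect_equal(unclass(a2)[names(seqs)], seqs)
  expect_equal(unclass(a3)[names(seqs)], seqs)
})

test_that("dating input bundle carries calibrations and refuses polytomies", {
  tree <- ape::read.tree(text = "((t1,t2)O,(t3,t4)R);")
  aln <- alignment_block(c(t1 = "ACGT", t2 = "ACGA", t3 = "TCGT",
                           t4 = "TCGA"))
  dir <- withr::local_tempdir()
  paths <- generate_dating_inputs(tree, aln, out_dir = dir)
  ctl <- readLines(paths["control"])
  expect_true(any(grepl(basename(paths["tree"]), ctl, fixed = TRUE)))
  expect_true(any(grepl(basename(paths["alignment"]), ctl, fixed = TRUE)))
  tstr <- readLines(paths["tree"])[2]
  expect_match(tstr, "\\(t1,t2\\)'>25<40'")
  expect_match(tstr, "\\(t3,t4\\)'>20<40'")
  # user calibration overrides the built-in value at the same node
  p2 <- generate_dating_inputs(tree, aln,
                               calibrations = tibble::tibble(
                                 haplogroup = "O", lower = 30, upper = 38),
                               out_dir = dir, prefix = "user")
  expect_match(readLines(p2["tree"])[2], ">30<38")
  poly <- ape::read.tree(text = "((t1,t2,t3)O,t4);")
  expect_error(generate_dating_inputs(poly, aln, out_dir = dir),
               class = "patriline_validation_error")
  unlabeled <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_error(generate_dating_inputs(unlabeled, aln, out_dir = dir),
               class = "patriline_validation_error")
})

test_that("dating output summaries parse fixture text and flag problems", {
  out <- withr::local_tempfile()
  # synthetic mcmctree-style posterior block
  writeLines(c("MCMC run started", "",
               "Posterior time estimates:",
               "t_n6   0.0512 (0.0410, 0.0650)",
               "t_n7   0.0301 (0.0221, 0.0399)",
               "t_n9   0.0100 (0.0080, 0.0120)"), out)
  tree <- ape::read.tree(text = "((t1,t2)O,(t3,t4)R)root;")
  expect_warning(tab <- summarize_dating_output(out, tree), "mapped")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$mean, c(0.0512, 0.0301, 0.0100))
  expect_equal(tab$haplogroup[tab$node == "6"], "O")
  expect_true(is.na(tab$haplogroup[tab$node == "9"]))  # beyond tree nodes
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(summarize_dating_output(empty), class = "patriline_parse_error")
})
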