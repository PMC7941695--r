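# Synthetic-data generators: every input format the analysis modules read
# can be produced here with known truth, under a mandatory seed.

#' Generate a toy haplogroup tree and marker panel
#'
#' Builds a balanced (or randomly pruned) haplogroup tree of the given
#' depth and branching factor, attaches `markers_per_node` synthetic SNP
#' markers to every haplogroup (at least one forced key marker per node;
#' further markers flagged key with probability `key_fraction`), and
#' returns it as a validated `marker_panel` plus the truth structures.
#'
#' A fraction `hidden_ref_fraction` of markers is created with the
#' reference base equal to the *derived* allele, so that simulated variant
#' tables exercise the hidden-reference rule of the classifier.
#'
#' @param depth Tree depth (>= 1).
#' @param branching Children per internal node.
#' @param markers_per_node Markers per haplogroup (>= 1). The default of 12
#'   mirrors the marker density of the full ISOGG-scale classification
#'   panel (on the order of 74,570 markers across roughly 5,800
#'   haplogroups, i.e. over a dozen defining markers per haplogroup).
#' @param key_fraction Probability that a non-forced marker is a key marker.
#' @param hidden_ref_fraction Fraction of markers whose reference base is
#'   the derived allele.
#' @param random Randomly prune the balanced tree to irregular shape?
#' @param seed Mandatory seed.
#' @return List with `panel` (a `marker_panel`) and `terminals` (leaf
#'   haplogroup names).
#' @export
make_toy_panel_tree <- function(depth, branching = 2, markers_per_node = 12,
                                key_fraction = 0.5, hidden_ref_fraction = 0.1,
                                random = FALSE, seed) {
  if (depth < 1) pl_abort("depth must be >= 1", "patriline_argument_error")
  stopifnot(!missing(seed))
  withr::with_seed(seed, {
    parent <- character(0)
    level <- list("Y-Adam")
    for (d in seq_len(depth)) {
      prev <- level[[d]]
      cur <- character(0)
      for (p in prev) {
        nb <- if (random && d > 1) sample(0:branching, 1) else branching
        if (p == "Y-Adam") nb <- max(nb, 2)
        if (nb == 0) next
        kids <- if (p == "Y-Adam") paste0("HG", LETTERS[seq_len(nb)])
        else paste0(p, letters[seq_len(nb)])
        parent[kids] <- p
        cur <- c(cur, kids)
      }
      level[[d + 1]] <- cur
    }
    nodes <- names(parent)
    bases <- c("A", "C", "G", "T")
    rows <- lapply(seq_along(nodes), function(i) {
      h <- nodes[i]
      k <- markers_per_node
      anc <- sample(bases, k, replace = TRUE)
      der <- vapply(anc, function(a) sample(setdiff(bases, a), 1), character(1))
      key <- c(1L, as.integer(stats::runif(k - 1) < key_fraction))
      hidden <- stats::runif(k) < hidden_ref_fraction
      tibble(haplogroup = h, parent = parent[[h]],
             marker = paste0("M", i * 100 + seq_len(k)),
             position = as.integer(i * 1000 + seq_len(k)),
             ancestral = anc, derived = unname(der), key = key,
             ref = ifelse(hidden, unname(der), anc))
    })
    panel <- marker_panel(bind_rows(rows))
    terminals <- setdiff(nodes, unique(parent))
    list(panel = panel, terminals = terminals)
  })
}

#' Simulate a multi-sample haploid chrY variant table with known truth
#'
#' Each sample is assigned a terminal haplogroup and carries the derived
#' allele at every marker on its root path (ancestral elsewhere), then a
#' genotype error process (flip to the opposite allele) and a missingness
#' process are applied. The VCF emitted by [write_sim_vcf()] omits
#' positions at which every sample equals the reference base — including
#' markers whose reference is the derived allele — reproducing the hidden
#' reference situation of real variant tables.
#'
#' @param panel A `marker_panel` (e.g. from [make_toy_panel_tree()]).
#' @param samples_per_terminal Samples simulated per terminal haplogroup.
#' @param terminals Terminal haplogroups to draw (default: all leaves).
#' @param error_rate Per-site probability of flipping the true base.
#' @param missing_rate Per-site probability of a missing call.
#' @param seed Mandatory seed.
#' @return List with `truth` (tibble `sample`, `haplogroup`), `geno`
#'   (base matrix positions x samples, `NA` = missing) and `panel`.
#' @export
simulate_genotype_table <- function(panel, samples_per_terminal = 1,
                                    terminals = NULL, error_rate = 0,
                                    missing_rate = 0, seed) {
  stopifnot(!missing(seed))
  tree <- panel$tree
  terminals <- terminals %||%
    setdiff(tree_nodes(tree), unique(unname(tree$parent)))
  withr::with_seed(seed, {
    truth <- tibble(
      sample = sprintf("S%03d", seq_len(length(terminals) * samples_per_terminal)),
      haplogroup = rep(terminals, each = samples_per_terminal))
    mk <- panel$markers
    geno <- matrix(NA_character_, nrow(mk), nrow(truth),
                   dimnames = list(mk$position, truth$sample))
    on_path <- lapply(truth$haplogroup, function(h)
      mk$haplogroup %in% haplogroup_path(tree, h))
    for (s in seq_len(nrow(truth))) {
      base <- ifelse(on_path[[s]], mk$derived, mk$ancestral)
      flip <- stats::runif(nrow(mk)) < error_rate
      base[flip] <- ifelse(on_path[[s]], mk$ancestral, mk$derived)[flip]
      base[stats::runif(nrow(mk)) < missing_rate] <- NA
      geno[, s] <- base
    }
    list(truth = truth, geno = geno, panel = panel)
  })
}

#' Write a simulated genotype table as a haploid VCF
#'
#' Records where every sample carries the reference base are omitted (the
#' hidden-reference situation); missing calls are written as `.`.
#'
#' @param sim Output of [simulate_genotype_table()].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(sim, path) {
  mk <- sim$panel$markers
  samples <- colnames(sim$geno)
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=Y>",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in order(mk$position)) {
    g <- sim$geno[as.character(mk$position[i]), ]
    ref <- mk$ref[i]
    obs <- g[!is.na(g)]
    if (!length(obs) || all(obs == ref)) next   # hidden: all samples reference
    alt <- sort(setdiff(unique(obs), ref))
    if (!length(alt)) next
    gt <- ifelse(is.na(g), ".", as.character(match(g, c(ref, alt)) - 1L))
    lines <- c(lines,
               paste(c("Y", mk$position[i], mk$marker[i], ref,
                       paste(alt, collapse = ","), ".", "PASS", ".", "GT", gt),
                     collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-read windows over Y-STR loci with known truth
#'
#' For each locus and sample, embeds the true allele's repeat sequence in
#' deterministic flanking context (derived per locus from the seed) and
#' emits `coverage` spanning windows starting at the locus start, plus
#' optionally some short non-spanning windows.
#'
#' @param panel An `str_panel`.
#' @param true_repeats Tibble `sample`, `locus`, `repeat_n` (total repeat
#'   number; for compound loci the deviation from the reference total is
#'   applied to the last motif block).
#' @param coverage Spanning windows per sample x locus.
#' @param context Length of trailing flanking context in bases.
#' @param truncated_fraction Fraction of additional windows emitted too
#'   short to span the locus.
#' @param seed Mandatory seed.
#' @return Tibble `sample`, `locus`, `window`.
#' @export
simulate_str_reads <- function(panel, true_repeats, coverage = 8,
                               context = 40, truncated_fraction = 0,
                               seed) {
  stopifnot(!missing(seed))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(true_repeats)), function(i) {
      loc <- panel[panel$name == true_repeats$locus[i], ]
      stopifnot(nrow(loc) == 1)
      motifs <- loc$motifs[[1]]
      delta <- true_repeats$repeat_n[i] - loc$p
      motifs$p[nrow(motifs)] <- motifs$p[nrow(motifs)] + delta
      stopifnot(motifs$p[nrow(motifs)] >= 0)
      allele <- str_reference_sequence(motifs)
      # flank must not begin with the extension motif
      last <- motifs$motif[nrow(motifs)]
      repeat {
        flank <- paste(sample(c("A", "C", "G", "T"), context, replace = TRUE),
                       collapse = "")
        if (substr(flank, 1, nchar(last)) != last) break
      }
      full <- paste0(allele, flank)
      wins <- rep(full, coverage)
      n_tr <- round(coverage * truncated_fraction)
      if (n_tr > 0) {
        wins <- c(wins, rep(substr(full, 1, max(1, nchar(allele) %/% 2)), n_tr))
      }
      tibble(sample = true_repeats$sample[i], locus = loc$name, window = wins)
    })
    bind_rows(rows)
  })
}

#' Simulate Y-STR haplotypes on a star genealogy
#'
#' Each of `n` lineages descends independently from the ancestral
#' haplotype for `depth` generations; per locus, the number of mutations
#' is Poisson(`mu * depth`) and each mutation moves the repeat number by
#' +1 or -1 with equal probability (symmetric single-step model).
#'
#' @param n Number of lineages (samples).
#' @param loci Locus names (default the 17-locus Yfiler set).
#' @param mu Mutation rate per locus per generation.
#' @param depth Genealogy depth in generations.
#' @param ancestral Ancestral repeat number(s): scalar or per-locus vector.
#' @param seed Mandatory seed.
#' @return List with `haps` (haplotype table) and `ancestor` (named
#'   integer vector).
#' @export
simulate_star_strs <- function(n, loci = str_panel_registry()[["yfiler"]],
                               mu, depth, ancestral = 14, seed) {
  stopifnot(!missing(seed))
  withr::with_seed(seed, {
    L <- length(loci)
    anc <- setNames(as.integer(rep_len(ancestral, L)), loci)
    m <- matrix(rep(anc, each = n), n, L, dimnames = list(NULL, loci))
    k <- matrix(stats::rpois(n * L, mu * depth), n, L)
    steps <- matrix(0L, n, L)
    nz <- which(k > 0)
    steps[nz] <- vapply(k[nz], function(kk)
      sum(sample(c(-1L, 1L), kk, replace = TRUE)), integer(1))
    m <- m + steps
    haps <- as_tibble(m)
    haps <- dplyr::bind_cols(tibble(sample = sprintf("L%04d", seq_len(n))), haps)
    list(haps = structure(haps, class = c("haplotype_table", class(haps))),
         ancestor = anc)
  })
}

#' Write a minimal single-sample chrY SAM for testing alignment readers
#'
#' Emits ungapped reads as a plain-text SAM (convertible to BAM with
#' `Rsamtools::asBam`); used by the test suite to exercise the pileup and
#' STR window extractors without binary fixtures.
#'
#' @param reads Tibble `pos`, `seq` (1-based leftmost position, read
#'   sequence), optional `mapq` (default 60).
#' @param path Output SAM path.
#' @param chrom Reference name (default "Y").
#' @param ref_len Reference length for the header.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(reads, path, chrom = "Y", ref_len = 60000000) {
  mapq <- if ("mapq" %in% names(reads)) reads$mapq else rep(60L, nrow(reads))
  lines <- c(paste0("@HD\tVN:1.6\tSO:coordinate"),
             paste0("@SQ\tSN:", chrom, "\tLN:", ref_len))
  ord <- order(reads$pos)
  for (i in ord) {
    sq <- reads$seq[i]
    lines <- c(lines, paste(
      c(sprintf("r%05d", i), 0, chrom, reads$pos[i], mapq[i],
        paste0(nchar(sq), "M"), "*", 0, 0, sq,
        strrep("I", nchar(sq))), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
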