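make_small_panel <- function() {
  # chain Y-Adam -> A -> B -> C plus sibling D under A; 2 markers each
  rows <- list()
  hgs <- c(A = "Y-Adam", B = "A", C = "B", D = "A")
  pos <- 0L
  for (h in names(hgs)) {
    for (k in 1:2) {
      pos <- pos + 10L
      rows[[length(rows) + 1]] <- tibble::tibble(
        haplogroup = h, parent = hgs[[h]], marker = paste0(h, "m", k),
        position = pos, ancestral = "A", derived = "G",
        key = as.integer(k == 1), ref = "A")
    }
  }
  marker_panel(dplyr::bind_rows(rows))
}

geno_for <- function(panel, derived_at, sample = "s1",
                     absent = integer(0)) {
  mk <- panel$markers
  obs <- mk[!mk$position %in% absent, ]
  structure(list(
    calls = tibble::tibble(
      sample = sample, position = obs$position,
      base = ifelse(obs$haplogroup %in% derived_at, obs$derived,
                    obs$ancestral)),
    absent = sort(absent), samples = sample, source = "variant-table"),
    class = "y_genotypes")
}

test_that("variant-table reader maps bases, missing calls and the absent set", {
  toy <- make_toy_panel_tree(depth = 3, branching = 2, seed = 21)
  sim <- simulate_genotype_table(toy$panel, samples_per_terminal = 2,
                                 missing_rate = 0.1, seed = 22)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(sim, vcf)
  g <- read_genotypes_vcf(vcf, toy$panel$markers$position)
  expect_setequal(g$samples, sim$truth$sample)
  # every call matches the generator's truth matrix
  for (i in seq_len(nrow(g$calls))) {
    expect_identical(g$calls$base[i],
                     sim$geno[as.character(g$calls$position[i]),
                              g$calls$sample[i]])
  }
  # records present in the VCF are not in the absent set; missing (".") calls
  # at recorded positions are excluded from the call map
  recorded <- unique(g$calls$position)
  expect_length(intersect(recorded, g$absent), 0)
  miss_pos <- as.integer(names(which(apply(is.na(sim$geno), 1, any))))
  some_recorded_missing <- intersect(miss_pos, recorded)
  if (length(some_recorded_missing)) {
    p0 <- some_recorded_missing[1]
    s0 <- colnames(sim$geno)[is.na(sim$geno[as.character(p0), ])][1]
    expect_false(any(g$calls$sample == s0 & g$calls$position == p0))
  }
})

test_that("heterozygous diploid calls are skipped with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=Y>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "Y\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
               "Y\t20\t.\tA\tG\t.\tPASS\t.\tGT\t1/1"), vcf)
  expect_warning(g <- read_genotypes_vcf(vcf, c(10L, 20L)), "heterozygous")
  expect_equal(nrow(g$calls), 1)
  expect_equal(g$calls$position, 20L)
  expect_equal(g$calls$base, "G")
})

test_that("a table without chrY records is an empty-input error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t1"), vcf)
  expect_error(read_genotypes_vcf(vcf, 10L),
               class = "patriline_empty_input_error")
})

test_that("matching rate counts derived hits over scorable markers", {
  panel <- marker_panel(tibble::tibble(
    haplogroup = "A", parent = "Y-Adam", marker = paste0("m", 1:4),
    position = c(10L, 20L, 30L, 40L), ancestral = "A", derived = "G",
    key = c(1L, 0L, 0L, 0L)))
  g <- structure(list(calls = tibble::tibble(
    sample = "s1", position = c(10L, 20L, 30L, 40L),
    base = c("G", "G", "A", "A")),
    absent = integer(0), samples = "s1", source = "variant-table"),
    class = "y_genotypes")
  sc <- score_haplogroups(g, panel)
  expect_equal(sc$n, 2L)
  expect_equal(sc$m, 4L)
  expect_equal(sc$rate, 0.5)
  expect_true(sc$key_derived)
})

test_that("hidden reference rule scores absent positions as reference, in sequencing mode only", {
  # marker whose derived allele equals the reference base, absent from table
  panel <- marker_panel(tibble::tibble(
    haplogroup = "A", parent = "Y-Adam", marker = c("m1", "m2"),
    position = c(10L, 20L), ancestral = c("A", "C"), derived = c("G", "T"),
    key = c(1L, 1L), ref = c("G", "C")))  # m1: ref == derived
  g <- structure(list(calls = tibble::tibble(
    sample = "s1", position = 20L, base = "T"),
    absent = 10L, samples = "s1", source = "variant-table"),
    class = "y_genotypes")
  seq_sc <- score_haplogroups(g, panel, mode = "sequencing")
  expect_equal(seq_sc$n, 2L)   # hidden m1 counted derived
  expect_equal(seq_sc$m, 2L)
  arr_sc <- score_haplogroups(g, panel, mode = "array")
  expect_equal(arr_sc$m, 1L)   # m1 unscorable in array mode
  expect_equal(arr_sc$n, 1L)
})

test_that("hidden-reference rule is a no-op when no derived allele equals the reference", {
  toy <- make_toy_panel_tree(depth = 3, branching = 2,
                             hidden_ref_fraction = 0, seed = 31)
  sim <- simulate_genotype_table(toy$panel, samples_per_terminal = 1, seed = 32)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(sim, vcf)
  g <- read_genotypes_vcf(vcf, toy$panel$markers$position)
  for (s in utils::head(g$samples, 3)) {
    seq_sc <- score_haplogroups(g, toy$panel, s, mode = "sequencing")
    seq_sc <- seq_sc[order(seq_sc$haplogroup), ]
    # derived hits identical under both modes (m may differ where ancestral
    # reference-equal sites are hidden)
    arr_sc <- score_haplogroups(g, toy$panel, s, mode = "array")
    arr_sc <- arr_sc[order(arr_sc$haplogroup), ]
    shared <- intersect(seq_sc$haplogroup, arr_sc$haplogroup)
    expect_equal(seq_sc$n[match(shared, seq_sc$haplogroup)],
                 arr_sc$n[match(shared, arr_sc$haplogroup)])
  }
})

test_that("track enumeration follows the tracking-rate formula on a chain", {
  panel <- make_small_panel()
  g <- geno_for(panel, derived_at = c("A", "B", "C"))
  sc <- score_haplogroups(g, panel)
  tracks <- enumerate_tracks(sc, panel$tree, cutoff = 0.7)
  best <- tracks[tracks$terminal == "C", ]
  expect_equal(best$r, 3L)
  expect_equal(best$t, 1.0)
  expect_identical(best$track[[1]], c("A", "B", "C"))
  # B unscorable: drop B's markers from the calls entirely (array mode)
  gB <- geno_for(panel, derived_at = c("A", "B", "C"),
                 absent = panel$markers$position[panel$markers$haplogroup == "B"])
  scB <- score_haplogroups(gB, panel, mode = "array")
  trB <- enumerate_tracks(scB, panel$tree, cutoff = 0.7)
  expect_equal(trB$t[trB$terminal == "C"], 2 / 3)
})

test_that("track selection breaks ties by resolution then terminal name", {
  tracks <- tibble::tibble(
    terminal = c("X", "Y"), r = c(5L, 3L), n_pass = c(5L, 3L),
    t = c(1.0, 1.0), n_key_on_track = c(5L, 3L),
    track = list(letters[1:5], letters[1:3]))
  expect_equal(select_track(tracks)$terminal, "X")
  tracks2 <- tibble::tibble(
    terminal = c("B", "A"), r = 3L, n_pass = 3L, t = 1.0,
    n_key_on_track = 3L, track = list(letters[1:3], letters[1:3]))
  expect_equal(select_track(tracks2)$terminal, "A")
  t3 <- tibble::tibble(terminal = c("X", "Y"), r = c(4L, 2L),
                       n_pass = c(4L, 2L), t = c(1.0, 0.6),
                       n_key_on_track = 1L, track = list("x", "y"))
  expect_equal(select_track(t3)$terminal, "X")
  expect_error(select_track(tracks[0, ]),
               class = "patriline_no_classification_error")
})

test_that("terminal refinement descends through ordinary-only children", {
  # C's child E has only ordinary markers, both derived
  base <- make_small_panel()
  df <- dplyr::bind_rows(
    tibble::tibble(haplogroup = base$markers$haplogroup,
                   parent = unname(base$tree$parent[base$markers$haplogroup]),
                   marker = base$markers$marker,
                   position = base$markers$position,
                   ancestral = base$markers$ancestral,
                   derived = base$markers$derived, key = base$markers$key,
                   ref = base$markers$ref),
    tibble::tibble(haplogroup = "E", parent = "C",
                   marker = c("Em1", "Em2"), position = c(100L, 110L),
                   ancestral = "A", derived = "G", key = 0L, ref = "A"))
  panel <- marker_panel(df)
  g <- geno_for(panel, derived_at = c("A", "B", "C", "E"))
  res <- classify_samples(g, panel)
  expect_equal(res$key_haplogroup, "C")
  expect_equal(res$haplogroup, "E")
  expect_match(res$mutations, "E:Em1/Em2")
  expect_equal(res$status, "refined")
  # without support below C, the terminal stays C with empty annotation
  g2 <- geno_for(panel, derived_at = c("A", "B", "C"))
  res2 <- classify_samples(g2, panel)
  expect_equal(res2$haplogroup, "C")
  expect_equal(res2$mutations, "")
})

test_that("unresolved samples are reported at the root with empty tables", {
  panel <- make_small_panel()
  g <- geno_for(panel, derived_at = character(0))
  res <- classify_samples(g, panel)
  expect_equal(res$status, "unresolved")
  expect_equal(res$haplogroup, "Y-Adam")
  expect_true(is.na(res$tracking_rate))
})

test_that("classification output is deterministic and round-trips via .hg", {
  toy <- make_toy_panel_tree(depth = 3, branching = 2, seed = 41)
  sim <- simulate_genotype_table(toy$panel, samples_per_terminal = 2,
                                 error_rate = 0.03, seed = 42)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(sim, vcf)
  hg1 <- classify_samples(vcf, toy$panel, input = "vcf")
  hg2 <- classify_samples(vcf, toy$panel, input = "vcf")
  expect_identical(hg1, hg2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hg(hg1, f1); write_hg(hg2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_hg(f1)
  expect_equal(back$sample, hg1$sample)
  expect_equal(back$haplogroup, hg1$haplogroup)
  expect_equal(back$tracking_rate, hg1$tracking_rate, tolerance = 1e-6)
})

test_that("pileup calls use majority base under depth and tie rules", {
  skip_if_not_installed("Rsamtools")
  toy <- make_toy_panel_tree(depth = 2, branching = 2, seed = 51)
  mk <- toy$panel$markers
  hgs <- unique(mk$haplogroup)
  p1 <- mk$position[1]; d1 <- mk$derived[1]; a1 <- mk$ancestral[1]
  p2 <- mk$position[mk$haplogroup == hgs[2]][1]  # far from p1's reads
  p3 <- mk$position[mk$haplogroup == hgs[3]][1]  # tie position, far from both
  stopifnot(abs(p2 - p1) > 100, abs(p3 - p1) > 100, abs(p3 - p2) > 100)
  reads <- dplyr::bind_rows(
    tibble::tibble(pos = rep(p1 - 5L, 6), seq = strrep(d1, 11)),  # 6 derived
    tibble::tibble(pos = rep(p1 - 5L, 4), seq = strrep(a1, 11)),  # 4 ancestral
    tibble::tibble(pos = p2 - 2L, seq = strrep("G", 5)),          # depth 1
    tibble::tibble(pos = rep(p3 - 1L, 2), seq = strrep("G", 3)),  # 2 G
    tibble::tibble(pos = rep(p3 - 1L, 2), seq = strrep("T", 3)))  # vs 2 T
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sim_sam(reads, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  g <- read_genotypes_pileup(bam, mk$position, sample = "s1", min_depth = 2)
  expect_equal(g$calls$base[g$calls$position == p1], d1)  # majority 6/4
  expect_false(p2 %in% g$calls$position)                  # below min depth
  expect_false(p3 %in% g$calls$position)                  # tied majority
  expect_length(g$absent, 0)
})
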