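#' Read haploid chrY genotypes at panel positions from a VCF
#'
#' Extracts the observed base of every sample at each marker-panel position
#' present in the variant table. Positions of the panel that carry no record
#' at all are returned in the *absent set*: for sequencing data these are
#' sites at which every sample matched the reference genome and so were not
#' emitted by the caller (the "hidden reference" situation the classifier
#' exploits in sequencing mode).
#'
#' Male chrY calls are expected haploid (`0`, `1`) or homozygous diploid
#' (`0/0`, `1/1`). Heterozygous diploid calls (pseudo-autosomal leakage or
#' artefacts) are skipped with a warning and count as unscorable. Missing
#' calls (`.`) are excluded from the call map but the position, being
#' present in the table, is *not* in the absent set.
#'
#' @param path Path to a VCF (plain or bgzip).
#' @param positions Integer vector of panel marker positions (1-based).
#' @param chrom Chromosome names accepted as chrY. Default `c("Y","chrY","24")`.
#' @return An object of class `y_genotypes`: list with `calls` (tibble
#'   `sample`, `position`, `base`), `absent` (integer vector of panel
#'   positions with no record), `samples` (character) and `source`
#'   (`"variant-table"`).
#' @export
read_genotypes_vcf <- function(path, positions, chrom = c("Y", "chrY", "24")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- fix$CHROM %in% chrom
  if (!any(keep)) {
    pl_abort("no chromosome-Y records found in variant table",
             "patriline_empty_input_error")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- v@gt[keep, , drop = FALSE]
  samples <- colnames(gt)[-1]
  pos <- as.integer(fix$POS)
  at_panel <- pos %in% positions
  absent <- sort(setdiff(positions, pos))
  fix <- fix[at_panel, , drop = FALSE]
  gt <- gt[at_panel, , drop = FALSE]
  pos <- pos[at_panel]
  calls <- list()
  n_het <- 0L
  if (nrow(fix)) {
    alleles <- lapply(seq_len(nrow(fix)), function(i) {
      c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    })
    gt_field <- sub(":.*$", "", gt[, -1, drop = FALSE])
    for (s in seq_along(samples)) {
      g <- gt_field[, s]
      idx <- strsplit(g, "[/|]")
      base <- character(length(g))
      for (i in seq_along(g)) {
        a <- idx[[i]]
        if (!length(a) || anyNA(a) || any(a == ".")) {
          base[i] <- NA_character_
          next
        }
        a <- unique(as.integer(a))
        if (length(a) > 1) { base[i] <- "HET"; next }
        b <- alleles[[i]][a + 1L]
        base[i] <- if (!is.na(b) && nchar(b) == 1 && is_acgt(b)) b else NA_character_
      }
      n_het <- n_het + sum(base == "HET", na.rm = TRUE)
      ok <- !is.na(base) & base != "HET"
      calls[[s]] <- tibble(sample = samples[s], position = pos[ok],
                           base = base[ok])
    }
  }
  if (n_het > 0) {
    warn(paste0(n_het, " heterozygous chrY call(s) skipped (treated as unscorable)"))
  }
  structure(list(calls = bind_rows(calls) %||% tibble(sample = character(),
                                                      position = integer(),
                                                      base = character()),
                 absent = absent, samples = samples, source = "variant-table"),
            class = "y_genotypes")
}

#' Call haploid genotypes at panel positions from an alignment pileup
#'
#' For one indexed BAM (one sample), takes the majority base among reads
#' passing depth and quality thresholds at each marker position. Positions
#' below the depth threshold, or with a tied majority, are unscorable. In
#' pileup mode there is no hidden-reference inference: only observed
#' positions are scorable (the absent set is empty and scoring behaves as
#' in array mode).
#'
#' @param path Path to an indexed BAM file.
#' @param positions Integer vector of panel marker positions.
#' @param sample Sample name to assign; defaults to the file base name.
#' @param min_depth Minimum passing-read depth to call a base (default 2).
#' @param min_base_q Minimum base quality (default 13).
#' @param min_map_q Minimum mapping quality (default 20).
#' @param chrom Accepted chrY sequence names.
#' @return A `y_genotypes` object with `source = "pileup"`.
#' @export
read_genotypes_pileup <- function(path, positions, sample = NULL,
                                  min_depth = 2, min_base_q = 13,
                                  min_map_q = 20,
                                  chrom = c("Y", "chrY", "24")) {
  sample <- sample %||% sub("\\.bam$", "", basename(path))
  bf <- tryCatch(Rsamtools::BamFile(path),
                 error = function(e) pl_abort(conditionMessage(e),
                                              "patriline_io_error"))
  seqs <- tryCatch(Rsamtools::scanBamHeader(path)[[1]]$targets,
                   error = function(e) pl_abort(conditionMessage(e),
                                                "patriline_io_error"))
  use_chrom <- intersect(names(seqs), chrom)
  if (!length(use_chrom)) {
    pl_abort("no chromosome-Y reference sequence in BAM header",
             "patriline_empty_input_error")
  }
  which <- GenomicRanges::GRanges(use_chrom[1],
                                  IRanges::IRanges(positions, positions))
  res <- Rsamtools::pileup(
    bf,
    scanBamParam = Rsamtools::ScanBamParam(which = which,
                                           mapqFilter = min_map_q),
    pileupParam = Rsamtools::PileupParam(min_base_quality = min_base_q,
                                         min_mapq = min_map_q,
                                         min_nucleotide_depth = 1,
                                         distinguish_strands = FALSE,
                                         max_depth = 10000L))
  calls <- tibble(sample = character(), position = integer(), base = character())
  if (nrow(res)) {
    res <- res[res$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
    by_pos <- split(res, res$pos)
    rows <- lapply(by_pos, function(d) {
      if (sum(d$count) < min_depth) return(NULL)
      top <- d[order(-d$count, as.character(d$nucleotide)), , drop = FALSE]
      if (nrow(top) > 1 && top$count[1] == top$count[2]) return(NULL)  # tie
      tibble(sample = sample, position = as.integer(top$pos[1]),
             base = as.character(top$nucleotide[1]))
    })
    calls <- bind_rows(rows)
    if (!nrow(calls)) calls <- tibble(sample = character(),
                                      position = integer(), base = character())
  }
  structure(list(calls = calls, absent = integer(0), samples = sample,
                 source = "pileup"),
            class = "y_genotypes")
}

#' @export
print.y_genotypes <- function(x, ...) {
  cat("<y_genotypes> ", length(x$samples), " sample(s), ", nrow(x$calls),
      " calls, ", length(x$absent), " panel position(s) absent from table [",
      x$source, "]\n", sep = "")
  invisible(x)
}
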