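# greedy motif-block count over the first `limit` bases of `window`:
# parse (M1)q1 (M2)q2 ... in order, each block as many whole copies of its
# motif as fit before the next block starts
count_blocks <- function(window, motifs, limit) {
  prefix <- substr(window, 1, min(limit, nchar(window)))
  pos <- 1L
  q <- 0L
  for (i in seq_len(nrow(motifs))) {
    mot <- motifs$motif[i]
    w <- nchar(mot)
    while (pos + w - 1L <= nchar(prefix) &&
           substr(prefix, pos, pos + w - 1L) == mot) {
      q <- q + 1L
      pos <- pos + w
    }
  }
  q
}

#' Genotype one Y-STR locus from a sequence window by iterative extension
#'
#' Implements the forward-extension repeat counter. The initial window is
#' the reference repeat region plus one trailing motif unit (`R = L'(N)_s`,
#' `s` the motif length). The total motif count `q` over the current window
#' is compared with the current reference total `p`: if `q <= p` the call
#' is `q`; if the window is saturated (`q = p + 1`) the window is extended
#' by one further motif unit, `p` is incremented, and `q` recounted — until
#' `q` stabilises at `p`, meaning no more motifs extend the repeat. For
#' compound loci the extension unit is the last motif.
#'
#' @param window Sample sequence starting exactly at the locus start on the
#'   reference frame, with trailing flanking context.
#' @param locus One row of an [load_str_panel()] panel (or a list with
#'   `motifs`, `p`, `motif_len`).
#' @param cap Maximum number of extension iterations (default 30); hitting
#'   the cap yields a no-call.
#' @return List `repeat_n` (integer or `NA`) and `status` (`"ok"`,
#'   `"truncated"`, `"ambiguous"` or `"cap"`).
#' @examples
#' panel <- load_str_panel("minimal")
#' loc <- panel[panel$name == "DYS393", ]   # (AGAT)12
#' win <- paste0(strrep("AGAT", 14), "GGCCTTAA")
#' genotype_window(win, loc)$repeat_n      # 14
#' @export
genotype_window <- function(window, locus, cap = 30) {
  motifs <- if (is.data.frame(locus) && "motifs" %in% names(locus) &&
                is.list(locus$motifs)) locus$motifs[[1]] else locus$motifs
  p0 <- sum(motifs$p)
  s <- nchar(motifs$motif[nrow(motifs)])
  ref_len <- sum(motifs$p * nchar(motifs$motif))
  window <- toupper(window)
  if (nchar(window) < ref_len) {
    return(list(repeat_n = NA_integer_, status = "truncated"))
  }
  if (grepl("[^ACGT]", substr(window, 1, ref_len))) {
    return(list(repeat_n = NA_integer_, status = "ambiguous"))
  }
  p <- p0
  len <- ref_len + s
  for (iter in seq_len(cap)) {
    q <- count_blocks(window, motifs, len)
    if (q <= p) return(list(repeat_n = q, status = "ok"))
    # saturated window (q >= p + 1): grow by one extension unit and recount
    p <- p + 1L
    len <- len + s
  }
  list(repeat_n = NA_integer_, status = "cap")
}

#' Genotype Y-STR loci from per-read sequence windows
#'
#' Applies [genotype_window()] to every spanning read window and takes the
#' modal repeat number per sample and locus as the consensus. A locus is
#' no-called for a sample when fewer than `min_reads` windows yield a call
#' or the modal fraction falls below `min_modal_frac` (favouring no-call
#' over a wrong call).
#'
#' @param windows Tibble with columns `sample`, `locus`, `window` (one row
#'   per spanning read).
#' @param panel An `str_panel`.
#' @param min_reads Minimum calls required (default 2).
#' @param min_modal_frac Minimum modal fraction (default 0.6).
#' @param cap Extension iteration cap.
#' @return A haplotype table: tibble with `sample` and one integer column
#'   per panel locus (`NA` = no-call).
#' @export
genotype_from_reads <- function(windows, panel, min_reads = 2,
                                min_modal_frac = 0.6, cap = 30) {
  loci <- panel$name
  calls <- windows |>
    filter(.data$locus %in% loci) |>
    group_by(.data$sample, .data$locus) |>
    summarise(repeat_n = {
      loc <- panel[panel$name == .data$locus[1], ]
      reps <- vapply(.data$window,
                     function(w) genotype_window(w, loc, cap)$repeat_n,
                     integer(1), USE.NAMES = FALSE)
      reps <- reps[!is.na(reps)]
      if (length(reps) < min_reads) NA_integer_ else {
        tab <- sort(table(reps), decreasing = TRUE)
        if (tab[1] / length(reps) < min_modal_frac) NA_integer_
        else as.integer(names(tab)[1])
      }
    }, .groups = "drop")
  hap_widen(calls, loci)
}

hap_widen <- function(calls, loci) {
  wide <- tidyr::pivot_wider(calls, names_from = "locus",
                             values_from = "repeat_n")
  for (l in setdiff(loci, names(wide))) wide[[l]] <- NA_integer_
  out <- arrange(wide[, c("sample", loci)], .data$sample)
  structure(out, class = c("haplotype_table", class(out)))
}

#' Extract per-read STR windows from an indexed BAM
#'
#' Collects, for each panel locus, the sequence windows of reads that fully
#' span `[start - flank, end + flank]` with an ungapped (all-match CIGAR)
#' alignment, clipped to start at the locus start.
#'
#' @param path Indexed BAM path.
#' @param panel An `str_panel`.
#' @param sample Sample name (defaults to the file base name).
#' @param flank Required flanking coverage in bases (default 5).
#' @param chrom Accepted chrY sequence names.
#' @return Tibble `sample`, `locus`, `window` suitable for
#'   [genotype_from_reads()].
#' @export
str_windows_from_bam <- function(path, panel, sample = NULL, flank = 5,
                                 chrom = c("Y", "chrY", "24")) {
  sample <- sample %||% sub("\\.bam$", "", basename(path))
  hdr <- tryCatch(Rsamtools::scanBamHeader(path)[[1]]$targets,
                  error = function(e) pl_abort(conditionMessage(e),
                                               "patriline_io_error"))
  use_chrom <- intersect(names(hdr), chrom)
  if (!length(use_chrom)) {
    pl_abort("no chromosome-Y reference sequence in BAM header",
             "patriline_empty_input_error")
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    loc <- panel[i, ]
    gr <- GenomicRanges::GRanges(use_chrom[1],
                                 IRanges::IRanges(loc$start, loc$end))
    b <- Rsamtools::scanBam(path,
      param = Rsamtools::ScanBamParam(which = gr,
                                      what = c("pos", "seq", "cigar")))[[1]]
    if (!length(b$pos)) return(NULL)
    seqs <- as.character(b$seq)
    keep <- !is.na(b$pos) & grepl("^[0-9]+M$", b$cigar) &
      b$pos <= loc$start - flank &
      b$pos + nchar(seqs) - 1L >= loc$end + flank
    if (!any(keep)) return(NULL)
    tibble(sample = sample, locus = loc$name,
           window = substr(seqs[keep], loc$start - b$pos[keep] + 1L,
                           nchar(seqs[keep])))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) tibble(sample = character(), locus = character(),
                         window = character())
  else out
}

#' Genotype Y-STR repeat numbers from VCF indel records
#'
#' For each locus, sums the net length change of the sample's indel alleles
#' whose records fall within the locus interval and converts it to a repeat
#' number: `reference p + net / s` (s = extension-unit motif length). Net
#' changes that are not a multiple of `s` are no-called (`"off-frame"`);
#' overlapping contributing indels are no-called (`"conflict"`). Records
#' are prefix/suffix-trimmed first, so unnormalized representations of the
#' same event are handled.
#'
#' @param path VCF path (plain or bgzip).
#' @param panel An `str_panel`.
#' @param chrom Accepted chrY sequence names.
#' @return A haplotype table (tibble, `sample` + one column per locus).
#' @export
genotype_from_indels <- function(path, panel, chrom = c("Y", "chrY", "24")) {
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
  gt_field <- sub(":.*$", "", gt[, -1, drop = FALSE])
  calls <- list()
  for (s in seq_along(samples)) {
    for (i in seq_len(nrow(panel))) {
      loc <- panel[i, ]
      in_locus <- which(pos >= loc$start & pos <= loc$end)
      net <- 0L
      spans <- list()
      bad <- FALSE
      for (r in in_locus) {
        g <- gt_field[r, s]
        a <- unique(strsplit(g, "[/|]")[[1]])
        if (any(a == ".") || length(a) != 1) next
        ai <- as.integer(a)
        if (ai == 0) next
        alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
        ref <- fix$REF[r]; alt <- alts[ai]
        # trim shared prefix/suffix (normalizes representation)
        while (nchar(ref) > 1 && nchar(alt) > 1 &&
               substr(ref, nchar(ref), nchar(ref)) ==
               substr(alt, nchar(alt), nchar(alt))) {
          ref <- substr(ref, 1, nchar(ref) - 1)
          alt <- substr(alt, 1, nchar(alt) - 1)
        }
        d <- nchar(alt) - nchar(ref)
        if (d == 0L) next                       # SNP within the repeat
        span <- c(pos[r], pos[r] + nchar(fix$REF[r]) - 1L)
        for (sp in spans) if (span[1] <= sp[2] && sp[1] <= span[2]) bad <- TRUE
        spans <- c(spans, list(span))
        net <- net + d
      }
      rep_n <- if (bad) NA_integer_
      else if (net %% loc$motif_len != 0L) NA_integer_    # off-frame
      else loc$p + net %/% loc$motif_len
      calls[[length(calls) + 1L]] <- tibble(sample = samples[s],
                                            locus = loc$name,
                                            repeat_n = as.integer(rep_n))
    }
  }
  hap_widen(bind_rows(calls), panel$name)
}

#' Write / read a Y-STR haplotype table
#'
#' Tab-delimited samples-by-loci matrix of integer repeat numbers; missing
#' calls are written as `"."`.
#'
#' @param haps Haplotype table (tibble, `sample` + locus columns).
#' @param path File path.
#' @return `path` invisibly (writer); the haplotype tibble (reader).
#' @export
write_haplotypes <- function(haps, path) {
  out <- as.data.frame(haps)
  for (j in seq(2, ncol(out))) out[[j]] <- ifelse(is.na(out[[j]]), ".", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  names(d)[1] <- "sample"
  d$sample <- as.character(d$sample)
  for (j in seq(2, ncol(d))) {
    d[[j]] <- suppressWarnings(as.integer(ifelse(d[[j]] == ".", NA, d[[j]])))
  }
  structure(as_tibble(d), class = c("haplotype_table", class(as_tibble(d))))
}
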