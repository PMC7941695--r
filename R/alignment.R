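#' Read a multiple sequence alignment
#'
#' Supports FASTA, PHYLIP (sequential or interleaved) and MEGA formats.
#' All sequences must have equal length; the alphabet is A, C, G, T, N, `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"`, `"phylip"` or `"mega"`.
#' @return Named character vector (one upper-case sequence string per
#'   sample) of class `alignment_block`.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "mega")) {
  format <- match.arg(format)
  seqs <- switch(format,
    fasta = {
      d <- ape::read.FASTA(path)
      vapply(as.character(d), function(s) paste(toupper(s), collapse = ""),
             character(1))
    },
    phylip = {
      d <- tryCatch(ape::read.dna(path, format = "sequential",
                                  as.character = TRUE),
                    error = function(e) ape::read.dna(path,
                                                      format = "interleaved",
                                                      as.character = TRUE))
      setNames(apply(d, 1, function(s) paste(toupper(s), collapse = "")),
               rownames(d))
    },
    mega = read_mega(path))
  alignment_block(seqs)
}

# minimal MEGA reader: "#mega" header, "!..." commands, "#name" then sequence
read_mega <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines) || !grepl("^#mega", lines[1], ignore.case = TRUE)) {
    pl_abort("not a MEGA alignment (missing '#mega' header)",
             "patriline_parse_error")
  }
  lines <- lines[-1]
  name <- NULL; acc <- list()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      name <- sub("^#", "", ln)
      acc[[name]] <- character(0)
    } else if (!is.null(name)) {
      acc[[name]] <- c(acc[[name]], gsub("\\s", "", ln))
    }
  }
  vapply(acc, function(x) toupper(paste(x, collapse = "")), character(1))
}

#' Construct an alignment block from named sequences
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return An `alignment_block`.
#' @export
alignment_block <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) > 1) {
    pl_abort("alignment sequences have unequal lengths",
             "patriline_validation_error")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    pl_abort(paste0("sequence '", names(seqs)[bad][1],
                    "' contains characters outside A,C,G,T,N,-"),
             "patriline_parse_error")
  }
  structure(seqs, class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("<alignment_block> ", length(x), " sequences x ", nchar(x[1]),
      " sites\n", sep = "")
  invisible(x)
}

#' Identity-by-state distance between aligned sequences
#'
#' Proportion of mismatching sites among sites where both sequences carry
#' an unambiguous base (non-N, non-gap). Pairs with no overlapping called
#' site get distance 1 with a warning.
#'
#' @param aln An `alignment_block` (or named character vector).
#' @param samples Optional subset of sample names.
#' @return Symmetric distance matrix.
#' @export
ibs_distance <- function(aln, samples = NULL) {
  seqs <- if (is.null(samples)) unclass(aln) else unclass(aln)[samples]
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  ok <- mat %in% c("A", "C", "G", "T")
  dim(ok) <- dim(mat)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  warned <- FALSE
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    shared <- ok[i, ] & ok[j, ]
    if (!any(shared)) {
      if (!warned) { warn("sequence pair(s) with no shared called site: distance set to 1") }
      warned <- TRUE
      D[i, j] <- D[j, i] <- 1
    } else {
      D[i, j] <- D[j, i] <- mean(mat[i, shared] != mat[j, shared])
    }
  }
  D
}

#' Write an alignment in sequential PHYLIP format
#'
#' @param aln An `alignment_block`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  seqs <- unclass(aln)
  lines <- c(paste0(" ", length(seqs), " ", nchar(seqs[1])),
             paste0(format(names(seqs), width = 12), seqs))
  writeLines(lines, path)
  invisible(path)
}
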