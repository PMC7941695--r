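#' Named Y-STR genotyping panels
#'
#' The cumulative forensic panel registry: Minimal (9 loci), PowerPlex Y
#' (12), Yfiler (17) and PowerPlex Y23 (23), each extending the previous
#' one; `named` resolves to every named locus of the loaded panel file and
#' `all` to every locus.
#'
#' @return Named list of locus-name character vectors for the four
#'   cumulative panels.
#' @export
str_panel_registry <- function() {
  minimal <- c("DYS19", "DYS385a", "DYS385b", "DYS389I", "DYS389II",
               "DYS390", "DYS391", "DYS392", "DYS393")
  powerplex_y <- c(minimal, "DYS437", "DYS438", "DYS439")
  yfiler <- c(powerplex_y, "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4")
  powerplex_y23 <- c(yfiler, "DYS481", "DYS533", "DYS549", "DYS570",
                     "DYS576", "DYS643")
  list("minimal" = minimal, "powerplex-y" = powerplex_y, "yfiler" = yfiler,
       "powerplex-y23" = powerplex_y23)
}

parse_motifs <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([ACGT]+)\\*([0-9]+)$", parts))
  if (any(lengths(m) != 3)) {
    pl_abort(paste0("malformed motif composition '", s, "'"),
             "patriline_parse_error")
  }
  tibble(motif = vapply(m, `[`, character(1), 2),
         p = as.integer(vapply(m, `[`, character(1), 3)))
}

#' Load a Y-STR locus reference panel
#'
#' A locus reference records the ordered motif composition of the
#' reference repeat sequence, `L = (M1)p1 (M2)p2 ... (Mn)pn`, its total
#' repeat number `p = sum(p_i)` and its chrY interval, whose length must
#' equal `sum(p_i * nchar(M_i))`. The extension unit of a locus is its
#' last motif; its length is the step size `s` of the iterative genotyper.
#'
#' The packaged panel (`inst/extdata/str_panel_synthetic.tsv`) is a
#' synthetic stand-in carrying the standard forensic locus names with
#' representative motifs and self-consistent synthetic coordinates; users
#' with a curated panel supply their own TSV in the same schema
#' (`name`, `motifs` as `"MOTIF*count,..."`, `start_hg19`, `end_hg19`,
#' `start_hg38`, `end_hg38`, `named`).
#'
#' @param panel Panel selector: one of `"minimal"`, `"powerplex-y"`,
#'   `"yfiler"`, `"powerplex-y23"`, `"named"`, `"all"`, or a path to a
#'   panel TSV (which loads all its loci).
#' @param build `"19"` or `"38"`.
#' @param path Path of the panel file to draw loci from (defaults to the
#'   packaged synthetic panel).
#' @return Tibble of class `str_panel`: `name`, `motifs` (list column of
#'   tibbles `motif`, `p`), `start`, `end`, `p`, `motif_len`, `named`.
#' @export
load_str_panel <- function(panel = "all", build = "38", path = NULL) {
  builtin <- names(str_panel_registry())
  file <- path %||% system.file("extdata", "str_panel_synthetic.tsv",
                                package = "patriline")
  if (file.exists(panel)) { file <- panel; panel <- "all" }
  if (!panel %in% c(builtin, "named", "all")) {
    pl_abort(paste0("unknown panel '", panel, "'; valid panels: ",
                    paste(c(builtin, "named", "all"), collapse = ", "),
                    ", or a panel TSV path"), "patriline_argument_error")
  }
  d <- as_tibble(utils::read.delim(file, stringsAsFactors = FALSE,
                                   comment.char = "#"))
  d$motifs <- lapply(d$motifs, parse_motifs)
  d$p <- vapply(d$motifs, function(m) sum(m$p), integer(1))
  d$motif_len <- vapply(d$motifs, function(m) nchar(m$motif[nrow(m)]), integer(1))
  d$start <- as.integer(d[[paste0("start_hg", build)]])
  d$end <- as.integer(d[[paste0("end_hg", build)]])
  len <- vapply(d$motifs, function(m) sum(m$p * nchar(m$motif)), integer(1))
  bad <- (d$end - d$start + 1L) != len
  if (any(bad)) {
    pl_abort(paste0("locus '", d$name[bad][1], "': interval length ",
                    d$end[bad][1] - d$start[bad][1] + 1L,
                    " != motif composition length ", len[bad][1]),
             "patriline_validation_error")
  }
  unnamed <- !as.logical(d$named)
  if (any(d$p < 4 & unnamed)) {
    pl_abort(paste0("unnamed locus '", d$name[d$p < 4 & unnamed][1],
                    "' has total repeat number < 4"),
             "patriline_validation_error")
  }
  keep <- switch(panel,
                 named = d$name[as.logical(d$named)],
                 all = d$name,
                 str_panel_registry()[[panel]])
  missing <- setdiff(keep, d$name)
  if (length(missing)) {
    pl_abort(paste0("panel file lacks locus/loci: ",
                    paste(missing, collapse = ", ")),
             "patriline_validation_error")
  }
  out <- d[match(keep, d$name),
           c("name", "motifs", "start", "end", "p", "motif_len", "named")]
  structure(out, class = c("str_panel", class(out)), build = build)
}

#' Reference repeat sequence of a panel locus
#'
#' Expands the motif composition `(M1)p1 ... (Mn)pn` into the literal
#' reference repeat sequence.
#'
#' @param locus One row of an `str_panel` (or a motif-composition tibble).
#' @return Character string.
#' @export
str_reference_sequence <- function(locus) {
  m <- if (is.data.frame(locus) && "motifs" %in% names(locus)) {
    locus$motifs[[1]]
  } else locus
  paste(mapply(function(mot, p) strrep(mot, p), m$motif, m$p), collapse = "")
}
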