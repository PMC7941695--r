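#' Score every haplogroup of a marker panel against one sample
#'
#' For each haplogroup with at least one scorable marker, counts `n`, the
#' number of markers observed in the derived state, out of `m` scorable
#' markers, and reports the matching rate `n/m`. A marker is scorable when
#' the sample has an observed base at its position or, in sequencing mode,
#' when the position is absent from the variant table altogether — such
#' positions are scored as carrying the reference-genome base (the hidden
#' reference rule: callers omit sites at which all samples match the
#' reference). In array mode absent positions are unscorable.
#'
#' @param genotypes A `y_genotypes` object (see [read_genotypes_vcf()]).
#' @param panel A `marker_panel`.
#' @param sample Sample name to score; defaults to the first sample.
#' @param mode `"sequencing"` (hidden reference rule active) or `"array"`.
#' @return Tibble with one row per scorable haplogroup: `haplogroup`, `n`,
#'   `m`, `rate`, `key_derived` (any key marker derived), `n_ord`, `m_ord`,
#'   `rate_ord` (ordinary-marker subset).
#' @export
score_haplogroups <- function(genotypes, panel, sample = NULL,
                              mode = c("sequencing", "array")) {
  mode <- match.arg(mode)
  sample <- sample %||% genotypes$samples[1]
  mk <- panel$markers
  obs <- filter(genotypes$calls, .data$sample == !!sample)
  base_at <- setNames(obs$base, obs$position)
  mk$obs <- base_at[as.character(mk$position)]
  if (mode == "sequencing" && length(genotypes$absent)) {
    hid <- is.na(mk$obs) & mk$position %in% genotypes$absent
    mk$obs[hid] <- mk$ref[hid]
  }
  mk <- filter(mk, !is.na(.data$obs))
  if (!nrow(mk)) {
    return(tibble(haplogroup = character(), n = integer(), m = integer(),
                  rate = double(), key_derived = logical(),
                  n_ord = integer(), m_ord = integer(), rate_ord = double()))
  }
  mk$derived_hit <- mk$obs == mk$derived
  ord_der <- mk[mk$derived_hit & mk$key == 0, c("haplogroup", "marker")]
  res <- mk |>
    group_by(.data$haplogroup) |>
    summarise(n = sum(.data$derived_hit),
              m = dplyr::n(),
              key_derived = any(.data$derived_hit & .data$key == 1),
              n_ord = sum(.data$derived_hit & .data$key == 0),
              m_ord = sum(.data$key == 0),
              .groups = "drop") |>
    mutate(rate = .data$n / .data$m,
           rate_ord = ifelse(.data$m_ord > 0, .data$n_ord / .data$m_ord, NA_real_)) |>
    select("haplogroup", "n", "m", "rate", "key_derived",
           "n_ord", "m_ord", "rate_ord")
  attr(res, "derived_ordinary") <- split(ord_der$marker, ord_der$haplogroup)
  res
}

#' Enumerate candidate lineage tracks
#'
#' A lineage track is the root-to-terminal path of a candidate terminal
#' haplogroup. Candidates are haplogroups whose matching rate passes the
#' cutoff `U` and which, in the key pass, carry at least one derived key
#' marker. For a track ending at depth `r`, each of the `r` haplogroups on
#' the path contributes an indicator `R_i = 1` if its matching rate passes
#' `U` (unscorable haplogroups contribute 0), and the tracking rate is
#' `t = sum(R_i) / r`.
#'
#' @param scores Output of [score_haplogroups()].
#' @param tree A [haplo_tree].
#' @param cutoff Matching-rate cutoff `U` in (0, 1]. Default 0.7.
#' @param key_only Restrict candidate terminals to key-supported
#'   haplogroups (the key pass)? Default `TRUE`.
#' @return Tibble with one row per candidate track: `terminal`, `r`,
#'   `n_pass`, `t`, `n_key_on_track`, and `track` (list column of the
#'   path, root child first).
#' @export
enumerate_tracks <- function(scores, tree, cutoff = 0.7, key_only = TRUE) {
  stopifnot(cutoff > 0, cutoff <= 1)
  pass <- scores$haplogroup[scores$rate >= cutoff]
  keyd <- scores$haplogroup[scores$key_derived]
  cand <- if (key_only) intersect(pass, keyd) else pass
  if (!length(cand)) {
    return(tibble(terminal = character(), r = integer(), n_pass = integer(),
                  t = double(), n_key_on_track = integer(), track = list()))
  }
  pass_set <- pass
  rows <- lapply(sort(cand), function(h) {
    path <- haplogroup_path(tree, h)
    r <- length(path)
    n_pass <- sum(path %in% pass_set)
    tibble(terminal = h, r = r, n_pass = n_pass, t = n_pass / r,
           n_key_on_track = sum(path %in% keyd), track = list(path))
  })
  bind_rows(rows)
}

#' Select the optimal lineage track
#'
#' Returns the track with the maximal tracking rate `t` (the final track
#' `T_f` over the `s` candidate tracks). Ties are broken deterministically:
#' greater resolution `r`, then more key-derived haplogroups on the track,
#' then lexicographically smallest terminal name.
#'
#' @param tracks Output of [enumerate_tracks()].
#' @return A one-row tibble (same columns as `tracks`).
#' @export
select_track <- function(tracks) {
  if (!nrow(tracks)) {
    pl_abort("no candidate lineage track: sample unresolved",
             "patriline_no_classification_error")
  }
  ord <- order(-tracks$t, -tracks$r, -tracks$n_key_on_track, tracks$terminal)
  tracks[ord[1], , drop = FALSE]
}

#' Refine the terminal haplogroup through key-less descendants
#'
#' From the selected key terminal, greedily descends into child haplogroups
#' supported only by ordinary markers (ordinary matching rate >= `U`),
#' yielding a possibly deeper final terminal. When the final terminal
#' differs from the key terminal, the supporting ordinary derived markers
#' are recorded in the mutation annotation.
#'
#' @param terminal The selected key terminal haplogroup.
#' @param scores Output of [score_haplogroups()].
#' @param panel A `marker_panel`.
#' @param cutoff Matching-rate cutoff `U`.
#' @return List with `final_terminal` and `mutations` (annotation string,
#'   `""` when no descent happened).
#' @export
refine_terminal <- function(terminal, scores, panel, cutoff = 0.7) {
  tree <- panel$tree
  rate_ord <- setNames(scores$rate_ord, scores$haplogroup)
  der_ord <- attr(scores, "derived_ordinary") %||% list()
  derived_markers <- function(h) sort(der_ord[[h]] %||% character(0))
  cur <- terminal
  ann <- character(0)
  repeat {
    kids <- tree_children(tree, cur)
    if (!length(kids)) break
    sup <- kids[!is.na(rate_ord[kids]) & rate_ord[kids] >= cutoff]
    if (!length(sup)) break
    if (length(sup) > 1) {
      ord <- order(-rate_ord[sup], sup)
      inform(paste0("ambiguous terminal refinement under '", cur, "': ",
                    paste(sup, collapse = ", "), "; descending into '",
                    sup[ord[1]], "'"))
      sup <- sup[ord]
    }
    cur <- sup[1]
    ann <- c(ann, paste0(cur, ":", paste(derived_markers(cur), collapse = "/")))
  }
  list(final_terminal = cur,
       mutations = if (length(ann)) paste(ann, collapse = ";") else "")
}

classify_one <- function(genotypes, panel, sample, cutoff, mode) {
  scores <- score_haplogroups(genotypes, panel, sample, mode)
  status <- "ok"
  tracks <- enumerate_tracks(scores, panel$tree, cutoff, key_only = TRUE)
  if (!nrow(tracks)) {
    # ordinary fallback: non-sequencing data or low resolution may match no
    # key haplogroup; apply the same tracking approach to ordinary matches
    tracks <- enumerate_tracks(scores, panel$tree, cutoff, key_only = FALSE)
    status <- "ordinary"
  }
  if (!nrow(tracks)) {
    return(tibble(sample = sample, key_haplogroup = panel$tree$root,
                  haplogroup = panel$tree$root, tracking_rate = NA_real_,
                  mutations = "", status = "unresolved"))
  }
  best <- select_track(tracks)
  ref <- refine_terminal(best$terminal, scores, panel, cutoff)
  if (ref$final_terminal != best$terminal && status == "ok") status <- "refined"
  tibble(sample = sample, key_haplogroup = best$terminal,
         haplogroup = ref$final_terminal, tracking_rate = best$t,
         mutations = ref$mutations, status = status)
}

#' Classify NRY haplogroups for all samples of one or more inputs
#'
#' End-to-end classification: reads genotypes (one or several VCFs, or one
#' or several single-sample BAMs), scores haplogroups, enumerates lineage
#' tracks, selects the maximal-tracking-rate track per sample and refines
#' the terminal. Samples for which no haplogroup passes the cutoff — even
#' via the ordinary-marker fallback — are reported at the root with status
#' `"unresolved"`.
#'
#' @param x Input: a `y_genotypes` object, a character vector of VCF paths
#'   (`input = "vcf"`), or of BAM paths (`input = "bam"`).
#' @param panel A `marker_panel`.
#' @param cutoff Matching-rate cutoff `U` in (0, 1]. Default 0.7.
#' @param mode `"sequencing"` or `"array"`; see [score_haplogroups()].
#' @param input `"vcf"` or `"bam"` when `x` is a path vector.
#' @param ... Passed to the genotype reader (e.g. `min_depth`).
#' @return A haplogroup-assignment tibble (".hg table"): `sample`,
#'   `key_haplogroup`, `haplogroup`, `tracking_rate`, `mutations`, `status`.
#' @examples
#' sim <- with(make_toy_panel_tree(depth = 3, branching = 2, seed = 1),
#'             simulate_genotype_table(panel, samples_per_terminal = 1, seed = 1))
#' @export
classify_samples <- function(x, panel, cutoff = 0.7,
                             mode = c("sequencing", "array"),
                             input = c("vcf", "bam"), ...) {
  mode <- match.arg(mode)
  gts <- if (inherits(x, "y_genotypes")) {
    list(x)
  } else {
    input <- match.arg(input)
    positions <- panel$markers$position
    lapply(x, function(p) {
      if (input == "vcf") read_genotypes_vcf(p, positions, ...)
      else read_genotypes_pileup(p, positions, ...)
    })
  }
  rows <- lapply(gts, function(g) {
    bind_rows(lapply(g$samples, function(s)
      classify_one(g, panel, s, cutoff, mode)))
  })
  arrange(bind_rows(rows), .data$sample)
}

#' Write / read a haplogroup assignment table (.hg file)
#'
#' Tab-delimited with header
#' `SampleID KeyHaplogroup Haplogroup TrackingRate Mutations Status`.
#'
#' @param hg Classification tibble from [classify_samples()].
#' @param path Output path.
#' @return `path` invisibly (writer); the assignment tibble (reader).
#' @export
write_hg <- function(hg, path) {
  out <- data.frame(SampleID = hg$sample, KeyHaplogroup = hg$key_haplogroup,
                    Haplogroup = hg$haplogroup,
                    TrackingRate = ifelse(is.na(hg$tracking_rate), ".",
                                          format(hg$tracking_rate, digits = 6)),
                    Mutations = ifelse(hg$mutations == "", ".", hg$mutations),
                    Status = hg$status)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hg
#' @export
read_hg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tibble(sample = as.character(d$SampleID),
         key_haplogroup = d$KeyHaplogroup,
         haplogroup = d$Haplogroup,
         tracking_rate = suppressWarnings(as.numeric(d$TrackingRate)),
         mutations = ifelse(d$Mutations == ".", "", d$Mutations),
         status = if ("Status" %in% names(d)) d$Status else "ok")
}
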