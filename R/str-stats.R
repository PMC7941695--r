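complete_haps <- function(haps) {
  m <- as.matrix(haps[, -1, drop = FALSE])
  rownames(m) <- haps$sample
  ok <- stats::complete.cases(m)
  if (any(!ok)) {
    warn(paste0(sum(!ok), " haplotype(s) with no-calls dropped"))
  }
  m[ok, , drop = FALSE]
}

#' Haplotype diversity of a Y-STR haplotype table
#'
#' `HD = n/(n-1) * (1 - sum(p_i^2))` over the frequencies `p_i` of the
#' distinct multi-locus haplotypes. With a population map, also reported
#' per population.
#'
#' @param haps Haplotype table (tibble, `sample` + locus columns); rows
#'   with no-calls are dropped with a warning.
#' @param popmap Optional tibble `sample`, `population`.
#' @return Tibble `statistic`, `population` (`"(all)"` for the pooled
#'   estimate), `value`, `n`.
#' @export
haplotype_diversity <- function(haps, popmap = NULL) {
  m <- complete_haps(haps)
  hd_of <- function(rows) {
    n <- length(rows)
    if (n < 2) pl_abort("haplotype diversity undefined for n < 2",
                        "patriline_argument_error")
    key <- apply(m[rows, , drop = FALSE], 1, paste, collapse = ",")
    p <- as.numeric(table(key)) / n
    n / (n - 1) * (1 - sum(p^2))
  }
  out <- tibble(statistic = "haplotype_diversity", population = "(all)",
                value = hd_of(rownames(m)), n = nrow(m))
  if (!is.null(popmap)) {
    pm <- popmap[popmap$sample %in% rownames(m), ]
    per <- pm |>
      group_by(.data$population) |>
      summarise(value = hd_of(.data$sample), n = dplyr::n(), .groups = "drop") |>
      mutate(statistic = "haplotype_diversity")
    out <- bind_rows(out, per[, c("statistic", "population", "value", "n")])
  }
  out
}

# pairwise distance between two haplotype vectors over shared called loci
hap_dist <- function(x, y, metric) {
  shared <- !is.na(x) & !is.na(y)
  if (!any(shared)) return(NA_real_)
  if (metric == "mismatch") sum(x[shared] != y[shared])
  else sum((x[shared] - y[shared])^2)
}

hap_dist_matrix <- function(m, metric) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    D[i, j] <- D[j, i] <- hap_dist(m[i, ], m[j, ], metric)
  }
  D
}

#' Mean pairwise distance between Y-STR haplotypes
#'
#' Mean over all unordered sample pairs of the per-pair distance: the
#' number of mismatching loci (default) or the summed squared repeat
#' difference (`metric = "squared"`). Pairs with no shared called locus are
#' skipped with a warning.
#'
#' @inheritParams haplotype_diversity
#' @param metric `"mismatch"` or `"squared"`.
#' @return Tibble `statistic`, `population`, `value`, `n`.
#' @export
mean_pairwise_distance <- function(haps, popmap = NULL,
                                   metric = c("mismatch", "squared")) {
  metric <- match.arg(metric)
  m <- as.matrix(haps[, -1, drop = FALSE])
  rownames(m) <- haps$sample
  mpd_of <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    if (nrow(sub) < 2) pl_abort("MPD undefined for n < 2",
                                "patriline_argument_error")
    D <- hap_dist_matrix(sub, metric)
    v <- D[upper.tri(D)]
    if (anyNA(v)) {
      warn(paste0(sum(is.na(v)), " pair(s) with no shared called locus skipped"))
      v <- v[!is.na(v)]
    }
    mean(v)
  }
  out <- tibble(statistic = "mean_pairwise_distance", population = "(all)",
                value = mpd_of(rownames(m)), n = nrow(m))
  if (!is.null(popmap)) {
    pm <- popmap[popmap$sample %in% rownames(m), ]
    per <- pm |>
      group_by(.data$population) |>
      summarise(value = mpd_of(.data$sample), n = dplyr::n(), .groups = "drop") |>
      mutate(statistic = "mean_pairwise_distance")
    out <- bind_rows(out, per[, c("statistic", "population", "value", "n")])
  }
  out
}

#' Nei's Gst over Y-STR loci
#'
#' Per locus, `Gst = (H_T - H_S)/H_T` with `H = 1 - sum(p^2)`; `H_S` is the
#' unweighted mean of within-population allele diversities and `H_T` the
#' diversity of the unweighted mean allele-frequency vector. Loci
#' monomorphic across all populations are skipped; the summary value is
#' the mean over the remaining loci.
#'
#' @inheritParams haplotype_diversity
#' @param popmap Tibble `sample`, `population` (required; >= 2 populations).
#' @return Tibble with one row per retained locus plus a `"(mean)"` row:
#'   `statistic`, `locus`, `value`, `n`.
#' @export
gst <- function(haps, popmap) {
  stopifnot(!is.null(popmap))
  d <- left_join(haps, popmap, by = "sample")
  d <- d[!is.na(d$population), , drop = FALSE]
  pops <- unique(d$population)
  if (length(pops) < 2) pl_abort("need >= 2 populations", "patriline_argument_error")
  loci <- setdiff(names(haps), "sample")
  rows <- list()
  for (l in loci) {
    x <- d[[l]]
    keep <- !is.na(x)
    if (length(unique(x[keep])) < 2) next  # monomorphic (or uncalled)
    alleles <- sort(unique(x[keep]))
    freqs <- vapply(pops, function(pp) {
      xs <- x[keep & d$population == pp]
      as.numeric(table(factor(xs, levels = alleles))) / length(xs)
    }, numeric(length(alleles)))
    hs <- mean(apply(freqs, 2, function(p) 1 - sum(p^2)))
    pt <- rowMeans(freqs)
    ht <- 1 - sum(pt^2)
    g <- if (ht <= 0) 0 else min(1, max(0, (ht - hs) / ht))
    rows[[l]] <- tibble(statistic = "gst", locus = l, value = g,
                        n = sum(keep))
  }
  if (!length(rows)) pl_abort("all loci monomorphic", "patriline_empty_input_error")
  per <- bind_rows(rows)
  bind_rows(per, tibble(statistic = "gst", locus = "(mean)",
                        value = mean(per$value), n = nrow(d)))
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Decomposes the total molecular variance of Y-STR haplotypes into
#' among-population and within-population components from the pairwise
#' distance matrix (same metric as [mean_pairwise_distance()], treated as
#' squared distances in the sum-of-squares identities), yielding
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)` and a
#' permutation p-value obtained by reshuffling population labels.
#'
#' @inheritParams gst
#' @param permutations Number of label permutations (0 omits the p-value).
#' @param seed Seed for the permutation stream.
#' @param metric `"mismatch"` or `"squared"`.
#' @return An object of class `pl_amova`: list with `table` (tibble of
#'   source, df, SS, variance components), `phi_st`, `p_value`,
#'   `permutations`, `seed`, `n`, `metric`.
#' @export
amova <- function(haps, popmap, permutations = 999, seed = 1,
                  metric = c("mismatch", "squared")) {
  metric <- match.arg(metric)
  m <- complete_haps(haps)
  pm <- popmap[match(rownames(m), popmap$sample), ]
  ok <- !is.na(pm$population)
  m <- m[ok, , drop = FALSE]
  labels <- pm$population[ok]
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2)) {
    pl_abort("AMOVA needs >= 2 populations with >= 2 samples each",
             "patriline_argument_error")
  }
  D <- hap_dist_matrix(m, metric)
  res <- amova_components(D, labels)
  phi_obs <- res$phi_st
  p_val <- NA_real_
  if (permutations >= 1) {
    phi_perm <- withr::with_seed(seed, {
      vapply(seq_len(permutations), function(b) {
        amova_components(D, sample(labels))$phi_st
      }, numeric(1))
    })
    p_val <- (sum(phi_perm >= phi_obs - 1e-12) + 1) / (permutations + 1)
  }
  structure(list(table = res$table, phi_st = phi_obs, p_value = p_val,
                 permutations = permutations, seed = seed, n = nrow(m),
                 metric = metric),
            class = "pl_amova")
}

# SS decomposition from a (squared-)distance matrix and group labels
amova_components <- function(D, labels) {
  n <- nrow(D)
  groups <- split(seq_len(n), labels)
  k <- length(groups)
  ss_of <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(D[idx, idx][upper.tri(D[idx, idx])]) / length(idx)
  }
  ss_total <- sum(D[upper.tri(D)]) / n
  ss_within <- sum(vapply(groups, ss_of, numeric(1)))
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- n - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n - sum(lengths(groups)^2) / n) / (k - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  phi <- if (sigma_among + sigma_within <= 0) 0
  else sigma_among / (sigma_among + sigma_within)
  list(table = tibble(source = c("among populations", "within populations",
                                 "total"),
                      df = c(df_among, df_within, n - 1),
                      SS = c(ss_among, ss_within, ss_total),
                      MS = c(ms_among, ms_within, NA),
                      sigma2 = c(sigma_among, sigma_within,
                                 sigma_among + sigma_within)),
       phi_st = phi)
}

#' @export
print.pl_amova <- function(x, ...) {
  cat("One-level AMOVA (", x$metric, " distance), n = ", x$n, "\n", sep = "")
  print(as.data.frame(x$table))
  cat("Phi_ST = ", format(x$phi_st, digits = 4),
      if (!is.na(x$p_value)) paste0(", p = ", format(x$p_value, digits = 3),
                                    " (", x$permutations, " permutations, seed ",
                                    x$seed, ")"), "\n", sep = "")
  invisible(x)
}

#' Read a Y-STR haplogroup-prediction reference data set
#'
#' The reference is a TSV of per-haplogroup allele counts:
#' `haplogroup`, `locus`, `allele`, `count`. Haplogroup priors default to
#' the haplogroups' total counts (pass `uniform_prior = TRUE` for equal
#' priors). The packaged file is a small synthetic demonstration reference.
#'
#' @param path Reference TSV path, or `"synthetic"` for the packaged
#'   demonstration reference.
#' @param pseudocount Smoothing pseudocount added per allele bin
#'   (default 0.5).
#' @param uniform_prior Use equal haplogroup priors?
#' @return Object of class `str_freq_ref`.
#' @export
read_str_reference <- function(path = "synthetic", pseudocount = 0.5,
                               uniform_prior = FALSE) {
  if (identical(path, "synthetic")) {
    path <- system.file("extdata", "str_reference_synthetic.tsv",
                        package = "patriline")
  }
  d <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                   comment.char = "#"))
  str_reference(d, pseudocount, uniform_prior)
}

#' @rdname read_str_reference
#' @param counts Tibble `haplogroup`, `locus`, `allele`, `count`.
#' @export
str_reference <- function(counts, pseudocount = 0.5, uniform_prior = FALSE) {
  stopifnot(all(c("haplogroup", "locus", "allele", "count") %in% names(counts)))
  hgs <- sort(unique(counts$haplogroup))
  prior <- if (uniform_prior) {
    setNames(rep(1 / length(hgs), length(hgs)), hgs)
  } else {
    tot <- vapply(hgs, function(h) sum(counts$count[counts$haplogroup == h]),
                  numeric(1))
    tot / sum(tot)
  }
  structure(list(counts = as_tibble(counts), haplogroups = hgs,
                 prior = prior, pseudocount = pseudocount),
            class = "str_freq_ref")
}

#' Predict the NRY haplogroup of a Y-STR haplotype (Bayesian)
#'
#' Posterior over haplogroups: `P(h | x) proportional to prior(h) *
#' prod_l f_h(x_l)` over the loci shared between the haplotype and the
#' reference, where `f_h` is the smoothed allele frequency of haplogroup
#' `h` at locus `l` (pseudocount added per allele bin, bins being the
#' union of alleles seen at the locus plus the observed one).
#'
#' @param hap Named integer vector (locus -> repeat number), or a one-row
#'   haplotype table.
#' @param ref An `str_freq_ref` ([read_str_reference()]).
#' @param top_k Return only the `top_k` most probable haplogroups
#'   (default all).
#' @return Tibble `haplogroup`, `posterior`, sorted decreasing; attribute
#'   `n_loci` = number of loci used.
#' @export
predict_haplogroup <- function(hap, ref, top_k = NULL) {
  if (is.data.frame(hap)) {
    stopifnot(nrow(hap) == 1)
    hap <- unlist(hap[, setdiff(names(hap), "sample"), drop = FALSE])
  }
  hap <- hap[!is.na(hap)]
  loci <- intersect(names(hap), unique(ref$counts$locus))
  if (!length(loci)) pl_abort("no locus shared with the reference",
                              "patriline_argument_error")
  pc <- ref$pseudocount
  logpost <- log(ref$prior[ref$haplogroups])
  for (l in loci) {
    sub <- ref$counts[ref$counts$locus == l, ]
    bins <- sort(unique(c(sub$allele, hap[[l]])))
    for (h in ref$haplogroups) {
      ch <- sub[sub$haplogroup == h, ]
      cnt <- setNames(rep(0, length(bins)), bins)
      cnt[as.character(ch$allele)] <- ch$count
      f <- (cnt + pc) / (sum(cnt) + pc * length(bins))
      if (pc == 0 && sum(cnt) == 0) f[] <- 1 / length(bins)  # uninformative
      like <- f[[as.character(hap[[l]])]]
      logpost[h] <- logpost[h] + log(like)
    }
  }
  logpost[!is.finite(logpost)] <- -Inf
  w <- exp(logpost - max(logpost))
  post <- w / sum(w)
  out <- tibble(haplogroup = ref$haplogroups, posterior = unname(post)) |>
    arrange(dplyr::desc(.data$posterior), .data$haplogroup)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  attr(out, "n_loci") <- length(loci)
  out
}
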