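#' Built-in divergence-time calibration table
#'
#' Loads the packaged calibration bounds (in kyr) for main-trunk Y
#' haplogroups, used to annotate nodes of the dating input tree when the
#' user supplies no bound of their own. The packaged values are
#' configuration data at literature scale, not asserted estimates; users
#' performing real dating should supply their own calibrations.
#'
#' @return Tibble `haplogroup`, `lower`, `upper` (kyr).
#' @export
builtin_calibrations <- function() {
  p <- system.file("extdata", "calibrations.tsv", package = "patriline")
  d <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
  as_tibble(d)
}

#' Generate the input bundle for an external Bayesian dating run
#'
#' Bayesian MCMC divergence dating itself is delegated to an external
#' executable (a PAML-mcmctree-style program); this function prepares the
#' three files such a program requires: a rooted, strictly bifurcating,
#' branch-length-free newick tree with calibration bounds annotated as
#' `'>lower<upper'` at calibrated nodes, a sequential PHYLIP alignment,
#' and a control file referencing both.
#'
#' @param tree Rooted bifurcating `phylo`; internal node labels identify
#'   haplogroups to be matched against calibrations.
#' @param aln An `alignment_block` covering the tree tips.
#' @param calibrations Optional tibble `haplogroup`, `lower`, `upper` (kyr);
#'   bounds given here override the built-in table for the same node.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix (default `"dating"`).
#' @param params Named list of control-file settings to override the
#'   defaults (`clock`, `model`, `alpha`, `burnin`, `sampfreq`, `nsample`).
#' @return Named character vector with paths `tree`, `alignment`, `control`.
#' @export
generate_dating_inputs <- function(tree, aln, calibrations = NULL,
                                   out_dir = ".", prefix = "dating",
                                   params = list()) {
  if (!ape::is.binary(tree)) {
    pl_abort(paste0("tree contains polytomies; resolve them first with ",
                    "resolve_polytomies()"), "patriline_validation_error")
  }
  calib <- builtin_calibrations()
  if (!is.null(calibrations)) {
    calib <- bind_rows(as_tibble(calibrations),
                       calib[!calib$haplogroup %in% calibrations$haplogroup, ])
  }
  if (any(calib$lower >= calib$upper)) {
    pl_abort("calibration lower bound must be below upper bound",
             "patriline_validation_error")
  }
  labs <- tree$node.label %||% character(0)
  hit <- calib$haplogroup %in% labs
  if (!any(hit)) {
    pl_abort("no calibration matches any labelled node of the tree",
             "patriline_validation_error")
  }
  used <- calib[hit, , drop = FALSE]
  tr <- tree
  tr$edge.length <- NULL
  idx <- match(used$haplogroup, labs)
  tr$node.label[idx] <- sprintf("'>%g<%g'", used$lower, used$upper)
  tr$node.label[-idx][tr$node.label[-idx] != ""] <- ""
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree_path <- file.path(out_dir, paste0(prefix, ".trees"))
  aln_path <- file.path(out_dir, paste0(prefix, ".phy"))
  ctl_path <- file.path(out_dir, paste0(prefix, ".ctl"))
  writeLines(c(paste0(" ", length(tree$tip.label), " 1"),
               ape::write.tree(tr)), tree_path)
  write_phylip(aln, aln_path)
  p <- utils::modifyList(
    list(clock = 2, model = 4, alpha = 0.5, burnin = 2000,
         sampfreq = 2, nsample = 20000, rootage = max(used$upper) * 1.2),
    params)
  writeLines(c(
    sprintf("seqfile = %s", aln_path),
    sprintf("treefile = %s", tree_path),
    sprintf("outfile = %s", file.path(out_dir, paste0(prefix, ".out"))),
    "seqtype = 0", "usedata = 1", "ndata = 1",
    sprintf("clock = %s", p$clock),
    sprintf("RootAge = <%g", p$rootage),
    sprintf("model = %s", p$model),
    sprintf("alpha = %g", p$alpha),
    sprintf("burnin = %s", p$burnin),
    sprintf("sampfreq = %s", p$sampfreq),
    sprintf("nsample = %s", p$nsample)), ctl_path)
  c(tree = tree_path, alignment = aln_path, control = ctl_path)
}

#' Summarize the output of an external Bayesian dating run
#'
#' Parses the posterior node-time table of a mcmctree-style output file:
#' lines of the form `t_nLABEL  mean (lower, upper)` in the posterior
#' time-estimate section. Node identifiers are mapped back to haplogroup
#' labels of `tree` when one is supplied.
#'
#' @param path Path to the dating program's output text.
#' @param tree Optional `phylo` whose node labels provide the mapping from
#'   node numbers to haplogroup names.
#' @return Tibble `node`, `haplogroup`, `mean`, `lower`, `upper`.
#' @export
summarize_dating_output <- function(path, tree = NULL) {
  lines <- readLines(path)
  pat <- "^\\s*t_n(\\S+)\\s+([0-9.eE+-]+)\\s*\\(\\s*([0-9.eE+-]+)\\s*,\\s*([0-9.eE+-]+)\\s*\\)"
  hits <- regmatches(lines, regexec(pat, lines))
  rows <- which(lengths(hits) == 5)
  if (!length(rows)) {
    bad <- which(grepl("^\\s*t_n", lines))[1]
    pl_abort(paste0("no parseable node-time lines",
                    if (!is.na(bad)) paste0(" (first malformed line: ", bad, ")")
                    else " (empty or unrecognized file)"),
             "patriline_parse_error")
  }
  out <- bind_rows(lapply(hits[rows], function(h) {
    tibble(node = h[2], mean = as.numeric(h[3]),
           lower = as.numeric(h[4]), upper = as.numeric(h[5]))
  }))
  out$haplogroup <- NA_character_
  if (!is.null(tree) && !is.null(tree$node.label)) {
    ntip <- length(tree$tip.label)
    num <- suppressWarnings(as.integer(out$node))
    ok <- !is.na(num) & num > ntip & num <= ntip + tree$Nnode
    out$haplogroup[ok] <- tree$node.label[num[ok] - ntip]
    if (any(!ok)) {
      warn(paste0(sum(!ok), " node label(s) in the output could not be ",
                  "mapped to the tree; rows retained unmapped"))
    }
  }
  out[, c("node", "haplogroup", "mean", "lower", "upper")]
}
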