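#' Build a haplogroup tree from parent links
#'
#' Constructs the rooted hierarchy of Y-chromosome haplogroups used
#' throughout the package. Every haplogroup except the root has exactly one
#' parent; the root ("Y-Adam", the ancestral Y chromosome carrying no derived
#' mutation) is implicit and need not appear as a row of the panel file.
#'
#' @param parents Named character vector: `parents[h]` is the parent
#'   haplogroup of `h`. Parents equal to `root` attach directly to the root.
#' @param root Name of the root node. Default `"Y-Adam"`.
#' @param build Genome build tag, `"19"` or `"38"` (metadata only).
#' @return An object of class `haplo_tree`: a list with elements `root`,
#'   `parent` (named character), `children` (named list), `depth` (named
#'   integer, root = 0) and `build`.
#' @examples
#' tr <- haplo_tree(c(A = "Y-Adam", B = "A", C = "A"))
#' haplogroup_depth(tr, c("A", "C"))
#' @export
haplo_tree <- function(parents, root = "Y-Adam", build = "19") {
  stopifnot(is.character(parents), !is.null(names(parents)))
  nodes <- names(parents)
  if (anyDuplicated(nodes)) {
    dup <- nodes[duplicated(nodes)][1]
    pl_abort(paste0("haplogroup '", dup, "' defined more than once"),
             "patriline_structure_error")
  }
  if (root %in% nodes) {
    pl_abort("the root must not be listed as a child node",
             "patriline_structure_error")
  }
  orphan <- setdiff(parents, c(nodes, root))
  if (length(orphan)) {
    bad <- nodes[match(orphan[1], parents)]
    pl_abort(paste0("haplogroup '", bad, "' lists undefined parent '",
                    orphan[1], "'"), "patriline_structure_error")
  }
  # depths by iterative propagation; failure to converge means a cycle
  depth <- setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[parents == root] <- 1L
  repeat {
    known <- !is.na(depth)
    newly <- !known & parents %in% nodes[known]
    if (!any(newly)) break
    depth[newly] <- depth[parents[newly]] + 1L
  }
  if (anyNA(depth)) {
    pl_abort(paste0("cycle detected involving haplogroup '",
                    nodes[is.na(depth)][1], "'"), "patriline_structure_error")
  }
  children <- split(nodes, parents)[unique(parents)]
  structure(
    list(root = root, parent = parents,
         children = children,
         depth = c(setNames(0L, root), depth),
         build = as.character(build)),
    class = "haplo_tree")
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("<haplo_tree> ", length(x$parent), " haplogroups, root '", x$root,
      "', max depth ", max(x$depth), ", build hg", x$build, "\n", sep = "")
  invisible(x)
}

tree_nodes <- function(tree) names(tree$parent)

tree_children <- function(tree, name) tree$children[[name]] %||% character(0)

check_node <- function(tree, name) {
  bad <- setdiff(name, c(tree_nodes(tree), tree$root))
  if (length(bad)) {
    pl_abort(paste0("unknown haplogroup '", bad[1], "'"),
             "patriline_lookup_error")
  }
}

#' Depth (resolution) of a haplogroup
#'
#' The number of edges from the root to the haplogroup. Depth is the
#' operational definition of haplogroup *resolution* used by the lineage
#' classifier: the resolution `r` of a terminal haplogroup is its depth.
#'
#' @param tree A [haplo_tree].
#' @param name Character vector of haplogroup names.
#' @return Integer vector of depths; the root has depth 0.
#' @export
haplogroup_depth <- function(tree, name) {
  check_node(tree, name)
  unname(tree$depth[name])
}

#' Root-to-node path of a haplogroup
#'
#' @param tree A [haplo_tree].
#' @param name A single haplogroup name.
#' @param include_root Include the root as the first element?
#' @return Character vector of haplogroup names from (just below) the root
#'   down to `name`.
#' @export
haplogroup_path <- function(tree, name, include_root = FALSE) {
  check_node(tree, name)
  if (name == tree$root) return(if (include_root) tree$root else character(0))
  path <- name
  while ((p <- tree$parent[[path[1]]]) != tree$root) path <- c(p, path)
  if (include_root) c(tree$root, path) else path
}

#' Simplify a haplogroup to a fixed resolution level
#'
#' Replaces a haplogroup by its ancestor at tree depth `level`, so that
#' haplogroups classified at heterogeneous resolutions can be compared at
#' the same level (e.g. before computing population frequencies).
#' Haplogroups at or above the requested level are returned unchanged.
#'
#' @param name Character vector of haplogroup names.
#' @param level Target depth (>= 1).
#' @param tree A [haplo_tree].
#' @param scheme `"depth"` (default): ancestor at depth `level`;
#'   `"string"`: truncate ISOGG-style names to `level + 1` characters
#'   (e.g. "O2a1b" at level 2 becomes "O2a"). The string scheme is only
#'   meaningful for panels using ISOGG nomenclature.
#' @return Character vector of simplified haplogroup names.
#' @examples
#' tr <- haplo_tree(c(A = "Y-Adam", A1 = "A", A1a = "A1"))
#' simplify_haplogroup("A1a", 1, tr)
#' @export
simplify_haplogroup <- function(name, level, tree, scheme = c("depth", "string")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(level) || length(level) != 1 || level < 1) {
    pl_abort("`level` must be a single integer >= 1", "patriline_argument_error")
  }
  if (scheme == "string") {
    return(ifelse(nchar(name) <= level + 1, name, substr(name, 1, level + 1)))
  }
  check_node(tree, name)
  vapply(name, function(h) {
    if (h == tree$root) return(h)
    while (tree$depth[[h]] > level) h <- tree$parent[[h]]
    h
  }, character(1), USE.NAMES = FALSE)
}

#' Read a haplogroup marker panel
#'
#' Reads the tab-delimited marker panel that defines both the haplogroup
#' tree topology and the SNP markers attached to each haplogroup. The format
#' is a 7(+)-column TSV with a header row:
#'
#' | column | meaning |
#' |---|---|
#' | `haplogroup` | haplogroup name |
#' | `parent`     | its parent haplogroup (the root's children list the root name) |
#' | `marker`     | marker (SNP) identifier, or `.` for a structure-only row |
#' | `position`   | 1-based chrY coordinate (or `position_hg19` / `position_hg38`) |
#' | `ancestral`  | ancestral base (A/C/G/T) |
#' | `derived`    | derived base (A/C/G/T) |
#' | `key`        | 1 if a key (lab-standard, bold-on-tree) marker, else 0 |
#' | `ref`        | optional: reference-genome base at the position (defaults to `ancestral`) |
#'
#' Lines starting with `#` are ignored. Duplicate identical
#' (marker, haplogroup) rows are collapsed; duplicates with conflicting
#' alleles are an error. The same marker name may legitimately occur at
#' several haplogroups (recurrent mutation); each occurrence scores only its
#' own haplogroup.
#'
#' @param path Path to the panel TSV, or `"toy"` for the small packaged
#'   demonstration panel.
#' @param build `"19"` or `"38"`: which position column set to use when the
#'   panel carries both.
#' @param root Root node name.
#' @return An object of class `marker_panel`: list with `tree` (a
#'   [haplo_tree]) and `markers` (a tibble with columns `haplogroup`,
#'   `marker`, `position`, `ancestral`, `derived`, `key`, `ref`).
#' @export
read_marker_panel <- function(path, build = "19", root = "Y-Adam") {
  if (identical(path, "toy")) {
    path <- system.file("extdata", "toy_marker_panel.tsv", package = "patriline")
  }
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("haplogroup", "parent", "marker", "ancestral", "derived", "key")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    pl_abort(paste0("panel is missing column(s): ", paste(miss, collapse = ", ")),
             "patriline_parse_error")
  }
  poscol <- paste0("position_hg", build)
  if (!poscol %in% names(raw)) poscol <- "position"
  if (!poscol %in% names(raw)) {
    pl_abort(paste0("panel has neither 'position' nor 'position_hg", build,
                    "' column"), "patriline_parse_error")
  }
  raw$position <- as.integer(raw[[poscol]])
  if (!"ref" %in% names(raw)) raw$ref <- raw$ancestral
  marker_panel(as_tibble(raw[, c("haplogroup", "parent", "marker", "position",
                                 "ancestral", "derived", "key", "ref")]),
               build = build, root = root)
}

#' Assemble a marker panel from a tidy data frame
#'
#' Programmatic counterpart of [read_marker_panel()]: takes a data frame in
#' the panel schema and returns a validated `marker_panel`.
#'
#' @param df Data frame with columns `haplogroup`, `parent`, `marker`,
#'   `position`, `ancestral`, `derived`, `key` and optionally `ref`.
#' @inheritParams read_marker_panel
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(df, build = "19", root = "Y-Adam") {
  df <- as_tibble(df)
  if (!"ref" %in% names(df)) df$ref <- df$ancestral
  links <- distinct(df, .data$haplogroup, .data$parent)
  if (anyDuplicated(links$haplogroup)) {
    bad <- links$haplogroup[duplicated(links$haplogroup)][1]
    pl_abort(paste0("haplogroup '", bad, "' listed with two different parents"),
             "patriline_structure_error")
  }
  tree <- haplo_tree(setNames(links$parent, links$haplogroup),
                     root = root, build = build)
  mk <- filter(df, !is.na(.data$marker) & .data$marker != ".")
  if (nrow(mk)) {
    bad <- !is_acgt(mk$ancestral) | !is_acgt(mk$derived) | !is_acgt(mk$ref)
    if (any(bad)) {
      pl_abort(paste0("non-ACGT allele for marker '", mk$marker[bad][1], "'"),
               "patriline_parse_error")
    }
    if (any(mk$ancestral == mk$derived)) {
      m <- mk$marker[mk$ancestral == mk$derived][1]
      pl_abort(paste0("marker '", m, "' has identical ancestral and derived alleles"),
               "patriline_parse_error")
    }
    if (any(mk$position < 1, na.rm = TRUE) || anyNA(mk$position)) {
      pl_abort("marker positions must be integers >= 1", "patriline_parse_error")
    }
    mk <- distinct(mk, .data$haplogroup, .data$marker, .data$position,
                   .data$ancestral, .data$derived, .data$key, .data$ref)
    dup <- duplicated(mk[, c("haplogroup", "marker")])
    if (any(dup)) {
      m <- mk$marker[dup][1]
      pl_abort(paste0("marker '", m, "' listed twice at one haplogroup with ",
                      "conflicting definitions"), "patriline_conflict_error")
    }
  }
  structure(list(tree = tree,
                 markers = mutate(mk, key = as.integer(.data$key))),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(tree_nodes(x$tree)), " haplogroups, ",
      nrow(x$markers), " markers (", sum(x$markers$key), " key), build hg",
      x$tree$build, "\n", sep = "")
  invisible(x)
}

#' Write a marker panel back to TSV
#'
#' Inverse of [read_marker_panel()]; a written panel reloads to an identical
#' tree and marker set.
#'
#' @param panel A `marker_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  tree <- panel$tree
  nodes <- tree_nodes(tree)
  mk <- panel$markers
  bare <- setdiff(nodes, mk$haplogroup)   # structure-only rows
  rows <- bind_rows(
    mutate(mk, parent = unname(tree$parent[.data$haplogroup])),
    tibble(haplogroup = bare, parent = unname(tree$parent[bare]),
           marker = ".", position = 0L, ancestral = "A", derived = "C",
           key = 0L, ref = "A"))
  rows <- arrange(rows, unname(tree$depth[rows$haplogroup]), .data$haplogroup,
                  .data$marker)
  utils::write.table(
    rows[, c("haplogroup", "parent", "marker", "position", "ancestral",
             "derived", "key", "ref")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
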