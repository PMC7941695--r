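#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct pull rename n count across all_of
#' @importFrom stats setNames
NULL

# stop with a classed condition so callers/tests can distinguish error kinds
pl_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "patriline_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_acgt <- function(x) x %in% c("A", "C", "G", "T")

# deterministic seed derivation for sub-simulations; keeps values < 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}
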