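#' Deterministic seed derivation for parallel simulation streams
#'
#' Mixes two non-negative integers into a single seed in `[0, 2^31 - 2]`.
#' Cell- and replicate-level seeds are derived from a master seed by repeated
#' mixing, so results are identical regardless of the order in which grid
#' cells execute (and hence of the worker count). All arithmetic stays below
#' 2^53 and is exact in doubles.
#'
#' @param a,b non-negative integers (doubles accepted).
#' @return An integer seed suitable for [set.seed()].
#' @examples
#' mix_seed(42, 7)
#' @export
mix_seed <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1,
            is.finite(a), is.finite(b), a >= 0, b >= 0)
  m <- 2147483647  # 2^31 - 1
  x <- a %% m
  x <- (x * 69069 + b %% m + 1) %% m
  x <- (x * 69069 + 2846379) %% m
  as.integer(x)
}

#' @rdname mix_seed
#' @param master_seed master seed for the whole run.
#' @param cell_index zero- or one-based index of the grid cell.
#' @param replicate replicate index within the cell.
#' @export
replicate_seed <- function(master_seed, cell_index, replicate) {
  mix_seed(mix_seed(master_seed, cell_index), replicate)
}
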