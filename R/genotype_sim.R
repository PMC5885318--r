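#' Hardy-Weinberg genotype probabilities
#'
#' Probabilities of carrying 0, 1 or 2 copies of the minor allele under
#' Hardy-Weinberg equilibrium at minor allele frequency `maf`:
#' \deqn{(1-q)^2,\; 2q(1-q),\; q^2.}
#'
#' @param maf minor allele frequency, in `[0, 0.5]`. `maf = 0` is allowed as a
#'   degenerate case (monomorphic SNP); values above 0.5 are rejected because
#'   the minor allele is by definition the rarer one.
#' @return Named numeric triple `c(g0, g1, g2)` summing to 1.
#' @examples
#' hwe_genotype_probs(0.05)
#' @export
hwe_genotype_probs <- function(maf) {
  check_maf(maf, allow_zero = TRUE)
  c(g0 = (1 - maf)^2, g1 = 2 * maf * (1 - maf), g2 = maf^2)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual's minor-allele count is drawn i.i.d. from the multinomial
#' distribution given by [hwe_genotype_probs()]. Draws consume R's global
#' random number stream, so results are reproducible under [set.seed()].
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param n number of individuals (>= 1).
#' @return Integer vector of length `n` with entries in `{0, 1, 2}`.
#' @examples
#' set.seed(1)
#' table(draw_genotypes(0.25, 1000))
#' @export
draw_genotypes <- function(maf, n) {
  check_maf(maf, allow_zero = TRUE)
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (maf == 0) return(integer(n))
  sample.int(3L, n, replace = TRUE, prob = hwe_genotype_probs(maf)) - 1L
}

#' Draw a noise SNP
#'
#' Noise SNPs share the signal SNP's minor allele frequency but are assigned
#' independently of every phenotype, so any association with them is a false
#' positive. Distributionally identical to [draw_genotypes()].
#'
#' @inheritParams draw_genotypes
#' @return Integer genotype vector of length `n`.
#' @export
draw_noise_genotypes <- function(maf, n) {
  draw_genotypes(maf, n)
}

check_maf <- function(maf, allow_zero = FALSE) {
  if (!is.numeric(maf) || length(maf) != 1 || !is.finite(maf)) {
    stop("'maf' must be a single finite number", call. = FALSE)
  }
  lo_ok <- if (allow_zero) maf >= 0 else maf > 0
  if (!lo_ok || maf > 0.5) {
    stop(sprintf("'maf' must be in %s0, 0.5], got %g",
                 if (allow_zero) "[" else "(", maf), call. = FALSE)
  }
  invisible(maf)
}
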