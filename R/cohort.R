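#' Sample a case/control cohort under a penetrance model
#'
#' Retrospective (draw-until-quota) sampling: individuals are generated by
#' drawing a genotype from Hardy-Weinberg equilibrium at `maf` and then a
#' disease status `Bernoulli(f(g))`, and are accepted into the case or control
#' stratum until both quotas are filled. The genotype distribution among
#' accepted cases is therefore proportional to `HWE(g) * f(g)` and among
#' controls to `HWE(g) * (1 - f(g))` (see [expected_case_genotype_dist()]).
#' Draws beyond a filled stratum are discarded.
#'
#' @param pf a [penetrance_table()] object (or numeric triple `(f0, f1, f2)`).
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param n_cases number of cases (>= 1).
#' @param ratio controls per case (>= 1); non-integer control counts are
#'   rounded to the nearest integer.
#' @param max_draws cap on the total number of individuals generated before
#'   giving up (guards against degenerate penetrance functions that make a
#'   stratum unfillable).
#' @return An object of class `binary_cohort`: list with integer `genotypes`,
#'   0/1 integer `status` (cases first), `n_cases`, `n_controls`.
#' @examples
#' set.seed(1)
#' co <- sample_case_control(penetrance_table(0.1, 0.3), maf = 0.05,
#'                           n_cases = 100, ratio = 2)
#' table(co$status)
#' @export
sample_case_control <- function(pf, maf, n_cases, ratio = 1, max_draws = 1e7) {
  f <- as_penetrance_vec(pf)
  check_maf(maf, allow_zero = TRUE)
  stopifnot(is.numeric(n_cases), length(n_cases) == 1, n_cases >= 1,
            is.numeric(ratio), length(ratio) == 1, ratio >= 1)
  n_cases <- as.integer(n_cases)
  n_controls <- as.integer(round(n_cases * ratio))

  p_case <- marginal_case_prob(f, maf)
  case_g <- integer(0)
  ctrl_g <- integer(0)
  drawn <- 0
  while (length(case_g) < n_cases || length(ctrl_g) < n_controls) {
    if (drawn >= max_draws) {
      stop(sprintf(
        "case/control quota not filled after %g draws (P(case) = %.3g); %s",
        drawn, p_case, "degenerate penetrance function?"), call. = FALSE)
    }
    # size batches by the acceptance probability of the scarcer stratum
    need_ca <- n_cases - length(case_g)
    need_co <- n_controls - length(ctrl_g)
    exp_need <- 0
    if (need_ca > 0) exp_need <- max(exp_need, need_ca / max(p_case, 1e-12))
    if (need_co > 0) exp_need <- max(exp_need, need_co / max(1 - p_case, 1e-12))
    batch <- min(max(ceiling(1.2 * exp_need), 256), 2e6, max_draws - drawn)
    batch <- as.integer(batch)
    g <- draw_genotypes(maf, batch)
    s <- rbinom(batch, 1L, f[g + 1L])
    drawn <- drawn + batch
    if (need_ca > 0) {
      gc_new <- g[s == 1L]
      case_g <- c(case_g, gc_new[seq_len(min(need_ca, length(gc_new)))])
    }
    if (need_co > 0) {
      gn_new <- g[s == 0L]
      ctrl_g <- c(ctrl_g, gn_new[seq_len(min(need_co, length(gn_new)))])
    }
  }
  structure(
    list(genotypes = c(case_g, ctrl_g),
         status = rep(c(1L, 0L), c(n_cases, n_controls)),
         n_cases = n_cases, n_controls = n_controls),
    class = "binary_cohort"
  )
}

#' Sample a quantitative-trait cohort
#'
#' Genotypes are drawn from Hardy-Weinberg equilibrium and the trait is
#' `Y = beta * g + eps`, `eps ~ Normal(0, 1)`, where `beta` comes from
#' [liability_effect_size()] so that the same penetrance function drives both
#' binary and quantitative simulations.
#'
#' @param beta per-allele mean shift (trait units per minor allele).
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param n sample size (>= 2).
#' @return An object of class `quant_cohort`: list with integer `genotypes`
#'   and numeric `trait`.
#' @examples
#' set.seed(1)
#' qc <- sample_quantitative(liability_effect_size(0.1, 0.3), 0.25, 500)
#' tapply(qc$trait, qc$genotypes, mean)
#' @export
sample_quantitative <- function(beta, maf, n) {
  stopifnot(is.numeric(beta), length(beta) == 1, is.finite(beta))
  check_maf(maf, allow_zero = TRUE)
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  g <- draw_genotypes(maf, n)
  structure(
    list(genotypes = g, trait = beta * g + rnorm(n)),
    class = "quant_cohort"
  )
}

#' Generate a noise phenotype matched to a cohort
#'
#' Noise phenotypes are independent of every genotype. For a binary cohort the
#' case labels are reassigned by a uniformly random permutation of the status
#' vector, preserving the case and control counts exactly; for a quantitative
#' cohort a fresh `Normal(0, 1)` vector is drawn.
#'
#' @param template a `binary_cohort` or `quant_cohort`.
#' @return A phenotype vector of the same length as the template cohort.
#' @export
make_noise_phenotype <- function(template) {
  UseMethod("make_noise_phenotype")
}

#' @export
make_noise_phenotype.binary_cohort <- function(template) {
  sample(template$status)
}

#' @export
make_noise_phenotype.quant_cohort <- function(template) {
  rnorm(length(template$trait))
}
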