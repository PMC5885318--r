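#' Additive-risk penetrance function
#'
#' A penetrance function gives the disease probability for each minor-allele
#' count: `f0 = P(case | g = 0)`, `f1`, `f2`. The simulation parameterises it
#' by the baseline prevalence among non-carriers (`f0`, the regression
#' intercept on the risk scale, 0.1 by default) and the homozygous-carrier
#' penetrance (`f2`); the heterozygote risk is the midpoint, i.e. additive on
#' the risk scale. `penetrance = baseline` gives the null model.
#'
#' @param baseline prevalence for genotype 0, in `(0, 1]`.
#' @param penetrance disease probability for genotype 2; must satisfy
#'   `baseline <= penetrance <= 1` (protective minor alleles are not modelled).
#' @return An object of class `penetrance_fn`: list with `f0`, `f1`, `f2`.
#' @examples
#' penetrance_table(0.1, 0.3)   # (0.10, 0.20, 0.30)
#' @export
penetrance_table <- function(baseline = 0.1, penetrance) {
  stopifnot(is.numeric(baseline), length(baseline) == 1,
            is.numeric(penetrance), length(penetrance) == 1)
  if (!(baseline > 0 && baseline <= 1)) {
    stop("'baseline' must be in (0, 1]", call. = FALSE)
  }
  if (!(penetrance >= baseline && penetrance <= 1)) {
    stop("'penetrance' must satisfy baseline <= penetrance <= 1 ",
         "(protective coding not modelled)", call. = FALSE)
  }
  structure(
    list(f0 = baseline, f1 = (baseline + penetrance) / 2, f2 = penetrance),
    class = "penetrance_fn"
  )
}

#' @export
print.penetrance_fn <- function(x, ...) {
  cat(sprintf("Penetrance function: f0 = %g, f1 = %g, f2 = %g\n",
              x$f0, x$f1, x$f2))
  invisible(x)
}

# Accept a penetrance_fn or a bare numeric triple (f0, f1, f2).
as_penetrance_vec <- function(pf) {
  if (inherits(pf, "penetrance_fn")) {
    c(pf$f0, pf$f1, pf$f2)
  } else if (is.numeric(pf) && length(pf) == 3) {
    if (any(pf < 0 | pf > 1)) stop("penetrance values must be probabilities",
                                   call. = FALSE)
    as.numeric(pf)
  } else {
    stop("'pf' must be a penetrance_fn or a numeric triple", call. = FALSE)
  }
}

#' Genotype distribution among cases (or controls)
#'
#' Closed-form genotype distribution in the case stratum under retrospective
#' sampling: by Bayes' rule the probability of genotype `g` among cases is
#' proportional to `HWE(g) * f(g)`; among controls, to `HWE(g) * (1 - f(g))`.
#' These are the analytic oracles for the case/control sampler.
#'
#' @param pf a [penetrance_table()] object or numeric triple `(f0, f1, f2)`.
#' @param maf minor allele frequency.
#' @return Named probability triple over genotypes 0, 1, 2.
#' @examples
#' expected_case_genotype_dist(penetrance_table(0.1, 0.3), maf = 0.05)
#' @export
expected_case_genotype_dist <- function(pf, maf) {
  f <- as_penetrance_vec(pf)
  w <- hwe_genotype_probs(maf) * f
  s <- sum(w)
  if (s <= 0) stop("P(case) is zero for this penetrance/MAF", call. = FALSE)
  w / s
}

#' @rdname expected_case_genotype_dist
#' @export
expected_control_genotype_dist <- function(pf, maf) {
  f <- as_penetrance_vec(pf)
  w <- hwe_genotype_probs(maf) * (1 - f)
  s <- sum(w)
  if (s <= 0) stop("P(control) is zero for this penetrance/MAF", call. = FALSE)
  w / s
}

#' Marginal disease probability under a penetrance function
#'
#' `P(case) = sum_g HWE(g) f(g)` — the acceptance probability of the case
#' stratum in retrospective sampling.
#'
#' @inheritParams expected_case_genotype_dist
#' @return A probability.
#' @export
marginal_case_prob <- function(pf, maf) {
  sum(hwe_genotype_probs(maf) * as_penetrance_vec(pf))
}

#' Per-allele effect size on the liability scale
#'
#' Converts a (baseline, penetrance) pair into the mean shift per minor allele
#' of a standard-normal quantitative trait. The trait is modelled as
#' `Y | g ~ Normal(beta * g, 1)` with the case threshold fixed at the
#' `1 - baseline` quantile of the non-carrier distribution, so that
#' non-carriers exceed it with probability `baseline` and homozygous carriers
#' with probability `penetrance`:
#' \deqn{\beta = \{\Phi^{-1}(1 - f_0) - \Phi^{-1}(1 - f_2)\} / 2.}
#' This reuses the binary penetrance function to drive genotype enrichment in
#' the upper tail of the trait distribution.
#'
#' @param baseline tail probability for genotype 0, in `(0, 1)`.
#' @param penetrance tail probability for genotype 2, in `[baseline, 1)`.
#' @return Non-negative per-allele mean shift; 0 iff `penetrance == baseline`.
#' @examples
#' liability_effect_size(0.1, 0.3)    # 0.37858
#' liability_effect_size(0.1, 0.15)   # 0.12256
#' @export
liability_effect_size <- function(baseline, penetrance) {
  stopifnot(is.numeric(baseline), length(baseline) == 1,
            is.numeric(penetrance), length(penetrance) == 1)
  if (!(baseline > 0 && baseline < 1) || !(penetrance > 0 && penetrance < 1)) {
    stop("'baseline' and 'penetrance' must be in (0, 1)", call. = FALSE)
  }
  if (penetrance < baseline) {
    stop("'penetrance' must be >= 'baseline'", call. = FALSE)
  }
  (qnorm(1 - baseline) - qnorm(1 - penetrance)) / 2
}
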