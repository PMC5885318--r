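#' Per-test significance threshold
#'
#' Bonferroni-style division of a family-wise level by the number of tests in
#' one replicate dataset: 40 tests (4 SNPs x 10 phenotypes) for binary traits
#' gives `0.01 / 40 = 0.00025`; 4 tests (4 SNPs x 1 phenotype) for
#' quantitative traits gives `0.01 / 4 = 0.004`.
#'
#' @param family_level family-wise significance level, in `(0, 1)`.
#' @param n_tests number of tests per replicate (>= 1).
#' @return The per-test threshold `family_level / n_tests`.
#' @examples
#' alpha_threshold(0.01, 40)
#' alpha_threshold(0.01, 4)
#' @export
alpha_threshold <- function(family_level, n_tests) {
  stopifnot(is.numeric(family_level), length(family_level) == 1,
            family_level > 0, family_level < 1,
            is.numeric(n_tests), length(n_tests) == 1)
  if (n_tests < 1) stop("'n_tests' must be >= 1", call. = FALSE)
  family_level / n_tests
}

#' Define one cell of the simulation grid
#'
#' A design fixes everything needed to simulate one parameter combination:
#' the trait type, the cohort size (case count and controls-per-case ratio for
#' binary traits; total `n` for quantitative), the signal SNP's minor allele
#' frequency and penetrance, the baseline prevalence, the replicate count and
#' the per-test significance threshold. Each replicate dataset contains 4 SNPs
#' (1 signal + 3 noise at the same MAF) and 10 phenotypes (binary; 1 signal +
#' 9 noise) or 1 phenotype (quantitative), i.e. 40 or 4 tests, exactly one of
#' which carries signal.
#'
#' @param trait `"binary"` or `"quantitative"`.
#' @param n_cases,ratio case count and controls-per-case ratio (binary only).
#' @param n total sample size (quantitative only).
#' @param maf signal-SNP minor allele frequency, in `(0, 0.5]`.
#' @param penetrance homozygous-carrier penetrance `f2`, in `[baseline, 1]`.
#' @param baseline baseline prevalence `f0` (default 0.1).
#' @param replicates simulated datasets per cell (default 1000).
#' @param alpha per-test significance threshold; defaults to
#'   `alpha_threshold(0.01, 40) = 0.00025` for binary designs and to `0.004`
#'   for quantitative designs (the threshold the quantitative 4-test battery
#'   is calibrated at; always explicit in outputs and overridable).
#' @return An object of class `sim_design`.
#' @examples
#' sim_design("binary", n_cases = 10, ratio = 2, maf = 0.01, penetrance = 0.15)
#' @export
sim_design <- function(trait = c("binary", "quantitative"),
                       n_cases = NULL, ratio = NULL, n = NULL,
                       maf, penetrance, baseline = 0.1,
                       replicates = 1000, alpha = NULL) {
  trait <- match.arg(trait)
  check_maf(maf)
  stopifnot(is.numeric(penetrance), length(penetrance) == 1,
            is.numeric(baseline), length(baseline) == 1,
            is.numeric(replicates), length(replicates) == 1, replicates >= 1)
  if (!(baseline > 0 && baseline <= penetrance && penetrance <= 1)) {
    stop("need 0 < baseline <= penetrance <= 1", call. = FALSE)
  }
  if (trait == "binary") {
    if (is.null(n_cases) || is.null(ratio)) {
      stop("binary designs need 'n_cases' and 'ratio'", call. = FALSE)
    }
    stopifnot(n_cases >= 1, ratio >= 1)
    n_cases <- as.integer(n_cases)
    n <- n_cases + as.integer(round(n_cases * ratio))
    n_phenotypes <- 10L
  } else {
    if (is.null(n)) stop("quantitative designs need 'n'", call. = FALSE)
    stopifnot(n >= 2)
    n <- as.integer(n)
    n_cases <- NA_integer_
    ratio <- NA_real_
    n_phenotypes <- 1L
  }
  n_snps <- 4L
  if (is.null(alpha)) {
    alpha <- if (trait == "binary") alpha_threshold(0.01, 40) else 0.004
  }
  stopifnot(alpha > 0, alpha < 1)
  structure(
    list(trait = trait, n_cases = n_cases, ratio = ratio, n = n,
         maf = maf, penetrance = penetrance, baseline = baseline,
         n_snps = n_snps, n_phenotypes = n_phenotypes,
         replicates = as.integer(replicates), alpha = alpha),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  if (x$trait == "binary") {
    cat(sprintf(
      "Binary design: %d cases, 1:%g ratio (n = %d), MAF %g, penetrance %g (f0 = %g)\n",
      x$n_cases, x$ratio, x$n, x$maf, x$penetrance, x$baseline))
  } else {
    cat(sprintf(
      "Quantitative design: n = %d, MAF %g, penetrance %g (f0 = %g)\n",
      x$n, x$maf, x$penetrance, x$baseline))
  }
  cat(sprintf("  %d SNPs x %d phenotypes (%d tests, 1 signal), %d replicates, alpha = %g\n",
              x$n_snps, x$n_phenotypes, x$n_snps * x$n_phenotypes,
              x$replicates, x$alpha))
  invisible(x)
}

#' Assemble one replicate dataset
#'
#' Builds the per-replicate data layout: a genotype matrix whose first column
#' is the signal SNP and remaining columns are independent noise SNPs at the
#' same MAF, and a phenotype matrix whose first column is the signal phenotype
#' generated from the signal SNP through the penetrance model. Binary designs
#' add 9 noise phenotypes, each a random permutation of the case/control
#' labels (so every phenotype column has identical case and control counts).
#' Every (SNP, phenotype) pair is one association test; only the (1, 1) pair
#' carries signal.
#'
#' @param design a [sim_design()].
#' @return List of class `replicate_dataset` with `genotypes` (n x 4 integer
#'   matrix), `phenotypes` (n x 10 or n x 1 matrix), `trait`, and the design.
#' @export
assemble_replicate <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (design$trait == "binary") {
    pf <- penetrance_table(design$baseline, design$penetrance)
    cohort <- sample_case_control(pf, design$maf, design$n_cases, design$ratio)
    n <- length(cohort$status)
    G <- matrix(0L, n, design$n_snps,
                dimnames = list(NULL, paste0("snp", seq_len(design$n_snps))))
    G[, 1L] <- cohort$genotypes
    for (j in seq_len(design$n_snps - 1L) + 1L) {
      G[, j] <- draw_noise_genotypes(design$maf, n)
    }
    P <- matrix(0L, n, design$n_phenotypes,
                dimnames = list(NULL, paste0("phe", seq_len(design$n_phenotypes))))
    P[, 1L] <- cohort$status
    for (k in seq_len(design$n_phenotypes - 1L) + 1L) {
      P[, k] <- make_noise_phenotype(cohort)
    }
  } else {
    beta <- liability_effect_size(design$baseline, design$penetrance)
    cohort <- sample_quantitative(beta, design$maf, design$n)
    n <- design$n
    G <- matrix(0L, n, design$n_snps,
                dimnames = list(NULL, paste0("snp", seq_len(design$n_snps))))
    G[, 1L] <- cohort$genotypes
    for (j in seq_len(design$n_snps - 1L) + 1L) {
      G[, j] <- draw_noise_genotypes(design$maf, n)
    }
    P <- matrix(cohort$trait, n, 1L, dimnames = list(NULL, "phe1"))
  }
  structure(
    list(genotypes = G, phenotypes = P, trait = design$trait,
         signal_snp = 1L, signal_phenotype = 1L, design = design),
    class = "replicate_dataset"
  )
}

#' Estimate power and Type I error for one grid cell
#'
#' Simulates `design$replicates` datasets, fits every (SNP, phenotype) pair
#' with the additive logistic (binary) or linear (quantitative) test, and
#' counts rejections at `design$alpha`. Power is the fraction of replicates in
#' which the single signal pair rejects; Type I error is the fraction of noise
#' tests (39 or 3 per replicate) that reject. Non-converged fits count as
#' non-significant and are tallied in `n_nonconverged`. The per-replicate seed
#' is derived from `master_seed` and `cell_index` via [replicate_seed()], so
#' results do not depend on execution order.
#'
#' @param design a [sim_design()].
#' @param master_seed integer master seed.
#' @param cell_index index of this cell within a grid (any fixed integer).
#' @return One-row `data.frame` of class `power_estimate` with the design
#'   fields, `power`, `type1`, Monte-Carlo standard errors, test counts and
#'   the non-convergence tally.
#' @examples
#' d <- sim_design("binary", n_cases = 50, ratio = 1, maf = 0.25,
#'                 penetrance = 0.3, replicates = 50)
#' run_cell(d, master_seed = 1)
#' @export
run_cell <- function(design, master_seed = 1L, cell_index = 0L) {
  stopifnot(inherits(design, "sim_design"))
  R <- design$replicates
  n_pairs <- design$n_snps * design$n_phenotypes
  n_noise_pairs <- n_pairs - 1L
  sig_rej <- 0L
  noise_rej <- 0L
  nonconv <- 0L
  fitfun <- if (design$trait == "binary") fit_logistic_additive else fit_linear_additive
  for (r in seq_len(R)) {
    set.seed(replicate_seed(master_seed, cell_index, r))
    dat <- assemble_replicate(design)
    for (j in seq_len(ncol(dat$genotypes))) {
      gj <- dat$genotypes[, j]
      for (k in seq_len(ncol(dat$phenotypes))) {
        fit <- fitfun(gj, dat$phenotypes[, k])
        if (!fit$converged) nonconv <- nonconv + 1L
        hit <- fit$converged && !is.na(fit$pvalue) && fit$pvalue < design$alpha
        if (j == dat$signal_snp && k == dat$signal_phenotype) {
          if (hit) sig_rej <- sig_rej + 1L
        } else if (hit) {
          noise_rej <- noise_rej + 1L
        }
      }
    }
  }
  power <- sig_rej / R
  n_noise_tests <- R * n_noise_pairs
  type1 <- noise_rej / n_noise_tests
  out <- data.frame(
    trait = design$trait, n_cases = design$n_cases, ratio = design$ratio,
    n = design$n, maf = design$maf, penetrance = design$penetrance,
    baseline = design$baseline, replicates = R, alpha = design$alpha,
    power = power, type1 = type1,
    n_signal_tests = R, n_noise_tests = n_noise_tests,
    mc_se_power = sqrt(power * (1 - power) / R),
    mc_se_type1 = sqrt(type1 * (1 - type1) / n_noise_tests),
    n_nonconverged = nonconv,
    stringsAsFactors = FALSE
  )
  class(out) <- c("power_estimate", class(out))
  out
}

#' Run a grid of simulation designs
#'
#' Applies [run_cell()] to each design; per-cell seeds are derived from the
#' master seed and the cell's position in the list, so the result table is
#' identical for any `workers` value. Cell failures are caught and recorded in
#' the `error` column; the rest of the grid continues.
#'
#' @param grid list of [sim_design()] objects.
#' @param master_seed integer master seed.
#' @param workers number of forked workers (`parallel::mclapply`); 1 runs
#'   sequentially.
#' @return A `data.frame` with one row per cell (design fields, power, type1,
#'   Monte-Carlo standard errors, diagnostics, `error`).
#' @export
run_grid <- function(grid, master_seed = 1L, workers = 1L) {
  stopifnot(is.list(grid), length(grid) >= 1)
  lapply(grid, function(d) stopifnot(inherits(d, "sim_design")))
  run1 <- function(i) {
    tryCatch({
      row <- run_cell(grid[[i]], master_seed = master_seed, cell_index = i)
      row$error <- NA_character_
      row
    }, error = function(e) {
      d <- grid[[i]]
      data.frame(
        trait = d$trait, n_cases = d$n_cases, ratio = d$ratio, n = d$n,
        maf = d$maf, penetrance = d$penetrance, baseline = d$baseline,
        replicates = d$replicates, alpha = d$alpha,
        power = NA_real_, type1 = NA_real_,
        n_signal_tests = NA_integer_, n_noise_tests = NA_integer_,
        mc_se_power = NA_real_, mc_se_type1 = NA_real_,
        n_nonconverged = NA_integer_,
        error = conditionMessage(e), stringsAsFactors = FALSE
      )
    })
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(seq_along(grid), run1, mc.cores = workers)
  } else {
    lapply(seq_along(grid), run1)
  }
  out <- as.data.frame(data.table::rbindlist(rows))
  class(out) <- c("power_estimate", class(out))
  out
}

#' Closed-form power for the quantitative simulation
#'
#' Normal-approximation power of the two-sided slope test in the model
#' `Y = beta * g + eps` with `g ~ HWE(maf)` and unit error variance:
#' \deqn{\Phi(-z_{1-\alpha/2} + \lambda) + \Phi(-z_{1-\alpha/2} - \lambda),
#'   \quad \lambda = \beta \sqrt{2\,maf(1-maf)\,n}.}
#' Used as an independent oracle for the simulated quantitative power.
#'
#' @param beta per-allele mean shift.
#' @param maf minor allele frequency.
#' @param n sample size.
#' @param alpha two-sided significance level.
#' @return Approximate power in `[0, 1]`.
#' @examples
#' analytic_power_linear(liability_effect_size(0.1, 0.15), 0.05, 5000, 0.004)
#' @export
analytic_power_linear <- function(beta, maf, n, alpha) {
  check_maf(maf, allow_zero = TRUE)
  stopifnot(alpha > 0, alpha < 1, n > 0)
  zc <- qnorm(1 - alpha / 2)
  lam <- beta * sqrt(2 * maf * (1 - maf) * n)
  pnorm(-zc + lam) + pnorm(-zc - lam)
}
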