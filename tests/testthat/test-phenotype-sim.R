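test_that("additive-risk penetrance tables interpolate the heterozygote", {
  pf <- penetrance_table(0.1, 0.3)
  expect_equal(c(pf$f0, pf$f1, pf$f2), c(0.10, 0.20, 0.30))
  pf <- penetrance_table(0.1, 0.15)
  expect_equal(c(pf$f0, pf$f1, pf$f2), c(0.10, 0.125, 0.15))
  null <- penetrance_table(0.1, 0.1)
  expect_equal(c(null$f0, null$f1, null$f2), rep(0.1, 3))
  expect_error(penetrance_table(0.1, 0.05), "penetrance")
  expect_error(penetrance_table(0, 0.3), "baseline")
})

test_that("case/control genotype distributions follow Bayes enumeration", {
  pf <- penetrance_table(0.1, 0.3)
  expect_equal(unname(expected_case_genotype_dist(pf, 0.05)),
               c(0.82045, 0.17273, 0.00682), tolerance = 1e-4)
  expect_equal(unname(expected_case_genotype_dist(c(1, 1, 1), 0.2)),
               unname(hwe_genotype_probs(0.2)))
  expect_equal(unname(expected_case_genotype_dist(c(0, 0, 1), 0.05)),
               c(0, 0, 1))
  expect_equal(marginal_case_prob(pf, 0.05), 0.11)
  # control stratum analogue: HWE(g) (1 - f(g)) / 0.89
  expect_equal(unname(expected_control_genotype_dist(pf, 0.05)),
               c(0.9025 * 0.9, 0.095 * 0.8, 0.0025 * 0.7) / 0.89)
})

test_that("retrospective sampler reproduces the analytic stratum distributions", {
  combos <- list(
    list(pf = penetrance_table(0.1, 0.3), maf = 0.05),
    list(pf = penetrance_table(0.1, 0.3), maf = 0.25),
    list(pf = penetrance_table(0.1, 0.15), maf = 0.05),
    list(pf = penetrance_table(0.1, 0.15), maf = 0.25),
    list(pf = penetrance_table(0.1, 0.2), maf = 0.1),
    list(pf = penetrance_table(0.1, 0.25), maf = 0.01)
  )
  set.seed(303)
  for (cmb in combos) {
    co <- sample_case_control(cmb$pf, cmb$maf, n_cases = 1e5, ratio = 1)
    expect_identical(sum(co$status), 100000L)
    expect_identical(length(co$genotypes), 200000L)
    case_counts <- tabulate(co$genotypes[co$status == 1L] + 1L, 3L)
    ctrl_counts <- tabulate(co$genotypes[co$status == 0L] + 1L, 3L)
    expect_gt(gof_pvalue(case_counts,
                         expected_case_genotype_dist(cmb$pf, cmb$maf)), 0.001)
    expect_gt(gof_pvalue(ctrl_counts,
                         expected_control_genotype_dist(cmb$pf, cmb$maf)), 0.001)
  }
})

test_that("under the null penetrance, status is independent of genotype", {
  set.seed(304)
  pf <- penetrance_table(0.1, 0.1)
  co <- sample_case_control(pf, 0.25, n_cases = 5e4, ratio = 1)
  case_counts <- tabulate(co$genotypes[co$status == 1L] + 1L, 3L)
  ctrl_counts <- tabulate(co$genotypes[co$status == 0L] + 1L, 3L)
  hwe <- hwe_genotype_probs(0.25)
  expect_gt(gof_pvalue(case_counts, hwe), 0.001)
  expect_gt(gof_pvalue(ctrl_counts, hwe), 0.001)
  # empirical per-allele odds ratio near 1
  af_ca <- mean(co$genotypes[co$status == 1L]) / 2
  af_co <- mean(co$genotypes[co$status == 0L]) / 2
  or <- (af_ca / (1 - af_ca)) / (af_co / (1 - af_co))
  expect_lt(abs(log(or)), 0.05)
})

test_that("degenerate penetrance makes a stratum unfillable", {
  expect_error(
    sample_case_control(c(0, 0, 0), 0.25, n_cases = 10, ratio = 1,
                        max_draws = 1e4),
    "quota")
})

test_that("liability effect size matches normal-quantile arithmetic", {
  expect_equal(liability_effect_size(0.1, 0.3),
               (qnorm(0.9) - qnorm(0.7)) / 2)
  expect_equal(liability_effect_size(0.1, 0.3), 0.37857, tolerance = 1e-4)
  expect_equal(liability_effect_size(0.1, 0.15), 0.12256, tolerance = 1e-4)
  expect_identical(liability_effect_size(0.1, 0.1), 0)
  # monotone increasing in penetrance at fixed baseline
  pens <- seq(0.1, 0.9, by = 0.05)
  betas <- vapply(pens, function(p) liability_effect_size(0.1, p), numeric(1))
  expect_true(all(diff(betas) > 0))
  expect_error(liability_effect_size(0.1, 1), "penetrance")
})

test_that("quantitative cohorts have the designed slope and standard-normal residuals", {
  set.seed(305)
  beta <- liability_effect_size(0.1, 0.3)
  qc <- sample_quantitative(beta, 0.25, 1e5)
  fit <- fit_linear_additive(qc$genotypes, qc$trait)
  expect_lt(abs(fit$beta - beta), 4 * fit$se)
  # residuals about genotype-group means are standard normal
  centred <- qc$trait - ave(qc$trait, qc$genotypes)
  expect_gt(suppressWarnings(ks.test(centred, "pnorm", 0, sd(centred))$p.value),
            0.001)
  expect_lt(abs(sd(centred) - 1), 0.02)
  # maf = 0: trait is pure standard normal noise
  qc0 <- sample_quantitative(beta, 0, 1e5)
  expect_identical(qc0$genotypes, integer(1e5))
  expect_gt(suppressWarnings(ks.test(qc0$trait, "pnorm")$p.value), 0.001)
})

test_that("noise phenotypes preserve counts and are independent of genotypes", {
  set.seed(306)
  co <- sample_case_control(penetrance_table(0.1, 0.15), 0.01,
                            n_cases = 10, ratio = 2)
  noise <- make_noise_phenotype(co)
  expect_identical(sum(noise), 10L)
  expect_identical(length(noise), 30L)
  # different rng substreams give different permutations (w.h.p.)
  expect_false(identical(make_noise_phenotype(co), make_noise_phenotype(co)))
  # quantitative template: fresh normals of matching length
  qc <- sample_quantitative(0.3, 0.25, 50)
  expect_identical(length(make_noise_phenotype(qc)), 50L)
})

test_that("noise phenotypes reject at the nominal rate against the signal SNP", {
  set.seed(307)
  alpha <- alpha_threshold(0.01, 40)
  reps <- 2000
  rej <- 0L
  pf <- penetrance_table(0.1, 0.3)
  for (r in seq_len(reps)) {
    co <- sample_case_control(pf, 0.25, n_cases = 100, ratio = 2)
    noise <- make_noise_phenotype(co)
    fit <- fit_logistic_additive(co$genotypes, noise)
    if (fit$converged && fit$pvalue < alpha) rej <- rej + 1L
  }
  expect_in_binom99(rej, reps, alpha)
})
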