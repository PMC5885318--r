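# Independent oracles and small utilities shared across the test files.
# These deliberately avoid the package's own code paths.

# Maximum-likelihood logistic fit via a generic numerical optimiser on the
# raw (non-aggregated) log-likelihood.
oracle_logistic_ml <- function(g, y) {
  nll <- function(b) {
    eta <- b[1] + b[2] * g
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  vcv <- solve(fit$hessian)
  list(beta = fit$par[2], se = sqrt(vcv[2, 2]), convergence = fit$convergence)
}

# Closed-form OLS slope inference via explicit normal equations.
oracle_ols <- function(g, y) {
  X <- cbind(1, g)
  xtx_inv <- solve(t(X) %*% X)
  b <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - 2)
  se <- sqrt(s2 * xtx_inv[2, 2])
  tt <- b[2] / se
  list(beta = as.numeric(b[2]), se = as.numeric(se), stat = as.numeric(tt),
       pvalue = 2 * pt(-abs(tt), length(y) - 2))
}

# Two-proportion normal-approximation power oracle for the binary design:
# contrasts the minor allele frequency of cases vs controls implied by the
# penetrance function, on the log-odds scale.
oracle_power_binary <- function(baseline, penetrance, maf, n_cases, ratio,
                                alpha) {
  pf <- phewaspower::penetrance_table(baseline, penetrance)
  pc <- phewaspower::expected_case_genotype_dist(pf, maf)
  pn <- phewaspower::expected_control_genotype_dist(pf, maf)
  af_ca <- (pc[2] + 2 * pc[3]) / 2
  af_co <- (pn[2] + 2 * pn[3]) / 2
  lor <- log(af_ca / (1 - af_ca)) - log(af_co / (1 - af_co))
  n_controls <- round(n_cases * ratio)
  se <- sqrt(1 / (2 * n_cases * af_ca * (1 - af_ca)) +
             1 / (2 * n_controls * af_co * (1 - af_co)))
  zc <- qnorm(1 - alpha / 2)
  unname(pnorm(-zc + lor / se) + pnorm(-zc - lor / se))
}

# Acceptance region (exact binomial, two-sided 99%) for a rejection count
# out of n trials at nominal probability p.
binom99_region <- function(p, n) {
  c(lo = qbinom(0.005, n, p), hi = qbinom(0.995, n, p))
}

expect_in_binom99 <- function(k, n, p, label = "") {
  reg <- binom99_region(p, n)
  expect_gte(k, reg[["lo"]])
  expect_lte(k, reg[["hi"]])
}

# Chi-square goodness-of-fit p-value of observed genotype counts against a
# probability triple (no package code involved).
gof_pvalue <- function(counts, probs) {
  keep <- probs > 0
  suppressWarnings(chisq.test(counts[keep], p = probs[keep] / sum(probs[keep]))$p.value)
}

# Brute-force recount of rule-of-three case counts: nested loops over
# patients and codes, counting unique dates.
brute_force_case_counts <- function(records, min_visits = 3) {
  records <- as.data.frame(records)
  codes <- sort(unique(records$code))
  out <- data.frame(code = codes, n_cases = 0L)
  for (i in seq_along(codes)) {
    sub <- records[records$code == codes[i], ]
    n <- 0L
    for (p in unique(sub$patient_id)) {
      if (length(unique(sub$date[sub$patient_id == p])) >= min_visits) {
        n <- n + 1L
      }
    }
    out$n_cases[i] <- n
  }
  out
}
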