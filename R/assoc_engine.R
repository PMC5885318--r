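#' Single-SNP association tests under the additive model
#'
#' `fit_logistic_additive()` fits `logit P(case) = b0 + b1 * g` by
#' Newton-Raphson / iteratively reweighted least squares on the
#' genotype-aggregated sufficient statistics (per-genotype totals and case
#' counts), stopping when the log-likelihood changes by less than `1e-8` or
#' after 50 iterations. `fit_linear_additive()` fits ordinary least squares
#' `y = b0 + b1 * g` with a two-sided t-test on the slope (`n - 2` df).
#' Both report a two-sided Wald p-value on the per-allele coefficient.
#'
#' Degenerate inputs never raise errors inside a power run: a constant
#' genotype, a single-class status vector, or (quasi-)separation yields a
#' result with `converged = FALSE` and an `NA` p-value, which the power engine
#' counts as non-significant and tallies separately.
#'
#' @param genotypes integer vector of minor-allele counts in `{0, 1, 2}`.
#' @param status 0/1 integer vector (1 = case), same length as `genotypes`.
#' @return An object of class `assoc_result`: list with `beta`, `se`, `stat`
#'   (Wald z or t), `pvalue`, `converged`, `n`, `df` (`NA` for logistic) and
#'   `note` (diagnostic string or `NA`).
#' @examples
#' set.seed(1)
#' co <- sample_case_control(penetrance_table(0.1, 0.3), 0.25, 200, 1)
#' fit_logistic_additive(co$genotypes, co$status)
#' @export
fit_logistic_additive <- function(genotypes, status) {
  n <- length(status)
  if (length(genotypes) != n) stop("length mismatch", call. = FALSE)
  idx <- as.integer(genotypes) + 1L
  ng <- tabulate(idx, 3L)
  kg <- tabulate(idx[status == 1L], 3L)
  k <- sum(kg)
  if (sum(ng > 0L) < 2L) {
    return(assoc_result(converged = FALSE, n = n, note = "constant genotype"))
  }
  if (k == 0L || k == n) {
    return(assoc_result(converged = FALSE, n = n, note = "single-class status"))
  }

  g <- c(0, 1, 2)
  b <- c(qlogis(k / n), 0)
  ll_old <- logistic_loglik(b, g, ng, kg)
  iter_ok <- FALSE
  info <- NULL
  for (it in seq_len(50L)) {
    eta <- b[1] + b[2] * g
    mu <- plogis(eta)
    w <- ng * mu * (1 - mu)
    score <- c(sum(kg - ng * mu), sum((kg - ng * mu) * g))
    info <- matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g * g)), 2L, 2L)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # step-halve if the likelihood would decrease
    b_new <- b + step
    ll_new <- logistic_loglik(b_new, g, ng, kg)
    h <- 0L
    while (ll_new < ll_old && h < 10L) {
      step <- step / 2
      b_new <- b + step
      ll_new <- logistic_loglik(b_new, g, ng, kg)
      h <- h + 1L
    }
    b <- b_new
    if (abs(ll_new - ll_old) < 1e-8) {
      iter_ok <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  if (!iter_ok || is.null(info)) {
    return(assoc_result(converged = FALSE, n = n, note = "no convergence"))
  }
  eta <- b[1] + b[2] * g
  mu <- plogis(eta)
  w <- ng * mu * (1 - mu)
  info <- matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g * g)), 2L, 2L)
  vcv <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vcv)) NA_real_ else sqrt(vcv[2L, 2L])
  if (!is.finite(se) || se <= 0 || max(abs(b)) > 15) {
    return(assoc_result(converged = FALSE, n = n, note = "separation"))
  }
  z <- b[2] / se
  assoc_result(beta = b[2], se = se, stat = z,
               pvalue = 2 * pnorm(-abs(z)), converged = TRUE, n = n)
}

logistic_loglik <- function(b, g, ng, kg) {
  eta <- b[1] + b[2] * g
  # log(1 + exp(eta)) computed stably for large |eta|
  sum(kg * eta - ng * (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' @param trait numeric trait vector, same length as `genotypes`.
#' @rdname fit_logistic_additive
#' @export
fit_linear_additive <- function(genotypes, trait) {
  n <- length(trait)
  if (length(genotypes) != n) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("'n' must be >= 3 for the slope t-test", call. = FALSE)
  if (any(!is.finite(trait))) stop("trait values must be finite", call. = FALSE)
  g <- as.numeric(genotypes)
  mg <- mean(g)
  sxx <- sum((g - mg)^2)
  if (sxx <= 0) {
    return(assoc_result(converged = FALSE, n = n, df = n - 2L,
                        note = "constant genotype"))
  }
  my <- mean(trait)
  b1 <- sum((g - mg) * (trait - my)) / sxx
  b0 <- my - b1 * mg
  res <- trait - b0 - b1 * g
  rss <- sum(res^2)
  df <- n - 2L
  s2 <- rss / df
  if (s2 <= 1e-12 * (sum(trait^2) / n + 1)) {
    # zero residual variance: exact fit
    if (abs(b1) < 1e-12) {
      return(assoc_result(beta = 0, se = 0, stat = 0, pvalue = 1,
                          converged = TRUE, n = n, df = df,
                          note = "zero residual variance"))
    }
    return(assoc_result(beta = b1, se = 0, stat = Inf, pvalue = 0,
                        converged = TRUE, n = n, df = df,
                        note = "zero residual variance"))
  }
  se <- sqrt(s2 / sxx)
  tt <- b1 / se
  assoc_result(beta = b1, se = se, stat = tt,
               pvalue = 2 * pt(-abs(tt), df), converged = TRUE, n = n, df = df)
}

assoc_result <- function(beta = NA_real_, se = NA_real_, stat = NA_real_,
                         pvalue = NA_real_, converged = FALSE, n = NA_integer_,
                         df = NA_integer_, note = NA_character_) {
  structure(
    list(beta = beta, se = se, stat = stat, pvalue = pvalue,
         converged = converged, n = n, df = df, note = note),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("beta = %.5g  se = %.5g  stat = %.4g  p = %.4g  (n = %d)\n",
                x$beta, x$se, x$stat, x$pvalue, x$n))
  } else {
    cat(sprintf("not converged (%s), n = %d\n", x$note, x$n))
  }
  invisible(x)
}
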