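#' Point estimates for a three-variable mediation model
#'
#' Fits the standard X -> M -> Y mediation decomposition with optional
#' covariates by least squares on complete cases: `M ~ X + covs` gives path
#' a, `Y ~ X + M + covs` gives the direct effect c' and path b, and
#' `Y ~ X + covs` gives the total effect c. The indirect effect is
#' `ab = a * b`; for least-squares fits on the same subjects the identity
#' `c = c' + ab` holds exactly. With `standardize = TRUE` (default) x, m and
#' y are z-scored first so the coefficients are beta-style.
#'
#' @param x,m,y numeric vectors: predictor, mediator, outcome.
#' @param covariates optional matrix/data.frame of covariates.
#' @param standardize z-score x, m, y before fitting.
#' @return list: `a`, `b`, `cprime`, `c`, `ab`, `cprimeT`, `cprimeP`, `n`.
#' @export
fitMediation <- function(x, m, y, covariates = NULL, standardize = TRUE) {
  covariates <- prepareCovariates(covariates, length(x))
  keep <- stats::complete.cases(x, m, y, covariates)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  k <- ncol(covariates)
  n <- length(x)
  if (n <= k + 4L) stop("too few complete cases for mediation")
  if (standardize) {
    x <- zscore(x); m <- zscore(m); y <- zscore(y)
  }
  Xa <- cbind(1, x, covariates)
  Xb <- cbind(1, x, m, covariates)
  if (qr(Xb)$rank < ncol(Xb)) stop("collinear mediation design")
  fa <- stats::lm.fit(Xa, m)
  fb <- stats::lm.fit(Xb, y)
  fc <- stats::lm.fit(Xa, y)
  a <- unname(fa$coefficients[2L])
  cprime <- unname(fb$coefficients[2L])
  b <- unname(fb$coefficients[3L])
  cc <- unname(fc$coefficients[2L])
  dfb <- n - ncol(Xb)
  sigma2 <- sum(fb$residuals^2) / dfb
  XtXinv <- chol2inv(qr.R(qr(Xb)))
  seCprime <- sqrt(sigma2 * XtXinv[2L, 2L])
  tCprime <- if (seCprime > 0) cprime / seCprime else 0
  pCprime <- 2 * stats::pt(-abs(tCprime), dfb)
  list(a = a, b = b, cprime = cprime, c = cc, ab = a * b,
       cprimeT = tCprime, cprimeP = pCprime, n = n)
}

# Minimal ab estimate on an index resample; X matrices prebuilt by caller.
abOnIndex <- function(idx, x, m, y, covariates) {
  Xa <- cbind(1, x[idx], covariates[idx, , drop = FALSE])
  Xb <- cbind(Xa[, 1:2, drop = FALSE], m[idx],
              covariates[idx, , drop = FALSE])
  a <- stats::lm.fit(Xa, m[idx])$coefficients[2L]
  b <- stats::lm.fit(Xb, y[idx])$coefficients[3L]
  unname(a * b)
}

#' Bootstrap mediation analysis with percentile confidence interval
#'
#' Resamples whole subject rows (x, m, y and covariates jointly) with
#' replacement `nBoot` times, recomputes the indirect effect `ab` on each
#' resample, and reports the 2.5/97.5 percentile interval. The indirect
#' effect is called significant when the interval excludes zero; mediation is
#' classified as *full* when the indirect effect is significant and the
#' direct path c' is not (p >= 0.05), *partial* when both are significant,
#' and *none* otherwise. Resamples in which any variable is constant are
#' redrawn (at most 100 retries each). Variables are z-scored on the full
#' complete-case sample before resampling, so coefficients are beta-style.
#'
#' @inheritParams fitMediation
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed for the resampling (required for reproducibility).
#' @param variables optional named character vector (x, m, y labels).
#' @return a [MediationResult-class] object.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(80); m <- 0.6 * x + rnorm(80); y <- 0.5 * m + rnorm(80)
#' bootstrapMediation(x, m, y, nBoot = 200, seed = 42)
bootstrapMediation <- function(x, m, y, covariates = NULL, nBoot = 5000,
                               seed = 1L, standardize = TRUE,
                               variables = c(x = "x", m = "m", y = "y")) {
  if (nBoot < 1) stop("nBoot must be >= 1")
  covariates <- prepareCovariates(covariates, length(x))
  keep <- stats::complete.cases(x, m, y, covariates)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  fit <- fitMediation(x, m, y, covariates, standardize = standardize)
  if (standardize) {
    x <- zscore(x); m <- zscore(m); y <- zscore(y)
  }
  n <- length(x)
  abBoot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        ok <- stats::sd(x[idx]) > 0 && stats::sd(m[idx]) > 0 &&
          stats::sd(y[idx]) > 0 &&
          (ncol(covariates) == 0 ||
             all(apply(covariates[idx, , drop = FALSE], 2, stats::sd) > 0))
        if (ok) return(abOnIndex(idx, x, m, y, covariates))
      }
      stop("could not draw a non-degenerate bootstrap resample")
    }, numeric(1))
  })
  ci <- unname(stats::quantile(abBoot, c(0.025, 0.975), type = 7))
  significant <- ci[1] > 0 || ci[2] < 0
  classification <- if (significant && fit$cprimeP >= 0.05) "full"
                    else if (significant) "partial" else "none"
  new("MediationResult",
      estimates = c(a = fit$a, b = fit$b, cprime = fit$cprime, c = fit$c,
                    ab = fit$ab),
      cprimeT = fit$cprimeT, cprimeP = fit$cprimeP, ci = ci,
      nBoot = as.integer(nBoot), seed = as.integer(seed),
      n = as.integer(fit$n), standardized = isTRUE(standardize),
      classification = classification, variables = variables)
}
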