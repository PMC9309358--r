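# Independent oracles used to check the package implementations.
# Each one deliberately takes a different computational route than the
# package code (precision matrix instead of residualization, brute-force
# definition instead of step-up recursion, Frisch-Waugh two-step instead of
# a single linear model).

# partial correlation via the inverse covariance (precision) matrix
oraclePartialCor <- function(x, y, covs = NULL) {
  M <- cbind(x, y, covs)
  Om <- solve(stats::cov(M))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# Benjamini-Hochberg from its definition: q_i = min over j with
# p_(j) >= p_(i) of m * p_(j) / j, capped at 1
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# ANCOVA group F by two-step residualization (Frisch-Waugh): residualize
# both y and the group dummy on [1 | covariates], then simple regression
# with the residual degrees of freedom n - 2 - k
oracleAncovaF <- function(y, group, covs) {
  g <- as.numeric(factor(group)) - 1
  X <- cbind(1, covs)
  ry <- stats::resid(stats::lm.fit(X, y))
  rg <- stats::resid(stats::lm.fit(X, g))
  slope <- sum(ry * rg) / sum(rg^2)
  rss <- sum(ry^2) - slope^2 * sum(rg^2)
  df <- length(y) - 2 - ncol(as.matrix(covs))
  se2 <- rss / df / sum(rg^2)
  slope^2 / se2
}

# paired t statistic from its closed form
oraclePairedT <- function(a, b) {
  d <- b - a
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# build a small between-module CouplingMatrix directly from a Z matrix,
# bypassing buildCoupling (used to feed compareCoupling known entries)
zMatrixCoupling <- function(z, group = "HC", scope = "test") {
  r <- tanh(z)
  info <- function(nm, module) data.frame(feature = nm, module = module,
                                          subset = NA_character_,
                                          stringsAsFactors = FALSE)
  rn <- rownames(z) %||% paste0("a", seq_len(nrow(z)))
  cn <- colnames(z) %||% paste0("b", seq_len(ncol(z)))
  dimnames(r) <- dimnames(z) <- list(rn, cn)
  new("CouplingMatrix", group = group, scope = scope,
      rowInfo = info(rn, "gene"), colInfo = info(cn, "cortex"),
      r = r, z = z, p = matrix(0.5, nrow(z), ncol(z), dimnames = dimnames(z)),
      n = matrix(50L, nrow(z), ncol(z), dimnames = dimnames(z)),
      nCovariates = 0L, symmetric = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write lines to a temp file and return its path
tmpTSV <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a tiny left+right thickness table for all 34 DK regions
makeThicknessLines <- function(n = 4, seed = 1) {
  set.seed(seed)
  regions <- dkRegions()
  cols <- as.vector(t(outer(regions, c("_lh", "_rh"), paste0)))
  vals <- matrix(round(stats::runif(n * length(cols), 1.8, 3.2), 4), n)
  c(paste(c("subject_id", cols), collapse = "\t"),
    vapply(seq_len(n), function(i)
      paste(c(sprintf("S%02d", i), vals[i, ]), collapse = "\t"),
      character(1)))
}
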