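#' Covariate-adjusted partial correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and returns the Pearson correlation of the residuals, with
#' `df = n - 2 - k` and the two-sided p value from
#' \eqn{t = r\sqrt{df/(1-r^2)}}. Only subjects complete in x, y and all
#' covariates are used (pairwise exclusion). With no covariates this is the
#' plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional matrix/data.frame of covariates.
#' @return list with `r`, `p`, `df`, `n` and a `degenerate` flag set when a
#'   residual has (numerically) zero variance left after |r| reaches 1.
#' @export
#' @examples
#' partialCorrelation(rnorm(30), rnorm(30))$df  # 28
partialCorrelation <- function(x, y, covariates = NULL) {
  covariates <- prepareCovariates(covariates, length(x))
  keep <- stats::complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- length(x); k <- ncol(covariates)
  if (n <= k + 3L) stop("too few complete cases (n = ", n, ", k = ", k, ")")
  X <- cbind(1, covariates)
  qx <- qr(X)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  tol <- 1e-12 * max(1, stats::sd(x), stats::sd(y))
  if (stats::sd(rx) < tol || stats::sd(ry) < tol)
    stop("zero residual variance; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  degenerate <- abs(r) >= 1 - 1e-12
  if (degenerate) {
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, p = p, df = df, n = n, degenerate = degenerate)
}

#' Fisher Z transformation of correlations
#'
#' `fisherZ` is the variance-stabilizing transform
#' \eqn{Z_r = \mathrm{atanh}(r) = \frac12 \log((1+r)/(1-r))}; `fisherZInv`
#' is its inverse `tanh`. Correlations with \eqn{|r| \ge 1 - 10^{-12}} are
#' clipped to that bound (with a warning) so Z stays finite.
#'
#' @param r correlations in (-1, 1); `z` Fisher Z values.
#' @return numeric vector (or matrix, preserved shape).
#' @export
fisherZ <- function(r) {
  clip <- is.finite(r) & abs(r) >= 1 - 1e-12
  if (any(clip)) {
    warning(sum(clip), " correlation(s) with |r| ~ 1 clipped before atanh")
    r[clip] <- sign(r[clip]) * (1 - 1e-12)
  }
  atanh(r)
}

#' @rdname fisherZ
#' @param z Fisher Z values.
#' @export
fisherZInv <- function(z) tanh(z)

# Partial-correlation block between feature matrices A and B (subjects in
# rows). Fast path: when every column of a block shares one missingness
# pattern (whole-block missing subjects, the usual structure here), all
# features are residualized jointly and the full correlation block comes from
# one crossproduct; otherwise each pair falls back to partialCorrelation().
couplingBlock <- function(A, B, covariates, symmetric = FALSE) {
  covariates <- prepareCovariates(covariates, nrow(A))
  k <- ncol(covariates)
  okA <- !is.na(A); okB <- !is.na(B)
  covOK <- stats::complete.cases(covariates)
  uniformA <- all(okA == okA[, 1L])
  uniformB <- all(okB == okB[, 1L])
  nr <- ncol(A); nc <- ncol(B)
  r <- matrix(NA_real_, nr, nc, dimnames = list(colnames(A), colnames(B)))
  p <- r
  nmat <- matrix(NA_integer_, nr, nc, dimnames = dimnames(r))
  if (uniformA && uniformB) {
    keep <- okA[, 1L] & okB[, 1L] & covOK
    n <- sum(keep)
    if (n <= k + 3L) stop("too few shared subjects (n = ", n, ")")
    X <- cbind(1, covariates[keep, , drop = FALSE])
    qx <- qr(X)
    RA <- qr.resid(qx, A[keep, , drop = FALSE])
    RB <- if (symmetric) RA else qr.resid(qx, B[keep, , drop = FALSE])
    r[] <- stats::cor(RA, RB)
    df <- n - 2L - k
    rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tt <- rr * sqrt(df / (1 - rr^2))
    p[] <- 2 * stats::pt(-abs(tt), df)
    nmat[] <- n
  } else {
    for (i in seq_len(nr)) {
      jseq <- if (symmetric) seq_len(i) else seq_len(nc)
      for (j in jseq) {
        pc <- partialCorrelation(A[, i], B[, j], covariates)
        r[i, j] <- pc$r; p[i, j] <- pc$p; nmat[i, j] <- pc$n
        if (symmetric) {
          r[j, i] <- pc$r; p[j, i] <- pc$p; nmat[j, i] <- pc$n
        }
      }
    }
  }
  if (symmetric) {
    diag(r) <- 1; diag(p) <- 0
  }
  z <- r
  off <- if (symmetric) row(r) != col(r) else !logical(length(r))
  z[off] <- suppressWarnings(fisherZ(r[off]))
  z[!off] <- Inf
  list(r = r, z = z, p = p, n = nmat, k = k)
}

featureInfo <- function(features, module, subset = NULL) {
  data.frame(feature = features, module = module,
             subset = if (is.null(subset)) NA_character_
                      else as.character(subset),
             stringsAsFactors = FALSE)
}

newCoupling <- function(blk, group, scope, rowInfo, colInfo, symmetric) {
  new("CouplingMatrix", group = group, scope = scope,
      rowInfo = rowInfo, colInfo = colInfo, r = blk$r, z = blk$z, p = blk$p,
      n = blk$n, nCovariates = as.integer(blk$k), symmetric = symmetric)
}

#' Build all within- and between-module coupling matrices for one group
#'
#' Computes every pairwise covariate-adjusted partial correlation among the
#' signature-gene expression block, the averaged cortical-thickness block and
#' the MCCB cognition block, for the subjects of one group, and returns the
#' five coupling matrices: within-gene, within-cortex, gene-cortex,
#' gene-cognition and cortex-cognition. By convention the covariates are age
#' and sex for gene/cortex analyses and additionally education years for any
#' analysis touching cognition; pass explicit covariate column names to
#' override.
#'
#' @param expr genes x subjects log2-CPM matrix (with optional `"subset"`
#'   attribute from [selectSignatureGenes()]).
#' @param thickness subjects x 34 averaged thickness matrix.
#' @param cognition subjects x domains matrix of MCCB T-scores (may have NAs).
#' @param phenotype phenotype data.frame supplying covariates and group.
#' @param group which group's subjects to use ("HC" or "FES").
#' @param covariates covariate column names for analyses without cognition.
#' @param covariatesCognition covariate column names when cognition enters.
#' @return named list of [CouplingMatrix-class]: `gene_gene`,
#'   `cortex_cortex`, `gene_cortex`, `gene_cognition`, `cortex_cognition`.
#' @export
buildCoupling <- function(expr, thickness, cognition, phenotype,
                          group = c("HC", "FES"),
                          covariates = c("age", "sex"),
                          covariatesCognition = c("age", "sex", "education")) {
  group <- match.arg(group)
  ids <- phenotype$subject_id[phenotype$group == group]
  shared <- Reduce(intersect, list(ids, colnames(expr), rownames(thickness),
                                   rownames(cognition)))
  if (length(shared) < 10L)
    stop("fewer than 10 shared subjects across blocks for group ", group)
  ph <- phenotype[match(shared, phenotype$subject_id), , drop = FALSE]
  G <- t(expr[, shared, drop = FALSE])
  Tk <- thickness[shared, , drop = FALSE]
  C <- cognition[shared, , drop = FALSE]
  covA <- prepareCovariates(ph[, covariates, drop = FALSE], length(shared))
  covC <- prepareCovariates(ph[, covariatesCognition, drop = FALSE],
                            length(shared))
  sub <- attr(expr, "subset")
  gInfo <- featureInfo(colnames(G), "gene",
                       if (!is.null(sub)) sub[colnames(G)] else NULL)
  tInfo <- featureInfo(colnames(Tk), "cortex")
  cInfo <- featureInfo(colnames(C), "cognition")
  list(
    gene_gene = newCoupling(couplingBlock(G, G, covA, symmetric = TRUE),
                            group, "within-gene", gInfo, gInfo, TRUE),
    cortex_cortex = newCoupling(couplingBlock(Tk, Tk, covA, symmetric = TRUE),
                                group, "within-cortex", tInfo, tInfo, TRUE),
    gene_cortex = newCoupling(couplingBlock(G, Tk, covA),
                              group, "gene-cortex", gInfo, tInfo, FALSE),
    gene_cognition = newCoupling(couplingBlock(G, C, covC),
                                 group, "gene-cognition", gInfo, cInfo, FALSE),
    cortex_cognition = newCoupling(couplingBlock(Tk, C, covC),
                                   group, "cortex-cognition", tInfo, cInfo,
                                   FALSE)
  )
}

couplingEntries <- function(cm, rows = NULL) {
  z <- cm@z
  if (!is.null(rows)) z <- z[rows, , drop = FALSE]
  if (isTRUE(cm@symmetric)) {
    if (!is.null(rows))
      stop("row restriction is only defined for between-module matrices")
    z[upper.tri(z)]
  } else as.vector(z)
}

#' Paired comparison of two coupling profiles
#'
#' Compares the Fisher-Z entries of two coupling matrices with identical
#' feature sets (typically the HC and FES versions of the same block) by a
#' paired two-sided t test over matched entries. Within-module matrices use
#' the strict upper triangle; between-module matrices use all entries. The
#' reported t is for `b - a` (second group minus first). Zero-variance
#' difference vectors are reported as `t = 0, p = 1` with a flag instead of
#' NaN.
#'
#' @param a,b [CouplingMatrix-class] objects with identical features.
#' @param scope label for the result row (defaults to the matrices' scope).
#' @return one-row data.frame: `scope`, `mean_z_a`, `mean_z_b`, `t`, `df`,
#'   `p`, `n_entries`, `zero_variance`.
#' @export
compareCoupling <- function(a, b, scope = NULL) {
  if (!identical(a@rowInfo$feature, b@rowInfo$feature) ||
      !identical(a@colInfo$feature, b@colInfo$feature))
    stop("coupling matrices have mismatched feature sets")
  za <- couplingEntries(a); zb <- couplingEntries(b)
  ok <- is.finite(za) & is.finite(zb)
  za <- za[ok]; zb <- zb[ok]
  if (length(za) < 3L) stop("fewer than 3 paired entries")
  d <- zb - za
  n <- length(d)
  sdd <- stats::sd(d)
  zeroVar <- !is.finite(sdd) || sdd < .Machine$double.eps^0.5
  if (zeroVar) {
    t <- 0; p <- 1
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1L)
  }
  data.frame(scope = scope %||% a@scope,
             mean_z_a = mean(za), mean_z_b = mean(zb),
             t = t, df = n - 1L, p = p, n_entries = n,
             zero_variance = zeroVar, stringsAsFactors = FALSE)
}

#' Compare a family of coupling scopes between two groups
#'
#' Applies [compareCoupling()] to every matched scope in two coupling sets
#' (as returned by [buildCoupling()]) and adjusts the p values by
#' Benjamini-Hochberg across the scopes of the family.
#'
#' @param a,b named lists of [CouplingMatrix-class] (same names).
#' @param scopes which scopes to include (default: all shared names).
#' @return data.frame, one row per scope, with a `q` column.
#' @export
compareCouplingSets <- function(a, b, scopes = NULL) {
  scopes <- scopes %||% intersect(names(a), names(b))
  rows <- lapply(scopes, function(s) compareCoupling(a[[s]], b[[s]]))
  out <- do.call(rbind, rows)
  out$q <- bhFDR(out$p)
  out
}

#' Monocyte-subset-stratified coupling comparison
#'
#' Restricts the gene-cortex and gene-cognition coupling matrices to the
#' gene rows of each monocyte subset (classical, intermediate, nonclassical)
#' and runs the paired comparison per subset and scope, with BH adjustment
#' across all subset-by-scope rows. Empty subsets are skipped with a warning.
#'
#' @param a,b named lists of [CouplingMatrix-class] from [buildCoupling()]
#'   for the two groups.
#' @param subsets subset labels to stratify on.
#' @param scopes which between-module scopes to stratify.
#' @return data.frame with columns `subset`, `scope`, the paired-comparison
#'   fields, and `q`.
#' @export
subsetStratifiedComparison <- function(a, b,
    subsets = c("classical", "intermediate", "nonclassical"),
    scopes = c("gene_cortex", "gene_cognition")) {
  rows <- list()
  for (s in subsets) {
    for (sc in scopes) {
      ca <- a[[sc]]; cb <- b[[sc]]
      idx <- which(ca@rowInfo$subset == s)
      if (!length(idx)) {
        warning("subset ", s, " has no genes; skipped")
        next
      }
      sa <- restrictCoupling(ca, idx); sb <- restrictCoupling(cb, idx)
      row <- compareCoupling(sa, sb, scope = paste0(s, ":", ca@scope))
      row$subset <- s
      rows[[paste(s, sc)]] <- row
    }
  }
  if (!length(rows)) stop("no non-empty subset to compare")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bhFDR(out$p)
  out[, c("subset", setdiff(names(out), "subset"))]
}

restrictCoupling <- function(cm, idx) {
  new("CouplingMatrix", group = cm@group, scope = cm@scope,
      rowInfo = cm@rowInfo[idx, , drop = FALSE], colInfo = cm@colInfo,
      r = cm@r[idx, , drop = FALSE], z = cm@z[idx, , drop = FALSE],
      p = cm@p[idx, , drop = FALSE], n = cm@n[idx, , drop = FALSE],
      nCovariates = cm@nCovariates, symmetric = FALSE)
}

#' Pairwise gene-by-feature screening
#'
#' Computes every gene x feature covariate-adjusted partial correlation,
#' flags pairs at the nominal significance level, and adjusts over the full
#' gene-by-feature family (e.g. 54 x 34) by Benjamini-Hochberg, flagging
#' pairs that survive FDR < `alphaFDR` separately.
#'
#' @param expr genes x subjects log2-CPM matrix.
#' @param features subjects x features matrix (thickness regions or MCCB
#'   domains).
#' @param phenotype phenotype data.frame supplying covariates and group.
#' @param group group label to screen in.
#' @param covariates covariate column names.
#' @param alphaNominal nominal per-pair significance level.
#' @param alphaFDR family FDR threshold.
#' @return data.frame of all pairs: `gene`, `feature`, `r`, `p`, `q`,
#'   `nominal`, `fdr_hit`, sorted by p.
#' @export
pairwiseScreen <- function(expr, features, phenotype, group = c("HC", "FES"),
                           covariates = c("age", "sex", "education"),
                           alphaNominal = 0.01, alphaFDR = 0.05) {
  group <- match.arg(group)
  ids <- phenotype$subject_id[phenotype$group == group]
  shared <- Reduce(intersect, list(ids, colnames(expr), rownames(features)))
  if (length(shared) < 10L)
    stop("fewer than 10 shared subjects for group ", group)
  ph <- phenotype[match(shared, phenotype$subject_id), , drop = FALSE]
  cov <- prepareCovariates(ph[, covariates, drop = FALSE], length(shared))
  blk <- couplingBlock(t(expr[, shared, drop = FALSE]),
                       features[shared, , drop = FALSE], cov)
  out <- data.frame(
    gene = rep(rownames(blk$r), times = ncol(blk$r)),
    feature = rep(colnames(blk$r), each = nrow(blk$r)),
    r = as.vector(blk$r), p = as.vector(blk$p),
    stringsAsFactors = FALSE)
  out$q <- bhFDR(out$p)
  out$nominal <- out$p < alphaNominal
  out$fdr_hit <- out$q < alphaFDR
  out[order(out$p), ]
}
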