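#' Covariate-adjusted group comparison (ANCOVA partial F test)
#'
#' Fits `y ~ group + covariates` by least squares and reports the partial F
#' test for the group term (1 numerator degree of freedom), i.e. the
#' univariate-GLM F that accompanies adjusted group means. Adjusted means are
#' the model predictions for each group at the covariate means.
#'
#' @param y numeric outcome vector.
#' @param group two-level factor or character vector of group labels.
#' @param covariates numeric matrix or data.frame of covariates (may be NULL).
#' @param outcome label carried into the result row.
#' @return one-row data.frame: `outcome`, one `adj_mean_<level>` column per
#'   group, `F`, `df1`, `df2`, `p`, `n`.
#' @export
ancovaGroupTest <- function(y, group, covariates = NULL, outcome = "y") {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  covariates <- prepareCovariates(covariates, length(y))
  keep <- stats::complete.cases(y, group, covariates)
  y <- y[keep]; group <- group[keep]
  covariates <- covariates[keep, , drop = FALSE]
  k <- ncol(covariates)
  if (length(y) <= k + 2L) stop("too few complete cases for ANCOVA")
  if (nlevels(droplevels(group)) != 2L)
    stop("both groups must be represented among complete cases")
  X <- cbind(`(Intercept)` = 1, g = as.numeric(group == levels(group)[2]),
             covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(y = y, group = group, covariates, check.names = TRUE)
  covNames <- colnames(dat)[-(1:2)]
  fml <- stats::reformulate(c("group", covNames), response = "y")
  fit <- stats::lm(fml, data = dat)
  tg <- summary(fit)$coefficients[2L, "t value"]
  df2 <- fit$df.residual
  Fg <- tg^2
  p <- stats::pf(Fg, 1, df2, lower.tail = FALSE)
  nd <- dat[c(1L, 1L), , drop = FALSE]
  nd$group <- factor(levels(group), levels = levels(group))
  for (cn in covNames) nd[[cn]] <- mean(dat[[cn]])
  adj <- stats::predict(fit, newdata = nd)
  out <- data.frame(outcome = outcome, F = Fg, df1 = 1L, df2 = df2, p = p,
                    n = length(y), stringsAsFactors = FALSE)
  out[paste0("adj_mean_", levels(group))] <- as.list(adj)
  out[, c("outcome", paste0("adj_mean_", levels(group)),
          "F", "df1", "df2", "p", "n")]
}

prepareCovariates <- function(covariates, n) {
  if (is.null(covariates))
    return(matrix(numeric(), nrow = n, ncol = 0))
  if (is.data.frame(covariates)) {
    covariates <- vapply(covariates, function(col) {
      if (is.factor(col)) as.numeric(col) - 1
      else if (is.logical(col)) as.numeric(col)
      else as.numeric(col)
    }, numeric(nrow(covariates)))
    if (is.null(dim(covariates))) covariates <- matrix(covariates, nrow = 1)
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop("covariates must have one row per observation")
  covariates
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square WITHOUT Yates continuity correction,
#' \eqn{\chi^2 = N(ad-bc)^2/(r_1 r_2 c_1 c_2)}, with the p value from the
#' chi-square distribution on 1 degree of freedom. This is the variant that
#' reproduces published 2x2 statistics computed by mainstream statistics
#' suites with the correction disabled.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param variable label carried into the result row.
#' @return one-row data.frame: `variable`, `test`, `statistic`, `p`.
#' @export
#' @examples
#' chiSquare2x2(matrix(c(55, 56, 73, 55), 2))  # statistic 1.338
chiSquare2x2 <- function(tab, variable = "variable") {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || sum(tab) <= 0) stop("cells must be >= 0 with total > 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in 2x2 table")
  ht <- stats::chisq.test(tab, correct = FALSE)
  data.frame(variable = variable, test = "chi-square",
             statistic = unname(ht$statistic), p = unname(ht$p.value),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test with normal approximation Z
#'
#' Computes the U statistic using midranks for ties and the tie-corrected
#' normal-approximation Z without continuity correction:
#' \eqn{Z = (U - mn/2)/\sigma_U}. The sign convention makes Z negative when
#' the first sample has the smaller rank sum.
#'
#' @param x,y numeric samples for the two groups.
#' @param variable label carried into the result row.
#' @return one-row data.frame: `variable`, `test`, `U`, `statistic` (the Z),
#'   `p`.
#' @export
mannWhitneyZ <- function(x, y, variable = "variable") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(m)])
  U <- R1 - m * (m + 1) / 2        # number of (x, y) pairs with x > y
  N <- m + n
  ties <- table(c(x, y))
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- m * n / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0)
    stop("all values identical across both samples; Z undefined")
  Z <- (U - m * n / 2) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(Z))
  data.frame(variable = variable, test = "mann-whitney", U = U,
             statistic = Z, p = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjusted p values (q values), returned in input order:
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} m\, p_{(j)}/j}, capped at 1.
#'
#' @param p numeric vector of p values in \[0, 1\]; NAs are propagated.
#' @return numeric vector of q values.
#' @export
bhFDR <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Demographics comparison table
#'
#' Compares demographic variables between the two groups the way clinical
#' baseline tables are built: categorical variables (sex, smoking) by Pearson
#' chi-square without continuity correction, continuous variables by
#' Student's t when Shapiro-Wilk does not reject normality in either group
#' (alpha = 0.05), otherwise by the Mann-Whitney U test with approximate Z.
#'
#' @param phenotype data.frame from [readPhenotypes()].
#' @param variables continuous columns to compare (default age, education).
#' @return data.frame with one row per variable: test used, statistic, p.
#' @export
demographicsTable <- function(phenotype, variables = c("age", "education")) {
  g <- phenotype$group
  rows <- list()
  for (v in intersect(variables, names(phenotype))) {
    x <- phenotype[[v]][g == "FES"]; y <- phenotype[[v]][g == "HC"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    normal <- tryCatch(
      stats::shapiro.test(x)$p.value > 0.05 &&
        stats::shapiro.test(y)$p.value > 0.05,
      error = function(e) FALSE)
    if (normal) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      rows[[v]] <- data.frame(variable = v, test = "t", U = NA_real_,
                              statistic = unname(ht$statistic),
                              p = ht$p.value, stringsAsFactors = FALSE)
    } else {
      rows[[v]] <- mannWhitneyZ(x, y, variable = v)
    }
  }
  if ("sex" %in% names(phenotype)) {
    tab <- table(factor(phenotype$group, c("FES", "HC")),
                 factor(phenotype$sex, c("male", "female")))
    r <- chiSquare2x2(tab, variable = "sex")
    r$U <- NA_real_
    rows[["sex"]] <- r[, c("variable", "test", "U", "statistic", "p")]
  }
  if ("smoker" %in% names(phenotype)) {
    tab <- table(factor(phenotype$group, c("FES", "HC")),
                 factor(phenotype$smoker, c(TRUE, FALSE)))
    r <- chiSquare2x2(tab, variable = "smoker")
    r$U <- NA_real_
    rows[["smoker"]] <- r[, c("variable", "test", "U", "statistic", "p")]
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simplified per-gene differential expression on log2-CPM
#'
#' Fits, for every gene, the linear model `log2cpm ~ group + covariates` and
#' reports the group coefficient as the log2 fold change (second level vs
#' first level of `group`) with an ordinary (unmoderated) t test on that
#' coefficient and BH q values across genes. This is a deliberately simple
#' log-linear stand-in for count-model differential expression; it is not a
#' negative-binomial fit. Constant genes are flagged and reported with
#' `log2FC = 0`, `p = 1`.
#'
#' @param expr numeric matrix of log2-CPM values, genes x subjects.
#' @param group two-level factor (first level is the reference, e.g. HC).
#' @param covariates optional matrix/data.frame of per-subject covariates.
#' @return data.frame: `gene`, `log2FC`, `t`, `p`, `q`, `constant`.
#' @export
differentialExpression <- function(expr, group, covariates = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (min(table(group)) < 3L) stop("need at least 3 subjects per group")
  covariates <- prepareCovariates(covariates, ncol(expr))
  keep <- stats::complete.cases(as.numeric(group), covariates)
  expr <- expr[, keep, drop = FALSE]
  design <- cbind(Intercept = 1,
                  group = as.numeric(group[keep] == levels(group)[2]),
                  covariates[keep, , drop = FALSE])
  fit <- limma::lmFit(expr, design)
  dfres <- fit$df.residual
  const <- !is.finite(fit$sigma) | fit$sigma < .Machine$double.eps^0.5
  se <- fit$stdev.unscaled[, "group"] * fit$sigma
  tstat <- fit$coefficients[, "group"] / se
  p <- 2 * stats::pt(-abs(tstat), dfres)
  lfc <- fit$coefficients[, "group"]
  lfc[const] <- 0; tstat[const] <- 0; p[const] <- 1
  data.frame(gene = rownames(expr), log2FC = unname(lfc), t = unname(tstat),
             p = unname(p), q = bhFDR(unname(p)), constant = unname(const),
             stringsAsFactors = FALSE)
}
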