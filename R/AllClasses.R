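#' @import methods
NULL

#' TrimodalCohort: a two-group multi-modal cohort
#'
#' Container for the four aligned tables the coupling analysis consumes: a
#' per-subject phenotype table (group, covariates, MCCB cognitive scores,
#' optional monocyte subset percentages), a gene-by-subject raw count matrix,
#' a gene annotation assigning each signature gene to a monocyte subset, and a
#' subject-by-region cortical thickness table. Synthetic cohorts additionally
#' carry a ground-truth record (all latent generator parameters), which is
#' sufficient to recompute every implied moment and to regenerate the cohort.
#'
#' @slot phenotype data.frame, one row per subject; see [readPhenotypes()].
#' @slot counts integer matrix, genes x subjects, non-negative.
#' @slot annotation data.frame with columns `gene` and `subset`
#'   (pan/classical/intermediate/nonclassical).
#' @slot thickness numeric matrix, subjects x regions, mm.
#' @slot thicknessMode `"leftright"` (68 hemisphere columns) or `"averaged"`
#'   (34 bilateral columns).
#' @slot groundTruth list of generator parameters for synthetic cohorts,
#'   empty for cohorts assembled from files.
#'
#' @seealso [generateCohort()], [trimodalCohort()]
#' @exportClass TrimodalCohort
setClass("TrimodalCohort",
  representation(
    phenotype     = "data.frame",
    counts        = "matrix",
    annotation    = "data.frame",
    thickness     = "matrix",
    thicknessMode = "character",
    groundTruth   = "list"
  )
)

setValidity("TrimodalCohort", function(object) {
  msg <- character()
  ph <- object@phenotype
  if (!all(c("subject_id", "group") %in% names(ph)))
    msg <- c(msg, "phenotype must have subject_id and group columns")
  else {
    if (anyDuplicated(ph$subject_id))
      msg <- c(msg, "duplicated subject_id in phenotype")
    if (anyNA(ph$group))
      msg <- c(msg, "group must be non-null for every subject")
    if (!all(as.character(ph$group) %in% c("HC", "FES")))
      msg <- c(msg, "group labels must be HC or FES")
  }
  if (length(object@counts)) {
    if (any(object@counts < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (anyDuplicated(rownames(object@counts)))
      msg <- c(msg, "gene symbols must be unique")
    if (!is.null(colnames(object@counts)) &&
        !all(colnames(object@counts) %in% ph$subject_id))
      msg <- c(msg, "count matrix columns must match phenotype subject_id")
  }
  if (length(object@thickness)) {
    if (!object@thicknessMode %in% c("leftright", "averaged"))
      msg <- c(msg, "thicknessMode must be 'leftright' or 'averaged'")
    nreg <- ncol(object@thickness)
    if (object@thicknessMode == "averaged" && nreg != 34L)
      msg <- c(msg, "averaged thickness table must have 34 regions")
    if (object@thicknessMode == "leftright" && nreg != 68L)
      msg <- c(msg, "left+right thickness table must have 68 columns")
    tv <- object@thickness[is.finite(object@thickness)]
    if (length(tv) && (any(tv <= 0) || any(tv >= 6)))
      msg <- c(msg, "thickness values must lie in (0, 6) mm")
  }
  subs <- object@phenotype[, grep("^subset_", names(ph)), drop = FALSE]
  if (ncol(subs)) {
    sv <- unlist(subs)
    if (any(sv < 0 | sv > 100, na.rm = TRUE))
      msg <- c(msg, "subset percentages must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' CouplingMatrix: covariate-adjusted partial-correlation block
#'
#' Holds all pairwise partial correlations between two feature blocks (or
#' within one block) for one group, together with their Fisher
#' \eqn{Z_r = \mathrm{atanh}(r)} transforms, two-sided p values, the number of
#' subjects per entry, and feature metadata (module and monocyte subset
#' labels). Within-module matrices are symmetric with a unit diagonal in `r`;
#' paired comparisons exclude the diagonal and use the strict upper triangle.
#'
#' @slot group group label the matrix was computed in ("HC" or "FES").
#' @slot scope short label such as "gene-cortex" or "within-gene".
#' @slot rowInfo,colInfo data.frames with columns `feature`, `module`, and
#'   `subset` (NA outside the gene module).
#' @slot r,z,p numeric matrices (rows = block A features, cols = block B).
#' @slot n integer matrix of subjects used per entry.
#' @slot nCovariates number of covariates partialled out.
#' @slot symmetric TRUE for within-module matrices.
#'
#' @seealso [buildCoupling()], [compareCoupling()]
#' @exportClass CouplingMatrix
setClass("CouplingMatrix",
  representation(
    group       = "character",
    scope       = "character",
    rowInfo     = "data.frame",
    colInfo     = "data.frame",
    r           = "matrix",
    z           = "matrix",
    p           = "matrix",
    n           = "matrix",
    nCovariates = "integer",
    symmetric   = "logical"
  )
)

setValidity("CouplingMatrix", function(object) {
  msg <- character()
  d <- dim(object@r)
  if (!identical(dim(object@z), d) || !identical(dim(object@p), d) ||
      !identical(dim(object@n), d))
    msg <- c(msg, "r, z, p, n must share dimensions")
  if (nrow(object@rowInfo) != d[1] || nrow(object@colInfo) != d[2])
    msg <- c(msg, "rowInfo/colInfo must match matrix dimensions")
  off <- if (isTRUE(object@symmetric)) object@r[upper.tri(object@r)] else object@r
  off <- off[is.finite(off)]
  if (length(off) && any(abs(off) >= 1))
    msg <- c(msg, "off-diagonal partial correlations must lie in (-1, 1)")
  if (isTRUE(object@symmetric) && d[1] == d[2] &&
      !isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-8)))
    msg <- c(msg, "within-module r matrix must be symmetric")
  chk <- is.finite(object@r) & abs(object@r) < 1
  if (any(abs(object@z[chk] - atanh(object@r[chk])) > 1e-8))
    msg <- c(msg, "z must equal atanh(r) elementwise")
  if (length(msg)) msg else TRUE
})

#' MediationResult: three-variable mediation with bootstrap CI
#'
#' Result of an X -> M -> Y mediation fit with covariates: path coefficients
#' a (X to M), b (M to Y given X), the direct effect c' (X to Y given M) with
#' its t and p, the total effect c, the indirect effect ab = a*b, a percentile
#' bootstrap confidence interval for ab, and a classification as full, partial
#' or no mediation. Coefficients are beta-style (variables z-scored before
#' fitting) unless the fit was requested on the raw scale.
#'
#' @slot estimates named numeric: a, b, cprime, c, ab.
#' @slot cprimeT,cprimeP t statistic and two-sided p of the direct path.
#' @slot ci length-2 numeric, 2.5 and 97.5 percentile bootstrap bounds for ab.
#' @slot nBoot number of bootstrap resamples.
#' @slot seed RNG seed used for resampling.
#' @slot n complete-case sample size.
#' @slot standardized TRUE when variables were z-scored before fitting.
#' @slot classification "full", "partial" or "none".
#' @slot variables named character recording which columns were x, m, y.
#'
#' @seealso [bootstrapMediation()]
#' @exportClass MediationResult
setClass("MediationResult",
  representation(
    estimates      = "numeric",
    cprimeT        = "numeric",
    cprimeP        = "numeric",
    ci             = "numeric",
    nBoot          = "integer",
    seed           = "integer",
    n              = "integer",
    standardized   = "logical",
    classification = "character",
    variables      = "character"
  )
)

setValidity("MediationResult", function(object) {
  msg <- character()
  need <- c("a", "b", "cprime", "c", "ab")
  if (!all(need %in% names(object@estimates)))
    msg <- c(msg, "estimates must contain a, b, cprime, c, ab")
  if (length(object@ci) != 2L)
    msg <- c(msg, "ci must have two elements")
  if (!object@classification %in% c("full", "partial", "none"))
    msg <- c(msg, "classification must be full, partial or none")
  if (length(msg)) msg else TRUE
})
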