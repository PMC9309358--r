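#' Accessors for TrimodalCohort and CouplingMatrix objects
#'
#' @param object a [TrimodalCohort-class], [CouplingMatrix-class] or
#'   [MediationResult-class] object.
#' @return `phenotypes` the phenotype data.frame; `rawCounts` the integer
#'   count matrix; `geneAnnotation` the gene/subset table; `thicknessTable`
#'   the thickness matrix (with a `"mode"` attribute); `groundTruth` the
#'   generator parameter list (empty list for file-based cohorts);
#'   `couplingR`/`couplingZ`/`couplingP` the correlation, Fisher-Z and p
#'   matrices; `couplingGroup` the group label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("rawCounts", function(object) standardGeneric("rawCounts"))
#' @rdname accessors
#' @export
setGeneric("geneAnnotation", function(object) standardGeneric("geneAnnotation"))
#' @rdname accessors
#' @export
setGeneric("thicknessTable", function(object) standardGeneric("thicknessTable"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("couplingR", function(object) standardGeneric("couplingR"))
#' @rdname accessors
#' @export
setGeneric("couplingZ", function(object) standardGeneric("couplingZ"))
#' @rdname accessors
#' @export
setGeneric("couplingP", function(object) standardGeneric("couplingP"))
#' @rdname accessors
#' @export
setGeneric("couplingGroup", function(object) standardGeneric("couplingGroup"))

#' @rdname accessors
setMethod("phenotypes", "TrimodalCohort", function(object) object@phenotype)
#' @rdname accessors
setMethod("rawCounts", "TrimodalCohort", function(object) object@counts)
#' @rdname accessors
setMethod("geneAnnotation", "TrimodalCohort", function(object) object@annotation)
#' @rdname accessors
setMethod("thicknessTable", "TrimodalCohort", function(object) {
  t <- object@thickness
  attr(t, "mode") <- object@thicknessMode
  t
})
#' @rdname accessors
setMethod("groundTruth", "TrimodalCohort", function(object) object@groundTruth)

#' @rdname accessors
setMethod("couplingR", "CouplingMatrix", function(object) object@r)
#' @rdname accessors
setMethod("couplingZ", "CouplingMatrix", function(object) object@z)
#' @rdname accessors
setMethod("couplingP", "CouplingMatrix", function(object) object@p)
#' @rdname accessors
setMethod("couplingGroup", "CouplingMatrix", function(object) object@group)

setMethod("show", "TrimodalCohort", function(object) {
  ph <- object@phenotype
  tab <- table(ph$group)
  cat("TrimodalCohort:", nrow(ph), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  if (length(object@counts))
    cat("  counts:   ", nrow(object@counts), "genes x",
        ncol(object@counts), "subjects\n")
  if (nrow(object@annotation))
    cat("  genes:    ", nrow(object@annotation), "annotated (",
        paste(sprintf("%s=%d", names(table(object@annotation$subset)),
                      table(object@annotation$subset)), collapse = ", "), ")\n")
  if (length(object@thickness))
    cat("  thickness:", nrow(object@thickness), "subjects x",
        ncol(object@thickness), "columns [", object@thicknessMode, "]\n")
  mccb <- grep("^mccb_", names(ph), value = TRUE)
  if (length(mccb)) cat("  cognition:", length(mccb), "MCCB columns\n")
  if (length(object@groundTruth))
    cat("  synthetic: ground-truth record attached\n")
  invisible(NULL)
})

setMethod("show", "CouplingMatrix", function(object) {
  zoff <- if (isTRUE(object@symmetric))
    object@z[upper.tri(object@z)] else as.vector(object@z)
  zoff <- zoff[is.finite(zoff)]
  cat(sprintf(
    "CouplingMatrix [%s, group %s]: %d x %d, %d covariates, mean Zr = %.4f\n",
    object@scope, object@group, nrow(object@r), ncol(object@r),
    object@nCovariates, mean(zoff)))
  invisible(NULL)
})

setMethod("show", "MediationResult", function(object) {
  e <- object@estimates
  cat(sprintf("MediationResult (%s): x=%s, m=%s, y=%s, n=%d\n",
              if (object@standardized) "standardized" else "raw scale",
              object@variables[["x"]], object@variables[["m"]],
              object@variables[["y"]], object@n))
  cat(sprintf("  a = %.4f  b = %.4f  c' = %.4f (t = %.3f, p = %.4g)  c = %.4f\n",
              e[["a"]], e[["b"]], e[["cprime"]], object@cprimeT,
              object@cprimeP, e[["c"]]))
  cat(sprintf("  indirect ab = %.4f, 95%% bootstrap CI [%.4f, %.4f] (%d resamples)\n",
              e[["ab"]], object@ci[1], object@ci[2], object@nBoot))
  cat("  classification:", object@classification, "mediation\n")
  invisible(NULL)
})
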