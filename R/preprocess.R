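#' Filter a count matrix on abundance and variance
#'
#' Two-stage gene filter mirroring a common bulk RNA-seq pre-processing
#' recipe: genes with mean raw count across subjects below `minMeanCount` are
#' removed first; then, among the remaining genes, those whose raw-count
#' variance falls in the lowest `varPercentile` percent are removed
#' (`floor(varPercentile/100 * n_remaining)` genes). Variance-rank ties are
#' broken by keeping the gene with the larger mean, then by gene symbol, so
#' the output is deterministic.
#'
#' @param counts integer matrix, genes x subjects.
#' @param minMeanCount abundance threshold on the per-gene mean raw count.
#' @param varPercentile percentile (0-100) of the variance distribution below
#'   which genes are dropped.
#' @return list with `counts` (the filtered matrix) and `report`, a list with
#'   fields `n_genes_in`, `n_removed_low_count`, `n_removed_low_variance`,
#'   `n_genes_out` and the thresholds used.
#' @export
#' @examples
#' m <- matrix(rpois(200, 50), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' filterCounts(m)$report
filterCounts <- function(counts, minMeanCount = 4, varPercentile = 15) {
  stopifnot(is.matrix(counts), nrow(counts) > 0)
  if (varPercentile < 0 || varPercentile >= 100)
    stop("varPercentile must lie in [0, 100)")
  mu <- rowMeans(counts)
  keepAbund <- mu >= minMeanCount
  nLow <- sum(!keepAbund)
  m2 <- counts[keepAbund, , drop = FALSE]
  if (nrow(m2) == 0L)
    stop("all genes removed by the abundance filter; ",
         "lower minMeanCount or check the input")
  v <- apply(m2, 1L, stats::var)
  k <- floor(varPercentile / 100 * nrow(m2))
  if (k > 0) {
    ord <- order(v, -rowMeans(m2), rownames(m2))
    drop <- rownames(m2)[ord[seq_len(k)]]
    m2 <- m2[setdiff(rownames(m2), drop), , drop = FALSE]
  }
  if (nrow(m2) == 0L)
    stop("all genes removed by the variance filter; lower varPercentile")
  report <- list(
    n_genes_in = nrow(counts),
    n_removed_low_count = nLow,
    n_removed_low_variance = k,
    n_genes_out = nrow(m2),
    min_mean_count = minMeanCount,
    var_percentile = varPercentile)
  list(counts = m2, report = report)
}

#' Log2 reads-per-million normalization
#'
#' Converts raw counts to `log2(count / library_size * 1e6 + pseudocount)`.
#' By default library sizes are the column sums of `counts`; pass `libSizes`
#' (e.g. the column sums of the matrix before gene filtering) to normalize
#' against pre-filter totals. With the default pseudocount of 1, zero counts
#' map to exactly 0.
#'
#' @param counts integer matrix, genes x subjects.
#' @param pseudocount value added after per-million scaling.
#' @param libSizes optional named vector of per-subject library sizes.
#' @return numeric matrix of log2-CPM values with a `"provenance"` attribute.
#' @export
log2RPM <- function(counts, pseudocount = 1, libSizes = NULL) {
  stopifnot(is.matrix(counts))
  tot <- libSizes %||% colSums(counts)
  if (!is.null(libSizes)) {
    if (!is.null(names(libSizes)) && !is.null(colnames(counts)))
      tot <- libSizes[colnames(counts)]
    if (length(tot) != ncol(counts) || anyNA(tot))
      stop("libSizes must cover every subject column")
  }
  zero <- which(tot <= 0)
  if (length(zero))
    stop("zero library size for subject(s): ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  e <- log2(sweep(counts, 2L, tot, "/") * 1e6 + pseudocount)
  attr(e, "provenance") <- "raw-normalized"
  e
}

#' Restrict an expression matrix to annotated signature genes
#'
#' Keeps only genes present in the annotation and orders rows pan ->
#' classical -> intermediate -> nonclassical, alphabetically within subset.
#' Annotated genes absent from the matrix produce a warning; zero overlap is
#' an error.
#'
#' @param expr numeric matrix, genes x subjects (log2-CPM).
#' @param annotation data.frame from [readGeneAnnotation()].
#' @return the row-subset matrix, with a `"subset"` attribute giving each
#'   retained gene's subset label in row order.
#' @export
selectSignatureGenes <- function(expr, annotation) {
  stopifnot(nrow(annotation) > 0)
  ann <- annotation[order(annotation$subset, annotation$gene), ]
  present <- ann$gene %in% rownames(expr)
  if (!any(present))
    stop("no annotated gene is present in the expression matrix")
  if (any(!present))
    warning("annotated gene(s) absent from expression matrix: ",
            paste(ann$gene[!present], collapse = ", "))
  ann <- ann[present, ]
  out <- expr[ann$gene, , drop = FALSE]
  attr(out, "subset") <- setNames(as.character(ann$subset), ann$gene)
  attr(out, "provenance") <- attr(expr, "provenance")
  out
}

#' Average left and right hemisphere thickness columns
#'
#' Collapses a 68-column left+right thickness table to the 34 bilateral
#' Desikan-Killiany regions by the arithmetic mean of the `_lh` and `_rh`
#' columns.
#'
#' @param thickness matrix from [readThickness()] in `leftright` mode.
#' @return subjects x 34 matrix with `"mode"` attribute `"averaged"`.
#' @export
averageHemispheres <- function(thickness) {
  mode <- attr(thickness, "mode") %||%
    (if (ncol(thickness) == 68L) "leftright" else "averaged")
  if (mode != "leftright")
    stop("averageHemispheres expects a left+right (68-column) table")
  canon <- dkRegions()
  lh <- thickness[, paste0(canon, "_lh"), drop = FALSE]
  rh <- thickness[, paste0(canon, "_rh"), drop = FALSE]
  out <- (lh + rh) / 2
  colnames(out) <- canon
  attr(out, "mode") <- "averaged"
  out
}
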