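#' Canonical Desikan-Killiany region names
#'
#' The 34 gyrally defined cortical regions of the Desikan-Killiany atlas,
#' in the package's canonical order (alphabetical by FreeSurfer label).
#' Thickness tables are validated against this list; left/right tables use
#' `<region>_lh` / `<region>_rh` column names.
#'
#' @return character vector of length 34.
#' @export
#' @examples
#' length(dkRegions())
dkRegions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' MCCB cognitive domain column names
#'
#' Column names used for the seven MCCB domain T-scores and the composite in
#' phenotype tables.
#'
#' @param composite include the composite column.
#' @return character vector.
#' @export
mccbDomains <- function(composite = FALSE) {
  d <- c("mccb_processing_speed", "mccb_attention_vigilance",
         "mccb_working_memory", "mccb_verbal_learning",
         "mccb_visual_learning", "mccb_reasoning", "mccb_social_cognition")
  if (composite) c(d, "mccb_composite") else d
}

sniffDelim <- function(path, dialect = "auto") {
  if (dialect == "tsv") return("\t")
  if (dialect == "csv") return(",")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

readTable <- function(path, dialect = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sniffDelim(path, dialect),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", na.strings = c("NA", ""))
}

writeTable <- function(x, path, rowLabel = NULL, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  if (!is.null(rowLabel)) {
    x <- data.frame(setNames(list(rownames(x)), rowLabel), x,
                    check.names = FALSE)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-subject phenotype tables
#'
#' A phenotype table has one row per subject with columns `subject_id`,
#' `group` (HC or FES), `age`, `sex` (male/female), `education` (years),
#' `smoker` (TRUE/FALSE), optionally the seven MCCB domain T-scores plus
#' composite (see [mccbDomains()]) and monocyte subset percentages
#' (`subset_classical`, `subset_intermediate`, `subset_nonclassical`).
#' Missing numeric cells become `NA` and the subject is excluded pairwise,
#' analysis by analysis, not listwise. In model matrices sex is coded
#' 0 = female, 1 = male throughout the package.
#'
#' @param path file path; TSV by default, CSV recognized by extension.
#' @param dialect `"auto"` (sniff from extension), `"tsv"` or `"csv"`.
#' @return `readPhenotypes` returns a validated data.frame with `group` and
#'   `sex` as factors and `smoker` logical.
#' @export
readPhenotypes <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- readTable(path, dialect)
  need <- c("subject_id", "group", "age", "sex", "education")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table missing required columns: ",
         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(as.character(df$group)), c("HC", "FES"))
  if (length(bad) || anyNA(df$group))
    stop("unknown group label(s): ",
         paste(c(bad, if (anyNA(df$group)) "<NA>"), collapse = ", "))
  df$group <- factor(df$group, levels = c("HC", "FES"))
  df$sex <- factor(tolower(as.character(df$sex)),
                   levels = c("female", "male"))
  if ("smoker" %in% names(df)) {
    if (is.character(df$smoker))
      df$smoker <- df$smoker %in% c("TRUE", "true", "1", "yes")
    df$smoker <- as.logical(df$smoker)
  }
  num <- setdiff(names(df), c("subject_id", "group", "sex", "smoker"))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  sub <- grep("^subset_", names(df), value = TRUE)
  for (cn in sub)
    if (any(df[[cn]] < 0 | df[[cn]] > 100, na.rm = TRUE))
      stop("subset percentage outside [0, 100] in column ", cn)
  df
}

#' @rdname readPhenotypes
#' @param x table to write.
#' @export
writePhenotypes <- function(x, path) {
  out <- x
  if ("smoker" %in% names(out)) out$smoker <- as.integer(out$smoker)
  writeTable(out, path)
}

#' Read and write gene-by-subject raw count matrices
#'
#' The first column holds gene symbols; the remaining columns are subjects.
#' Cells must be non-negative integers; violations are reported with the
#' offending gene and subject.
#'
#' @param path file path (TSV, or CSV by extension).
#' @return `readCounts` returns an integer matrix, genes x subjects.
#' @export
readCounts <- function(path) {
  df <- readTable(path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at (gene %s, subject %s): %s",
                 genes[bad[1, 1]], colnames(m)[bad[1, 2]],
                 df[bad[1, 1], bad[1, 2] + 1L]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname readCounts
#' @param x count matrix to write.
#' @export
writeCounts <- function(x, path) {
  writeTable(as.data.frame(x, check.names = FALSE), path, rowLabel = "gene")
}

#' Read a gene-to-monocyte-subset annotation table
#'
#' Two columns: `gene` (symbol) and `subset`, one of pan, classical,
#' intermediate, nonclassical.
#'
#' @param path file path.
#' @return data.frame with `gene` character and `subset` factor.
#' @export
readGeneAnnotation <- function(path) {
  df <- readTable(path)
  if (!all(c("gene", "subset") %in% names(df)))
    stop("annotation table must have columns gene, subset")
  if (anyDuplicated(df$gene))
    stop("gene annotated more than once: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  lv <- c("pan", "classical", "intermediate", "nonclassical")
  bad <- setdiff(unique(as.character(df$subset)), lv)
  if (length(bad) || anyNA(df$subset))
    stop("unknown subset label(s): ", paste(bad, collapse = ", "))
  data.frame(gene = as.character(df$gene),
             subset = factor(df$subset, levels = lv))
}

#' Read and write subject-by-region cortical thickness tables
#'
#' In `leftright` mode columns are `<region>_lh` and `<region>_rh` for the 34
#' Desikan-Killiany regions; in `averaged` mode they are the bare region
#' names. Region names are checked against [dkRegions()]: an unknown column
#' is dropped with a warning, a region with only one hemisphere column is an
#' error. The first column must be `subject_id`.
#'
#' @param path file path.
#' @param mode `"leftright"` or `"averaged"`.
#' @return numeric matrix subjects x regions with a `"mode"` attribute.
#' @export
readThickness <- function(path, mode = c("leftright", "averaged")) {
  mode <- match.arg(mode)
  df <- readTable(path)
  if (names(df)[1] != "subject_id")
    stop("first column of a thickness table must be subject_id")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  canon <- dkRegions()
  expect <- if (mode == "averaged") canon
            else as.vector(t(outer(canon, c("_lh", "_rh"), paste0)))
  unknown <- setdiff(colnames(m), expect)
  if (length(unknown)) {
    warning("dropping unknown region column(s): ",
            paste(unknown, collapse = ", "))
    m <- m[, setdiff(colnames(m), unknown), drop = FALSE]
  }
  if (mode == "leftright") {
    base <- sub("_(lh|rh)$", "", colnames(m))
    for (rg in unique(base)) {
      have <- colnames(m)[base == rg]
      if (length(have) != 2L)
        stop("region ", rg, " is missing its hemisphere partner column")
    }
    miss <- setdiff(canon, unique(base))
    if (length(miss))
      stop("thickness table missing region(s): ", paste(miss, collapse = ", "))
    m <- m[, expect, drop = FALSE]
  } else {
    miss <- setdiff(canon, colnames(m))
    if (length(miss))
      stop("thickness table missing region(s): ", paste(miss, collapse = ", "))
    m <- m[, canon, drop = FALSE]
  }
  v <- m[is.finite(m)]
  if (length(v) && (any(v <= 0) || any(v >= 6)))
    stop("thickness values must lie in (0, 6) mm")
  attr(m, "mode") <- mode
  m
}

#' @rdname readThickness
#' @param x thickness matrix to write.
#' @export
writeThickness <- function(x, path) {
  writeTable(as.data.frame(x, check.names = FALSE), path,
             rowLabel = "subject_id")
}

#' Assemble a TrimodalCohort from its component tables
#'
#' @param phenotype data.frame as returned by [readPhenotypes()].
#' @param counts integer matrix as returned by [readCounts()].
#' @param annotation data.frame as returned by [readGeneAnnotation()].
#' @param thickness matrix as returned by [readThickness()].
#' @param groundTruth optional generator parameter list (synthetic cohorts).
#' @return a validated [TrimodalCohort-class] object.
#' @export
trimodalCohort <- function(phenotype, counts = matrix(0L, 0, 0),
                           annotation = data.frame(),
                           thickness = matrix(numeric(), 0, 0),
                           groundTruth = list()) {
  mode <- attr(thickness, "mode") %||%
    (if (ncol(thickness) == 68L) "leftright" else "averaged")
  attr(thickness, "mode") <- NULL
  new("TrimodalCohort", phenotype = phenotype, counts = counts,
      annotation = annotation, thickness = thickness,
      thicknessMode = mode, groundTruth = groundTruth)
}
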