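#' Pipeline configuration
#'
#' Builds the configuration object that [runPipeline()] consumes. Either the
#' four input paths are given, or `synthetic = TRUE` generates the inputs
#' from [defaultConfig()] at run time.
#'
#' @param phenotypes,counts,annotation,thickness input file paths (ignored
#'   when `synthetic = TRUE`).
#' @param synthetic generate a synthetic cohort instead of reading files.
#' @param preset generator preset for synthetic runs.
#' @param thicknessMode `"leftright"` or `"averaged"` for the thickness file.
#' @param covariates covariate columns for gene/cortex analyses.
#' @param covariatesCognition covariate columns when cognition is involved.
#' @param minMeanCount,varPercentile,pseudocount preprocessing parameters
#'   (see [filterCounts()], [log2RPM()]).
#' @param alphaNominal,alphaFDR screening thresholds (see [pairwiseScreen()]).
#' @param nBoot bootstrap resamples for the mediation stage.
#' @param seed integer seed; with fixed inputs and config the pipeline output
#'   is byte-identical across runs.
#' @param outdir output directory.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(phenotypes = NULL, counts = NULL,
                           annotation = NULL, thickness = NULL,
                           synthetic = FALSE, preset = "paper-like",
                           thicknessMode = "leftright",
                           covariates = c("age", "sex"),
                           covariatesCognition = c("age", "sex", "education"),
                           minMeanCount = 4, varPercentile = 15,
                           pseudocount = 1, alphaNominal = 0.01,
                           alphaFDR = 0.05, nBoot = 5000, seed = 1L,
                           outdir = "trimodal-output") {
  if (varPercentile < 0 || varPercentile >= 100)
    stop("varPercentile must lie in [0, 100)")
  if (nBoot < 1) stop("nBoot must be >= 1")
  if (length(seed) != 1L || is.na(seed) || seed < 0)
    stop("seed must be a non-negative integer")
  cfg <- list(
    inputs = list(phenotypes = phenotypes, counts = counts,
                  annotation = annotation, thickness = thickness),
    synthetic = isTRUE(synthetic), preset = preset,
    thicknessMode = thicknessMode,
    covariates = covariates, covariatesCognition = covariatesCognition,
    preprocess = list(minMeanCount = minMeanCount,
                      varPercentile = varPercentile,
                      pseudocount = pseudocount),
    coupling = list(alphaNominal = alphaNominal, alphaFDR = alphaFDR),
    mediation = list(nBoot = nBoot),
    seed = as.integer(seed), outdir = outdir)
  if (!cfg$synthetic) {
    missing <- names(Filter(is.null, cfg$inputs))
    if (length(missing))
      stop("configuration error: missing input path(s) ",
           paste(missing, collapse = ", "),
           " and synthetic mode is off")
  }
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Sections: `inputs` (phenotypes/counts/annotation/thickness paths),
#' `preprocess`, `coupling`, `mediation`, `output` (outdir), plus top-level
#' `synthetic`, `preset`, `seed`, `covariates`, `covariates_cognition`.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pipelineConfig(
    phenotypes = y$inputs$phenotypes, counts = y$inputs$counts,
    annotation = y$inputs$annotation, thickness = y$inputs$thickness,
    synthetic = isTRUE(y$synthetic), preset = y$preset %||% "paper-like",
    thicknessMode = y$inputs$thickness_mode %||% "leftright",
    covariates = unlist(y$covariates) %||% c("age", "sex"),
    covariatesCognition = unlist(y$covariates_cognition) %||%
      c("age", "sex", "education"),
    minMeanCount = y$preprocess$min_mean_count %||% 4,
    varPercentile = y$preprocess$var_percentile %||% 15,
    pseudocount = y$preprocess$pseudocount %||% 1,
    alphaNominal = y$coupling$alpha_nominal %||% 0.01,
    alphaFDR = y$coupling$alpha_fdr %||% 0.05,
    nBoot = y$mediation$n_boot %||% 5000,
    seed = y$seed %||% 1L,
    outdir = y$output$outdir %||% "trimodal-output")
}

#' Run the full tri-modal coupling pipeline
#'
#' Executes the four stages in order -- preprocess (count filter, log2-CPM,
#' signature-gene selection, hemisphere averaging), group statistics
#' (demographics, ANCOVA tables, differential expression), coupling
#' (per-group Fisher-Z matrices, paired scope comparisons, subset-stratified
#' comparisons, gene-by-feature screens) and mediation (bootstrap indirect
#' effect for the top screen hit) -- writing every output table to
#' `config$outdir` together with a manifest recording the package version,
#' config hash, seed and stage outputs. Identical inputs, config and seed
#' give byte-identical outputs. If a stage fails, partial outputs are
#' removed and the error names the stage.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  # hash covers the analysis parameters, not the output location
  hash <- configHash(unclass(config)[setdiff(names(config), "outdir")])
  stamp <- paste0("trimodal ", as.character(utils::packageVersion("trimodal")),
                  " config=", hash, " seed=", config$seed)
  emit <- function(x, name, rowLabel = NULL) {
    p <- file.path(outdir, name)
    writeTable(x, p, rowLabel = rowLabel, comment = stamp)
    written <<- c(written, p)
    p
  }
  emitJSON <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    written <<- c(written, p)
    p
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(package = "trimodal",
                   version = as.character(utils::packageVersion("trimodal")),
                   config_hash = hash, seed = config$seed, stages = list())

  # ---- inputs ----
  dat <- stage("input", {
    if (config$synthetic) {
      coh <- generateCohort(defaultConfig(config$preset), seed = config$seed)
      list(phenotype = phenotypes(coh), counts = rawCounts(coh),
           annotation = geneAnnotation(coh),
           thickness = thicknessTable(coh))
    } else {
      list(phenotype = readPhenotypes(config$inputs$phenotypes),
           counts = readCounts(config$inputs$counts),
           annotation = readGeneAnnotation(config$inputs$annotation),
           thickness = readThickness(config$inputs$thickness,
                                     mode = config$thicknessMode))
    }
  })

  # ---- stage 1: preprocess ----
  pre <- stage("preprocess", {
    flt <- filterCounts(dat$counts, config$preprocess$minMeanCount,
                        config$preprocess$varPercentile)
    expr <- log2RPM(flt$counts, pseudocount = config$preprocess$pseudocount,
                    libSizes = colSums(dat$counts))
    sig <- selectSignatureGenes(expr, dat$annotation)
    thick <- if (identical(attr(dat$thickness, "mode"), "leftright"))
      averageHemispheres(dat$thickness) else dat$thickness
    emitJSON(flt$report, "filter_report.json")
    emit(as.data.frame(signif(sig, 10)), "expression_log2cpm.tsv",
         rowLabel = "gene")
    emit(as.data.frame(signif(thick, 10)), "thickness_averaged.tsv",
         rowLabel = "subject_id")
    list(expr = sig, thickness = thick)
  })
  manifest$stages$preprocess <- c("filter_report.json",
                                  "expression_log2cpm.tsv",
                                  "thickness_averaged.tsv")

  # ---- stage 2: group statistics ----
  stage("group_stats", {
    ph <- dat$phenotype
    demo <- demographicsTable(ph)
    emit(demo, "demographics.tsv")
    covCog <- ph[, config$covariatesCognition, drop = FALSE]
    mccb <- intersect(mccbDomains(composite = TRUE), names(ph))
    if (length(mccb)) {
      rows <- lapply(mccb, function(v)
        ancovaGroupTest(ph[[v]], ph$group, covCog, outcome = v))
      tab <- do.call(rbind, rows)
      tab$q <- bhFDR(tab$p)
      emit(tab, "mccb_ancova.tsv")
    }
    subs <- grep("^subset_", names(ph), value = TRUE)
    if (length(subs)) {
      rows <- lapply(subs, function(v)
        ancovaGroupTest(ph[[v]], ph$group,
                        ph[, config$covariates, drop = FALSE], outcome = v))
      tab <- do.call(rbind, rows)
      tab$q <- bhFDR(tab$p)
      emit(tab, "subset_ancova.tsv")
    }
    de <- differentialExpression(pre$expr, ph$group,
                                 ph[, config$covariates, drop = FALSE])
    emit(de, "differential_expression.tsv")
  })
  manifest$stages$group_stats <- c("demographics.tsv", "mccb_ancova.tsv",
                                   "subset_ancova.tsv",
                                   "differential_expression.tsv")

  # ---- stage 3: coupling ----
  coup <- stage("coupling", {
    ph <- dat$phenotype
    cog <- cognitionMatrix(ph)
    sets <- lapply(c(HC = "HC", FES = "FES"), function(g)
      buildCoupling(pre$expr, pre$thickness, cog, ph, group = g,
                    covariates = config$covariates,
                    covariatesCognition = config$covariatesCognition))
    for (g in names(sets))
      for (s in names(sets[[g]]))
        emit(as.data.frame(signif(couplingZ(sets[[g]][[s]]), 10)),
             sprintf("zr_%s_%s.tsv", g, s), rowLabel = "feature")
    cmp <- compareCouplingSets(sets$HC, sets$FES)
    emit(cmp, "coupling_comparison.tsv")
    strat <- subsetStratifiedComparison(sets$HC, sets$FES)
    emit(strat, "subset_comparison.tsv")
    screens <- list()
    for (g in c("HC", "FES")) {
      screens[[paste0(g, "_cortex")]] <-
        cbind(group = g, block = "cortex",
              pairwiseScreen(pre$expr, pre$thickness, ph, group = g,
                             covariates = config$covariatesCognition,
                             alphaNominal = config$coupling$alphaNominal,
                             alphaFDR = config$coupling$alphaFDR))
      screens[[paste0(g, "_cognition")]] <-
        cbind(group = g, block = "cognition",
              pairwiseScreen(pre$expr, cog, ph, group = g,
                             covariates = config$covariatesCognition,
                             alphaNominal = config$coupling$alphaNominal,
                             alphaFDR = config$coupling$alphaFDR))
    }
    screenTab <- do.call(rbind, c(screens, list(make.row.names = FALSE)))
    emit(screenTab, "pairwise_screen.tsv")
    list(sets = sets, screens = screenTab, cog = cog)
  })
  manifest$stages$coupling <-
    c(sprintf("zr_%s_%s.tsv", rep(c("HC", "FES"), each = 5),
              c("gene_gene", "cortex_cortex", "gene_cortex",
                "gene_cognition", "cortex_cognition")),
      "coupling_comparison.tsv", "subset_comparison.tsv",
      "pairwise_screen.tsv")

  # ---- stage 4: mediation ----
  stage("mediation", {
    ph <- dat$phenotype
    hits <- coup$screens[coup$screens$block == "cortex", ]
    hits <- hits[order(hits$p, hits$gene, hits$feature), ]
    top <- hits[1L, ]
    grpSubj <- ph$subject_id[ph$group == top$group]
    ids <- Reduce(intersect, list(grpSubj, colnames(pre$expr),
                                  rownames(pre$thickness),
                                  rownames(coup$cog)))
    x <- pre$expr[top$gene, ids]
    m <- pre$thickness[ids, top$feature]
    # outcome: the MCCB domain most associated with the mediator region
    phG <- ph[match(ids, ph$subject_id), ]
    covs <- phG[, config$covariatesCognition, drop = FALSE]
    domP <- vapply(colnames(coup$cog), function(d) {
      ok <- stats::complete.cases(m, coup$cog[ids, d], covs)
      if (sum(ok) < 10) return(1)
      partialCorrelation(m[ok], coup$cog[ids, d][ok],
                         covs[ok, , drop = FALSE])$p
    }, numeric(1))
    yDom <- names(which.min(domP))
    y <- coup$cog[ids, yDom]
    med <- bootstrapMediation(x, m, y, covs,
                              nBoot = config$mediation$nBoot,
                              seed = config$seed,
                              variables = c(x = top$gene, m = top$feature,
                                            y = yDom))
    emitJSON(list(x = top$gene, m = top$feature, y = yDom,
                  group = top$group,
                  estimates = as.list(med@estimates),
                  cprime_t = med@cprimeT, cprime_p = med@cprimeP,
                  ci = med@ci, n_boot = med@nBoot, n = med@n,
                  classification = med@classification),
             "mediation.json")
  })
  manifest$stages$mediation <- "mediation.json"

  emitJSON(manifest, "manifest.json")
  invisible(manifest)
}
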