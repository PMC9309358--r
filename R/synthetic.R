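# Synthetic two-group tri-modal cohort generator.
#
# One latent factor u_s ~ N(0,1) per subject couples the three modalities;
# per-feature loadings (lambda for genes, mu for regions, nu for cognition)
# are group-specific, so group differences in coupling are encoded entirely
# by loadings while group differences in level are encoded by mean shifts.
# For unit-variance feature noise the implied latent correlation between two
# features with loadings l and m is l*m / sqrt((l^2+1)(m^2+1)), which gives
# the closed-form oracle in impliedCoupling().

# mean and sd of 100 * plogis(N(mu, sigma)) by numerical integration
logitNormalMoments <- function(mu, sigma) {
  m1 <- stats::integrate(function(z) stats::plogis(mu + sigma * z) *
                           stats::dnorm(z), -8, 8)$value
  m2 <- stats::integrate(function(z) stats::plogis(mu + sigma * z)^2 *
                           stats::dnorm(z), -8, 8)$value
  c(mean = 100 * m1, sd = 100 * sqrt(max(m2 - m1^2, 0)))
}

# solve (mu, sigma) so that 100*plogis(N(mu,sigma)) has the target pct
# mean and sd; deterministic (no RNG)
calibrateLogitNormal <- function(meanPct, sdPct) {
  obj <- function(par) {
    mo <- logitNormalMoments(par[1], exp(par[2]))
    (mo["mean"] - meanPct)^2 + (mo["sd"] - sdPct)^2
  }
  start <- c(stats::qlogis(meanPct / 100), log(sdPct / meanPct))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = unname(fit$par[1]), sigma = unname(exp(fit$par[2])))
}

# per-gene attenuation of the observed log2-CPM correlation caused by
# negative-binomial counting noise (delta method on the log scale)
geneAttenuation <- function(config, group) {
  g <- config$genes
  fc <- if (group == "FES") g$log2FC else 0
  lam <- config$lambdaScale[[group]] * g$pattern
  meanLib <- exp(config$libSize[["meanlog"]] + config$libSize[["sdlog"]]^2 / 2)
  muCount <- meanLib / 1e6 * 2^(g$base + fc)
  v <- (trigamma(1 / config$dispersion) + 1 / muCount) / log(2)^2
  sv <- config$sigmaX^2 * (lam^2 + 1)
  sqrt(sv / (sv + v))
}

latentBlock <- function(l, m) {
  outer(l / sqrt(l^2 + 1), m / sqrt(m^2 + 1))
}

# mean Fisher Z over the gene x feature block as a function of the feature
# loading scale b; used to calibrate muScale / nuScale against a target
blockMeanZ <- function(b, lam, alphaGene, pat) {
  m <- b * pat
  r <- latentBlock(lam, m) * alphaGene
  mean(atanh(r))
}

# Background (non-signature) genes: zero loadings and zero fold change, with
# log2-CPM baselines spread so that (i) the column totals are dominated by
# factor-free genes -- otherwise per-million normalization of a 54-gene
# matrix would cancel the shared latent factor -- and (ii) the low-abundance
# tail exercises the count filter. Baselines are shifted so the expected
# per-million total of all genes is ~1e6, making baselines true log2-CPMs.
backgroundGeneTable <- function(n = 446L, sigBase) {
  base <- seq(-7, 14.5, length.out = n)
  shift <- log2(1e6 / (sum(2^base) + sum(2^sigBase)))
  base <- base + shift
  nLow <- min(20L, n)
  base[seq_len(nLow)] <- seq(-8, -2.5, length.out = nLow)
  data.frame(gene = sprintf("BKG%03d", seq_len(n)), base = base)
}

#' Generator configuration presets
#'
#' Builds a `GeneratorConfig`: the full parameter set of the synthetic
#' cohort generator (sample sizes, gene/region/domain tables, group-specific
#' latent-factor loading scales, covariate distributions, negative-binomial
#' dispersion, library-size distribution, monocyte subset-percentage
#' distributions and optional sub-cohort missingness).
#'
#' Presets:
#' \describe{
#' \item{paper-like}{111 controls vs 128 patients, 54 signature genes split
#'   4/9/20/21 across subsets, 34 regions with mean thinning of about
#'   -0.05 mm, MCCB composite deficit of about -13.8 T, a nonclassical
#'   monocyte decrease (7.61\% to 5.27\%), and loading scales calibrated so
#'   the implied block-mean gene-cortex Fisher Z is about -0.116 (HC) vs
#'   -0.025 (FES) and gene-cognition about -0.088 (HC) vs +0.085 (FES).}
#' \item{null}{all loadings and all group effects zero.}
#' \item{strong-coupling}{loading scales of +/-3 so every implied latent
#'   correlation has magnitude at least 0.3.}
#' }
#'
#' @param preset one of "paper-like", "null", "strong-coupling".
#' @return a `GeneratorConfig` list.
#' @seealso [generateCohort()], [impliedCoupling()]
#' @export
defaultConfig <- function(preset = c("paper-like", "null", "strong-coupling")) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    nPerGroup = c(HC = 111L, FES = 128L),
    genes = signatureGeneTable(),
    background = backgroundGeneTable(446L, signatureGeneTable()$base),
    regions = corticalRegionTable(),
    domains = mccbDomainTable(),
    lambdaScale = c(HC = 0.6, FES = 0.4),
    muScale = c(HC = NA_real_, FES = NA_real_),
    nuScale = c(HC = NA_real_, FES = NA_real_),
    covariates = list(
      age = list(HC = c(mean = 32.99, sd = 9.57),
                 FES = c(mean = 30.64, sd = 9.53), range = c(18, 55)),
      sexPMale = c(HC = 56 / 111, FES = 55 / 128),
      education = list(HC = c(mean = 13.79, sd = 2.59),
                       FES = c(mean = 12.76, sd = 3.41), range = c(8, 22)),
      smokerP = c(HC = 23 / 111, FES = 18 / 128)),
    effects = list(betaAgeGene = 0.01, betaSexGene = 0.10,
                   gammaAgeThickness = -0.005, gammaEduCognition = 0.8),
    sigmaX = 1, sThickness = 0.10, hemisphericSD = 0.02,
    dispersion = 0.2,
    libSize = c(meanlog = log(2e7), sdlog = 0.25),
    subsetPct = list(
      nonclassical = list(HC = calibrateLogitNormal(7.61, 3.21),
                          FES = calibrateLogitNormal(5.27, 3.01)),
      intermediate = list(HC = calibrateLogitNormal(5.0, 2.0),
                          FES = calibrateLogitNormal(5.0, 2.0))),
    missingness = list(imaging = NULL, mccb = NULL, flow = NULL)
  )
  if (preset == "null") {
    cfg$lambdaScale[] <- 0; cfg$muScale[] <- 0; cfg$nuScale[] <- 0
    cfg$genes$log2FC <- 0
    cfg$regions$shift <- 0
    cfg$domains$shift <- 0
    cfg$subsetPct$nonclassical$FES <- cfg$subsetPct$nonclassical$HC
  } else if (preset == "strong-coupling") {
    cfg$lambdaScale[] <- 3; cfg$muScale[] <- -3; cfg$nuScale[] <- -3
  } else {
    targets <- list(gene_cortex = c(HC = -0.116, FES = -0.025),
                    gene_cognition = c(HC = -0.088, FES = 0.085))
    pat7 <- cfg$domains$pattern[seq_len(7)]
    for (g in c("HC", "FES")) {
      lam <- cfg$lambdaScale[[g]] * cfg$genes$pattern
      alpha <- geneAttenuation(cfg, g)
      cfg$muScale[[g]] <- stats::uniroot(function(b)
        blockMeanZ(b, lam, alpha, cfg$regions$pattern) -
          targets$gene_cortex[[g]], c(-50, 50), tol = 1e-10)$root
      cfg$nuScale[[g]] <- stats::uniroot(function(b)
        blockMeanZ(b, lam, alpha, pat7) -
          targets$gene_cognition[[g]], c(-50, 50), tol = 1e-10)$root
    }
  }
  structure(cfg, class = "GeneratorConfig")
}

validateConfig <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig") || is.list(config))
  stopifnot(all(config$nPerGroup >= 1),
            config$dispersion > 0,
            config$libSize[["meanlog"]] > 0,
            !anyNA(config$muScale), !anyNA(config$nuScale))
  split <- table(config$genes$subset)
  stopifnot(sum(split) == nrow(config$genes))
  invisible(config)
}

#' Closed-form implied correlations of the generator
#'
#' For the one-factor model, the implied correlation between two features
#' with loadings \eqn{l} and \eqn{m} (unit-variance feature noise) is
#' \eqn{l\,m / \sqrt{(l^2+1)(m^2+1)}}. The `"latent"` layer returns exactly
#' these values. The `"observed"` layer additionally multiplies in each
#' gene's attenuation factor for negative-binomial counting noise on the
#' log2-CPM scale (delta-method variance
#' \eqn{(\psi'(1/\phi) + 1/\mu)/\ln(2)^2}), which is what empirical partial
#' correlations of the generated tables converge to. Covariate effects do
#' not appear because partial correlation removes them. Cognition blocks use
#' the seven MCCB domains (no composite).
#'
#' @param config a `GeneratorConfig` from [defaultConfig()].
#' @param group "HC" or "FES".
#' @param layer "latent" (pure closed form) or "observed" (count-noise
#'   attenuated).
#' @return named list of implied correlation matrices: `gene_gene`,
#'   `cortex_cortex`, `gene_cortex`, `gene_cognition`, `cortex_cognition`.
#' @export
impliedCoupling <- function(config, group = c("HC", "FES"),
                            layer = c("latent", "observed")) {
  group <- match.arg(group)
  layer <- match.arg(layer)
  validateConfig(config)
  lam <- config$lambdaScale[[group]] * config$genes$pattern
  mu <- config$muScale[[group]] * config$regions$pattern
  dom <- config$domains[config$domains$domain %in% mccbDomains(), ]
  nu <- config$nuScale[[group]] * dom$pattern
  alpha <- if (layer == "observed") geneAttenuation(config, group)
           else rep(1, length(lam))
  gg <- latentBlock(lam, lam) * outer(alpha, alpha)
  diag(gg) <- 1
  cc <- latentBlock(mu, mu); diag(cc) <- 1
  out <- list(
    gene_gene = gg,
    cortex_cortex = cc,
    gene_cortex = latentBlock(lam, mu) * alpha,
    gene_cognition = latentBlock(lam, nu) * alpha,
    cortex_cognition = latentBlock(mu, nu))
  dn <- list(gene = config$genes$gene, cortex = config$regions$region,
             cognition = dom$domain)
  blocks <- list(gene_gene = c("gene", "gene"),
                 cortex_cortex = c("cortex", "cortex"),
                 gene_cortex = c("gene", "cortex"),
                 gene_cognition = c("gene", "cognition"),
                 cortex_cognition = c("cortex", "cognition"))
  for (b in names(out))
    dimnames(out[[b]]) <- list(dn[[blocks[[b]][1]]], dn[[blocks[[b]][2]]])
  out
}

truncNorm <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

#' Generate a synthetic tri-modal cohort
#'
#' Draws a complete two-group cohort from the one-factor model: covariates
#' (truncated-normal age and education, Bernoulli sex and smoking), one
#' latent factor per subject, negative-binomial signature-gene counts whose
#' log2 mean carries the group fold change and the latent signal,
#' left/right cortical thickness (bilateral value plus/minus hemispheric
#' noise), MCCB domain scores, and logistic-normal monocyte subset
#' percentages with the group shift on the nonclassical component. Optional
#' sub-cohort missingness (`config$missingness$imaging`, `$mccb`, `$flow`,
#' each a named vector like `c(HC = 54, FES = 60)`) blanks the corresponding
#' block for all but the first k subjects of each group, emulating nested
#' imaging/cognition/flow-cytometry sub-cohorts.
#'
#' The returned cohort carries a ground-truth record (config, seed, latent
#' loadings and implied correlations); `generateCohort(groundTruth(x)$config,
#' groundTruth(x)$seed)` regenerates the cohort bit-identically.
#'
#' @param config a `GeneratorConfig` from [defaultConfig()].
#' @param seed integer RNG seed; the cohort is a pure function of
#'   (config, seed).
#' @return a [TrimodalCohort-class] with left+right thickness columns.
#' @export
#' @examples
#' coh <- generateCohort(defaultConfig("null"), seed = 1)
#' coh
generateCohort <- function(config = defaultConfig(), seed = 1L) {
  validateConfig(config)
  withSeed(seed, {
    groups <- c("HC", "FES")
    nTot <- sum(config$nPerGroup)
    ids <- sprintf("S%04d", seq_len(nTot))
    grp <- factor(rep(groups, config$nPerGroup[groups]), levels = groups)
    genes <- config$genes; regions <- config$regions; domains <- config$domains
    nG <- nrow(genes); nR <- nrow(regions)
    phenotype <- NULL; counts <- NULL; thickLR <- NULL
    uAll <- stats::setNames(numeric(nTot), ids)
    for (g in groups) {
      n <- config$nPerGroup[[g]]
      sel <- which(grp == g)
      cv <- config$covariates
      age <- truncNorm(n, cv$age[[g]]["mean"], cv$age[[g]]["sd"],
                       cv$age$range)
      sex <- stats::rbinom(n, 1, cv$sexPMale[[g]])     # 1 = male
      edu <- truncNorm(n, cv$education[[g]]["mean"], cv$education[[g]]["sd"],
                       cv$education$range)
      smoker <- stats::rbinom(n, 1, cv$smokerP[[g]]) == 1
      u <- stats::rnorm(n)
      uAll[sel] <- u
      ef <- config$effects
      # genes: latent signal -> negative-binomial counts
      lam <- config$lambdaScale[[g]] * genes$pattern
      covTerm <- ef$betaAgeGene * (age - mean(age)) +
        ef$betaSexGene * (sex - mean(sex))
      x <- outer(lam, u) + matrix(stats::rnorm(nG * n), nG, n) +
        matrix(covTerm, nG, n, byrow = TRUE)
      fc <- if (g == "FES") genes$log2FC else 0
      lib <- stats::rlnorm(n, config$libSize[["meanlog"]],
                           config$libSize[["sdlog"]])
      muC <- sweep(2^(genes$base + fc + config$sigmaX * x), 2, lib / 1e6, "*")
      cnt <- matrix(stats::rnbinom(nG * n, mu = muC,
                                   size = 1 / config$dispersion), nG, n)
      dimnames(cnt) <- list(genes$gene, ids[sel])
      bg <- config$background
      if (!is.null(bg) && nrow(bg)) {
        nB <- nrow(bg)
        xB <- matrix(stats::rnorm(nB * n), nB, n)
        muB <- sweep(2^(bg$base + config$sigmaX * xB), 2, lib / 1e6, "*")
        cntB <- matrix(stats::rnbinom(nB * n, mu = muB,
                                      size = 1 / config$dispersion), nB, n)
        dimnames(cntB) <- list(bg$gene, ids[sel])
        cnt <- rbind(cnt, cntB)
      }
      # thickness: bilateral latent value split into hemispheres
      mu <- config$muScale[[g]] * regions$pattern
      shift <- if (g == "FES") regions$shift else 0
      tb <- regions$mean + shift +
        config$sThickness * (outer(mu, u) + matrix(stats::rnorm(nR * n),
                                                   nR, n)) +
        matrix(ef$gammaAgeThickness * (age - mean(age)), nR, n, byrow = TRUE)
      hem <- matrix(stats::rnorm(nR * n, 0, config$hemisphericSD), nR, n)
      lr <- matrix(NA_real_, n, 2 * nR,
                   dimnames = list(ids[sel],
                     as.vector(t(outer(regions$region, c("_lh", "_rh"),
                                       paste0)))))
      lr[, paste0(regions$region, "_lh")] <- t(tb + hem)
      lr[, paste0(regions$region, "_rh")] <- t(tb - hem)
      # cognition
      cog <- matrix(NA_real_, n, nrow(domains),
                    dimnames = list(ids[sel], domains$domain))
      nuFull <- config$nuScale[[g]] * domains$pattern
      sdEdu <- cv$education[[g]]["sd"]
      for (k in seq_len(nrow(domains))) {
        sdT <- if (g == "FES") domains$sd_fes[k] else domains$sd_hc[k]
        resVar <- max(sdT^2 - ef$gammaEduCognition^2 * sdEdu^2,
                      0.25 * sdT^2)
        sK <- sqrt(resVar / (nuFull[k]^2 + 1))
        cog[, k] <- domains$mean_hc[k] +
          (if (g == "FES") domains$shift[k] else 0) +
          ef$gammaEduCognition * (edu - mean(edu)) +
          sK * (nuFull[k] * u + stats::rnorm(n))
      }
      # monocyte subset percentages (logistic-normal components)
      pn <- config$subsetPct$nonclassical[[g]]
      pint <- config$subsetPct$intermediate[[g]]
      pctNon <- 100 * stats::plogis(stats::rnorm(n, pn["mu"], pn["sigma"]))
      pctInt <- 100 * stats::plogis(stats::rnorm(n, pint["mu"],
                                                 pint["sigma"]))
      ph <- data.frame(
        subject_id = ids[sel], group = g, age = age,
        sex = factor(ifelse(sex == 1, "male", "female"),
                     levels = c("female", "male")),
        education = edu, smoker = smoker,
        stringsAsFactors = FALSE)
      ph[, domains$domain] <- cog
      ph$subset_classical <- 100 - pctNon - pctInt
      ph$subset_intermediate <- pctInt
      ph$subset_nonclassical <- pctNon
      phenotype <- rbind(phenotype, ph)
      counts <- cbind(counts, cnt)
      thickLR <- rbind(thickLR, lr)
    }
    phenotype$group <- factor(phenotype$group, levels = groups)
    # optional nested sub-cohorts: keep the first k subjects of each group
    droppedIds <- function(kVec) {
      keep <- unlist(lapply(groups, function(g) {
        idsG <- phenotype$subject_id[phenotype$group == g]
        idsG[seq_len(min(kVec[[g]], length(idsG)))]
      }))
      setdiff(phenotype$subject_id, keep)
    }
    ms <- config$missingness
    if (!is.null(ms$imaging))
      thickLR[droppedIds(ms$imaging), ] <- NA_real_
    if (!is.null(ms$mccb))
      phenotype[match(droppedIds(ms$mccb), phenotype$subject_id),
                domains$domain] <- NA_real_
    if (!is.null(ms$flow))
      phenotype[match(droppedIds(ms$flow), phenotype$subject_id),
                grep("^subset_", names(phenotype))] <- NA_real_
    ann <- data.frame(gene = genes$gene, subset = genes$subset)
    gt <- list(seed = as.integer(seed), config = config, u = uAll,
               implied = list(
                 HC = impliedCoupling(config, "HC", "observed"),
                 FES = impliedCoupling(config, "FES", "observed")))
    attr(thickLR, "mode") <- "leftright"
    trimodalCohort(phenotype, counts, ann, thickLR, groundTruth = gt)
  })
}

#' Extract the MCCB cognition block as a matrix
#'
#' @param phenotype phenotype data.frame with MCCB columns.
#' @param composite include the composite column.
#' @return subjects x domains numeric matrix with subject_id rownames.
#' @export
cognitionMatrix <- function(phenotype, composite = FALSE) {
  cols <- intersect(mccbDomains(composite), names(phenotype))
  if (!length(cols)) stop("phenotype has no MCCB columns")
  m <- as.matrix(phenotype[, cols, drop = FALSE])
  rownames(m) <- phenotype$subject_id
  m
}

#' Write a cohort's four input tables plus ground truth to a directory
#'
#' Emits `phenotypes.tsv`, `counts.tsv`, `annotation.tsv`, `thickness.tsv`
#' and, for synthetic cohorts, `ground_truth.json`.
#'
#' @param cohort a [TrimodalCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             counts = file.path(dir, "counts.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             thickness = file.path(dir, "thickness.tsv"))
  writePhenotypes(phenotypes(cohort), paths["phenotypes"])
  writeCounts(rawCounts(cohort), paths["counts"])
  writeTable(geneAnnotation(cohort), paths["annotation"])
  writeThickness(thicknessTable(cohort), paths["thickness"])
  gt <- groundTruth(cohort)
  if (length(gt)) {
    gtPath <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, gtPath, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    paths <- c(paths, ground_truth = gtPath)
  }
  invisible(paths)
}
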