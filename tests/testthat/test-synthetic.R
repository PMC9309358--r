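test_that("implied coupling matches its closed form and a simulation", {
  cfg <- defaultConfig("null")
  cfg$lambdaScale[] <- c(0.5, 0.5)
  cfg$muScale[] <- c(-0.4, -0.4)
  cfg$genes$pattern[] <- 1
  cfg$regions$pattern[] <- 1
  imp <- impliedCoupling(cfg, "HC", layer = "latent")
  expect_equal(unique(as.vector(imp$gene_cortex)),
               -0.2 / sqrt(1.25 * 1.16), tolerance = 1e-12)

  # simulate the latent one-factor signals directly as an oracle
  set.seed(55)
  n <- 1e5
  u <- rnorm(n)
  g <- 0.5 * u + rnorm(n)
  t <- -0.4 * u + rnorm(n)
  expect_equal(cor(g, t), imp$gene_cortex[1, 1], tolerance = 0.012)

  # zero gene loadings kill every gene block
  null <- defaultConfig("null")
  impNull <- impliedCoupling(null, "FES")
  expect_true(all(impNull$gene_cortex == 0))
  expect_true(all(impNull$gene_cognition == 0))
  expect_equal(unname(diag(impNull$gene_gene)), rep(1, 54))

  # lambda = mu = 1 gives exactly 1/2
  cfg2 <- cfg
  cfg2$lambdaScale[] <- 1; cfg2$muScale[] <- 1
  expect_equal(unique(as.vector(
    impliedCoupling(cfg2, "HC", "latent")$gene_cortex)), 0.5,
    tolerance = 1e-12)
})

test_that("presets encode their contract", {
  null <- defaultConfig("null")
  expect_true(all(null$lambdaScale == 0) && all(null$muScale == 0))
  expect_true(all(null$genes$log2FC == 0))
  expect_true(all(null$regions$shift == 0))

  paper <- defaultConfig("paper-like")
  expect_identical(unname(paper$nPerGroup), c(111L, 128L))
  expect_identical(as.integer(table(paper$genes$subset)), c(4L, 9L, 20L, 21L))
  expect_equal(mean(paper$regions$shift), -0.049, tolerance = 0.005)
  dom <- paper$domains
  expect_equal(dom$shift[dom$domain == "mccb_composite"], -13.76)
  # calibrated implied block means hit the published-scale targets
  for (g in c("HC", "FES")) {
    imp <- impliedCoupling(paper, g, "observed")
    expect_equal(mean(atanh(imp$gene_cortex)),
                 c(HC = -0.116, FES = -0.025)[[g]], tolerance = 1e-6)
    expect_equal(mean(atanh(imp$gene_cognition)),
                 c(HC = -0.088, FES = 0.085)[[g]], tolerance = 1e-6)
  }

  strong <- defaultConfig("strong-coupling")
  impS <- impliedCoupling(strong, "HC", "latent")
  for (b in names(impS)) {
    off <- impS[[b]]
    if (nrow(off) == ncol(off) &&
        all(rownames(off) == colnames(off))) diag(off) <- NA
    expect_true(all(abs(off) >= 0.3, na.rm = TRUE), label = b)
  }

  expect_error(defaultConfig("unknown"), "arg")
})

test_that("cohorts are deterministic in seed and regenerable", {
  cfg <- defaultConfig("paper-like")
  cfg$nPerGroup <- c(HC = 30L, FES = 30L)
  a <- generateCohort(cfg, seed = 9)
  b <- generateCohort(cfg, seed = 9)
  expect_identical(rawCounts(a), rawCounts(b))
  expect_identical(phenotypes(a), phenotypes(b))
  expect_identical(thicknessTable(a), thicknessTable(b))

  c2 <- generateCohort(cfg, seed = 10)
  expect_false(identical(rawCounts(a), rawCounts(c2)))

  # the ground-truth record regenerates the cohort bit-identically
  gt <- groundTruth(a)
  re <- generateCohort(gt$config, gt$seed)
  expect_identical(rawCounts(re), rawCounts(a))
  expect_identical(phenotypes(re), phenotypes(a))
})

test_that("generated marginals match the generator's stated moments", {
  cfg <- defaultConfig("paper-like")
  cfg$nPerGroup <- c(HC = 3000L, FES = 3000L)
  coh <- generateCohort(cfg, seed = 14)
  ph <- phenotypes(coh)

  # monocyte subset percentages reach their calibration targets
  mN <- tapply(ph$subset_nonclassical, ph$group, mean)
  expect_equal(unname(mN["HC"]), 7.61, tolerance = 0.25)
  expect_equal(unname(mN["FES"]), 5.27, tolerance = 0.25)
  sdN <- tapply(ph$subset_nonclassical, ph$group, sd)
  expect_equal(unname(sdN["HC"]), 3.21, tolerance = 0.3)

  # covariates: age truncated to [18, 55], education to [8, 22]
  expect_true(all(ph$age >= 18 & ph$age <= 55))
  expect_true(all(ph$education >= 8 & ph$education <= 22))

  # thickness means: whole-cortex average near 2.59 (HC) with ~-0.05 shift
  th <- averageHemispheres(thicknessTable(coh))
  wb <- rowMeans(th)
  mW <- tapply(wb, ph$group[match(rownames(th), ph$subject_id)], mean)
  expect_equal(unname(mW["HC"]), 2.59, tolerance = 0.02)
  expect_lt(abs(unname(mW["FES"] - mW["HC"]) + 0.049), 0.01)

  # MCCB composite deficit near its configured shift
  mC <- tapply(ph$mccb_composite, ph$group, mean)
  expect_equal(unname(mC["FES"] - mC["HC"]), -13.76, tolerance = 0.7)

  # per-gene count means match the negative-binomial mean within MC error:
  # E[count] = E[lib]/1e6 * 2^(base+FC) * exp((ln2 * sigmaX)^2 Var(x) / 2)
  cnt <- rawCounts(coh)
  g <- cfg$genes
  lam <- cfg$lambdaScale[["FES"]] * g$pattern
  meanLib <- exp(cfg$libSize[["meanlog"]] + cfg$libSize[["sdlog"]]^2 / 2)
  expected <- meanLib / 1e6 * 2^(g$base + g$log2FC) *
    exp((log(2) * cfg$sigmaX)^2 * (lam^2 + 1) / 2)
  emp <- rowMeans(cnt[g$gene, ph$group == "FES"])
  relDev <- abs(emp - expected) / expected
  expect_lt(stats::median(relDev), 0.05)
  expect_lt(max(relDev), 0.25)
})

test_that("null cohorts show no coupling and loaded cohorts show it", {
  cfg <- defaultConfig("null")
  cfg$nPerGroup <- c(HC = 400L, FES = 30L)
  coh <- generateCohort(cfg, seed = 20)
  cnt <- rawCounts(coh); ph <- phenotypes(coh)
  expr <- log2RPM(filterCounts(cnt)$counts, libSizes = colSums(cnt))
  sig <- selectSignatureGenes(expr, geneAnnotation(coh))
  th <- averageHemispheres(thicknessTable(coh))
  cog <- cognitionMatrix(ph)
  cp <- buildCoupling(sig, th, cog, ph, "HC")
  r <- couplingR(cp$gene_cortex)
  expect_lt(abs(mean(r)), 0.01)
  expect_lt(mean(abs(r)), 3 / sqrt(400))

  # paper-like controls: negative mean gene-cortex partial correlation,
  # consistent with the implied closed form at moderate n
  cfgP <- defaultConfig("paper-like")
  cfgP$nPerGroup <- c(HC = 2000L, FES = 30L)
  cohP <- generateCohort(cfgP, seed = 21)
  cntP <- rawCounts(cohP); phP <- phenotypes(cohP)
  exprP <- log2RPM(filterCounts(cntP)$counts, libSizes = colSums(cntP))
  sigP <- selectSignatureGenes(exprP, geneAnnotation(cohP))
  thP <- averageHemispheres(thicknessTable(cohP))
  cogP <- cognitionMatrix(phP)
  cpP <- buildCoupling(sigP, thP, cogP, phP, "HC")
  imp <- impliedCoupling(cfgP, "HC", "observed")
  expect_lt(mean(couplingR(cpP$gene_cortex)), 0)
  expect_equal(mean(couplingR(cpP$gene_cortex)), mean(imp$gene_cortex),
               tolerance = 3 / sqrt(2000))
})

test_that("sub-cohort missingness blanks the right blocks", {
  cfg <- defaultConfig("paper-like")
  cfg$nPerGroup <- c(HC = 40L, FES = 40L)
  cfg$missingness <- list(imaging = c(HC = 20, FES = 25),
                          mccb = c(HC = 18, FES = 23),
                          flow = c(HC = 10, FES = 12))
  coh <- generateCohort(cfg, seed = 30)
  ph <- phenotypes(coh)
  th <- thicknessTable(coh)
  nObs <- tapply(stats::complete.cases(th),
                 ph$group[match(rownames(th), ph$subject_id)], sum)
  expect_equal(as.integer(nObs[c("HC", "FES")]), c(20L, 25L))
  nM <- tapply(!is.na(ph$mccb_composite), ph$group, sum)
  expect_equal(as.integer(nM[c("HC", "FES")]), c(18L, 23L))
  nF <- tapply(!is.na(ph$subset_nonclassical), ph$group, sum)
  expect_equal(as.integer(nF[c("HC", "FES")]), c(10L, 12L))
})
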