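test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(25:50, 1)
    k <- sample(1:5, 1)
    covs <- matrix(rnorm(n * k), n)
    x <- rnorm(n) + covs %*% rnorm(k)
    y <- rnorm(n) + covs %*% rnorm(k)
    pc <- partialCorrelation(as.numeric(x), as.numeric(y), covs)
    expect_equal(pc$r, oraclePartialCor(as.numeric(x), as.numeric(y), covs),
                 tolerance = 1e-10)
    expect_equal(pc$df, n - 2 - k)
  }
})

test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(19)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(partialCorrelation(x, y)$r, cor(x, y), tolerance = 1e-14)

  perf <- partialCorrelation(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(perf$r, 1)
  expect_true(perf$degenerate)

  # shared confounder is removed: x and y both driven by the covariate
  set.seed(23)
  z <- rnorm(4000)
  x2 <- z + rnorm(4000); y2 <- z + rnorm(4000)
  expect_gt(cor(x2, y2), 0.3)
  expect_lt(abs(partialCorrelation(x2, y2, cbind(z))$r), 0.05)

  expect_error(partialCorrelation(rep(1, 20), rnorm(20)), "zero residual")
})

test_that("Fisher Z is atanh with clipping and an exact inverse", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log(3), tolerance = 1e-14)
  set.seed(29)
  r <- runif(1e4, -0.999, 0.999)
  expect_equal(fisherZInv(fisherZ(r)), r, tolerance = 1e-12)
  expect_equal(fisherZ(fisherZInv(seq(-3, 3, 0.1))), seq(-3, 3, 0.1),
               tolerance = 1e-12)
  expect_warning(z1 <- fisherZ(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("coupling matrices are consistent and permutation invariant", {
  cfg <- defaultConfig("paper-like")
  cfg$nPerGroup <- c(HC = 40L, FES = 40L)
  coh <- generateCohort(cfg, seed = 2)
  cnt <- rawCounts(coh); ph <- phenotypes(coh)
  expr <- log2RPM(filterCounts(cnt)$counts, libSizes = colSums(cnt))
  sig <- selectSignatureGenes(expr, geneAnnotation(coh))
  th <- averageHemispheres(thicknessTable(coh))
  cog <- cognitionMatrix(ph)
  cp <- buildCoupling(sig, th, cog, ph, "HC")
  expect_named(cp, c("gene_gene", "cortex_cortex", "gene_cortex",
                     "gene_cognition", "cortex_cognition"))
  gg <- cp$gene_gene
  expect_equal(couplingR(gg), t(couplingR(gg)), tolerance = 1e-12)
  expect_equal(unname(diag(couplingR(gg))), rep(1, 54))
  off <- upper.tri(couplingR(gg))
  expect_equal(couplingZ(gg)[off], atanh(couplingR(gg)[off]),
               tolerance = 1e-12)
  expect_equal(couplingGroup(gg), "HC")

  # gene-cortex entries agree with the scalar partialCorrelation route
  gc <- cp$gene_cortex
  ids <- intersect(ph$subject_id[ph$group == "HC"], colnames(sig))
  covs <- ph[match(ids, ph$subject_id), c("age", "sex")]
  pc <- partialCorrelation(sig["RNASE2", ids], th[ids, "lateraloccipital"],
                           covs)
  expect_equal(couplingR(gc)["RNASE2", "lateraloccipital"], pc$r,
               tolerance = 1e-10)
  expect_equal(couplingP(gc)["RNASE2", "lateraloccipital"], pc$p,
               tolerance = 1e-10)

  # permuting subject order consistently leaves every r unchanged
  set.seed(3)
  perm <- sample(nrow(ph))
  cp2 <- buildCoupling(sig[, ph$subject_id[perm]],
                       th[ph$subject_id[perm], ],
                       cog[ph$subject_id[perm], ],
                       ph[perm, ], "HC")
  expect_equal(couplingR(cp2$gene_cortex), couplingR(gc), tolerance = 1e-12)

  # disjoint subject sets between blocks fail loudly
  th2 <- th; rownames(th2) <- paste0("X", rownames(th2))
  expect_error(buildCoupling(sig, th2, cog, ph, "HC"), "shared subjects")
})

test_that("paired comparison handles degenerate and shifted profiles", {
  set.seed(37)
  z <- matrix(rnorm(100, 0, 0.3), 10, 10)
  a <- zMatrixCoupling(z)

  selfCmp <- compareCoupling(a, a)
  expect_equal(selfCmp$t, 0)
  expect_equal(selfCmp$p, 1)
  expect_true(selfCmp$zero_variance)

  constShift <- zMatrixCoupling(z + 0.1)
  shiftCmp <- compareCoupling(a, constShift)
  expect_true(shiftCmp$zero_variance)

  # noisy +0.1 shift over 100 entries: t ~ 0.1 / (0.05 / 10) = 20
  set.seed(41)
  noisy <- zMatrixCoupling(z + rnorm(100, 0.1, 0.05))
  noisyCmp <- compareCoupling(a, noisy)
  expect_equal(noisyCmp$t, oraclePairedT(as.vector(a@z), as.vector(noisy@z)),
               tolerance = 1e-12)
  expect_gt(noisyCmp$t, 12)
  expect_lt(noisyCmp$t, 28)
  expect_equal(noisyCmp$df, 99)

  tiny <- zMatrixCoupling(matrix(0.1, 1, 2))
  expect_error(compareCoupling(tiny, tiny), "fewer than 3")
  b <- zMatrixCoupling(z)
  b@rowInfo$feature[1] <- "other"
  expect_error(compareCoupling(a, b), "mismatched")
})

test_that("subset stratification reduces and bookkeeps correctly", {
  cfg <- defaultConfig("paper-like")
  cfg$nPerGroup <- c(HC = 40L, FES = 40L)
  coh <- generateCohort(cfg, seed = 6)
  cnt <- rawCounts(coh); ph <- phenotypes(coh)
  expr <- log2RPM(filterCounts(cnt)$counts, libSizes = colSums(cnt))
  sig <- selectSignatureGenes(expr, geneAnnotation(coh))
  th <- averageHemispheres(thicknessTable(coh))
  cog <- cognitionMatrix(ph)
  hc <- buildCoupling(sig, th, cog, ph, "HC")
  fes <- buildCoupling(sig, th, cog, ph, "FES")

  strat <- subsetStratifiedComparison(hc, fes)
  expect_equal(nrow(strat), 6)  # 3 subsets x 2 scopes
  expect_setequal(unique(strat$subset),
                  c("classical", "intermediate", "nonclassical"))

  # single-gene stratum against 34 regions: 34 paired entries, df = 33
  one <- subsetStratifiedComparison(hc, fes, subsets = "classical",
                                    scopes = "gene_cortex")
  nCl <- sum(hc$gene_cortex@rowInfo$subset == "classical")
  expect_equal(one$n_entries, nCl * 34)
  idx <- which(hc$gene_cortex@rowInfo$subset == "classical")[1]
  soloHC <- trimodal:::restrictCoupling(hc$gene_cortex, idx)
  soloFES <- trimodal:::restrictCoupling(fes$gene_cortex, idx)
  solo <- compareCoupling(soloHC, soloFES)
  expect_equal(solo$n_entries, 34)
  expect_equal(solo$df, 33)

  # a stratification covering all genes equals the unstratified comparison
  allAnn <- hc$gene_cortex@rowInfo
  allIdx <- seq_len(nrow(allAnn))
  full <- compareCoupling(trimodal:::restrictCoupling(hc$gene_cortex, allIdx),
                          trimodal:::restrictCoupling(fes$gene_cortex, allIdx))
  plain <- compareCoupling(hc$gene_cortex, fes$gene_cortex)
  expect_equal(full$t, plain$t, tolerance = 1e-12)
  expect_equal(full$mean_z_a, plain$mean_z_a, tolerance = 1e-12)
})

test_that("pairwise screen controls its family and finds planted pairs", {
  cfg <- defaultConfig("null")
  cfg$nPerGroup <- c(HC = 60L, FES = 20L)
  coh <- generateCohort(cfg, seed = 12)
  cnt <- rawCounts(coh); ph <- phenotypes(coh)
  expr <- log2RPM(filterCounts(cnt)$counts, libSizes = colSums(cnt))
  sig <- selectSignatureGenes(expr, geneAnnotation(coh))
  th <- averageHemispheres(thicknessTable(coh))

  scr <- pairwiseScreen(sig, th, ph, "HC")
  expect_equal(nrow(scr), 54 * 34)
  # null data: nominal hit rate near alpha, no FDR survivors expected
  expect_lt(abs(mean(scr$nominal) - 0.01), 0.012)
  expect_equal(scr$q, bhFDR(scr$p), tolerance = 1e-12)
  expect_lt(sum(scr$fdr_hit), 3)

  # single-column feature block: family size 54, q consistent with BH
  one <- pairwiseScreen(sig, th[, "lateraloccipital", drop = FALSE], ph, "HC")
  expect_equal(nrow(one), 54)
  expect_equal(one$q, bhFDR(one$p), tolerance = 1e-12)

  # a planted pair with a strong negative partial correlation at n = 60
  # is recovered as the top FDR hit
  ids <- ph$subject_id[ph$group == "HC"]
  sig2 <- sig
  covs <- ph[match(ids, ph$subject_id), c("age", "sex", "education")]
  resid <- residuals(lm(th[ids, "lateraloccipital"] ~ age + sex + education,
                        data = cbind(covs)))
  sig2["RNASE2", ids] <- mean(sig2["RNASE2", ids]) -
    6 * resid + rnorm(length(ids), 0, 0.6 * sd(resid) * 6)
  scr2 <- pairwiseScreen(sig2, th, ph, "HC")
  expect_identical(scr2$gene[1], "RNASE2")
  expect_identical(scr2$feature[1], "lateraloccipital")
  expect_true(scr2$fdr_hit[1])
  expect_lt(scr2$r[1], -0.3)
})
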