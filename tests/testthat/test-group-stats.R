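test_that("ANCOVA group F equals the two-step residualization oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    k <- sample(1:3, 1)
    covs <- matrix(rnorm(n * k), n)
    group <- factor(sample(c("HC", "FES"), n, replace = TRUE),
                    c("HC", "FES"))
    y <- rnorm(n, sd = 1) + 0.8 * (group == "FES") +
      covs %*% rnorm(k, sd = 0.5)
    res <- ancovaGroupTest(as.numeric(y), group, covs)
    expect_equal(res$F, oracleAncovaF(as.numeric(y), group, covs),
                 tolerance = 1e-8)
    expect_equal(res$df2, n - 2 - k)
  }
})

test_that("ANCOVA adjusts covariate-driven differences away", {
  set.seed(2)
  n <- 200
  group <- factor(rep(c("HC", "FES"), each = n / 2), c("HC", "FES"))
  age <- rnorm(n, 35, 8)          # same distribution in both groups
  y <- age + rnorm(n, sd = 0.01)  # outcome is (almost) the covariate
  res <- ancovaGroupTest(y, group, cbind(age = age))
  expect_lt(res$F, qf(0.999, 1, res$df2))
  expect_equal(res$adj_mean_HC, res$adj_mean_FES, tolerance = 0.01)

  dup <- cbind(age = age, age2 = age)
  expect_error(ancovaGroupTest(y, group, dup), "collinear")
})

test_that("2x2 chi-square has its closed form and invariances", {
  # proportional rows: independence, statistic exactly 0
  prop <- matrix(c(10, 20, 20, 40), 2)
  r0 <- chiSquare2x2(prop)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # closed form N(ad-bc)^2/(r1 r2 c1 c2) on a random table
  set.seed(5)
  tab <- matrix(sample(10:90, 4), 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- sum(tab)
  byHand <- N * (a * d - b * c)^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  expect_equal(chiSquare2x2(tab)$statistic, byHand, tolerance = 1e-12)

  # invariant to transposition and to simultaneous row+column swaps
  expect_equal(chiSquare2x2(t(tab))$statistic,
               chiSquare2x2(tab)$statistic, tolerance = 1e-12)
  expect_equal(chiSquare2x2(tab[2:1, 2:1])$statistic,
               chiSquare2x2(tab)$statistic, tolerance = 1e-12)

  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("Mann-Whitney Z matches closed form, symmetry and the exact null", {
  r <- mannWhitneyZ(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$statistic, -4.5 / sqrt(5.25), tolerance = 1e-12)

  same <- mannWhitneyZ(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)

  set.seed(8)
  x <- rnorm(12); y <- rnorm(15)
  expect_equal(mannWhitneyZ(x, y)$statistic,
               -mannWhitneyZ(y, x)$statistic, tolerance = 1e-12)

  expect_error(mannWhitneyZ(rep(1, 4), rep(1, 5)), "identical")

  # exact null at m = n = 3: enumerate all C(6,3) = 20 labelings and
  # compare the permutation p-value with the normal approximation; the
  # approximation is crude at n = 6, so the documented tolerance is loose
  vals <- c(0.3, 1.1, 2.2, 3.5, 4.1, 5.9)
  combs <- combn(6, 3)
  refZ <- apply(combs, 2, function(ix)
    mannWhitneyZ(vals[ix], vals[-ix])$statistic)
  obs <- mannWhitneyZ(vals[c(1, 2, 3)], vals[c(4, 5, 6)])
  pExact <- mean(abs(refZ) >= abs(obs$statistic) - 1e-12)
  expect_lt(abs(obs$p - pExact), 0.08)
})

test_that("BH adjustment equals the brute-force definition", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhFDR(p), oracleBH(p), tolerance = 1e-12)
  }
  # NAs are propagated, not dropped silently
  p <- c(0.01, NA, 0.5)
  q <- bhFDR(p)
  expect_true(is.na(q[2]))
  expect_equal(q[-2], oracleBH(p[-2]))
})

test_that("differential expression recovers coefficients and calibrates", {
  set.seed(21)
  n <- 60
  group <- factor(rep(c("HC", "FES"), each = n / 2), c("HC", "FES"))
  base <- rnorm(5, 6)
  expr <- matrix(rnorm(5 * n, sd = 0.3), 5, n,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
  expr <- expr + base
  expr[1, group == "FES"] <- expr[1, group == "FES"] + 1  # exact 1 log2 unit
  de <- differentialExpression(expr, group)
  expect_equal(de$log2FC[de$gene == "g1"],
               mean(expr[1, group == "FES"]) - mean(expr[1, group == "HC"]),
               tolerance = 1e-12)
  expect_lt(de$q[de$gene == "g1"], 0.01)

  # constant gene flagged with p = 1 and zero fold change
  expr[3, ] <- 5
  de2 <- differentialExpression(expr, group)
  expect_true(de2$constant[de2$gene == "g3"])
  expect_equal(de2$p[de2$gene == "g3"], 1)
  expect_equal(de2$log2FC[de2$gene == "g3"], 0)

  # type-I calibration under the null: 500 genes, n = 50/50
  set.seed(31)
  g2 <- factor(rep(c("HC", "FES"), each = 50), c("HC", "FES"))
  nullExpr <- matrix(rnorm(500 * 100), 500, 100,
                     dimnames = list(paste0("n", 1:500), NULL))
  deN <- differentialExpression(nullExpr, g2)
  expect_lt(abs(mean(deN$p < 0.05) - 0.05), 0.02)
})

test_that("demographics table dispatches tests by variable type", {
  coh <- generateCohort(defaultConfig("paper-like"), seed = 4)
  tab <- demographicsTable(phenotypes(coh))
  expect_setequal(tab$variable, c("age", "education", "sex", "smoker"))
  expect_identical(tab$test[tab$variable == "sex"], "chi-square")
  expect_true(all(tab$test[tab$variable %in% c("age", "education")]
                  %in% c("t", "mann-whitney")))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
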