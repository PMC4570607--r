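test_that("degenerate zero-covariance component generates exact means", {
  p <- fmmParams(pi = 1, mu = c(0.8, 0.15), Sigma = matrix(0, 2, 2))
  sim <- simulateFmmPoints(p, 5, seed = 7)
  expect_equal(unname(sim$points),
               matrix(rep(c(0.8, 0.15), each = 5), 5, 2))
  expect_equal(sim$label, rep(1L, 5))
})

test_that("mixture sampling matches the generating proportions and means", {
  p <- igf1FmmParams()
  sim <- simulateFmmPoints(p, 10000, seed = 11)
  freq <- tabulate(sim$label, 3) / 10000
  se <- sqrt(mixingProportions(p) * (1 - mixingProportions(p)) / 10000)
  expect_true(all(abs(freq - mixingProportions(p)) < 3 * se))

  sep <- simulateFmmPoints(sepFmmParams(), 1000, seed = 3)
  for (g in 1:2) {
    m <- colMeans(sep$points[sep$label == g, ])
    expect_true(all(abs(m - componentMeans(sepFmmParams())[, g]) < 0.2))
  }
})

test_that("generation is reproducible under a fixed seed", {
  a <- simulateFmmPoints(igf1FmmParams(), 50, seed = 42)
  b <- simulateFmmPoints(igf1FmmParams(), 50, seed = 42)
  expect_identical(a, b)
  pa <- simulateFmlmmPanel(igf1FmlmmParams(), 8, 3, seed = 42)
  pb <- simulateFmlmmPanel(igf1FmlmmParams(), 8, 3, seed = 42)
  expect_identical(panelValues(pa$panel), panelValues(pb$panel))
  expect_identical(pa$label, pb$label)
})

test_that("noiseless panel generation collapses to the fixed effects", {
  p <- fmlmmParams(pi = 1, alpha = c(0.8, 0.15),
                   Phi = matrix(0, 2, 2), sigma2 = matrix(0, 2, 1))
  sim <- simulateFmlmmPanel(p, 4, 3, seed = 5)
  v <- panelValues(sim$panel)
  expect_equal(unname(v["Ea", ]), rep(0.8, 12))
  expect_equal(unname(v["Eb", ]), rep(0.15, 12))
  expect_equal(unname(v["Ec", ]), rep(0.05, 12))
})

test_that("panel generation recovers component-level fixed effects", {
  p <- igf1FmlmmParams()
  sim <- simulateFmlmmPanel(p, 5000, 3, seed = 13)
  v <- panelValues(sim$panel)
  tis <- tissueIds(sim$panel)
  tmean <- tapply(v["Ea", ], factor(tis, levels = unique(tis)), mean)
  for (g in 1:3) {
    x <- tmean[names(sim$label)[sim$label == g]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - componentMeans(p)[1, g]), 3 * se + 1e-12)
  }
})

test_that("random-effect-only generation has the stated variance structure", {
  v0 <- 0.04
  p <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3), Phi = diag(v0, 2),
                   sigma2 = matrix(0, 2, 1))
  sim <- simulateFmlmmPanel(p, 4000, 3, seed = 17)
  vals <- panelValues(sim$panel)
  tis <- factor(tissueIds(sim$panel), levels = unique(tissueIds(sim$panel)))
  # replicates within a tissue are identical (no measurement error)
  withinSd <- tapply(vals["Ea", ], tis, sd)
  expect_true(all(withinSd < 1e-12))
  # between-tissue variance of tissue means is the random-effect variance
  tmean <- tapply(vals["Ea", ], tis, mean)
  seVar <- v0 * sqrt(2 / (length(tmean) - 1))
  expect_lt(abs(var(as.numeric(tmean)) - v0), 3 * seVar)
})

test_that("marginal covariance of a tissue vector is V Phi V' + Omega", {
  p <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3),
                   Phi = matrix(c(4e-3, -3e-3, -3e-3, 5e-3), 2, 2),
                   sigma2 = matrix(c(2e-3, 1e-3), 2, 1))
  sim <- simulateFmlmmPanel(p, 20000, 2, seed = 19)
  X <- do.call(cbind, tissueVectors(sim$panel))
  S <- cov(t(X))
  expected <- marginalMoments(p, 1, 2)$Sigma
  expect_true(max(abs(S - expected)) < 0.0005)
})

test_that("CT table emission inverts exactly through preprocessing", {
  set.seed(23)
  q <- matrix(rexp(60, 1), 3, 20, dimnames = list(c("Ea", "Eb", "Ec"), NULL))
  r <- sweep(q, 2, colSums(q), "/")
  panel <- tissuePanel(r, tissue = rep(sprintf("t%02d", 1:10), each = 2),
                       replicate = rep(1:2, 10), valueType = "ratio")
  ct <- simulateCtTable(panel, panLevel = 7, referenceCt = 21)
  rec <- ctToPanel(ct, calibrator = "calibrator")
  # PAN agrees with the isoform sum by construction
  pan <- panConsistencyTest(rec)
  expect_equal(pan$statistic, 0)
  expect_equal(pan$p.value, 1)
  expect_true(pan$consistent)
  recR <- asRatioPanel(rec)
  expect_true(max(abs(panelValues(recR)[c("Ea", "Eb", "Ec"), ] -
                        panelValues(panel))) < 1e-9)
})

test_that("CT noise degrades but does not destroy ratio recovery", {
  set.seed(29)
  q <- matrix(rexp(180, 1) + 0.05, 3, 60,
              dimnames = list(c("Ea", "Eb", "Ec"), NULL))
  r <- sweep(q, 2, colSums(q), "/")
  panel <- tissuePanel(r, tissue = rep(sprintf("t%02d", 1:20), each = 3),
                       replicate = rep(1:3, 20), valueType = "ratio")
  ct <- simulateCtTable(panel, panLevel = 10, noiseSd = 0.1, seed = 31)
  rec <- asRatioPanel(ctToPanel(ct, calibrator = "calibrator"))
  a <- panelValues(rec)["Ea", ]
  b <- panelValues(panel)["Ea", colnames(rec)]
  expect_length(a, 60)
  expect_gt(cor(a, b), 0.95)
})

test_that("replicate masking produces duplicate tissues at roughly the rate", {
  sim <- simulateFmlmmPanel(igf1FmlmmParams(), 200, 3, seed = 37)
  set.seed(38)
  masked <- maskReplicates(sim$panel, rate = 0.25)
  r <- nReplicates(masked)
  expect_true(all(r %in% c(2L, 3L)))
  expect_gt(sum(r == 2), 20)
  expect_lt(sum(r == 2), 90)
})

test_that("generator rejects invalid inputs", {
  expect_error(simulateFmmPoints(igf1FmmParams(), 0), "positive")
  bad <- igf1FmmParams()
  bad@Sigma[[1]] <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(simulateFmmPoints(bad, 10), "positive semi-definite")
  p <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3), Phi = diag(2) * 0.1,
                   sigma2 = matrix(0.1, 2, 1))
  expect_error(simulateFmlmmPanel(p, 0, 3), ">= 1")
})
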