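test_that("the replicate design matrix has the block structure", {
  expect_equal(buildDesign(1), diag(2))
  V3 <- buildDesign(3)
  expect_equal(dim(V3), c(6L, 2L))
  expect_equal(V3[, 1], c(1, 1, 1, 0, 0, 0))
  expect_equal(V3[, 2], c(0, 0, 0, 1, 1, 1))
  for (R in 1:5) {
    V <- buildDesign(R)
    expect_equal(crossprod(V), R * diag(2))
  }
})

test_that("marginal moments compose the random-effect and error pieces", {
  p0 <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3), Phi = matrix(0, 2, 2),
                    sigma2 = matrix(c(0.4, 0.9), 2, 1))
  mm <- marginalMoments(p0, 1, 3)
  expect_equal(mm$Sigma, diag(c(0.4, 0.4, 0.4, 0.9, 0.9, 0.9)))
  expect_equal(mm$mu, rep(c(0.5, 0.3), each = 3))

  v <- 0.25
  p1 <- fmlmmParams(pi = 1, alpha = c(0, 0), Phi = diag(v, 2),
                    sigma2 = matrix(0, 2, 1))
  S <- marginalMoments(p1, 1, 2)$Sigma
  expect_equal(S[1, 2], v)   # within-variant replicate covariance
  expect_equal(S[1, 3], 0)   # cross-variant covariance = Phi[1,2] = 0
  expect_equal(S[1, 1], v)

  # second published component, R = 3: build the expected matrix entrywise
  p <- igf1FmlmmParams()
  S2 <- marginalMoments(p, 2, 3)$Sigma
  Phi <- componentCovariances(p)[[2]]
  s2 <- errorVariances(p)[, 2]
  expected <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    hi <- ifelse(i <= 3, 1, 2)
    hj <- ifelse(j <= 3, 1, 2)
    expected[i, j] <- Phi[hi, hj] + ifelse(i == j, s2[hi], 0)
  }
  expect_equal(S2, expected, tolerance = 1e-12)
})

test_that("E step posteriors are exact on degenerate and tiny cases", {
  p1 <- fmlmmParams(pi = 1, alpha = c(0.5, 0.2), Phi = diag(1e-3, 2),
                    sigma2 = matrix(1e-3, 2, 1))
  sim <- simulateFmlmmPanel(p1, 5, 3, seed = 40)
  x <- tissueVectors(sim$panel)
  expect_equal(unname(fmlmmEStep(x, p1)), matrix(1, 5, 1))

  # two indistinguishable components: posterior equals the prior
  p2 <- fmlmmParams(pi = c(0.3, 0.7),
                    alpha = cbind(c(0.5, 0.2), c(0.5, 0.2)),
                    Phi = diag(1e-3, 2), sigma2 = matrix(1e-3, 2, 2))
  w <- fmlmmEStep(x, p2)
  expect_equal(unname(w), matrix(rep(c(0.3, 0.7), each = 5), 5, 2),
               tolerance = 1e-12)

  # brute-force density oracle
  p3 <- igf1FmlmmParams()
  sim3 <- simulateFmlmmPanel(p3, 6, 3, seed = 41)
  x3 <- tissueVectors(sim3$panel)
  expect_equal(fmlmmLoglik(x3, p3), refFmlmmLoglik(x3, p3),
               tolerance = 1e-10)
  w3 <- fmlmmEStep(x3, p3)
  expect_equal(rowSums(w3), rep(1, 6), tolerance = 1e-12)
})

test_that("random-effect predictions vanish when they must", {
  p0 <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3), Phi = matrix(0, 2, 2),
                    sigma2 = matrix(0.01, 2, 1))
  x <- rep(c(0.6, 0.4), each = 3)
  expect_equal(blup(x, p0, 1), c(0, 0))
  p1 <- igf1FmlmmParams()
  x0 <- rep(componentMeans(p1)[, 2], each = 3)
  expect_equal(blup(x0, p1, 2), c(0, 0), tolerance = 1e-12)
})

test_that("the noise-free limit of the prediction is the replicate mean residual", {
  p <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3),
                   Phi = matrix(c(2e-3, 5e-4, 5e-4, 3e-3), 2, 2),
                   sigma2 = matrix(1e-12, 2, 1))
  set.seed(43)
  x <- rep(c(0.55, 0.27), each = 3) + rnorm(6, 0, 0.01)
  u <- blup(x, p, 1, w = 1)
  V <- buildDesign(3)
  resid <- x - drop(V %*% c(0.5, 0.3))
  proj <- drop(solve(crossprod(V), crossprod(V, resid)))  # replicate means
  expect_equal(u, proj, tolerance = 1e-6)
})

test_that("M step closed forms hold in degenerate cases", {
  # one component, zero random effect: sigma^2 equals the mean squared
  # residual per variant
  p0 <- fmlmmParams(pi = 1, alpha = c(0.5, 0.3), Phi = matrix(0, 2, 2),
                    sigma2 = matrix(0.01, 2, 1))
  set.seed(44)
  xl <- lapply(1:8, function(i) rep(c(0.5, 0.3), each = 3) + rnorm(6, 0, 0.05))
  up <- fmlmmMStep(xl, matrix(1, 8, 1), p0)
  aNew <- componentMeans(up)[, 1]
  resid <- vapply(xl, function(x) {
    r <- x - rep(aNew, each = 3)
    c(mean(r[1:3]^2), mean(r[4:6]^2))
  }, numeric(2))
  expect_equal(errorVariances(up)[, 1], rowMeans(resid), tolerance = 1e-10)

  # uniform weights give uniform mixing proportions
  p2 <- fmlmmParams(pi = c(0.5, 0.5), alpha = cbind(c(0.5, 0.3), c(0.4, 0.4)),
                    Phi = diag(1e-3, 2), sigma2 = matrix(1e-3, 2, 2))
  up2 <- fmlmmMStep(xl, matrix(0.5, 8, 2), p2)
  expect_equal(mixingProportions(up2), c(0.5, 0.5))
})

test_that("the generating parameters are near a fixed point of one EM step", {
  p <- igf1FmlmmParams()
  sim <- simulateFmlmmPanel(p, 5000, 3, seed = 45)
  x <- tissueVectors(sim$panel)
  w <- fmlmmEStep(x, p)
  up <- fmlmmMStep(x, w, p)
  relA <- abs(componentMeans(up) - componentMeans(p)) /
    abs(componentMeans(p))
  expect_lt(max(relA), 0.02)
  relPi <- abs(mixingProportions(up) - mixingProportions(p)) /
    mixingProportions(p)
  expect_lt(max(relPi), 0.05)
  for (g in 1:3) {
    relPhi <- abs(componentCovariances(up)[[g]] -
                    componentCovariances(p)[[g]]) /
      max(abs(componentCovariances(p)[[g]]))
    expect_lt(max(relPhi), 0.1)
  }
  relS <- abs(errorVariances(up) - errorVariances(p)) / errorVariances(p)
  expect_lt(max(relS), 0.1)
})

test_that("with no random effect the model reduces to a shared-membership FMM", {
  sig <- 0.0008
  pRed <- fmlmmParams(pi = c(0.6, 0.4),
                      alpha = cbind(c(0.8, 0.15), c(0.68, 0.3)),
                      Phi = matrix(0, 2, 2),
                      sigma2 = matrix(sig, 2, 2))
  sim <- simulateFmlmmPanel(igf1FmlmmParams(), 30, 3, seed = 46)
  x <- tissueVectors(sim$panel)
  ll <- fmlmmLoglik(x, pRed)
  # oracle: sum_i log sum_g pi_g prod_r N(x_ir | alpha_g, sig I_2)
  oracle <- sum(vapply(x, function(xi) {
    log(sum(vapply(1:2, function(g) {
      a <- pRed@alpha[, g]
      dens <- prod(vapply(1:3, function(r) {
        exp(-((xi[r] - a[1])^2 + (xi[3 + r] - a[2])^2) / (2 * sig)) /
          (2 * pi * sig)
      }, 0))
      pRed@pi[g] * dens
    }, 0)))
  }, 0))
  expect_equal(ll, oracle, tolerance = 1e-6)
})

test_that("well-separated panels are labelled exactly", {
  sim <- simulateFmlmmPanel(sepFmlmmParams(), 60, 3, seed = 47)
  fit <- fmlmmFit(sim$panel, G = 3, nStarts = 5, seed = 48)
  al <- allocationTable(fit)
  perm <- alignComponents(componentMeans(sepFmlmmParams()),
                          componentMeans(fit))
  mapped <- match(al$units$label, perm)
  expect_equal(mapped, unname(sim$label[al$units$tissue]))
  expect_true(all(al$units$entropy < 1e-6))
})

test_that("free parameter counts and permutation invariance", {
  expect_identical(fmlmmFreeParams(3), 23L)
  expect_identical(fmlmmFreeParams(1), 7L)
  p <- igf1FmlmmParams()
  perm <- c(2, 3, 1)
  q <- fmlmmParams(p@pi[perm], p@alpha[, perm], p@Phi[perm],
                   p@sigma2[, perm])
  sim <- simulateFmlmmPanel(p, 25, 3, seed = 49)
  x <- tissueVectors(sim$panel)
  expect_equal(fmlmmLoglik(x, q), fmlmmLoglik(x, p), tolerance = 1e-10)
})

test_that("EM monotonicity and invariants hold for both alpha updates", {
  sim <- simulateFmlmmPanel(igf1FmlmmParams(), 60, 3, seed = 50)
  fits <- list(
    printed = fmlmmFit(sim$panel, G = 2, nStarts = 3, seed = 51,
                       alphaUpdate = "printed", maxIter = 200),
    gls = fmlmmFit(sim$panel, G = 2, nStarts = 3, seed = 51,
                   alphaUpdate = "gls", maxIter = 200))
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    expect_true(all(diff(fit@trace) > -1e-8), label = nm)
    expect_equal(rowSums(posteriorWeights(fit)), rep(1, 60),
                 tolerance = 1e-10)
    for (Phi in componentCovariances(fit)) {
      expect_equal(Phi, t(Phi), tolerance = 1e-12)
      expect_gte(min(eigen(Phi, only.values = TRUE)$values), -1e-15)
    }
    expect_true(all(errorVariances(fit) >= 0))
  }
  # both updates share a fixed point: converged logliks agree closely
  expect_equal(fits$printed@loglik, fits$gls@loglik, tolerance = 1e-3)
})

test_that("tissues with unequal replicate counts are handled", {
  sim <- simulateFmlmmPanel(igf1FmlmmParams(), 40, 3, seed = 52)
  set.seed(53)
  masked <- maskReplicates(sim$panel, rate = 0.3)
  expect_true(any(nReplicates(masked) == 2))
  fit <- fmlmmFit(masked, G = 2, nStarts = 3, seed = 54, maxIter = 150)
  expect_s4_class(fit, "FmlmmFit")
  expect_true(all(diff(fit@trace) > -1e-8))
})
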