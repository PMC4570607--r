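test_that("mixture loglik matches closed forms and brute force", {
  p1 <- fmmParams(pi = 1, mu = c(0.3, 0.7), Sigma = diag(2))
  x <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(fmmLoglik(x, p1), log(1 / (2 * pi)), tolerance = 1e-12)

  set.seed(12)
  pts <- matrix(rnorm(8), 4, 2)
  p2 <- fmmParams(pi = c(0.4, 0.6), mu = cbind(c(0, 0), c(1, 1)),
                  Sigma = list(diag(2), matrix(c(1, .5, .5, 2), 2, 2)))
  expect_equal(fmmLoglik(pts, p2),
               refFmmLoglik(pts, p2@pi, p2@mu, p2@Sigma), tolerance = 1e-10)
  # duplicating every point doubles the loglik
  expect_equal(fmmLoglik(rbind(pts, pts), p2), 2 * fmmLoglik(pts, p2),
               tolerance = 1e-10)
})

test_that("E step posteriors are normalized and symmetric where they must be", {
  p1 <- fmmParams(pi = 1, mu = c(0, 0), Sigma = diag(2))
  expect_equal(unname(fmmEStep(matrix(rnorm(10), 5, 2), p1)),
               matrix(1, 5, 1))
  p2 <- fmmParams(pi = c(0.5, 0.5), mu = cbind(c(-1, 0), c(1, 0)),
                  Sigma = diag(2))
  w <- fmmEStep(matrix(c(0, 5), 1, 2), p2)  # equidistant from both means
  expect_equal(unname(w), matrix(0.5, 1, 2), tolerance = 1e-12)
  set.seed(14)
  w3 <- fmmEStep(matrix(rnorm(60, sd = 3), 30, 2), igf1FmmParams())
  expect_equal(rowSums(w3), rep(1, 30), tolerance = 1e-12)
})

test_that("M step reduces to weighted sample moments", {
  set.seed(16)
  pts <- matrix(rnorm(40, sd = 2), 20, 2)
  w <- matrix(1, 20, 1)
  p <- fmmMStep(pts, w, family = "VVV")
  expect_equal(p@mu[, 1], colMeans(pts), tolerance = 1e-12)
  expect_equal(p@Sigma[[1]], cov(pts) * 19 / 20, tolerance = 1e-12)

  # hard weights on two separated blobs recover per-blob moments
  blob <- rbind(pts, sweep(pts, 2, c(50, 50), "+"))
  wh <- cbind(rep(1:0, each = 20), rep(0:1, each = 20))
  p2 <- fmmMStep(blob, wh, family = "VVV")
  expect_equal(p2@mu[, 2], colMeans(blob[21:40, ]), tolerance = 1e-12)
  expect_equal(p2@Sigma[[1]], cov(pts) * 19 / 20, tolerance = 1e-12)
  expect_equal(p2@pi, c(0.5, 0.5))
})

test_that("EEV fitting recovers shared scale and shape", {
  rot <- function(t) matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  lamA <- diag(c(2, 0.2))
  S1 <- rot(0.4) %*% lamA %*% t(rot(0.4))
  S2 <- rot(-0.9) %*% lamA %*% t(rot(-0.9))
  p <- fmmParams(pi = c(0.5, 0.5), mu = cbind(c(-6, 0), c(6, 0)),
                 Sigma = list(S1, S2), family = "EEV")
  sim <- simulateFmmPoints(p, 5000, seed = 18)
  fit <- fmmFit(sim$points, G = 2, family = "EEV", seed = 19)
  for (g in 1:2) {
    ev <- eigen(componentCovariances(fit)[[g]], symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(abs(ev - c(2, 0.2)) / c(2, 0.2) < 0.05))
  }
  # shared eigenvalues across components by construction of the family
  e1 <- eigen(componentCovariances(fit)[[1]], only.values = TRUE)$values
  e2 <- eigen(componentCovariances(fit)[[2]], only.values = TRUE)$values
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("CEM initialization is deterministic and finds clean partitions", {
  sim <- simulateFmmPoints(sepFmmParams(), 200, seed = 20)
  a <- cemInit(sim$points, G = 2, nStarts = 5, seed = 21)
  b <- cemInit(sim$points, G = 2, nStarts = 5, seed = 21)
  expect_equal(a@mu, b@mu, tolerance = 1e-14)
  perm <- alignComponents(componentMeans(sepFmmParams()), a@mu)
  expect_lt(max(abs(componentMeans(sepFmmParams()) - a@mu[, perm])), 0.3)
  one <- cemInit(sim$points, G = 1, nStarts = 3, seed = 22)
  expect_equal(one@mu[, 1], unname(colMeans(sim$points)), tolerance = 1e-12)
})

test_that("EM attains the G=1 closed form and beats a numeric optimizer", {
  set.seed(24)
  pts <- matrix(rnorm(30), 15, 2)
  fit1 <- suppressWarnings(fmmFit(pts, G = 1, family = "VVV", seed = 25))
  expect_equal(componentMeans(fit1)[, 1], colMeans(pts), tolerance = 1e-10)
  expect_equal(componentCovariances(fit1)[[1]], cov(pts) * 14 / 15,
               tolerance = 1e-10)

  # tiny G=2 instance: EM loglik must reach an independent direct maximizer
  set.seed(26)
  tiny <- rbind(matrix(rnorm(6, -2, 0.6), 3, 2), matrix(rnorm(6, 2, 0.6), 3, 2))
  fit2 <- suppressWarnings(fmmFit(tiny, G = 2, family = "VVV", seed = 27,
                                  tol = 1e-10, maxIter = 2000))
  obj <- function(th) {
    pi1 <- 1 / (1 + exp(-th[1]))
    mu <- matrix(th[2:5], 2)
    L1 <- matrix(c(exp(th[6]), th[7], 0, exp(th[8])), 2, 2)
    L2 <- matrix(c(exp(th[9]), th[10], 0, exp(th[11])), 2, 2)
    S <- list(L1 %*% t(L1), L2 %*% t(L2))
    -refFmmLoglik(tiny, c(pi1, 1 - pi1), mu, S)
  }
  set.seed(28)
  bestRef <- -Inf
  for (k in 1:8) {
    th0 <- c(0, rnorm(4), rnorm(6, 0, 0.5))
    o <- tryCatch(optim(th0, obj, method = "BFGS",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o)) bestRef <- max(bestRef, -o$value)
  }
  expect_gte(fit2@loglik, bestRef - 1e-4)
})

test_that("free parameter counts follow the family dimensions", {
  expect_identical(nFreeParams("EEV", 3), 13L)
  expect_identical(nFreeParams("VVV", 2), 11L)
  expect_identical(nFreeParams("EII", 1), 3L)
  expect_identical(nFreeParams("EEE", 2), 8L)
  expect_identical(nFreeParams("VII", 3), 11L)
  expect_error(nFreeParams("XXX", 2))
})

test_that("BIC arithmetic and selection bookkeeping", {
  expect_equal(bicScore(0, 1, 1), 0)
  expect_equal(bicScore(-10, 2, 100), 20 + 2 * log(100), tolerance = 1e-10)
  expect_equal(bicScore(-10, 2, 100), 29.21034, tolerance = 1e-5)
  expect_error(bicScore(0, 1, 0), ">= 1")
})

test_that("MAP allocation and normalized entropy behave at the anchors", {
  expect_equal(normalizedEntropy(c(1, 0, 0)), 0)
  expect_equal(normalizedEntropy(rep(1 / 4, 4)), 1, tolerance = 1e-12)
  expect_equal(normalizedEntropy(c(0.51, 0.49)), 0.99971, tolerance = 1e-4)
  expect_equal(normalizedEntropy(c(0.99, 0.01)), 0.08079, tolerance = 1e-4)

  w <- rbind(c(1, 0, 0), c(0.2, 0.5, 0.3), c(1 / 3, 1 / 3, 1 / 3))
  a <- suppressMessages(mapAllocate(w, tissue = c("t1", "t1", "t2"),
                                    replicate = c(1, 2, 1)))
  expect_equal(a$units$label, c(1L, 2L, 1L))  # tie in row 3 -> lowest index
  expect_equal(a$units$entropy[1], 0)
  expect_equal(a$tissues$label, c(1L, 1L))    # t1 majority tie -> lowest
  expect_equal(a$tissues$n1, c(1L, 1L))
  expect_equal(a$tissues$entropy[2], 1, tolerance = 1e-12)
})

test_that("EM loglik trace is monotone and invariants hold for every family", {
  sim <- simulateFmmPoints(igf1FmmParams(), 400, seed = 30)
  for (fam in c("EII", "VII", "EEE", "VVV", "EEV")) {
    fit <- fmmFit(sim$points, G = 3, family = fam, seed = 31, nStarts = 5)
    expect_true(all(diff(fit@trace) > -1e-10), label = fam)
    expect_equal(sum(mixingProportions(fit)), 1, tolerance = 1e-12)
    expect_equal(rowSums(posteriorWeights(fit)), rep(1, 400),
                 tolerance = 1e-10)
    for (S in componentCovariances(fit)) {
      expect_gte(min(eigen(S, only.values = TRUE)$values), 0)
    }
  }
})

test_that("mixture densities agree with an established implementation", {
  skip_if_not_installed("mclust")
  sim <- simulateFmmPoints(igf1FmmParams(), 200, seed = 32)
  p <- igf1FmmParams()
  ref <- sum(log(Reduce(`+`, lapply(1:3, function(g) {
    p@pi[g] * mclust::dmvnorm(sim$points, p@mu[, g], p@Sigma[[g]])
  }))))
  expect_equal(fmmLoglik(sim$points, p), ref, tolerance = 1e-10)
})

test_that("loglik and BIC are invariant under component relabeling", {
  p <- igf1FmmParams()
  perm <- c(3, 1, 2)
  q <- fmmParams(p@pi[perm], p@mu[, perm], p@Sigma[perm], p@family)
  sim <- simulateFmmPoints(p, 150, seed = 33)
  expect_equal(fmmLoglik(sim$points, q), fmmLoglik(sim$points, p),
               tolerance = 1e-10)
})
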