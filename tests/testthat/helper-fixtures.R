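# Small generating models used across tests.

# two far-apart spherical components
sepFmmParams <- function() {
  fmmParams(pi = c(0.5, 0.5), mu = cbind(c(-10, -10), c(10, 10)),
            Sigma = diag(2), family = "VVV")
}

# well-separated LMM mixture with small variances (near-exact recovery)
sepFmlmmParams <- function() {
  fmlmmParams(pi = c(0.5, 0.3, 0.2),
              alpha = cbind(c(0.9, 0.05), c(0.5, 0.4), c(0.1, 0.8)),
              Phi = diag(1e-4, 2),
              sigma2 = matrix(1e-5, 2, 3))
}

# direct bivariate normal log density, written independently of the
# package internals (solve + determinant instead of Cholesky)
refLogDnorm2 <- function(x, mu, Sigma) {
  d <- x - mu
  -log(2 * pi) - 0.5 * log(det(Sigma)) -
    0.5 * drop(t(d) %*% solve(Sigma) %*% d)
}

# reference mixture loglik by brute-force summation
refFmmLoglik <- function(points, pi_, mu, Sigma) {
  sum(apply(points, 1, function(x) {
    log(sum(vapply(seq_along(pi_), function(g) {
      pi_[g] * exp(refLogDnorm2(x, mu[, g], Sigma[[g]]))
    }, 0)))
  }))
}

# reference marginal loglik of the LMM mixture via its marginal moments
refFmlmmLoglik <- function(xlist, params) {
  G <- nComponents(params)
  pi_ <- mixingProportions(params)
  sum(vapply(xlist, function(x) {
    R <- length(x) / 2
    dens <- vapply(seq_len(G), function(g) {
      mm <- marginalMoments(params, g, R)
      d <- x - mm$mu
      pi_[g] * exp(-0.5 * length(x) * log(2 * pi) -
                     0.5 * determinant(mm$Sigma)$modulus -
                     0.5 * drop(t(d) %*% solve(mm$Sigma) %*% d))
    }, 0)
    log(sum(dens))
  }, 0))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
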