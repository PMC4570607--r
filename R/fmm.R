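# --- low-level Gaussian machinery -------------------------------------------

# Cholesky with an eigenvalue floor of 1e-10 * trace, so the near-singular
# component covariances seen in compositional couples stay invertible.
.safeChol <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ev <- pmax(e$values, 1e-10 * max(sum(diag(S)), .Machine$double.eps))
    ch <- chol(e$vectors %*% (ev * t(e$vectors)))
  }
  ch
}

# log N(x | mu, Sigma) for the rows of an n x d matrix
.mvnLogDensity <- function(x, mu, Sigma) {
  d <- ncol(x)
  ch <- .safeChol(Sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

.logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

.logDensMatrix <- function(points, params) {
  matrix(vapply(seq_len(params@G), function(g) {
    .mvnLogDensity(points, params@mu[, g], params@Sigma[[g]])
  }, numeric(nrow(points))), nrow = nrow(points))
}

# --- likelihood, E and M steps ----------------------------------------------

#' Mixture log-likelihood of pooled points
#'
#' `sum_i log sum_g pi_g N(x_i | mu_g, Sigma_g)` over the pooled
#' tissue-replicate units, computed in log space (log-sum-exp) for
#' stability.
#'
#' @param points n x 2 matrix of (Ratio1, Ratio2) units.
#' @param params a [GaussianMixtureParams-class].
#' @return scalar log-likelihood.
#' @export
fmmLoglik <- function(points, params) {
  points <- as.matrix(points)
  ld <- .logDensMatrix(points, params)
  sum(.logsumexp(sweep(ld, 2, log(params@pi), "+")))
}

#' E step: posterior membership probabilities
#'
#' Posterior probability that each pooled tissue-replicate unit belongs to
#' each component, `w_irg = pi_g f_irg / sum_g' pi_g' f_irg'`, computed in
#' log space. Rows sum to one.
#'
#' @inheritParams fmmLoglik
#' @return n x G weight matrix.
#' @export
fmmEStep <- function(points, params) {
  points <- as.matrix(points)
  a <- sweep(.logDensMatrix(points, params), 2, log(params@pi), "+")
  w <- exp(a - .logsumexp(a))
  w / rowSums(w)
}

# constrain a list of weighted scatter matrices W_g (sum_i w_ig (x-mu)(x-mu)')
# to the requested covariance family; n = total weight, ng = per-component
.familyCovariances <- function(W, ng, n, family) {
  d <- nrow(W[[1]])
  G <- length(W)
  switch(family,
    VVV = lapply(seq_len(G), function(g) W[[g]] / ng[g]),
    EEE = {
      S <- Reduce(`+`, W) / n
      rep(list(S), G)
    },
    EII = {
      s2 <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * d)
      rep(list(diag(s2, d)), G)
    },
    VII = lapply(seq_len(G), function(g) diag(sum(diag(W[[g]])) / (ng[g] * d), d)),
    EEV = {
      # eigen-based constrained update: per-component orientation from the
      # scatter eigenvectors, shared scale/shape from the pooled eigenvalues
      eg <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
      lam <- Reduce(`+`, lapply(eg, function(e) e$values)) / n
      lapply(seq_len(G), function(g) {
        D <- eg[[g]]$vectors
        D %*% (lam * t(D))
      })
    },
    stop("unknown covariance family: ", family))
}

#' M step: weighted maximum likelihood update
#'
#' Component means and covariances are the weight-averaged sample moments
#' (covariance denominator the component mass), mixing proportions the
#' average weights; the covariance set is then projected to the requested
#' family (VVV unconstrained, EEE pooled, EII/VII spherical, EEV shared
#' scale and shape with per-component orientation via the eigen-based
#' constrained update).
#'
#' @inheritParams fmmLoglik
#' @param weights n x G posterior weight matrix with unit row sums.
#' @param family covariance family.
#' @return A [GaussianMixtureParams-class].
#' @export
fmmMStep <- function(points, weights, family = "VVV") {
  points <- as.matrix(points)
  weights <- as.matrix(weights)
  n <- nrow(points)
  G <- ncol(weights)
  ng <- colSums(weights)
  if (any(ng < 1e-10)) {
    stop2 <- simpleError("component collapse: empty component in M step")
    class(stop2) <- c("splicemixCollapse", class(stop2))
    stop(stop2)
  }
  mu <- t(crossprod(weights, points) / ng)
  W <- lapply(seq_len(G), function(g) {
    c1 <- sweep(points, 2, mu[, g])
    crossprod(c1 * weights[, g], c1)
  })
  Sigma <- .familyCovariances(W, ng, n, family)
  # deterministic eigenvalue floor tied to the data scale: clamping is the
  # exact maximizer under the eigenvalue constraint, so EM stays monotone
  # even when a component degenerates onto collinear points
  floor_ <- 1e-10 * sum(diag(cov(points)))
  Sigma <- lapply(Sigma, function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (min(e$values) >= floor_) return(S)
    e$vectors %*% (pmax(e$values, floor_) * t(e$vectors))
  })
  fmmParams(pi = ng / n, mu = mu, Sigma = Sigma, family = family)
}

#' Free parameter count of a covariance family
#'
#' Number of independently estimated parameters of a G-component bivariate
#' mixture: `G d` means, `G - 1` proportions, plus the family-specific
#' covariance count (for EEV in dimension 2: one scale, one shape, one
#' orientation angle per component).
#'
#' @param family covariance family.
#' @param G number of components.
#' @param dim data dimension (only 2 is exercised).
#' @return integer.
#' @examples
#' nFreeParams("EEV", G = 3)  # 13
#' @export
nFreeParams <- function(family, G, dim = 2) {
  family <- match.arg(family, .FAMILIES)
  d <- dim
  covp <- switch(family,
    EII = 1,
    VII = G,
    EEE = d * (d + 1) / 2,
    VVV = G * d * (d + 1) / 2,
    EEV = 1 + (d - 1) + G * d * (d - 1) / 2)
  as.integer(G * d + (G - 1) + covp)
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 loglik + k log n`, minimized: smaller is better under this
#' sign convention (some software maximizes the negated form).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observation units entering the likelihood.
#' @return scalar BIC.
#' @export
bicScore <- function(loglik, k, n) {
  if (n < 1) stop("n must be >= 1")
  -2 * loglik + k * log(n)
}

# --- initialization and fitting ---------------------------------------------

# params from a hard partition (one-hot weights)
.hardParams <- function(points, z, G, family) {
  w <- matrix(0, nrow(points), G)
  w[cbind(seq_len(nrow(points)), z)] <- 1
  fmmMStep(points, w, family)
}

#' CEM initialization
#'
#' Short classification-EM runs from random starts: points are hard
#' assigned to their highest-posterior component between the E and M
#' steps. The start with the highest complete-data log-likelihood is
#' returned; CEM is robust to extreme values and gives the subsequent EM a
#' good basin.
#'
#' @inheritParams fmmLoglik
#' @param G number of components.
#' @param family covariance family.
#' @param nStarts number of random starts.
#' @param nIter CEM iterations per start.
#' @param seed optional integer seed.
#' @return A [GaussianMixtureParams-class].
#' @export
cemInit <- function(points, G, family = "VVV", nStarts = 20, nIter = 10,
                    seed = NULL) {
  points <- as.matrix(points)
  .maybeSeed(seed)
  n <- nrow(points)
  if (nStarts < 1) stop("nStarts must be >= 1")
  if (G == 1) return(.hardParams(points, rep(1L, n), 1L, family))
  best <- NULL
  bestScore <- -Inf
  for (s in seq_len(nStarts)) {
    centers <- points[sample.int(n, G), , drop = FALSE]
    d2 <- vapply(seq_len(G), function(g) {
      rowSums(sweep(points, 2, centers[g, ])^2)
    }, numeric(n))
    z <- max.col(-d2, ties.method = "first")
    ok <- TRUE
    par <- NULL
    for (it in seq_len(nIter)) {
      if (length(unique(z)) < G) { ok <- FALSE; break }
      par <- tryCatch(.hardParams(points, z, G, family),
                      error = function(e) NULL)
      if (is.null(par)) { ok <- FALSE; break }
      a <- sweep(.logDensMatrix(points, par), 2, log(pmax(par@pi, 1e-300)), "+")
      z <- max.col(a, ties.method = "first")
    }
    if (!ok || is.null(par)) next
    if (length(unique(z)) == G) {
      a <- sweep(.logDensMatrix(points, par), 2, log(pmax(par@pi, 1e-300)), "+")
      score <- sum(a[cbind(seq_len(n), z)])
      if (score > bestScore) { bestScore <- score; best <- par }
    }
  }
  if (is.null(best)) stop("CEM initialization failed: all starts collapsed")
  best
}

#' Fit a Gaussian mixture by EM
#'
#' Alternates the E and M steps from a CEM initialization until the
#' log-likelihood change drops below `tol` or `maxIter` is reached. The
#' log-likelihood trace is non-decreasing; a component collapse triggers a
#' fresh CEM restart (up to 3 times).
#'
#' @inheritParams cemInit
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param init optional [GaussianMixtureParams-class] to start from
#'   (skips CEM).
#' @param sortByPi relabel components by descending mixing proportion
#'   after fitting (reporting convention).
#' @return An [FmmFit-class].
#' @examples
#' sim <- simulateFmmPoints(igf1FmmParams(), 300, seed = 1)
#' fit <- fmmFit(sim$points, G = 3, family = "EEV", seed = 1)
#' @export
fmmFit <- function(points, G, family = "VVV", tol = 1e-8, maxIter = 500,
                   nStarts = 20, nIter = 10, init = NULL, seed = NULL,
                   sortByPi = TRUE) {
  points <- as.matrix(points)
  .maybeSeed(seed)
  n <- nrow(points)
  if (n < nFreeParams(family, G))
    warning("fewer points than free parameters (n = ", n, ")")
  for (attempt in 1:4) {
    par <- if (!is.null(init) && attempt == 1) init else
      cemInit(points, G, family, nStarts, nIter)
    trace <- numeric()
    res <- tryCatch({
      ll <- fmmLoglik(points, par)
      for (it in seq_len(maxIter)) {
        w <- fmmEStep(points, par)
        par <- fmmMStep(points, w, family)
        llNew <- fmmLoglik(points, par)
        trace <- c(trace, llNew)
        if (abs(llNew - ll) < tol) { ll <- llNew; break }
        ll <- llNew
      }
      list(par = par, ll = ll, trace = trace)
    }, splicemixCollapse = function(e) NULL, error = function(e) {
      if (inherits(e, "splicemixCollapse")) NULL else stop(e)
    })
    if (!is.null(res)) break
    if (attempt == 4) stop("EM failed: repeated component collapse")
  }
  par <- res$par
  if (sortByPi && G > 1) {
    o <- order(par@pi, decreasing = TRUE)
    par <- fmmParams(par@pi[o], par@mu[, o, drop = FALSE], par@Sigma[o],
                     family)
  }
  w <- fmmEStep(points, par)
  tis <- attr(points, "tissue")
  rep_ <- attr(points, "replicate")
  methods::new("FmmFit", params = par, weights = w, loglik = res$ll,
               trace = res$trace,
               bic = bicScore(res$ll, nFreeParams(family, G), n),
               n = as.integer(n),
               tissue = if (is.null(tis)) character() else as.character(tis),
               replicate = if (is.null(rep_)) character() else
                 as.character(rep_),
               selection = data.frame())
}

#' BIC model selection over (G, family) candidates
#'
#' Fits every combination of component count and covariance family and
#' returns the minimum-BIC fit; the full score table is kept in the
#' `selection` slot ([selectionTable()]). Candidates whose fit fails are
#' excluded with a warning.
#'
#' @inheritParams fmmFit
#' @param Gs integer vector of component counts.
#' @param families character vector of covariance families.
#' @return An [FmmFit-class] (the best model).
#' @export
fmmSelect <- function(points, Gs = 1:6, families = "EEV", tol = 1e-8,
                      maxIter = 500, nStarts = 20, nIter = 10, seed = NULL) {
  .maybeSeed(seed)
  fits <- list()
  tab <- data.frame()
  for (fam in families) for (G in Gs) {
    fit <- tryCatch(
      suppressWarnings(fmmFit(points, G, fam, tol, maxIter, nStarts, nIter)),
      error = function(e) {
        warning(sprintf("fit G=%d family=%s failed: %s", G, fam,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit) || !is.finite(fit@loglik)) next
    fits[[length(fits) + 1]] <- fit
    tab <- rbind(tab, data.frame(G = G, family = fam, loglik = fit@loglik,
                                 df = nFreeParams(fam, G), bic = fit@bic))
  }
  if (nrow(tab) == 0) stop("no candidate model could be fitted")
  best <- fits[[which.min(tab$bic)]]
  best@selection <- tab
  best
}

#' @rdname mixingProportions
setMethod("mixingProportions", "FmmFit", function(object) object@params@pi)
#' @rdname mixingProportions
setMethod("componentMeans", "FmmFit", function(object) object@params@mu)
#' @rdname mixingProportions
setMethod("componentCovariances", "FmmFit", function(object) object@params@Sigma)
#' @rdname mixingProportions
setMethod("nComponents", "FmmFit", function(object) object@params@G)

#' @rdname posteriorWeights
setMethod("posteriorWeights", "FmmFit", function(object) object@weights)

#' @rdname selectionTable
setMethod("selectionTable", "FmmFit", function(object) object@selection)

setMethod("show", "FmmFit", function(object) {
  cat(sprintf("FmmFit: G = %d, family = %s, n = %d pooled units\n",
              object@params@G, object@params@family, object@n))
  cat(sprintf("  loglik = %.4f, BIC = %.4f (%d EM iterations)\n",
              object@loglik, object@bic, length(object@trace)))
  cat("  pi:", paste(signif(object@params@pi, 4), collapse = ", "), "\n")
})
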