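#' Replicate design matrix
#'
#' The known 2R x 2 block design `V = [[1_R, 0_R], [0_R, 1_R]]` mapping
#' the two variant-level effects onto the stacked replicate vector
#' (first R entries: variant 1 replicates; last R: variant 2). Satisfies
#' `V'V = R I_2`.
#'
#' @param R replicate count (>= 1).
#' @return a 2R x 2 matrix of zeros and ones.
#' @examples
#' buildDesign(3)
#' @export
buildDesign <- function(R) {
  if (R < 1) stop("R must be >= 1")
  kronecker(diag(2), matrix(1, R, 1))
}

#' Component marginal moments of a tissue vector
#'
#' Mean `V alpha_g` and covariance `V Phi_g V' + Omega_g` with
#' `Omega_g = diag(V sigma2_g)` of the 2R-dimensional stacked replicate
#' vector under component g: the random effect induces within-variant
#' replicate covariance `Phi_g[h,h]` and cross-variant covariance
#' `Phi_g[1,2]`, while the measurement error adds per-variant variance on
#' the diagonal.
#'
#' @param params a [LmmMixtureParams-class].
#' @param g component index.
#' @param R replicate count.
#' @return list with `mu` (2R-vector) and `Sigma` (2R x 2R matrix).
#' @export
marginalMoments <- function(params, g, R) {
  V <- buildDesign(R)
  mu <- drop(V %*% params@alpha[, g])
  Omega <- diag(rep(params@sigma2[, g], each = R), 2 * R)
  Sigma <- V %*% params@Phi[[g]] %*% t(V) + Omega
  list(mu = mu, Sigma = (Sigma + t(Sigma)) / 2)
}

# stacked data grouped by replicate count: list of (R, idx, X[2R x m])
.fmlmmGroups <- function(xlist) {
  lapply(.stackByR(xlist), function(idx) {
    list(R = length(xlist[[idx[1]]]) / 2, idx = idx,
         X = do.call(cbind, xlist[idx]))
  })
}

# per-(R, g) cache of the matrices every E/M step needs
.fmlmmCache <- function(params, R) {
  V <- buildDesign(R)
  lapply(seq_len(params@G), function(g) {
    mm <- marginalMoments(params, g, R)
    ch <- .safeChol(mm$Sigma)
    SigInv <- chol2inv(ch)
    Omega <- diag(rep(params@sigma2[, g], each = R), 2 * R)
    K <- params@Phi[[g]] %*% t(V) %*% SigInv        # 2 x 2R
    Ce <- Omega - Omega %*% SigInv %*% Omega        # cov(e | x)
    trh <- c(sum(diag(Ce)[1:R]), sum(diag(Ce)[R + 1:R]))
    list(mu = mm$mu, ch = ch, SigInv = SigInv, K = K, KV = K %*% V,
         trh = trh, V = V, R = R)
  })
}

.stackByR <- function(xlist) {
  Rs <- vapply(xlist, length, 0L) / 2L
  split(seq_along(xlist), Rs)
}

# log N(x_i | mu_g, Sigma_g) for all tissues/components, given the grouped
# data and per-group caches
.fmlmmLogDensCore <- function(groups, caches, n, G) {
  ld <- matrix(NA_real_, n, G)
  for (k in seq_along(groups)) {
    grp <- groups[[k]]
    for (g in seq_len(G)) {
      cg <- caches[[k]][[g]]
      z <- backsolve(cg$ch, grp$X - cg$mu, transpose = TRUE)
      ld[grp$idx, g] <- -0.5 * 2 * grp$R * log(2 * pi) -
        sum(log(diag(cg$ch))) - 0.5 * colSums(z^2)
    }
  }
  ld
}

.fmlmmLogDens <- function(xlist, params) {
  groups <- .fmlmmGroups(xlist)
  caches <- lapply(groups, function(grp) .fmlmmCache(params, grp$R))
  .fmlmmLogDensCore(groups, caches, length(xlist), params@G)
}

#' Marginal log-likelihood of an LMM mixture
#'
#' `sum_i log sum_g pi_g N(x_i | V alpha_g, V Phi_g V' + Omega_g)` over
#' tissues (the random effects are integrated out).
#'
#' @param xlist list of stacked tissue vectors (see [tissueVectors()]).
#' @param params a [LmmMixtureParams-class].
#' @return scalar log-likelihood.
#' @export
fmlmmLoglik <- function(xlist, params) {
  ld <- .fmlmmLogDens(xlist, params)
  sum(.logsumexp(sweep(ld, 2, log(params@pi), "+")))
}

#' E step of the LMM mixture
#'
#' Posterior probability that each tissue (all its replicates jointly)
#' arises from each component, computed in log space from the marginal
#' Gaussian densities.
#'
#' @inheritParams fmlmmLoglik
#' @return n x G weight matrix with unit row sums.
#' @export
fmlmmEStep <- function(xlist, params) {
  a <- sweep(.fmlmmLogDens(xlist, params), 2, log(params@pi), "+")
  w <- exp(a - .logsumexp(a))
  w / rowSums(w)
}

#' Random-effect prediction (posterior mean)
#'
#' The estimator of the tissue-level random effect under component g,
#' `u_ig = w_ig Phi_g V' (V Phi_g V' + Omega_g)^{-1} (x_i - V alpha_g)`,
#' i.e. the BLUP-type posterior mean damped by the tissue's posterior
#' membership weight `w`.
#'
#' @param x a stacked 2R tissue vector.
#' @param params a [LmmMixtureParams-class].
#' @param g component index.
#' @param w posterior membership weight of the tissue for component g
#'   (default 1).
#' @return 2-vector random effect estimate.
#' @export
blup <- function(x, params, g, w = 1) {
  R <- length(x) / 2
  if (R != round(R)) stop("x must have even length 2R")
  cache <- .fmlmmCache(params, R)[[g]]
  drop(w * cache$K %*% (x - cache$mu))
}

#' M step of the LMM mixture
#'
#' Updates the mixing proportions (average posterior weights), fixed
#' effects, random-effect covariances and per-variant error variances
#' from the current posterior weights. The fixed-effect update is, by
#' default, the iterative correction
#' `alpha + diag(sigma2) (V'V)^{-1} V' Sigma^{-1} sum_i w_i (x_i - V alpha) / sum_i w_i`
#' (`alphaUpdate = "printed"`); a closed-form weighted GLS solve is
#' available via `alphaUpdate = "gls"` — both share the same fixed point,
#' and the default is the exact conditional maximizer of the expected
#' complete-data log-likelihood over the fixed effects.
#' `Phi` is updated from the conditional second moment of the random
#' effect, `E(u u' | x) = u0 u0' + (I - K V) Phi` with
#' `u0 = K (x - V alpha)` the conditional mean, then symmetrized and
#' floored to the PSD cone.
#' The error variances use the conditional error moment: per variant h,
#' `sigma2_h = sum_i w_i (||e_i(h)||^2 + tr_h cov(e|x)) / (R sum_i w_i)`
#' with `cov(e|x) = Omega - Omega Sigma^{-1} Omega`, its trace restricted
#' to the variant's R diagonal entries, and `e_i = x_i - V(alphaNew + u0_i)`
#' evaluated at the freshly updated fixed effects (sequential conditional
#' maximization, which keeps the marginal log-likelihood non-decreasing).
#'
#' @inheritParams fmlmmLoglik
#' @param weights n x G posterior matrix.
#' @param alphaUpdate `"printed"` or `"gls"`.
#' @return updated [LmmMixtureParams-class].
#' @export
fmlmmMStep <- function(xlist, weights, params,
                       alphaUpdate = c("printed", "gls")) {
  alphaUpdate <- match.arg(alphaUpdate)
  groups <- .fmlmmGroups(xlist)
  caches <- lapply(groups, function(grp) .fmlmmCache(params, grp$R))
  .fmlmmMStepCore(groups, caches, as.matrix(weights), params, alphaUpdate)
}

.fmlmmMStepCore <- function(groups, caches, weights, params, alphaUpdate) {
  n <- nrow(weights)
  G <- params@G
  ng <- colSums(weights)
  if (any(ng < 1e-10)) {
    e <- simpleError("component collapse: empty component in M step")
    class(e) <- c("splicemixCollapse", class(e))
    stop(e)
  }
  alphaNew <- matrix(0, 2, G)
  PhiNew <- vector("list", G)
  sig2New <- matrix(0, 2, G)
  for (g in seq_len(G)) {
    corrNum <- c(0, 0)      # printed-update correction: numerator
    corrDen <- c(0, 0)      # and its V'Omega^-1 V normalizer
    A <- matrix(0, 2, 2)    # GLS normal matrix
    b <- c(0, 0)            # GLS right-hand side
    M2 <- matrix(0, 2, 2)   # sum_i w E(u u' | x, z = g)
    denom <- 0              # sum_i w_i R_i
    resid <- vector("list", length(groups))
    for (k in seq_along(groups)) {
      grp <- groups[[k]]
      R <- grp$R
      cache <- caches[[k]][[g]]
      w <- weights[grp$idx, g]
      Rm <- grp$X - cache$mu                     # residuals x_i - V alpha
      u0 <- cache$K %*% Rm                       # conditional mean of u_ig
      if (alphaUpdate == "printed") {
        # iterative correction alpha + (V'Omega^-1 V)^-1 V'Sigma^-1 r;
        # for a single replicate count this is exactly
        # diag(sigma2) (V'V)^-1 V' Sigma^-1 sum_i w_i r_i / sum_i w_i
        SiR <- cache$SigInv %*% (Rm %*% w)
        corrNum <- corrNum + drop(crossprod(cache$V, SiR))
        corrDen <- corrDen + sum(w) * R / params@sigma2[, g]
      } else {
        A <- A + sum(w) * crossprod(cache$V, cache$SigInv %*% cache$V)
        b <- b + drop(crossprod(cache$V, cache$SigInv %*% (grp$X %*% w)))
      }
      # E(u u' | x) = u0 u0' + (I - K V) Phi, with K V specific to this
      # replicate-count group
      M2 <- M2 + u0 %*% (w * t(u0)) +
        sum(w) * (diag(2) - cache$KV) %*% params@Phi[[g]]
      resid[[k]] <- Rm - cache$V %*% u0          # conditional error at old alpha
      denom <- denom + sum(w) * R
    }
    if (alphaUpdate == "printed") {
      alphaNew[, g] <- params@alpha[, g] + corrNum / corrDen
    } else {
      alphaNew[, g] <- drop(solve(A, b))
    }
    # error variances at the updated fixed effects (sequential conditional
    # maximization): shift the conditional residual by V (alpha_new - alpha)
    dAlpha <- alphaNew[, g] - params@alpha[, g]
    num <- c(0, 0)
    for (k in seq_along(groups)) {
      grp <- groups[[k]]
      R <- grp$R
      cache <- caches[[k]][[g]]
      w <- weights[grp$idx, g]
      E <- resid[[k]] - rep(dAlpha, each = R)
      num <- num + c(sum(w * colSums(E[1:R, , drop = FALSE]^2)) +
                       sum(w) * cache$trh[1],
                     sum(w * colSums(E[R + 1:R, , drop = FALSE]^2)) +
                       sum(w) * cache$trh[2])
    }
    Phi <- M2 / ng[g]
    Phi <- (Phi + t(Phi)) / 2
    ePhi <- eigen(Phi, symmetric = TRUE)
    ev <- pmax(ePhi$values, 0)
    PhiNew[[g]] <- ePhi$vectors %*% (ev * t(ePhi$vectors))
    sig2New[, g] <- pmax(num / denom, 1e-12)
  }
  fmlmmParams(pi = ng / n, alpha = alphaNew, Phi = PhiNew, sigma2 = sig2New)
}

# EM driver: one marginal-density evaluation and one shared cache per
# iteration; returns params whose loglik equals the last trace entry
.fmlmmEM <- function(groups, n, par, tol, maxIter, alphaUpdate) {
  G <- par@G
  llPrev <- -Inf
  trace <- numeric()
  for (it in seq_len(maxIter)) {
    caches <- lapply(groups, function(grp) .fmlmmCache(par, grp$R))
    ld <- .fmlmmLogDensCore(groups, caches, n, G)
    a <- sweep(ld, 2, log(par@pi), "+")
    lse <- .logsumexp(a)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (abs(ll - llPrev) < tol) break
    llPrev <- ll
    w <- exp(a - lse)
    w <- w / rowSums(w)
    par <- .fmlmmMStepCore(groups, caches, w, par, alphaUpdate)
    if (it == maxIter) {
      # ran out of iterations right after an M step: report the loglik of
      # the parameters actually returned
      caches <- lapply(groups, function(grp) .fmlmmCache(par, grp$R))
      ld <- .fmlmmLogDensCore(groups, caches, n, G)
      trace <- c(trace, sum(.logsumexp(sweep(ld, 2, log(par@pi), "+"))))
    }
  }
  list(par = par, ll = trace[length(trace)], trace = trace)
}

# initial parameters from a hard tissue partition
.fmlmmInitFromLabels <- function(xlist, lab, G, jitterSd = 0) {
  tm <- t(vapply(xlist, function(x) {
    R <- length(x) / 2
    c(mean(x[1:R]), mean(x[R + 1:R]))
  }, numeric(2)))
  withinVar <- rowMeans(vapply(xlist, function(x) {
    R <- length(x) / 2
    if (R < 2) return(c(NA_real_, NA_real_))
    c(var(x[1:R]), var(x[R + 1:R]))
  }, numeric(2)), na.rm = TRUE)
  if (anyNA(withinVar)) withinVar[is.na(withinVar)] <- 1e-4
  withinVar <- pmax(withinVar, 1e-8)
  alpha <- matrix(0, 2, G)
  Phi <- vector("list", G)
  pi_ <- numeric(G)
  for (g in seq_len(G)) {
    idx <- which(lab == g)
    if (length(idx) == 0) stop("empty class in initialization")
    alpha[, g] <- colMeans(tm[idx, , drop = FALSE])
    S <- if (length(idx) >= 3) cov(tm[idx, , drop = FALSE]) else
      diag(pmax(apply(tm, 2, var) / 4, 1e-6))
    eS <- eigen((S + t(S)) / 2, symmetric = TRUE)
    Phi[[g]] <- eS$vectors %*% (pmax(eS$values, 1e-8) * t(eS$vectors))
    pi_[g] <- length(idx) / length(xlist)
  }
  if (jitterSd > 0) alpha <- alpha + rnorm(length(alpha), 0, jitterSd)
  fmlmmParams(pi = pi_, alpha = alpha, Phi = Phi,
              sigma2 = matrix(withinVar, 2, G))
}

#' Fit a finite mixture of linear mixed models
#'
#' EM over the marginal likelihood of the stacked tissue vectors:
#' [fmlmmEStep()] / [fmlmmMStep()] alternated until the marginal
#' log-likelihood change drops below `tol`. Several initializations are
#' tried — the first aggregates the MAP labels of a pooled-replicate
#' Gaussian mixture to tissues, the others use k-means on tissue means
#' (with jittered fixed effects on alternate starts) — and the best
#' converged log-likelihood is kept. Tissues may have unequal replicate
#' counts; the design matrix and error covariance are built per tissue.
#'
#' @param panel a ratio [TissuePanel-class], or a list of stacked tissue
#'   vectors.
#' @param G number of components.
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param nStarts number of initializations.
#' @param seed optional integer seed.
#' @param alphaUpdate fixed-effect update variant (see [fmlmmMStep()]).
#' @param init optional [LmmMixtureParams-class] start (used as the only
#'   start).
#' @param sortByPi relabel components by descending mixing proportion.
#' @return An [FmlmmFit-class].
#' @examples
#' sim <- simulateFmlmmPanel(igf1FmlmmParams(), 40, 3, seed = 1)
#' fit <- fmlmmFit(sim$panel, G = 2, nStarts = 3, seed = 1)
#' @export
fmlmmFit <- function(panel, G, tol = 1e-8, maxIter = 500, nStarts = 10,
                     seed = NULL, alphaUpdate = c("printed", "gls"),
                     init = NULL, sortByPi = TRUE) {
  alphaUpdate <- match.arg(alphaUpdate)
  .maybeSeed(seed)
  if (methods::is(panel, "TissuePanel")) {
    xlist <- tissueVectors(panel)
  } else {
    xlist <- panel
    if (is.null(names(xlist)))
      names(xlist) <- sprintf("tissue%03d", seq_along(xlist))
  }
  n <- length(xlist)
  if (n < G) stop("fewer tissues than components")
  tm <- t(vapply(xlist, function(x) {
    R <- length(x) / 2
    c(mean(x[1:R]), mean(x[R + 1:R]))
  }, numeric(2)))
  starts <- list()
  if (!is.null(init)) {
    starts <- list(init)
  } else {
    lab0 <- tryCatch({
      pooled <- do.call(rbind, lapply(seq_along(xlist), function(i) {
        x <- xlist[[i]]
        R <- length(x) / 2
        cbind(x[1:R], x[R + 1:R])
      }))
      tisRep <- rep(seq_len(n), vapply(xlist, length, 0L) / 2L)
      fit0 <- suppressWarnings(fmmFit(pooled, G, "VVV", nStarts = 10))
      lab <- max.col(fit0@weights, ties.method = "first")
      maj <- vapply(split(lab, tisRep), function(l) {
        which.max(tabulate(l, G))
      }, 0L)
      if (length(unique(maj)) < G) NULL else maj
    }, error = function(e) NULL)
    if (!is.null(lab0)) {
      starts[[1]] <- tryCatch(.fmlmmInitFromLabels(xlist, lab0, G),
                              error = function(e) NULL)
      starts <- Filter(Negate(is.null), starts)
    }
    while (length(starts) < nStarts) {
      lab <- tryCatch(kmeans(tm, centers = G, nstart = 1)$cluster,
                      error = function(e) sample.int(G, n, replace = TRUE))
      jit <- if (length(starts) %% 2 == 1) 0.01 else 0
      s <- tryCatch(.fmlmmInitFromLabels(xlist, lab, G, jitterSd = jit),
                    error = function(e) NULL)
      if (!is.null(s)) starts[[length(starts) + 1]] <- s
    }
  }
  groups <- .fmlmmGroups(xlist)
  # screen starts with short EM runs, then run the best start to
  # convergence (standard practice for multi-start mixture fitting)
  shortIter <- min(50L, maxIter)
  screened <- NULL
  for (par0 in starts) {
    res <- tryCatch(.fmlmmEM(groups, n, par0, tol, shortIter, alphaUpdate),
                    splicemixCollapse = function(e) NULL,
                    error = function(e) NULL)
    if (!is.null(res) && is.finite(res$ll) &&
        (is.null(screened) || res$ll > screened$ll)) screened <- res
  }
  if (is.null(screened)) stop("all FMLMM starts failed")
  best <- tryCatch(.fmlmmEM(groups, n, screened$par, tol, maxIter,
                            alphaUpdate),
                   splicemixCollapse = function(e) screened,
                   error = function(e) screened)
  if (best$ll < screened$ll) best <- screened
  par <- best$par
  if (sortByPi && G > 1) {
    o <- order(par@pi, decreasing = TRUE)
    par <- fmlmmParams(par@pi[o], par@alpha[, o, drop = FALSE], par@Phi[o],
                       par@sigma2[, o, drop = FALSE])
  }
  w <- fmlmmEStep(xlist, par)
  blups <- lapply(seq_len(G), function(g) {
    t(vapply(seq_len(n), function(i) blup(xlist[[i]], par, g, w[i, g]),
             numeric(2)))
  })
  methods::new("FmlmmFit", params = par, weights = w, loglik = best$ll,
               trace = best$trace,
               bic = bicScore(best$ll, fmlmmFreeParams(G), n),
               nTissues = as.integer(n), tissue = names(xlist),
               blup = blups, selection = data.frame())
}

#' Free parameter count of the LMM mixture
#'
#' Per component: 2 fixed effects, 3 random-effect covariance entries and
#' 2 error variances; plus G - 1 mixing proportions.
#'
#' @param G number of components.
#' @return integer `G (2 + 3 + 2) + (G - 1)`.
#' @examples
#' fmlmmFreeParams(3)  # 23
#' @export
fmlmmFreeParams <- function(G) as.integer(G * 7 + (G - 1))

#' BIC model selection for the LMM mixture
#'
#' Fits the model for each candidate G and returns the minimum-BIC fit
#' with the score table in the `selection` slot. The BIC sample size is
#' the number of tissues — the statistical units of this model — not the
#' pooled replicate count.
#'
#' @inheritParams fmlmmFit
#' @param Gs integer vector of candidate component counts.
#' @return An [FmlmmFit-class].
#' @export
fmlmmSelect <- function(panel, Gs = c(2, 3), tol = 1e-8, maxIter = 500,
                        nStarts = 10, seed = NULL,
                        alphaUpdate = c("printed", "gls")) {
  alphaUpdate <- match.arg(alphaUpdate)
  .maybeSeed(seed)
  fits <- list()
  tab <- data.frame()
  for (G in Gs) {
    fit <- tryCatch(
      fmlmmFit(panel, G, tol, maxIter, nStarts, alphaUpdate = alphaUpdate),
      error = function(e) {
        warning(sprintf("FMLMM fit G=%d failed: %s", G, conditionMessage(e)))
        NULL
      })
    if (is.null(fit) || !is.finite(fit@loglik)) next
    fits[[length(fits) + 1]] <- fit
    tab <- rbind(tab, data.frame(G = G, loglik = fit@loglik,
                                 df = fmlmmFreeParams(G), bic = fit@bic))
  }
  if (nrow(tab) == 0) stop("no candidate model could be fitted")
  best <- fits[[which.min(tab$bic)]]
  best@selection <- tab
  best
}

#' @rdname mixingProportions
setMethod("mixingProportions", "FmlmmFit", function(object) object@params@pi)
#' @rdname mixingProportions
setMethod("componentMeans", "FmlmmFit", function(object) object@params@alpha)
#' @rdname mixingProportions
setMethod("componentCovariances", "FmlmmFit", function(object) object@params@Phi)
#' @rdname mixingProportions
setMethod("nComponents", "FmlmmFit", function(object) object@params@G)
#' @rdname errorVariances
setMethod("errorVariances", "FmlmmFit", function(object) object@params@sigma2)
#' @rdname posteriorWeights
setMethod("posteriorWeights", "FmlmmFit", function(object) object@weights)
#' @rdname selectionTable
setMethod("selectionTable", "FmlmmFit", function(object) object@selection)

#' @rdname allocationTable
setMethod("allocationTable", "FmlmmFit", function(object) {
  a <- mapAllocate(object@weights, tissue = object@tissue,
                   replicate = rep("1", nrow(object@weights)))
  a$units$replicate <- NULL
  a
})

setMethod("show", "FmlmmFit", function(object) {
  cat(sprintf("FmlmmFit: G = %d, n = %d tissues\n", object@params@G,
              object@nTissues))
  cat(sprintf("  marginal loglik = %.4f, BIC = %.4f (%d EM iterations)\n",
              object@loglik, object@bic, length(object@trace)))
  cat("  pi:", paste(signif(object@params@pi, 4), collapse = ", "), "\n")
})
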