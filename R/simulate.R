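# MVN sampling tolerant of the near-singular covariances typical of
# compositional couples (|rho| ~ 0.99): MASS::mvrnorm is eigen-based.
.rmvn <- function(n, mu, Sigma) {
  if (all(abs(Sigma) < .Machine$double.eps)) {
    matrix(rep(mu, each = n), n, length(mu))
  } else {
    MASS::mvrnorm(n, mu = mu, Sigma = Sigma, tol = 1e-6)
  }
}

.maybeSeed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Simulate points from a Gaussian mixture
#'
#' Draws `n` bivariate (Ratio1, Ratio2) points: a component is sampled from
#' the mixing proportions, then the point from that component's bivariate
#' Gaussian. True component labels are returned for recovery studies.
#' Following the generative model, no clamping to the unit simplex is
#' applied by default — the fitted Gaussians are unconstrained; set
#' `renormalize = TRUE` to project onto the simplex (dividing the implied
#' triple (r1, r2, 1 - r1 - r2) by its sum after flooring at 0) for
#' realism studies.
#'
#' @param params a [GaussianMixtureParams-class].
#' @param n number of points (positive).
#' @param seed optional integer seed fixing the output.
#' @param renormalize project generated triples back onto the simplex.
#' @return list with `points` (n x 2 matrix) and `label` (integer vector).
#' @examples
#' sim <- simulateFmmPoints(igf1FmmParams(), 100, seed = 1)
#' table(sim$label)
#' @export
simulateFmmPoints <- function(params, n, seed = NULL, renormalize = FALSE) {
  stopifnot(methods::is(params, "GaussianMixtureParams"))
  methods::validObject(params)
  if (length(n) != 1 || n <= 0) stop("n must be a positive integer")
  .maybeSeed(seed)
  lab <- sample.int(params@G, n, replace = TRUE, prob = params@pi)
  x <- matrix(0, n, 2, dimnames = list(NULL, c("ratio1", "ratio2")))
  for (g in seq_len(params@G)) {
    idx <- which(lab == g)
    if (length(idx))
      x[idx, ] <- .rmvn(length(idx), params@mu[, g], params@Sigma[[g]])
  }
  if (renormalize) {
    r3 <- pmax(1 - rowSums(x), 0)
    xp <- pmax(x, 0)
    s <- rowSums(xp) + r3
    x <- xp / s
  }
  list(points = x, label = lab)
}

#' Simulate a replicated tissue panel from an LMM mixture
#'
#' For each tissue a component is drawn from the mixing proportions, a
#' tissue-level random effect `u ~ MVN(0, Phi_g)` shared by all its
#' replicates, and per-replicate measurement errors
#' `e ~ MVN(0, diag(V sigma2_g))`; the observed stacked vector is
#' `x = V (alpha_g + u) + e` with `V` the replicate design matrix. Ratio3
#' is derived as `1 - Ratio1 - Ratio2` (the unit constraint), so generated
#' triples sum to one exactly while individual values may leave \[0, 1\]
#' in the Gaussian tails.
#'
#' @param params a [LmmMixtureParams-class].
#' @param nTissues number of tissues.
#' @param nReplicates technical replicates per tissue (R >= 1).
#' @param seed optional integer seed.
#' @param renormalize floor the triple at 0 and renormalize to sum 1.
#' @return list with `panel` (a ratio [TissuePanel-class]) and `label`
#'   (true component per tissue, named).
#' @examples
#' sim <- simulateFmlmmPanel(igf1FmlmmParams(), 10, 3, seed = 1)
#' sim$panel
#' @export
simulateFmlmmPanel <- function(params, nTissues, nReplicates = 3,
                               seed = NULL, renormalize = FALSE) {
  stopifnot(methods::is(params, "LmmMixtureParams"))
  methods::validObject(params)
  if (nTissues < 1 || nReplicates < 1) stop("need nTissues, nReplicates >= 1")
  .maybeSeed(seed)
  R <- as.integer(nReplicates)
  lab <- sample.int(params@G, nTissues, replace = TRUE, prob = params@pi)
  tid <- sprintf("tissue%03d", seq_len(nTissues))
  names(lab) <- tid
  vals <- matrix(0, 3, nTissues * R,
                 dimnames = list(.ISOFORMS, NULL))
  for (i in seq_len(nTissues)) {
    g <- lab[i]
    u <- drop(.rmvn(1, c(0, 0), params@Phi[[g]]))
    m <- params@alpha[, g] + u
    e1 <- rnorm(R, 0, sqrt(params@sigma2[1, g]))
    e2 <- rnorm(R, 0, sqrt(params@sigma2[2, g]))
    r1 <- m[1] + e1
    r2 <- m[2] + e2
    r3 <- 1 - r1 - r2
    if (renormalize) {
      tr <- rbind(pmax(r1, 0), pmax(r2, 0), pmax(r3, 0))
      tr <- sweep(tr, 2, colSums(tr), "/")
      r1 <- tr[1, ]; r2 <- tr[2, ]; r3 <- tr[3, ]
    }
    vals[, (i - 1) * R + seq_len(R)] <- rbind(r1, r2, r3)
  }
  panel <- tissuePanel(vals, tissue = rep(tid, each = R),
                       replicate = rep(seq_len(R), nTissues),
                       valueType = "ratio")
  list(panel = panel, label = lab)
}

#' Emit a synthetic raw CT table for a panel
#'
#' Builds the instrument-style export that [ctToPanel()] consumes, such
#' that comparative-CT processing followed by compositional equalization
#' recovers the panel's ratios exactly when no CT noise is added. Each
#' unit's isoform quantity is its ratio times the tissue's `panLevel`; CTs
#' are `referenceCt - log2(quantity)` with the reference gene at
#' `referenceCt`. A dedicated synthetic calibrator sample with unit
#' quantity in every assay (including PAN) is appended: calibrating
#' against it rescales all assays by a common factor, which the
#' compositional ratios then cancel. The PAN assay measures the summed
#' isoform quantity, so the PAN-consistency check passes by construction
#' on noiseless output.
#'
#' @param panel a ratio [TissuePanel-class] with strictly positive values.
#' @param panLevel total IGF-1 quantity per tissue (scalar or named
#'   vector).
#' @param referenceCt CT of the reference gene (cycles).
#' @param calibratorId tissue_id given to the appended calibrator sample.
#' @param noiseSd optional Gaussian CT noise standard deviation (cycles).
#' @param seed optional integer seed (used only when `noiseSd > 0`).
#' @return data frame with columns `tissue_id`, `replicate_id`, `assay`,
#'   `ct`.
#' @export
simulateCtTable <- function(panel, panLevel = 10, referenceCt = 20,
                            calibratorId = "calibrator", noiseSd = 0,
                            seed = NULL) {
  v <- panelValues(panel)
  if (!all(.ISOFORMS %in% rownames(v))) stop("panel must contain Ea, Eb, Ec")
  v <- v[.ISOFORMS, , drop = FALSE]
  if (any(v <= 0)) stop("panel values must be strictly positive")
  tis <- tissueIds(panel)
  if (calibratorId %in% tis) stop("calibratorId collides with a panel tissue")
  if (length(panLevel) == 1) {
    lev <- setNames(rep(panLevel, length(unique(tis))), unique(tis))
  } else {
    lev <- panLevel[unique(tis)]
    if (anyNA(lev)) stop("panLevel must name every tissue")
  }
  if (any(lev <= 0)) stop("panLevel must be positive")
  q <- sweep(v, 2, lev[tis], "*")
  q <- rbind(q, PAN = colSums(q))
  rep_ <- replicateIds(panel)
  long <- data.frame(
    tissue_id = rep(tis, each = nrow(q)),
    replicate_id = rep(rep_, each = nrow(q)),
    assay = rep(rownames(q), ncol(q)),
    ct = referenceCt - log2(as.vector(q)), stringsAsFactors = FALSE)
  refRows <- data.frame(tissue_id = tis, replicate_id = rep_,
                        assay = "reference", ct = referenceCt,
                        stringsAsFactors = FALSE)
  calRows <- data.frame(tissue_id = calibratorId, replicate_id = 1L,
                        assay = c(.ASSAYS, "reference"),
                        ct = c(rep(referenceCt - log2(1), 4), referenceCt),
                        stringsAsFactors = FALSE)
  ct <- rbind(long, refRows, calRows)
  if (noiseSd > 0) {
    .maybeSeed(seed)
    ct$ct <- ct$ct + rnorm(nrow(ct), 0, noiseSd)
  }
  rownames(ct) <- NULL
  ct
}
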