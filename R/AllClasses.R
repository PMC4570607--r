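#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats dnorm quantile sd var setNames rnorm runif t.test
#'   kmeans cov ave addmargins bw.nrd0 bw.nrd bw.ucv bw.SJ
#' @importFrom utils read.csv write.csv head
NULL

.ISOFORMS <- c("Ea", "Eb", "Ec")
.ASSAYS <- c("Ea", "Eb", "Ec", "PAN")
.FAMILIES <- c("EII", "VII", "EEE", "VVV", "EEV")

#' TissuePanel: tissue x isoform x replicate measurements
#'
#' An S4 container for a panel of quantitative real-time PCR measurements,
#' extending [SummarizedExperiment::SummarizedExperiment]. Rows are isoforms
#' (`Ea`, `Eb`, `Ec`, optionally `PAN`), columns are tissue-replicate units
#' with `tissue` and `replicate` columns in `colData`. The panel carries a
#' `valueType` flag (`"quantity"` for relative expression quantities,
#' `"ratio"` for compositional ratios). For ratio panels the three isoform
#' values of every unit must sum to one; values slightly outside \[0, 1\]
#' are tolerated because the Gaussian generative models used for simulation
#' have unbounded support.
#'
#' @seealso [tissuePanel()], [panelFromLong()], [asRatioPanel()]
#' @exportClass TissuePanel
setClass("TissuePanel", contains = "SummarizedExperiment")

setValidity("TissuePanel", function(object) {
  vt <- S4Vectors::metadata(object)$valueType
  msg <- character()
  if (is.null(vt) || !vt %in% c("quantity", "ratio"))
    msg <- c(msg, "metadata 'valueType' must be 'quantity' or 'ratio'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("tissue", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'tissue' and 'replicate'")
  if (!all(rownames(object) %in% .ASSAYS))
    msg <- c(msg, "rownames must be isoforms among Ea, Eb, Ec, PAN")
  if (length(msg) == 0 && anyDuplicated(paste(cd$tissue, cd$replicate)))
    msg <- c(msg, "duplicated (tissue, replicate) units")
  if (length(msg) == 0 && identical(vt, "ratio")) {
    v <- SummarizedExperiment::assay(object)
    if (!all(.ISOFORMS %in% rownames(v))) {
      msg <- c(msg, "ratio panels must contain rows Ea, Eb, Ec")
    } else {
      s <- colSums(v[.ISOFORMS, , drop = FALSE])
      if (any(abs(s - 1) > 1e-6))
        msg <- c(msg, "ratios must sum to 1 per (tissue, replicate) unit")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture parameters
#'
#' Parameters of a finite mixture of bivariate Gaussian densities: mixing
#' proportions `pi` on the simplex, a 2 x G matrix of component means `mu`
#' (rows are the two modelled compositional ratios), a list of G symmetric
#' positive semi-definite 2 x 2 covariance matrices `Sigma`, and the
#' covariance `family` constraint used (or to be used) in fitting, one of
#' EII, VII, EEE, VVV, EEV in the scale/shape/orientation nomenclature.
#'
#' @exportClass GaussianMixtureParams
setClass("GaussianMixtureParams", representation(
  G = "integer", pi = "numeric", mu = "matrix", Sigma = "list",
  family = "character"))

.checkPsd <- function(S, label) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    return(sprintf("%s must be symmetric", label))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    return(sprintf("%s must be positive semi-definite", label))
  NULL
}

setValidity("GaussianMixtureParams", function(object) {
  msg <- character()
  G <- object@G
  if (length(object@pi) != G || any(object@pi < 0) ||
      abs(sum(object@pi) - 1) > 1e-8)
    msg <- c(msg, "pi must be a nonnegative G-vector summing to 1")
  if (!all(dim(object@mu) == c(2L, G)))
    msg <- c(msg, "mu must be a 2 x G matrix")
  if (length(object@Sigma) != G) {
    msg <- c(msg, "Sigma must be a list of G matrices")
  } else {
    for (g in seq_len(G)) {
      bad <- .checkPsd(object@Sigma[[g]], sprintf("Sigma[[%d]]", g))
      if (!is.null(bad)) msg <- c(msg, bad)
    }
  }
  if (!object@family %in% .FAMILIES)
    msg <- c(msg, paste("family must be one of", paste(.FAMILIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Linear mixed model mixture parameters
#'
#' Parameters of a finite mixture of linear mixed models for replicated
#' bivariate compositional measurements: mixing proportions `pi`, a 2 x G
#' matrix of fixed effects `alpha` (component-level means of the two
#' ratios), a list of G symmetric PSD 2 x 2 random-effect covariance
#' matrices `Phi` (non-diagonal allowed: the two ratios of one tissue may
#' be correlated), and a 2 x G matrix `sigma2` of per-variant measurement
#' error variances. The implied within-component marginal covariance of a
#' tissue's stacked replicate vector is `V Phi V' + diag(V sigma2)`.
#'
#' @exportClass LmmMixtureParams
setClass("LmmMixtureParams", representation(
  G = "integer", pi = "numeric", alpha = "matrix", Phi = "list",
  sigma2 = "matrix"))

setValidity("LmmMixtureParams", function(object) {
  msg <- character()
  G <- object@G
  if (length(object@pi) != G || any(object@pi < 0) ||
      abs(sum(object@pi) - 1) > 1e-8)
    msg <- c(msg, "pi must be a nonnegative G-vector summing to 1")
  if (!all(dim(object@alpha) == c(2L, G)))
    msg <- c(msg, "alpha must be a 2 x G matrix")
  if (length(object@Phi) != G) {
    msg <- c(msg, "Phi must be a list of G matrices")
  } else {
    for (g in seq_len(G)) {
      bad <- .checkPsd(object@Phi[[g]], sprintf("Phi[[%d]]", g))
      if (!is.null(bad)) msg <- c(msg, bad)
    }
  }
  if (!all(dim(object@sigma2) == c(2L, G)) || any(object@sigma2 < 0))
    msg <- c(msg, "sigma2 must be a nonnegative 2 x G matrix")
  if (length(msg)) msg else TRUE
})

#' Fitted finite mixture model (pooled replicates)
#'
#' Result of [fmmFit()] / [fmmSelect()]: estimated
#' [GaussianMixtureParams-class], posterior membership weights of every
#' pooled tissue-replicate unit, the log-likelihood trace, BIC, and (after
#' model selection) the full score table over (G, family) candidates.
#'
#' @exportClass FmmFit
setClass("FmmFit", representation(
  params = "GaussianMixtureParams", weights = "matrix", loglik = "numeric",
  trace = "numeric", bic = "numeric", n = "integer",
  tissue = "character", replicate = "character", selection = "data.frame"))

#' Fitted finite mixture of linear mixed models
#'
#' Result of [fmlmmFit()] / [fmlmmSelect()]: estimated
#' [LmmMixtureParams-class], per-tissue posterior weights, marginal
#' log-likelihood trace, BIC, random-effect predictions (one 2-vector per
#' tissue and component), and the model-selection score table.
#'
#' @exportClass FmlmmFit
setClass("FmlmmFit", representation(
  params = "LmmMixtureParams", weights = "matrix", loglik = "numeric",
  trace = "numeric", bic = "numeric", nTissues = "integer",
  tissue = "character", blup = "list", selection = "data.frame"))
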