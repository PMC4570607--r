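#' Construct Gaussian mixture parameters
#'
#' @param pi mixing proportions (length G, nonnegative, summing to 1).
#' @param mu 2 x G matrix of component means, or a list of 2-vectors.
#' @param Sigma list of G symmetric PSD 2 x 2 covariance matrices (a single
#'   matrix is recycled).
#' @param family covariance family label, one of `EII`, `VII`, `EEE`,
#'   `VVV`, `EEV`.
#' @return A [GaussianMixtureParams-class].
#' @export
fmmParams <- function(pi, mu, Sigma, family = "VVV") {
  G <- length(pi)
  if (is.list(mu)) mu <- do.call(cbind, mu)
  mu <- matrix(as.numeric(mu), nrow = 2)
  if (is.matrix(Sigma)) Sigma <- rep(list(Sigma), G)
  Sigma <- lapply(Sigma, function(S) {
    S <- matrix(as.numeric(S), 2, 2); (S + t(S)) / 2
  })
  methods::new("GaussianMixtureParams", G = as.integer(G),
               pi = as.numeric(pi), mu = mu, Sigma = Sigma,
               family = as.character(family))
}

#' Construct linear mixed model mixture parameters
#'
#' @param pi mixing proportions (length G).
#' @param alpha 2 x G matrix of fixed effects, or a list of 2-vectors.
#' @param Phi list of G symmetric PSD 2 x 2 random-effect covariance
#'   matrices (a single matrix is recycled).
#' @param sigma2 2 x G matrix of per-variant measurement error variances,
#'   or a list of 2-vectors.
#' @return A [LmmMixtureParams-class].
#' @export
fmlmmParams <- function(pi, alpha, Phi, sigma2) {
  G <- length(pi)
  if (is.list(alpha)) alpha <- do.call(cbind, alpha)
  alpha <- matrix(as.numeric(alpha), nrow = 2)
  if (is.matrix(Phi)) Phi <- rep(list(Phi), G)
  Phi <- lapply(Phi, function(S) {
    S <- matrix(as.numeric(S), 2, 2); (S + t(S)) / 2
  })
  if (is.list(sigma2)) sigma2 <- do.call(cbind, sigma2)
  sigma2 <- matrix(as.numeric(sigma2), nrow = 2)
  methods::new("LmmMixtureParams", G = as.integer(G), pi = as.numeric(pi),
               alpha = alpha, Phi = Phi, sigma2 = sigma2)
}

#' Published IGF-1 mixture estimates
#'
#' Component parameter estimates obtained on a 20-tissue human panel of
#' IGF-1 splice-variant compositional ratios (Ratio1 = Ea, Ratio2 = Eb).
#' `igf1FmmParams()` returns the three-component EEV Gaussian mixture
#' estimated on pooled technical replicates; `igf1FmlmmParams()` the
#' three-component mixture of linear mixed models (fixed effects,
#' tissue-level random-effect covariances and per-variant measurement
#' variances). These sets serve as realistic default generators for
#' simulation studies: they feature means on the unit simplex, strongly
#' negatively correlated near-singular component covariances and small
#' measurement variances.
#'
#' @return A [GaussianMixtureParams-class] or [LmmMixtureParams-class].
#' @examples
#' p <- igf1FmmParams()
#' mixingProportions(p)
#' @export
igf1FmmParams <- function() {
  fmmParams(
    pi = c(0.68322399, 0.22616579, 0.09061023),
    mu = cbind(c(0.8420, 0.1468), c(0.8443, 0.1166), c(0.6772, 0.2992)),
    Sigma = list(
      matrix(c(0.0016, -0.0014, -0.0014, 0.0013), 2, 2),
      matrix(c(0.0023, -0.0011, -0.0011, 0.0006), 2, 2),
      matrix(c(0.0011, -0.0014, -0.0014, 0.0018), 2, 2)),
    family = "EEV")
}

#' @rdname igf1FmmParams
#' @export
igf1FmlmmParams <- function() {
  fmlmmParams(
    pi = c(0.3229, 0.5772, 0.0999),
    alpha = cbind(c(0.8171, 0.1546), c(0.8629, 0.1262), c(0.6742, 0.3033)),
    Phi = list(
      matrix(c(0.00006, -0.00008, -0.00008, 0.00016), 2, 2),
      matrix(c(0.00182, -0.00176, -0.00176, 0.00171), 2, 2),
      matrix(c(0.00021, -0.00028, -0.00028, 0.00038), 2, 2)),
    sigma2 = cbind(c(0.00059, 0.00046), c(0.00014, 0.00014),
                   c(0.00010, 0.00014)))
}

#' Published IGF-1 tissue allocations
#'
#' The maximum a posteriori allocations reported for the 20-tissue human
#' IGF-1 panel. `igf1FmmAllocation()` gives, per tissue, the number of
#' technical replicates the pooled-replicate Gaussian mixture assigned to
#' each of its three components together with the tissue-average normalized
#' entropy; `igf1FmlmmAllocation()` gives the single component per tissue
#' chosen by the mixture of linear mixed models and its entropy. These
#' tables support worked examples such as cross-method confusion matrices.
#'
#' @return A data frame.
#' @examples
#' table(igf1FmlmmAllocation()$component)
#' @export
igf1FmmAllocation <- function() {
  x <- data.frame(
    tissue = c("Brain A", "Brain B", "Brain C", "Fetal heart",
               "Fetal kidney", "Fetal lung", "Fetal sk. muscle",
               "Fetal spleen", "Fetal thymus", "Heart A", "Heart B",
               "Kidney", "Liver A", "Liver B", "Lung", "Pancreas",
               "Placenta", "Sk. muscle A", "Sk. muscle B", "Uterus"),
    n1 = c(3, 3, 2, 2, 3, 3, 3, 3, 3, 3, 0, 2, 0, 0, 2, 0, 3, 3, 2, 0),
    n2 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 3, 0, 0, 0, 0, 1, 3),
    n3 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3, 0, 0, 0, 0, 2, 0, 0, 0, 0),
    entropy = c(0.0204, 0.3287, 0.1691, 0.0000, 0.1690, 0.0000, 0.0000,
                0.0199, 0.0150, 0.0000, 0.0067, 0.0000, 0.0008, 0.0005,
                0.0000, 0.0001, 0.0000, 0.0010, 0.1928, 0.0035),
    stringsAsFactors = FALSE)
  x$component <- max.col(as.matrix(x[, c("n1", "n2", "n3")]),
                         ties.method = "first")
  x
}

#' @rdname igf1FmmAllocation
#' @export
igf1FmlmmAllocation <- function() {
  data.frame(
    tissue = c("Brain A", "Brain B", "Brain C", "Fetal heart",
               "Fetal kidney", "Fetal lung", "Fetal sk. muscle",
               "Fetal spleen", "Fetal thymus", "Heart A", "Heart B",
               "Kidney", "Liver A", "Liver B", "Lung", "Pancreas",
               "Placenta", "Sk. muscle A", "Sk. muscle B", "Uterus"),
    component = c(2, 2, 2, 1, 2, 2, 1, 2, 1, 2, 3, 2, 1, 1, 2, 3, 1, 2,
                  2, 2),
    entropy = c(0.0000, 0.0000, 0.0000, 0.0000, 0.0000, 0.6804, 0.1189,
                0.0097, 0.0000, 0.0000, 0.0102, 0.1573, 0.0041, 0.0002,
                0.1039, 0.0000, 0.0311, 0.0501, 0.0001, 0.0001),
    stringsAsFactors = FALSE)
}

#' @rdname mixingProportions
setMethod("mixingProportions", "GaussianMixtureParams", function(object) object@pi)
#' @rdname mixingProportions
setMethod("mixingProportions", "LmmMixtureParams", function(object) object@pi)
#' @rdname mixingProportions
setMethod("componentMeans", "GaussianMixtureParams", function(object) object@mu)
#' @rdname mixingProportions
setMethod("componentMeans", "LmmMixtureParams", function(object) object@alpha)
#' @rdname mixingProportions
setMethod("componentCovariances", "GaussianMixtureParams", function(object) object@Sigma)
#' @rdname mixingProportions
setMethod("componentCovariances", "LmmMixtureParams", function(object) object@Phi)
#' @rdname mixingProportions
setMethod("nComponents", "GaussianMixtureParams", function(object) object@G)
#' @rdname mixingProportions
setMethod("nComponents", "LmmMixtureParams", function(object) object@G)

#' @rdname errorVariances
setMethod("errorVariances", "LmmMixtureParams", function(object) object@sigma2)

setMethod("show", "GaussianMixtureParams", function(object) {
  cat(sprintf("GaussianMixtureParams: G = %d, family = %s\n",
              object@G, object@family))
  cat("  pi:", paste(signif(object@pi, 4), collapse = ", "), "\n")
  cat("  mu (Ratio1):", paste(signif(object@mu[1, ], 4), collapse = ", "), "\n")
  cat("  mu (Ratio2):", paste(signif(object@mu[2, ], 4), collapse = ", "), "\n")
})

setMethod("show", "LmmMixtureParams", function(object) {
  cat(sprintf("LmmMixtureParams: G = %d\n", object@G))
  cat("  pi:", paste(signif(object@pi, 4), collapse = ", "), "\n")
  cat("  alpha (Ratio1):", paste(signif(object@alpha[1, ], 4), collapse = ", "), "\n")
  cat("  alpha (Ratio2):", paste(signif(object@alpha[2, ], 4), collapse = ", "), "\n")
})
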