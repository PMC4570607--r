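#' Accessors for mixture parameter objects
#'
#' @param object a [GaussianMixtureParams-class], [LmmMixtureParams-class],
#'   [FmmFit-class] or [FmlmmFit-class].
#' @return `mixingProportions`: numeric vector; `componentMeans`: 2 x G
#'   matrix (FMM means or FMLMM fixed effects); `componentCovariances`:
#'   list of 2 x 2 matrices; `nComponents`: integer.
#' @export
setGeneric("mixingProportions", function(object) standardGeneric("mixingProportions"))

#' @rdname mixingProportions
#' @export
setGeneric("componentMeans", function(object) standardGeneric("componentMeans"))

#' @rdname mixingProportions
#' @export
setGeneric("componentCovariances", function(object) standardGeneric("componentCovariances"))

#' @rdname mixingProportions
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' Measurement error variances of an LMM mixture
#' @param object a [LmmMixtureParams-class] or [FmlmmFit-class].
#' @return 2 x G matrix of per-variant variances.
#' @export
setGeneric("errorVariances", function(object) standardGeneric("errorVariances"))

#' Posterior membership weights of a fit
#' @param object an [FmmFit-class] or [FmlmmFit-class].
#' @return matrix of unit x component posterior probabilities.
#' @export
setGeneric("posteriorWeights", function(object) standardGeneric("posteriorWeights"))

#' Model-selection score table of a fit
#' @param object an [FmmFit-class] or [FmlmmFit-class] returned by a
#'   select function.
#' @return data frame of candidates with log-likelihood, df and BIC.
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))

#' Allocation table of a fitted mixture
#' @param object an [FmmFit-class] (unit = tissue replicate) or
#'   [FmlmmFit-class] (unit = tissue).
#' @return an `AllocationTable` (see [mapAllocate()]).
#' @export
setGeneric("allocationTable", function(object) standardGeneric("allocationTable"))
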