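#' Comparative CT relative quantity
#'
#' Relative quantification of a target transcript by the comparative CT
#' method: `2^-ddCT` with
#' `ddCT = (ct_target - ct_reference) - (ct_target_calibrator - ct_reference_calibrator)`.
#' All arguments are threshold-cycle values in cycles; the result is a
#' dimensionless quantity relative to the calibrator sample (which maps to
#' 1 by construction). Vectorized over all arguments.
#'
#' @param ctTarget,ctReference target and reference-gene CT in the sample.
#' @param ctTargetCalibrator,ctReferenceCalibrator the same two CTs in the
#'   calibrator sample.
#' @return numeric relative quantity.
#' @examples
#' comparativeCt(21, 20, 21, 20)  # the calibrator itself: 1
#' comparativeCt(22, 20, 21, 20)  # one extra cycle: 0.5
#' @export
comparativeCt <- function(ctTarget, ctReference, ctTargetCalibrator,
                          ctReferenceCalibrator) {
  ddct <- (ctTarget - ctReference) - (ctTargetCalibrator - ctReferenceCalibrator)
  if (any(!is.finite(ddct))) stop("CT values must be finite")
  2^(-ddct)
}

#' Compositional ratios of three isoform quantities
#'
#' Equalizes isoform quantities into compositional ratios
#' `ratio_k = q_k / (q_Ea + q_Eb + q_Ec)`, so the three ratios sum to one
#' (the unit constraint) and are invariant to the per-sample scale of the
#' quantities. Vectorized.
#'
#' @param ea,eb,ec nonnegative quantities of the three isoforms.
#' @return matrix with columns `ratio1`, `ratio2`, `ratio3`.
#' @examples
#' compositionalRatios(2, 1, 1)
#' @export
compositionalRatios <- function(ea, eb, ec) {
  if (any(ea < 0 | eb < 0 | ec < 0)) stop("quantities must be nonnegative")
  s <- ea + eb + ec
  if (any(s <= 0)) stop("quantities must not be all zero")
  cbind(ratio1 = ea / s, ratio2 = eb / s, ratio3 = ec / s)
}

#' PAN-consistency check
#'
#' Tests whether the total IGF-1 signal measured by a PAN assay (detecting
#' all isoforms simultaneously) agrees with the sum of the three
#' isoform-specific quantities, i.e. the null hypothesis
#' `[PAN] = [Ea] + [Eb] + [Ec]`. Implemented as a paired two-sided t-test
#' of `log(PAN)` against `log(Ea + Eb + Ec)` across all tissue-replicate
#' units; the log scale reflects the multiplicative error structure of
#' qPCR quantities. The exact test behind the published claim is not
#' specified, so this is a documented stand-in with the same null.
#'
#' @param panel a quantity [TissuePanel-class] containing a `PAN` row.
#' @param alpha significance level for the reported decision.
#' @return list with `statistic`, `p.value`, `consistent` (TRUE when the
#'   null is not rejected at `alpha`), and `n` (number of paired units).
#' @export
panConsistencyTest <- function(panel, alpha = 0.05) {
  v <- panelValues(panel)
  if (!all(c(.ISOFORMS, "PAN") %in% rownames(v)))
    stop("panel must contain PAN and all three isoform quantities")
  if (!identical(valueType(panel), "quantity"))
    stop("PAN consistency is a test on quantities, not ratios")
  pan <- v["PAN", ]
  tot <- colSums(v[.ISOFORMS, , drop = FALSE])
  if (any(pan <= 0) || any(tot <= 0)) stop("quantities must be positive")
  d <- log(pan) - log(tot)
  if (length(d) < 2) stop("need at least two paired units")
  if (sd(d) < 1e-12) {
    # constant log difference: either exact agreement (no evidence against
    # the null) or a systematic offset (certain rejection)
    out <- if (abs(mean(d)) < 1e-9) list(statistic = 0, p.value = 1) else
      list(statistic = sign(mean(d)) * Inf, p.value = 0)
  } else {
    tt <- t.test(d)
    out <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  out$consistent <- out$p.value >= alpha
  out$n <- length(d)
  out
}

#' Six-number summary
#'
#' Minimum, first quartile, median, mean, third quartile and maximum, with
#' quartiles computed by linear interpolation between order statistics
#' (type-7 quantiles).
#'
#' @param values nonempty numeric vector.
#' @return named numeric vector of length 6.
#' @examples
#' summaryStats(c(1, 2, 3, 4, 5))
#' @export
summaryStats <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) stop("nonempty numeric input required")
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], mean = mean(values), q3 = q[4],
    max = q[5])
}

#' Comparative-CT processing of a raw CT table
#'
#' Turns an instrument-style CT table (columns `tissue_id`,
#' `replicate_id`, `assay`, `ct`) into a quantity [TissuePanel-class] by
#' the comparative CT method: for every unit and target assay, the quantity
#' is `2^-ddCT` relative to the named calibrator sample, using the
#' reference-gene CT measured in the same unit. The calibrator's CTs are
#' averaged across its replicates and the calibrator sample itself is
#' excluded from the returned panel.
#'
#' @param ct data frame of CT records.
#' @param calibrator tissue_id of the calibrator sample.
#' @param referenceAssay assay name of the reference (housekeeping) gene.
#' @return A quantity [TissuePanel-class].
#' @export
ctToPanel <- function(ct, calibrator, referenceAssay = "reference") {
  need <- c("tissue_id", "replicate_id", "assay", "ct")
  if (!all(need %in% colnames(ct)))
    stop("CT table must have columns ", paste(need, collapse = ", "))
  if (!calibrator %in% ct$tissue_id)
    stop("calibrator tissue not present: ", calibrator)
  if (!referenceAssay %in% ct$assay)
    stop("reference assay not present: ", referenceAssay)
  cal <- ct[ct$tissue_id == calibrator, ]
  calCt <- tapply(cal$ct, cal$assay, mean)
  if (!referenceAssay %in% names(calCt))
    stop("calibrator lacks the reference assay")
  targets <- setdiff(unique(as.character(ct$assay)), referenceAssay)
  smp <- ct[ct$tissue_id != calibrator, ]
  unit <- paste(smp$tissue_id, smp$replicate_id, sep = ":")
  refCt <- setNames(smp$ct[smp$assay == referenceAssay],
                    unit[smp$assay == referenceAssay])
  rows <- lapply(targets, function(a) {
    sel <- smp$assay == a
    u <- unit[sel]
    if (anyNA(refCt[u])) stop("reference assay missing for some units")
    q <- comparativeCt(smp$ct[sel], refCt[u], calCt[[a]],
                       calCt[[referenceAssay]])
    data.frame(tissue_id = smp$tissue_id[sel],
               replicate_id = smp$replicate_id[sel],
               isoform = a, value = q, stringsAsFactors = FALSE)
  })
  panelFromLong(do.call(rbind, rows), valueType = "quantity")
}
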