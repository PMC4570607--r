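#' Cross-method confusion matrix
#'
#' Tabulates two clusterings of the same tissues against each other: cell
#' (g, g') counts the tissues labelled g by the first method and g' by the
#' second, with row and column margins appended. Used to compare, e.g.,
#' the pooled-replicate Gaussian mixture allocation (rows) against the
#' mixture of linear mixed models allocation (columns).
#'
#' @param labelsA,labelsB integer (or factor) labels named by tissue, or
#'   data frames with columns `tissue` and `label`/`component`.
#' @param methodA,methodB display names of the two methods.
#' @return list of class `ConfusionMatrix` with the counts matrix
#'   (including margins), the raw cell matrix, and the method names.
#' @examples
#' a <- setNames(c(1, 1, 2), c("t1", "t2", "t3"))
#' confusionMatrix(a, a)
#' @export
confusionMatrix <- function(labelsA, labelsB, methodA = "A", methodB = "B") {
  toNamed <- function(x) {
    if (is.data.frame(x)) {
      lab <- if ("label" %in% colnames(x)) x$label else x$component
      setNames(lab, x$tissue)
    } else x
  }
  a <- toNamed(labelsA)
  b <- toNamed(labelsB)
  if (is.null(names(a)) || is.null(names(b)))
    stop("labels must be named by tissue")
  if (!setequal(names(a), names(b))) {
    d <- union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("tissue sets differ: ", paste(d, collapse = ", "))
  }
  b <- b[names(a)]
  lev <- function(x) sort(unique(as.integer(x)))
  tab <- table(factor(as.integer(a), levels = lev(a)),
               factor(as.integer(b), levels = lev(b)))
  m <- stats::addmargins(tab)
  dimnames(m) <- list(
    setNames(dimnames(m)[[1]], NULL),
    setNames(dimnames(m)[[2]], NULL))
  names(dimnames(m)) <- c(methodA, methodB)
  out <- list(table = m, counts = unclass(tab), methodA = methodA,
              methodB = methodB)
  class(out) <- "ConfusionMatrix"
  out
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: %s (rows) vs %s (columns)\n", x$methodA,
              x$methodB))
  print(x$table)
  invisible(x)
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

#' Align component labels between two fits
#'
#' Component indices of independently fitted mixtures are arbitrary; this
#' finds the label permutation of the second parameter set that minimizes
#' the total Euclidean distance between matched component means
#' (exhaustive over the G! permutations, intended for G <= 5).
#'
#' @param muA,muB 2 x G matrices of component means, or objects with a
#'   [componentMeans()] method.
#' @return integer permutation `p` such that component g of the first set
#'   matches component `p[g]` of the second.
#' @export
alignComponents <- function(muA, muB) {
  if (!is.matrix(muA)) muA <- componentMeans(muA)
  if (!is.matrix(muB)) muB <- componentMeans(muB)
  G <- ncol(muA)
  if (ncol(muB) != G) stop("component counts differ")
  best <- NULL
  bestCost <- Inf
  for (p in .permutations(G)) {
    cost <- sum(sqrt(colSums((muA - muB[, p, drop = FALSE])^2)))
    if (cost < bestCost) { bestCost <- cost; best <- p }
  }
  as.integer(best)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> equalize -> kernel density ->
#' pooled-replicate mixture -> mixture of linear mixed models -> compare,
#' writing every artifact as CSV/JSON under `outDir`: the long-format
#' panel, per-ratio density estimates, both model fits (parameters, score
#' tables, allocations) and the cross-method confusion matrix, plus a
#' run log with seeds and timings. Runs are reproducible bit-for-bit
#' given the same config and seed.
#'
#' @param config list with elements: `outDir` (required); either `panel`
#'   (a ratio [TissuePanel-class]) or `simulate = list(params, nTissues,
#'   nReplicates)`; `seed`; `kdeRules` (bandwidth rules, default
#'   silverman); `fmmGs`, `fmmFamilies`, `fmlmmGs`; `nStarts`.
#' @return invisible list with the fitted objects and written file paths.
#' @export
runPipeline <- function(config) {
  if (is.null(config$outDir)) stop("config$outDir is required")
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  t0 <- Sys.time()
  log <- c(sprintf("splicemix pipeline, seed %d", seed),
           sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")))
  stage <- function(msg) {
    log <<- c(log, sprintf("[%.2fs] %s",
                           as.numeric(difftime(Sys.time(), t0, units = "secs")),
                           msg))
    message(msg)
  }
  if (!is.null(config$panel)) {
    panel <- config$panel
    trueLabel <- NULL
    stage("using supplied panel")
  } else {
    sim <- config$simulate
    if (is.null(sim)) sim <- list()
    params <- if (is.null(sim$params)) igf1FmlmmParams() else sim$params
    nT <- if (is.null(sim$nTissues)) 20L else sim$nTissues
    R <- if (is.null(sim$nReplicates)) 3L else sim$nReplicates
    s <- simulateFmlmmPanel(params, nT, R)
    panel <- s$panel
    trueLabel <- s$label
    stage(sprintf("simulated panel: %d tissues x %d replicates", nT, R))
  }
  panel <- asRatioPanel(panel)
  paths <- list(panel = file.path(outDir, "panel.csv"))
  writePanelCsv(panel, paths$panel)
  if (!is.null(trueLabel)) {
    paths$labels <- file.path(outDir, "true_labels.csv")
    write.csv(data.frame(tissue_id = names(trueLabel),
                         true_component = as.integer(trueLabel)),
              paths$labels, row.names = FALSE)
  }
  rules <- if (is.null(config$kdeRules)) "silverman" else config$kdeRules
  v <- panelValues(panel)
  for (iso in .ISOFORMS) {
    for (rule in rules) {
      d <- kdeEvaluate(v[iso, ], h = rule)
      p <- file.path(outDir, sprintf("density_%s_%s.csv", iso, rule))
      write.csv(data.frame(x = signif(d$x, 6), density = signif(d$density, 6)),
                p, row.names = FALSE)
      paths[[sprintf("density_%s_%s", iso, rule)]] <- p
    }
  }
  stage("kernel density estimates written")
  nStarts <- if (is.null(config$nStarts)) 10L else config$nStarts
  fmmGs <- if (is.null(config$fmmGs)) 1:4 else config$fmmGs
  fams <- if (is.null(config$fmmFamilies)) "EEV" else config$fmmFamilies
  pts <- ratioPoints(panel)
  fmm <- fmmSelect(pts, Gs = fmmGs, families = fams, nStarts = nStarts)
  stage(sprintf("FMM selected G = %d (%s)", nComponents(fmm),
                fmm@params@family))
  paths$fmmBic <- file.path(outDir, "fmm_bic.csv")
  write.csv(selectionTable(fmm), paths$fmmBic, row.names = FALSE)
  alloc <- allocationTable(fmm)
  paths$fmmAlloc <- file.path(outDir, "fmm_allocation.csv")
  write.csv(cbind(alloc$units[, c("tissue", "replicate", "label")],
                  entropy = signif(alloc$units$entropy, 6)),
            paths$fmmAlloc, row.names = FALSE)
  paths$fmmTissue <- file.path(outDir, "fmm_tissue_summary.csv")
  write.csv(cbind(alloc$tissues[, setdiff(colnames(alloc$tissues), "entropy")],
                  entropy = signif(alloc$tissues$entropy, 6)),
            paths$fmmTissue, row.names = FALSE)
  paths$fmmParams <- file.path(outDir, "fmm_params.json")
  jsonlite::write_json(list(
    G = nComponents(fmm), family = fmm@params@family,
    pi = mixingProportions(fmm), mu = componentMeans(fmm),
    Sigma = componentCovariances(fmm), loglik = fmm@loglik, bic = fmm@bic),
    paths$fmmParams, digits = NA, auto_unbox = TRUE)
  fmlmmGs <- if (is.null(config$fmlmmGs)) c(2, 3) else config$fmlmmGs
  fml <- fmlmmSelect(panel, Gs = fmlmmGs, nStarts = nStarts)
  stage(sprintf("FMLMM selected G = %d", nComponents(fml)))
  paths$fmlmmBic <- file.path(outDir, "fmlmm_bic.csv")
  write.csv(selectionTable(fml), paths$fmlmmBic, row.names = FALSE)
  allocL <- allocationTable(fml)
  paths$fmlmmAlloc <- file.path(outDir, "fmlmm_allocation.csv")
  write.csv(cbind(allocL$units[, c("tissue", "label")],
                  entropy = signif(allocL$units$entropy, 6)),
            paths$fmlmmAlloc, row.names = FALSE)
  paths$fmlmmParams <- file.path(outDir, "fmlmm_params.json")
  jsonlite::write_json(list(
    G = nComponents(fml), pi = mixingProportions(fml),
    alpha = componentMeans(fml), Phi = componentCovariances(fml),
    sigma2 = errorVariances(fml), loglik = fml@loglik, bic = fml@bic),
    paths$fmlmmParams, digits = NA, auto_unbox = TRUE)
  paths$blup <- file.path(outDir, "fmlmm_blup.csv")
  blupDf <- do.call(rbind, lapply(seq_len(nComponents(fml)), function(g) {
    data.frame(tissue = fml@tissue, component = g,
               u1 = signif(fml@blup[[g]][, 1], 6),
               u2 = signif(fml@blup[[g]][, 2], 6))
  }))
  write.csv(blupDf, paths$blup, row.names = FALSE)
  fmmLab <- setNames(alloc$tissues$label, alloc$tissues$tissue)
  fmlLab <- setNames(allocL$units$label, allocL$units$tissue)
  cm <- confusionMatrix(fmmLab, fmlLab, "FMM", "FMLMM")
  paths$confusion <- file.path(outDir, "confusion.csv")
  write.csv(as.data.frame.matrix(cm$table), paths$confusion)
  # the tissue-level FMM label above is the replicate majority; the
  # replicate-level split is also emitted so split tissues stay visible
  stage("confusion matrix written")
  log <- c(log, sprintf("done in %.2fs",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  paths$log <- file.path(outDir, "run_log.txt")
  writeLines(log, paths$log)
  invisible(list(panel = panel, fmm = fmm, fmlmm = fml, confusion = cm,
                 paths = paths, trueLabel = trueLabel))
}
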