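#' Construct a TissuePanel from a value matrix
#'
#' @param values numeric matrix, isoforms in rows (rownames among
#'   `Ea`, `Eb`, `Ec`, `PAN`), tissue-replicate units in columns.
#' @param tissue character vector of tissue identifiers, one per column.
#' @param replicate replicate identifiers (coerced to character), one per
#'   column.
#' @param valueType `"quantity"` or `"ratio"`.
#' @return A [TissuePanel-class].
#' @examples
#' v <- rbind(Ea = c(.8, .81), Eb = c(.15, .14), Ec = c(.05, .05))
#' tissuePanel(v, tissue = c("liver", "liver"), replicate = 1:2,
#'             valueType = "ratio")
#' @export
tissuePanel <- function(values, tissue, replicate, valueType = c("quantity", "ratio")) {
  valueType <- match.arg(valueType)
  values <- as.matrix(values)
  if (length(tissue) != ncol(values) || length(replicate) != ncol(values))
    stop("tissue and replicate must have one entry per column of 'values'")
  cd <- S4Vectors::DataFrame(tissue = as.character(tissue),
                             replicate = as.character(replicate))
  colnames(values) <- paste(cd$tissue, cd$replicate, sep = ":")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = values), colData = cd)
  S4Vectors::metadata(se)$valueType <- valueType
  methods::new("TissuePanel", se)
}

#' Build a TissuePanel from a long-format table
#'
#' @param df data frame with columns `tissue_id`, `replicate_id`,
#'   `isoform`, `value`.
#' @param valueType `"quantity"` or `"ratio"`.
#' @return A [TissuePanel-class].
#' @export
panelFromLong <- function(df, valueType = c("quantity", "ratio")) {
  valueType <- match.arg(valueType)
  need <- c("tissue_id", "replicate_id", "isoform", "value")
  if (!all(need %in% colnames(df)))
    stop("long table must have columns ", paste(need, collapse = ", "))
  unit <- paste(df$tissue_id, df$replicate_id, sep = ":")
  units <- unique(unit)
  isoforms <- intersect(.ASSAYS, unique(as.character(df$isoform)))
  m <- matrix(NA_real_, length(isoforms), length(units),
              dimnames = list(isoforms, units))
  m[cbind(as.character(df$isoform), unit)] <- df$value
  if (anyNA(m)) stop("incomplete panel: every unit needs every isoform")
  first <- !duplicated(unit)
  tissuePanel(m, tissue = df$tissue_id[first],
              replicate = df$replicate_id[first], valueType = valueType)
}

#' Export a TissuePanel to a long-format data frame
#' @param panel a [TissuePanel-class].
#' @return data frame with columns `tissue_id`, `replicate_id`, `isoform`,
#'   `value`.
#' @export
panelToLong <- function(panel) {
  v <- SummarizedExperiment::assay(panel)
  cd <- SummarizedExperiment::colData(panel)
  data.frame(
    tissue_id = rep(cd$tissue, each = nrow(v)),
    replicate_id = rep(cd$replicate, each = nrow(v)),
    isoform = rep(rownames(v), ncol(v)),
    value = as.vector(v), stringsAsFactors = FALSE)
}

#' @rdname panelToLong
#' @param path file path for the long-format CSV.
#' @export
writePanelCsv <- function(panel, path) {
  write.csv(panelToLong(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname panelFromLong
#' @param path file path of a long-format CSV.
#' @export
readPanelCsv <- function(path, valueType = c("quantity", "ratio")) {
  panelFromLong(read.csv(path), match.arg(valueType))
}

#' Panel accessors
#'
#' `tissueIds` and `replicateIds` return the per-unit identifiers,
#' `valueType` the quantity/ratio flag, `panelValues` the isoform x unit
#' value matrix, and `nReplicates` the per-tissue replicate counts.
#'
#' @param panel a [TissuePanel-class].
#' @return character vectors, a matrix, or a named integer vector.
#' @export
tissueIds <- function(panel) SummarizedExperiment::colData(panel)$tissue

#' @rdname tissueIds
#' @export
replicateIds <- function(panel) SummarizedExperiment::colData(panel)$replicate

#' @rdname tissueIds
#' @export
valueType <- function(panel) S4Vectors::metadata(panel)$valueType

#' @rdname tissueIds
#' @export
panelValues <- function(panel) SummarizedExperiment::assay(panel)

#' @rdname tissueIds
#' @export
nReplicates <- function(panel) {
  t <- table(tissueIds(panel))
  setNames(as.integer(t), names(t))
}

#' Convert a quantity panel to compositional ratios
#'
#' Each (tissue, replicate) unit's isoform quantities are divided by their
#' sum, so the three ratios sum to one (the unit constraint); a `PAN` row,
#' if present, is dropped. Ratios are computed per replicate, not on
#' replicate means, because downstream mixture fitting pools replicates.
#'
#' @param panel a [TissuePanel-class] of quantities.
#' @return A [TissuePanel-class] with `valueType == "ratio"`.
#' @export
asRatioPanel <- function(panel) {
  if (identical(valueType(panel), "ratio")) return(panel)
  v <- panelValues(panel)
  if (!all(.ISOFORMS %in% rownames(v)))
    stop("quantity panel must contain rows Ea, Eb, Ec")
  q <- v[.ISOFORMS, , drop = FALSE]
  r <- compositionalRatios(q["Ea", ], q["Eb", ], q["Ec", ])
  m <- rbind(Ea = r[, 1], Eb = r[, 2], Ec = r[, 3])
  tissuePanel(m, tissueIds(panel), replicateIds(panel), valueType = "ratio")
}

#' Pooled bivariate ratio points
#'
#' Returns the (Ratio1, Ratio2) = (Ea, Eb) values of every tissue-replicate
#' unit as an n x 2 matrix, the pooled layout consumed by [fmmFit()]. Due
#' to the unit constraint the third ratio carries no extra information and
#' the mixture is fitted to the first two.
#'
#' @param panel a ratio [TissuePanel-class].
#' @param variants which two isoforms form the modelled couple.
#' @return numeric matrix with attributes `tissue` and `replicate`.
#' @export
ratioPoints <- function(panel, variants = c("Ea", "Eb")) {
  stopifnot(length(variants) == 2)
  if (!identical(valueType(panel), "ratio")) panel <- asRatioPanel(panel)
  v <- panelValues(panel)
  x <- t(v[variants, , drop = FALSE])
  attr(x, "tissue") <- tissueIds(panel)
  attr(x, "replicate") <- replicateIds(panel)
  x
}

#' Stacked per-tissue replicate vectors
#'
#' For each tissue the R replicate values of the first variant are stacked
#' above the R replicate values of the second, giving the 2R-vector on
#' which the mixture of linear mixed models operates.
#'
#' @param panel a ratio [TissuePanel-class].
#' @param variants which two isoforms form the modelled couple.
#' @return named list of numeric vectors (length 2R per tissue).
#' @export
tissueVectors <- function(panel, variants = c("Ea", "Eb")) {
  stopifnot(length(variants) == 2)
  if (!identical(valueType(panel), "ratio")) panel <- asRatioPanel(panel)
  v <- panelValues(panel)
  tis <- tissueIds(panel)
  lapply(split(seq_along(tis), factor(tis, levels = unique(tis))), function(j) {
    as.vector(t(v[variants, j, drop = FALSE]))
  })
}

#' Randomly mask third replicates
#'
#' Emulates the common situation where only duplicates instead of
#' triplicates are available for some tissues, by dropping the last
#' replicate of a random subset of tissues.
#'
#' @param panel a [TissuePanel-class] with 3 replicates per tissue.
#' @param rate fraction of tissues to reduce to duplicates.
#' @return A [TissuePanel-class].
#' @export
maskReplicates <- function(panel, rate = 0.1) {
  tis <- tissueIds(panel)
  rep_ <- replicateIds(panel)
  ids <- unique(tis)
  drop_t <- ids[runif(length(ids)) < rate]
  keep <- !(tis %in% drop_t & ave(seq_along(tis), tis, FUN = seq_along) ==
              ave(seq_along(tis), tis, FUN = length))
  tissuePanel(panelValues(panel)[, keep, drop = FALSE], tis[keep], rep_[keep],
              valueType = valueType(panel))
}

setMethod("show", "TissuePanel", function(object) {
  cat(sprintf("TissuePanel: %d tissues, %d units, %s values\n",
              length(unique(tissueIds(object))), ncol(object),
              valueType(object)))
  cat("  isoforms:", paste(rownames(object), collapse = ", "), "\n")
  r <- nReplicates(object)
  cat("  replicates per tissue:",
      paste(names(table(r)), "x", table(r), collapse = ", "), "\n")
})
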