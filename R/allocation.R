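#' Normalized Shannon entropy of posterior rows
#'
#' `-sum_g w_g log w_g / log G`, mapped to \[0, 1\]: 0 for a certain
#' allocation, 1 for a uniform posterior. Zero weights contribute zero; a
#' single-component model has entropy 0 by convention.
#'
#' @param weights a posterior weight vector or an n x G matrix of rows
#'   summing to one.
#' @return numeric entropy per row.
#' @examples
#' normalizedEntropy(c(0.99, 0.01))
#' normalizedEntropy(c(0.5, 0.5))
#' @export
normalizedEntropy <- function(weights) {
  w <- if (is.matrix(weights)) weights else matrix(weights, nrow = 1)
  G <- ncol(w)
  if (G == 1) return(rep(0, nrow(w)))
  wl <- w * log(w)
  wl[w <= 0] <- 0
  -rowSums(wl) / log(G)
}

#' MAP allocation with uncertainty
#'
#' Hard maximum a posteriori labels from a posterior weight matrix: each
#' unit goes to its highest-weight component (ties broken toward the
#' lowest index, with a message). When tissue identifiers are supplied, a
#' tissue-level summary is added: replicate counts per component, a
#' majority-vote tissue label (lowest index on ties) and the tissue
#' average of the per-replicate normalized entropy.
#'
#' @param weights n x G posterior matrix (rows sum to 1).
#' @param tissue optional tissue identifier per row.
#' @param replicate optional replicate identifier per row.
#' @return list of class `AllocationTable` with `units` (data frame:
#'   tissue, replicate, label, entropy) and, when tissues are known,
#'   `tissues` (data frame: tissue, per-component replicate counts,
#'   label, entropy).
#' @export
mapAllocate <- function(weights, tissue = NULL, replicate = NULL) {
  w <- as.matrix(weights)
  G <- ncol(w)
  lab <- max.col(w, ties.method = "first")
  nTies <- sum(abs(w[cbind(seq_len(nrow(w)), lab)] -
                     apply(w, 1, max)) < .Machine$double.eps &
                 rowSums(w == apply(w, 1, max)) > 1)
  if (nTies > 0)
    message(nTies, " tied MAP allocation(s) broken toward the lowest index")
  ent <- normalizedEntropy(w)
  units <- data.frame(
    tissue = if (is.null(tissue)) NA_character_ else as.character(tissue),
    replicate = if (is.null(replicate)) NA_character_ else
      as.character(replicate),
    label = lab, entropy = ent, stringsAsFactors = FALSE)
  out <- list(units = units, G = G)
  if (!is.null(tissue)) {
    tis <- factor(as.character(tissue), levels = unique(as.character(tissue)))
    counts <- t(vapply(split(lab, tis), function(l) {
      tabulate(l, nbins = G)
    }, integer(G)))
    colnames(counts) <- paste0("n", seq_len(G))
    maj <- max.col(counts, ties.method = "first")
    out$tissues <- data.frame(tissue = levels(tis), counts,
                              label = maj,
                              entropy = as.numeric(tapply(ent, tis, mean)),
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  class(out) <- "AllocationTable"
  out
}

#' @export
print.AllocationTable <- function(x, ...) {
  cat(sprintf("AllocationTable: %d units, G = %d\n", nrow(x$units), x$G))
  if (!is.null(x$tissues)) {
    cat(sprintf("  %d tissues (majority labels: %s)\n", nrow(x$tissues),
                paste(tabulate(x$tissues$label, x$G), collapse = "/")))
  }
  invisible(x)
}

#' @rdname allocationTable
setMethod("allocationTable", "FmmFit", function(object) {
  mapAllocate(object@weights,
              tissue = if (length(object@tissue)) object@tissue else NULL,
              replicate = if (length(object@replicate)) object@replicate
              else NULL)
})
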