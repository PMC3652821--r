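# Normalization and probe-to-gene summarization.

#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values are replaced by the row means of the column-sorted
#' matrix, so all columns share one multiset of values while within-column
#' ranks are preserved. Ties within a column receive the mean of the
#' reference values at their tied ranks. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Numeric matrix (features x samples), all finite, >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("'mat' must be a numeric matrix")
  if (ncol(mat) < 2) stopf("quantile normalization needs >= 2 samples")
  if (any(!is.finite(mat))) stopf("'mat' contains non-finite entries")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse probes to a gene-level matrix
#'
#' Maps each probe to its harmonized gene key (Entrez ID when present, else
#' MGI symbol; see [gene_key()]) and summarizes multi-probe genes:
#' `max_mean` keeps the probe with the highest mean intensity (ties broken
#' by lexicographically smallest probe ID), `mean` averages probes.
#' Probes with no gene mapping are dropped and counted.
#'
#' @param study An [expression_study()].
#' @param method `"max_mean"` (default) or `"mean"`.
#' @return Gene x sample matrix with harmonized keys as rownames. Attributes:
#'   `dropped_probes` (count of unmapped probes), `symbol` (named key ->
#'   display-symbol vector).
#' @export
collapse_probes <- function(study, method = c("max_mean", "mean")) {
  stopifnot(inherits(study, "expression_study"))
  method <- match.arg(method)
  keys <- gene_key(study$probe_map)
  key_of_row <- keys[rownames(study$exprs)]
  mapped <- !is.na(key_of_row)
  n_dropped <- sum(!mapped)
  if (!any(mapped)) stopf("no probe maps to a gene; nothing to collapse")
  if (n_dropped > 0)
    message(sprintf("collapse_probes: dropped %d unmapped probe(s)", n_dropped))
  m <- study$exprs[mapped, , drop = FALSE]
  key <- key_of_row[mapped]

  if (method == "max_mean") {
    pm <- rowMeans(m)
    # best probe per gene: highest mean, ties -> smallest probe ID
    ord <- order(key, -pm, rownames(m), method = "radix")
    keep <- !duplicated(key[ord])
    sel <- ord[keep]
    out <- m[sel, , drop = FALSE]
    rownames(out) <- key[sel]
  } else {
    out <- rowsum(m, group = key, reorder = TRUE)
    cnt <- as.vector(table(key)[rownames(out)])
    out <- out / cnt
  }
  out <- out[order(rownames(out), method = "radix"), , drop = FALSE]
  attr(out, "dropped_probes") <- n_dropped
  sym <- key_symbol_map(study$probe_map)
  attr(out, "symbol") <- sym[rownames(out)]
  out
}
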