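# Signature validation: gene-centered heatmap preparation, correlation-based
# sample clustering, and consensus clustering with feature subsampling
# against a random-signature null.

#' Center each gene to mean zero
#'
#' @param mat Gene x sample numeric matrix.
#' @return Matrix with every row mean exactly 0 (to 1e-12).
#' @export
center_genes <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 1) stopf("'mat' must be a matrix with >= 1 column")
  mat - rowMeans(mat)
}

#' Cluster samples on a gene set
#'
#' Agglomerative clustering of sample expression profiles at distance
#' `1 - Pearson correlation` (or Euclidean), average (or complete) linkage,
#' tree cut at `k` clusters. Deterministic for fixed input.
#'
#' @param mat Gene x sample matrix (already restricted to the gene set of
#'   interest).
#' @param k Number of clusters, `<= ncol(mat)`.
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return Integer cluster assignment named by sample.
#' @export
cluster_samples <- function(mat, k, distance = c("pearson", "euclidean"),
                            linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (k > ncol(mat)) stopf("k (%d) exceeds the number of samples (%d)", k, ncol(mat))
  if (distance == "pearson") {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0))
      stopf("zero-variance sample profile(s): %s (correlation undefined)",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(mat))
  } else {
    d <- stats::dist(t(mat))
  }
  stats::cutree(stats::hclust(d, method = linkage), k = k)
}

# 1 iff `part` equals `labels` up to cluster relabeling.
partitions_match <- function(part, labels) {
  ari <- mclust::adjustedRandIndex(part, as.character(labels))
  as.numeric(isTRUE(all.equal(ari, 1)))
}

#' Consensus clustering of samples by signature subsampling
#'
#' Each replicate draws `ceiling(frac * |signature|)` signature genes
#' without replacement, centers them, and clusters the samples at `k`. The
#' consensus matrix entry (i, j) is the fraction of replicates in which
#' samples i and j co-cluster (features are subsampled, so every sample pair
#' occurs in every replicate and the denominator is `reps`). A replicate is
#' accurate iff its partition equals the exposure labels up to relabeling
#' (adjusted Rand index 1); `signature_accuracy` is the mean over
#' replicates. `mean_within_consensus` / `mean_between_consensus` summarize
#' the consensus matrix over same-label / different-label sample pairs.
#'
#' @param expr Gene x sample matrix (gene-level, log2).
#' @param labels Exposure group label per sample.
#' @param signature Character vector of signature genes; at least 5 must be
#'   matrix rows.
#' @param frac Fraction of the signature per replicate (default 0.8).
#' @param reps Replicates (default 1000).
#' @param k Clusters; default = number of distinct labels.
#' @param seed RNG seed.
#' @param distance,linkage Passed to [cluster_samples()].
#' @return Object of class `consensus_result`: `consensus_matrix`,
#'   `partitions` (reps x samples), `signature_accuracy`,
#'   `mean_within_consensus`, `mean_between_consensus`, `config`.
#' @export
consensus_cluster <- function(expr, labels, signature, frac = 0.8,
                              reps = 1000, k = NULL, seed = NULL,
                              distance = "pearson", linkage = "average") {
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) stopf("one label per sample required")
  genes <- intersect(unique(signature), rownames(expr))
  if (length(genes) < 5)
    stopf("only %d signature genes found in the matrix; need >= 5", length(genes))
  k <- k %||% length(unique(labels))
  if (k > ncol(expr)) stopf("k (%d) exceeds the number of samples (%d)", k, ncol(expr))
  n_take <- ceiling(frac * length(genes))
  ns <- ncol(expr)
  with_seed(seed, {
    co <- matrix(0, ns, ns, dimnames = list(colnames(expr), colnames(expr)))
    parts <- matrix(0L, reps, ns, dimnames = list(NULL, colnames(expr)))
    acc <- numeric(reps)
    for (r in seq_len(reps)) {
      sub <- if (n_take == length(genes)) genes else sample(genes, n_take)
      part <- cluster_samples(center_genes(expr[sub, , drop = FALSE]), k,
                              distance = distance, linkage = linkage)
      parts[r, ] <- part
      co <- co + outer(part, part, "==")
      acc[r] <- partitions_match(part, labels)
    }
    co <- co / reps
    same <- outer(labels, labels, "==")
    off <- !diag(ns)
    structure(list(
      consensus_matrix = co, partitions = parts,
      signature_accuracy = mean(acc),
      mean_within_consensus = mean(co[same & off]),
      mean_between_consensus = if (any(!same)) mean(co[!same]) else NA_real_,
      labels = stats::setNames(labels, colnames(expr)),
      config = list(frac = frac, reps = reps, k = k, seed = seed,
                    n_signature_genes = length(genes),
                    distance = distance, linkage = linkage)),
      class = "consensus_result")
  })
}

#' @export
print.consensus_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Consensus clustering: %d reps, %.0f%% of %d genes, k = %d\n",
              cfg$reps, 100 * cfg$frac, cfg$n_signature_genes, cfg$k))
  cat(sprintf("  partition-match accuracy: %.4f\n", x$signature_accuracy))
  cat(sprintf("  mean consensus within / between groups: %.3f / %.3f\n",
              x$mean_within_consensus, x$mean_between_consensus))
  invisible(x)
}

#' Heatmap image of a consensus matrix
#'
#' @param x A `consensus_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.consensus_result <- function(x, ...) {
  ord <- order(x$labels)
  m <- x$consensus_matrix[ord, ord]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m[, rev(seq_len(ncol(m)))],
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Random-signature consensus baseline
#'
#' Draws `n_signatures` gene sets of the given size uniformly from the
#' matrix rows (the study universe) and evaluates each with the same
#' subsampled consensus-clustering procedure, yielding the null distribution
#' of partition-match accuracy for signatures with no claim to biology.
#'
#' @inheritParams consensus_cluster
#' @param size Signature size to draw.
#' @param n_signatures Number of random signatures (default 1000).
#' @param reps_per_signature Consensus replicates per random signature
#'   (default 50; the signature of interest typically gets more).
#' @return List of class `signature_baseline`: `accuracies` (one per random
#'   signature), `mean_baseline`, `config`.
#' @export
random_signature_baseline <- function(expr, labels, size,
                                      n_signatures = 1000,
                                      reps_per_signature = 50, frac = 0.8,
                                      k = NULL, seed = NULL,
                                      distance = "pearson",
                                      linkage = "average") {
  if (size > nrow(expr))
    stopf("size (%d) exceeds the universe (%d matrix rows)", size, nrow(expr))
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, n_signatures)
    accs <- vapply(seq_len(n_signatures), function(i) {
      sig <- sample(rownames(expr), size)
      consensus_cluster(expr, labels, sig, frac = frac,
                        reps = reps_per_signature, k = k,
                        seed = sub_seeds[i], distance = distance,
                        linkage = linkage)$signature_accuracy
    }, numeric(1))
    structure(list(accuracies = accs, mean_baseline = mean(accs),
                   config = list(size = size, n_signatures = n_signatures,
                                 reps_per_signature = reps_per_signature,
                                 frac = frac, k = k, seed = seed)),
              class = "signature_baseline")
  })
}

#' @export
print.signature_baseline <- function(x, ...) {
  cat(sprintf("Random-signature baseline: %d signatures of size %d, mean accuracy %.4f\n",
              x$config$n_signatures, x$config$size, x$mean_baseline))
  invisible(x)
}

#' Per-condition log2 fold-change table for a signature
#'
#' For each signature gene present on the platform, the mean log2 expression
#' of each non-reference condition minus the reference mean - the matrix
#' behind a fold-change heatmap of a multi-exposure study.
#'
#' @param expr Gene x sample matrix (log2).
#' @param labels Condition label per sample.
#' @param signature Signature genes; those absent from the matrix are
#'   dropped with a warning, never imputed.
#' @param reference Reference condition label (e.g. `"air"`).
#' @return Matrix: signature genes x non-reference conditions.
#' @export
fold_change_table <- function(expr, labels, signature, reference) {
  labels <- as.character(labels)
  if (!reference %in% labels) stopf("reference group '%s' not present", reference)
  genes <- intersect(unique(signature), rownames(expr))
  missing <- setdiff(unique(signature), rownames(expr))
  if (length(missing))
    warnf("%d signature gene(s) absent from the platform were dropped (first: %s)",
          length(missing), missing[1])
  if (length(genes) == 0) stopf("no signature gene present on the platform")
  conds <- setdiff(unique(labels), reference)
  ref_mean <- rowMeans(expr[genes, labels == reference, drop = FALSE])
  out <- vapply(conds, function(cn)
    rowMeans(expr[genes, labels == cn, drop = FALSE]) - ref_mean,
    numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, conds))
  out
}
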