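# Two-class unpaired SAM: moderated t-like statistic d = (m1 - m2)/(s + s0)
# with a fudge factor s0 chosen to decouple d from per-gene variance, a
# permutation null of expected order statistics, and a delta threshold tuned
# to a target FDR. This is the per-study differential-expression engine of
# the cross-study signature pipeline.

#' SAM configuration
#'
#' @param n_permutations Number of label permutations; if fewer distinct
#'   two-group label assignments exist, all of them are used exhaustively.
#' @param target_fdr Target false discovery rate for delta selection.
#' @param delta_grid_step Step of the delta search grid.
#' @param pi0_mode `"one"` (conservative, pi0 = 1; default) or `"quantile"`
#'   (pi0 estimated from the fraction of observed d inside the interquartile
#'   band of the permuted d values).
#' @param seed RNG seed for permutation sampling.
#' @return List of class `sam_config`.
#' @export
sam_config <- function(n_permutations = 200, target_fdr = 0.05,
                       delta_grid_step = 0.05,
                       pi0_mode = c("one", "quantile"), seed = NULL) {
  if (target_fdr <= 0 || target_fdr >= 1) stopf("target_fdr must be in (0, 1)")
  if (delta_grid_step <= 0) stopf("delta_grid_step must be > 0")
  structure(list(n_permutations = as.integer(n_permutations),
                 target_fdr = target_fdr,
                 delta_grid_step = delta_grid_step,
                 pi0_mode = match.arg(pi0_mode), seed = seed),
            class = "sam_config")
}

#' SAM relative-difference statistic
#'
#' `d = (mean(group1) - mean(group2)) / (s + s0)` per gene, where `s` is the
#' pooled standard error of the mean difference and `s0` the fudge factor
#' that damps large `|d|` at tiny variances.
#'
#' @param group1,group2 Numeric matrices (genes x samples), or vectors for a
#'   single gene. Each group needs >= 2 samples.
#' @param s0 Fudge factor, >= 0.
#' @return data.frame with per-gene `d`, `s`, `log2fc`
#'   (= mean(group1) - mean(group2)).
#' @examples
#' sam_statistic(c(2, 2), c(0, 0), s0 = 1)  # s = 0, d = 2
#' @export
sam_statistic <- function(group1, group2, s0 = 0) {
  if (is.vector(group1)) group1 <- matrix(group1, nrow = 1)
  if (is.vector(group2)) group2 <- matrix(group2, nrow = 1)
  n1 <- ncol(group1); n2 <- ncol(group2)
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 samples (got %d and %d)", n1, n2)
  if (nrow(group1) != nrow(group2)) stopf("groups must have the same genes")
  m1 <- rowMeans(group1); m2 <- rowMeans(group2)
  ss <- rowSums((group1 - m1)^2) + rowSums((group2 - m2)^2)
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * ss)
  data.frame(d = (m1 - m2) / (s + s0), s = s, log2fc = m1 - m2,
             row.names = rownames(group1))
}

#' Estimate the SAM fudge factor s0
#'
#' Searches the 21 percentiles (0, 5, ..., 100) of the per-gene standard
#' errors `s` and picks the candidate minimizing the coefficient of
#' variation of the median absolute deviation of `d(s0)` computed within 100
#' equal-count windows of `s`. A flat CV profile means `d` no longer tracks
#' variance. Ties are broken by the smallest candidate.
#'
#' @param numerator Per-gene mean differences (the numerator of `d`).
#' @param s Per-gene pooled standard errors.
#' @return The selected `s0` (one of the 21 candidate percentile values).
#' @export
estimate_s0 <- function(numerator, s) {
  if (length(numerator) != length(s)) stopf("numerator and s lengths differ")
  g <- length(s)
  if (g < 100) warnf("estimate_s0: only %d genes; s0 estimate is unstable below 100", g)
  if (diff(range(s)) == 0) {
    warnf("estimate_s0: all standard errors equal; returning s0 = 0")
    return(0)
  }
  cand <- unname(stats::quantile(s, probs = seq(0, 1, by = 0.05)))
  nbin <- min(100L, g)
  bin <- ceiling(rank(s, ties.method = "first") / (g / nbin))
  cv <- vapply(cand, function(s0) {
    d <- numerator / (s + s0)
    d[!is.finite(d)] <- 0
    v <- tapply(d, bin, stats::mad)
    mv <- mean(v)
    if (mv == 0) 0 else stats::sd(v) / mv
  }, numeric(1))
  cand[which.min(cv)]  # which.min takes the first (smallest) on ties
}

# All (or a seeded sample of) distinct assignments of n1 of n columns to
# "group1". Returned as an n1 x B index matrix; includes the observed
# assignment when exhaustive.
perm_assignments <- function(n, n1, n_perm, seed = NULL) {
  total <- choose(n, n1)
  if (total <= n_perm) return(utils::combn(n, n1))
  with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- matrix(0L, n1, n_perm)
    got <- 0L
    while (got < n_perm) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ".")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[, got] <- cand
      }
    }
    out
  })
}

# d statistics for every assignment column of `assign`: G x B matrix.
d_for_assignments <- function(x, assign, s0) {
  n <- ncol(x); b <- ncol(assign); n1 <- nrow(assign); n2 <- n - n1
  ind <- matrix(0, n, b)
  ind[cbind(as.vector(assign), rep(seq_len(b), each = n1))] <- 1
  s1 <- x %*% ind
  q1 <- (x^2) %*% ind
  st <- rowSums(x); qt <- rowSums(x^2)
  m1 <- s1 / n1; m2 <- (st - s1) / n2
  ss <- (q1 - n1 * m1^2) + ((qt - q1) - n2 * m2^2)
  ss[ss < 0] <- 0  # guard tiny negative round-off
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * ss)
  dmat <- (m1 - m2) / (s + s0)
  dmat[!is.finite(dmat)] <- 0  # constant genes (s + s0 = 0) carry no evidence
  dmat
}

# Cutoffs for one delta from sorted observed d and expected order stats.
delta_cutoffs <- function(d_sorted, dbar, delta) {
  diff <- d_sorted - dbar
  up <- d_sorted[diff > delta]
  low <- d_sorted[diff < -delta]
  c(cut_low = if (length(low)) max(low) else -Inf,
    cut_up = if (length(up)) min(up) else Inf)
}

#' Fit a two-class SAM analysis with permutation FDR
#'
#' Computes per-gene SAM statistics (contrast: second factor level minus
#' first, e.g. exposed - control), estimates the fudge factor, builds the
#' permutation null of expected order statistics, evaluates the estimated
#' FDR over a grid of delta thresholds, and selects the smallest delta whose
#' FDR is at or below the target.
#'
#' For each delta, `cut_up` is the smallest observed order statistic
#' exceeding its permutation expectation by more than delta (symmetrically
#' `cut_low` below); genes beyond the cutoffs are called, and
#' `FDR(delta) = pi0 * median_b(# permuted d beyond cutoffs) / max(1, # called)`.
#'
#' @param expr Gene x sample numeric matrix (log2 scale).
#' @param labels Two-level factor (or coercible), one label per column.
#' @param config A [sam_config()].
#' @return Object of class `sam_fit`: `genes` (data.frame with `d`, `s`,
#'   `log2fc`, `called`, `direction`), `s0`, `pi0`, `delta_selected`,
#'   `fdr_estimate`, `cutoffs`, `expected_order_stats`, `delta_table`
#'   (delta / n_called / fdr profile), `n_permutations_used`, `target_met`
#'   flag, and the config.
#' @examples
#' m <- matrix(rnorm(200 * 8), 200, 8,
#'             dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
#' fit <- sam_fit(m, rep(c("control", "exposed"), each = 4),
#'                sam_config(n_permutations = 50, seed = 1))
#' fit
#' @export
sam_fit <- function(expr, labels, config = sam_config()) {
  stopifnot(inherits(config, "sam_config"))
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stopf("SAM here is two-class: got %d label classes", nlevels(labels))
  if (length(labels) != ncol(expr)) stopf("one label per sample required")
  idx1 <- which(labels == levels(labels)[2])
  idx2 <- which(labels == levels(labels)[1])
  obs0 <- sam_statistic(expr[, idx1, drop = FALSE],
                        expr[, idx2, drop = FALSE], s0 = 0)
  s0 <- estimate_s0(obs0$log2fc, obs0$s)
  den <- obs0$s + s0
  # a gene constant within and between groups (den = 0) carries no evidence
  d <- ifelse(den > 0, obs0$log2fc / den, 0)

  n <- ncol(expr)
  assign <- perm_assignments(n, length(idx1), config$n_permutations,
                             seed = config$seed)
  dp <- d_for_assignments(expr, assign, s0)
  b <- ncol(dp)
  dp_sorted <- apply(dp, 2, sort)
  dbar <- rowMeans(dp_sorted)
  d_sorted <- sort(d)

  pi0 <- if (config$pi0_mode == "one") 1 else {
    q <- stats::quantile(dp, c(0.25, 0.75))
    min(1, sum(d >= q[1] & d <= q[2]) / (0.5 * length(d)))
  }

  max_gap <- max(abs(d_sorted - dbar))
  grid <- seq(0, max_gap + config$delta_grid_step,
              by = config$delta_grid_step)
  tab <- lapply(grid, function(delta) {
    cuts <- delta_cutoffs(d_sorted, dbar, delta)
    called <- d >= cuts["cut_up"] | d <= cuts["cut_low"]
    n_called <- sum(called)
    if (n_called == 0) {
      fdr <- 0
    } else {
      false_per_perm <- colSums(dp >= cuts["cut_up"]) +
        colSums(dp <= cuts["cut_low"])
      fdr <- pi0 * stats::median(false_per_perm) / n_called
    }
    list(delta = delta, n_called = n_called, fdr = fdr, cuts = cuts)
  })
  delta_table <- data.frame(
    delta = vapply(tab, `[[`, numeric(1), "delta"),
    n_called = vapply(tab, `[[`, numeric(1), "n_called"),
    fdr = vapply(tab, `[[`, numeric(1), "fdr"))

  ok <- which(delta_table$fdr <= config$target_fdr)
  target_met <- length(ok) > 0 && any(delta_table$n_called[ok] > 0)
  sel <- if (length(ok)) ok[1] else nrow(delta_table)
  cuts <- tab[[sel]]$cuts
  called <- d >= cuts["cut_up"] | d <= cuts["cut_low"]
  if (!length(ok)) called[] <- FALSE  # no delta achieves the target

  genes <- data.frame(
    d = d, s = obs0$s, log2fc = obs0$log2fc, called = called,
    direction = ifelse(d >= 0, "up", "down"),
    row.names = rownames(expr), stringsAsFactors = FALSE)
  structure(list(
    genes = genes, s0 = s0, pi0 = pi0,
    delta_selected = delta_table$delta[sel],
    fdr_estimate = delta_table$fdr[sel],
    cutoffs = cuts,
    expected_order_stats = dbar,
    delta_table = delta_table,
    n_permutations_used = b,
    exhaustive = choose(n, length(idx1)) <= config$n_permutations,
    target_met = target_met,
    contrast = paste(levels(labels)[2], "-", levels(labels)[1]),
    config = config), class = "sam_fit")
}

#' Genes called differentially expressed by a SAM fit
#'
#' @param fit A [sam_fit()] object.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of called gene IDs.
#' @export
called_genes <- function(fit, direction = c("both", "up", "down")) {
  stopifnot(inherits(fit, "sam_fit"))
  direction <- match.arg(direction)
  g <- fit$genes[fit$genes$called, , drop = FALSE]
  if (direction != "both") g <- g[g$direction == direction, , drop = FALSE]
  rownames(g)
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("SAM fit (%s), %d genes, %d permutations%s\n",
              x$contrast, nrow(x$genes), x$n_permutations_used,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, delta = %.2f, est. FDR = %.4f\n",
              x$s0, x$pi0, x$delta_selected, x$fdr_estimate))
  cat(sprintf("  called: %d (%d up, %d down)%s\n",
              sum(x$genes$called),
              sum(x$genes$called & x$genes$direction == "up"),
              sum(x$genes$called & x$genes$direction == "down"),
              if (!x$target_met) " [no delta reached the target FDR]" else ""))
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  out <- list(delta_table = object$delta_table,
              s0 = object$s0, pi0 = object$pi0,
              delta_selected = object$delta_selected,
              fdr_estimate = object$fdr_estimate,
              n_called = sum(object$genes$called))
  class(out) <- "summary.sam_fit"
  out
}

#' @export
print.summary.sam_fit <- function(x, ...) {
  cat("Delta / calls / estimated FDR profile:\n")
  print(utils::head(x$delta_table[x$delta_table$n_called > 0, ], 15),
        row.names = FALSE)
  cat(sprintf("selected delta %.2f: %d genes at estimated FDR %.4f (s0 = %.4g)\n",
              x$delta_selected, x$n_called, x$fdr_estimate, x$s0))
  invisible(x)
}

#' Quantile-quantile SAM plot
#'
#' Observed ordered d against the permutation-expected order statistics,
#' with the selected cutoffs; called genes highlighted.
#'
#' @param x A `sam_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sam_fit <- function(x, ...) {
  d_sorted <- sort(x$genes$d)
  called_sorted <- d_sorted >= x$cutoffs["cut_up"] |
    d_sorted <= x$cutoffs["cut_low"]
  graphics::plot(x$expected_order_stats, d_sorted,
                 xlab = "expected d (permutation)", ylab = "observed d",
                 col = ifelse(called_sorted, "firebrick", "grey40"),
                 pch = 20, ...)
  graphics::abline(0, 1, col = "grey60")
  graphics::abline(h = x$cutoffs, lty = 3, col = "firebrick")
  invisible(x)
}

#' Write a SAM fit as the pipeline's TSV + JSON summary
#'
#' @param fit A `sam_fit`.
#' @param tsv_path Output TSV (columns gene, d, s, log2fc, called,
#'   direction).
#' @param json_path Optional JSON run summary (s0, delta, FDR, counts).
#' @return Invisibly, `tsv_path`.
#' @export
write_sam_result <- function(fit, tsv_path, json_path = NULL) {
  stopifnot(inherits(fit, "sam_fit"))
  df <- data.frame(gene = rownames(fit$genes), fit$genes,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      s0 = fit$s0, pi0 = fit$pi0, delta = fit$delta_selected,
      fdr_estimate = fit$fdr_estimate, n_called = sum(fit$genes$called),
      n_genes = nrow(fit$genes), n_permutations = fit$n_permutations_used,
      target_met = fit$target_met, contrast = fit$contrast),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsv_path)
}
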