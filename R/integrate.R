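# Cross-study harmonization: common gene background, intersection signature,
# and exact overlap significance. The 2-way test is the classical
# hypergeometric tail; the 3-way test is an exact composition over the size
# of the first pairwise intersection, under the null that each study's
# called set is an independent uniform fixed-size subset of the background.

#' Common background gene universe
#'
#' Exact intersection of the studies' harmonized gene universes: the genes
#' every platform interrogates, i.e. the sampling frame for overlap tests.
#'
#' @param universes List (>= 2) of character vectors of harmonized gene keys.
#' @return Character vector (sorted).
#' @export
build_common_background <- function(universes) {
  if (length(universes) < 2) stopf("need >= 2 universes")
  bg <- sort(Reduce(intersect, lapply(universes, unique)), method = "radix")
  if (length(bg) == 0) stopf("the universes have an empty intersection")
  bg
}

#' Intersection gene signature across studies
#'
#' Restricts each study's called gene set to the common background and
#' intersects: the signature is the set of genes differentially expressed in
#' every study.
#'
#' @param per_study_called Named list of character vectors of called genes.
#' @param background Common background from [build_common_background()].
#' @param provenance Optional list of per-study settings (FDR, delta) to
#'   carry along.
#' @return Object of class `gene_signature`: `genes`, `per_study_called`
#'   (background-restricted), `background`, `provenance`.
#' @export
intersect_signature <- function(per_study_called, background,
                                provenance = NULL) {
  if (is.null(names(per_study_called)))
    names(per_study_called) <- sprintf("study%d", seq_along(per_study_called))
  restricted <- lapply(per_study_called,
                       function(g) sort(intersect(unique(g), background), method = "radix"))
  empty <- names(restricted)[lengths(restricted) == 0]
  if (length(empty))
    warnf("no called genes on the common background for: %s",
          paste(empty, collapse = ", "))
  genes <- sort(Reduce(intersect, restricted), method = "radix")
  if (length(genes) == 0)
    warnf("empty signature: no gene is called in every study")
  structure(list(genes = genes, per_study_called = restricted,
                 background = sort(unique(background), method = "radix"),
                 provenance = provenance), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature: %d genes shared across %d studies\n",
              length(x$genes), length(x$per_study_called)))
  cat(sprintf("  background: %d genes; per-study called: %s\n",
              length(x$background),
              paste(sprintf("%s=%d", names(x$per_study_called),
                            lengths(x$per_study_called)), collapse = ", ")))
  invisible(x)
}

#' Two-way hypergeometric overlap tail probability
#'
#' `P(X >= t)` for `X ~ Hypergeometric(N, a, b)`: the chance that two
#' independent uniform subsets of sizes `a` and `b` drawn from a universe of
#' `N` genes share at least `t` members. Exact, computed in log space.
#'
#' @param N Universe size.
#' @param a,b Set sizes (0 <= a, b <= N).
#' @param t Observed overlap.
#' @param log10p If `TRUE`, return log10 of the p-value (the tails of real
#'   cross-study overlaps underflow double precision).
#' @return Upper-tail probability (or its log10).
#' @examples
#' hypergeom_overlap_p(4, 2, 2, 2)  # 1/6
#' @export
hypergeom_overlap_p <- function(N, a, b, t, log10p = FALSE) {
  check_overlap_args(N, c(a, b))
  if (t > min(a, b)) {
    warnf("impossible overlap: t = %d > min(a, b) = %d; p = 0", t, min(a, b))
    return(if (log10p) -Inf else 0)
  }
  if (t <= 0) return(if (log10p) 0 else 1)
  lp <- stats::phyper(t - 1, a, N - a, b, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Exact three-way hypergeometric overlap tail probability
#'
#' Null model: three independent uniform fixed-size subsets `A`, `B`, `C`
#' (sizes `a`, `b`, `c`) of an `N`-gene universe. Conditioning on
#' `|A intersect B| = m`, the triple intersection is hypergeometric in `m`,
#' so `P(X3 >= t) = sum_m h(m; N, a, b) * P(Hyper(N, m, c) >= t)`, summed in
#' log space. With `c = N` this reduces to the two-way tail.
#'
#' @inheritParams hypergeom_overlap_p
#' @param c Third set size.
#' @return Upper-tail probability (or its log10).
#' @examples
#' threeway_overlap_p(4, 2, 2, 2, 1)  # 17/36
#' @export
threeway_overlap_p <- function(N, a, b, c, t, log10p = FALSE) {
  check_overlap_args(N, base::c(a, b, c))  # arg `c` shadows base::c here
  if (t > min(a, b, c)) {
    warnf("impossible overlap: t = %d > min(a, b, c) = %d; p = 0",
          t, min(a, b, c))
    return(if (log10p) -Inf else 0)
  }
  if (t <= 0) return(if (log10p) 0 else 1)
  m <- 0:min(a, b)
  lw <- stats::dhyper(m, a, N - a, b, log = TRUE)
  lt <- stats::phyper(t - 1, m, N - m, c, lower.tail = FALSE, log.p = TRUE)
  lp <- logsumexp(lw + lt)
  lp <- min(lp, 0)  # clip tiny positive round-off
  if (log10p) lp / log(10) else exp(lp)
}

check_overlap_args <- function(N, sizes) {
  if (N < 1) stopf("universe size N must be >= 1")
  if (any(sizes < 0) || any(sizes > N))
    stopf("set sizes must lie in [0, N]")
  invisible(TRUE)
}

new_overlap_test <- function(label, N, sizes, t, p, log10_p, arity) {
  structure(list(label = label, universe_N = N, set_sizes = sizes,
                 observed_t = t, p_value = p, log10_p = log10_p,
                 arity = arity), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("%d-way overlap [%s]: N = %d, sizes = (%s), t = %d, p = %.3g (log10 p = %.2f)\n",
              x$arity, x$label, x$universe_N,
              paste(x$set_sizes, collapse = ", "), x$observed_t,
              x$p_value, x$log10_p))
  invisible(x)
}

#' Overlap significance report for a signature
#'
#' One two-way hypergeometric test per study pair, plus the exact three-way
#' test when three studies are present. Pairwise tests use the intersection
#' of the two studies' universes as the sampling frame by default
#' (`background = "pairwise"`); `"common"` uses the all-study background for
#' every test. The three-way test always uses the common background.
#'
#' @param signature A [intersect_signature()] result.
#' @param universes Named list of per-study gene universes (required for
#'   `background = "pairwise"`); defaults to the common background for all.
#' @param background `"pairwise"` or `"common"`.
#' @return List of class `overlap_report`: `tests` (list of `overlap_test`),
#'   `background_mode`.
#' @export
overlap_report <- function(signature, universes = NULL,
                           background = c("pairwise", "common")) {
  stopifnot(inherits(signature, "gene_signature"))
  background <- match.arg(background)
  called <- signature$per_study_called
  ids <- names(called)
  if (length(ids) < 2) stopf("need >= 2 studies")
  if (background == "pairwise" && is.null(universes)) {
    background <- "common"
  }
  tests <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq((i + 1), length(ids))) {
      if (background == "pairwise") {
        frame <- intersect(unique(universes[[ids[i]]]),
                           unique(universes[[ids[j]]]))
      } else {
        frame <- signature$background
      }
      gi <- intersect(called[[ids[i]]], frame)
      gj <- intersect(called[[ids[j]]], frame)
      t_obs <- length(intersect(gi, gj))
      p <- hypergeom_overlap_p(length(frame), length(gi), length(gj), t_obs)
      lp <- hypergeom_overlap_p(length(frame), length(gi), length(gj), t_obs,
                                log10p = TRUE)
      tests[[paste(ids[i], "vs", ids[j])]] <-
        new_overlap_test(paste(ids[i], "vs", ids[j]), length(frame),
                         c(length(gi), length(gj)), t_obs, p, lp, 2L)
    }
  }
  if (length(ids) == 3) {
    frame <- signature$background
    sizes <- lengths(called)
    t_obs <- length(signature$genes)
    p <- threeway_overlap_p(length(frame), sizes[1], sizes[2], sizes[3], t_obs)
    lp <- threeway_overlap_p(length(frame), sizes[1], sizes[2], sizes[3],
                             t_obs, log10p = TRUE)
    tests[["3-way"]] <- new_overlap_test(paste(ids, collapse = " & "),
                                         length(frame), unname(sizes),
                                         t_obs, p, lp, 3L)
  }
  structure(list(tests = tests, background_mode = background),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report (%s background):\n", x$background_mode))
  for (t in x$tests) print(t)
  invisible(x)
}

#' Write signature, background and overlap tests to disk
#'
#' `signature.txt` and `background.txt` (one gene per line, display symbols
#' when a symbol map is given) and `overlap_tests.json`.
#'
#' @param signature A `gene_signature`.
#' @param report An [overlap_report()].
#' @param dir Output directory.
#' @param symbol_map Optional named key -> symbol vector for display.
#' @return Invisibly, the directory.
#' @export
write_signature <- function(signature, report, dir, symbol_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  disp <- function(keys) {
    if (is.null(symbol_map) || length(keys) == 0) return(as.character(keys))
    out <- symbol_map[keys]
    as.character(ifelse(is.na(out), keys, out))
  }
  writeLines(disp(signature$genes), file.path(dir, "signature.txt"))
  writeLines(disp(signature$background), file.path(dir, "background.txt"))
  jsonlite::write_json(
    lapply(report$tests, function(t)
      list(label = t$label, arity = t$arity, universe_N = t$universe_N,
           set_sizes = t$set_sizes, observed_t = t$observed_t,
           p_value = t$p_value, log10_p = t$log10_p)),
    file.path(dir, "overlap_tests.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
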