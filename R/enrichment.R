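# Hypergeometric pathway enrichment against GMT collections, and merging of
# top terms across studies into an enrichment-map network export.

#' Hypergeometric pathway enrichment
#'
#' For each pathway, tests whether the differentially expressed gene set
#' overlaps it more than expected for a uniform draw from the universe:
#' `p = P(X >= k)`, `X ~ Hypergeometric(N = |universe|, K, n)` with `K` the
#' universe-restricted pathway size and `n = |de_genes|`. Pathways are
#' intersected with the universe before testing; Benjamini-Hochberg q-values
#' are computed across the tested pathways.
#'
#' @param de_genes Character vector of DE gene IDs (subset of `universe`).
#' @param universe Character vector: the platform's gene universe.
#' @param gmt Named list of gene sets (see [read_gmt()]).
#' @return data.frame sorted by p: `pathway`, `K` (pathway size in
#'   universe), `n` (DE set size), `k` (overlap), `p_value`, `q_value`,
#'   `overlap_genes` (comma-separated). Pathways with `K = 0` are omitted.
#' @examples
#' uni <- paste0("g", 1:20)
#' hypergeom_enrich(paste0("g", 1:5), uni, list(hit = paste0("g", 1:5)))
#' @export
hypergeom_enrich <- function(de_genes, universe, gmt) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stopf("empty universe")
  de <- unique(as.character(de_genes))
  extra <- setdiff(de, universe)
  if (length(extra))
    stopf("%d DE gene(s) are not in the universe (first: %s)",
          length(extra), extra[1])
  if (length(gmt) == 0)
    return(data.frame(pathway = character(0), K = integer(0), n = integer(0),
                      k = integer(0), p_value = numeric(0),
                      q_value = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE))
  sets <- lapply(gmt, function(g) intersect(unique(as.character(g)), universe))
  keep <- lengths(sets) >= 1
  sets <- sets[keep]
  N <- length(universe); n <- length(de)
  rows <- lapply(names(sets), function(nm) {
    set <- sets[[nm]]
    ov <- intersect(de, set)
    k <- length(ov); K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, K = K, n = n, k = k, p_value = p,
               overlap_genes = paste(sort(ov, method = "radix"), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway, method = "radix"), c("pathway", "K", "n", "k",
                                                "p_value", "q_value",
                                                "overlap_genes")]
  rownames(out) <- NULL
  out
}

jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0) return(0)
  length(intersect(x, y)) / u
}

#' Merge top enriched terms across studies into an enrichment map
#'
#' Candidate nodes are the union of each study's `top_n` most significant
#' terms; a candidate is retained iff its raw p-value is at or below `alpha`
#' in at least one study. Edges connect retained terms whose
#' universe-restricted gene sets have Jaccard similarity at or above
#' `similarity_threshold`. The node/edge tables import directly into
#' network tools.
#'
#' @param tables Named list of per-study enrichment tables from
#'   [hypergeom_enrich()].
#' @param gmt The gene-set collection the tables were computed against.
#' @param top_n Terms taken per study (default 20).
#' @param alpha Raw-p significance threshold (default 0.05).
#' @param similarity_threshold Minimum Jaccard for an edge (default 0.25).
#' @param universe Optional gene universe to restrict sets before Jaccard;
#'   default: sets as given.
#' @return Object of class `enrichment_map`: `nodes` (term, per-study p/q,
#'   per-study significance flags), `edges` (source, target, jaccard).
#' @export
merge_top_terms <- function(tables, gmt, top_n = 20, alpha = 0.05,
                            similarity_threshold = 0.25, universe = NULL) {
  if (length(tables) == 0) stopf("need >= 1 enrichment table")
  if (is.null(names(tables)))
    names(tables) <- sprintf("study%d", seq_along(tables))
  cand <- unique(unlist(lapply(tables, function(tb)
    utils::head(tb$pathway, top_n))))
  p_of <- function(tb, term) {
    i <- match(term, tb$pathway)
    if (is.na(i)) NA_real_ else tb$p_value[i]
  }
  q_of <- function(tb, term) {
    i <- match(term, tb$pathway)
    if (is.na(i)) NA_real_ else tb$q_value[i]
  }
  nodes <- data.frame(term = cand, stringsAsFactors = FALSE)
  for (sid in names(tables)) {
    nodes[[paste0("p_", sid)]] <- vapply(cand, p_of, numeric(1),
                                         tb = tables[[sid]])
    nodes[[paste0("q_", sid)]] <- vapply(cand, q_of, numeric(1),
                                         tb = tables[[sid]])
    nodes[[paste0("sig_", sid)]] <-
      !is.na(nodes[[paste0("p_", sid)]]) & nodes[[paste0("p_", sid)]] <= alpha
  }
  sig_any <- rowSums(as.matrix(nodes[grep("^sig_", names(nodes))])) > 0
  nodes <- nodes[sig_any, , drop = FALSE]
  rownames(nodes) <- NULL

  sets <- lapply(gmt, function(g) {
    g <- unique(as.character(g))
    if (is.null(universe)) g else intersect(g, universe)
  })
  edges <- data.frame(source = character(0), target = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE)
  terms <- nodes$term
  if (length(terms) >= 2) {
    pairs <- utils::combn(terms, 2)
    sim <- apply(pairs, 2, function(pr) jaccard(sets[[pr[1]]], sets[[pr[2]]]))
    keep <- sim >= similarity_threshold
    edges <- data.frame(source = pairs[1, keep], target = pairs[2, keep],
                        jaccard = sim[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 top_n = top_n,
                 similarity_threshold = similarity_threshold),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("Enrichment map: %d terms, %d edges (top %d per study, p <= %g, Jaccard >= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$top_n, x$alpha,
              x$similarity_threshold))
  invisible(x)
}

#' Write an enrichment map as node/edge TSVs
#'
#' @param emap An [merge_top_terms()] result.
#' @param dir Output directory; writes `emap_nodes.tsv` and
#'   `emap_edges.tsv`.
#' @return Invisibly, the directory.
#' @export
write_enrichment_map <- function(emap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(emap$nodes, file.path(dir, "emap_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(emap$edges, file.path(dir, "emap_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
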