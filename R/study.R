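#' Expression study container
#'
#' Bundles one study's probe-level log2 expression matrix (features x
#' samples) with its sample group labels and probe-to-gene map. This is the
#' unit every pipeline stage consumes: normalization and probe collapsing
#' operate on it, and its probe map defines the study's gene universe.
#'
#' @param exprs Numeric matrix of log2 intensities, features in rows (rownames
#'   required), samples in columns (colnames required). No missing values.
#' @param groups Character or factor of exposure group labels, one per sample,
#'   either named by sample ID or in column order of `exprs`.
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`,
#'   `entrez_id` (`NA` allowed in `entrez_id`). Every row of `exprs` must
#'   appear in `probe_id`.
#' @param study_id Single character label for the study.
#' @return An object of class `expression_study`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' pm <- data.frame(probe_id = paste0("p", 1:3),
#'                  gene_symbol = c("A", "B", "C"), entrez_id = c(1, 2, NA))
#' st <- expression_study(m, rep(c("control", "exposed"), each = 2), pm, "demo")
#' st
#' @export
expression_study <- function(exprs, groups, probe_map, study_id) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stopf("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stopf("'exprs' needs row and column names")
  if (anyNA(exprs) || any(!is.finite(exprs)))
    stopf("'exprs' contains missing or non-finite values; impute or drop before building the study")
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(exprs), names(groups))
    if (length(missing))
      stopf("no group label for sample(s): %s", paste(missing, collapse = ", "))
    groups <- groups[colnames(exprs)]
  } else if (length(groups) != ncol(exprs)) {
    stopf("length(groups) (%d) != number of samples (%d)",
          length(groups), ncol(exprs))
  }
  names(groups) <- colnames(exprs)
  probe_map <- validate_probe_map(probe_map)
  unmapped_rows <- setdiff(rownames(exprs), probe_map$probe_id)
  if (length(unmapped_rows))
    stopf("%d matrix rows absent from probe_map (first: %s)",
          length(unmapped_rows), unmapped_rows[1])
  structure(list(exprs = exprs, groups = groups, probe_map = probe_map,
                 study_id = as.character(study_id)[1]),
            class = "expression_study")
}

validate_probe_map <- function(probe_map) {
  need <- c("probe_id", "gene_symbol", "entrez_id")
  if (!is.data.frame(probe_map) || !all(need %in% names(probe_map)))
    stopf("probe_map must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  probe_map$probe_id <- as.character(probe_map$probe_id)
  probe_map$gene_symbol <- as.character(probe_map$gene_symbol)
  probe_map$entrez_id <- suppressWarnings(as.integer(probe_map$entrez_id))
  if (anyDuplicated(probe_map$probe_id))
    stopf("duplicated probe_id in probe_map")
  probe_map
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study '%s': %d features x %d samples\n",
              x$study_id, nrow(x$exprs), ncol(x$exprs)))
  tab <- table(x$groups)
  cat("  groups: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  gene universe: %d harmonized genes\n",
              length(study_universe(x))))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$exprs)

#' Harmonized gene identifiers
#'
#' Maps probe annotations to one identifier per gene: the Entrez ID when
#' present (prefixed `"eg:"`), otherwise the exact MGI symbol. Entrez is
#' preferred because symbols drift between annotation releases; the dual
#' mapping lets genes keyed by symbol on one platform and Entrez on another
#' still join.
#'
#' @param probe_map data.frame as in [expression_study()].
#' @return Character vector of harmonized keys, one per probe-map row
#'   (names = probe IDs). `NA` symbol and `NA` Entrez yields `NA`.
#' @export
gene_key <- function(probe_map) {
  probe_map <- validate_probe_map(probe_map)
  key <- ifelse(!is.na(probe_map$entrez_id),
                paste0("eg:", probe_map$entrez_id),
                probe_map$gene_symbol)
  key[!nzchar(key) | key %in% "NA"] <- NA_character_
  names(key) <- probe_map$probe_id
  key
}

#' Gene universe of a study
#'
#' The set of harmonized gene identifiers interrogated by the study's
#' platform (the image of its probe map under [gene_key()]).
#'
#' @param study An `expression_study`.
#' @return Character vector of unique harmonized gene keys.
#' @export
study_universe <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  unique(gene_key(study$probe_map)[!is.na(gene_key(study$probe_map))])
}

# key -> display symbol lookup built from one or more probe maps
key_symbol_map <- function(probe_maps) {
  if (is.data.frame(probe_maps)) probe_maps <- list(probe_maps)
  out <- character(0)
  for (pm in probe_maps) {
    k <- gene_key(pm)
    new <- !is.na(k) & !(k %in% names(out))
    add <- pm$gene_symbol[new]
    names(add) <- k[new]
    out <- c(out, add)
  }
  out
}
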