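# Plain-text interchange formats. All tables are tab-separated with a header
# row; expression tables carry the feature IDs in a leading `feature_id`
# column so they round-trip through any TSV reader.

#' Read / write an expression matrix TSV
#'
#' First column `feature_id`, remaining columns one per sample, tab-separated
#' log2 intensities.
#'
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stopf("expected first column 'feature_id' in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param mat Numeric matrix, features x samples.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Columns `sample_id`, `study_id`, `group`. Group labels live here, never in
#' sample-ID strings.
#'
#' @param path File path.
#' @return `read_metadata_tsv`: data.frame with the three columns.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "study_id", "group")
  if (!all(need %in% names(df)))
    stopf("metadata %s must have columns %s", path, paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_metadata_tsv
#' @param meta data.frame with columns `sample_id`, `study_id`, `group`.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta[c("sample_id", "study_id", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe-to-gene map TSV
#'
#' Columns `probe_id`, `gene_symbol`, `entrez_id` (`NA` allowed).
#'
#' @param path File path.
#' @return `read_probe_map_tsv`: validated data.frame.
#' @export
read_probe_map_tsv <- function(path) {
  validate_probe_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_probe_map_tsv
#' @param probe_map data.frame as in [expression_study()].
#' @export
write_probe_map_tsv <- function(probe_map, path) {
  utils::write.table(validate_probe_map(probe_map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene...`.
#' Reading delegates to [fgsea::gmtPathways()].
#'
#' @param path File path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' @rdname read_gmt
#' @param sets Named list of character vectors of gene IDs.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled; default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (length(sets) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("all gene sets must be named")
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression study to a directory
#'
#' Emits `<study>_expression.tsv`, `<study>_metadata.tsv`,
#' `<study>_probe_map.tsv` in the interchange dialects above.
#'
#' @param study An `expression_study`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- study$study_id
  paths <- c(
    expression = file.path(dir, paste0(id, "_expression.tsv")),
    metadata   = file.path(dir, paste0(id, "_metadata.tsv")),
    probe_map  = file.path(dir, paste0(id, "_probe_map.tsv")))
  write_expression_tsv(study$exprs, paths[["expression"]])
  write_metadata_tsv(
    data.frame(sample_id = colnames(study$exprs), study_id = id,
               group = unname(study$groups), stringsAsFactors = FALSE),
    paths[["metadata"]])
  write_probe_map_tsv(study$probe_map, paths[["probe_map"]])
  invisible(paths)
}

#' Read an expression study from its three TSV files
#'
#' @param expr_path,meta_path,map_path Paths to the expression, metadata and
#'   probe-map TSVs.
#' @param study_id Optional study label; defaults to the metadata's
#'   `study_id`.
#' @return An `expression_study`.
#' @export
read_study <- function(expr_path, meta_path, map_path, study_id = NULL) {
  m <- read_expression_tsv(expr_path)
  meta <- read_metadata_tsv(meta_path)
  pm <- read_probe_map_tsv(map_path)
  groups <- meta$group
  names(groups) <- meta$sample_id
  expression_study(m, groups, pm, study_id %||% meta$study_id[1])
}

#' The published 101-gene chronic inhaled endotoxin signature
#'
#' MGI symbols of the 101 genes found differentially expressed in common
#' across three independent murine models of repeated low-dose inhaled
#' endotoxin exposure. Shipped as a reference fixture so downstream analyses
#' (heatmap preparation, enrichment, consensus clustering) can be exercised
#' against the real signature without any expression data.
#'
#' @return Character vector of 101 MGI gene symbols.
#' @examples
#' length(endotoxin_signature())
#' @export
endotoxin_signature <- function() {
  readLines(system.file("extdata", "endotoxin_signature_101.txt",
                        package = "endosig"))
}
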