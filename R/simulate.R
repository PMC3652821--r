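# Synthetic multi-study expression data with a planted shared signature.
#
# The generator emulates the study designs this pipeline was built for:
# several independent two-group (control vs. LPS-exposed) murine lung
# studies run on distinct platforms whose gene universes only partially
# overlap, plus one four-condition exposure study
# (air / LPS / smoke / LPS+smoke). Values are log2 intensities, i.e. the
# scale of RMA-summarized arrays; platform preprocessing upstream of that
# scale is out of scope.

#' Simulation configuration
#'
#' Parameters of the multi-study generator. Defaults encode the emulated
#' designs: 3 studies on distinct platforms, each platform carrying 70% of a
#' 2000-gene master universe, 100 planted shared differentially expressed
#' (DE) genes forced onto every platform, per-study private DE genes, and
#' group sizes in the 4-8 range typical of murine exposure studies.
#'
#' @param n_studies Number of two-group studies.
#' @param genes_master Size of the master gene universe.
#' @param universe_frac Fraction of the master universe on each platform,
#'   in (0, 1].
#' @param probes_per_gene Integer range `c(min, max)`; each gene carries a
#'   uniform random number of probes in this range (multi-probe genes
#'   exercise probe collapsing).
#' @param n_per_group Samples per exposure group per study; scalar or vector
#'   of length `n_studies`.
#' @param signature_size Number of planted shared DE genes.
#' @param private_de_per_study Number of additional DE genes private to each
#'   study (disjoint from the signature).
#' @param effect_size Standardized mean shift of DE genes in exposed samples,
#'   in units of `noise_sd`.
#' @param noise_sd Within-group standard deviation on the log2 scale.
#' @param baseline_mean Grand mean log2 intensity.
#' @param seed RNG seed; same seed and config give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 3, genes_master = 2000, universe_frac = 0.7,
                       probes_per_gene = c(1L, 3L), n_per_group = 6,
                       signature_size = 100, private_de_per_study = 150,
                       effect_size = 3.0, noise_sd = 0.25,
                       baseline_mean = 8.0, seed = NULL) {
  cfg <- list(n_studies = as.integer(n_studies),
              genes_master = as.integer(genes_master),
              universe_frac = universe_frac,
              probes_per_gene = as.integer(probes_per_gene),
              n_per_group = as.integer(rep_len(n_per_group, n_studies)),
              signature_size = as.integer(signature_size),
              private_de_per_study = as.integer(private_de_per_study),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_mean = baseline_mean, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_studies < 1 || genes_master < 1 || signature_size < 1 ||
        any(n_per_group < 1))
      stopf("all counts in a sim_config must be >= 1")
    if (universe_frac <= 0 || universe_frac > 1)
      stopf("universe_frac must be in (0, 1]")
    if (effect_size < 0) stopf("effect_size must be >= 0")
    if (noise_sd < 0) stopf("noise_sd must be >= 0")
    if (length(probes_per_gene) != 2 || probes_per_gene[1] < 1 ||
        probes_per_gene[2] < probes_per_gene[1])
      stopf("probes_per_gene must be an increasing positive integer pair")
    u <- round(universe_frac * genes_master)
    if (signature_size > u)
      stopf(paste0("infeasible config: signature_size (%d) exceeds the ",
                   "per-study universe round(universe_frac * genes_master) = %d"),
            signature_size, u)
    exp_int <- genes_master * universe_frac^n_studies
    if (signature_size > exp_int)
      stopf(paste0("infeasible config: signature_size (%d) exceeds the expected ",
                   "%d-study universe intersection genes_master * universe_frac^",
                   "n_studies = %.1f"), signature_size, n_studies, exp_int)
    if (private_de_per_study < 0) stopf("private_de_per_study must be >= 0")
  })
  cfg
}

# Master gene annotation: symbols Gm00001..; ~10% of genes lack an Entrez ID
# so the symbol-fallback path of gene harmonization is exercised.
master_genes <- function(genes_master) {
  idx <- seq_len(genes_master)
  data.frame(gene_symbol = sprintf("Gm%05d", idx),
             entrez_id = ifelse(idx %% 10 == 0, NA_integer_, 500000L + idx),
             stringsAsFactors = FALSE)
}

#' Generate a set of synthetic two-group studies with a planted signature
#'
#' Each study receives a seeded random subset of the master universe
#' (`round(universe_frac * genes_master)` genes) forced to include every
#' planted signature gene, 1 or more probes per gene, and Gaussian log2
#' noise. Signature and per-study private DE genes are shifted by
#' `effect_size * noise_sd` in the exposed group; half the planted effects
#' are up, half down (directions fixed by seed, signature directions shared
#' across studies).
#'
#' @param config A [sim_config()].
#' @return List with `studies` (list of [expression_study()]) and `truth`,
#'   a `ground_truth` list: `signature_genes`, `per_study_private_de`,
#'   `per_study_universe` (all harmonized gene keys), `signature_direction`
#'   (+1/-1 per signature gene), and the master annotation.
#' @examples
#' sim <- generate_multistudy(sim_config(genes_master = 300, n_studies = 2,
#'                                       signature_size = 20, seed = 1))
#' sim$studies[[1]]
#' @export
generate_multistudy <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  with_seed(config$seed, {
    ann <- master_genes(config$genes_master)
    keys <- gene_key(data.frame(probe_id = ann$gene_symbol, ann,
                                stringsAsFactors = FALSE))
    names(keys) <- NULL
    u_size <- round(config$universe_frac * config$genes_master)

    sig_idx <- sort(sample.int(config$genes_master, config$signature_size))
    sig_dir <- sample(c(-1, 1), config$signature_size, replace = TRUE)

    studies <- vector("list", config$n_studies)
    private <- vector("list", config$n_studies)
    universes <- vector("list", config$n_studies)
    for (s in seq_len(config$n_studies)) {
      id <- sprintf("study%d", s)
      extra <- sample(setdiff(seq_len(config$genes_master), sig_idx),
                      u_size - length(sig_idx))
      uni_idx <- sort(c(sig_idx, extra))
      n_priv <- min(config$private_de_per_study, length(extra))
      priv_idx <- sort(sample(extra, n_priv))
      priv_dir <- sample(c(-1, 1), n_priv, replace = TRUE)

      de_idx <- c(sig_idx, priv_idx)
      de_dir <- c(sig_dir, priv_dir)
      shift <- numeric(config$genes_master)
      shift[de_idx] <- de_dir * config$effect_size * config$noise_sd

      studies[[s]] <- simulate_study_matrix(
        id, uni_idx, shift, ann, config)
      private[[s]] <- keys[priv_idx]
      universes[[s]] <- keys[uni_idx]
    }
    names(studies) <- names(private) <- names(universes) <-
      vapply(studies, function(x) x$study_id, character(1))
    truth <- structure(list(
      signature_genes = keys[sig_idx],
      signature_direction = stats::setNames(sig_dir, keys[sig_idx]),
      per_study_private_de = private,
      per_study_universe = universes,
      master_annotation = ann), class = "ground_truth")
    list(studies = studies, truth = truth)
  })
}

# One study's probe-level matrix. `shift` is a per-master-gene log2 shift
# applied to exposed samples; carried by all probes of the gene.
simulate_study_matrix <- function(id, uni_idx, shift, ann, config) {
  s_pos <- match(id, sprintf("study%d", seq_len(config$n_studies)))
  n <- config$n_per_group[s_pos]
  n_genes <- length(uni_idx)
  npr <- if (config$probes_per_gene[1] == config$probes_per_gene[2])
    rep(config$probes_per_gene[1], n_genes)
  else sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
              n_genes, replace = TRUE)
  gene_of_probe <- rep(uni_idx, npr)
  probe_rank <- sequence(npr)
  probe_id <- sprintf("%s_%s_p%d", id, ann$gene_symbol[gene_of_probe], probe_rank)

  gene_base <- config$baseline_mean + stats::rnorm(config$genes_master, 0, 1.5)
  probe_off <- stats::rnorm(length(probe_id), 0, 0.3)
  base <- gene_base[gene_of_probe] + probe_off

  groups <- rep(c("control", "exposed"), each = n)
  samples <- sprintf("%s_s%02d", id, seq_len(2 * n))
  mu <- outer(base, rep(0, 2 * n), "+")
  mu[, groups == "exposed"] <- mu[, groups == "exposed"] +
    shift[gene_of_probe]
  m <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                   nrow(mu), ncol(mu))
  dimnames(m) <- list(probe_id, samples)
  pm <- data.frame(probe_id = probe_id,
                   gene_symbol = ann$gene_symbol[gene_of_probe],
                   entrez_id = ann$entrez_id[gene_of_probe],
                   stringsAsFactors = FALSE)
  expression_study(m, stats::setNames(groups, samples), pm, id)
}

#' Generate a multi-condition exposure study
#'
#' One study whose signature genes carry condition-specific log2 shifts so
#' exposure groups are separable on the signature, emulating a
#' four-condition air / LPS / smoke / LPS+smoke design. Non-signature genes
#' carry no group structure.
#'
#' @param signature Character vector of gene symbols (or harmonized keys)
#'   to plant condition effects on.
#' @param groups Named integer vector of group sizes, first group = the
#'   reference condition, e.g. `c(air = 6, lps = 5, smoke = 6, lps_smoke = 5)`.
#' @param effects Either a named numeric vector of per-condition shift
#'   magnitudes (one per group; each condition gets an independent random
#'   +/- sign pattern over signature genes, so two conditions with equal
#'   magnitude still differ in expression pattern), or a full numeric matrix
#'   `length(signature) x length(groups)` of per-gene per-condition shifts.
#' @param universe_size Total genes on the platform (signature genes are
#'   always included).
#' @param noise_sd,baseline_mean As in [sim_config()].
#' @param seed RNG seed.
#' @return An [expression_study()] whose `truth` attribute holds the planted
#'   gene x condition effect matrix.
#' @examples
#' st <- generate_multicondition(paste0("Gs", 1:40),
#'                               groups = c(air = 6, lps = 5, smoke = 6, lps_smoke = 5),
#'                               effects = c(air = 0, lps = 2, smoke = 4, lps_smoke = 2),
#'                               seed = 3)
#' ncol(st$exprs)  # 22 samples
#' @export
generate_multicondition <- function(signature,
                                    groups = c(air = 6, lps = 5,
                                               smoke = 6, lps_smoke = 5),
                                    effects = c(air = 0, lps = 2,
                                                smoke = 4, lps_smoke = 2),
                                    universe_size = 2000,
                                    noise_sd = 0.25, baseline_mean = 8.0,
                                    seed = NULL) {
  if (length(groups) < 2) stopf("need at least 2 exposure groups")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stopf("group labels must be unique and named")
  signature <- unique(as.character(signature))
  if (universe_size < length(signature))
    stopf("universe_size smaller than the signature")
  with_seed(seed, {
    cond <- names(groups)
    if (is.matrix(effects)) {
      if (!all(dim(effects) == c(length(signature), length(groups))))
        stopf("effects matrix must be length(signature) x length(groups)")
      eff <- effects
      dimnames(eff) <- list(signature, cond)
    } else {
      if (is.null(names(effects))) names(effects) <- cond
      if (!setequal(names(effects), cond))
        stopf("effects names must match group labels")
      eff <- vapply(cond, function(cn) {
        mag <- effects[[cn]]
        if (mag == 0) rep(0, length(signature))
        else mag * sample(c(-1, 1), length(signature), replace = TRUE)
      }, numeric(length(signature)))
      dimnames(eff) <- list(signature, cond)
    }
    n_extra <- universe_size - length(signature)
    extra <- if (n_extra > 0) sprintf("Bg%05d", seq_len(n_extra)) else character(0)
    genes <- c(signature, extra)
    probe_id <- paste0(genes, "_p1")
    gene_base <- baseline_mean + stats::rnorm(length(genes), 0, 1.5)

    glab <- rep(cond, times = groups)
    samples <- sprintf("mc_s%02d", seq_along(glab))
    mu <- matrix(gene_base, length(genes), length(glab))
    for (cn in cond) {
      cols <- glab == cn
      mu[seq_along(signature), cols] <- mu[seq_along(signature), cols] + eff[, cn]
    }
    m <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))
    dimnames(m) <- list(probe_id, samples)
    pm <- data.frame(probe_id = probe_id, gene_symbol = genes,
                     entrez_id = NA_integer_, stringsAsFactors = FALSE)
    st <- expression_study(m, stats::setNames(glab, samples), pm,
                           "multiexposure")
    attr(st, "truth") <- eff
    st
  })
}

#' Generate a synthetic pathway collection
#'
#' Random gene sets drawn from a universe, optionally with planted pathways
#' sharing a controlled fraction of their members with a source set (e.g. a
#' DE signature), standing in for curated collections such as KEGG,
#' WikiPathways, Reactome and NetPath.
#'
#' @param universe Character vector of gene IDs to draw from.
#' @param n_pathways Number of random pathways.
#' @param size_range Integer range `c(min, max)` of pathway sizes.
#' @param planted Optional list of planted pathways, each
#'   `list(name =, source =, overlap_frac =)`: the planted set has the size
#'   of its (universe-restricted) source set, takes
#'   `round(overlap_frac * size)` members from `source` and the rest from
#'   the remaining universe.
#' @param seed RNG seed.
#' @return Named list of gene sets (write with [write_gmt()]).
#' @export
generate_pathway_db <- function(universe, n_pathways = 50,
                                size_range = c(10, 100), planted = list(),
                                seed = NULL) {
  universe <- unique(as.character(universe))
  size_range <- as.integer(size_range)
  if (n_pathways > 0 && (size_range[1] < 1 || size_range[2] > length(universe)))
    stopf("size_range must lie within [1, |universe|]")
  with_seed(seed, {
    sets <- list()
    if (n_pathways > 0) {
      sizes <- if (size_range[1] == size_range[2]) rep(size_range[1], n_pathways)
      else sample(seq(size_range[1], size_range[2]), n_pathways, replace = TRUE)
      sets <- lapply(sizes, function(sz) sample(universe, sz))
      names(sets) <- sprintf("RANDOM_PATHWAY_%03d", seq_len(n_pathways))
    }
    for (p in planted) {
      if (is.null(p$overlap_frac) || p$overlap_frac < 0 || p$overlap_frac > 1)
        stopf("planted overlap_frac must be in [0, 1]")
      src <- intersect(as.character(p$source), universe)
      size <- length(src)
      n_in <- min(round(p$overlap_frac * size), length(src))
      members <- c(sample(src, n_in),
                   sample(setdiff(universe, src), size - n_in))
      sets[[p$name]] <- members
    }
    sets
  })
}

#' Write a simulated multi-study data set to disk
#'
#' Per-study expression/metadata/probe-map TSVs plus `ground_truth.json`.
#'
#' @param sim Result of [generate_multistudy()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in sim$studies) write_study(st, dir)
  truth <- unclass(sim$truth)
  truth$master_annotation <- NULL
  truth$signature_direction <- as.list(truth$signature_direction)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
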