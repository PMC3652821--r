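# Synthetic multi-study generator: feasibility checks, determinism, planted
# structure.

test_that("infeasible or invalid configs are rejected with the violated bound", {
  expect_error(sim_config(genes_master = 100, universe_frac = 0.5,
                          signature_size = 80),
               "signature_size")
  expect_error(sim_config(n_studies = 3, genes_master = 1000,
                          universe_frac = 0.4, signature_size = 100),
               "universe_frac\\^")
  expect_error(sim_config(universe_frac = 0), "universe_frac")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(n_per_group = 0), "counts")
})

test_that("same seed and config give identical studies and identical files", {
  cfg <- sim_config(genes_master = 200, n_studies = 2, signature_size = 15,
                    private_de_per_study = 10, n_per_group = 4, seed = 11)
  s1 <- generate_multistudy(cfg)
  s2 <- generate_multistudy(cfg)
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("signature genes are forced onto every platform and survive the intersection", {
  cfg <- sim_config(n_studies = 3, genes_master = 2000, universe_frac = 0.7,
                    signature_size = 100, seed = 7)
  sim <- generate_multistudy(cfg)
  inter <- Reduce(intersect, sim$truth$per_study_universe)
  expect_gte(length(inter), 100)
  expect_true(all(sim$truth$signature_genes %in% inter))
  for (uni in sim$truth$per_study_universe) {
    expect_length(uni, round(0.7 * 2000))
    expect_true(all(sim$truth$signature_genes %in% uni))
  }
  # private DE sets are disjoint from the signature
  for (pv in sim$truth$per_study_private_de)
    expect_length(intersect(pv, sim$truth$signature_genes), 0)
})

test_that("planted exposed-vs-control shift matches effect_size * noise_sd in expectation", {
  cfg <- sim_config(n_studies = 1, genes_master = 400, universe_frac = 1,
                    signature_size = 80, private_de_per_study = 0,
                    n_per_group = 6, effect_size = 2, noise_sd = 0.5, seed = 3)
  sim <- generate_multistudy(cfg)
  st <- sim$studies[[1]]
  keys <- gene_key(st$probe_map)
  sig_probes <- names(keys)[keys %in% sim$truth$signature_genes]
  dirs <- sim$truth$signature_direction[keys[sig_probes]]
  diff <- rowMeans(st$exprs[sig_probes, st$groups == "exposed"]) -
    rowMeans(st$exprs[sig_probes, st$groups == "control"])
  observed <- mean(diff * dirs)
  expected <- 2 * 0.5
  se <- 0.5 * sqrt(1 / 6 + 1 / 6) / sqrt(length(sig_probes))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("multi-condition study emits the requested design", {
  st <- generate_multicondition(paste0("Gs", 1:30), universe_size = 100,
                                seed = 5)
  expect_equal(ncol(st$exprs), 22)  # 6 + 5 + 6 + 5
  expect_equal(as.vector(table(st$groups)[c("air", "lps", "smoke", "lps_smoke")]),
               c(6, 5, 6, 5))
  expect_error(generate_multicondition(paste0("Gs", 1:30),
                                       groups = c(a = 3, a = 3)),
               "unique")
  expect_error(generate_multicondition(paste0("Gs", 1:30),
                                       groups = c(a = 5)),
               "2 exposure groups")
  # all-zero effects plant no structure
  st0 <- generate_multicondition(paste0("Gs", 1:30), universe_size = 100,
                                 effects = c(air = 0, lps = 0, smoke = 0,
                                             lps_smoke = 0), seed = 5)
  expect_true(all(attr(st0, "truth") == 0))
  # explicit effect matrices are honored
  eff <- matrix(1, 30, 4, dimnames = list(paste0("Gs", 1:30),
                                          c("air", "lps", "smoke", "lps_smoke")))
  stm <- generate_multicondition(paste0("Gs", 1:30), universe_size = 100,
                                 effects = eff, seed = 5)
  expect_equal(attr(stm, "truth"), eff)
})

test_that("equal-magnitude conditions still get distinct expression patterns", {
  st <- generate_multicondition(paste0("Gs", 1:50), universe_size = 200,
                                seed = 9)
  eff <- attr(st, "truth")
  expect_false(identical(eff[, "lps"], eff[, "lps_smoke"]))
  expect_true(all(abs(eff[, "lps"]) == 2) && all(abs(eff[, "lps_smoke"]) == 2))
})

test_that("pathway generator respects sizes, planting and GMT round-trip", {
  uni <- sprintf("u%03d", 1:200)
  expect_length(generate_pathway_db(uni, n_pathways = 0), 0)
  db <- generate_pathway_db(uni, n_pathways = 5, size_range = c(10, 10),
                            seed = 2)
  expect_true(all(lengths(db) == 10))
  src <- uni[1:25]
  db2 <- generate_pathway_db(uni, n_pathways = 3, size_range = c(5, 20),
                             planted = list(list(name = "HIT", source = src,
                                                 overlap_frac = 1.0)),
                             seed = 2)
  expect_true(all(db2$HIT %in% src))
  expect_error(generate_pathway_db(uni, planted = list(
    list(name = "X", source = src, overlap_frac = 1.5)), seed = 1),
    "overlap_frac")
  gmt_path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db2, gmt_path)
  back <- read_gmt(gmt_path)
  expect_equal(back[order(names(back))],
               lapply(db2, as.character)[order(names(db2))])
})
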