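# Gene centering, sample clustering, consensus clustering and the
# random-signature baseline.

test_that("gene centering zeroes every row mean and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  out <- center_genes(m)
  expect_equal(out["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(out["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_equal(center_genes(out), out)
})

test_that("sample clustering separates planted groups and enforces preconditions", {
  set.seed(2)
  # two groups with opposite gene-expression patterns (correlation distance
  # is location-invariant, so the structure must live in the profiles)
  m <- matrix(rnorm(50 * 8, 0, 0.05), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  m[1:25, 1:4] <- m[1:25, 1:4] + 4
  m[26:50, 5:8] <- m[26:50, 5:8] + 4
  part <- cluster_samples(m, k = 2)
  expect_equal(length(unique(part[1:4])), 1)
  expect_equal(length(unique(part[5:8])), 1)
  expect_false(part[1] == part[5])
  # k = number of samples: singletons
  expect_equal(sort(unname(cluster_samples(m, k = 8))), 1:8)
  expect_error(cluster_samples(m, k = 9), "exceeds")
  m0 <- m; m0[, 3] <- 7
  expect_error(cluster_samples(m0, k = 2), "s3")
})

test_that("4-condition synthetic study is perfectly recovered at k = 4", {
  st <- generate_multicondition(paste0("Gs", 1:60), universe_size = 300,
                                noise_sd = 0.1, seed = 6)
  gm <- collapse_probes(st)
  part <- cluster_samples(center_genes(gm[paste0("Gs", 1:60), ]), k = 4)
  expect_equal(mclust::adjustedRandIndex(part, st$groups), 1)
})

test_that("consensus matrix is well-formed, deterministic and order-equivariant", {
  st <- generate_multicondition(paste0("Gs", 1:40), universe_size = 200,
                                noise_sd = 0.5, seed = 8)
  gm <- collapse_probes(st)
  sig <- paste0("Gs", 1:40)
  c1 <- consensus_cluster(gm, st$groups, sig, reps = 60, seed = 5)
  c2 <- consensus_cluster(gm, st$groups, sig, reps = 60, seed = 5)
  expect_identical(c1$consensus_matrix, c2$consensus_matrix)
  expect_identical(c1$signature_accuracy, c2$signature_accuracy)
  cm <- c1$consensus_matrix
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_true(all(cm >= 0 & cm <= 1))
  # permuting samples permutes the consensus matrix identically
  perm <- sample(ncol(gm))
  c3 <- consensus_cluster(gm[, perm], st$groups[perm], sig, reps = 60, seed = 5)
  expect_equal(c3$consensus_matrix[colnames(gm), colnames(gm)], cm)
})

test_that("without subsampling randomness the consensus is binary", {
  st <- generate_multicondition(paste0("Gs", 1:30), universe_size = 100,
                                noise_sd = 0.3, seed = 4)
  gm <- collapse_probes(st)
  cc <- consensus_cluster(gm, st$groups, paste0("Gs", 1:30), frac = 1.0,
                          reps = 25, seed = 9)
  expect_true(all(cc$consensus_matrix %in% c(0, 1)))
  expect_true(cc$signature_accuracy %in% c(0, 1))
})

test_that("clean separation yields accuracy 1 and zero between-group consensus", {
  st <- generate_multicondition(paste0("Gs", 1:50), universe_size = 200,
                                noise_sd = 0.05, seed = 2)
  gm <- collapse_probes(st)
  cc <- consensus_cluster(gm, st$groups, paste0("Gs", 1:50), reps = 100,
                          seed = 3)
  expect_equal(cc$signature_accuracy, 1.0)
  expect_equal(cc$mean_between_consensus, 0)
})

test_that("stronger planted effects never degrade median consensus accuracy", {
  acc_at_effect <- function(scale) {
    med <- vapply(1:3, function(s) {
      st <- generate_multicondition(
        paste0("Gs", 1:40), universe_size = 150,
        effects = c(air = 0, lps = 1, smoke = 2, lps_smoke = 1) * scale,
        noise_sd = 1.0, seed = 100 + s)
      gm <- collapse_probes(st)
      consensus_cluster(gm, st$groups, paste0("Gs", 1:40), reps = 40,
                        seed = 200 + s)$signature_accuracy
    }, numeric(1))
    median(med)
  }
  accs <- vapply(c(0.5, 1.5, 3), acc_at_effect, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("random-signature baseline matches its degenerate and directional cases", {
  st <- generate_multicondition(paste0("Gs", 1:40), universe_size = 150,
                                noise_sd = 0.8, seed = 13)
  gm <- collapse_probes(st)
  # size = full universe, no subsampling: every evaluation is identical
  bl_full <- random_signature_baseline(gm, st$groups, size = nrow(gm),
                                       n_signatures = 8, frac = 1.0,
                                       reps_per_signature = 15, seed = 3)
  expect_equal(length(unique(bl_full$accuracies)), 1)
  expect_error(random_signature_baseline(gm, st$groups, size = nrow(gm) + 1,
                                         n_signatures = 2,
                                         reps_per_signature = 5, seed = 1),
               "exceeds")
  # structure confined to the signature: the true signature must beat random
  cc <- consensus_cluster(gm, st$groups, paste0("Gs", 1:40), reps = 100,
                          seed = 21)
  bl <- random_signature_baseline(gm, st$groups, size = 40, n_signatures = 40,
                                  reps_per_signature = 20, seed = 22)
  expect_gt(cc$signature_accuracy, bl$mean_baseline)
})

test_that("fold-change table recovers planted shifts and drops absent genes", {
  sig <- paste0("Gs", 1:50)
  eff <- cbind(air = 0, lps = 2, smoke = -1, lps_smoke = 0.5)
  eff <- matrix(rep(t(eff), 50), ncol = 4, byrow = TRUE,
                dimnames = list(sig, colnames(eff)))
  st <- generate_multicondition(sig, universe_size = 120, effects = eff,
                                noise_sd = 0.2, seed = 19)
  gm <- collapse_probes(st)
  fc <- fold_change_table(gm, st$groups, sig, reference = "air")
  expect_setequal(colnames(fc), c("lps", "smoke", "lps_smoke"))
  se <- 0.2 * sqrt(1 / 5 + 1 / 6)
  expect_true(all(abs(fc[, "lps"] - 2) < 3 * se + 0.2))
  expect_lt(abs(mean(fc[, "lps"]) - 2), 3 * se / sqrt(50))
  expect_warning(fc2 <- fold_change_table(gm, st$groups, c(sig, "Ghost"),
                                          reference = "air"), "dropped")
  expect_false("Ghost" %in% rownames(fc2))
  expect_error(fold_change_table(gm, st$groups, sig, reference = "vacuum"),
               "not present")
})
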