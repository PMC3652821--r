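# Common background, intersection signature, 2-way and 3-way overlap tests.

test_that("common background is the exact universe intersection", {
  expect_equal(build_common_background(list(c("A", "B", "C"),
                                            c("B", "C", "D"),
                                            c("C", "E"))), "C")
  u <- c("x", "y", "z")
  expect_setequal(build_common_background(list(u, u)), u)
  expect_error(build_common_background(list(c("A"), c("B"))), "empty")
  expect_error(build_common_background(list(c("A"))), ">= 2")
})

test_that("intersection signature honors background restriction and edge cases", {
  bg <- c("A", "B", "C", "D")
  sig <- intersect_signature(list(s1 = c("A", "B", "Z"), s2 = c("A", "B", "C")),
                             bg)
  expect_setequal(sig$genes, c("A", "B"))
  expect_false("Z" %in% sig$per_study_called$s1)
  # any empty called set -> empty signature (flagged, not an error)
  wns <- testthat::capture_warnings(
    sig0 <- intersect_signature(list(s1 = character(0), s2 = c("A")), bg))
  expect_match(wns, "no called genes", all = FALSE)
  expect_match(wns, "empty signature", all = FALSE)
  expect_length(sig0$genes, 0)
  # identical called sets -> signature equals them
  sigS <- intersect_signature(list(a = c("C", "A"), b = c("A", "C")), bg)
  expect_equal(sigS$genes, c("A", "C"))
})

test_that("2-way hypergeometric tail matches enumeration and closed forms", {
  expect_equal(hypergeom_overlap_p(4, 2, 2, 2), 1 / 6)
  expect_equal(hypergeom_overlap_p(10, 3, 4, 0), 1)
  expect_warning(p <- hypergeom_overlap_p(10, 3, 4, 5), "impossible")
  expect_equal(p, 0)
  # identical called sets of size k: p = 1/choose(N, k)
  for (k in c(2, 5)) expect_equal(hypergeom_overlap_p(12, k, k, k),
                                  1 / choose(12, k))
  # tail is non-increasing in t
  ps <- vapply(0:4, function(t) hypergeom_overlap_p(20, 6, 4, t), numeric(1))
  expect_true(all(diff(ps) <= 0))
  # spot-check against the exhaustive subset oracle
  for (N in c(5, 8)) for (a in c(2, 4)) for (b in c(3, 5))
    for (t in 0:min(a, b))
      expect_equal(hypergeom_overlap_p(N, a, b, t), enum_overlap_tail(N, a, b, t),
                   tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(4, 2, 2, 2, log10p = TRUE), log10(1 / 6))
})

test_that("3-way exact tail matches enumeration, reduces to 2-way, and is symmetric", {
  expect_equal(threeway_overlap_p(4, 2, 2, 2, 1), 17 / 36)
  expect_equal(threeway_overlap_p(4, 2, 2, 2, 1),
               enum_threeway_tail(4, 2, 2, 2, 1))
  for (t in 0:3)
    expect_equal(threeway_overlap_p(6, 3, 4, 3, t),
                 enum_threeway_tail(6, 3, 4, 3, t), tolerance = 1e-12)
  # third set = whole universe collapses to the 2-way tail
  for (t in 0:3)
    expect_equal(threeway_overlap_p(15, 5, 7, 15, t),
                 hypergeom_overlap_p(15, 5, 7, t), tolerance = 1e-12)
  expect_equal(threeway_overlap_p(9, 4, 5, 2, 0), 1)
  expect_warning(p0 <- threeway_overlap_p(9, 4, 5, 2, 3), "impossible")
  expect_equal(p0, 0)
  # exchangeable in the three set sizes
  combos <- rbind(c(5, 8, 11), c(8, 11, 5), c(11, 5, 8), c(11, 8, 5))
  ps <- apply(combos, 1, function(x)
    threeway_overlap_p(30, x[1], x[2], x[3], 3))
  expect_true(all(abs(ps - ps[1]) < 1e-12))
})

test_that("overlap report covers all pairs plus the 3-way test and respects backgrounds", {
  bg <- sprintf("g%02d", 1:40)
  u1 <- bg; u2 <- c(bg, "extra1"); u3 <- bg[1:35]
  common <- build_common_background(list(u1, u2, u3))
  called <- list(s1 = bg[1:10], s2 = bg[3:14], s3 = bg[5:20])
  sig <- intersect_signature(called, common)
  rep_pw <- overlap_report(sig, universes = list(s1 = u1, s2 = u2, s3 = u3))
  expect_length(rep_pw$tests, 4)  # 3 pairs + 3-way
  expect_equal(rep_pw$tests[["3-way"]]$arity, 3L)
  expect_equal(rep_pw$tests[["3-way"]]$observed_t, length(sig$genes))
  expect_equal(rep_pw$tests[["s1 vs s2"]]$universe_N, 40)  # |u1 n u2|
  rep_cm <- overlap_report(sig, background = "common")
  expect_equal(rep_cm$tests[["s1 vs s2"]]$universe_N, length(common))

  # disjoint called sets: t = 0 and p = 1 for every pair
  dis <- suppressWarnings(intersect_signature(list(a = bg[1:5], b = bg[6:10]), bg))
  rd <- overlap_report(dis, background = "common")
  expect_equal(rd$tests[[1]]$observed_t, 0)
  expect_equal(rd$tests[[1]]$p_value, 1)
})

test_that("study order never changes the signature or the 3-way p-value", {
  set.seed(14)
  bg <- sprintf("g%03d", 1:200)
  called <- list(s1 = sample(bg, 60), s2 = sample(bg, 80), s3 = sample(bg, 70))
  base_sig <- intersect_signature(called, bg)
  base_p <- overlap_report(base_sig,
                           background = "common")$tests[["3-way"]]$p_value
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    sig_p <- intersect_signature(called[perm], bg)
    expect_setequal(sig_p$genes, base_sig$genes)
    p <- overlap_report(sig_p, background = "common")$tests[["3-way"]]$p_value
    expect_equal(p, base_p, tolerance = 1e-12)
  }
})

test_that("signature files round-trip with display symbols", {
  bg <- c("eg:1", "eg:2", "S3")
  sig <- intersect_signature(list(a = c("eg:1", "S3"), b = c("eg:1", "S3")), bg)
  rp <- overlap_report(sig, background = "common")
  d <- withr::local_tempdir()
  write_signature(sig, rp, d, symbol_map = c("eg:1" = "Alpha", "eg:2" = "Beta"))
  # keys sort in C collation ("S3" < "eg:1"), then map to display symbols
  expect_equal(readLines(file.path(d, "signature.txt")), c("S3", "Alpha"))
  js <- jsonlite::read_json(file.path(d, "overlap_tests.json"))
  expect_equal(js[[1]]$observed_t, 2)
})
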