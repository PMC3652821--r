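# Independent oracles and fixture builders shared across tests.

# Exhaustive 2-way overlap oracle. By exchangeability, fix A = {1..a} and
# enumerate every size-b subset B of {1..N}; the tail is the fraction of
# subsets with |A intersect B| >= t.
enum_overlap_tail <- function(N, a, b, t) {
  if (t <= 0) return(1)
  if (b == 0 || a == 0) return(0)
  combos <- utils::combn(N, b)
  if (is.null(dim(combos))) combos <- matrix(combos, nrow = b)
  hits <- colSums(combos <= a)
  mean(hits >= t)
}

# Exhaustive 3-way overlap oracle for tiny N: A fixed, all (B, C) pairs.
enum_threeway_tail <- function(N, a, b, c, t) {
  if (t <= 0) return(1)
  A <- seq_len(a)
  subsets <- function(k) {
    if (k == 0) return(list(integer(0)))
    m <- utils::combn(N, k)
    lapply(seq_len(ncol(m)), function(i) m[, i])
  }
  Bs <- subsets(b); Cs <- subsets(c)
  hit <- 0L
  for (B in Bs) for (C in Cs)
    if (length(intersect(intersect(A, B), C)) >= t) hit <- hit + 1L
  hit / (length(Bs) * length(Cs))
}

# Seeded Monte-Carlo draws of the 3-way intersection size (A fixed).
mc_threeway_counts <- function(N, a, b, c, reps, seed) {
  set.seed(seed)
  vapply(seq_len(reps), function(i) {
    B <- sample.int(N, b)
    C <- sample.int(N, c)
    sum(seq_len(a) %in% B & seq_len(a) %in% C)
  }, integer(1))
}

# Small two-group matrix with `n_de` genes shifted by `shift` in group 2.
make_two_group_matrix <- function(n_genes = 300, n_per_group = 6, n_de = 30,
                                  shift = 3, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  m <- matrix(rnorm(n_genes * n, 8, sd), n_genes, n,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  labels <- rep(c("control", "exposed"), each = n_per_group)
  de <- sprintf("g%04d", seq_len(n_de))
  dirs <- rep(c(1, -1), length.out = n_de)
  m[de, labels == "exposed"] <- m[de, labels == "exposed"] + dirs * shift * sd
  list(expr = m, labels = labels, de = de)
}

tiny_study <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(5 * 4, 8), 5, 4,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  pm <- data.frame(probe_id = paste0("p", 1:5),
                   gene_symbol = c("A", "A", "B", "C", "Unmapped"),
                   entrez_id = c(11, 11, 22, NA, NA),
                   stringsAsFactors = FALSE)
  pm$gene_symbol[5] <- NA
  expression_study(m, rep(c("control", "exposed"), each = 2), pm, "tiny")
}
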