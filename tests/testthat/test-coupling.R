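test_that("column entropy matches closed forms", {
  expect_equal(column_entropy(c(4, rep(0, 19))), 0)
  expect_equal(column_entropy(c(2, 2, rep(0, 18))), 1)
  expect_equal(column_entropy(c(1, 1, 1, 1, rep(0, 16))), 2)
  expect_error(column_entropy(rep(0, 20)), "zero")
  expect_error(column_entropy(c(-1, 2)), "non-negative")
})

test_that("joint distributions count pair states and drop gap rows", {
  aln <- aln_from_rows(c("AN", "AN", "RD", "RD"))
  p <- joint_distribution(aln, 1, 2)
  expect_equal(p$support_count, 4L)
  s_an <- 20 * (match("A", aa_alphabet()) - 1) + match("N", aa_alphabet())
  s_rd <- 20 * (match("R", aa_alphabet()) - 1) + match("D", aa_alphabet())
  expect_equal(p$probs[s_an], 0.5)
  expect_equal(p$probs[s_rd], 0.5)
  expect_equal(sum(p$probs), 1)

  gappy <- aln_from_rows(c("AN", "-D", "RD"))
  pg <- joint_distribution(gappy, 1, 2)
  expect_equal(pg$support_count, 2L)
  expect_equal(pg$probs[s_an], 0.5)
  expect_equal(pg$probs[s_rd], 0.5)

  # identical columns live on the diagonal pair states only
  same <- aln_from_rows(c("AA", "CC", "DD", "AA"))
  ps <- joint_distribution(same, 1, 2)
  diag_states <- 20 * (0:19) + 1:20
  expect_equal(sum(ps$probs[diag_states]), 1)
  expect_error(joint_distribution(aln, 2, 2), "distinct")
})

test_that("u_metric hits the exact anchor cases", {
  aln <- function(ci, cj) {
    joint_distribution(aln_from_rows(paste0(ci, cj)), 1, 2)
  }
  # perfect covariation
  expect_equal(u_metric(aln(c("A","A","R","R"), c("N","N","D","D"))), 1)
  # sample independence
  expect_equal(u_metric(aln(c("A","A","R","R"), c("N","D","N","D"))), 0)
  # hand case: H_i = H(3/4, 1/4), H_j = 1, H_ij = 1.5
  hi <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  u_expect <- 2 * (hi + 1 - 1.5) / (hi + 1)
  expect_equal(u_metric(aln(c("A","A","A","R"), c("N","N","D","D"))),
               u_expect, tolerance = 1e-12)
  expect_equal(u_metric(aln(c("A","A","A","R"), c("N","N","D","D"))),
               oracle_u(c("A","A","A","R"), c("N","N","D","D")),
               tolerance = 1e-12)
  # constant columns: 0/0 convention
  expect_equal(u_metric(aln(c("A","A"), c("N","N"))), 0)
})

test_that("U equals the direct-summation oracle on random micro-alignments", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    alphabet <- sample(aa_alphabet(), sample(2:4, 1))
    ci <- sample(alphabet, n, replace = TRUE)
    cj <- sample(alphabet, n, replace = TRUE)
    p <- joint_distribution(aln_from_rows(paste0(ci, cj)), 1, 2)
    expect_equal(u_metric(p), oracle_u(ci, cj), tolerance = 1e-12)
  }
})

test_that("the D(alpha) transform preserves mass and never loses entropy", {
  set.seed(21)
  D <- as_dcm(oracle_random_ds(400, seed = 21))
  # identity matrix, any alpha: q = p exactly
  p <- joint_distribution(
    aln_from_rows(c("AN", "RD", "AN", "WY")), 1, 2)
  q_id <- transform_distribution(p, identity_dcm(), 0.37)
  expect_equal(q_id$probs, p$probs)

  # alpha = 1, point mass on state s: q = column s of the matrix
  s <- 137L
  pm <- pair_distribution(replace(numeric(400), s, 1), 5L)
  q <- transform_distribution(pm, D, 1)
  expect_equal(q$probs, unname(D$values[, s]), tolerance = 1e-12)
  expect_gt(oracle_entropy(q$probs), 0)

  # entropy majorization on random distributions
  for (rep in 1:20) {
    raw <- stats::rexp(400)
    pr <- pair_distribution(raw / sum(raw), 10L)
    alpha <- stats::runif(1, 0.05, 1)
    qr <- transform_distribution(pr, D, alpha)
    expect_equal(sum(qr$probs), 1, tolerance = 1e-12)
    expect_gte(oracle_entropy(qr$probs),
               oracle_entropy(pr$probs) - 1e-12)
  }
  expect_error(transform_distribution(p, D, 0), "alpha")
  expect_error(transform_distribution(p, D, 1.2), "alpha")
})

test_that("UD reduces to U under the identity and fixes the uniform", {
  aln <- aln_from_rows(c("AN", "RD", "AA", "WY", "RD"))
  p <- joint_distribution(aln, 1, 2)
  expect_equal(ud_metric(p, identity_dcm(), 1), u_metric(p))
  expect_equal(ud_metric(p, identity_dcm(), 0.4), u_metric(p))

  unif <- pair_distribution(rep(1 / 400, 400), 400L)
  D <- as_dcm(oracle_random_ds(400, seed = 5))
  expect_equal(ud_metric(unif, D, 1), 0, tolerance = 1e-9)
})

test_that("UD against a brute-force transform on a small fixture", {
  # mass 1/2 on (A,A), 1/2 on (D,R); alpha = 1
  aa <- aa_alphabet()
  s_aa <- 1L
  s_dr <- 20L * (match("D", aa) - 1L) + match("R", aa)
  p <- pair_distribution(
    replace(replace(numeric(400), s_aa, 0.5), s_dr, 0.5), 4L)
  D <- as_dcm(oracle_random_ds(400, seed = 9))
  # independent route: apply the matrix, then direct-summation U
  q <- as.vector(D$values %*% p$probs)
  qm <- matrix(0, 20, 20)
  qm[cbind((seq_len(400) - 1) %/% 20 + 1, (seq_len(400) - 1) %% 20 + 1)] <- q
  hi <- oracle_entropy(rowSums(qm))
  hj <- oracle_entropy(colSums(qm))
  hij <- oracle_entropy(q)
  expect_equal(ud_metric(p, D, 1), 2 * (hi + hj - hij) / (hi + hj),
               tolerance = 1e-12)
})

test_that("all_pair_scores is complete, symmetric and order-invariant", {
  g <- generate_msa(synthetic_spec(
    n_seqs = 40, n_cols = 10, seed = 13,
    coupled_pairs = list(coupled_pair(2, 7, 0.9))))
  aln <- g$alignment
  tab <- all_pair_scores(aln, "U")
  expect_equal(nrow(tab), choose(10, 2))
  expect_true(all(tab$score >= 0 & tab$score <= 1))

  # per-pair consistency with u_metric / joint_distribution
  for (k in sample(nrow(tab), 8)) {
    expect_equal(tab$score[k],
                 u_metric(joint_distribution(aln, tab$i[k], tab$j[k])),
                 tolerance = 1e-12)
  }
  # symmetry: transposing a pair's columns leaves the score unchanged
  k <- 17
  expect_equal(u_metric(joint_distribution(aln, tab$j[k], tab$i[k])),
               tab$score[k], tolerance = 1e-12)

  # permuting sequence order leaves the table unchanged
  set.seed(2)
  perm <- sample(length(aln$rows))
  aln2 <- aln
  aln2$ids <- aln$ids[perm]
  aln2$rows <- aln$rows[perm]
  aln2$ref_index <- match(aln$ref_index, perm)
  tab2 <- all_pair_scores(aln2, "U")
  expect_equal(tab2$score, tab$score)

  expect_error(all_pair_scores(aln, "UD"), "dcm")
  # UD table equals per-pair ud_metric calls
  D <- as_dcm(oracle_random_ds(400, seed = 3))
  tud <- all_pair_scores(aln, "UD", dcm = D, alpha = 0.8)
  for (k in sample(nrow(tud), 5)) {
    expect_equal(tud$score[k],
                 ud_metric(joint_distribution(aln, tud$i[k], tud$j[k]),
                           D, 0.8),
                 tolerance = 1e-12)
  }
})

test_that("pair-score tables serialize with both coordinate systems", {
  g <- generate_msa(synthetic_spec(n_seqs = 30, n_cols = 8, seed = 4))
  aln <- g$alignment
  tab <- all_pair_scores(aln, "U")
  f <- tempfile(fileext = ".tsv")
  write_pair_scores(tab, aln, f)
  df <- read.delim(f)
  expect_equal(nrow(df), nrow(tab))
  expect_named(df, c("col_i", "col_j", "ref_res_i", "ref_res_j", "score"))
})
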