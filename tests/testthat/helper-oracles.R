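# Independent oracles and small fixture builders shared by the tests.
# The oracles deliberately avoid the package's own code paths: direct
# summation over observed states via table(), no 400-state encoding.

# alignment from plain character rows
aln_from_rows <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  f <- tempfile(fileext = ".fasta")
  writeLines(rbind(paste0(">", ids), rows), f)
  read_msa(f)
}

# direct-summation normalized mutual information of two residue vectors
# (characters; rows with a gap in either column are dropped)
oracle_u <- function(ci, cj) {
  ok <- ci != "-" & cj != "-"
  ci <- ci[ok]; cj <- cj[ok]
  if (length(ci) == 0) return(0)
  ent <- function(x) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log2(p))
  }
  hi <- ent(ci); hj <- ent(cj)
  if (hi + hj == 0) return(0)
  hij <- ent(paste(ci, cj, sep = "|"))
  2 * (hi + hj - hij) / (hi + hj)
}

# entropy of a probability vector, base 2
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# random doubly stochastic matrix (independent implementation: plain
# alternate normalization of a strictly positive random matrix)
oracle_random_ds <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0.01, 1), n, n)
  for (it in 1:500) {
    A <- A / rowSums(A)
    A <- sweep(A, 2, colSums(A), "/")
    if (max(abs(rowSums(A) - 1), abs(colSums(A) - 1)) < 1e-12) break
  }
  A
}

# wrap a plain matrix as a cmf_dcm without going through training
as_dcm <- function(M, tol = 1e-8) {
  d <- identity_dcm()
  d$values <- M
  d$tolerance <- tol
  d
}

# standard planted-pair benchmark spec used across tests
bench_spec <- function(seed, rho = 0.9, n_pairs = 10,
                       states = "dissimilar") {
  synthetic_spec(
    seed = seed,
    coupled_pairs = plant_coupled_pairs(n_pairs, 120, rho = rho,
                                        states = states,
                                        seed = seed + 500))
}

# recovery / false-positive bookkeeping for one benchmark run
planted_recovery <- function(run, truth) {
  aln <- run$alignment
  sp <- run$u$significant_pairs
  found <- paste(aln$col_map[sp$i], aln$col_map[sp$j])
  planted <- paste(truth$coupled_pairs$col_i, truth$coupled_pairs$col_j)
  list(recovered = mean(planted %in% found),
       n_sig = nrow(sp),
       false_pos = sum(!(found %in% planted)))
}
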