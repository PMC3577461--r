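# Amino-acid alphabet and pair-state index conventions.
#
# All pair statistics live on the 400 ordered amino-acid pair states
# (a, b), indexed as 20 * (idx(a) - 1) + idx(b) with residues in
# alphabetical one-letter order. Every matrix in the package uses this
# convention; it is also written into trained-matrix file headers.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter order. This
#' order fixes the indexing of the 400 ordered pair states used by all
#' pair-distribution and pair-transition matrices.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# residue letter -> 1..20, NA for anything else (incl. gap)
aa_index <- function(x) {
  match(x, aa_alphabet())
}

# (a_idx, b_idx) in 1..20 -> pair-state index in 1..400
pair_state_index <- function(a, b) {
  20L * (a - 1L) + b
}

# pair-state index -> cbind(a_idx, b_idx)
pair_state_residues <- function(s) {
  cbind(a = (s - 1L) %/% 20L + 1L, b = (s - 1L) %% 20L + 1L)
}

#' Pair-state labels
#'
#' Labels for the 400 ordered pair states, in index order, e.g. "AA",
#' "AC", ..., "YY".
#'
#' @return Character vector of length 400.
#' @export
pair_state_labels <- function() {
  aa <- aa_alphabet()
  as.vector(t(outer(aa, aa, paste0)))
}

# package-level cache (BLOSUM62 submatrix, aggregators, dissimilarity mask)
.cmf_cache <- new.env(parent = emptyenv())

# 20x20 BLOSUM62 submatrix in alphabetical order, from Biostrings
blosum62_matrix <- function() {
  if (is.null(.cmf_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa <- aa_alphabet()
    .cmf_cache$blosum62 <- e$BLOSUM62[aa, aa]
  }
  .cmf_cache$blosum62
}

# 400x400 logical: dis[(a,b),(c,d)] <=> B62(a,c) < 0 and B62(b,d) < 0
dissimilar_mask <- function() {
  if (is.null(.cmf_cache$dismask)) {
    neg <- blosum62_matrix() < 0
    J <- matrix(TRUE, 20, 20)
    .cmf_cache$dismask <- kronecker(neg, J) & kronecker(J, neg)
  }
  .cmf_cache$dismask
}

# 20x400 0/1 aggregators mapping a 400-vector to its two marginals
marginal_aggregators <- function() {
  if (is.null(.cmf_cache$aggr)) {
    s <- seq_len(400L)
    res <- pair_state_residues(s)
    A <- matrix(0, 20, 400)
    B <- matrix(0, 20, 400)
    A[cbind(res[, "a"], s)] <- 1
    B[cbind(res[, "b"], s)] <- 1
    .cmf_cache$aggr <- list(first = A, second = B)
  }
  .cmf_cache$aggr
}
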