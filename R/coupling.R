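# Column-pair coupling scores: the normalized mutual-information
# U-metric and its UD(alpha) variant, which transforms the empirical
# pair distribution by D(alpha) = (1 - alpha) I + alpha D_CompMut
# before taking the U-value.

#' Shannon entropy of a residue count vector
#'
#' @param counts Non-negative numeric vector (typically length 20) with
#'   at least one positive entry.
#' @return Entropy in bits; \eqn{0 \log 0 = 0}.
#' @export
#' @examples
#' column_entropy(c(2, 2))      # 1 bit
#' column_entropy(c(1, 1, 1, 1))  # 2 bits
column_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("all counts are zero")
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# entropy of a probability vector (assumed >= 0), 0 log 0 = 0
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Construct a pair distribution over the 400 ordered pair states
#'
#' @param probs Numeric 400-vector, non-negative, summing to 1 (or all
#'   zero when \code{support_count} is 0).
#' @param support_count Number of sequences the distribution was
#'   estimated from (gap-free at both columns).
#' @return An object of class \code{cmf_pair_distribution}.
#' @export
pair_distribution <- function(probs, support_count) {
  probs <- as.numeric(probs)
  if (length(probs) != 400L) stop("probs must have length 400")
  if (any(probs < 0)) stop("probs must be non-negative")
  s <- sum(probs)
  if (support_count == 0L) {
    if (s != 0) stop("support_count 0 requires an all-zero distribution")
  } else if (abs(s - 1) > 1e-9) {
    stop("probs must sum to 1 (got ", format(s), ")")
  }
  structure(list(probs = probs, support_count = as.integer(support_count)),
            class = "cmf_pair_distribution")
}

#' Empirical joint distribution of one column pair
#'
#' Counts ordered residue pairs over the sequences that carry no gap at
#' either column; the resulting 400-vector indexes pair state
#' \eqn{(a, b)} at \eqn{20 (idx(a) - 1) + idx(b)} in alphabetical
#' amino-acid order.
#'
#' @param msa A \code{cmf_alignment}.
#' @param i,j Distinct column indices (positions in \code{msa}).
#' @return A \code{cmf_pair_distribution}.
#' @export
joint_distribution <- function(msa, i, j) {
  stopifnot(inherits(msa, "cmf_alignment"))
  L <- nchar(msa$rows[1L])
  if (i == j) stop("i and j must be distinct columns")
  if (i < 1L || j < 1L || i > L || j > L) stop("column index out of range")
  enc <- encode_alignment(msa)
  joint_from_encoded(enc[, i], enc[, j])
}

joint_from_encoded <- function(ci, cj) {
  ok <- ci > 0L & cj > 0L
  n <- sum(ok)
  if (n == 0L) return(pair_distribution(numeric(400L), 0L))
  tab <- tabulate(pair_state_index(ci[ok], cj[ok]), 400L)
  pair_distribution(tab / n, n)
}

#' Normalized mutual information (U-metric) of a pair distribution
#'
#' \eqn{U = 2 (H_i + H_j - H_{ij}) / (H_i + H_j)}, where \eqn{H_i} and
#' \eqn{H_j} are the entropies of the two marginals of the pair
#' distribution and \eqn{H_{ij}} its joint entropy. Ranges over
#' \eqn{[0, 1]}; defined as 0 when both marginal entropies vanish or the
#' distribution has no support.
#'
#' @param p A \code{cmf_pair_distribution}.
#' @return U score in \eqn{[0, 1]}.
#' @export
u_metric <- function(p) {
  stopifnot(inherits(p, "cmf_pair_distribution"))
  if (p$support_count == 0L) return(0)
  u_from_vector(p$probs)
}

u_from_vector <- function(q) {
  aggr <- marginal_aggregators()
  hi <- entropy_bits(as.vector(aggr$first %*% q))
  hj <- entropy_bits(as.vector(aggr$second %*% q))
  if (hi + hj <= 0) return(0)
  hij <- entropy_bits(q)
  u <- 2 * (hi + hj - hij) / (hi + hj)
  min(max(u, 0), 1)
}

#' Transform a pair distribution by D(alpha)
#'
#' Applies \eqn{q = D(\alpha) p} with
#' \eqn{D(\alpha) = (1 - \alpha) I + \alpha D}, where \eqn{D} is a
#' doubly stochastic 400x400 pair-transition matrix. Because
#' \eqn{D(\alpha)} is doubly stochastic, the transform never decreases
#' entropy and preserves normalization.
#'
#' @param p A \code{cmf_pair_distribution}.
#' @param dcm A \code{cmf_dcm} doubly stochastic matrix (see
#'   [identity_dcm()], [train_dcm()], [read_dcm()]).
#' @param alpha Mixing weight in \eqn{(0, 1]}.
#' @return The transformed \code{cmf_pair_distribution}.
#' @export
transform_distribution <- function(p, dcm, alpha) {
  stopifnot(inherits(p, "cmf_pair_distribution"))
  validate_dcm(dcm)
  check_alpha(alpha)
  if (p$support_count == 0L) return(p)
  q <- (1 - alpha) * p$probs + alpha * as.vector(dcm$values %*% p$probs)
  q <- pmax(q, 0)
  q <- q / sum(q)
  pair_distribution(q, p$support_count)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must be a number in (0, 1]")
  }
  invisible(alpha)
}

#' UD(alpha) coupling score of a pair distribution
#'
#' The U-value of the D(alpha)-transformed pair distribution, with
#' marginals recomputed from the transformed 400-vector.
#'
#' @inheritParams transform_distribution
#' @return UD(alpha) score in \eqn{[0, 1]}.
#' @export
ud_metric <- function(p, dcm, alpha) {
  u_metric(transform_distribution(p, dcm, alpha))
}

#' Coupling scores for all retained column pairs
#'
#' Computes one score per unordered pair of columns of a (filtered)
#' alignment, either the U-metric or the UD(alpha)-metric.
#'
#' @param msa A \code{cmf_alignment} (typically the output of
#'   [filter_alignment()]).
#' @param metric \code{"U"} or \code{"UD"}.
#' @param dcm Doubly stochastic pair-transition matrix; required for
#'   \code{metric = "UD"}.
#' @param alpha Mixing weight in \eqn{(0, 1]} for \code{metric = "UD"}
#'   (default 1).
#' @return A \code{cmf_pair_scores} data frame with columns \code{i},
#'   \code{j} (column indices in \code{msa}, \code{i < j}),
#'   \code{score} and \code{support}; attributes record the metric and
#'   alpha.
#' @export
all_pair_scores <- function(msa, metric = c("U", "UD"), dcm = NULL,
                            alpha = 1) {
  stopifnot(inherits(msa, "cmf_alignment"))
  metric <- match.arg(metric)
  if (metric == "UD") {
    if (is.null(dcm)) stop("metric \"UD\" requires a dcm")
    validate_dcm(dcm)
    check_alpha(alpha)
  }
  enc <- encode_alignment(msa)
  L <- ncol(enc)
  if (L < 2L) stop("need at least two columns to score pairs")
  pairs <- utils::combn(L, 2L)
  npairs <- ncol(pairs)

  P <- matrix(0, 400L, npairs)
  support <- integer(npairs)
  for (k in seq_len(npairs)) {
    ci <- enc[, pairs[1L, k]]
    cj <- enc[, pairs[2L, k]]
    ok <- ci > 0L & cj > 0L
    n <- sum(ok)
    support[k] <- n
    if (n > 0L) {
      P[, k] <- tabulate(pair_state_index(ci[ok], cj[ok]), 400L) / n
    }
  }

  if (metric == "UD") {
    P <- (1 - alpha) * P + alpha * (dcm$values %*% P)
    P <- pmax(P, 0)
    cs <- colSums(P)
    nz <- cs > 0
    P[, nz] <- sweep(P[, nz, drop = FALSE], 2L, cs[nz], "/")
  }

  aggr <- marginal_aggregators()
  HA <- col_entropies(aggr$first %*% P)
  HB <- col_entropies(aggr$second %*% P)
  HIJ <- col_entropies(P)
  denom <- HA + HB
  score <- ifelse(denom > 0, 2 * (denom - HIJ) / denom, 0)
  score <- pmin(pmax(score, 0), 1)
  score[support == 0L] <- 0

  res <- data.frame(i = pairs[1L, ], j = pairs[2L, ],
                    score = score, support = support)
  structure(res, metric = metric,
            alpha = if (metric == "UD") alpha else NA_real_,
            class = c("cmf_pair_scores", "data.frame"))
}

# column-wise entropies (bits) of a non-negative matrix of probabilities
col_entropies <- function(X) {
  X <- pmax(X, 0)
  lg <- X
  pos <- X > 0
  lg[pos] <- log2(X[pos])
  lg[!pos] <- 0
  -colSums(X * lg)
}

#' Write a pair-score table as TSV
#'
#' Coordinates are reported both as original alignment columns and as
#' reference-residue numbers (NA where the reference is gapped).
#'
#' @param scores A \code{cmf_pair_scores} table.
#' @param msa The \code{cmf_alignment} the scores were computed from.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_pair_scores <- function(scores, msa, path) {
  stopifnot(inherits(scores, "cmf_pair_scores"),
            inherits(msa, "cmf_alignment"))
  df <- data.frame(
    col_i = msa$col_map[scores$i], col_j = msa$col_map[scores$j],
    ref_res_i = msa$ref_residue[scores$i],
    ref_res_j = msa$ref_residue[scores$j],
    score = scores$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
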