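# Alignment-specific significance of coupling scores: a beta-distributed
# null F0 fitted by method of moments (mean from all pair scores,
# variance from column-shuffled pairs), p-values X = 1 - F0(score), the
# estimated null fraction gamma-hat, the FDR-controlling threshold tau,
# per-site connectivity degrees and percentile-based site calls.

#' Estimate the null moments of a pair-score distribution
#'
#' The null mean is the sample mean of all scores in the table. The
#' null variance is the sample variance of the scores of \code{nu}
#' column pairs \eqn{(C, D)}: \eqn{C} is drawn (seeded) from the pairs
#' whose score lies in \code{subinterval}, and \eqn{D} is \eqn{C}'s
#' second column with its rows randomly permuted, which destroys any
#' coupling while preserving both marginal compositions.
#'
#' @param msa The filtered \code{cmf_alignment} the scores came from.
#' @param scores A \code{cmf_pair_scores} table.
#' @param nu Number of shuffled pairs (default \code{min(1000, }number
#'   of pairs\code{)}).
#' @param subinterval Score window the sampled pairs are drawn from
#'   (default \code{c(0.2, 0.8)}); if no pair falls inside it, all
#'   pairs are used (with a warning).
#' @param seed Integer seed for the pair draw and the shuffles.
#' @param dcm,alpha If the table is a UD table, the same transform is
#'   applied to the shuffled pairs.
#' @return List with \code{mean}, \code{variance}, \code{nu_used}.
#' @export
estimate_null_moments <- function(msa, scores, nu = NULL,
                                  subinterval = c(0.2, 0.8), seed = 1L,
                                  dcm = NULL, alpha = 1) {
  stopifnot(inherits(msa, "cmf_alignment"),
            inherits(scores, "cmf_pair_scores"))
  npairs <- nrow(scores)
  if (npairs < 2L) stop("need at least two pairs")
  nu <- min(nu %||% 1000L, npairs)
  if (nu < 2L) stop("nu must be at least 2")
  m <- mean(scores$score)

  pool <- which(scores$score >= subinterval[1L] &
                  scores$score <= subinterval[2L])
  if (length(pool) == 0L) {
    warning("no pair score inside the subinterval [",
            subinterval[1L], ", ", subinterval[2L], "]; using all pairs")
    pool <- seq_len(npairs)
  }
  rng <- seeded_sampler(seed)
  take <- if (length(pool) <= nu) pool else rng$sample(pool, nu)

  is_ud <- attr(scores, "metric") == "UD"
  if (is_ud && is.null(dcm)) {
    stop("shuffling a UD table requires the dcm used to build it")
  }
  enc <- encode_alignment(msa)
  shuffled <- vapply(take, function(k) {
    ci <- enc[, scores$i[k]]
    cj <- enc[, scores$j[k]]
    p <- joint_from_encoded(ci, rng$perm(cj))
    if (is_ud) ud_metric(p, dcm, alpha) else u_metric(p)
  }, numeric(1))
  list(mean = m, variance = stats::var(shuffled),
       nu_used = length(take))
}

#' Fit a beta null distribution by method of moments
#'
#' \eqn{k = m(1 - m)/v - 1}, \eqn{a = mk}, \eqn{b = (1 - m)k}; requires
#' the feasibility condition \eqn{v < m(1 - m)}.
#'
#' @param mean Null mean in \eqn{(0, 1)}.
#' @param variance Null variance, positive and below
#'   \code{mean * (1 - mean)}.
#' @param metric_name Label stored with the fit.
#' @return A \code{cmf_beta_null}: list with shapes \code{a}, \code{b}
#'   and the moments they were fitted from.
#' @export
#' @examples
#' fit_beta_moments(0.5, 1 / 12)  # a = b = 1, the uniform distribution
fit_beta_moments <- function(mean, variance, metric_name = "U") {
  if (!(mean > 0 && mean < 1)) stop("mean must lie in (0, 1)")
  if (!(variance > 0)) stop("variance must be positive")
  if (variance >= mean * (1 - mean)) {
    stop("infeasible moments: variance ", format(variance),
         " >= mean*(1-mean) = ", format(mean * (1 - mean)))
  }
  k <- mean * (1 - mean) / variance - 1
  structure(list(a = mean * k, b = (1 - mean) * k,
                 mean = mean, variance = variance,
                 metric_name = metric_name),
            class = "cmf_beta_null")
}

#' @export
print.cmf_beta_null <- function(x, ...) {
  cat(sprintf("Beta null for %s: a = %.4g, b = %.4g (mean %.4g, var %.3g)\n",
              x$metric_name, x$a, x$b, x$mean, x$variance))
  invisible(x)
}

#' Upper-tail p-values of pair scores under the beta null
#'
#' \eqn{p = 1 - F_0(score)}; strictly decreasing in the score.
#'
#' @param scores A \code{cmf_pair_scores} table or numeric vector.
#' @param null A \code{cmf_beta_null}.
#' @return Numeric vector of p-values in \eqn{[0, 1]}.
#' @export
p_values <- function(scores, null) {
  stopifnot(inherits(null, "cmf_beta_null"))
  x <- if (inherits(scores, "cmf_pair_scores")) scores$score else scores
  stats::pbeta(x, null$a, null$b, lower.tail = FALSE)
}

#' Estimate the null fraction gamma-hat of a p-value collection
#'
#' \eqn{\hat\gamma = \#\{p \in [\lambda_1, \lambda_2]\} /
#' (\mu (\lambda_2 - \lambda_1))}, where \eqn{\mu} is the number of
#' p-values. The tuning window defaults to \eqn{[0.25, 0.70]}, where
#' the p-value distributions of both metrics are approximately uniform.
#' The estimate is clipped to \eqn{[1/\mu, 1]} (a warning notes
#' clipping).
#'
#' @param pvalues Numeric vector of p-values.
#' @param lambda1,lambda2 Window bounds, \eqn{0 \le \lambda_1 <
#'   \lambda_2 \le 1}.
#' @return The estimate \eqn{\hat\gamma}.
#' @export
estimate_gamma <- function(pvalues, lambda1 = 0.25, lambda2 = 0.70) {
  if (!(lambda1 >= 0 && lambda2 <= 1 && lambda1 < lambda2)) {
    stop("need 0 <= lambda1 < lambda2 <= 1")
  }
  mu <- length(pvalues)
  if (mu < 1L) stop("no p-values")
  g <- sum(pvalues >= lambda1 & pvalues <= lambda2) /
    (mu * (lambda2 - lambda1))
  if (g < 1 / mu - 1e-9 || g > 1 + 1e-9) {
    warning("gamma-hat ", format(g), " clipped to [1/mu, 1]")
  }
  min(max(g, 1 / mu), 1)
}

#' FDR-controlling p-value threshold tau
#'
#' Scans the observed p-values \eqn{t \le \lambda_1} as candidate
#' thresholds and returns the largest with estimated false discovery
#' rate \eqn{\widehat{FDR}(t) = \hat\gamma \mu t / \#\{p \le t\}} at or
#' below \code{target_fdr}; \eqn{\tau = 0} (no significant pairs) when
#' none qualifies.
#'
#' @param pvalues Numeric vector of p-values.
#' @param gamma_hat Estimated null fraction (see [estimate_gamma()]).
#' @param target_fdr Target false discovery rate in \eqn{(0, 1)}.
#' @param lambda1 Upper bound on the threshold (the gamma window's
#'   lower edge).
#' @return List with \code{tau} and \code{fdr_hat_at_tau}.
#' @export
fdr_threshold <- function(pvalues, gamma_hat, target_fdr,
                          lambda1 = 0.25) {
  if (!(target_fdr > 0 && target_fdr < 1)) {
    stop("target_fdr must lie in (0, 1)")
  }
  mu <- length(pvalues)
  cand <- sort(unique(pvalues[pvalues <= lambda1]))
  if (length(cand) == 0L) return(list(tau = 0, fdr_hat_at_tau = 0))
  counts <- findInterval(cand, sort(pvalues))
  fdr_hat <- gamma_hat * mu * cand / counts
  ok <- which(fdr_hat <= target_fdr)
  if (length(ok) == 0L) return(list(tau = 0, fdr_hat_at_tau = 0))
  k <- max(ok)
  list(tau = cand[k], fdr_hat_at_tau = fdr_hat[k])
}

#' Significant column pairs at threshold tau
#'
#' @param scores A \code{cmf_pair_scores} table.
#' @param pvalues Parallel vector of p-values.
#' @param tau Threshold from [fdr_threshold()]; \code{tau = 0} yields
#'   an empty set.
#' @return Subset of \code{scores} rows (with a \code{p_value} column)
#'   whose p-value is at or below \code{tau}.
#' @export
significant_pairs <- function(scores, pvalues, tau) {
  stopifnot(nrow(scores) == length(pvalues))
  df <- cbind(as.data.frame(scores), p_value = pvalues)
  if (tau <= 0) return(df[integer(0), ])
  df[pvalues <= tau, ]
}

#' Per-site connectivity degrees
#'
#' The connectivity degree of site \eqn{i} is the number of significant
#' pairs containing \eqn{i}.
#'
#' @param sig_pairs Data frame with columns \code{i}, \code{j}
#'   (distinct unordered pairs).
#' @param n_sites Total number of sites (columns) in the alignment.
#' @return Integer vector of length \code{n_sites}.
#' @export
connectivity_degrees <- function(sig_pairs, n_sites) {
  tabulate(c(sig_pairs$i, sig_pairs$j), n_sites)
}

#' Metric-significant sites at a connectivity percentile
#'
#' The degree threshold is the nearest-rank percentile (the
#' \eqn{\lceil q n \rceil}-th order statistic) of the degrees of sites
#' with degree at least 1; sites at or above the threshold are
#' significant (strictly above with \code{strict = TRUE}).
#'
#' @param connectivity Integer vector of per-site degrees.
#' @param percentile Percentile in \eqn{(0, 100)} (default 90).
#' @param strict Use a strict inequality at the threshold.
#' @return List with \code{degree_threshold} (\code{NA} when no site
#'   has positive degree) and \code{sites} (integer site indices).
#' @export
significant_sites <- function(connectivity, percentile = 90,
                              strict = FALSE) {
  if (!(percentile > 0 && percentile < 100)) {
    stop("percentile must lie in (0, 100)")
  }
  d <- connectivity[connectivity >= 1L]
  if (length(d) == 0L) {
    return(list(degree_threshold = NA_real_, sites = integer(0)))
  }
  thr <- sort(d)[ceiling(percentile / 100 * length(d))]
  sites <- if (strict) which(connectivity > thr) else
    which(connectivity >= thr)
  list(degree_threshold = thr, sites = sites)
}

#' Full significance analysis of a pair-score table
#'
#' Runs the null-moment estimation, beta fit, p-values, gamma-hat, tau,
#' significant pairs, connectivity degrees and site calls for one
#' metric on one alignment.
#'
#' @inheritParams estimate_null_moments
#' @param fdr Target false discovery rate in \eqn{(0, 1)}.
#' @param lambda1,lambda2 Gamma-estimation window (defaults 0.25 and
#'   0.70).
#' @param percentile Connectivity percentile for site calls
#'   (default 90).
#' @param strict_percentile Strict inequality at the degree threshold.
#' @return A \code{cmf_significance} with the fitted null, p-values,
#'   \code{gamma_hat}, \code{tau}, \code{fdr_hat_at_tau},
#'   \code{significant_pairs}, \code{connectivity},
#'   \code{degree_threshold} and \code{significant_sites}.
#' @export
significance_analysis <- function(msa, scores, fdr, nu = NULL,
                                  subinterval = c(0.2, 0.8),
                                  lambda1 = 0.25, lambda2 = 0.70,
                                  percentile = 90,
                                  strict_percentile = FALSE,
                                  seed = 1L, dcm = NULL, alpha = 1) {
  if (!(fdr > 0 && fdr < 1)) stop("fdr must lie in (0, 1)")
  mom <- estimate_null_moments(msa, scores, nu = nu,
                               subinterval = subinterval, seed = seed,
                               dcm = dcm, alpha = alpha)
  null <- fit_beta_moments(mom$mean, mom$variance,
                           metric_name = attr(scores, "metric"))
  pv <- p_values(scores, null)
  gamma_hat <- estimate_gamma(pv, lambda1, lambda2)
  thr <- fdr_threshold(pv, gamma_hat, fdr, lambda1)
  sig <- significant_pairs(scores, pv, thr$tau)
  n_sites <- max(scores$j)
  conn <- connectivity_degrees(sig, n_sites)
  sites <- significant_sites(conn, percentile, strict_percentile)
  structure(
    list(metric_name = attr(scores, "metric"),
         alpha = attr(scores, "alpha"),
         null = null, pvalues = pv, gamma_hat = gamma_hat,
         tau = thr$tau, fdr_hat_at_tau = thr$fdr_hat_at_tau,
         significant_pairs = sig, connectivity = conn,
         degree_threshold = sites$degree_threshold,
         significant_sites = sites$sites,
         lambda1 = lambda1, lambda2 = lambda2,
         nu = mom$nu_used, percentile = percentile, seed = seed,
         fdr = fdr),
    class = "cmf_significance")
}

#' @export
print.cmf_significance <- function(x, ...) {
  cat(sprintf("Significance analysis [%s]%s\n", x$metric_name,
              if (!is.na(x$alpha)) sprintf(" (alpha = %g)", x$alpha)
              else ""))
  cat(sprintf("  mu = %d pairs; gamma-hat = %.3f; tau = %.3g; FDRhat(tau) = %.3g\n",
              length(x$pvalues), x$gamma_hat, x$tau, x$fdr_hat_at_tau))
  cat(sprintf("  %d significant pairs; %d significant sites (degree >= %s)\n",
              nrow(x$significant_pairs), length(x$significant_sites),
              format(x$degree_threshold)))
  invisible(x)
}

#' Union of U- and UD-significant sites
#'
#' A site is predicted functionally or structurally important when it
#' is significant under either metric. Sites are reported in
#' reference-residue coordinates where the reference is ungapped, with
#' both connectivity degrees and per-metric flags.
#'
#' @param u_result,ud_result \code{cmf_significance} objects for the
#'   U- and UD-metric on the same filtered alignment.
#' @param msa The filtered \code{cmf_alignment} both were computed on.
#' @return Data frame with columns \code{site} (filtered column
#'   index), \code{original_col}, \code{ref_residue} (\code{NA} where
#'   the reference is gapped), \code{degree_U}, \code{degree_UD},
#'   \code{sig_U}, \code{sig_UD}.
#' @export
cmf_sites <- function(u_result, ud_result, msa) {
  stopifnot(inherits(u_result, "cmf_significance"),
            inherits(ud_result, "cmf_significance"),
            inherits(msa, "cmf_alignment"))
  L <- nchar(msa$rows[1L])
  if (length(u_result$connectivity) > L ||
      length(ud_result$connectivity) > L) {
    stop("significance results do not match the alignment")
  }
  deg_u <- c(u_result$connectivity,
             integer(L - length(u_result$connectivity)))
  deg_ud <- c(ud_result$connectivity,
              integer(L - length(ud_result$connectivity)))
  sites <- sort(union(u_result$significant_sites,
                      ud_result$significant_sites))
  data.frame(
    site = sites,
    original_col = msa$col_map[sites],
    ref_residue = msa$ref_residue[sites],
    degree_U = deg_u[sites],
    degree_UD = deg_ud[sites],
    sig_U = sites %in% u_result$significant_sites,
    sig_UD = sites %in% ud_result$significant_sites)
}
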