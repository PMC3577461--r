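# End-to-end analysis: filter -> score (per metric) -> significance
# (per metric) -> connectivity -> union of site calls, with report
# files mirroring the tool's original service outputs.

#' Run the full compensatory-mutation analysis on one alignment
#'
#' Executes the pre-processing filters, per-metric coupling scores
#' (U and/or UD(alpha)), the per-metric significance analysis, and the
#' union of site calls. Both metric pipelines use the same seed, so
#' with the identity pair-transition matrix the UD results coincide
#' with the U results exactly.
#'
#' @param msa Path to a multiple-FASTA alignment, or a
#'   \code{cmf_alignment}.
#' @param fdr Target false discovery rate in \eqn{(0, 1)}.
#' @param alpha Mixing weight of the pair-transition matrix in
#'   \eqn{(0, 1]} (default 1, the operating point at which the two
#'   site sets best complement each other).
#' @param dcm A \code{cmf_dcm}, a path to a matrix file, or
#'   \code{"identity"} (default).
#' @param metric \code{"both"} (default), \code{"U"} or \code{"UD"}.
#' @param out_dir If non-\code{NULL}, report files are written there:
#'   \code{pairs_U.tsv} / \code{pairs_UD.tsv} (significant pairs),
#'   \code{sites.tsv}, \code{filter_report.tsv}, \code{summary.txt}
#'   and \code{manifest.json}.
#' @param seed Integer seed for the significance shuffles.
#' @param min_id,max_id,max_cons,max_gap,min_depth,strict_depth Filter
#'   thresholds (see [filter_alignment()]).
#' @param lambda1,lambda2,nu,subinterval,percentile,strict_percentile
#'   Significance tunables (see [significance_analysis()]).
#' @return A \code{cmf_run}: list with \code{alignment} (filtered),
#'   \code{filter_report}, \code{u}, \code{ud}
#'   (\code{cmf_significance} or \code{NULL}), \code{sites} (the union
#'   table) and \code{config}.
#' @export
run_cmf <- function(msa, fdr, alpha = 1, dcm = "identity",
                    metric = c("both", "U", "UD"), out_dir = NULL,
                    seed = 1L, min_id = 0.20, max_id = 0.90,
                    max_cons = 0.95, max_gap = 0.25, min_depth = 125L,
                    strict_depth = FALSE, lambda1 = 0.25,
                    lambda2 = 0.70, nu = NULL,
                    subinterval = c(0.2, 0.8), percentile = 90,
                    strict_percentile = FALSE) {
  metric <- match.arg(metric)
  if (!(fdr > 0 && fdr < 1)) stop("fdr must lie in (0, 1)")
  input_path <- NA_character_
  if (is.character(msa)) {
    input_path <- msa
    msa <- read_msa(msa)
  }
  stopifnot(inherits(msa, "cmf_alignment"))

  dcm_label <- "identity"
  if (metric != "U") {
    if (is.character(dcm)) {
      dcm_label <- dcm
      dcm <- if (identical(dcm, "identity")) identity_dcm() else
        read_dcm(dcm)
    } else {
      validate_dcm(dcm)
      dcm_label <- dcm$provenance$source %||% "matrix"
    }
    check_alpha(alpha)
  }

  filt <- filter_alignment(msa, min_id = min_id, max_id = max_id,
                           max_cons = max_cons, max_gap = max_gap,
                           min_depth = min_depth,
                           strict_depth = strict_depth)
  aln <- filt$alignment
  if (nchar(aln$rows[1L]) < 2L) {
    stop("fewer than two columns survive filtering")
  }

  run_one <- function(m) {
    sc <- if (m == "U") all_pair_scores(aln, "U") else
      all_pair_scores(aln, "UD", dcm = dcm, alpha = alpha)
    significance_analysis(
      aln, sc, fdr = fdr, nu = nu, subinterval = subinterval,
      lambda1 = lambda1, lambda2 = lambda2, percentile = percentile,
      strict_percentile = strict_percentile, seed = seed,
      dcm = if (m == "UD") dcm else NULL, alpha = alpha)
  }
  u_res <- if (metric %in% c("both", "U")) run_one("U") else NULL
  ud_res <- if (metric %in% c("both", "UD")) run_one("UD") else NULL

  sites <- if (!is.null(u_res) && !is.null(ud_res)) {
    cmf_sites(u_res, ud_res, aln)
  } else {
    one <- u_res %||% ud_res
    s <- one$significant_sites
    data.frame(site = s, original_col = aln$col_map[s],
               ref_residue = aln$ref_residue[s],
               degree = one$connectivity[s])
  }

  config <- list(input = input_path, fdr = fdr, alpha = alpha,
                 dcm = dcm_label, metric = metric, seed = seed,
                 min_id = min_id, max_id = max_id, max_cons = max_cons,
                 max_gap = max_gap, min_depth = min_depth,
                 strict_depth = strict_depth, lambda1 = lambda1,
                 lambda2 = lambda2, nu = nu, subinterval = subinterval,
                 percentile = percentile,
                 strict_percentile = strict_percentile,
                 package_version = as.character(
                   utils::packageVersion("cmfinder")))
  res <- structure(list(alignment = aln, filter_report = filt$report,
                        u = u_res, ud = ud_res, sites = sites,
                        config = config),
                   class = "cmf_run")
  if (!is.null(out_dir)) write_run_reports(res, out_dir)
  res
}

#' @export
print.cmf_run <- function(x, ...) {
  cat("CMF analysis\n")
  print(x$filter_report)
  if (!is.null(x$u)) print(x$u)
  if (!is.null(x$ud)) print(x$ud)
  cat(sprintf("  predicted important sites: %d\n", nrow(x$sites)))
  invisible(x)
}

sig_pair_table <- function(res, msa) {
  sp <- res$significant_pairs
  data.frame(col_i = msa$col_map[sp$i], col_j = msa$col_map[sp$j],
             ref_res_i = msa$ref_residue[sp$i],
             ref_res_j = msa$ref_residue[sp$j],
             score = sp$score, p_value = sp$p_value,
             metric = res$metric_name)
}

write_run_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- res$alignment
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$u)) tsv(sig_pair_table(res$u, aln), "pairs_U.tsv")
  if (!is.null(res$ud)) tsv(sig_pair_table(res$ud, aln), "pairs_UD.tsv")
  tsv(res$sites, "sites.tsv")
  write_filter_report(res$filter_report,
                      file.path(out_dir, "filter_report.tsv"))

  summ <- c(
    sprintf("kept_sequences\t%d", res$filter_report$n_kept_sequences),
    sprintf("kept_columns\t%d", res$filter_report$n_kept_columns),
    unlist(lapply(list(res$u, res$ud), function(r) {
      if (is.null(r)) return(NULL)
      m <- r$metric_name
      c(sprintf("%s_gamma_hat\t%.6g", m, r$gamma_hat),
        sprintf("%s_tau\t%.6g", m, r$tau),
        sprintf("%s_fdr_hat_at_tau\t%.6g", m, r$fdr_hat_at_tau),
        sprintf("%s_significant_pairs\t%d", m,
                nrow(r$significant_pairs)),
        sprintf("%s_significant_sites\t%d", m,
                length(r$significant_sites)))
    })),
    sprintf("cmf_significant_sites\t%d", nrow(res$sites)))
  writeLines(summ, file.path(out_dir, "summary.txt"))
  jsonlite::write_json(res$config,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Train and persist a pair-transition matrix
#'
#' Thin wrapper over [train_dcm()] + [write_dcm()].
#'
#' @inheritParams train_dcm
#' @param out_path Output matrix file path.
#' @param ... Passed to [train_dcm()].
#' @return The trained \code{cmf_dcm}, invisibly.
#' @export
run_train <- function(corpus_dir, fdr, seed, out_path, ...) {
  dcm <- train_dcm(corpus_dir, fdr = fdr, seed = seed, ...)
  write_dcm(dcm, out_path)
  invisible(dcm)
}
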