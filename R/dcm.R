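# Training of the 400x400 doubly stochastic pair-transition matrix
# D_CompMut from a corpus of alignments, in five phases:
#   1. count pair substitutions in a signal set (significant column
#      pairs) and a null set (random column pairs), BLOSUM-style;
#   2. keep signal counts whose relative frequency beats the null
#      (diagonal entries always kept);
#   3. zero off-diagonal entries that are not formal dissimilar
#      compensatory mutations; normalize to P_CompMut;
#   4. log-odds against the product of marginals (S_CompMut);
#   5. zero negatives and Sinkhorn-normalize to doubly stochastic.

#' BLOSUM62 substitution score of two residues
#'
#' @param a,b Standard amino-acid one-letter codes.
#' @return Integer substitution score (symmetric).
#' @export
#' @examples
#' blosum62_score("A", "A")  # 4
#' blosum62_score("D", "R")  # -2
blosum62_score <- function(a, b) {
  ia <- aa_index(toupper(a))
  ib <- aa_index(toupper(b))
  if (any(is.na(ia)) || any(is.na(ib))) {
    stop("non-standard residue code")
  }
  unname(blosum62_matrix()[cbind(ia, ib)])
}

#' Is a pair-state exchange a formal dissimilar compensatory mutation?
#'
#' A pair \eqn{((a_i, a_j), (a_k, a_l))} of residue-pair states is a
#' formal dissimilar compensatory mutation when both positional
#' BLOSUM62 scores, of \eqn{(a_i, a_k)} and of \eqn{(a_j, a_l)}, are
#' negative.
#'
#' @param p1,p2 Character vectors of length 2: ordered residue pairs.
#' @return Logical.
#' @export
#' @examples
#' is_formal_dissimilar_compensatory(c("D", "R"), c("R", "D"))  # TRUE
#' is_formal_dissimilar_compensatory(c("A", "N"), c("S", "N"))  # FALSE
is_formal_dissimilar_compensatory <- function(p1, p2) {
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  blosum62_score(p1[1L], p2[1L]) < 0 && blosum62_score(p1[2L], p2[2L]) < 0
}

#' Count residue-pair substitutions over column pairs (Phase 1 counts)
#'
#' BLOSUM-style counting lifted to pair states: for every unordered
#' pair of sequences with no gap at either column, one count is added
#' at both ordered entries \eqn{((s_i, s_j), (t_i, t_j))} and
#' \eqn{((t_i, t_j), (s_i, s_j))}, so the result is symmetric.
#'
#' @param msa A filtered \code{cmf_alignment}.
#' @param pairs Two-column integer matrix of column-index pairs
#'   (positions in \code{msa}).
#' @param max_seqs For column pairs with more gap-free sequences than
#'   this, a seeded subsample of rows is used (cost control);
#'   \code{Inf} disables subsampling.
#' @param seed Integer seed for the subsampling.
#' @return A symmetric 400x400 count matrix.
#' @export
count_pair_substitutions <- function(msa, pairs, max_seqs = 300L,
                                     seed = 1L) {
  stopifnot(inherits(msa, "cmf_alignment"))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) stop("no column pairs to count")
  enc <- encode_alignment(msa)
  tabs <- matrix(0, 400L, nrow(pairs))
  rng <- seeded_sampler(seed)
  for (k in seq_len(nrow(pairs))) {
    ci <- enc[, pairs[k, 1L]]
    cj <- enc[, pairs[k, 2L]]
    ok <- which(ci > 0L & cj > 0L)
    if (length(ok) > max_seqs) ok <- rng$sample(ok, max_seqs)
    if (length(ok) < 2L) next
    tabs[, k] <- tabulate(pair_state_index(ci[ok], cj[ok]), 400L)
  }
  # sum over pairs of outer(tab, tab) - diag(tab): ordered pairs of
  # distinct sequences per column pair
  C <- tabs %*% t(tabs)
  diag(C) <- diag(C) - rowSums(tabs)
  C
}

# small closure giving reproducible draws without touching .Random.seed
seeded_sampler <- function(seed) {
  env <- new.env()
  env$state <- NULL
  draw <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    if (is.null(env$state)) set.seed(seed) else {
      assign(".Random.seed", env$state, globalenv())
    }
    res <- expr()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    sample = function(x, size) draw(function() sample(x, size)),
    perm = function(x) draw(function() sample(x, length(x))),
    runif = function(n) draw(function() stats::runif(n))
  )
}

#' Phase 2: keep signal counts that beat the null (C_sig)
#'
#' An entry of the signal count matrix is retained iff it is diagonal
#' (identical pair states) or its relative frequency in \code{c_alt}
#' strictly exceeds its relative frequency in \code{c_null}.
#'
#' @param c_alt,c_null Symmetric 400x400 count matrices from
#'   [count_pair_substitutions()] on the signal and null column-pair
#'   sets.
#' @return The filtered count matrix \code{C_sig}.
#' @export
phase2_signal_counts <- function(c_alt, c_null) {
  stopifnot(all(dim(c_alt) == c(400L, 400L)),
            all(dim(c_null) == c(400L, 400L)))
  if (sum(c_alt) == 0) stop("signal count matrix is all zero")
  if (sum(c_null) == 0) stop("null count matrix is all zero")
  keep <- (c_alt / sum(c_alt)) > (c_null / sum(c_null))
  diag(keep) <- TRUE
  c_alt * keep
}

#' Phase 3: restrict to dissimilar compensatory exchanges
#'
#' Off-diagonal entries of \code{C_sig} that are not formal dissimilar
#' compensatory mutations are zeroed, giving \code{C_CompMut};
#' normalizing by the grand total gives the probability matrix
#' \code{P_CompMut}.
#'
#' @param c_sig Output of [phase2_signal_counts()].
#' @return List with \code{c_compmut} and \code{p_compmut}.
#' @export
phase3_compmut <- function(c_sig) {
  stopifnot(all(dim(c_sig) == c(400L, 400L)))
  keep <- dissimilar_mask()
  diag(keep) <- TRUE
  cc <- c_sig * keep
  tot <- sum(cc)
  if (tot == 0) stop("no compensatory signal in corpus")
  list(c_compmut = cc, p_compmut = cc / tot)
}

#' Phase 4: log-odds matrix S_CompMut
#'
#' \eqn{S(s, t) = \log[P(s, t) / (P^b(s) P^b(t))]} with \eqn{P^b} the
#' marginal of \code{P_CompMut} over the first index (natural log; only
#' the sign matters downstream). Entries with \eqn{P(s, t) = 0} are
#' \code{-Inf} and are zeroed in phase 5.
#'
#' @param p_compmut Normalized matrix from [phase3_compmut()].
#' @return The 400x400 log-odds matrix.
#' @export
phase4_log_odds <- function(p_compmut) {
  stopifnot(all(dim(p_compmut) == c(400L, 400L)))
  if (abs(sum(p_compmut) - 1) > 1e-9) stop("p_compmut must sum to 1")
  pb <- rowSums(p_compmut)
  S <- suppressWarnings(log(p_compmut) - log(pb %o% pb))
  S[p_compmut == 0] <- -Inf
  S
}

#' Phase 5: Sinkhorn scaling to a doubly stochastic matrix
#'
#' Negative entries (and the \code{-Inf} sentinels of phase 4) are set
#' to zero; zero diagonal entries are then repaired with the smallest
#' positive entry of the matrix (identity substitutions are always
#' possible, and a fully positive diagonal with symmetric support
#' guarantees the total support the iteration needs to converge). Then
#' iterated row-column normalization runs until every row and column
#' sum is within \code{tol} of 1. The result is symmetrized as
#' \eqn{(D + D^T)/2} and re-checked against \code{tol}.
#'
#' @param s A square non-negative-after-thresholding matrix (typically
#'   \code{S_CompMut}; any size is accepted, 400x400 in training).
#' @param tol Convergence tolerance on row/column sums (default 1e-8).
#' @param max_iter Maximum Sinkhorn iterations (default 10000).
#' @return A \code{cmf_dcm}: list with \code{values}, \code{tolerance}
#'   (achieved deviation), \code{iterations}, \code{repaired} (indices
#'   of repaired rows/columns) and \code{provenance}.
#' @export
phase5_sinkhorn <- function(s, tol = 1e-8, max_iter = 10000L) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  A <- pmax(s, 0)
  A[!is.finite(A)] <- 0
  if (sum(A) == 0) stop("matrix is all zero after thresholding")
  # A zero diagonal entry can leave the matrix without total support,
  # in which case the iteration cannot converge; identity substitutions
  # are always possible biologically, so zero diagonal entries are
  # repaired with the smallest positive entry (full positive diagonal
  # plus symmetric support guarantees total support).
  repaired <- which(diag(A) == 0)
  if (length(repaired)) {
    A[cbind(repaired, repaired)] <- min(A[A > 0])
    message("phase5_sinkhorn: repaired ", length(repaired),
            " zero diagonal entr", if (length(repaired) == 1L) "y"
            else "ies", " via diagonal injection")
  }
  dev <- function(M) max(abs(rowSums(M) - 1), abs(colSums(M) - 1))
  it <- 0L
  repeat {
    while (dev(A) > tol) {
      it <- it + 1L
      if (it > max_iter) {
        stop("Sinkhorn did not converge in ", max_iter,
             " iterations (achieved tolerance ", format(dev(A)), ")")
      }
      A <- A / rowSums(A)
      A <- sweep(A, 2L, colSums(A), "/")
    }
    A <- (A + t(A)) / 2
    if (dev(A) <= tol) break
  }
  new_dcm(A, tolerance = dev(A), iterations = it, repaired = repaired)
}

new_dcm <- function(values, tolerance, iterations = 0L,
                    repaired = integer(0), provenance = list()) {
  structure(list(values = values, tolerance = tolerance,
                 iterations = iterations, repaired = repaired,
                 provenance = provenance),
            class = "cmf_dcm")
}

#' Validate a doubly stochastic matrix object
#'
#' @param dcm A \code{cmf_dcm}.
#' @param tol Maximum allowed deviation of any row/column sum from 1
#'   (default 1e-8).
#' @return \code{dcm}, invisibly; errors if invalid.
#' @export
validate_dcm <- function(dcm, tol = 1e-8) {
  if (!inherits(dcm, "cmf_dcm")) stop("not a cmf_dcm object")
  v <- dcm$values
  if (!is.matrix(v) || nrow(v) != ncol(v)) stop("dcm values not square")
  if (any(v < 0)) stop("dcm has negative entries")
  d <- max(abs(rowSums(v) - 1), abs(colSums(v) - 1))
  if (d > max(tol, dcm$tolerance %||% tol)) {
    stop("matrix is not doubly stochastic (max row/column deviation ",
         format(d), ")")
  }
  invisible(dcm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The identity pair-transition matrix
#'
#' Under the identity matrix, \code{UD(alpha)} coincides with \code{U}
#' for every alpha.
#'
#' @return A \code{cmf_dcm} wrapping the 400x400 identity.
#' @export
identity_dcm <- function() {
  new_dcm(diag(400L), tolerance = 0,
          provenance = list(source = "identity"))
}

#' @export
print.cmf_dcm <- function(x, ...) {
  cat(sprintf(
    "Doubly stochastic pair-transition matrix: %dx%d, tolerance %.2e\n",
    nrow(x$values), ncol(x$values), x$tolerance))
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance), unlist(x$provenance),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Train the pair-transition matrix D_CompMut from an alignment corpus
#'
#' For every alignment in \code{corpus_dir} (multiple-FASTA), the
#' pre-processing filters, U-scoring and significance analysis are run;
#' the significant column pairs of all alignments form the signal set,
#' and a seeded random draw of non-significant column pairs forms the
#' null set. Pair-substitution counts of the two sets feed the five
#' training phases.
#'
#' @param corpus_dir Directory of aligned multiple-FASTA files
#'   (\code{.fasta}/\code{.fa}).
#' @param fdr Target false discovery rate for the per-alignment
#'   significance calls (default 0.01).
#' @param seed Integer seed; the run is deterministic given it.
#' @param null_per_msa Null-set size per alignment; default
#'   \code{max(}number of signal pairs\code{, 50)}, capped at the number
#'   of available non-signal pairs.
#' @param max_seqs Row-subsampling cap for counting (see
#'   [count_pair_substitutions()]).
#' @param min_depth,strict_depth Depth filtering: alignments below
#'   \code{min_depth} kept sequences are skipped (training corpora of
#'   small synthetic alignments can lower this).
#' @param iterations Number of training passes; the default single pass
#'   is the standard procedure. Additional passes re-run the
#'   significance step with the UD-metric under the previously trained
#'   matrix before re-counting (experimental hook).
#' @param tol,max_iter Sinkhorn parameters (see [phase5_sinkhorn()]).
#' @param ... Further arguments passed to [significance_analysis()]
#'   (lambda1, lambda2, nu, subinterval, ...).
#' @return A trained \code{cmf_dcm} with provenance (corpus hash, seed,
#'   fdr, number of signal pairs).
#' @export
train_dcm <- function(corpus_dir, fdr = 0.01, seed = 1L,
                      null_per_msa = NULL, max_seqs = 300L,
                      min_depth = 125L, strict_depth = FALSE,
                      iterations = 1L, tol = 1e-8, max_iter = 10000L,
                      ...) {
  files <- sort(list.files(corpus_dir, pattern = "\\.(fa|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files in ", corpus_dir)
  rng <- seeded_sampler(seed)

  dcm_prev <- NULL
  for (pass in seq_len(iterations)) {
    c_alt <- matrix(0, 400L, 400L)
    c_null <- matrix(0, 400L, 400L)
    n_signal <- 0L
    n_msas_used <- 0L
    for (f in files) {
      msa <- read_msa(f)
      filt <- filter_alignment(msa, min_depth = min_depth,
                               strict_depth = strict_depth)
      if (!filt$report$depth_ok && strict_depth) next
      aln <- filt$alignment
      if (nchar(aln$rows[1L]) < 2L) next
      scores <- if (is.null(dcm_prev)) {
        all_pair_scores(aln, metric = "U")
      } else {
        all_pair_scores(aln, metric = "UD", dcm = dcm_prev, alpha = 1)
      }
      sig <- significance_analysis(aln, scores, fdr = fdr,
                                   seed = seed, ...)
      sig_pairs <- sig$significant_pairs
      if (nrow(sig_pairs) == 0L) next
      n_msas_used <- n_msas_used + 1L
      n_signal <- n_signal + nrow(sig_pairs)
      c_alt <- c_alt + count_pair_substitutions(
        aln, as.matrix(sig_pairs[, c("i", "j")]),
        max_seqs = max_seqs, seed = seed)

      # null draw: random retained pairs, signal pairs excluded
      all_idx <- seq_len(nrow(scores))
      sig_idx <- match(paste(sig_pairs$i, sig_pairs$j),
                       paste(scores$i, scores$j))
      pool <- setdiff(all_idx, sig_idx)
      if (length(pool) == 0L) next
      want <- null_per_msa %||% max(nrow(sig_pairs), 50L)
      take <- if (length(pool) <= want) pool else rng$sample(pool, want)
      c_null <- c_null + count_pair_substitutions(
        aln, as.matrix(scores[take, c("i", "j")]),
        max_seqs = max_seqs, seed = seed + 1L)
    }
    if (n_signal == 0L) {
      stop("no significant pairs in corpus; cannot train")
    }
    if (sum(c_null) == 0) stop("empty null set; cannot train")

    c_sig <- phase2_signal_counts(c_alt, c_null)
    ph3 <- phase3_compmut(c_sig)
    s_mat <- phase4_log_odds(ph3$p_compmut)
    dcm <- phase5_sinkhorn(s_mat, tol = tol, max_iter = max_iter)
    dcm_prev <- dcm
  }
  dcm$provenance <- list(
    source = "trained",
    corpus = basename(corpus_dir),
    corpus_hash = corpus_hash(files),
    n_msas = length(files), n_msas_used = n_msas_used,
    n_signal_pairs = n_signal, fdr = fdr, seed = seed,
    passes = iterations)
  dcm
}

corpus_hash <- function(files) {
  h <- tools::md5sum(files)
  substr(tools::md5sum(
    textConnection_file(paste(basename(files), h, collapse = "\n"))), 1, 12)
}

# md5 of a string via a temp file (tools::md5sum wants a path)
textConnection_file <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  f
}

#' Write / read a trained pair-transition matrix
#'
#' Plain-text format: a header block of \code{# key=value} lines
#' (alphabet order, pair-index convention, tolerance, provenance),
#' followed by 400 whitespace-separated rows at full precision. The
#' round trip is lossless and the matrix is re-validated on load.
#'
#' @param dcm A \code{cmf_dcm}.
#' @param path File path.
#' @return \code{write_dcm}: \code{path}, invisibly. \code{read_dcm}:
#'   the validated \code{cmf_dcm}.
#' @export
write_dcm <- function(dcm, path) {
  validate_dcm(dcm)
  hdr <- c(
    "# cmfinder pair-transition matrix",
    paste0("# alphabet=", paste(aa_alphabet(), collapse = "")),
    "# pair_index=20*(idx(a)-1)+idx(b)",
    paste0("# dim=", nrow(dcm$values)),
    paste0("# tolerance=", format(dcm$tolerance, digits = 17)),
    vapply(names(dcm$provenance), function(k) {
      paste0("# ", k, "=", dcm$provenance[[k]])
    }, character(1)))
  rows <- apply(dcm$values, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_dcm
#' @export
read_dcm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- strsplit(hdr[grepl("=", hdr, fixed = TRUE)], "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) paste(x[-1L], collapse = "=")),
    vapply(kv, `[[`, character(1), 1L))
  if (!is.null(meta$alphabet) &&
      meta$alphabet != paste(aa_alphabet(), collapse = "")) {
    stop("matrix file uses a different alphabet order: ", meta$alphabet)
  }
  body <- lines[!is_hdr & nzchar(lines)]
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  d <- length(body)
  if (is.null(meta$dim)) meta$dim <- d
  if (d != as.integer(meta$dim) ||
      any(lengths(vals) != as.integer(meta$dim))) {
    stop("malformed matrix file: expected ", meta$dim, "x", meta$dim)
  }
  M <- do.call(rbind, vals)
  tol <- as.numeric(meta$tolerance %||% 1e-8)
  dcm <- new_dcm(M, tolerance = tol,
                 provenance = meta[setdiff(names(meta),
                                           c("alphabet", "pair_index",
                                             "dim", "tolerance"))])
  validate_dcm(dcm, tol = max(tol, 1e-8))
  dcm
}
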