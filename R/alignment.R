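# Reading, writing and pre-processing of protein multiple sequence
# alignments (multiple-FASTA, gap character '-').

#' Construct an alignment object
#'
#' Internal constructor; users normally obtain alignments from
#' [read_msa()] or [generate_msa()]. Rows are equal-length strings over
#' the 20 standard amino acids plus the gap character \code{-};
#' non-standard residue codes (B, Z, X, U, O, J, \code{*}, \code{.})
#' are normalized to gaps because all pair statistics live on the fixed
#' 400-state pair space.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Character vector of aligned sequences (equal lengths).
#' @param ref_index Index of the reference sequence (default first).
#' @param col_map Integer vector: for each retained column, its 1-based
#'   column index in the original (unfiltered) alignment.
#' @param ref_residue Integer vector parallel to \code{col_map}: the
#'   1-based residue number in the ungapped reference sequence, or
#'   \code{NA} where the reference carries a gap.
#' @return An object of class \code{cmf_alignment}.
#' @keywords internal
new_alignment <- function(ids, rows, ref_index = 1L,
                          col_map = NULL, ref_residue = NULL) {
  ids <- as.character(ids)
  rows <- normalize_residues(toupper(as.character(rows)))
  if (length(ids) != length(rows)) {
    stop("ids and rows must have the same length")
  }
  if (length(rows) == 0L) {
    stop("alignment must contain at least one sequence")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("not aligned: sequences have unequal lengths (",
         paste(range(widths), collapse = "-"), ")")
  }
  if (widths[1L] < 1L) stop("alignment has zero columns")
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_dup")
  }
  if (ref_index < 1L || ref_index > length(rows)) {
    stop("ref_index out of range")
  }
  if (is.null(col_map)) col_map <- seq_len(widths[1L])
  if (is.null(ref_residue)) {
    ref_residue <- reference_numbering(rows[[ref_index]])
  }
  stopifnot(length(col_map) == widths[1L],
            length(ref_residue) == widths[1L],
            !is.unsorted(col_map, strictly = TRUE))
  structure(
    list(ids = ids, rows = rows, ref_index = as.integer(ref_index),
         col_map = as.integer(col_map),
         ref_residue = as.integer(ref_residue)),
    class = "cmf_alignment")
}

# map non-standard residue codes to gap; keep 20 standard letters and '-'
normalize_residues <- function(rows) {
  gsub("[BZXUOJ*.]", "-", rows, perl = TRUE)
}

# 1-based residue numbers of the reference at each column; NA at gaps
reference_numbering <- function(ref_row) {
  ch <- strsplit(ref_row, "", fixed = TRUE)[[1L]]
  isres <- ch != "-"
  num <- cumsum(isres)
  num[!isres] <- NA_integer_
  num
}

#' @export
print.cmf_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[1L])))
  cat(sprintf("  reference: %s (row %d), %d ungapped residues\n",
              x$ids[x$ref_index], x$ref_index,
              max(0L, x$ref_residue, na.rm = TRUE)))
  invisible(x)
}

#' Number of sequences and columns of an alignment
#' @param msa A \code{cmf_alignment}.
#' @return Integer vector \code{c(sequences, columns)}.
#' @export
alignment_dim <- function(msa) {
  stopifnot(inherits(msa, "cmf_alignment"))
  c(sequences = length(msa$rows), columns = nchar(msa$rows[1L]))
}

# integer encoding: n_seqs x n_cols matrix, 1..20 residues, 0 gaps
encode_alignment <- function(msa) {
  stopifnot(inherits(msa, "cmf_alignment"))
  ch <- matrix(unlist(strsplit(msa$rows, "", fixed = TRUE), use.names = FALSE),
               nrow = length(msa$rows), byrow = TRUE)
  m <- aa_index(ch)
  m[is.na(m)] <- 0L
  dim(m) <- dim(ch)
  m
}

#' Read a protein multiple sequence alignment from multiple-FASTA
#'
#' Sequences are upper-cased and non-standard residue codes are mapped
#' to gaps. The first record is taken as the reference sequence, and
#' column-to-reference-residue numbering is derived from it.
#'
#' @param path Path to a multiple-FASTA file of aligned sequences.
#' @return A \code{cmf_alignment}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-D", ">s2", "ACED"), f)
#' read_msa(f)
read_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             " (", conditionMessage(e), ")"))
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aas))
  rows <- as.character(aas)
  new_alignment(ids = ids, rows = rows)
}

#' Write an alignment to multiple-FASTA
#'
#' @param msa A \code{cmf_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "cmf_alignment"))
  out <- character(2L * length(msa$rows))
  out[c(TRUE, FALSE)] <- paste0(">", msa$ids)
  out[c(FALSE, TRUE)] <- msa$rows
  writeLines(out, path)
  invisible(path)
}

#' Fraction of identical residues between two aligned sequences
#'
#' Columns where either sequence carries a gap are excluded from both
#' numerator and denominator; returns 0 when no gap-free column exists.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @return Identity fraction in \eqn{[0, 1]}.
#' @export
#' @examples
#' pairwise_identity("AC-E", "ACDE")  # 1: three comparable columns
#' pairwise_identity("ACDE", "ACDF")  # 0.75
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  ca <- strsplit(normalize_residues(toupper(a)), "", fixed = TRUE)[[1L]]
  cb <- strsplit(normalize_residues(toupper(b)), "", fixed = TRUE)[[1L]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) return(0)
  mean(ca[ok] == cb[ok])
}

# identity on encoded rows (0 = gap)
identity_encoded <- function(a, b) {
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) return(0)
  sum(a[ok] == b[ok]) / n
}

#' Pre-processing filters for an alignment
#'
#' Applies, in order: (1) greedy sequence filtering so that every kept
#' pair of sequences has identity within \code{[min_id, max_id]} (the
#' reference sequence is always kept; a sequence is dropped if its
#' identity to the reference falls below \code{min_id} or its identity
#' to any already-kept sequence exceeds \code{max_id}); (2) removal of
#' conserved columns, i.e. columns whose most frequent residue exceeds
#' \code{max_cons} of the non-gap rows; (3) removal of columns with a
#' gap fraction above \code{max_gap}; (4) a depth check requiring at
#' least \code{min_depth} kept sequences.
#'
#' Coordinate maps (\code{col_map}, \code{ref_residue}) are updated so
#' every retained column remains addressable in original-column and
#' reference-residue space.
#'
#' @param msa A \code{cmf_alignment}.
#' @param min_id,max_id Pairwise identity band for kept sequences
#'   (defaults 0.20 and 0.90, inclusive).
#' @param max_cons Conservation cutoff: columns whose most frequent
#'   residue exceeds this fraction of non-gap rows are removed
#'   (default 0.95).
#' @param max_gap Columns with gap fraction strictly above this are
#'   removed (default 0.25).
#' @param min_depth Minimum number of kept sequences (default 125).
#' @param strict_depth If \code{TRUE}, failing the depth check is an
#'   error; otherwise it is only flagged in the report.
#' @return A list with elements \code{alignment} (the filtered
#'   \code{cmf_alignment}) and \code{report} (a \code{cmf_filter_report}
#'   with removed sequences/columns, reasons, statistics and the
#'   depth flag).
#' @export
filter_alignment <- function(msa, min_id = 0.20, max_id = 0.90,
                             max_cons = 0.95, max_gap = 0.25,
                             min_depth = 125L, strict_depth = FALSE) {
  stopifnot(inherits(msa, "cmf_alignment"))
  enc <- encode_alignment(msa)
  n <- nrow(enc)

  # (1) greedy sequence filter, reference first, then file order
  order_idx <- c(msa$ref_index, setdiff(seq_len(n), msa$ref_index))
  kept <- msa$ref_index
  removed_seq <- data.frame(id = character(), reason = character(),
                            statistic = numeric(), stringsAsFactors = FALSE)
  for (s in order_idx[-1L]) {
    id_ref <- identity_encoded(enc[s, ], enc[msa$ref_index, ])
    if (id_ref < min_id) {
      removed_seq <- rbind(removed_seq, data.frame(
        id = msa$ids[s], reason = "too-dissimilar", statistic = id_ref))
      next
    }
    ids_kept <- vapply(kept, function(t) identity_encoded(enc[s, ], enc[t, ]),
                       numeric(1))
    if (any(ids_kept > max_id)) {
      removed_seq <- rbind(removed_seq, data.frame(
        id = msa$ids[s], reason = "too-similar", statistic = max(ids_kept)))
      next
    }
    kept <- c(kept, s)
  }
  kept <- sort(kept)
  enc2 <- enc[kept, , drop = FALSE]

  # (2) conserved columns: most frequent residue among non-gap rows
  cons_frac <- apply(enc2, 2L, function(col) {
    col <- col[col > 0L]
    if (length(col) == 0L) return(1)
    max(tabulate(col, 20L)) / length(col)
  })
  conserved <- which(cons_frac > max_cons)

  # (3) gapped columns among the remainder
  gap_frac <- colMeans(enc2 == 0L)
  gapped <- setdiff(which(gap_frac > max_gap), conserved)

  removed_cols <- rbind(
    if (length(conserved)) data.frame(column = msa$col_map[conserved],
                                      reason = "conserved",
                                      statistic = cons_frac[conserved]),
    if (length(gapped)) data.frame(column = msa$col_map[gapped],
                                   reason = "gapped",
                                   statistic = gap_frac[gapped]))
  if (is.null(removed_cols)) {
    removed_cols <- data.frame(column = integer(), reason = character(),
                               statistic = numeric())
  }
  keep_cols <- setdiff(seq_len(ncol(enc2)), c(conserved, gapped))

  rows_new <- vapply(msa$rows[kept], function(r) {
    paste(strsplit(r, "", fixed = TRUE)[[1L]][keep_cols], collapse = "")
  }, character(1), USE.NAMES = FALSE)

  depth_ok <- length(kept) >= min_depth
  if (!depth_ok && strict_depth) {
    stop("insufficient depth: ", length(kept), " sequences kept, ",
         min_depth, " required")
  }

  out <- new_alignment(
    ids = msa$ids[kept], rows = rows_new,
    ref_index = match(msa$ref_index, kept),
    col_map = msa$col_map[keep_cols],
    ref_residue = msa$ref_residue[keep_cols])

  report <- structure(
    list(removed_sequences = removed_seq,
         removed_columns = removed_cols,
         depth_ok = depth_ok,
         n_kept_sequences = length(kept),
         n_kept_columns = length(keep_cols),
         thresholds = list(min_id = min_id, max_id = max_id,
                           max_cons = max_cons, max_gap = max_gap,
                           min_depth = min_depth)),
    class = "cmf_filter_report")
  list(alignment = out, report = report)
}

#' @export
print.cmf_filter_report <- function(x, ...) {
  cat(sprintf(
    "Filter report: kept %d sequences, %d columns (depth %s)\n",
    x$n_kept_sequences, x$n_kept_columns,
    if (x$depth_ok) "ok" else "INSUFFICIENT"))
  if (nrow(x$removed_sequences)) {
    cat("  removed sequences:",
        paste(sprintf("%d %s", table(x$removed_sequences$reason),
                      names(table(x$removed_sequences$reason))),
              collapse = ", "), "\n")
  }
  if (nrow(x$removed_columns)) {
    cat("  removed columns:",
        paste(sprintf("%d %s", table(x$removed_columns$reason),
                      names(table(x$removed_columns$reason))),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a filter report as TSV
#'
#' One row per removed sequence or column with its reason and the
#' statistic that triggered removal.
#'
#' @param report A \code{cmf_filter_report}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "cmf_filter_report"))
  seqs <- report$removed_sequences
  cols <- report$removed_columns
  df <- rbind(
    if (nrow(seqs)) data.frame(item = seqs$id, kind = "sequence",
                               reason = seqs$reason,
                               statistic = seqs$statistic),
    if (nrow(cols)) data.frame(item = as.character(cols$column),
                               kind = "column", reason = cols$reason,
                               statistic = cols$statistic))
  if (is.null(df)) {
    df <- data.frame(item = character(), kind = character(),
                     reason = character(), statistic = numeric())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
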