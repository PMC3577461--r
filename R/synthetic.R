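# Seeded synthetic protein alignments with known coevolving column
# pairs, for benchmarking and training experiments. Background columns
# are drawn independently across sequences from a per-column
# distribution (a consensus residue carried at a fixed weight, the
# remaining mass spread per the background frequency vector);
# phylogenetic redundancy is emulated by near-duplicate rows.

#' Specification of a synthetic alignment
#'
#' @param n_seqs Number of sequences (default 150).
#' @param n_cols Number of columns (default 120).
#' @param coupled_pairs List of coupled-pair descriptors from
#'   [coupled_pair()], or the result of [plant_coupled_pairs()];
#'   default none.
#' @param background Length-20 residue frequency vector (alphabetical
#'   order, sums to 1; default uniform).
#' @param consensus_weight Probability that a background-column cell
#'   carries the column's consensus residue (default 0.55). The
#'   remaining mass follows \code{background}. The default keeps
#'   expected pairwise identities near 0.3, inside the 20--90 percent
#'   band of the pre-processing filters, while leaving columns far from
#'   the 95 percent conservation cutoff.
#' @param duplication_rate Fraction of sequences generated as mutated
#'   copies of earlier rows (phylogenetic redundancy; default 0.2).
#' @param point_mutation_rate Per-site substitution probability applied
#'   to duplicated rows (default 0.15, i.e. about 85 percent identity
#'   to the source row).
#' @param gap_rate Per-cell gap probability (default 0.02).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A \code{cmf_synthetic_spec}.
#' @export
synthetic_spec <- function(n_seqs = 150L, n_cols = 120L,
                           coupled_pairs = list(),
                           background = rep(1 / 20, 20L),
                           consensus_weight = 0.55,
                           duplication_rate = 0.2,
                           point_mutation_rate = 0.15,
                           gap_rate = 0.02, seed = 1L) {
  stopifnot(n_seqs >= 2L, n_cols >= 2L,
            length(background) == 20L, all(background >= 0),
            abs(sum(background) - 1) < 1e-9,
            consensus_weight >= 0, consensus_weight < 1,
            duplication_rate >= 0, duplication_rate < 1,
            point_mutation_rate >= 0, point_mutation_rate <= 1,
            gap_rate >= 0, gap_rate < 1)
  cols_used <- integer(0)
  for (cp in coupled_pairs) {
    stopifnot(inherits(cp, "cmf_coupled_pair"))
    if (cp$i == cp$j || cp$i > n_cols || cp$j > n_cols) {
      stop("coupled pair (", cp$i, ", ", cp$j, ") out of range")
    }
    if (any(c(cp$i, cp$j) %in% cols_used)) {
      stop("column ", intersect(c(cp$i, cp$j), cols_used)[1L],
           " used by more than one coupled pair")
    }
    cols_used <- c(cols_used, cp$i, cp$j)
  }
  structure(list(n_seqs = as.integer(n_seqs),
                 n_cols = as.integer(n_cols),
                 coupled_pairs = coupled_pairs,
                 background = background,
                 consensus_weight = consensus_weight,
                 duplication_rate = duplication_rate,
                 point_mutation_rate = point_mutation_rate,
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "cmf_synthetic_spec")
}

#' Describe one planted coevolving column pair
#'
#' With probability \code{rho} a sequence's residues at columns
#' \code{i} and \code{j} are drawn jointly (uniformly) from
#' \code{states}; otherwise both are drawn independently from the
#' background.
#'
#' @param i,j Distinct column indices.
#' @param rho Coupling strength in \eqn{[0, 1]}.
#' @param states Two-column character matrix of residue-pair states.
#' @return A \code{cmf_coupled_pair}.
#' @export
coupled_pair <- function(i, j, rho,
                         states = rbind(c("D", "R"), c("R", "D"))) {
  states <- matrix(as.character(states), ncol = 2L)
  stopifnot(rho >= 0, rho <= 1, nrow(states) >= 1L,
            all(states %in% aa_alphabet()))
  structure(list(i = as.integer(i), j = as.integer(j), rho = rho,
                 states = states),
            class = "cmf_coupled_pair")
}

#' Draw pair-state sets that are mutually dissimilar-compensatory
#'
#' Returns \code{k} residue-pair states such that every exchange
#' between two of them is a formal dissimilar compensatory mutation
#' (both positional BLOSUM62 scores negative).
#'
#' @param k Number of states (default 2).
#' @param seed Integer seed.
#' @return Two-column character matrix of pair states.
#' @export
random_dissimilar_states <- function(k = 2L, seed = 1L) {
  rng <- seeded_sampler(seed)
  aa <- aa_alphabet()
  neg <- blosum62_matrix() < 0
  for (attempt in 1:1000) {
    idx <- matrix(rng$sample(seq_len(20L * 20L), k), ncol = 1L)
    a <- (idx - 1L) %/% 20L + 1L
    b <- (idx - 1L) %% 20L + 1L
    ok <- TRUE
    if (k >= 2L) {
      for (u in 1:(k - 1L)) for (v in (u + 1L):k) {
        if (!(neg[a[u], a[v]] && neg[b[u], b[v]])) ok <- FALSE
      }
    }
    if (ok) return(cbind(aa[a], aa[b]))
  }
  stop("could not find ", k, " mutually dissimilar pair states")
}

#' Place coupled pairs on random disjoint columns
#'
#' Convenience builder for [synthetic_spec()]: \code{n} coupled pairs
#' at strength \code{rho}, each on a fresh pair of columns with its own
#' seeded dissimilar (or similar) state set.
#'
#' @param n Number of pairs.
#' @param n_cols Number of alignment columns available.
#' @param rho Coupling strength shared by all pairs.
#' @param states \code{"dissimilar"} for BLOSUM62-dissimilar
#'   compensatory state sets, \code{"similar"} for state sets whose
#'   exchanges have non-negative BLOSUM62 scores in at least one
#'   position.
#' @param n_states States per pair (default 2).
#' @param seed Integer seed.
#' @return List of \code{cmf_coupled_pair}, usable as
#'   \code{coupled_pairs} in [synthetic_spec()].
#' @export
plant_coupled_pairs <- function(n, n_cols, rho = 0.9,
                                states = c("dissimilar", "similar"),
                                n_states = 2L, seed = 1L) {
  states <- match.arg(states)
  if (2L * n > n_cols) stop("not enough columns for ", n, " pairs")
  rng <- seeded_sampler(seed)
  cols <- rng$sample(seq_len(n_cols), 2L * n)
  lapply(seq_len(n), function(k) {
    st <- if (states == "dissimilar") {
      random_dissimilar_states(n_states, seed = seed + k)
    } else {
      similar_states(n_states, seed = seed + k)
    }
    coupled_pair(cols[2L * k - 1L], cols[2L * k], rho, st)
  })
}

# k pair states whose mutual exchanges are NOT dissimilar-compensatory
similar_states <- function(k = 2L, seed = 1L) {
  rng <- seeded_sampler(seed)
  aa <- aa_alphabet()
  nonneg <- blosum62_matrix() >= 0
  for (attempt in 1:1000) {
    a <- rng$sample(seq_len(20L), k)
    b <- rng$sample(seq_len(20L), k)
    ok <- TRUE
    if (k >= 2L) {
      for (u in 1:(k - 1L)) for (v in (u + 1L):k) {
        if (!nonneg[a[u], a[v]]) ok <- FALSE
      }
    }
    if (ok) return(cbind(aa[a], aa[b]))
  }
  stop("could not find ", k, " mutually similar pair states")
}

#' Generate a synthetic alignment with ground truth
#'
#' Background cells are drawn independently per column (consensus
#' residue at \code{consensus_weight}, remainder per the background
#' vector); coupled columns follow their [coupled_pair()] descriptors;
#' a \code{duplication_rate} fraction of rows are point-mutated copies
#' of earlier rows; gaps are injected per cell at \code{gap_rate}.
#' Byte-identical output for equal specs.
#'
#' @param spec A \code{cmf_synthetic_spec}.
#' @return List with \code{alignment} (a \code{cmf_alignment}) and
#'   \code{truth} (coupled-pair table in both column coordinates, the
#'   per-sequence lineage, and the per-column generative family).
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "cmf_synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_seqs
  L <- spec$n_cols
  aa <- aa_alphabet()
  coupled_cols <- unlist(lapply(spec$coupled_pairs,
                                function(cp) c(cp$i, cp$j)))
  bg_cols <- setdiff(seq_len(L), coupled_cols)

  consensus <- sample(20L, L, replace = TRUE, prob = spec$background)
  n_dup <- round(n * spec$duplication_rate)
  n_ind <- n - n_dup
  M <- matrix(0L, n, L)

  draw_bg <- function(m) sample(20L, m, replace = TRUE,
                                prob = spec$background)
  # independent rows
  for (s in seq_len(n_ind)) {
    keep <- stats::runif(L) < spec$consensus_weight
    row <- ifelse(keep, consensus, draw_bg(L))
    M[s, ] <- row
  }
  # coupled columns overwrite the background (independent rows only)
  for (cp in spec$coupled_pairs) {
    st_a <- aa_index(cp$states[, 1L])
    st_b <- aa_index(cp$states[, 2L])
    for (s in seq_len(n_ind)) {
      if (stats::runif(1L) < cp$rho) {
        z <- sample.int(nrow(cp$states), 1L)
        M[s, cp$i] <- st_a[z]
        M[s, cp$j] <- st_b[z]
      } else {
        M[s, cp$i] <- draw_bg(1L)
        M[s, cp$j] <- draw_bg(1L)
      }
    }
  }
  # duplicated lineages
  lineage <- integer(n)
  if (n_dup > 0L) {
    for (s in (n_ind + 1L):n) {
      src <- sample.int(s - 1L, 1L)
      lineage[s] <- src
      row <- M[src, ]
      mut <- stats::runif(L) < spec$point_mutation_rate
      row[mut] <- draw_bg(sum(mut))
      M[s, ] <- row
    }
  }
  # gaps
  chars <- matrix(aa[M], n, L)
  if (spec$gap_rate > 0) {
    gap <- matrix(stats::runif(n * L) < spec$gap_rate, n, L)
    chars[gap] <- "-"
  }
  rows <- apply(chars, 1L, paste, collapse = "")
  ids <- sprintf("seq%04d", seq_len(n))
  aln <- new_alignment(ids = ids, rows = rows)

  truth_pairs <- if (length(spec$coupled_pairs)) {
    do.call(rbind, lapply(spec$coupled_pairs, function(cp) {
      data.frame(col_i = min(cp$i, cp$j), col_j = max(cp$i, cp$j),
                 rho = cp$rho,
                 states = paste(paste0(cp$states[, 1L], cp$states[, 2L]),
                                collapse = ","))
    }))
  } else {
    data.frame(col_i = integer(), col_j = integer(), rho = numeric(),
               states = character())
  }
  family <- rep("background", L)
  family[coupled_cols] <- "coupled"
  list(alignment = aln,
       truth = list(coupled_pairs = truth_pairs,
                    column_family = family, lineage = lineage,
                    spec = spec))
}

#' Generate a corpus of synthetic alignments
#'
#' Writes \code{n_msas} seeded variants of \code{spec_template} (fresh
#' coupled-pair placements and state sets per file when
#' \code{replant} is set) as multiple-FASTA plus a tab-separated truth
#' manifest.
#'
#' @param n_msas Number of alignments.
#' @param spec_template A \code{cmf_synthetic_spec} used as template.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; alignment \code{k} uses
#'   \code{seed + k}.
#' @param replant If not \code{NULL}, a list
#'   \code{list(n =, rho =, states =)} passed to
#'   [plant_coupled_pairs()] per alignment, replacing the template's
#'   coupled pairs with per-file placements.
#' @return Invisibly, a data frame manifest (file, col_i, col_j, rho,
#'   states), also written to \code{truth_manifest.tsv} in \code{dir}.
#' @export
generate_corpus <- function(n_msas, spec_template, dir, seed = 1L,
                            replant = NULL) {
  stopifnot(n_msas >= 1L, inherits(spec_template, "cmf_synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (k in seq_len(n_msas)) {
    sp <- spec_template
    sp$seed <- as.integer(seed + k)
    if (!is.null(replant)) {
      sp$coupled_pairs <- plant_coupled_pairs(
        n = replant$n, n_cols = sp$n_cols,
        rho = replant$rho %||% 0.9,
        states = replant$states %||% "dissimilar",
        seed = seed + 1000L * k)
    }
    out <- generate_msa(sp)
    f <- file.path(dir, sprintf("msa_%03d.fasta", k))
    write_msa(out$alignment, f)
    tp <- out$truth$coupled_pairs
    if (nrow(tp)) {
      tp$file <- basename(f)
      manifest[[k]] <- tp[, c("file", "col_i", "col_j", "rho", "states")]
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(file = character(), col_i = integer(), col_j = integer(),
               rho = numeric(), states = character())
  utils::write.table(manifest, file.path(dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
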