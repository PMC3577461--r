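---
title: "Detecting compensatory mutations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting compensatory mutations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `cmfinder`, the
tunable parameters and their defaults, the synthetic benchmark the
package tests itself against, and the design decisions taken where the
procedure leaves genuine freedom.

## The problem

Compensatory mutations — a substitution at one protein site offset by a
substitution at another — leave a statistical footprint: the two
alignment columns covary across the family. Two confounders make naive
mutual information a poor detector. First, columns of a finite
alignment carry a large positive mutual-information bias that depends
on column composition. Second, sequences share ancestry, so unrelated
columns covary through the phylogeny ("phylogenetic noise"). The
package addresses both with an alignment-specific empirical null rather
than bias-correction formulas: the null distribution is fitted to the
very alignment under study, so whatever bias and shared-ancestry signal
its background pairs carry is absorbed into the null.

## Pre-processing

An input alignment (multiple FASTA, gap `-`, first record = reference)
passes four filters, in this order:

1. **Sequence identity band** [20%, 90%] (inclusive): sequences too
   close to an already-kept sequence mostly duplicate phylogenetic
   information; sequences too far from the reference are likely
   misaligned or non-homologous. The scan is greedy in file order with
   the reference always kept: a sequence is dropped when its identity
   to the reference is below 0.20 or its identity to any kept sequence
   exceeds 0.90. Identity counts only columns where neither sequence
   has a gap. The greedy rule is a deliberate choice: it is
   deterministic, order-stable and cheap; a maximum-subset formulation
   would be NP-hard without changing the statistics materially.
2. **Conserved columns**: columns whose most frequent residue exceeds
   95% of the non-gap rows carry almost no entropy and cannot support a
   coupling signal. Gaps are excluded from the denominator because the
   rule concerns identical *residues*.
3. **Gapped columns**: columns with more than 25% gaps (all rows
   counted) are removed; their pair distributions would rest on shifting
   row subsets.
4. **Depth**: at least 125 sequences must remain, otherwise the beta
   null cannot be fitted stably. Below the threshold the run is flagged
   (or aborted in strict mode).

Both boundaries of the identity band are inclusive, and the conserved /
gapped rules use strict inequalities (`> 0.95`, `> 0.25`), so a column
at exactly 95% conservation or exactly 25% gaps is kept. Non-standard
residue codes (B, Z, X, U, O, J, `*`, `.`) are normalized to gaps at
read time: all pair statistics live on a fixed 400-state space of
ordered amino-acid pairs, indexed `20·(idx(a)−1) + idx(b)` in
alphabetical order `ACDEFGHIKLMNPQRSTVWY`.

Every retained column keeps two coordinates: its original column index
and the 1-based residue number in the ungapped reference sequence (`NA`
where the reference is gapped). All reports carry both.

## The U-metric

For retained columns *i*, *j*, rows with a gap at either column are
dropped, the empirical distribution over the 400 ordered pair states is
formed, and

$$U_{i,j} = \frac{2\,(H_i + H_j - H_{i,j})}{H_i + H_j} \in [0,1],$$

with entropies in bits. Two conventions matter:

* **Marginals from the shared support.** \(H_i\) and \(H_j\) are
  computed from the same gap-free row subset as the joint. This
  guarantees \(H_{i,j} \le H_i + H_j\) and hence \(U \ge 0\); mixing
  supports can violate it.
* **Degenerate pairs.** When both marginal entropies vanish (both
  columns constant on the shared support, or no gap-free row exists),
  \(U := 0\). The 0/0 case has no signal to report.

No pseudocounts are added; the empirical distribution enters as is.
The tests verify \(U\) against an independent direct-summation oracle
to \(10^{-12}\) on random micro-alignments.

## The UD(α)-metric

A pair of pair states \(((a_i,a_j),(a_k,a_l))\) is a *formal dissimilar
compensatory mutation* when both positional BLOSUM62 scores,
\(s(a_i,a_k)\) and \(s(a_j,a_l)\), are negative — both sites exchanged
their residue for a biochemically dissimilar one. The trained
400 × 400 doubly stochastic matrix \(D\) concentrates its off-diagonal
mass on such transitions. With

$$D(\alpha) = (1-\alpha)\,I + \alpha D, \qquad \alpha \in (0,1],$$

the UD(α) score of a column pair is the U-value of
\(q = D(\alpha)\,p\), where \(p\) is the pair's empirical 400-vector
and the marginals entering the U formula are recomputed from \(q\).
Recomputing them from the transform is the only reading consistent with
"the U-value of the transform": \(D(\alpha)\) does not preserve the
marginals, so reusing raw-column entropies would mix two different
distributions. Since every doubly stochastic matrix is a convex
combination of permutation matrices, the transform never decreases
entropy (verified as a property test over random distributions and
matrices); the default mixing weight is α = 1, which makes the two
metrics maximally complementary rather than interpolating between
them.

## Training the pair-transition matrix

`train_dcm()` runs five phases over a corpus of alignments:

1. **Counting.** Each corpus alignment is filtered, U-scored and taken
   through the significance analysis below. Its significant pairs form
   the signal set; an equally sized seeded random draw of non-significant
   retained pairs (at least 50 per alignment) forms the null set.
   Counting lifts the classic substitution-matrix scheme to pair
   states: for every unordered pair of gap-free sequences at a column
   pair, one count goes to each of the two ordered entries, so all
   count matrices are symmetric by construction. Null pairs are drawn
   without replacement and exclude signal pairs, keeping the two
   relative-frequency estimates in phase 2 comparable. For column
   pairs with more than 300 usable sequences a seeded row subsample of
   300 caps the quadratic cost; the cap is configurable.
2. **Signal filter.** An entry of the signal count matrix survives iff
   it is diagonal (identical pair states) or its relative frequency
   strictly exceeds that in the null counts.
3. **Dissimilarity mask.** Off-diagonal survivors that are not formal
   dissimilar compensatory mutations are zeroed; the result is
   normalized to a probability matrix \(P\).
4. **Log-odds.** \(S(s,t) = \log\!\big[P(s,t) / (P^b(s)P^b(t))\big]\)
   with \(P^b\) the first-index marginal (natural log — only the sign
   survives phase 5); zero-probability entries become \(-\infty\).
5. **Sinkhorn scaling.** Negative entries are zeroed and iterated
   row/column normalization runs to tolerance \(10^{-8}\) (at most
   10000 iterations), followed by symmetrization \((D + D^T)/2\) and a
   re-check. Convergence requires *total support*; after thresholding
   this can fail even when every row has a positive entry, so every
   zero diagonal entry is first repaired with the smallest positive
   entry of the matrix. The repair is logged; biologically it says
   identity substitutions are never impossible. The 2 × 2 fixture
   `[[1,1],[1,3]]`, whose symmetric scaling has the closed form
   \(d_1^2 = 3 d_2^2\), \(d_1(d_1+d_2) = 1\), pins the implementation
   to the analytic solution in the tests.

Training is deterministic given the seed (same corpus + seed →
byte-identical matrix file). The persisted format is plain text: a
`# key=value` header (alphabet order, pair-index convention, tolerance,
corpus hash, seed, FDR) plus 400 rows at full precision; loading
re-validates double stochasticity. An experimental `iterations`
argument re-runs the significance step under the previously trained
matrix before re-counting; the default of one pass is the standard
procedure, and the loop is a hook, not a convergence claim.

## Significance model

Per metric and alignment, the scores \(U_1,\dots,U_\mu\) of all
retained column pairs are treated as an iid sample from a mixture of a
beta-distributed null \(F_0\) (background and phylogenetic noise) and
non-null components. The workflow:

* **Null moments.** The null mean is the sample mean of *all* pair
  scores (signal pairs are a vanishing fraction, and including them
  errs conservative). The null variance comes from shuffling: ν pairs
  are drawn (seeded) from those whose score lies in a preassigned
  subinterval of score space, each has its second column randomly
  permuted across rows — destroying coupling, preserving both marginal
  compositions — and the sample variance of the re-scored pairs is
  used. Defaults: ν = min(1000, μ), subinterval [0.2, 0.8]; both
  configurable, and if the subinterval is empty all pairs are used
  (with a warning). For a UD table the same transform is applied to
  the shuffled pairs.
* **Beta fit.** Method of moments: \(k = m(1-m)/v - 1\), \(a = mk\),
  \(b = (1-m)k\), requiring \(v < m(1-m)\); an infeasible variance is
  an error, not a silent fallback.
* **p-values.** \(X_\iota = 1 - F_0(U_\iota)\), antitone in the score.
* **Null fraction.** \(\hat\gamma = \#\{p \in [\lambda_1,\lambda_2]\}
  / (\mu(\lambda_2-\lambda_1))\) with \([\lambda_1, \lambda_2] =
  [0.25, 0.70]\), the window where the p-value distributions of both
  metrics are approximately uniform; the estimate is clipped to
  \([1/\mu, 1]\) (a zero \(\hat\gamma\) would zero the FDR estimate).
* **Threshold.** τ is the largest observed p-value \(t \le \lambda_1\)
  with \(\widehat{FDR}(t) = \hat\gamma\,\mu\,t / \#\{p \le t\} \le\)
  the target; scanning observed p-values maximizes the discovery set
  without interpolation, and τ = 0 (no discoveries) when none
  qualifies.
* **Sites.** The connectivity degree of site *i* counts significant
  pairs containing *i*. The degree threshold is the nearest-rank 90th
  percentile (the ⌈0.9 n⌉-th order statistic) of the degrees of sites
  with positive degree — deterministic and interpolation-free; sites
  at or above it are metric-significant. The inequality at the
  threshold is ≥ by default with a strict variant exposed, and the
  percentile is configurable. Zero-degree sites are excluded from the
  percentile so that a sparse discovery set does not drive the
  threshold to zero.
* **Union.** A site is predicted functionally or structurally
  important when it is significant under U or UD(α); reports carry
  per-metric flags and both degrees.

The iid assumption on pair scores is a modeling idealization — pairs
sharing a column are dependent — and no dependence correction is
attempted; the synthetic benchmark below measures what the procedure
actually delivers under that violation.

## The synthetic benchmark

`generate_msa()` emulates the regime the detector targets: alignments
of at least 125 sequences with independent background columns, planted
coevolving column pairs, and shared-ancestry redundancy. Defaults
(150 sequences × 120 columns) and mechanisms:

* **Background columns.** Each column gets a consensus residue (drawn
  from the background frequency vector, default uniform) carried by a
  cell with probability 0.55, the remaining mass following the
  background vector; rows are independent. A fully uniform column
  model would put expected pairwise identity near 1/20 and no sequence
  would survive the 20% identity filter, so the consensus weight is
  the package's choice of a realistic conservation level: it yields
  pairwise identities around 0.3 and column conservation far below the
  95% cutoff.
* **Coupled pairs.** With probability ρ a sequence draws its two
  residues jointly (uniformly) from the pair's state set, else both
  independently from the background. State-set helpers provide
  BLOSUM62-dissimilar sets (every exchange a formal dissimilar
  compensatory mutation) and similar sets (no exchange dissimilar),
  the latter serving as the contrast corpus in the training
  experiment.
* **Phylogenetic redundancy.** 20% of rows are copies of earlier rows
  with 15% per-site point mutations (≈85% identity, inside the filter
  band). Lineage duplication is the minimal mechanism that reproduces
  shared-ancestry covariation; a full tree simulator with realistic
  substitution models is deliberately out of scope, so passing
  benchmarks bound performance under duplication-style redundancy
  only, not under deep phylogenetic structure, alignment error, or
  non-uniform residue usage of real families.
* **Gaps** are injected per cell at rate 0.02.

Everything is reproducible from the spec's seed, and the ground truth
(coupled pairs, per-column family, lineage) is returned alongside the
alignment.

## Benchmark problem sizes

The acceptance-level checks run: 200 random micro-alignments for the
U oracle; 1000 random 400-state distributions for the entropy-gain
property; Sinkhorn on random matrices up to 400 × 400; 50000 samples
for beta-parameter recovery; a 70/30 uniform/Beta(0.1, 1) mixture of
10000 p-values for \(\hat\gamma\) (expected value 0.763 with a ±4
standard-error band); 20 seeded benchmarks at ρ = 0.9 (plus 8 each at
ρ = 0.3, 0.6) for realized FDR and power at target 1%; and two
4-alignment corpora (dissimilar vs similar planted couplings, same
seeds) for the training discrimination. These sizes were chosen so the
whole suite runs in a few minutes on one CPU while keeping Monte-Carlo
error well inside the asserted margins.

## Known limitations

* The beta null is a two-moment approximation; its tail accuracy is
  what the realized-FDR benchmark measures, not a theorem.
* Scores of pairs sharing a column are dependent; the FDR estimate
  inherits the usual robustness of null-fraction estimators to weak
  dependence but carries no formal guarantee.
* The trained matrix reflects its training corpus. A matrix trained on
  the bundled synthetic generator is suitable for method studies, not
  as a stand-in for one trained on a large curated family corpus.
* Columns where the reference sequence is gapped are reported by
  original column index only; residue-level interpretation then needs
  an external numbering.
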