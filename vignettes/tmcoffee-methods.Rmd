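---
title: "Methods: consistency alignment of transmembrane proteins with homology extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consistency alignment of transmembrane proteins with homology extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model and its assumptions

Alpha-helical transmembrane proteins consist of hydrophobic
membrane-spanning helices — up to about 30 residues when tilted in the
bilayer — separated by intra/extracellular loops of variable length. The
helices are the structurally conserved, reliably alignable part; loops
tolerate substitutions and indels far more freely. An aligner for this
class of proteins should therefore (a) learn the position-specific
substitution pattern of each sequence from its database homologs rather
than trusting a single generic score matrix, and (b) propagate pairwise
alignment evidence consistently across the whole family.

`tmcoffee` implements this as a four-stage pipeline.

## Homology extension

Each input sequence is searched against a protein database. Hits are kept
when

* percent identity lies between 50 and 90 (both bounds inclusive — the
  "between" reading), and
* query coverage is strictly greater than 70% ("higher than"), and
* optionally, the e-value is at or below a ceiling (`NULL` means the
  unfiltered setting; tightening the ceiling can only remove hits, never
  add them).

The identity cap matters: it removes self-hits and near-duplicates that
would only echo the query back into its own profile. Kept hit segments
are stacked under the query: inside a hit's query span the aligned
subject symbol (residue or gap) is recorded at every query position,
subject residues opposite *query* gaps are discarded, and query positions
outside the span are padded with gaps. The profile therefore always has
exactly one column per query residue. Frequencies are counts over the
21-letter alphabet (20 residues + gap) divided by the rows counted at the
column; the query itself counts as one row. Keeping the gap symbol in the
denominator preserves occupancy information (how many homologs actually
cover a position) while the emission model renormalizes it away.

Unknown residues (`X`, which also absorbs B/Z/U/O/J on input) contribute
background-distributed mass; this makes their emission likelihood ratio
exactly 1, i.e. neutral.

Three search backends satisfy the same contract: a built-in affine-gap
Smith–Waterman (Gotoh) aligner in C++ over BLOSUM62 (open 11 / extend 1),
an external `blastp` wrapper, and a reader for precomputed tabular hits.
The built-in backend reports e-values through the Karlin–Altschul form
`E = K m n exp(-lambda S)` with the gapped BLOSUM62-11-1 constants
(lambda = 0.267, K = 0.041). These are *surrogates* — no parity with
blast+ statistics is claimed; they exist so thresholds behave sensibly
offline. No per-query hit cap is applied by default: accuracy tends to
increase as more in-band hits are included, and remote homologs are
mostly removed by the coverage bound anyway.

## The profile pair-HMM

Every pair of profiles is aligned with a 5-state pair hidden Markov
model: one match state and two insert-state pairs implementing a
bi-phasic gap model (distinct open/extend probabilities for short and
long gaps). The transition parameters are the published ProbCons
defaults:

| parameter | short gaps | long gaps |
|---|---|---|
| gap open | 0.0119511066 | 0.008008334786 |
| gap extend | 0.3965826333 | 0.8988758326 |

Two substitutions were unavoidable, and both are documented here rather
than silently embedded:

* **Emission matrix.** The trained 20x20 joint emission matrix of
  ProbCons is not printed anywhere we could verify it from; fabricating
  210 numbers was not an option. Instead the joint residue-pair
  distribution is reconstructed from BLOSUM62 target frequencies:
  `p(a,b) ∝ 2^(S(a,b)/2)` (half-bit scores), normalised and
  symmetrised, with the background `q` taken as the marginals of `p`.
  This makes the likelihood-ratio emission model exactly
  self-consistent. All parameters are overridable through a key-value
  config file (`read_pairhmm_params()`).
* **Begin/end states.** The initial-state distribution of the original
  parameter set is likewise not reproducible; the standard Durbin
  convention is used instead (begin and end behave like the match
  state). This affects only terminal-gap probabilities.

Match emissions between profile columns are expected likelihood ratios
over the renormalized residue frequencies,
`sum_ab fA(a) fB(b) p(a,b) / (q(a) q(b))`. On point-mass columns this
reduces exactly to the sequence case, so running the pipeline with
degenerate self-profiles *is* the plain consistency aligner — the same
code path, not a switch. An occupancy multiplier `(1-gapA)(1-gapB)`
(default on, flag-controlled) damps emissions at sparsely covered profile
ends, preventing confident constraints from single-homolog columns.
All-gap columns emit neutrally (score 1).

The forward–backward recursion runs in log space with log-sum-exp
(compiled C++), so no scaling factors are needed and totals stay finite
for any realistic length. The forward and backward totals agree to 1e-6
relative, and posteriors are clipped to [0, 1] at machine precision.
Posterior cells strictly greater than 0.99 become library constraints
with integer weights `round(100 * posterior)` (half up). No
probabilistic-consistency transformation is applied to the posteriors
before thresholding — cross-sequence consistency is handled entirely by
the library-extension stage.

## Consistency library and extension

Constraints from all unordered profile pairs are pooled, stored once per
pair in canonical orientation, and looked up symmetrically. Triplet
extension adds, for each third sequence C and position k, the relay
weight `min(w(A_i, C_k), w(C_k, B_j))` — the classic min-relay rule,
summed over intermediates, with no normalisation by intermediate count.
Extension is monotone (never decreases a weight), symmetric, and *not*
idempotent (a second pass relays the relays; the tests pin this down).
During progressive alignment the extension is computed lazily per
sequence pair — verified identical to the eager whole-library extension —
so the full extended library is never materialised.

## Guide tree and progressive merge

Pairwise distances are `1 - min(1, sum of pair weights / (100 *
min(lenA, lenB)))`, clustered by UPGMA. All ties (and there are exact
ties whenever the library treats two pairs identically) break
lexicographically on the smallest member id of each cluster, and the
left child of every merge is the cluster with the smaller representative:
input order can permute output *rows* but never column content.

Sub-alignments are merged by global DP over columns. The score of
matching column u (of A) with column v (of B) is the sum of extended
weights over all residue-bearing row pairs, divided by the number of
contributing pairs — the averaging keeps large sub-families from
steamrolling small ones. There is no gap penalty: all positional signal
comes from the consistency weights (gap modelling lives in the pair-HMM
stage, as in classic consistency aligners). The tie-break prefers match
over gap-in-B over gap-in-A, which makes the no-information case (empty
library) deterministic and ungapped.

Optional leave-one-out refinement (`refine()`, default off because the
original method's iteration scheme is undocumented — this is a stand-in,
not a parity claim) realigns each sequence against the rest and accepts
a move only on *strict* total-score improvement. Strictness matters:
accepting score-equal moves lets the alignment wander among optima and
undoes the determinism guarantee; with strict acceptance the score is
still non-decreasing and a single shifted row is restored in one round.

## Evaluation

SP and TC are computed on reference core columns only. A residue
participates when it sits in a core block of its row and is not a gap in
the reference; a column is counted when it has at least two
participating residues (a single residue carries no alignment
constraint). SP is the fraction of participating same-column residue
pairs that are co-columned in the test alignment; TC is the fraction of
counted columns whose participating residues all land in one test
column. Families with empty cores are flagged and excluded from
aggregates instead of being scored 0. Note that TC <= SP is a theorem
only when all counted columns have equal occupancy (as they do for
BAliBASE-style full-depth core blocks and for the generator's cores);
with wildly uneven column occupancy it can fail, which is why the
randomized property tests use full-occupancy cores.

The paired significance test between two per-family score vectors is an
exact two-sided Wilcoxon signed-rank: zero differences dropped, the null
distribution enumerated by dynamic programming over doubled ranks (exact
even with ties) up to n = 20, normal approximation beyond, p = 1 when
all differences vanish. No single test is canonical for benchmark tables
of this kind; exact signed-rank is the natural choice at n = 8 families
(a uniform improvement gives p = 2/2^8 = 0.0078) and is documented here
as a choice, not a parity claim.

# The synthetic world

The generator is a *stated world*, not a tuning dial; its defaults were
fixed once:

* **Topology**: 1–4 TM helices of 15–30 residues (the upper bound
  reflecting tilted helices), loops of 5–20 residues; helix residues
  drawn from a hydrophobic pool (I/L/V/F/A-heavy), loop residues from a
  polar pool.
* **Evolution**: star tree; per-site substitution with replacement
  uniform over all 20 residues (so 1/20 of draws are silent); TM sites
  evolve at 0.3x the loop rate, reflecting helix conservation; indels
  are geometric (mean 3) and confined to loops, so core blocks stay
  well-defined. The true alignment is tracked column-exactly through
  every edit, and the TM segments *are* the core annotation.
* **Identity control**: requested pairwise identity is inverted through
  the exact star-tree match probability
  `P(match) = s^2 + 19 (p/20)^2`, `s = 1 - 19p/20`, mixed over the
  TM/loop site fractions. Because conserved helices impose an identity
  floor, targets below the floor saturate at the maximal rate.
* **Mini database**: every family member, plus shared homologs evolved
  from the family *ancestor* with divergence solved so their expected
  identity to the members lands in the 50–90% filter band, plus random
  decoy sequences (only family-derived records carry the
  `transmembrane` keyword). Deriving relatives from the ancestor rather
  than from individual members is deliberate: homologs shared across
  the family give the profiles common columns, which is the actual
  mechanism by which homology extension transfers alignment information.
  Member-derived mutants were tried first and merely blur each profile
  with private noise.

What a green test does establish: the pair-HMM matches an exhaustive
path-enumeration oracle; extension matches a brute-force triple loop;
the merge DP is optimal; the scorer matches its definition; on this
world, the full pipeline recovers planted core columns (TC >= 0.9 at
>= 60% identity) and homology extension helps directionally at 30–40%
identity. What it does not establish: parity with the original
implementation on real BAliBASE families, realistic BLAST statistics, or
realistic indel/rate-matrix processes — the generator has no rate
heterogeneity beyond the TM/loop split and no non-star phylogeny.

# Numerical and design choices

* Internal coordinates are 1-based inclusive throughout (the R
  convention); all supported external formats are also 1-based
  inclusive, so there is no conversion layer to get wrong.
* Library weights are integers (posterior percent); relay sums of
  integers stay exact in doubles far beyond any realistic library size.
* DP tie-breaks are exact comparisons on rational numbers
  (integer weights / integer pair counts), so determinism does not
  depend on floating-point luck in practice; ties prefer match, then
  consuming the left block.
* Profile building, search, and pair-library construction are
  embarrassingly parallel (`threads` argument); results are asserted
  identical across thread counts.
* The blast+ backend passes default parameters through and requests
  tabular output extended with aligned segment strings; it shares the
  filtering and profile code with the other backends.

# Known limitations

* The built-in search backend reports surrogate e-values; identity and
  coverage filtering are exact, but e-value sweeps against the built-in
  backend explore the surrogate scale.
* The emission matrix is BLOSUM62-derived, not the original trained
  matrix (see above); absolute posterior values differ from the original
  implementation even where the alignment ranking agrees.
* Guide-tree distances come from library scores, not a separate identity
  pass; for sequence sets with near-empty libraries the tree degenerates
  to lexicographic merging (deterministic, but arbitrary).
* `refine()` is an opt-in stand-in for an undocumented iteration scheme.
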