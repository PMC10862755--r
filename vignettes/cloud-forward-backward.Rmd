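---
title: "Sparse profile-HMM search by pruned cloud Forward/Backward"
author: "cloudfb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse profile-HMM search by pruned cloud Forward/Backward}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudfb)
```

## The problem and the model

Profile hidden Markov models (pHMMs) score a target protein sequence
against a position-specific model of a sequence family.  The quantity with
the best discrimination power is not the single best alignment (Viterbi)
but the Forward score: the log-odds of the summed probability of *all*
alignments against a background (null) model,

$$ S = \log \frac{\sum_\pi P(T, \pi \mid Q)}{P(T \mid \mathrm{null})}
\quad\text{(nats)}. $$

Computing Forward, Backward, and the posterior decoding they enable costs
three $(m+1)(n+1)$ dynamic-programming matrices per pair — the bottleneck
of sensitive search.  This package implements a sparse approximation:
a seeded, pruned anti-diagonal flood fill ("cloud search") locates the
subset of matrix cells that carries essentially all alignment probability,
and Forward/Backward, posterior decoding, and maximum-expected-accuracy
(MEA) alignment are computed only over that cloud, stored in a padded flat
array.

### Core model

The core model is the standard three-state pHMM: match states $M_i$ with
position-specific emissions $q_{ic}$, insert states $I_i$ sharing one
emission distribution (the background, so insert emissions score zero in
log-odds), and silent delete states $D_i$.  Each node carries the seven
core transitions
$t_{M_iM_{i+1}}, t_{M_iD_{i+1}}, t_{M_iI_i}, t_{I_iI_i}, t_{I_iM_{i+1}},
t_{D_iD_{i+1}}, t_{D_iM_{i+1}}$.
The Forward recurrence for cell $(i, j)$ sums the three predecessor
states; Viterbi replaces the sum with a max.  All arithmetic is done in
natural-log space with the usual
$\log(p_1 + p_2) = a + \mathrm{log1p}(e^{b-a})$ accumulation; $-\infty$
is the additive identity, and the fill order (row-major or
anti-diagonal) is irrelevant to the result — both orders are implemented
and tested for exact agreement.

### Local alignment wrapper

Local alignment uses begin/end wrapper states in the "implicit
probabilistic model" convention: entry $B \to M_i$ has probability
$2/(m(m+1))$ for every $i$ and exit from any match state is free, which
places uniform probability mass on each alignment fragment $(i \le j)$
and sums to exactly one over fragments.  Flanking N/C states emit
background residues with target-length-dependent loops
($t_{NN} = n/(n+2)$, unihit, no J state — multi-domain decoding is out of
scope).  During development the configuration was cross-checked against
HMMER 3.4's own implementation (`hmmsim` on the same profiles), which
guided the choices below; the shipped test suite anchors correctness
instead on exhaustive path enumeration and full-vs-sparse equivalence.

During development we found that weighting the entry distribution by
fragment count (an easy misreading of "uniform entry") makes the implicit
model improper (fragment probabilities sum above one) and visibly distorts
the null score distribution; the constant-entry form is the correct one.

## Cloud search

Given a seed — the begin cell $(i_b, j_b)$ and end cell $(i_e, j_e)$ of a
prefilter alignment — the forward pass initializes $M = I = D = 0$ at the
begin cell and sweeps anti-diagonals ($d = i + j$) down-right, computing
only cells reachable from surviving cells of the previous two
anti-diagonals.  Two drop-off rules prune each anti-diagonal inward from
its two ends, using match-state values only:

* cells scoring below $\max_d - \alpha$ (the anti-diagonal's own best) are
  pruned — default $\alpha = 12$ nats;
* cells scoring below $\max_o - \beta$ (the best seen anywhere so far) are
  pruned — default $\beta = 20$ nats, the X-drop analogue.

No pruning is applied while an anti-diagonal is shorter than $\gamma$
cells (default 5).  When every cell of an anti-diagonal is pruned the pass
stops.  A mirrored backward pass runs up-left from the end cell.  Both
passes run in linear space: only three anti-diagonals are resident, with
cell $(i, j)$ stored at row $(i+j) \bmod 3$, column $j$, so the row
written for $d$ recycles the storage of $d - 3$.  Each surviving
anti-diagonal is summarized by its two extreme cells (at most two index
pairs per anti-diagonal), and each pass records two maxima: the best
match score seen anywhere (`best`), and the best seen before extending
past the anti-diagonal containing the far seed cell (`best_in`) — the
inputs to the cloud filter.

The union of the two clouds covers both per anti-diagonal; non-overlapping
clouds (rare, caused by a low-homology gap between the seed cells) trigger
a rectangular fallback spanning the seed.  Trimming then removes
protrusions: a forward sweep clips each bound to the interval reachable
from the previous two retained bounds, a reverse sweep clips to the
interval that can reach the following two.  The result is verified in the
test suite against a brute-force reachability oracle on explicit cell
sets.

One subtlety is deliberate: pruning jitter can pinch a single
anti-diagonal and leave an interior one-cell hole in a row even though
both neighbors lie on legal through-paths (so reachability trimming must
keep them).  Because the sparse layout requires one contiguous run per
row, reorientation closes such holes with the row's hull — a strict
superset of the cloud that only improves the approximation, at negligible
cost.

## Sparse matrix organization and sparse Forward/Backward

Row-oriented bounds are laid out in a single flat array, one block per
row, with the retrieval rule
`flat[block_offset[i] + (j - row_offset[i])]`.  Padding slots are chosen
so that *every* recurrence dependency of every cloud cell —
$(i\!-\!1, j\!-\!1)$, $(i\!-\!1, j)$, $(i, j\!-\!1)$ forward and their
mirrors backward — resolves to an allocated slot: each row's allocation
extends one column past its run on both sides and covers the runs of the
adjacent rows, and one pure-padding row sits above and below the cloud.
Padding permanently holds log-space zero ($-\infty$), so it can never
inject probability; the test suite asserts both the dependency closure
and that padding is never written.  Sparse Forward/Backward then run the
unmodified recurrences over cloud cells (wrapper states are computed
densely per column, a linear cost), posterior decoding multiplies the two
sparse matrices, and the MEA alignment maximizes summed match (and,
weighted by `ins_weight`, insert) posteriors over legal paths, with ties
broken M over D over I.

With a layout covering the whole matrix, every sparse result equals the
full-matrix reference to within $10^{-6}$ — that equivalence, plus
path-enumeration oracles at $m, n \le 3$, anchors the correctness of the
whole stack.

## Score statistics and the filter cascade

Scores are converted to P-values against nulls calibrated per profile by
simulation (`calibrate()`, default 1,000 background-composition sequences
of length 100, reproducible from an integer seed):

* **Forward scores** get a generalized-Pareto threshold-excess tail over
  the empirical median (`tail_mass = 0.5`).  The scale is anchored so the
  fitted survival passes exactly through the empirical within-tail
  quantile at survival ratio 1/5 (keeping P-values uniform where data
  exist), and the shape is estimated by penalized maximum likelihood with
  a weak prior $\xi \sim N(0.05, 0.10)$, which stabilizes the deep-tail
  extrapolation from small calibration samples.  We initially fixed the
  tail rate at the conjectured $\ln 2$ per nat, but development-time
  measurement showed the rate to be profile-dependent — near the
  conjectured value for `hmmbuild`-prior models, visibly steeper for the
  peaked synthetic profiles used here, a pattern HMMER's own scores
  reproduce on the same profiles — with mild curvature that a
  one-parameter exponential extrapolates poorly; the nominal-level checks
  in the test suite exercise the fitted tail directly.
  The fitter was selected by replicate simulation
  studies of estimator quality (including held-out profiles) before
  being frozen; even so, extrapolating from a 1,000-sequence calibration
  to the $10^{-4}$ tail carries roughly half a decade of irreducible
  uncertainty.  The shape can be pinned (`tail_shape = 0`) to recover
  the closed-form exponential tail.
* **Gapped-maximum (Viterbi-type) scores**, used by the seed filter, get
  a Gumbel fitted by full maximum likelihood.

E-values multiply P-values by the number of target sequences searched;
reported scores are bits ($1$ bit $= \ln 2$ nats).

The pipeline applies three filters in order, mirroring the staged-filter
architecture of accelerated pHMM search: seed filter ($P < 0.01$), cloud
filter ($P \le 10^{-3}$) on the estimated Forward score
$A + \max(\mathrm{best\_infwd}, \mathrm{best\_inbkwd}) + Z$ with
$Z = \mathrm{best\_fwd} - \mathrm{best\_infwd}$ and
$A = \mathrm{best\_bkwd} - \mathrm{best\_inbkwd}$, and the Forward filter
($P \le 10^{-4}$) on the sparse Forward score.  Survivors get posterior
decoding, a simplified null2-style composition-bias correction (the
posterior-weighted emission distribution over the aligned region defines
a biased null; the nonnegative log-odds of the region under it is
subtracted — exactly zero when that distribution equals the background),
posterior-median alignment boundaries (cumulative begin/end wrapper-state
posteriors crossing 0.5, configurable), and the MEA alignment.

## Seeding

The internal prefilter mimics k-mer seeded protein search: (i) candidate
diagonals need two non-overlapping length-6 windows of summed match
log-odds above 3 nats; (ii) the diagonal's best ungapped segment must
exceed 8 nats; (iii) survivors get a banded (half-width 8) gapped Viterbi
that yields the seed cells and the gapped score fed to the seed filter.
The window and segment thresholds were calibrated once on synthetic
homolog/decoy sets (30/30 homologs seeded, 4/60 decoys reaching the
gapped stage) and are exposed as configuration.  External seeds in
m8-style TSV (with query coordinates already in profile positions) can
replace the internal stage; their E-values are converted to P-values by
inverting the database-size adjustment.

## The synthetic benchmark

The generator emulates a planted-homolog benchmark at desk scale: peaked
family profiles (`peak = 0.45` dominant-residue probability, about one
bit per position of relative entropy, typical of curated family models;
length 100, a typical domain scale), homologs that follow the consensus
with per-position substitution probability `divergence = 0.3` and indel
probability 0.02, each spliced into the midpoint of a shuffled decoy, and
pure shuffled decoys (drawn i.i.d. from the background, the
distributional equivalent of shuffling natural sequences — compositional
realism of real proteomes is deliberately not modeled).  `divergence`
near 0.8 produces the ~25% identity regime of hard benchmarks.  The truth
table records every planted interval; the evaluator scores a hit as a
true positive only when its alignment covers at least half the planted
interval, counts hits on pure shuffled sequence as false positives,
treats cross-family hits as neutral, and summarizes ranking quality as
*recall-0*, the fraction of planted positives ranked above the best false
positive.

Passing tests on this fixture demonstrate internal consistency and
calibration of the method under known truth; they do not demonstrate
sensitivity on real, compositionally biased proteins, for which the
k-mer prefilter (not the sparse Forward/Backward stage) is the expected
limiting factor.

## Numerical and design choices, problem sizes, limitations

* All DP kernels are exact log-space computations in C++; no probability
  -space rescaling and no vectorized approximations of `log1p`.
* Viterbi and MEA tracebacks break ties preferring M over D over I,
  making outputs deterministic.
* Degenerate inputs (empty posteriors, non-intersecting clouds, seeds on
  a single cell, all-mismatch targets) are exercised in the test suite;
  cloud search on a cell with no finite match score stops rather than
  propagating NaN.
* The test suite verifies oracle equivalence on roughly one hundred
  random pairs up to $60 \times 60$, enumeration oracles at $m, n \le 3$,
  sparse-score fidelity on fifty planted pairs at $m = 100$,
  $n \approx 300$ (at the default pruning parameters, the sparse score is
  within one nat of the full score for at least 90% of pairs), filter
  pass-rates on $3 \times 10^4$ and $10^4$ decoys, and end-to-end recall
  on a 20-homolog / 200-decoy database; these sizes were chosen so the
  whole suite runs in a few minutes on one CPU while keeping each check
  statistically meaningful.
* Known limitations: unihit only (a single reported domain per pair; no
  J state), protein only, one seed per pair (a badly placed seed cannot
  be recovered), and P-values below the calibration anchor rely on the
  fitted tail family.

## A worked call

```{r example, eval = FALSE}
bm <- make_benchmark(benchmark_spec(n_true = 5, n_decoys = 50, seed = 7))
hits <- search(bm$profiles[[1]], unname(bm$targets), rng_seed = 11)
head(as.data.frame(hits))
evaluate_ranking(hits, bm$truth)$recall0
```
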