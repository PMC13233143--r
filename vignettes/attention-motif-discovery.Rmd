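---
title: "Attention-guided motif discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided motif discovery: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promotif)
```

## The problem and the model

Tissue-specific (TSp) promoters carry sequence features — transcription
factor binding motifs and their arrangement around the transcription start
site (TSS) — that distinguish them from broadly active promoters and from
background genomic DNA. A sequence classifier trained on this contrast
encodes those features implicitly; `promotif` extracts them explicitly from
two complementary signals: the classifier's `[CLS]`-to-token attention and
model-agnostic Shapley attributions of its positive-class logit.

The pipeline assumes only a *provider contract*: a tokenizer producing
character spans that tile the sequence, per-layer per-head softmaxed
`[CLS]` attention rows over those tokens, a binary prediction, and a scorer
defined over masked token subsets. Anything satisfying the contract — a
fine-tuned transformer, a cached attention file, or the package's toy
provider — drives the identical downstream code. This is deliberate: every
statistical claim the package makes can therefore be tested end to end with
a fully deterministic model.

## From attention to motifs

Per sequence and layer, raw token saliency is the head-averaged attention
`alpha_j`; averaging rather than summing is immaterial because the next step
divides by the per-sequence maximum (`s_hat_j = alpha_j / max(alpha)`), and
the constant head count cancels. A layer's usefulness is screened with a
specificity score `Sp = (max(s_hat) - mean) / sd`. `Sp` uses the *sample*
standard deviation throughout the package (the choice affects constants
only, and consistency with the SHAP summary statistics seemed more valuable
than either convention in isolation); `Sp = 0` by convention when the
scores are constant. The default layer combination averages the mean of the
middle layers with the final layer — layers 5–7 for deep models, the middle
third for shallower ones — with equal weights; single-layer and
top-`Sp` strategies are available where a user prefers an empirical pick.

Candidate regions are maximal runs of tokens passing both
`s_hat_j > mean(s_hat)` and `s_hat_j > 2 * min(s_hat)`, concatenated at the
nucleotide level and kept when at least 4 bp long. Run concatenation
matters: informative motifs routinely straddle token boundaries, so a
token-level selection alone would fragment them (the merged consensus in
the README example reassembles an 8-mer from three 6-mer fragments). Two
degenerate regimes are handled explicitly: constant `s_hat` selects nothing
(the mean condition is strict), and a flat profile with
`2 * min(s_hat) >= 1` excludes every token — an empty candidate set is a
valid outcome, not an error.

## Enrichment testing

Presence/absence — not occurrence count — feeds the test: with `N`
sequences of which `K` are positive, and `n` carrying the motif of which
`k` are positive, the p-value is the upper tail `P(X >= k)` for
`X ~ Hypergeom(N, K, n)`. The point-mass `P(X = k)` is exposed separately
(`hypergeom_pmf()`) but is not the decision statistic: a pmf is not
monotone in enrichment, and over-representation calls need the tail.
Multiple testing uses Benjamini–Hochberg step-up — the default reading of
"FDR correction" — at `alpha = 0.01`. Motifs with fewer than
`min_instances = 3` total occurrences are discarded before testing.

The enrichment universe is the full labeled dataset. Correct-prediction
filtering gates *candidate discovery* only: attention is only trustworthy
where the model is right, but restricting `N` and `K` to the correctly
predicted subset would condition the null distribution on the model's
errors and bias the test.

Occurrence counting uses an Aho–Corasick automaton (compiled code),
counting overlapping matches and recording every position; a naive
sliding-window scan is the test oracle. Ambiguous bases (`N`) break matches
rather than wildcard-matching them.

## Merging and the B-minus-A contrast

Redundant motifs are greedily collapsed when their best ungapped-offset
alignment matches at least `merge_threshold = 0.8` of the shorter length
(the threshold value is a package default; it is configurable). Processing
order is descending length with lexicographic tie-break; the cluster
consensus is the positionwise majority base over members aligned at their
best offsets, ties resolved in `A < C < G < T` order, and the best offset
itself prefers the smallest shift among equals. These tie-break rules make
the merge idempotent and its consensus set insensitive to input order.

Model A (random non-promoter negatives) learns general promoter biology;
Model B (GC/repeat-matched negatives) must rely on finer TSp signal.
`motif_set_difference()` reports B's merged significant motifs absent from
A's — exact string matching by default, with a similarity mode (shared if
the ungapped overlap reaches the merge threshold) reported separately for
users who consider near-duplicates shared.

## SHAP cross-validation

Kernel SHAP estimates each token's Shapley contribution to the
positive-class logit with the all-masked pattern as baseline. The estimator
is the standard Shapley-kernel weighted least squares with the efficiency
constraint imposed exactly by coefficient elimination, so local accuracy
(`sum(phi) + f(empty) = f(full)`) holds by construction. When the budget
covers all `2^J - 2` interior coalitions the estimate is exact — the
package verifies this against brute-force enumeration (`exact_shapley()`,
refused above `J = 12`). The per-record coalition budget defaults to
`2J + 2048`; the value is a pragmatic default, since no canonical budget
exists for this estimator.

Per-token summaries report `n`, the mean, the mean of absolute values
*and* the absolute value of the mean (the phrase "absolute mean" is
genuinely ambiguous; both columns are emitted so either reading is
available, with `abs_mean_shap = mean(|x|)` — the usual SHAP importance —
used for default ranking), the sample standard deviation, and a 95% CI
half-width of `1.96 * sd / sqrt(n)`. The CI deliberately uses the plain
normal approximation with no t-correction. Tokens rarer than `min_count
= 5` are dropped as noise; the cutoff is a default, not a derived quantity.

## Positional analysis

Instance coordinates map back to the genome with strand adjustment
(minus-strand instances reflect through the window), and TSS distance is
defined in *transcription orientation* for both strands (upstream
negative), so profiles pool across strands. Distances aggregate into 100 bp
bins on a grid anchored at 0; a distance exactly on an edge goes to the
right-hand bin (half-open convention). The 3-bin rolling average runs over
occupied bins only, with edge bins averaging their available neighbors —
empty bins are skipped, not zero-filled, because a zero would fabricate an
attention value. The KDE uses a Gaussian kernel with Scott's-rule
bandwidth over `[min - 3h, max + 3h]`; all-identical distances are an
error with a pointer to the histogram. Overlap enrichment against
reference peak sets is a 2×2 Fisher exact test on any-overlap proportions
(motif vs background regions), with peak sets ranked by motif overlap
proportion — the ranking statistic is an interpretation, chosen for being
the simplest quantity the proportions already provide.

## The synthetic benchmark: what it does and does not show

`generate_planted_dataset()` defines the study condition used throughout
the tests: 200 positives and 200 negatives of 2 kb (1.5 kb upstream,
0.5 kb downstream), an 8 bp motif substituted into 80% of positives and 5%
of negatives at Gaussian(−150 bp, 50 bp) TSS-relative positions, i.i.d.
background at GC 0.5. Substitution (not insertion) keeps window arithmetic
exact. The toy provider attends with weight
`exp(kappa * overlap) + kappa * noise_sd * U(0,1)` per token
(`kappa = 8`, `noise_sd = 0.1`), so `kappa = 0` yields exactly uniform
rows and attention concentrates on planted tokens as `kappa` grows; its
classifier predicts planted-presence with logit
`4 * (visible planted bp) / (planted bp) - 2`, which doubles as the SHAP
scorer.

The generator emulates the *structure* of promoter classification data —
fixed-length TSS windows, class-conditional motif planting, positional
preference, GC control, soft-masking for the matched-null sampler — and
none of the sequence realism: no CpG islands, no TATA grammar, no
higher-order Markov background, no correlated motif co-occurrence. Passing
tests therefore demonstrate that the machinery is correct and calibrated
(planted signal is recovered; under a no-signal null with equal plant
rates in both classes, the fraction of 200 replicate datasets yielding any
FDR-significant motif stays within Monte-Carlo error of the nominal 0.01),
not that any particular biological motif is real. Results on real genomes
inherit the usual caveats of attention-based saliency.

## Dataset construction choices

Coordinates are 0-based half-open everywhere internally, BED on disk.
Minus-strand windows are reverse-complemented so upstream/downstream always
refer to transcription orientation; the reflection property (flipping all
strands and reverse-complementing the genome changes nothing) is tested.
Out-of-bounds windows are errors, never clipped — silent truncation would
break the fixed-length invariant. "Repeat patterns" for the matched-null
design are operationalized as the soft-masked (lowercase) fraction, the
standard encoding of repeat annotation in genome FASTA; default matching
tolerances are 0.02 (GC) and 0.05 (repeat fraction), both configurable.
Splits are train 80% / validation 10% / test 10% per class by
largest-remainder apportionment (train-major order), deterministic under
seed. Redundancy reduction follows an mmseqs2-style greedy scheme at 80%
identity and coverage; when no external clustering tool is available the
internal metric is the best ungapped-alignment identity over the shorter
sequence, which agrees with alignment identity for the equal-length,
substitution-dominated redundancy this pipeline produces. Whether matched
negatives should be drawn genome-wide or restricted to non-promoter space
is left to the caller via the exclusion set.

## Determinism and problem sizes

Every stochastic stage takes a seed; per-record noise streams derive from a
base seed plus a sequence hash, so results are independent of processing
order and bit-reproducible. The pipeline manifest records a hash of the
full configuration; two runs with equal configs produce byte-identical
motif tables.

The test suite and acceptance script run the benchmark at the sizes stated
above (400 × 2 kb for recovery; 200 replicates for null calibration; 50
motifs × 200 × 2 kb for the matching oracle; exhaustive enumeration at
`N <= 12` and `J <= 8` for the hypergeometric and Shapley oracles). These
sizes were chosen as the smallest at which the calibration statements are
statistically meaningful (the ±3 Monte-Carlo-standard-error band at 200
replicates).

## Known limitations

Attention saliency is a heuristic: the contract accepts any softmaxed
`[CLS]` row and takes no position on pre- versus post-residual attention in
a given transformer. Kernel SHAP at realistic token counts is sampled, not
exact, and its variance depends on the budget. The greedy merge is order-
stabilized but still greedy — a globally optimal multiple alignment of
motifs is out of scope. The internal clustering metric is ungapped;
indel-heavy redundancy needs an external tool.
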