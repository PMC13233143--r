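# promotif

Attention-guided motif discovery for tissue-specific promoters.

Transformer sequence classifiers trained to separate tissue-specific (TSp)
promoters from background DNA learn *where* to look: the `[CLS]` token's
attention over sequence tokens concentrates on short subsequences that drive
the decision. `promotif` turns that signal into testable biology. It builds
labeled promoter datasets under two negative-set designs, converts `[CLS]`
attention profiles into candidate motifs, tests their enrichment in the
positive class, cross-validates token importance with model-agnostic Shapley
attributions, and profiles where significant motifs sit relative to the
transcription start site (TSS).

The package is model-agnostic by construction: every stage consumes a small
provider contract (`tokenize` / `profile` / `scorer`), and ships a
deterministic toy provider plus a seed-reproducible planted-motif simulator,
so the entire pipeline runs — and is tested — without a trained model, a GPU,
or a reference genome. Plugging in a fine-tuned DNA language model only
requires wrapping its tokenizer, softmaxed `[CLS]` attention rows, and
masked-input logits in the same contract.

## The statistics at the core

For a sequence of `J` tokens, per-layer token saliency is the head-averaged
`[CLS]`-to-token attention `alpha_j`, max-normalized per sequence:

    s_hat_j = alpha_j / max(alpha)

Layers are screened with a specificity score `Sp = (max(s_hat) - mu) / sigma`
and combined (middle layers averaged with the final layer). Tokens with
`s_hat_j > mu` and `s_hat_j > 2 * min(s_hat)` are marked; maximal runs of
marked tokens at least 4 bp long become candidate motifs. Each motif's
occurrences are counted with an Aho–Corasick multi-pattern scan, and
enrichment of the positive class among the `n` motif-carrying sequences is
tested with the upper-tail hypergeometric probability

    p = P(X >= k),  X ~ Hypergeom(N, K, n)

(`N` sequences, `K` positive, `k` positive carriers), followed by
Benjamini–Hochberg correction at `alpha = 0.01`, a minimum-instance filter,
and greedy gapless merging of redundant motifs into consensus sequences.
Token-level importance is cross-validated with Kernel SHAP (weighted-least-
squares Shapley values, all-masked baseline), and motif instances are mapped
to signed TSS distances, binned at 100 bp with a 3-bin rolling average, and
summarized with a Gaussian KDE.

## Worked example

```r
library(promotif)

spec <- planted_dataset_spec(n_pos = 30, n_neg = 30, upstream = 600,
                             downstream = 200, seed = 7)
records  <- generate_planted_dataset(spec)       # 8 bp motif at N(-150, 50)
provider <- toy_attention_provider(seed = 7)     # kappa = 8 toy attention
disc     <- discover_motifs(records, provider)

disc
#> <motif_discovery> ModelA: 4 motif(s) tested, 3 significant (q <= 0.01), 1 after merging

head(tidy(disc))
#> # A tibble: 4 x 11
#>   motif        length     N     K     n     k total_occurrences        p       q
#> 1 ACGTCA            6    60    30    33    27                41  2.81e-8 5.62e-8
#> 2 CACGTC            6    60    30    35    28                45  1.74e-8 5.62e-8
#> 3 GCACGT            6    60    30    37    28                40  2.74e-7 3.65e-7
#> 4 CGCACGTCATGT     12    60    30     3     3                 3  1.19e-1 1.19e-1

disc$merged$consensus
#> [1] "GCACGTCA"          # the planted motif, reassembled from merged tokens

glance(positional_profile(disc, records))
#> # A tibble: 1 x 5
#>   n_instances n_bins bin_width peak_bin_start kde_mode
#> 1         126      8       100           -200    -174.
```

Reading the output: three 6-mer fragments of the planted motif are
individually enriched (27–28 of their carriers are positives, q below
1e-6); gapless merging reassembles them into the exact planted 8-mer; the
instance density peaks near the planted Gaussian center of −150 bp upstream
of the TSS. `autoplot()` methods draw the enrichment, positional, and SHAP
summaries.

Dataset construction for real genomes works the same way:
`extract_promoter_windows()` pulls strand-aware TSS windows from a FASTA,
`label_by_tissue()` applies the TransTEx-style expression groups
(TSp/TEn/Wide/Low/Null), `sample_random_negatives()` (Model A) and
`sample_matched_negatives()` (GC/repeat-matched, Model B) build the two
negative designs, and `cluster_reduce()` / `stratified_split()` prepare
training data. `pipeline_diff()` reports the merged significant motifs unique
to Model B — the B minus A set that isolates tissue-specific signal from
general promoter biology.

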