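---
title: "Measuring genome complexity by compression: models, parameters, and design choices"
author: "seqcomplexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome complexity by compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcomplexity)
```

## The model

A lossless compressor's output size upper-bounds the Kolmogorov
complexity of its input, so normalized compression,
$\mathrm{NC}(x) = C(x) / (2|x|)$, measures how much of the 2-bits-per-base
capacity of the quaternary alphabet a genome actually uses. The
compressor here is a mixture of adaptive finite-context models. Model $m$
with order $k_m$ keeps sparse counts $n(c, s)$ of symbol $s$ following
context $c$ (the previous $k_m$ bases) and predicts

$$P_m(s \mid c) = \frac{n(c,s) + \alpha_m}{\sum_{s'} n(c,s') + 4\alpha_m}.$$

The mixture prediction is $\sum_m w_m P_m$, computed before the symbol is
observed; afterwards each weight is decayed and rewarded,
$w_m \leftarrow w_m^{\gamma_m} \, P_m(x_i)$, and the weights renormalized.
The per-symbol cost is $-\log_2$ of the mixture probability of the
observed base; $C(x)$ is the total. This is an ideal code length: a real
arithmetic coder would add a constant number of bits, which the
normalization by $2|x|$ makes irrelevant for genome-scale inputs, so no
bitstream is produced. The weight-decay mixer is the classical
weighted-experts scheme; a learned (neural) mixer could substitute for it,
but the decay form is transparent, parameter-light, and sufficient for
every property this package asserts.

### Inverted repeats

Genomic structure that forward Markov statistics cannot see — an inverted
repeat, i.e. the reverse complement of earlier text — is handled by a
reverse-complement update rule. After observing the window
$x_{i-k} \ldots x_i$, the model reverse complements it and counts the
first $k$ symbols of that word as context and the last as symbol, in the
*same* table. Lookups always use the forward context, so when the
downstream reverse-complement copy arrives, its forward contexts are
exactly the seeded entries. The involution property (re-expanding the
reverse complement of a window recovers the original pair) is what makes
this construction correct, and is tested exhaustively at small $k$. The
three modes are: IR$_0$ forward counts only, IR$_1$ both updates, IR$_2$
reverse-complement counts only. NCC $= 1 - \mathrm{NC}_{IR_2}$, kept only
when strictly positive, and DIFF
$= \mathrm{NC}_{IR_0} - \mathrm{NC}_{IR_1}$ quantify IR content from two
angles; negative DIFF values are retained in tables, the strict-positive
filter applies to NCC only.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| order $k$ | 1 and 12 | context depth; memory grows as observed $(k{+}1)$-mers, guarded at $k \le 16$ |
| $\alpha$ | 1 (order 1), 1/50 (order 12) | estimator smoothing; small $\alpha$ lets a deep model commit fast |
| $\gamma$ | 0.7, 0.97 | mixer decay per model; guarded at $\le 0.99$ |
| irMode | 0 (order 1), 1 (order 12) | reverse-complement update rule |

The default two-model mixture (`level16Config()`) pairs a short-memory
order-1 model with an order-12 IR-aware model. Deeper single models gain
little on genomes of ~10 kb where repeats sit within a small genomic span,
and lose sensitivity on average; `bestLevelSweep()` exists precisely to
compare configuration pools on a given dataset (ties are credited to the
lowest-index configuration, which keeps the report order-stable).

Numerical conventions: every model starts from the all-A context with an
empty table, so the first symbol of any sequence costs exactly 2 bits;
counts are unbounded integers in a sparse map (viral genomes are small
enough that no counter halving is needed); mixing weights are floored at
$10^{-15}$ after renormalization so a long run of bad predictions cannot
underflow a weight to zero. Sequences must be strictly A/C/G/T —
`sanitizeSequence()` maps U to T (one alphabet serves DNA and RNA) and
replaces any other symbol by a uniformly random base from a dedicated,
seeded stream consumed in sequence order. A per-file seed makes ingestion
reproducible; this seeding policy is this package's own convention, as is
the rule that the accession is the FASTA header token before the first
whitespace.

## Bidirectional profiles

The per-symbol series is a local complexity measure, but a causal
compressor prices the *first* copy of any repeated structure at full cost.
Compressing the reversed sequence and re-mirroring the series prices the
other copy instead; the pointwise minimum
$B(x_i) = \min\{\overrightarrow{C}(x_i), \overleftarrow{C}(x_i)\}$ is low
wherever the position is explainable from either direction. The backward
pass is plain reversal; a reverse-complement variant is available via
`backward = "revcomp"`, but IR structure is normally already captured by
the IR model modes. For visualization the minimum series is smoothed by a
normalized Blackman window (default 501 positions, mirror-padded edges —
constants pass through unchanged and interior mass is conserved);
`callRegions()` then reports maximal sub-threshold runs as 1-based closed
intervals (converted to BED's 0-based half-open convention only at write
time). The filter family and width are deliberate stand-in defaults — any
symmetric low-pass window serves, and both are configurable.

## What the synthetic generators emulate

`randomSequence()` draws i.i.d. uniform DNA — the incompressible
baseline (NC within a few thousandths of 1 under the default mixture).
`makeIRConstruct()` builds the canonical IR test case: $n$ bases whose
second half is the reverse complement of the random first half, with
$n = 10{,}000$ by default, matching the scale of a median viral genome.
`mutateSequence()` applies independent point substitutions (a substituted
base becomes one of the other three uniformly; no indels, matching a
substitution-only benchmark design). `irBenchmark()` sweeps substitution
rates 0–10% with 5 replicates per rate, generating each rate's sequence
independently rather than accumulating mutations — the independent design
makes replicates exchangeable across rates and the per-rate expectation
identical to the cumulative design at the same effective rate. Mutations
are applied to the whole construct, not just one half.

These generators reproduce the *mechanics* real genomes exercise —
maximal inverted repeats, graded substitution noise, scale — but not
biased base composition, repeat mosaics, or phylogenetic correlation.
Passing the property suite therefore certifies the apparatus (the IR rule
fires, erodes under mutation at the expected rate, and the forward mode
stays flat), not any biological claim about a particular taxon.

`syntheticFeatureTable()` emulates the classification input: class-mean
Gaussians spaced `separation` standard deviations apart on every feature
axis. Separation 0 gives a class-blind table (harness accuracy must fall
at the analytic baseline $100/N$%), large separation a trivially
separable one (accuracy must reach ~100%). These two calibration points
bracket the harness without requiring any particular real dataset.

## Dataset pipeline choices

Taxonomy filtering keeps only records with a non-empty value at every
rank realm–genus, none of which contains the token "unclassified"
(case-insensitive). Taxonomy arrives as a TSV sidecar rather than by live
database queries, which keeps ingestion offline and reproducible. The
outlier filter screens SL, GC and NC_best (which NC variants to screen is
configurable) with a *single-pass* $\mu \pm 3\sigma$ rule: statistics are
computed once over the full table, removals happen in one sweep, and
boundary values are kept (strict inequality). A second pass would remove
more rows — one pass is the documented behavior, matching a design in
which a single removal count is meaningful. Cladograms aggregate the
feature table over the rank hierarchy with leaf-count-weighted means,
lexicographic child order for determinism, and are exported as Newick
(names quoted when they contain reserved characters) plus a node
annotation TSV; rendering and coloring are left to downstream viewers.

## Classification harness

Classes with fewer than 4 members are dropped once, before any split, so
the task's sample counts are fixed across repetitions. Each of the 50
repetitions draws a stratified 80/20 split (per-class test counts are
`round(0.2 n_c)` clamped to $[1, n_c - 1]$, so proportions hold to within
one sample and every class appears on both sides); repetition $r$ uses
seed $s + r$, and a repetition whose fit fails on a degenerate split is
re-drawn with a shifted seed and a message. Five classifier families are
exposed — LDA, Gaussian naive Bayes, KNN, SVM, XGBoost — at library
defaults, with two deliberate exceptions recorded in each result's
details: `class::knn` has no default $k$, so $k = 5$ on
train-standardized features; and XGBoost uses exact greedy split finding
because its default histogram binning places split thresholds at training
minima inside wide inter-class gaps, so a test point falling marginally
below its class's training minimum is confidently misrouted — a visible
artifact on the small feature tables this harness targets, and absent
with exact midpoint splits. Accuracy is reported in percent alongside
weighted F1 (class-support weights, F1 of an unpredicted class counted as
0), against the analytic random baseline $p_{hit} = 100/N$%, which is
invariant to class imbalance. The feature set defaults to the six scalar
features (SL, GC, NC_best, NC_IR0, NC_IR1, NC_IR2); NCC and DIFF are
available as derived columns and any subset can be requested, since which
derived measures to include is a genuinely open modeling choice.

## Problem sizes and limitations

The shipped tests and the acceptance script run at deliberate scales: the
compressor oracle is checked exhaustively over all $4^8$ length-8
sequences and on parameterized 120-base fixtures; the IR benchmark at
$n = 10{,}000$ with 5 replicates and 11 rates; profiles on 1–4 kb
fixtures; the harness on tables of 180–400 rows. These sizes make every
property sharp while keeping a full run in well under a minute of
compressor time.

Known limitations: the compressor has no substitution-tolerant contexts
or cache hashing, so its absolute NC values are not bit-comparable to any
specific external tool; the mixer is the decay scheme described above,
not a learned one; no decompressor is provided (ideal code lengths only);
profiles are single-sequence (no multi-genome alignment of profiles); and
classification quality on real data depends entirely on the
representativeness of the supplied feature table — the package certifies
the harness, not a taxonomy.
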