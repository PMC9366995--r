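# seqcomplexity

Compression-based complexity analysis of viral genome sequences.

Viral genomes are short, dense, and full of algorithmic structure —
repeats, and especially *inverted repeats* (IRs), subsequences whose
reverse complement occurs elsewhere in the genome (terminal IRs flank
parvovirus and adenovirus genomes; IR-rich pseudoknots drive ribosomal
frameshifting). How much information a genome actually carries, and how
much of it sits in such structures, can be measured without any alignment:
a lossless compressor's output size is an upper bound on the sequence's
Kolmogorov complexity. This package provides that measurement apparatus
for genome-scale DNA/RNA sequences, and everything that builds on it:
dataset curation, per-taxon aggregation, local complexity profiles, a
synthetic IR benchmark, and an alignment-free, feature-based taxonomic
classification harness.

## The measures

The compressor is a mixture of adaptive finite-context (Markov) models.
Model *m* of order *k* predicts the next base from smoothed counts,

    P(s | c) = (n(c, s) + α) / (Σ_s' n(c, s') + 4α),

where `c` is the previous *k* bases. Models are combined by
performance-weighted mixing: the mixture prediction is `Σ_m w_m P_m`, and
after each symbol the weights are updated as `w_m ← w_m^γ · P_m(x_i)` and
renormalized, with a per-model decay `γ` controlling how fast past
performance is forgotten. The per-symbol cost is `−log2` of the mixture
probability of the observed base, and `C(x)` is the total over the
sequence (an ideal code length; an arithmetic coder would add O(1) bits).

Inverted repeats are captured by a reverse-complement update rule: after
observing the window `x[i−k..i]`, a model can additionally (mode IR₁) or
exclusively (mode IR₂) record the reverse complement of that window in the
same count table. Because lookups always use the forward context, an
inverted repeat of earlier text lands exactly on the seeded counts. Mode
IR₀ disables the rule.

The default configuration (`level16Config()`) mixes an order-1 model
(α = 1, γ = 0.7, no IR) with an order-12 model (α = 1/50, γ = 0.97, with
IR) — well suited to small, compact genomes.

On top of `C(x)`:

* **NC** — normalized compression, `C(x) / (2|x|)`; ≈1 incompressible,
  ≈0 fully redundant.
* **NR** — normalized redundancy, `1 − NC`.
* **NCC** — normalized compression capacity, `1 − NC_IR₂`, kept only when
  strictly positive; quantifies IR content.
* **DIFF** — `NC_IR₀ − NC_IR₁`, a second IR-abundance measure.
* **GC**, **SL** — GC-content (percent) and sequence length.
* **B(xᵢ)** — the minimal bidirectional complexity profile,
  `min{→C(xᵢ), ←C(xᵢ)}` of per-symbol costs from compressing the sequence
  in both directions, low-pass smoothed for region visualization.

The classification harness feeds the per-genome feature vector
(SL, GC, NC and its three IR variants) to LDA, Gaussian naive Bayes, KNN,
SVM and XGBoost under repeated stratified 80/20 holdout (50 splits,
classes with fewer than 4 members dropped), reporting mean accuracy and
weighted F1 against the analytic random baseline
`p_hit = Σ_i p(c_i)/N = 100/N %`.

## Worked example

```r
library(seqcomplexity)

# a 10 kb sequence whose second half is the reverse complement of the first
s <- makeIRConstruct(10000, seed = 7)

for (m in c("0", "1", "2")) {
  nc <- normalizedCompression(compressSequence(s, level16Config(irOverride = m)))
  cat("NC_IR", m, "=", round(nc, 4), "\n")
}
#> NC_IR 0 = 1.0018
#> NC_IR 1 = 0.5255
#> NC_IR 2 = 0.5262
```

The forward-only mode (IR₀) sees an incompressible random sequence
(NC ≈ 1). Both IR-aware modes compress the second half almost for free
(NC ≈ 0.53): the genome's information is essentially its first half, and
NCC = 1 − 0.5262 ≈ 0.47 quantifies the inverted-repeat content. A
homopolymer control shows the opposite extreme:

```r
res <- compressSequence(strrep("A", 1000),
                        CompressorConfig(ModelSpec(1, alpha = 1)))
totalBits(res)
#> [1] 27.32104        # = log2(1001*1002*1003/6), NC = 0.0137
```

Mutating the construct erodes its inverted repeat:

```r
head(irBenchmark(n = 10000, replicates = 5, seed = 11), 3)
#>   rate NC_IR0 NC_IR1 NC_IR2   DIFF
#> 1 0.00 1.0014 0.5256 0.5259 0.4758
#> 2 0.01 1.0014 0.6547 0.6550 0.3467
#> 3 0.02 1.0014 0.7558 0.7561 0.2456
```

NC_IR₂ climbs toward 1 as substitutions accumulate while NC_IR₀ stays
flat — only the IR-aware modes were exploiting the structure.

A typical dataset run: `readGenomes()` (FASTA, with sanitization of
non-ACGT symbols), `readMetadata()` + `filterByTaxonomy()` (complete,
classified lineages only), `genomeFeatures()`, `outlierFilter()`
(single-pass μ ± 3σ on SL, GC, NC), then `aggregateByRank()`,
`buildCladogram()`/`exportCladogram()` (Newick + node annotations) and
`classifyFeatures()`. A thin command-line wrapper over these functions is
included at `inst/scripts/seqcomplexity-cli.R`.

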