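# The finite-context-model compressor and its building blocks.

test_that("symbolDistribution applies the smoothed count estimator", {
  tab <- newCountTable()
  expect_equal(symbolDistribution(tab, "A", alpha = 1), rep(0.25, 4),
               ignore_attr = TRUE)
  for (i in 1:3) updateModel(tab, "AA")          # counts A->A three times
  p <- symbolDistribution(tab, "A", alpha = 1)
  expect_equal(unname(p), c(4, 1, 1, 1) / 7)
  tab2 <- newCountTable()
  updateModel(tab2, "CA")                        # counts C->A once
  p2 <- symbolDistribution(tab2, "C", alpha = 1 / 50)
  expect_equal(unname(p2[1]), 1.02 / 1.08)
  expect_equal(sum(p2), 1)
  expect_error(symbolDistribution(tab, "A", alpha = 0), "alpha")
})

test_that("irExpand reverse-complements the window and splits context from symbol", {
  expect_equal(irExpand("ACG"), list(context = "CG", symbol = "T"))
  expect_equal(irExpand("ATA"), list(context = "TA", symbol = "T"))
  # involution: expanding the reverse complement recovers (context, symbol)
  bases <- c("A", "C", "G", "T")
  windows <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (w in windows) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    ir <- irExpand(rc)
    expect_equal(paste0(ir$context, ir$symbol), w)
  }
})

test_that("updateModel honors the three inverted-repeat modes", {
  get_counts <- function(mode) {
    tab <- newCountTable()
    updateModel(tab, "ACG", irMode = mode)
    c(fwd = unname(contextCounts(tab, "AC")["G"]),
      ir = unname(contextCounts(tab, "CG")["T"]),
      total = sum(contextCounts(tab, "AC")) + sum(contextCounts(tab, "CG")))
  }
  expect_equal(get_counts(0L), c(fwd = 1, ir = 0, total = 1))
  expect_equal(get_counts(2L), c(fwd = 0, ir = 1, total = 1))
  expect_equal(get_counts(1L), c(fwd = 1, ir = 1, total = 2))
})

test_that("mixStep mixes before observing and reweights by performance", {
  u <- rep(0.25, 4)
  # equal predictions, equal gamma: symmetry keeps the weights equal
  s <- mixStep(list(u, u), c(0.5, 0.5), c(0.9, 0.9), observed = 2L)
  expect_equal(s$weights, c(0.5, 0.5))
  expect_equal(s$pMix, u)
  # direct substitution at gamma = 1
  pa <- c(0.8, 0.1, 0.05, 0.05); pb <- c(0.2, 0.4, 0.2, 0.2)
  s <- mixStep(list(pa, pb), c(0.5, 0.5), c(1, 1), observed = 1L)
  expect_equal(s$weights, c(0.8, 0.2))
  expect_equal(s$pMix, 0.5 * pa + 0.5 * pb)
  # gamma = 0 forgets all history
  s <- mixStep(list(pa, pb), c(0.99, 0.01), c(0, 0), observed = 1L)
  expect_equal(s$weights, c(0.8, 0.2))
  expect_equal(sum(s$pMix), 1)
})

test_that("compressSequence matches the homopolymer closed form", {
  cfg <- single_model_config(k = 1, alpha = 1)
  res <- compressSequence(strrep("A", 1000), cfg)
  expect_equal(totalBits(res), log2(1001 * 1002 * 1003 / 6), tolerance = 1e-9)
  expect_equal(normalizedCompression(res), 0.01366, tolerance = 1e-3)
})

test_that("the first symbol always costs exactly 2 bits under a fresh model", {
  for (cfg in list(single_model_config(0, 1), single_model_config(4, 1 / 50),
                   level16Config())) {
    for (s in c("A", "C", "G", "T")) {
      expect_equal(perSymbolBits(compressSequence(paste0(s, "ACG"), cfg))[1], 2)
    }
  }
})

test_that("compressSequence agrees with the independent accumulator across parameters", {
  cases <- expand.grid(k = c(0, 1, 2, 4), alpha = c(1, 1 / 50),
                       ir = 0:2, seed = 1:2)
  for (i in seq_len(nrow(cases))) {
    s <- random_dna(120, seed = cases$seed[i] * 17)
    cfg <- single_model_config(cases$k[i], cases$alpha[i], ir = cases$ir[i])
    got <- compressSequence(s, cfg)
    want <- oracle_compress(s, cases$k[i], cases$alpha[i], cases$ir[i])
    expect_equal(perSymbolBits(got), want$bits, tolerance = 1e-9)
    expect_equal(totalBits(got), want$total, tolerance = 1e-9)
  }
})

test_that("per-symbol bits are non-negative, conserved, and deterministic", {
  for (seed in 1:5) {
    s <- random_dna(400, seed)
    res <- compressSequence(s, level16Config())
    expect_true(all(perSymbolBits(res) >= 0))
    expect_equal(totalBits(res), sum(perSymbolBits(res)), tolerance = 1e-9)
    res2 <- compressSequence(s, level16Config())
    expect_identical(perSymbolBits(res), perSymbolBits(res2))
  }
})

test_that("i.i.d. uniform sequences compress to NC near 1 under the default mixture", {
  ncs <- vapply(1:5, function(seed) {
    normalizedCompression(compressSequence(random_dna(10000, seed + 200)))
  }, numeric(1))
  expect_true(all(ncs >= 0.95 & ncs <= 1.03))
})

test_that("compressSequence refuses unsanitized symbols", {
  expect_error(compressSequence("ACGN"), "sanitize")
})

test_that("bestLevelSweep credits the best configuration with ties to the lowest index", {
  gs <- make_toy_genomeset(nGenera = 2, len = 150)
  one <- bestLevelSweep(gs, list(level16Config()))
  expect_equal(one$summary$bestFrequency, 1)
  # tie between identical configurations goes to the first
  cfgA <- single_model_config(1, 1, label = "first")
  cfgB <- single_model_config(1, 1, label = "second")
  tie <- bestLevelSweep(gs, list(cfgA, cfgB))
  expect_true(all(tie$perRecord$best == "first"))
  expect_equal(tie$summary$bestFrequency, c(1, 0))
  # a strict superset mixture wins on every repetitive record
  seqs <- vapply(1:6, function(i) strrep(random_dna(25, i + 50), 30),
                 character(1))
  reps <- new("GenomeSet",
              sequences = Biostrings::DNAStringSet(seqs),
              meta = S4Vectors::DataFrame(accession = sprintf("r%d", 1:6),
                                          nSanitized = integer(6)))
  small <- CompressorConfig(ModelSpec(1, 1, 0.7, 0), label = "small")
  super <- CompressorConfig(list(ModelSpec(1, 1, 0.7, 0),
                                 ModelSpec(12, 1 / 50, 0.97, 0)),
                            label = "super")
  sweep <- bestLevelSweep(reps, list(small, super))
  expect_true(all(sweep$perRecord$best == "super"))
  expect_equal(sum(sweep$summary$bestFrequency), 1)
  expect_true(sweep$summary$ncSum[2] < sweep$summary$ncSum[1])
})
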