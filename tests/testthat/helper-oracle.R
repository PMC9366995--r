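# Independent brute-force oracle for single-model finite-context
# compression.  Deliberately coded from scratch (dense count matrix, no
# package building blocks) so it can cross-check the package's compressor.
#
# Symbols are 0-based integer codes A=0, C=1, G=2, T=3.  The context is the
# previous k symbols packed base-4 (earliest most significant), starting
# from the all-A context; counts start empty.  ir_mode: 0 forward counts,
# 1 forward + reverse-complement counts, 2 reverse-complement counts only.
oracle_compress <- function(seq_str, k, alpha, ir_mode = 0L) {
  v <- match(strsplit(seq_str, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  stopifnot(!anyNA(v))
  n <- length(v)
  counts <- matrix(0, nrow = 4L^k, ncol = 4L)
  ctx <- 1L
  bits <- numeric(n)
  code <- function(sym_vec) {  # pack a base-4 word, earliest first
    out <- 0
    for (s in sym_vec) out <- out * 4 + s
    out + 1
  }
  hist <- function(j) if (j >= 1) v[j] else 0L  # A padding before the start
  for (i in seq_len(n)) {
    p <- (counts[ctx, ] + alpha) / (sum(counts[ctx, ]) + 4 * alpha)
    bits[i] <- -log2(p[v[i] + 1L])
    if (ir_mode != 2L) counts[ctx, v[i] + 1L] <- counts[ctx, v[i] + 1L] + 1
    if (ir_mode != 0L) {
      window <- vapply((i - k):i, hist, integer(1))    # x[i-k] .. x[i]
      rc <- rev(3L - window)                           # reverse complement
      irc <- if (k == 0) 1 else code(rc[seq_len(k)])
      counts[irc, rc[k + 1L] + 1L] <- counts[irc, rc[k + 1L] + 1L] + 1
    }
    ctx <- if (k == 0) 1L else code(vapply((i - k + 1L):i, hist, integer(1)))
  }
  list(total = sum(bits), bits = bits)
}

# Deterministic random fixtures for property tests.
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

single_model_config <- function(k, alpha, gamma = 0.5, ir = 0L,
                                label = "single") {
  CompressorConfig(ModelSpec(k, alpha, gamma, ir), label = label)
}

# Small annotated genome set built in code: nGenera genera, two genomes
# each, full seven-rank lineage, mixed genome types.
make_toy_genomeset <- function(nGenera = 4, len = 600, seed = 100) {
  n <- nGenera * 2
  seqs <- vapply(seq_len(n), function(i) random_dna(len, seed + i),
                 character(1))
  acc <- sprintf("ACC%03d", seq_len(n))
  genus <- rep(sprintf("Genus%02d", seq_len(nGenera)), each = 2)
  fam <- rep(sprintf("Fam%02d", ceiling(seq_len(nGenera) / 2)), each = 2)
  meta <- S4Vectors::DataFrame(
    accession = acc,
    nSanitized = rep(0L, n),
    genomeType = rep(c("dsDNA", "ssRNA"), length.out = n),
    realm = rep("RealmA", n), kingdom = rep("KingdomA", n),
    phylum = rep("PhylumA", n), class = rep("ClassA", n),
    order = rep("OrderA", n), family = fam, genus = genus)
  new("GenomeSet",
      sequences = stats::setNames(Biostrings::DNAStringSet(seqs), acc),
      meta = meta)
}
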