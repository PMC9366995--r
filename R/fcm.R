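# The compressor: adaptive finite-context models with optional
# inverted-repeat updates, performance-weighted mixing, and ideal
# code-length accounting.  The per-symbol loop lives in src/fcm.cpp; the
# functions below are the constructors plus the pedagogical single-step
# building blocks (count tables, estimator, IR expansion, mixer step).

#' Construct a finite-context model specification
#'
#' @param order context depth k (0--16).
#' @param alpha positive estimator smoothing (e.g. 1 or 1/50).
#' @param gamma mixing-weight decay in \[0, 0.99\].
#' @param irMode 0 = forward counts only, 1 = forward plus reverse-complement
#'   counts, 2 = reverse-complement counts only.
#' @return a [ModelSpec-class].
#' @export
ModelSpec <- function(order, alpha = 1, gamma = 0.9, irMode = 0L) {
  new("ModelSpec", order = as.integer(order), alpha = as.numeric(alpha),
      gamma = as.numeric(gamma), irMode = as.integer(irMode))
}

#' Construct a compressor configuration
#'
#' @param models list of [ModelSpec-class] objects (or a single ModelSpec).
#' @param irOverride "none" (each model keeps its own irMode) or "0"/"1"/"2"
#'   to force one mode on every model.
#' @param label configuration name carried into results.
#' @return a [CompressorConfig-class].
#' @export
CompressorConfig <- function(models, irOverride = "none", label = "custom") {
  if (is(models, "ModelSpec")) models <- list(models)
  new("CompressorConfig", models = models,
      irOverride = as.character(irOverride), label = label)
}

#' The default two-model configuration
#'
#' A short-memory order-1 model (alpha 1, gamma 0.7, no inverted-repeat
#' detection) mixed with an order-12 model (alpha 1/50, gamma 0.97, with
#' inverted-repeat detection).  This mixture suits short, compact genomes
#' where repeats and inverted repeats sit within a small genomic span.
#'
#' @param irOverride optionally force one irMode on both models.
#' @return a [CompressorConfig-class] labelled "level16".
#' @export
level16Config <- function(irOverride = "none") {
  CompressorConfig(
    list(ModelSpec(1L, alpha = 1, gamma = 0.7, irMode = 0L),
         ModelSpec(12L, alpha = 1 / 50, gamma = 0.97, irMode = 1L)),
    irOverride = irOverride, label = "level16")
}

#' A small pool of alternative single- and multi-model configurations
#'
#' Convenience set for [bestLevelSweep()]; spans increasing context depth.
#'
#' @return named list of [CompressorConfig-class] objects, ending with the
#'   default [level16Config()].
#' @export
defaultLevels <- function() {
  list(
    k2  = CompressorConfig(ModelSpec(2L, 1, 0.9, 0L), label = "k2"),
    k6  = CompressorConfig(ModelSpec(6L, 1 / 10, 0.9, 0L), label = "k6"),
    k10 = CompressorConfig(ModelSpec(10L, 1 / 20, 0.95, 1L), label = "k10"),
    k14 = CompressorConfig(list(ModelSpec(2L, 1, 0.8, 0L),
                                ModelSpec(14L, 1 / 50, 0.97, 1L)),
                           label = "k14"),
    level16 = level16Config())
}

effective_ir_modes <- function(config) {
  modes <- vapply(config@models, function(m) m@irMode, integer(1))
  if (config@irOverride != "none")
    modes <- rep(as.integer(config@irOverride), length(modes))
  modes
}

#' Create an empty sparse count table
#'
#' Count tables map "context|symbol" keys (context as a k-mer string) to
#' positive integer counts; they are environments, so [updateModel()]
#' mutates them in place.
#'
#' @return an empty count table.
#' @export
newCountTable <- function() new.env(parent = emptyenv())

count_key <- function(context, symbol) paste(context, symbol, sep = "|")

#' Look up the count 4-vector of one context
#'
#' @param table a count table from [newCountTable()].
#' @param context k-mer context string (possibly "" for order 0).
#' @return named integer vector of counts for A, C, G, T.
#' @export
contextCounts <- function(table, context) {
  out <- vapply(BASES, function(s) {
    key <- count_key(context, s)
    if (exists(key, envir = table, inherits = FALSE))
      get(key, envir = table) else 0L
  }, integer(1))
  out
}

#' Smoothed symbol distribution of a context
#'
#' P(s) = (n(context, s) + alpha) / (sum_s' n(context, s') + 4 alpha).
#'
#' @param table a count table.
#' @param context k-mer context string.
#' @param alpha positive smoothing parameter.
#' @return probability 4-vector over A, C, G, T (sums to 1).
#' @examples
#' symbolDistribution(newCountTable(), "A", alpha = 1)  # uniform
#' @export
symbolDistribution <- function(table, context, alpha) {
  if (!(is.numeric(alpha) && alpha > 0)) stop("alpha must be positive")
  n <- contextCounts(table, context)
  (n + alpha) / (sum(n) + 4 * alpha)
}

#' Reverse-complement expansion of a (k+1)-mer window
#'
#' Reads the window (x\[i-k\], ..., x\[i\]) as a (k+1)-mer, reverse
#' complements it (A<->T, C<->G), and splits the result into the context
#' (first k symbols) and symbol (last symbol) used for the inverted-repeat
#' count update.  Applying irExpand to the reverse complement of a window
#' recovers the original window's (context, symbol).
#'
#' @param window character string of length k+1 over A/C/G/T.
#' @return list with `context` (k-mer string) and `symbol` (single base).
#' @examples
#' irExpand("ACG")  # context "CG", symbol "T"
#' @export
irExpand <- function(window) {
  stopifnot(is.character(window), length(window) == 1L, nchar(window) >= 1L)
  rc <- revcomp_chr(window)
  k <- nchar(rc) - 1L
  list(context = substr(rc, 1L, k), symbol = substr(rc, k + 1L, k + 1L))
}

#' Record one window in a count table
#'
#' irMode 0 increments only the forward (context, symbol) pair; irMode 2
#' only the reverse-complement pair from [irExpand()]; irMode 1 increments
#' both in the same table. The table is modified in place.
#'
#' @param table a count table.
#' @param window (k+1)-mer string; the last base is the observed symbol.
#' @param irMode 0, 1 or 2.
#' @return the table, invisibly.
#' @export
updateModel <- function(table, window, irMode = 0L) {
  stopifnot(irMode %in% 0:2)
  k <- nchar(window) - 1L
  bump <- function(context, symbol) {
    key <- count_key(context, symbol)
    old <- if (exists(key, envir = table, inherits = FALSE))
      get(key, envir = table) else 0L
    assign(key, old + 1L, envir = table)
  }
  if (irMode != 2L) bump(substr(window, 1L, k), substr(window, k + 1L, k + 1L))
  if (irMode != 0L) {
    ir <- irExpand(window)
    bump(ir$context, ir$symbol)
  }
  invisible(table)
}

#' One step of performance-weighted model mixing
#'
#' The mixture prediction is the weight-average of the model predictions,
#' computed before the symbol is observed; afterwards each weight is decayed
#' and rewarded, w <- w^gamma * P(observed), and the weights renormalized
#' (with a 1e-15 floor against underflow).
#'
#' @param predictions list of probability 4-vectors, one per model.
#' @param weights current positive weights summing to 1.
#' @param gammas per-model decay values in \[0, 0.99\].
#' @param observed observed base index in 1..4 (A=1 ... T=4).
#' @return list with `pMix` (probability 4-vector) and `weights` (updated).
#' @export
mixStep <- function(predictions, weights, gammas, observed) {
  stopifnot(length(predictions) == length(weights),
            length(weights) == length(gammas),
            observed %in% 1:4)
  pm <- matrix(unlist(predictions), nrow = length(predictions), byrow = TRUE)
  p_mix <- as.numeric(weights %*% pm)
  w <- weights ^ gammas * pm[, observed]
  s <- sum(w)
  if (!(s > 0) || !is.finite(s)) stop("mixer weights degenerated (all zero)")
  w <- w / s
  w <- pmax(w, 1e-15)
  list(pMix = p_mix, weights = w / sum(w))
}

#' Compress a sequence with a finite-context-model mixture
#'
#' Processes the sequence left to right. Every model starts from the all-A
#' context with an empty count table (so the first prediction is uniform and
#' costs exactly 2 bits); at each position the models' smoothed
#' distributions are mixed, the per-symbol cost is -log2 of the mixture
#' probability of the observed base, the mixing weights are updated, and
#' every model records the window under its effective irMode (its own, or
#' the configuration's override). The total is an ideal code length; no
#' bitstream is produced.
#'
#' @param x sequence: character string or [Biostrings::DNAString], strictly
#'   over A/C/G/T (sanitize first).
#' @param config a [CompressorConfig-class]; default [level16Config()].
#' @return a [CompressionResult-class].
#' @examples
#' res <- compressSequence("ACGTACGTACGT")
#' totalBits(res)
#' @export
compressSequence <- function(x, config = level16Config()) {
  stopifnot(is(config, "CompressorConfig"))
  v <- seq_to_int(x)
  modes <- effective_ir_modes(config)
  out <- .fcm_compress(
    v,
    vapply(config@models, function(m) m@order, integer(1)),
    vapply(config@models, function(m) m@alpha, numeric(1)),
    vapply(config@models, function(m) m@gamma, numeric(1)),
    modes)
  new("CompressionResult", totalBits = out$total_bits,
      perSymbolBits = out$per_symbol_bits, label = config@label)
}

#' Sweep configurations over a genome set
#'
#' Compresses every record under every configuration and reports, per
#' record, the configuration with the lowest NC (ties go to the lowest
#' configuration index), and per configuration the fraction of records where
#' it is best plus its NC sum over all records.
#'
#' @param x a [GenomeSet-class].
#' @param configs list of [CompressorConfig-class] objects
#'   (default [defaultLevels()]).
#' @return list with `perRecord` (data.frame: accession, best label, NC) and
#'   `summary` (data.frame: label, bestFrequency, ncSum).
#' @export
bestLevelSweep <- function(x, configs = defaultLevels()) {
  stopifnot(is(x, "GenomeSet"), length(x) >= 1L, length(configs) >= 1L)
  labels <- vapply(configs, function(cf) cf@label, character(1))
  seqs <- as.character(sequences(x))
  nc <- vapply(configs, function(cf) {
    vapply(seq_along(seqs), function(i)
      normalizedCompression(totalBits(compressSequence(seqs[i], cf)),
                            nchar(seqs[i])), numeric(1))
  }, numeric(length(seqs)))
  nc <- matrix(nc, nrow = length(seqs))
  best_idx <- apply(nc, 1L, which.min)  # which.min takes the first on ties
  perRecord <- data.frame(accession = accessions(x),
                          best = labels[best_idx],
                          NC = nc[cbind(seq_along(best_idx), best_idx)],
                          stringsAsFactors = FALSE)
  summary <- data.frame(
    label = labels,
    bestFrequency = vapply(seq_along(configs),
                           function(j) mean(best_idx == j), numeric(1)),
    ncSum = colSums(nc),
    stringsAsFactors = FALSE)
  list(perRecord = perRecord, summary = summary)
}
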