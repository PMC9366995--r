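#' GenomeSet: sanitized genome sequences with taxonomy metadata
#'
#' Container pairing a [Biostrings::DNAStringSet] of sanitized sequences
#' (strictly over A/C/G/T; RNA stored as DNA with U mapped to T) with a
#' per-genome [S4Vectors::DataFrame] holding, at minimum, `accession` and
#' `nSanitized` columns, and optionally `genomeType` plus the seven lineage
#' ranks realm through genus.
#'
#' @slot sequences DNAStringSet of sanitized residues.
#' @slot meta DataFrame with one row per sequence.
#' @exportClass GenomeSet
setClass("GenomeSet",
  representation(sequences = "DNAStringSet", meta = "DataFrame"))

setValidity("GenomeSet", function(object) {
  msg <- character()
  if (length(object@sequences) != nrow(object@meta))
    msg <- c(msg, "sequences and metadata must have the same length")
  if (!all(c("accession", "nSanitized") %in% colnames(object@meta)))
    msg <- c(msg, "metadata must contain 'accession' and 'nSanitized' columns")
  else {
    ns <- object@meta$nSanitized
    if (any(ns < 0) || any(ns > width(object@sequences)))
      msg <- c(msg, "nSanitized must lie in [0, sequence length]")
  }
  if (length(object@sequences) > 0) {
    freq <- Biostrings::alphabetFrequency(object@sequences)
    bad <- rowSums(freq[, !colnames(freq) %in% BASES, drop = FALSE])
    if (any(bad > 0))
      msg <- c(msg, "sequences must contain only A/C/G/T; sanitize first")
  }
  if (length(msg)) msg else TRUE
})

#' ModelSpec: one finite-context model
#'
#' @slot order integer context depth k (0--16).
#' @slot alpha positive smoothing parameter of the count estimator.
#' @slot gamma decay of the mixing weight, in \[0, 0.99\].
#' @slot irMode 0 (forward counts only), 1 (forward plus reverse-complement
#'   counts) or 2 (reverse-complement counts only).
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(order = "integer", alpha = "numeric", gamma = "numeric",
                 irMode = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (object@order < 0L || object@order > 16L)
    msg <- c(msg, "order must lie in [0, 16]")
  if (!(object@alpha > 0)) msg <- c(msg, "alpha must be positive")
  if (object@gamma < 0 || object@gamma > 0.99)
    msg <- c(msg, "gamma must lie in [0, 0.99]")
  if (!object@irMode %in% 0:2) msg <- c(msg, "irMode must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' CompressorConfig: an ordered mixture of finite-context models
#'
#' @slot models list of [ModelSpec-class] objects.
#' @slot irOverride "none" or "0"/"1"/"2"; when not "none", forces every
#'   model's irMode during compression.
#' @slot label human-readable configuration name.
#' @exportClass CompressorConfig
setClass("CompressorConfig",
  representation(models = "list", irOverride = "character", label = "character"))

setValidity("CompressorConfig", function(object) {
  msg <- character()
  if (length(object@models) < 1L) msg <- c(msg, "at least one model is required")
  if (!all(vapply(object@models, is, logical(1), class2 = "ModelSpec")))
    msg <- c(msg, "models must all be ModelSpec objects")
  if (!object@irOverride %in% c("none", "0", "1", "2"))
    msg <- c(msg, "irOverride must be 'none', '0', '1' or '2'")
  if (length(msg)) msg else TRUE
})

#' CompressionResult: ideal code length of one sequence
#'
#' @slot totalBits total code length C(x) in bits.
#' @slot perSymbolBits per-position code lengths, length |x|.
#' @slot label label of the configuration used.
#' @exportClass CompressionResult
setClass("CompressionResult",
  representation(totalBits = "numeric", perSymbolBits = "numeric",
                 label = "character"))

setValidity("CompressionResult", function(object) {
  msg <- character()
  if (any(object@perSymbolBits < 0)) msg <- c(msg, "per-symbol bits must be >= 0")
  if (length(object@perSymbolBits) &&
      abs(object@totalBits - sum(object@perSymbolBits)) >
        1e-6 * max(1, object@totalBits))
    msg <- c(msg, "totalBits must equal the sum of perSymbolBits")
  if (length(msg)) msg else TRUE
})

#' ComplexityProfile: minimal bidirectional per-position code lengths
#'
#' @slot accession sequence identifier.
#' @slot bitsForward,bitsBackward,bitsMin numeric series of length |x|;
#'   `bitsMin` is the pointwise minimum of the other two.
#' @slot smoothed optional low-pass filtered series (length 0 when unset).
#' @slot window smoothing window size (NA when unset).
#' @exportClass ComplexityProfile
setClass("ComplexityProfile",
  representation(accession = "character", bitsForward = "numeric",
                 bitsBackward = "numeric", bitsMin = "numeric",
                 smoothed = "numeric", window = "integer"))

setValidity("ComplexityProfile", function(object) {
  msg <- character()
  n <- length(object@bitsForward)
  if (length(object@bitsBackward) != n || length(object@bitsMin) != n)
    msg <- c(msg, "forward, backward and min series must have equal length")
  else if (n > 0 &&
           max(abs(object@bitsMin - pmin(object@bitsForward,
                                         object@bitsBackward))) > 1e-9)
    msg <- c(msg, "bitsMin must be the pointwise minimum of the two passes")
  if (length(object@smoothed) && length(object@smoothed) != n)
    msg <- c(msg, "smoothed series must match profile length")
  if (length(msg)) msg else TRUE
})

#' TaxonNode: one node of an annotated rank cladogram
#'
#' @slot rank taxonomic rank of the node ("root" at the top).
#' @slot name taxon name.
#' @slot children list of child TaxonNode objects, lexicographic by name.
#' @slot mean mean of the annotated measure over descendant leaves.
#' @slot count number of genome rows under the node.
#' @slot measure name of the annotated measure.
#' @exportClass TaxonNode
setClass("TaxonNode",
  representation(rank = "character", name = "character", children = "list",
                 mean = "numeric", count = "integer", measure = "character"))

#' ClassificationTask: protocol of one repeated stratified holdout run
#'
#' @slot target label column to predict (genomeType or a lineage rank).
#' @slot features feature column names fed to the classifier.
#' @slot minClassSize classes with fewer members are dropped (default 4).
#' @slot testFraction held-out fraction per repetition (default 0.2).
#' @slot repetitions number of random splits averaged (default 50).
#' @slot seed base seed; repetition r uses seed + r.
#' @exportClass ClassificationTask
setClass("ClassificationTask",
  representation(target = "character", features = "character",
                 minClassSize = "integer", testFraction = "numeric",
                 repetitions = "integer", seed = "integer"))

setValidity("ClassificationTask", function(object) {
  msg <- character()
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must lie in (0, 1)")
  if (object@repetitions < 1L) msg <- c(msg, "repetitions must be >= 1")
  if (object@minClassSize < 1L) msg <- c(msg, "minClassSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TaskResult: summary of a repeated stratified holdout run
#'
#' @slot classifier classifier family name.
#' @slot meanAccuracy mean test accuracy over repetitions, in percent.
#' @slot meanF1 mean weighted F1 over repetitions, in \[0, 1\].
#' @slot nClasses,nSamples task size after class pruning.
#' @slot pHitRandom analytic random-classifier accuracy, in percent.
#' @slot details per-repetition accuracy and F1 plus classifier settings.
#' @exportClass TaskResult
setClass("TaskResult",
  representation(classifier = "character", meanAccuracy = "numeric",
                 meanF1 = "numeric", nClasses = "integer",
                 nSamples = "integer", pHitRandom = "numeric",
                 details = "list"))
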