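# Generics and basic methods for the package's S4 containers.

#' @rdname GenomeSet-class
#' @param x,object a GenomeSet.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname GenomeSet-class
#' @export
setGeneric("genomeType", function(x) standardGeneric("genomeType"))

#' @rdname GenomeSet-class
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @rdname GenomeSet-class
#' @export
setGeneric("nSanitized", function(x) standardGeneric("nSanitized"))

#' @rdname GenomeSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname CompressionResult-class
#' @param x,object a CompressionResult.
#' @export
setGeneric("totalBits", function(x) standardGeneric("totalBits"))

#' @rdname CompressionResult-class
#' @export
setGeneric("perSymbolBits", function(x) standardGeneric("perSymbolBits"))

#' @describeIn GenomeSet-class the sanitized sequences.
setMethod("sequences", "GenomeSet", function(x) x@sequences)

#' @describeIn GenomeSet-class accession identifiers.
setMethod("accessions", "GenomeSet", function(x) x@meta$accession)

#' @describeIn GenomeSet-class genome type per record (NA when unannotated).
setMethod("genomeType", "GenomeSet", function(x) {
  if ("genomeType" %in% colnames(x@meta)) x@meta$genomeType
  else rep(NA_character_, length(x))
})

#' @describeIn GenomeSet-class DataFrame of the seven lineage ranks.
setMethod("lineage", "GenomeSet", function(x) {
  have <- intersect(TAXONOMIC_RANKS, colnames(x@meta))
  out <- x@meta[, have, drop = FALSE]
  for (r in setdiff(TAXONOMIC_RANKS, have)) out[[r]] <- NA_character_
  out[, TAXONOMIC_RANKS, drop = FALSE]
})

#' @describeIn GenomeSet-class count of sanitized (replaced) symbols per record.
setMethod("nSanitized", "GenomeSet", function(x) x@meta$nSanitized)

#' @describeIn GenomeSet-class number of genomes.
setMethod("length", "GenomeSet", function(x) length(x@sequences))

#' @describeIn GenomeSet-class subset records.
#' @param i index vector.
#' @param j,...,drop ignored.
setMethod("[", "GenomeSet", function(x, i, j, ..., drop = FALSE) {
  new("GenomeSet", sequences = x@sequences[i], meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "GenomeSet", function(object) {
  cat("GenomeSet with", length(object), "genomes\n")
  if (length(object)) {
    w <- width(object@sequences)
    cat("  lengths:", min(w), "..", max(w), "bases\n")
    annotated <- sum(!is.na(lineage(object)$genus))
    cat("  taxonomy-annotated:", annotated, "\n")
  }
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec(k=%d, alpha=%g, gamma=%g, irMode=%d)\n",
              object@order, object@alpha, object@gamma, object@irMode))
})

setMethod("show", "CompressorConfig", function(object) {
  cat(sprintf("CompressorConfig '%s' (%d models, irOverride=%s)\n",
              object@label, length(object@models), object@irOverride))
  for (m in object@models) show(m)
})

#' @describeIn CompressionResult-class total code length in bits.
setMethod("totalBits", "CompressionResult", function(x) x@totalBits)

#' @describeIn CompressionResult-class per-position code lengths.
setMethod("perSymbolBits", "CompressionResult", function(x) x@perSymbolBits)

setMethod("show", "CompressionResult", function(object) {
  n <- length(object@perSymbolBits)
  cat(sprintf("CompressionResult [%s]: %.2f bits over %d symbols (NC = %.4f)\n",
              object@label, object@totalBits, n,
              object@totalBits / (2 * n)))
})

setMethod("show", "ComplexityProfile", function(object) {
  cat(sprintf("ComplexityProfile '%s': %d positions, mean min-bits %.3f%s\n",
              object@accession, length(object@bitsMin), mean(object@bitsMin),
              if (length(object@smoothed))
                sprintf(", smoothed (window %d)", object@window) else ""))
})

setMethod("show", "TaxonNode", function(object) {
  cat(sprintf("TaxonNode %s '%s': %s mean %.4f over %d genomes, %d children\n",
              object@rank, object@name, object@measure, object@mean,
              object@count, length(object@children)))
})

setMethod("show", "TaskResult", function(object) {
  cat(sprintf(
    "TaskResult [%s]: accuracy %.2f%%, weighted F1 %.4f (%d classes, %d samples, p_hit %.2f%%)\n",
    object@classifier, object@meanAccuracy, object@meanF1,
    object@nClasses, object@nSamples, object@pHitRandom))
})
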