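# Scalar complexity and composition measures per genome, and the
# per-genome feature table.

#' Normalized compression
#'
#' NC(x) = C(x) / (2 |x|): the code length divided by the log2(4)-bits-per-
#' base capacity of the quaternary alphabet. Values near 1 indicate an
#' incompressible (complex) sequence, values near 0 a fully redundant one.
#'
#' @param totalBits code length C(x) in bits (or a [CompressionResult-class]).
#' @param length sequence length |x| in bases (ignored when `totalBits` is a
#'   CompressionResult).
#' @return NC value.
#' @export
normalizedCompression <- function(totalBits, length = NULL) {
  if (is(totalBits, "CompressionResult")) {
    length <- base::length(perSymbolBits(totalBits))
    totalBits <- totalBits(totalBits)
  }
  stopifnot(is.numeric(totalBits), totalBits >= 0)
  if (is.null(length) || length < 1) stop("sequence length must be >= 1")
  totalBits / (2 * length)
}

#' GC-content in percent
#'
#' @param x sequence string or DNAString over A/C/G/T.
#' @return 100 x (number of G or C bases) / |x|.
#' @examples
#' gcContent("ACGT")  # 50
#' @export
gcContent <- function(x) {
  v <- seq_to_int(x)
  if (length(v) == 0L) stop("empty sequence")
  100 * mean(v == 1L | v == 2L)  # C = 1, G = 2
}

#' Normalized compression capacity under the IR-only mode
#'
#' NCC = 1 - NC_IR2, retained only when strictly positive; non-positive
#' values (the compressor could not exploit inverted repeats) are returned
#' as NA and excluded from aggregations.
#'
#' @param ncIR2 NC computed with irOverride = "2".
#' @return NCC, or NA when 1 - ncIR2 <= 0.
#' @export
nccIR2 <- function(ncIR2) {
  stopifnot(is.numeric(ncIR2), all(ncIR2 >= 0))
  out <- 1 - ncIR2
  out[out <= 0] <- NA_real_
  out
}

#' Difference between the no-IR and with-IR normalized compressions
#'
#' DIFF = NC_IR0 - NC_IR1; positive values indicate that adding
#' reverse-complement counts helped, i.e. inverted-repeat content.
#' Negative values are kept and reported.
#'
#' @param ncIR0,ncIR1 NC values under irOverride "0" and "1".
#' @return the difference.
#' @export
irDifference <- function(ncIR0, ncIR1) {
  stopifnot(all(ncIR0 >= 0), all(ncIR1 >= 0))
  ncIR0 - ncIR1
}

#' Normalized redundancy
#'
#' NR(x) = 1 - NC(x): the fraction of the 2-bits-per-base capacity not
#' needed to describe the sequence.
#'
#' @param nc NC value(s).
#' @return NR value(s).
#' @export
normalizedRedundancy <- function(nc) {
  stopifnot(all(nc >= 0))
  1 - nc
}

#' Per-genome feature vector
#'
#' Runs the compressor four times on one sequence -- with the configuration
#' as given (NC_best) and with irOverride forced to "0", "1" and "2" -- and
#' assembles the scalar features: sequence length (SL), GC-content (GC), the
#' four NC values, NCC, DIFF and NR. Deterministic.
#'
#' @param x sequence string or DNAString.
#' @param accession identifier carried into the row.
#' @param config base [CompressorConfig-class] (default [level16Config()]).
#' @return one-row data.frame with columns accession, SL, GC, NC_best,
#'   NC_IR0, NC_IR1, NC_IR2, NCC, DIFF, NR.
#' @export
featureVector <- function(x, accession = "seq", config = level16Config()) {
  s <- if (is.character(x)) x else as.character(x)
  n <- nchar(s)
  nc_of <- function(cf) normalizedCompression(compressSequence(s, cf))
  nc_best <- nc_of(config)
  cfg0 <- config; cfg0@irOverride <- "0"
  cfg1 <- config; cfg1@irOverride <- "1"
  cfg2 <- config; cfg2@irOverride <- "2"
  nc0 <- nc_of(cfg0); nc1 <- nc_of(cfg1); nc2 <- nc_of(cfg2)
  data.frame(accession = accession, SL = n, GC = gcContent(s),
             NC_best = nc_best, NC_IR0 = nc0, NC_IR1 = nc1, NC_IR2 = nc2,
             NCC = nccIR2(nc2), DIFF = irDifference(nc0, nc1),
             NR = normalizedRedundancy(nc_best),
             stringsAsFactors = FALSE)
}

#' Feature table of a genome set
#'
#' Applies [featureVector()] to every record and joins the genome type and
#' lineage annotation columns, yielding the table consumed by
#' [outlierFilter()], [aggregateByRank()], [buildCladogram()] and the
#' classification harness.
#'
#' @param x a [GenomeSet-class].
#' @param config base [CompressorConfig-class].
#' @return data.frame with one row per accession.
#' @export
genomeFeatures <- function(x, config = level16Config()) {
  stopifnot(is(x, "GenomeSet"))
  seqs <- as.character(sequences(x))
  rows <- lapply(seq_along(seqs), function(i)
    featureVector(seqs[i], accession = accessions(x)[i], config = config))
  out <- do.call(rbind, rows)
  out$genomeType <- genomeType(x)
  lin <- lineage(x)
  for (r in TAXONOMIC_RANKS) out[[r]] <- lin[[r]]
  rownames(out) <- NULL
  out
}
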