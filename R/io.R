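# FASTA ingestion, sequence sanitization and taxonomy filtering.

#' Sanitize a raw sequence to the quaternary alphabet
#'
#' Uppercases the input, maps U/u to T (RNA is stored as DNA so a single
#' alphabet serves the compressor), and replaces every remaining symbol
#' outside \{A,C,G,T\} by a base drawn uniformly from the four bases.
#' Replacements are consumed in sequence order from an RNG seeded by `seed`,
#' so a fixed seed gives reproducible output; U-to-T mapping and case folding
#' are not counted as replacements.
#'
#' @param raw single non-empty character string.
#' @param seed integer seed for the replacement RNG, or NULL to consume the
#'   current RNG stream (used when one seed covers a whole file).
#' @return list with `sequence` (cleaned string) and `nReplaced`.
#' @examples
#' sanitizeSequence("ACGU", seed = 1)   # "ACGT", 0 replacements
#' sanitizeSequence("ACGN", seed = 1)   # N replaced reproducibly
#' @export
sanitizeSequence <- function(raw, seed = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (nchar(raw) == 0L) stop("zero-length sequence record")
  up <- chartr("u", "T", chartr("U", "T", toupper(raw)))
  ch <- strsplit(up, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% BASES)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    ch[bad] <- with_seed(seed, sample(BASES, n_bad, replace = TRUE))
  }
  list(sequence = paste(ch, collapse = ""), nReplaced = n_bad)
}

#' Read genomes from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file, sanitizes every
#' sequence with [sanitizeSequence()] under a single file-level seed
#' (replacement draws are consumed across records in file order), and
#' returns a [GenomeSet-class]. The accession is the header token before the
#' first whitespace. When `meta` is supplied the records are annotated via
#' [attachMetadata()].
#'
#' @param path FASTA file path.
#' @param seed integer seed for the replacement RNG.
#' @param meta optional metadata table from [readMetadata()].
#' @return a [GenomeSet-class]; empty (with a warning) for an empty file.
#' @export
readGenomes <- function(path, seed = 1L, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(new("GenomeSet", sequences = DNAStringSet(),
               meta = DataFrame(accession = character(),
                                nSanitized = integer())))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA: sequence data before any header at line ",
         nonempty[1])
  raw <- readBStringSet(path)
  accession <- vapply(names(raw),
                      function(h) strsplit(trimws(h), "\\s+")[[1]][1],
                      character(1), USE.NAMES = FALSE)
  cleaned <- character(length(raw))
  n_rep <- integer(length(raw))
  with_seed(seed, {
    for (i in seq_along(raw)) {
      s <- sanitizeSequence(as.character(raw[[i]]), seed = NULL)
      cleaned[i] <- s$sequence
      n_rep[i] <- s$nReplaced
    }
  })
  gs <- new("GenomeSet",
            sequences = setNames(DNAStringSet(cleaned), accession),
            meta = DataFrame(accession = accession, nSanitized = n_rep))
  if (!is.null(meta)) gs <- attachMetadata(gs, meta)
  gs
}

#' Write a GenomeSet back to FASTA
#'
#' @param x a [GenomeSet-class].
#' @param path output file path.
#' @export
writeGenomes <- function(x, path) {
  stopifnot(is(x, "GenomeSet"))
  writeXStringSet(setNames(x@sequences, accessions(x)), path)
  invisible(path)
}

#' Read a taxonomy/metadata sidecar table
#'
#' TSV with a header row and columns `accession`, `genome_type` and the
#' seven lineage ranks realm through genus. Empty cells are treated as
#' missing lineage information.
#'
#' @param path TSV file path.
#' @return a [S4Vectors::DataFrame] keyed by accession.
#' @export
readMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("", "NA"))
  need <- c("accession", "genome_type", TAXONOMIC_RANKS)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("metadata table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("metadata accession values must be unique")
  if (!all(is.na(df$genome_type) | df$genome_type %in% GENOME_TYPES))
    stop("genome_type values must be one of: ",
         paste(GENOME_TYPES, collapse = ", "))
  DataFrame(df[, need, drop = FALSE])
}

#' Attach metadata to a GenomeSet
#'
#' Left-joins genome type and lineage onto the records by accession; records
#' absent from the table are kept with missing annotations (and are treated
#' as lacking taxonomy by [filterByTaxonomy()]).
#'
#' @param x a [GenomeSet-class].
#' @param meta table from [readMetadata()].
#' @return annotated [GenomeSet-class].
#' @export
attachMetadata <- function(x, meta) {
  stopifnot(is(x, "GenomeSet"))
  idx <- match(accessions(x), meta$accession)
  m <- x@meta
  m$genomeType <- as.character(meta$genome_type)[idx]
  for (r in TAXONOMIC_RANKS) m[[r]] <- as.character(meta[[r]])[idx]
  new("GenomeSet", sequences = x@sequences, meta = m)
}

#' Filter genomes on taxonomy completeness
#'
#' Retains only records whose lineage carries a non-empty value for every
#' rank realm through genus and where no rank value contains the token
#' "unclassified" (case-insensitive). Mirrors the curation applied to
#' reference databases before complexity aggregation.
#'
#' @param x an annotated [GenomeSet-class].
#' @param ranks ranks that must be present (default: all seven).
#' @return the retained subset of `x`.
#' @export
filterByTaxonomy <- function(x, ranks = TAXONOMIC_RANKS) {
  stopifnot(is(x, "GenomeSet"), all(ranks %in% TAXONOMIC_RANKS))
  lin <- lineage(x)
  keep <- rep(TRUE, length(x))
  for (r in ranks) {
    v <- lin[[r]]
    keep <- keep & !is.na(v) & nzchar(v) &
      !grepl("unclassified", v, ignore.case = TRUE)
  }
  x[keep]
}
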