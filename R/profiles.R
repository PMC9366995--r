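# Minimal bidirectional complexity profiles: per-position code lengths in
# both directions, pointwise minimum, low-pass smoothing, and region calls.

#' Minimal bidirectional complexity profile
#'
#' Compresses the sequence start-to-end (forward pass) and end-to-start
#' (backward pass: the sequence is reversed, compressed, and the per-symbol
#' series re-reversed so index i always refers to x\[i\] in original
#' coordinates), and takes the pointwise minimum B(x_i) of the two
#' per-symbol series. The backward direction is plain reversal by default;
#' set `backward = "revcomp"` to traverse the reverse complement instead
#' (inverted-repeat structure is normally already captured by the IR model
#' modes).
#'
#' @param x sequence string or DNAString, length >= 2.
#' @param config a [CompressorConfig-class].
#' @param accession identifier stored in the profile.
#' @param backward "reverse" (default) or "revcomp".
#' @return a [ComplexityProfile-class].
#' @export
bidirectionalProfile <- function(x, config = level16Config(),
                                 accession = "seq",
                                 backward = c("reverse", "revcomp")) {
  backward <- match.arg(backward)
  s <- if (is.character(x)) x else as.character(x)
  if (nchar(s) < 2L) stop("profile requires a sequence of length >= 2")
  fwd <- perSymbolBits(compressSequence(s, config))
  rev_s <- if (backward == "reverse")
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  else revcomp_chr(s)
  bwd <- rev(perSymbolBits(compressSequence(rev_s, config)))
  new("ComplexityProfile", accession = accession,
      bitsForward = fwd, bitsBackward = bwd, bitsMin = pmin(fwd, bwd),
      smoothed = numeric(), window = NA_integer_)
}

blackman_weights <- function(window) {
  if (window == 1L) return(1)
  w <- as.numeric(signal::blackman(window))
  w / sum(w)
}

#' Low-pass smooth a profile series
#'
#' Convolves the series with a normalized Blackman window (weights sum to
#' 1); edges are handled by mirror padding, so the output has the input's
#' length and constants are preserved exactly.
#'
#' @param series numeric series (or a [ComplexityProfile-class], whose
#'   `bitsMin` series is smoothed and stored in the `smoothed` slot).
#' @param window odd positive integer, at most the series length
#'   (default 501, for visualization of genome-scale profiles).
#' @return smoothed numeric series, or the updated profile object.
#' @export
smoothProfile <- function(series, window = 501L) {
  if (is(series, "ComplexityProfile")) {
    obj <- series
    obj@smoothed <- smoothProfile(obj@bitsMin, window)
    obj@window <- as.integer(window)
    return(obj)
  }
  window <- as.integer(window)
  n <- length(series)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  if (window > n) stop("window larger than the series")
  if (window == 1L) return(series)
  h <- (window - 1L) %/% 2L
  padded <- c(rev(series[seq_len(h)]), series,
              rev(series[(n - h + 1L):n]))
  out <- stats::filter(padded, blackman_weights(window), sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

#' Call low-complexity regions on a smoothed profile
#'
#' Maximal runs where the series falls strictly below the threshold, kept
#' when at least `minLen` positions long. Returned as 1-based closed
#' intervals.
#'
#' @param smoothed numeric series.
#' @param threshold bits threshold (>= 0).
#' @param minLen minimum run length.
#' @return an [IRanges::IRanges] of the called regions (sorted,
#'   non-overlapping).
#' @export
callRegions <- function(smoothed, threshold, minLen = 1L) {
  stopifnot(threshold >= 0, minLen >= 1L)
  r <- rle(smoothed < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  IRanges(start = starts[keep], end = ends[keep])
}

#' Write a profile as TSV
#'
#' Columns: position (1-based), forward, backward, min, and smoothed when
#' present.
#'
#' @param profile a [ComplexityProfile-class].
#' @param path output path.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "ComplexityProfile"))
  df <- data.frame(position = seq_along(profile@bitsMin),
                   forward = profile@bitsForward,
                   backward = profile@bitsBackward,
                   min = profile@bitsMin)
  if (length(profile@smoothed)) df$smoothed <- profile@smoothed
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called regions as BED
#'
#' The 1-based closed intervals are converted to BED's 0-based half-open
#' convention at write time.
#'
#' @param regions an [IRanges::IRanges] from [callRegions()].
#' @param name sequence name for the BED chrom column.
#' @param path output path.
#' @export
writeRegionsBed <- function(regions, name, path) {
  df <- data.frame(chrom = rep(name, length(regions)),
                   start = BiocGenerics::start(regions) - 1L,
                   end = BiocGenerics::end(regions))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
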