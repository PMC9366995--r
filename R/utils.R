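# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Character sequence -> 0-based integer codes (A=0, C=1, G=2, T=3).
seq_to_int <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  v <- utf8ToInt(x)
  codes <- rep(NA_integer_, 128L)
  codes[utf8ToInt("A")] <- 0L; codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L; codes[utf8ToInt("T")] <- 3L
  codes[utf8ToInt("a")] <- 0L; codes[utf8ToInt("c")] <- 1L
  codes[utf8ToInt("g")] <- 2L; codes[utf8ToInt("t")] <- 3L
  out <- codes[v]
  if (anyNA(out) || any(v > 128L))
    stop("sequence contains symbols outside {A,C,G,T}; run sanitizeSequence() first")
  out
}

int_to_seq <- function(v) paste(BASES[v + 1L], collapse = "")

# Reverse complement for plain character strings (A<->T, C<->G).
revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
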