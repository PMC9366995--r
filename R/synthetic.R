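# Generators emulating the inputs the analysis assumes: random DNA, the
# inverted-repeat construct, substitution mutation, the mutation-rate
# benchmark sweep, and labeled feature tables for the classification
# harness.  All generators are deterministic per (parameters, seed).

#' Random i.i.d. uniform DNA sequence
#'
#' @param n sequence length (>= 1).
#' @param seed integer seed.
#' @return character string over A/C/G/T.
#' @export
randomSequence <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, paste(sample(BASES, n, replace = TRUE), collapse = ""))
}

#' Inverted-repeat construct
#'
#' A sequence of n bases whose second half is the reverse complement of the
#' (random) first half -- the canonical maximal-inverted-repeat test case.
#' The default n of 10,000 matches the median viral genome size scale.
#'
#' @param n even length (>= 2).
#' @param seed integer seed for the first half.
#' @return character string of length n.
#' @export
makeIRConstruct <- function(n = 10000L, seed = 1L) {
  if (n < 2 || n %% 2 != 0) stop("n must be even and >= 2")
  w <- randomSequence(n %/% 2, seed)
  paste0(w, revcomp_chr(w))
}

#' Point-substitution mutation
#'
#' Each position is independently substituted with probability `rate`; a
#' substituted base is replaced by one of the other three bases uniformly
#' (so rate 1 changes every base). Length is preserved.
#'
#' @param x sequence string.
#' @param rate substitution probability per base, in \[0, 1\].
#' @param seed integer seed.
#' @return mutated character string.
#' @export
mutateSequence <- function(x, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  v <- seq_to_int(x)
  n <- length(v)
  with_seed(seed, {
    hit <- runif(n) < rate
    shift <- sample(3L, n, replace = TRUE)  # drawn for all positions so the
                                            # stream layout is rate-independent
    v[hit] <- (v[hit] + shift[hit]) %% 4L
  })
  int_to_seq(v)
}

#' Inverted-repeat mutation benchmark
#'
#' For each substitution rate and replicate, builds [makeIRConstruct()],
#' mutates the whole sequence at that rate (each rate is generated
#' independently), computes NC under irOverride "0", "1" and "2" plus
#' DIFF = NC_IR0 - NC_IR1, and reports per-rate means. As mutations
#' accumulate the inverted repeat erodes: NC_IR2 rises and DIFF falls,
#' while NC_IR0 stays flat.
#'
#' @param n construct length (default 10,000).
#' @param rates increasing substitution rates (default 0 to 0.10 by 0.01).
#' @param replicates replicates per rate (default 5); replicate j uses
#'   seed + j for the construct.
#' @param config base [CompressorConfig-class].
#' @param seed integer base seed.
#' @return data.frame with columns rate, NC_IR0, NC_IR1, NC_IR2, DIFF;
#'   attributes `replicates` and `seed`.
#' @export
irBenchmark <- function(n = 10000L, rates = seq(0, 0.10, by = 0.01),
                        replicates = 5L, config = level16Config(),
                        seed = 1L) {
  stopifnot(all(rates >= 0), all(rates <= 1), !is.unsorted(rates, strictly = TRUE),
            replicates >= 1L)
  cfg <- lapply(c("0", "1", "2"), function(m) {
    cf <- config; cf@irOverride <- m; cf
  })
  res <- matrix(0, nrow = length(rates), ncol = 3L)
  for (j in seq_len(replicates)) {
    construct <- makeIRConstruct(n, seed = seed + j)
    for (i in seq_along(rates)) {
      mut <- mutateSequence(construct, rates[i],
                            seed = seed + j + 1000L * i)
      for (m in 1:3)
        res[i, m] <- res[i, m] +
          normalizedCompression(compressSequence(mut, cfg[[m]]))
    }
  }
  res <- res / replicates
  out <- data.frame(rate = rates, NC_IR0 = res[, 1], NC_IR1 = res[, 2],
                    NC_IR2 = res[, 3], DIFF = res[, 1] - res[, 2])
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  out
}

#' Labeled synthetic feature table
#'
#' Draws feature vectors from class-specific multivariate normals (unit
#' variance, independent axes) whose means are `separation` standard
#' deviations apart along every feature axis, using the same column names
#' as [genomeFeatures()] classification features. Separation 0 yields
#' class-blind features; large separations yield a trivially separable
#' task.
#'
#' @param nClasses number of classes (>= 2).
#' @param perClass rows per class (>= 4, the default pruning threshold).
#' @param separation distance between adjacent class means, in SD units.
#' @param seed integer seed.
#' @return data.frame with feature columns SL, GC, NC_best, NC_IR0,
#'   NC_IR1, NC_IR2 and a factor column `label`.
#' @export
syntheticFeatureTable <- function(nClasses, perClass, separation = 1,
                                  seed = 1L) {
  stopifnot(nClasses >= 2L, perClass >= 4L)
  feats <- c("SL", "GC", "NC_best", "NC_IR0", "NC_IR1", "NC_IR2")
  with_seed(seed, {
    rows <- lapply(seq_len(nClasses), function(cl) {
      m <- matrix(rnorm(perClass * length(feats), mean = separation * cl),
                  nrow = perClass)
      df <- as.data.frame(m)
      names(df) <- feats
      df$label <- sprintf("class_%02d", cl)
      df
    })
    out <- do.call(rbind, rows)
  })
  out$label <- factor(out$label)
  rownames(out) <- NULL
  out
}
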