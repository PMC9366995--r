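# Dataset-level pipeline: outlier filtering, per-rank aggregation, and
# annotated cladogram construction/export.

AGGREGATION_RANKS <- c("genomeType", TAXONOMIC_RANKS)

#' Filter feature-table outliers at mean +/- k standard deviations
#'
#' Computes mean and SD per listed measure over the full input table in a
#' single pass (statistics are not recomputed after removals), then removes
#' any row with at least one measure strictly outside \[mu - k sd,
#' mu + k sd\]; boundary values are kept. A measure with zero SD removes
#' nothing.
#'
#' @param table feature table from [genomeFeatures()].
#' @param k width of the band in SD units (default 3).
#' @param measures columns screened (default SL, GC, NC_best).
#' @return list with `kept` (the filtered table) and `removed` (accessions).
#' @export
outlierFilter <- function(table, k = 3,
                          measures = c("SL", "GC", "NC_best")) {
  stopifnot(nrow(table) > 0, k > 0, all(measures %in% colnames(table)))
  drop <- rep(FALSE, nrow(table))
  for (m in measures) {
    v <- table[[m]]
    mu <- mean(v, na.rm = TRUE)
    sigma <- sd(v, na.rm = TRUE)
    if (is.na(sigma) || sigma == 0) next
    drop <- drop | (!is.na(v) & (v < mu - k * sigma | v > mu + k * sigma))
  }
  list(kept = table[!drop, , drop = FALSE],
       removed = table$accession[drop])
}

#' Aggregate measures by a taxonomic rank or genome type
#'
#' Per group: the mean and count of every numeric measure. NCC means are
#' computed over present (strictly positive capacity) values only, with
#' their own count column.
#'
#' @param table feature table with annotation columns.
#' @param rank one of "genomeType", "realm", "kingdom", "phylum", "class",
#'   "order", "family", "genus".
#' @param measures numeric columns to summarize.
#' @return data.frame with one row per group: group, n, then mean_<measure>
#'   columns (plus n_NCC when NCC is included).
#' @export
aggregateByRank <- function(table, rank,
                            measures = c("SL", "GC", "NC_best", "NC_IR0",
                                         "NC_IR1", "NC_IR2", "NCC", "DIFF")) {
  if (!rank %in% AGGREGATION_RANKS)
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(AGGREGATION_RANKS, collapse = ", "))
  measures <- intersect(measures, colnames(table))
  g <- table[[rank]]
  keep <- !is.na(g)
  table <- table[keep, , drop = FALSE]
  g <- factor(g[keep])
  out <- data.frame(group = levels(g),
                    n = as.integer(table(g)),
                    stringsAsFactors = FALSE)
  for (m in measures) {
    v <- table[[m]]
    means <- tapply(v, g, function(z) mean(z, na.rm = TRUE))
    means[!is.finite(means)] <- NA_real_
    out[[paste0("mean_", m)]] <- as.numeric(means)
    if (m == "NCC")
      out$n_NCC <- as.integer(tapply(v, g, function(z) sum(!is.na(z))))
  }
  out
}

#' Build an annotated rank cladogram
#'
#' Builds the realm-to-genus rank tree from the lineage columns of a
#' feature table and annotates every node with the mean of `measure` over
#' its descendant genome rows (so internal means are leaf-count weighted).
#' Children are ordered lexicographically. Rows with NA in `measure` (e.g.
#' absent NCC) are excluded from means but still counted in the tree.
#'
#' @param table lineage-complete feature table.
#' @param measure annotated measure column (default "NC_best").
#' @return the root [TaxonNode-class].
#' @export
buildCladogram <- function(table, measure = "NC_best") {
  stopifnot(measure %in% colnames(table),
            all(TAXONOMIC_RANKS %in% colnames(table)))
  if (nrow(table) == 0) stop("empty feature table")
  build <- function(rows, depth) {
    if (depth > length(TAXONOMIC_RANKS)) return(list())
    rank <- TAXONOMIC_RANKS[depth]
    groups <- split(rows, rows[[rank]])
    groups <- groups[order(names(groups))]
    lapply(names(groups), function(nm) {
      sub <- groups[[nm]]
      v <- sub[[measure]]
      new("TaxonNode", rank = rank, name = nm,
          children = build(sub, depth + 1L),
          mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
          count = nrow(sub), measure = measure)
    })
  }
  v <- table[[measure]]
  new("TaxonNode", rank = "root", name = "Viruses",
      children = build(table, 1L),
      mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
      count = nrow(table), measure = measure)
}

#' Flatten a cladogram into a node statistics table
#'
#' @param tree a [TaxonNode-class].
#' @return data.frame with columns rank, name, mean, count (preorder).
#' @export
cladogramStats <- function(tree) {
  stopifnot(is(tree, "TaxonNode"))
  rows <- list()
  walk <- function(node) {
    rows[[length(rows) + 1L]] <<- data.frame(
      rank = node@rank, name = node@name, mean = node@mean,
      count = node@count, stringsAsFactors = FALSE)
    for (ch in node@children) walk(ch)
  }
  walk(tree)
  do.call(rbind, rows)
}

newick_label <- function(name) {
  if (grepl("[\\s()\\[\\]:;,']", name, perl = TRUE))
    paste0("'", gsub("'", "''", name), "'")
  else name
}

newick_string <- function(node) {
  lab <- newick_label(node@name)
  if (length(node@children) == 0L) return(lab)
  paste0("(", paste(vapply(node@children, newick_string, character(1)),
                    collapse = ","), ")", lab)
}

#' Export a cladogram as Newick plus a node annotation table
#'
#' Writes a syntactically valid Newick tree with internal node labels
#' (names containing spaces or reserved characters are single-quoted) and a
#' TSV of node statistics from [cladogramStats()].
#'
#' @param tree a [TaxonNode-class].
#' @param treePath output Newick path.
#' @param statsPath output TSV path (optional).
#' @return the Newick string, invisibly.
#' @export
exportCladogram <- function(tree, treePath, statsPath = NULL) {
  stopifnot(is(tree, "TaxonNode"))
  if (length(tree@children) == 0L && tree@rank == "root")
    stop("empty cladogram")
  nwk <- paste0(newick_string(tree), ";")
  writeLines(nwk, treePath)
  if (!is.null(statsPath))
    write.table(cladogramStats(tree), statsPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(nwk)
}
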