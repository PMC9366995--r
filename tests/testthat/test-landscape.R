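# Outlier filtering, per-rank aggregation, and annotated cladograms.

make_feature_fixture <- function() {
  gs <- make_toy_genomeset(nGenera = 4, len = 400)
  genomeFeatures(gs)
}

test_that("outlierFilter removes only rows strictly outside the mu +/- k sigma band", {
  # 99 tightly clustered values plus one planted far outlier on SL
  set.seed(5)
  tab <- data.frame(accession = sprintf("a%03d", 1:100),
                    SL = c(rep(c(9.9, 10, 10.1), 33), 50),
                    GC = rep(50, 100), NC_best = rep(0.9, 100))
  mu <- mean(tab$SL); sigma <- sd(tab$SL)
  expect_gt(tab$SL[100], mu + 4 * sigma)  # fixture sanity: beyond 4 sigma
  out <- outlierFilter(tab)
  expect_equal(out$removed, "a100")
  expect_equal(nrow(out$kept), 99L)

  # identical rows: sigma = 0 removes nothing
  same <- data.frame(accession = c("x", "y"), SL = c(5, 5), GC = c(1, 1),
                     NC_best = c(0.5, 0.5))
  expect_equal(length(outlierFilter(same)$removed), 0L)
})

test_that("a value exactly at the 3-sigma boundary is kept", {
  # symmetric base data (mean 0) plus a +/-c pair chosen so that c equals
  # exactly 3 sample SDs of the augmented data
  base <- rep(c(-1, 1), 49)
  ss <- sum(base^2)
  n0 <- length(base)
  c_val <- sqrt(9 * ss / (n0 + 1 - 18))
  v <- c(base, c_val, -c_val)
  expect_equal(c_val, 3 * sd(v), tolerance = 1e-12)
  tab <- data.frame(accession = sprintf("b%03d", seq_along(v)), SL = v,
                    GC = 50, NC_best = 0.9)
  out <- outlierFilter(tab)
  expect_equal(length(out$removed), 0L)
})

test_that("aggregateByRank averages per group with NCC over present values only", {
  tab <- data.frame(accession = c("a", "b", "c"),
                    NC_best = c(0.4, 0.6, 0.8),
                    NCC = c(NA, NA, 0.3),
                    genus = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  agg <- aggregateByRank(tab, "genus", measures = c("NC_best", "NCC"))
  g1 <- agg[agg$group == "G1", ]
  expect_equal(g1$mean_NC_best, 0.5)
  expect_equal(g1$n, 2L)
  expect_true(is.na(g1$mean_NCC))
  expect_equal(g1$n_NCC, 0L)
  g2 <- agg[agg$group == "G2", ]
  expect_equal(g2$mean_NCC, 0.3)
  # count-weighted grand mean equals the table mean
  expect_equal(sum(agg$mean_NC_best * agg$n) / sum(agg$n), mean(tab$NC_best))
  expect_error(aggregateByRank(tab, "species"), "unknown rank")
})

test_that("cladogram node means are leaf-count-weighted and children sorted", {
  ft <- make_feature_fixture()
  tree <- buildCladogram(ft, measure = "NC_best")
  expect_equal(tree@count, nrow(ft))
  expect_equal(tree@mean, mean(ft$NC_best))
  # walk down to a family with two genera
  realm <- tree@children[[1]]
  fam <- realm@children[[1]]@children[[1]]@children[[1]]@children[[1]]@children[[1]]
  expect_equal(fam@rank, "family")
  expect_equal(length(fam@children), 2L)
  genus_names <- vapply(fam@children, function(x) x@name, character(1))
  expect_equal(genus_names, sort(genus_names))
  weighted <- sum(vapply(fam@children, function(g) g@mean * g@count,
                         numeric(1))) / fam@count
  expect_equal(fam@mean, weighted)
})

test_that("a single-row table yields a pure path annotated with that row's value", {
  ft <- make_feature_fixture()[1, , drop = FALSE]
  tree <- buildCladogram(ft, measure = "GC")
  node <- tree
  depth <- 0L
  while (length(node@children)) {
    expect_equal(length(node@children), 1L)
    expect_equal(node@mean, ft$GC)
    expect_equal(node@count, 1L)
    node <- node@children[[1]]
    depth <- depth + 1L
  }
  expect_equal(depth, 7L)  # realm..genus below the root
  expect_equal(node@rank, "genus")
})

test_that("exported cladograms are valid Newick and round-trip their statistics", {
  skip_if_not_installed("ape")
  ft <- make_feature_fixture()
  tree <- buildCladogram(ft, measure = "NC_best")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  stats <- withr::local_tempfile(fileext = ".tsv")
  exportCladogram(tree, nwk, stats)
  parsed <- ape::read.tree(nwk)
  expect_s3_class(parsed, "phylo")
  expect_setequal(parsed$tip.label, unique(ft$genus))
  st <- read.delim(stats)
  expect_equal(nrow(st), nrow(cladogramStats(tree)))
  expect_equal(st$mean, cladogramStats(tree)$mean, tolerance = 1e-9)
  # re-aggregating the leaves reproduces every internal mean
  for (i in seq_len(nrow(st))) {
    if (st$rank[i] == "genus") next
    if (st$rank[i] == "root") rows <- ft
    else rows <- ft[ft[[st$rank[i]]] == st$name[i], , drop = FALSE]
    expect_equal(st$mean[i], mean(rows$NC_best), tolerance = 1e-9)
  }
})

test_that("taxon names with spaces are quoted in Newick output", {
  ft <- make_feature_fixture()
  ft$genus[ft$genus == "Genus01"] <- "Genus one"
  tree <- buildCladogram(ft, measure = "NC_best")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  out <- exportCladogram(tree, nwk)
  expect_match(out, "'Genus one'", fixed = TRUE)
  skip_if_not_installed("ape")
  parsed <- ape::read.tree(nwk)
  expect_true(any(grepl("Genus one", parsed$tip.label)))
})

test_that("an empty cladogram cannot be exported", {
  tree <- new("TaxonNode", rank = "root", name = "Viruses", children = list(),
              mean = NA_real_, count = 0L, measure = "NC_best")
  expect_error(exportCladogram(tree, tempfile()), "empty")
})
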