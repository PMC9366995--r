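# Classification harness: pruning, metrics, baseline, repeated holdout.

test_that("dropRareClasses prunes below the threshold and keeps the boundary", {
  tab <- data.frame(x = rnorm(11),
                    label = rep(c("a", "b", "c"), c(4, 4, 3)))
  out <- dropRareClasses(tab, minN = 4)
  expect_equal(sort(unique(out$label)), c("a", "b"))
  expect_equal(attr(out, "removedClasses"), "c")
  full <- data.frame(x = rnorm(8), label = rep(c("a", "b"), each = 4))
  expect_equal(nrow(dropRareClasses(full)), 8L)
  solo <- data.frame(x = rnorm(7), label = rep(c("a", "b"), c(4, 3)))
  expect_error(dropRareClasses(solo), "fewer than 2")
})

test_that("pHitRandom is 100/N regardless of class imbalance", {
  expect_equal(round(pHitRandom(rep(10, 17)), 2), 5.88)
  expect_equal(pHitRandom(c(100, 1, 1, 1, 1)), 20)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(2:50, 1)
    counts <- sample(1:1000, n, replace = TRUE)
    expect_equal(pHitRandom(counts), 100 / n)
  }
  expect_error(pHitRandom(numeric(0)), "at least one")
  expect_error(pHitRandom(c(3, 0)), "positive")
})

test_that("weightedF1 matches hand-computed confusion tables", {
  expect_equal(weightedF1(c("a", "b", "a"), c("a", "b", "a")), 1)
  # two balanced classes, everything predicted as the first:
  # F1(a) = 2*(1/2*1)/(1/2+1) = 2/3, F1(b) = 0, weights 1/2 each -> 1/3
  expect_equal(weightedF1(c("a", "a", "b", "b"), rep("a", 4)), 1 / 3)
  expect_equal(weightedF1(rep("a", 5), rep("a", 5)), 1)
  # imbalanced weights
  truth <- c("a", "a", "a", "b")
  pred <- c("a", "a", "b", "b")
  # F1(a) = 2*(1*(2/3))/(1+2/3) = 0.8; F1(b) = 2*(0.5*1)/1.5 = 2/3
  expect_equal(weightedF1(truth, pred), 0.75 * 0.8 + 0.25 * 2 / 3)
})

test_that("stratified splits preserve per-class proportions to within one sample", {
  labels <- rep(c("a", "b", "c"), c(40, 10, 4))
  split_fn <- getFromNamespace("stratified_split", "seqcomplexity")
  set.seed(31)
  for (i in 1:20) {
    test <- split_fn(labels, 0.2)
    tab <- table(labels[test])
    expect_true(abs(tab[["a"]] - 8) <= 1)
    expect_true(abs(tab[["b"]] - 2) <= 1)
    expect_true(abs(tab[["c"]] - 0.8) <= 1)
    expect_true(all(c("a", "b", "c") %in% names(tab)))  # every class held out
  }
})

test_that("well-separated classes are classified near-perfectly by every family", {
  tab <- syntheticFeatureTable(3, 20, separation = 10, seed = 41)
  task <- ClassificationTask("label", repetitions = 5, seed = 11)
  for (cl in c("LDA", "GNB", "KNN", "SVM", "XGB")) {
    r <- repeatedStratifiedHoldout(tab, task, cl)
    expect_gte(r@meanAccuracy, 99)
    expect_gte(r@meanF1, 0.99)
    expect_equal(r@nClasses, 3L)
    expect_equal(round(r@pHitRandom, 2), 33.33)
  }
})

test_that("class-blind features score at the random baseline", {
  tab <- syntheticFeatureTable(2, 100, separation = 0, seed = 17)
  task <- ClassificationTask("label", repetitions = 50, seed = 23)
  r <- repeatedStratifiedHoldout(tab, task, "LDA")
  expect_true(abs(r@meanAccuracy - 50) <= 5)
})

test_that("holdout results are reproducible and robust to duplicated features", {
  tab <- syntheticFeatureTable(2, 30, separation = 6, seed = 19)
  task <- ClassificationTask("label", repetitions = 3, seed = 7)
  a <- repeatedStratifiedHoldout(tab, task, "GNB")
  b <- repeatedStratifiedHoldout(tab, task, "GNB")
  expect_identical(a@details$accuracy, b@details$accuracy)

  dup <- tab
  dup$SL2 <- dup$SL
  task2 <- ClassificationTask("label",
                              features = c("SL", "GC", "NC_best", "NC_IR0",
                                           "NC_IR1", "NC_IR2", "SL2"),
                              repetitions = 2, seed = 7)
  for (cl in c("LDA", "GNB", "KNN", "SVM", "XGB")) {
    r <- suppressWarnings(repeatedStratifiedHoldout(dup, task2, cl))
    expect_s4_class(r, "TaskResult")
    expect_equal(r@pHitRandom, 50)
  }
})

test_that("classifyFeatures mirrors a per-task results row across classifiers", {
  tab <- syntheticFeatureTable(3, 12, separation = 8, seed = 29)
  res <- classifyFeatures(tab, "label", classifiers = c("LDA", "GNB"),
                          repetitions = 3, seed = 5)
  expect_equal(nrow(res), 2L)
  expect_equal(res$nClasses, c(3L, 3L))
  expect_equal(res$pHit, c(33.33, 33.33))
  expect_true(all(res$accuracy > 90))
})
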