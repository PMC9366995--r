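# Feature-based taxonomic classification harness: class pruning, repeated
# stratified holdout over five classifier families, metrics, and the
# analytic random-classifier baseline.

CLASSIFIERS <- c("LDA", "GNB", "KNN", "SVM", "XGB")

#' Construct a classification task
#'
#' @param target label column to predict (e.g. "genomeType", "realm",
#'   "genus", or "label" for synthetic tables).
#' @param features feature column names.
#' @param minClassSize classes with fewer members are dropped before any
#'   split (default 4).
#' @param testFraction held-out fraction (default 0.2).
#' @param repetitions number of random stratified splits averaged
#'   (default 50).
#' @param seed base seed; repetition r uses seed + r.
#' @return a [ClassificationTask-class].
#' @export
ClassificationTask <- function(target, features = c("SL", "GC", "NC_best",
                                                    "NC_IR0", "NC_IR1",
                                                    "NC_IR2"),
                               minClassSize = 4L, testFraction = 0.2,
                               repetitions = 50L, seed = 1L) {
  new("ClassificationTask", target = target, features = features,
      minClassSize = as.integer(minClassSize),
      testFraction = as.numeric(testFraction),
      repetitions = as.integer(repetitions), seed = as.integer(seed))
}

#' Drop classes with too few members
#'
#' Removes all rows whose class has fewer than `minN` members and reports
#' the removed classes; errors when fewer than two classes remain (the
#' classification task is then undefined).
#'
#' @param table labeled table.
#' @param label label column name.
#' @param minN minimum class size (default 4).
#' @return the pruned table, with attribute `removedClasses`.
#' @export
dropRareClasses <- function(table, label = "label", minN = 4L) {
  stopifnot(label %in% colnames(table))
  cl <- as.character(table[[label]])
  keep_rows <- !is.na(cl)
  counts <- table(cl[keep_rows])
  rare <- names(counts)[counts < minN]
  keep_rows <- keep_rows & !(cl %in% rare)
  out <- table[keep_rows, , drop = FALSE]
  if (length(unique(cl[keep_rows])) < 2L)
    stop("fewer than 2 classes remain after pruning; task undefined")
  attr(out, "removedClasses") <- rare
  out
}

#' Analytic accuracy of a uniformly random classifier
#'
#' p_hit = sum_i p(c_i) * (1/N) with p(c_i) the class prevalence and N the
#' number of classes; the prevalences sum to 1, so p_hit = 100/N percent
#' for any class-size distribution (invariant to imbalance).
#'
#' @param classCounts vector (or table) of per-class counts, all > 0.
#' @return expected accuracy in percent.
#' @examples
#' round(pHitRandom(rep(1, 17)), 2)  # 5.88
#' @export
pHitRandom <- function(classCounts) {
  counts <- as.numeric(classCounts)
  if (length(counts) == 0L) stop("at least one class is required")
  if (any(counts <= 0)) stop("class counts must be positive")
  p <- counts / sum(counts)
  100 * sum(p * (1 / length(counts)))
}

#' Weighted F1 score
#'
#' Per-class F1 = 2PR/(P+R) (0 when P+R = 0), averaged with weights equal
#' to the class support in the true labels.
#'
#' @param truth true class labels.
#' @param predicted predicted class labels (same length).
#' @return weighted F1 in \[0, 1\].
#' @export
weightedF1 <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

# One stratified split: per class, round(testFraction * n) test rows
# (clamped to [1, n-1]) so per-class proportions are preserved to within
# one sample.
stratified_split <- function(labels, testFraction) {
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, min(length(idx) - 1L,
                          round(testFraction * length(idx))))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

fit_predict <- function(classifier, x_train, y_train, x_test, settings) {
  y_train <- factor(y_train)
  switch(classifier,
    LDA = {
      fit <- MASS::lda(x_train, grouping = y_train)
      as.character(predict(fit, x_test)$class)
    },
    GNB = {
      fit <- e1071::naiveBayes(x_train, y_train)
      as.character(predict(fit, x_test))
    },
    KNN = {
      mu <- colMeans(x_train)
      sc <- apply(x_train, 2, sd)
      sc[sc == 0] <- 1
      tr <- scale(x_train, center = mu, scale = sc)
      te <- scale(x_test, center = mu, scale = sc)
      as.character(class::knn(tr, te, cl = y_train, k = settings$knn_k))
    },
    SVM = {
      fit <- e1071::svm(x_train, y_train)
      as.character(predict(fit, x_test))
    },
    XGB = {
      # exact greedy splits: histogram binning places thresholds at training
      # minima inside inter-class gaps, misrouting marginal points on the
      # small feature tables this harness targets
      fit <- xgboost::xgboost(x_train, y_train,
                              nrounds = settings$xgb_nrounds,
                              tree_method = "exact",
                              nthreads = 1L, verbosity = 0L)
      as.character(predict(fit, x_test, type = "class"))
    },
    stop("unknown classifier '", classifier, "'"))
}

#' Repeated stratified holdout evaluation
#'
#' For each repetition r (seeded seed + r) the labeled table is split
#' stratified by class into train and held-out fractions, the named
#' classifier family is fit on the train rows and evaluated on the test
#' rows, and accuracy plus weighted F1 are recorded; means over repetitions
#' are returned. The table must already be class-pruned
#' ([dropRareClasses()]). A repetition whose fit fails on a degenerate
#' split is re-drawn with the next seed (at most 5 attempts, with a
#' message).
#'
#' Classifier settings are the library defaults (LDA: [MASS::lda];
#' GNB/SVM: [e1071::naiveBayes]/[e1071::svm]; KNN: [class::knn] with k = 5
#' on train-standardized features; XGB: [xgboost::xgboost] with 100 rounds
#' and exact greedy split finding) and are recorded in the result details.
#'
#' @param table labeled table with numeric, finite feature columns.
#' @param task a [ClassificationTask-class]; its `target` names the label
#'   column.
#' @param classifier one of "LDA", "GNB", "KNN", "SVM", "XGB".
#' @return a [TaskResult-class].
#' @export
repeatedStratifiedHoldout <- function(table, task, classifier = "XGB") {
  stopifnot(is(task, "ClassificationTask"),
            classifier %in% CLASSIFIERS,
            task@target %in% colnames(table),
            all(task@features %in% colnames(table)))
  labels <- as.character(table[[task@target]])
  x <- as.matrix(table[, task@features, drop = FALSE])
  if (!all(is.finite(x))) stop("features must be numeric and finite")
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs >= 2 members; prune first")
  settings <- list(knn_k = 5L, xgb_nrounds = 100L, xgb_tree_method = "exact")
  acc <- f1 <- numeric(task@repetitions)
  for (r in seq_len(task@repetitions)) {
    done <- FALSE
    attempt <- 0L
    while (!done) {
      split_seed <- task@seed + r + attempt * (task@repetitions + 1L)
      res <- with_seed(split_seed, {
        test <- stratified_split(labels, task@testFraction)
        tryCatch({
          pred <- fit_predict(classifier, x[-test, , drop = FALSE],
                              labels[-test], x[test, , drop = FALSE],
                              settings)
          list(acc = 100 * mean(pred == labels[test]),
               f1 = weightedF1(labels[test], pred))
        }, error = function(e) e)
      })
      if (inherits(res, "error")) {
        attempt <- attempt + 1L
        if (attempt > 5L) stop("repetition ", r, " failed repeatedly: ",
                               conditionMessage(res))
        message("repetition ", r, " re-drawn after fit error: ",
                conditionMessage(res))
      } else {
        acc[r] <- res$acc
        f1[r] <- res$f1
        done <- TRUE
      }
    }
  }
  new("TaskResult", classifier = classifier,
      meanAccuracy = mean(acc), meanF1 = mean(f1),
      nClasses = length(counts), nSamples = length(labels),
      pHitRandom = pHitRandom(counts),
      details = list(accuracy = acc, f1 = f1, settings = settings,
                     classCounts = counts))
}

#' Run a classification task across classifier families
#'
#' Prunes rare classes once, then evaluates each requested classifier with
#' [repeatedStratifiedHoldout()], mirroring a per-task results row: number
#' of classes and samples, the analytic random baseline, and mean accuracy
#' and weighted F1 per classifier.
#'
#' @param table labeled feature table.
#' @param target label column.
#' @param features feature columns (default: the six scalar features
#'   SL, GC and the four NC variants).
#' @param classifiers subset of "LDA", "GNB", "KNN", "SVM", "XGB".
#' @param minClassSize,testFraction,repetitions,seed protocol parameters,
#'   see [ClassificationTask()].
#' @return data.frame with one row per classifier.
#' @export
classifyFeatures <- function(table, target,
                             features = c("SL", "GC", "NC_best", "NC_IR0",
                                          "NC_IR1", "NC_IR2"),
                             classifiers = CLASSIFIERS,
                             minClassSize = 4L, testFraction = 0.2,
                             repetitions = 50L, seed = 1L) {
  task <- ClassificationTask(target, features, minClassSize, testFraction,
                             repetitions, seed)
  pruned <- dropRareClasses(table, label = target, minN = minClassSize)
  rows <- lapply(classifiers, function(cl) {
    r <- repeatedStratifiedHoldout(pruned, task, cl)
    data.frame(task = target, classifier = cl, nClasses = r@nClasses,
               nSamples = r@nSamples, pHit = round(r@pHitRandom, 2),
               accuracy = round(r@meanAccuracy, 2),
               weightedF1 = round(r@meanF1, 4),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
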