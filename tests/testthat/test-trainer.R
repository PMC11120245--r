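randomConfusion <- function() {
  matrix(sample(1:60, 16, replace = TRUE), 4, 4)
}

test_that("cross-entropy matches closed forms", {
  expect_equal(crossEntropy(c(0.1, 0.1, 0.7, 0.1), c(0, 0, 1, 0)),
               -log(0.7))
  expect_equal(crossEntropy(c(0, 1, 0, 0), c(0, 1, 0, 0)), 0)
  for (k in 0:3) {
    oneHot <- replace(numeric(4), k + 1, 1)
    expect_equal(crossEntropy(rep(0.25, 4), oneHot), log(4))
  }
  # zero predicted probability on the target class: clamped by default
  expect_equal(crossEntropy(c(1, 0, 0, 0), c(0, 1, 0, 0)), -log(1e-12))
  expect_equal(crossEntropy(c(1, 0, 0, 0), c(0, 1, 0, 0), clamp = 0), Inf)
})

test_that("stratified split reproduces the 1200 -> 960/240 bookkeeping", {
  labels <- rep(0:3, each = 300)   # balanced 1200-epoch subject
  sp <- splitSubject(labels, trainConfig(seed = 5L))
  expect_length(sp$test, 240L)
  expect_length(sp$train, 960L)
  expect_equal(as.integer(table(factor(labels[sp$test], 0:3))),
               rep(60L, 4))
  # folds partition the training set with sizes differing by <= 1
  sizes <- lengths(sp$folds)
  expect_equal(sum(sizes), 960L)
  expect_lte(diff(range(sizes)), 1L)
  expect_identical(sort(unlist(sp$folds, use.names = FALSE)), sp$train)
  expect_length(intersect(sp$test, sp$train), 0L)
  # determinism
  sp2 <- splitSubject(labels, trainConfig(seed = 5L))
  expect_identical(sp, sp2)
  expect_false(identical(sp, splitSubject(labels, trainConfig(seed = 6L))))
  expect_error(splitSubject(rep(0:2, 10), trainConfig()), "stratification")
})

test_that("metrics hit analytic values on identity and chance matrices", {
  ident <- diag(c(10, 20, 30, 40))
  m <- computeMetrics(ident)
  expect_equal(m$Acc, 1); expect_equal(m$P, 1); expect_equal(m$R, 1)
  expect_equal(m$F, 1); expect_equal(m$Kappa, 1)
  chance <- matrix(25, 4, 4)
  mc <- computeMetrics(chance)
  expect_equal(mc$Acc, 0.25)
  expect_equal(mc$Kappa, 0)
  # kappa is 0 whenever Acc equals chance agreement, 1 iff perfect
  expect_equal(cohenKappa(0.25, 0.25), 0)
  expect_equal(cohenKappa(1, 0.25), 1)
})

test_that("printed worked examples: kappa from accuracy at P0 = 1/4", {
  # the published per-subject kappas match (Acc - 1/4)/(3/4) to within one
  # unit in the fourth decimal (the table values are truncated)
  expect_lte(abs(round(cohenKappa(0.9089), 4) - 0.8784), 1e-4)
  expect_lte(abs(round(cohenKappa(0.8661), 4) - 0.8214), 1e-4)
  expect_lte(abs(round(cohenKappa(0.7614), 4) - 0.6818), 1e-4)
})

test_that("accuracy equals support-weighted recall on any confusion matrix", {
  set.seed(42)
  for (i in 1:25) {
    conf <- randomConfusion()
    m <- computeMetrics(conf)
    rec <- diag(conf) / rowSums(conf)
    expect_equal(m$Acc, sum(rec * rowSums(conf)) / sum(conf))
  }
})

test_that("metric suite agrees with the caret reference implementation", {
  set.seed(7)
  for (i in 1:20) {
    conf <- randomConfusion()
    m <- computeMetrics(conf)
    cm <- caret::confusionMatrix(as.table(t(conf)))  # caret: rows = predicted
    expect_equal(m$Acc, unname(cm$overall["Accuracy"]), tolerance = 1e-9)
    expect_equal(m$Kappa, unname(cm$overall["Kappa"]), tolerance = 1e-9)
    expect_equal(m$P, mean(cm$byClass[, "Precision"]), tolerance = 1e-9)
    expect_equal(m$R, mean(cm$byClass[, "Recall"]), tolerance = 1e-9)
    expect_equal(m$F, mean(cm$byClass[, "F1"]), tolerance = 1e-9)
  }
})

test_that("macro AUC agrees with pROC one-vs-rest", {
  set.seed(9)
  n <- 120
  labels <- sample(0:3, n, replace = TRUE)
  raw <- matrix(rexp(n * 4), n, 4) +
    0.8 * outer(labels, 0:3, function(a, b) as.numeric(a == b))
  scores <- raw / rowSums(raw)
  ref <- mean(vapply(0:3, function(cl)
    as.numeric(pROC::auc(pROC::roc(
      response = as.integer(labels == cl), predictor = scores[, cl + 1],
      direction = "<", quiet = TRUE))), numeric(1)))
  expect_equal(macroAUC(scores, labels), ref, tolerance = 1e-9)
  # perfect separation gives AUC 1, anti-separation 0
  perfect <- diag(4)[labels + 1, ]
  expect_equal(macroAUC(perfect, labels), 1)
})

test_that("cross-validated training produces a coherent, reproducible report", {
  set.seed(55)
  n <- 24L
  stacks <- new("TFStackSet",
    stacks = array(runif(60 * 100 * 177 * n), c(60, 100, 177, n)),
    labels = rep(0:3, n / 4), montage = standardMontage(),
    freqGrid = defaultFreqGrid(), subject = "T")
  cfg <- trainConfig(epochs = 1L, batch = 8L, folds = 3L, seed = 12L)
  # barely-trained networks may leave classes unpredicted, which the metric
  # suite reports with a warning by design
  res <- suppressWarnings(trainSubject(stacks, cfg))
  expect_s4_class(res$report, "CNNEvalReport")
  expect_equal(nrow(res$report@perFold), 3L)
  expect_length(res$models, 3L)
  # pooled confusion rows: per-class test counts x folds
  nTestClass <- as.integer(table(stacks@labels[res$split$test]))
  expect_equal(unname(rowSums(res$report@confusion)), 3 * nTestClass)
  expect_equal(dim(res$attention), c(3L, 177L))
  expect_true(all(res$attention >= 0.5 & res$attention < 1))
  expect_true(all(res$report@perFold$Acc >= 0 & res$report@perFold$Acc <= 1))
  # same config and stacks give a bit-identical report
  res2 <- suppressWarnings(trainSubject(stacks, cfg))
  expect_identical(res$report@perFold, res2$report@perFold)
  # disabling the attention block still trains and reports no attention
  resOff <- suppressWarnings(
    trainSubject(stacks, trainConfig(epochs = 1L, batch = 8L, folds = 3L,
                                     seed = 12L, cfaEnabled = FALSE)))
  expect_null(resOff$attention)
})

test_that("window sweep tabulates counts that shrink with window length", {
  rec <- tinyRecording()   # 12 s per state
  cfg <- trainConfig(sweepEpochs = 1L, batch = 8L, folds = 2L, seed = 4L)
  tab <- suppressWarnings(windowSweep(rec, cfg, lengths = c(3, 4)))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$nTrain + tab$nTest, c(16L, 12L))
  expect_true(all(tab$nTrain > tab$nTest))
  expect_true(all(tab$Acc >= 0 & tab$Acc <= 1))
  expect_true(all(c("class1", "class4") %in% names(tab)))
})

test_that("training configuration validates its invariants", {
  expect_error(trainConfig(testFraction = 0), "testFraction")
  expect_error(trainConfig(folds = 1L), "folds")
  expect_error(trainConfig(epochs = 0L), "epochs")
  cfg <- trainConfig()
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$sweepEpochs, 20L)
  expect_equal(cfg$batch, 32L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$folds, 5L)
})
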