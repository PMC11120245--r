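# Training protocol: per-subject stratified 80/20 split, K-fold
# cross-validation over the training portion with Adam + cross-entropy,
# metric suite, and the window-length sweep.

#' Training configuration
#'
#' @param epochs training epochs per fold (the full protocol uses 50).
#' @param sweepEpochs epochs per fold in window-length sweeps (protocol: 20).
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param dropout dropout probability.
#' @param folds number of cross-validation folds K.
#' @param testFraction held-out test fraction.
#' @param cfaEnabled include the attention block.
#' @param seed integer seed controlling the split, initialisation, batch
#'   shuffling and dropout.
#' @return list of validated settings.
#' @export
trainConfig <- function(epochs = 50L, sweepEpochs = 20L, lr = 1e-3,
                        batch = 32L, dropout = 0.5, folds = 5L,
                        testFraction = 0.2, cfaEnabled = TRUE, seed = 1L) {
  stopifnot(epochs >= 1L, folds >= 2L,
            testFraction > 0, testFraction < 1,
            dropout >= 0, dropout < 1, batch >= 1L)
  list(epochs = as.integer(epochs), sweepEpochs = as.integer(sweepEpochs),
       lr = lr, batch = as.integer(batch), dropout = dropout,
       folds = as.integer(folds), testFraction = testFraction,
       cfaEnabled = isTRUE(cfaEnabled), seed = as.integer(seed))
}

#' Cross-entropy between predicted and target distributions
#'
#' `-sum(p * log(q))` over the classes, the multiclass training loss.
#' Predicted probabilities are clamped at `clamp` so that a zero predicted
#' probability on a target class yields a large finite loss (set
#' `clamp = 0` to allow `Inf`).
#'
#' @param q predicted probability vector.
#' @param p target distribution (e.g. one-hot).
#' @param clamp lower clamp for `q`.
#' @export
crossEntropy <- function(q, p, clamp = 1e-12) {
  stopifnot(length(q) == length(p), all(q >= 0), all(p >= 0))
  on <- p > 0   # 0 * log(0) contributes nothing
  -sum(p[on] * log(pmax(q[on], clamp)))
}

#' Stratified train/test split with K folds
#'
#' Per class, `round(testFraction * n_class)` epochs are held out as the
#' fixed test set; the remaining training epochs are randomly partitioned
#' into K folds of near-equal size (differing by at most one). Fully
#' seeded: the same seed reproduces the same assignment.
#'
#' @param labels integer state labels (0-3), one per epoch.
#' @param cfg a [trainConfig()].
#' @return list with `test` (indices), `folds` (list of K index vectors)
#'   and `train` (all training indices).
#' @export
splitSubject <- function(labels, cfg = trainConfig()) {
  K <- cfg$folds
  if (length(labels) < K * 4L)
    stop("need at least folds x 4 epochs")
  if (length(unique(labels)) < 4L)
    stop("stratification error: some state has no epochs")
  .withSeed(cfg$seed * 613L + 7L, {
    test <- integer()
    for (cl in 0:3) {
      idx <- which(labels == cl)
      nTest <- round(cfg$testFraction * length(idx))
      test <- c(test, sample(idx, nTest))
    }
    test <- sort(test)
    train <- setdiff(seq_along(labels), test)
    perm <- sample(train)
    sizes <- rep(floor(length(train) / K), K)
    extra <- length(train) - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    folds <- split(perm, rep(seq_len(K), times = sizes))
    list(test = test, folds = lapply(folds, sort), train = sort(train))
  })
}

#' Cohen's kappa from accuracy and chance agreement
#'
#' `(Acc - P0) / (1 - P0)`; with balanced four-class data the chance
#' agreement P0 is 1/4.
#'
#' @param acc observed accuracy.
#' @param p0 chance agreement.
#' @export
cohenKappa <- function(acc, p0 = 0.25) (acc - p0) / (1 - p0)

#' Macro one-vs-rest ROC AUC
#'
#' For each class, the AUC of that class's score against the rest
#' (rank-based Mann-Whitney formulation, ties handled by midranks), then
#' averaged over classes present in `labels`.
#'
#' @param scores n x 4 matrix of class scores/probabilities.
#' @param labels integer labels 0-3.
#' @export
macroAUC <- function(scores, labels) {
  aucs <- vapply(0:3, function(cl) {
    pos <- labels == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, cl + 1L])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Multiclass evaluation metrics
#'
#' Accuracy (trace over total), macro precision and recall, macro F-score
#' (mean of per-class harmonic means), Cohen's kappa with chance agreement
#' from the confusion marginals (or fixed 1/4), and, when scores are
#' supplied, macro one-vs-rest AUC. Classes with no predicted positives
#' have undefined precision and are skipped from the macro average with a
#' warning.
#'
#' @param confusion 4 x 4 count matrix, rows = true, columns = predicted.
#' @param scores optional n x 4 score matrix for AUC.
#' @param labels optional integer labels matching `scores`.
#' @param p0 "marginal" for marginal chance agreement (Cohen's convention)
#'   or "fixed" for 1/4.
#' @return named list: Acc, P, R, F, Kappa, P0, AUC (NA without scores).
#' @export
computeMetrics <- function(confusion, scores = NULL, labels = NULL,
                           p0 = c("marginal", "fixed")) {
  p0 <- match.arg(p0)
  stopifnot(all(dim(confusion) == c(4L, 4L)), all(confusion >= 0))
  n <- sum(confusion)
  acc <- sum(diag(confusion)) / n
  tp <- diag(confusion)
  prec <- tp / colSums(confusion)
  rec <- tp / rowSums(confusion)
  if (anyNA(prec))
    warning("class(es) with no predicted positives skipped from macro precision")
  f <- 2 * prec * rec / (prec + rec)
  f[is.nan(f)] <- 0            # P = R = 0 for a class
  chance <- if (p0 == "marginal")
    sum(rowSums(confusion) * colSums(confusion)) / n^2 else 0.25
  auc <- if (!is.null(scores) && !is.null(labels))
    macroAUC(scores, labels) else NA_real_
  list(Acc = acc, P = mean(prec, na.rm = TRUE), R = mean(rec, na.rm = TRUE),
       F = mean(f, na.rm = TRUE), Kappa = cohenKappa(acc, chance),
       P0 = chance, AUC = auc)
}

#' Train one subject with K-fold cross-validation
#'
#' Implements the per-subject protocol: a stratified seeded 80/20 split,
#' K folds over the training portion; for each fold the network is trained
#' on the other K-1 folds with Adam and cross-entropy and evaluated on the
#' fixed 20% test set. Reports per-fold metrics, their mean and sd, the
#' pooled confusion matrix, and each fold's mean attention weights over the
#' test stacks.
#'
#' @param stacks a [TFStackSet-class].
#' @param cfg a [trainConfig()].
#' @param epochs override for epochs per fold (defaults to `cfg$epochs`).
#' @param verbose print per-epoch loss.
#' @return list with `models` (per-fold [CNNModel-class]), `report`
#'   (a [CNNEvalReport-class]), `attention` (folds x 177 matrix or NULL),
#'   `split`, and `scores` (per-fold list of test probability matrices).
#' @export
trainSubject <- function(stacks, cfg = trainConfig(), epochs = cfg$epochs,
                         verbose = FALSE) {
  stopifnot(is(stacks, "TFStackSet"))
  labels <- stacks@labels
  sp <- splitSubject(labels, cfg)
  x <- stacks@stacks
  spec <- networkSpec(cfaEnabled = cfg$cfaEnabled, dropout = cfg$dropout)
  models <- list(); perFold <- list(); scores <- list()
  att <- if (cfg$cfaEnabled) matrix(NA_real_, cfg$folds, 177L) else NULL
  pooled <- matrix(0, 4, 4, dimnames = list(COG_STATES, COG_STATES))
  for (k in seq_len(cfg$folds)) {
    trIdx <- sort(unlist(sp$folds[-k], use.names = FALSE))
    w0 <- cpp_init_weights(cfg$seed * 100L + k, cfg$cfaEnabled)
    w <- cpp_train(x, labels, as.integer(trIdx), w0, cfg$cfaEnabled,
                   as.integer(epochs), cfg$batch, cfg$lr, cfg$dropout,
                   cfg$seed * 100L + k, verbose)
    pred <- cpp_predict(x, as.integer(sp$test), w, cfg$cfaEnabled)
    yTrue <- labels[sp$test]
    yHat <- max.col(pred$probs) - 1L
    conf <- matrix(0, 4, 4)
    for (i in seq_along(yTrue))
      conf[yTrue[i] + 1L, yHat[i] + 1L] <- conf[yTrue[i] + 1L, yHat[i] + 1L] + 1
    pooled <- pooled + conf
    met <- computeMetrics(conf, pred$probs, yTrue)
    perFold[[k]] <- data.frame(fold = k, Acc = met$Acc, P = met$P,
                               R = met$R, F = met$F, Kappa = met$Kappa,
                               AUC = met$AUC,
                               loss = tail(attr(w, "loss"), 1))
    models[[k]] <- new("CNNModel", weights = w, spec = spec)
    scores[[k]] <- pred$probs
    if (cfg$cfaEnabled) att[k, ] <- colMeans(pred$attention)
    if (verbose)
      message(sprintf("fold %d: Acc %.3f", k, met$Acc))
  }
  pf <- do.call(rbind, perFold)
  metCols <- c("Acc", "P", "R", "F", "Kappa", "AUC")
  summ <- data.frame(metric = metCols,
                     mean = vapply(pf[metCols], mean, numeric(1)),
                     sd = vapply(pf[metCols], sd, numeric(1)))
  report <- new("CNNEvalReport", confusion = pooled, perFold = pf,
                summary = summ)
  list(models = models, report = report, attention = att, split = sp,
       scores = scores)
}

setMethod("show", "CNNEvalReport", function(object) {
  s <- object@summary
  cat("CNNEvalReport over", nrow(object@perFold), "folds:\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
})

#' Mean accuracy of a cross-validated report
#' @param report a [CNNEvalReport-class].
#' @export
meanAccuracy <- function(report) {
  stopifnot(is(report, "CNNEvalReport"))
  report@summary$mean[report@summary$metric == "Acc"]
}

#' Window-length sweep
#'
#' Re-runs segmentation, stacking and per-subject training for each window
#' length (with `cfg$sweepEpochs` epochs per fold) and tabulates sample
#' counts, mean accuracy and per-class accuracies.
#'
#' @param recordings list of preprocessed [EEGRecording-class] objects
#'   (one per subject).
#' @param cfg a [trainConfig()].
#' @param lengths window lengths in seconds.
#' @param verbose progress messages.
#' @return data.frame, one row per (length, subject), plus per-class
#'   accuracy columns; a `reports` attribute holds the full reports.
#' @export
windowSweep <- function(recordings, cfg = trainConfig(),
                        lengths = c(1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5),
                        verbose = FALSE) {
  if (is(recordings, "EEGRecording")) recordings <- list(recordings)
  rows <- list(); reports <- list()
  for (L in lengths) {
    for (s in seq_along(recordings)) {
      ep <- segmentEpochs(recordings[[s]], L)
      st <- buildStacks(ep)
      res <- trainSubject(st, cfg, epochs = cfg$sweepEpochs,
                          verbose = verbose)
      conf <- res$report@confusion
      perClass <- diag(conf) / pmax(rowSums(conf), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        windowLen = L, subject = recordings[[s]]@subject,
        nTrain = length(res$split$train), nTest = length(res$split$test),
        Acc = meanAccuracy(res$report),
        class1 = perClass[1], class2 = perClass[2],
        class3 = perClass[3], class4 = perClass[4])
      reports[[sprintf("L%s_%s", L, recordings[[s]]@subject)]] <- res$report
      if (verbose) message("L = ", L, " subject ", s, " done")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
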