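# Preprocessing chain: zero-phase band-pass filter, average reference,
# baseline correction, optional decimation, and segmentation into
# non-overlapping labeled windows.

.mapSignals <- function(rec, f) {
  out <- rec
  out@signals <- f(rec@signals)
  out
}

#' Zero-phase band-pass filter
#'
#' Butterworth filtering applied forward and backward (zero phase). The
#' band is realised as a cascade of a 2nd-order high-pass at `low` (skipped
#' when `low = 0`) and a 4th-order low-pass at `high`; the forward-backward
#' pass doubles the effective order. The default 0.1-45 Hz band retains the
#' EEG rhythms of interest while removing drift and line noise.
#'
#' @param rec an [EEGRecording-class].
#' @param low high-pass edge in Hz (>= 0).
#' @param high low-pass edge in Hz (must be below Nyquist).
#' @return The filtered recording (same shape).
#' @export
bandpassFilter <- function(rec, low = 0.1, high = 45) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@rate / 2
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq) stop("high edge must be below the Nyquist frequency")
  lp <- signal::butter(4, high / nyq, type = "low")
  hp <- if (low > 0) signal::butter(2, low / nyq, type = "high") else NULL
  .mapSignals(rec, function(sig) {
    t(apply(sig, 1, function(x) {
      y <- signal::filtfilt(lp, x)
      if (!is.null(hp)) y <- signal::filtfilt(hp, y)
      y
    }))
  })
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over all channels, so that the
#' channel mean is zero at each time point.
#'
#' @param rec an [EEGRecording-class].
#' @return The re-referenced recording.
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  .mapSignals(rec, function(sig) sweep(sig, 2, colMeans(sig)))
}

#' Optional artifact-removal hook
#'
#' Placeholder for ICA-based artifact rejection and bad-channel
#' interpolation on real recordings. The synthetic generator produces
#' artifact-light data, so the default is the identity; a custom function
#' operating on the channel x sample matrix may be supplied.
#'
#' @param rec an [EEGRecording-class].
#' @param fun function(matrix) -> matrix, or NULL for a no-op.
#' @export
artifactHook <- function(rec, fun = NULL) {
  if (is.null(fun)) rec else .mapSignals(rec, fun)
}

#' Baseline correction
#'
#' For every task interval, subtracts the per-channel mean of the
#' `baselineLen` seconds immediately preceding the task onset (the cue /
#' pre-task rest period) from the task interval's signal.
#'
#' @param rec an [EEGRecording-class].
#' @param baselineLen baseline window length in seconds (default 6 s).
#' @return The corrected recording.
#' @export
baselineCorrect <- function(rec, baselineLen = 6) {
  stopifnot(is(rec, "EEGRecording"))
  ann <- rec@annotations
  task <- ann[ann$label %in% COG_STATES, , drop = FALSE]
  sig <- rec@signals
  rate <- rec@rate
  for (i in seq_len(nrow(task))) {
    on <- task$onset[i]
    if (on < baselineLen - 1e-9)
      stop("annotation error: less than ", baselineLen,
           " s of signal before task onset at ", on, " s")
    b0 <- round((on - baselineLen) * rate) + 1L
    t0 <- round(on * rate) + 1L
    t1 <- min(ncol(sig), round((on + task$duration[i]) * rate))
    bl <- rowMeans(sig[, b0:(t0 - 1L), drop = FALSE])
    sig[, t0:t1] <- sig[, t0:t1] - bl
  }
  out <- rec
  out@signals <- sig
  out
}

#' Anti-aliased decimation
#'
#' Low-pass filters (zero-phase, 8th-order Butterworth at 80% of the target
#' Nyquist) and subsamples to `targetRate`, which must divide the current
#' rate. Annotation times are unchanged (they are in seconds).
#'
#' @param rec an [EEGRecording-class].
#' @param targetRate target sampling rate in Hz.
#' @export
decimateRecording <- function(rec, targetRate = 250) {
  stopifnot(is(rec, "EEGRecording"))
  if (targetRate >= rec@rate) return(rec)
  fac <- rec@rate / targetRate
  if (abs(fac - round(fac)) > 1e-9)
    stop("targetRate must divide the sampling rate")
  lp <- signal::butter(8, 0.8 * (targetRate / 2) / (rec@rate / 2),
                       type = "low")
  out <- rec
  out@signals <- t(apply(rec@signals, 1, function(x)
    signal::filtfilt(lp, x)))[, seq(1, ncol(rec@signals), by = fac),
                              drop = FALSE]
  out@rate <- targetRate
  out
}

# Per-interval epoch offsets: floor(duration / L) windows per task
# interval, partial tails discarded.
.intervalEpochCount <- function(duration, windowLen) {
  as.integer(floor(duration / windowLen + 1e-9))
}

#' Cut a recording into non-overlapping labeled windows
#'
#' Each task interval of duration D yields `floor(D / L)` consecutive
#' windows labeled with the interval's state; partial tails are discarded.
#' Windows never span interval boundaries and never reuse samples.
#'
#' @param rec an [EEGRecording-class].
#' @param windowLen window length L in seconds.
#' @return An [EEGEpochs-class].
#' @export
segmentEpochs <- function(rec, windowLen = 3) {
  stopifnot(is(rec, "EEGRecording"))
  if (windowLen <= 0) stop("windowLen must be > 0")
  ann <- rec@annotations
  task <- ann[ann$label %in% COG_STATES, , drop = FALSE]
  if (!nrow(task)) stop("no task annotations to segment")
  rate <- rec@rate
  nsamp <- as.integer(round(windowLen * rate))
  counts <- .intervalEpochCount(task$duration, windowLen)
  total <- sum(counts)
  if (!total) stop("no task interval is at least ", windowLen, " s long")
  ep <- array(0, dim = c(nrow(rec@signals), nsamp, total))
  labs <- integer(total)
  k <- 0L
  for (i in seq_len(nrow(task))) {
    i0 <- round(task$onset[i] * rate)
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      ep[, , k] <- rec@signals[, (i0 + (j - 1L) * nsamp + 1L):
                                 (i0 + j * nsamp), drop = FALSE]
      labs[k] <- match(task$label[i], COG_STATES) - 1L
    }
  }
  new("EEGEpochs", epochs = ep, labels = labs, windowLen = windowLen,
      rate = rate, subject = rec@subject)
}

#' @describeIn segmentEpochs Number of epochs.
#' @param x an [EEGEpochs-class] or [TFStackSet-class].
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname segmentEpochs
#' @export
setMethod("nEpochs", "EEGEpochs", function(x) length(x@labels))

#' @rdname segmentEpochs
#' @export
setMethod("nEpochs", "TFStackSet", function(x) length(x@labels))

#' @describeIn segmentEpochs Per-epoch state labels (0-3).
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname segmentEpochs
#' @export
setMethod("epochLabels", "EEGEpochs", function(x) x@labels)

#' @rdname segmentEpochs
#' @export
setMethod("epochLabels", "TFStackSet", function(x) x@labels)

setMethod("show", "EEGEpochs", function(object) {
  cat(sprintf(
    "EEGEpochs %s: %d epochs of %g s (%d channels at %g Hz); labels: %s\n",
    object@subject, nEpochs(object), object@windowLen,
    dim(object@epochs)[1], object@rate,
    paste(table(factor(object@labels, 0:3, COG_STATES)), collapse = "/")))
})

#' Sample bookkeeping for the acquisition protocol
#'
#' For each window length, counts the epochs produced by per-interval floor
#' segmentation of the block-design protocol and splits them into
#' stratified train/test totals, without generating any signal.
#'
#' @param lengths window lengths in seconds.
#' @param nSubjects number of subjects.
#' @param stateDuration imagery seconds per state per subject.
#' @param testFraction held-out fraction (per subject, per class).
#' @return data.frame with columns `windowLen`, `perSubject`, `train`,
#'   `test`.
#' @export
epochCountTable <- function(lengths = c(1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5),
                            nSubjects = 7L, stateDuration = 900,
                            testFraction = 0.2) {
  params <- simParams(nSubjects = nSubjects, stateDuration = stateDuration,
                      includeTiming = TRUE)
  rows <- lapply(lengths, function(L) {
    perSubj <- 0L; testPerSubj <- 0L
    tl <- protocolTimeline(params, 1L)
    task <- tl$annotations[tl$annotations$label %in% COG_STATES, ]
    perClass <- vapply(COG_STATES, function(st)
      sum(.intervalEpochCount(task$duration[task$label == st], L)),
      integer(1))
    perSubj <- sum(perClass)
    testPerSubj <- sum(round(perClass * testFraction))
    data.frame(windowLen = L, perSubject = perSubj,
               train = (perSubj - testPerSubj) * nSubjects,
               test = testPerSubj * nSubjects)
  })
  do.call(rbind, rows)
}
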