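#' @import methods
#' @importFrom stats rnorm runif sd fft mvfft approx aggregate
#' @importFrom utils head tail
#' @useDynLib CogStateCNN, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

COG_STATES <- c("resting", "memory", "music", "subtraction")
BAND_NAMES <- c("low", "mid", "high")
BAND_EDGES <- c(0, 15, 30, 45)

#' EEG electrode montage
#'
#' Ordered electrode labels with 2-D scalp coordinates (azimuthal projection
#' onto the unit disc). The decoding pipeline assumes the 59-electrode 10-20
#' arrangement returned by [standardMontage()].
#'
#' @slot labels character vector of electrode labels.
#' @slot positions numeric matrix (n x 2) of projected x/y coordinates,
#'   all inside the unit disc.
#' @export
setClass("EEGMontage",
  representation(labels = "character", positions = "matrix"))

setValidity("EEGMontage", function(object) {
  msg <- character()
  if (anyDuplicated(object@labels))
    msg <- c(msg, "electrode labels must be unique")
  if (nrow(object@positions) != length(object@labels) ||
      ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be an n x 2 matrix matching labels")
  r <- sqrt(rowSums(object@positions^2))
  if (any(r > 1 + 1e-9))
    msg <- c(msg, "all electrode positions must lie within the unit disc")
  if (length(msg)) msg else TRUE
})

#' Simulation parameters for the synthetic EEG generator
#'
#' Describes a multi-subject block-design acquisition: four cognitive states,
#' each with a spatial-spectral signature (an oscillation in one of the
#' low/mid/high bands on a small electrode set) added on top of 1/f^alpha
#' background noise on every channel.
#'
#' @slot nSubjects integer, number of subjects.
#' @slot stateDuration seconds of task (imagery) signal per state per subject.
#' @slot rate sampling rate in Hz.
#' @slot signatures named list (one per state) of lists with elements
#'   `band` ("low"/"mid"/"high"), `electrodes` (labels), `amplitude` (uV RMS).
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha background.
#' @slot noiseScale uV RMS of the background noise per channel.
#' @slot includeTiming logical; if TRUE emit the block structure
#'   (6 s cue / 60 s imagery / 24 s rest per state per block), otherwise lay
#'   the four state intervals back to back.
#' @slot subjectJitter relative per-subject perturbation of signature
#'   amplitude and centre frequency.
#' @slot seed integer base seed.
#' @export
setClass("SimParams",
  representation(nSubjects = "integer", stateDuration = "numeric",
    rate = "numeric", signatures = "list", noiseExponent = "numeric",
    noiseScale = "numeric", includeTiming = "logical",
    subjectJitter = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@stateDuration <= 0) msg <- c(msg, "stateDuration must be > 0")
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (!identical(sort(names(object@signatures)), sort(COG_STATES)))
    msg <- c(msg, "signatures must be named after the four states")
  for (sg in object@signatures) {
    if (!sg$band %in% BAND_NAMES) msg <- c(msg, "unknown band in signature")
    if (sg$amplitude < 0) msg <- c(msg, "signature amplitudes must be >= 0")
  }
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Annotated continuous EEG recording
#'
#' @slot signals numeric matrix, channels x samples, in microvolts.
#' @slot rate sampling rate in Hz.
#' @slot montage an [EEGMontage-class].
#' @slot annotations data.frame with columns `onset` (s), `duration` (s),
#'   `label` (a state name, "cue" or "rest").
#' @slot subject subject identifier.
#' @export
setClass("EEGRecording",
  representation(signals = "matrix", rate = "numeric",
    montage = "EEGMontage", annotations = "data.frame",
    subject = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@signals) != length(object@montage@labels))
    msg <- c(msg, "signal row count must match montage size")
  dur <- ncol(object@signals) / object@rate
  ann <- object@annotations
  if (nrow(ann)) {
    if (any(ann$onset < -1e-9) || any(ann$onset + ann$duration > dur + 1e-6))
      msg <- c(msg, "annotations must lie within the recording")
    task <- ann[ann$label %in% COG_STATES, , drop = FALSE]
    if (nrow(task) > 1L) {
      o <- order(task$onset)
      s <- task$onset[o]; e <- s + task$duration[o]
      if (any(s[-1] < e[-length(e)] - 1e-9))
        msg <- c(msg, "task annotations must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Labeled fixed-length EEG windows
#'
#' Non-overlapping windows of length `windowLen` seconds cut from the task
#' intervals of a recording, each carrying one state label.
#'
#' @slot epochs numeric array, channels x samples x epochs.
#' @slot labels integer vector, state index 0-3
#'   (0 resting, 1 memory, 2 music, 3 subtraction).
#' @slot windowLen window length in seconds.
#' @slot rate sampling rate in Hz.
#' @slot subject subject identifier.
#' @export
setClass("EEGEpochs",
  representation(epochs = "array", labels = "integer", windowLen = "numeric",
    rate = "numeric", subject = "character"))

setValidity("EEGEpochs", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-D array")
  else {
    if (d[2] != round(object@windowLen * object@rate))
      msg <- c(msg, "sample count must equal round(windowLen * rate)")
    if (d[3] != length(object@labels))
      msg <- c(msg, "labels must match epoch count")
  }
  if (length(object@labels) && !all(object@labels %in% 0:3))
    msg <- c(msg, "labels must be in 0..3")
  if (length(msg)) msg else TRUE
})

#' Single-channel time-frequency power map
#'
#' @slot power non-negative matrix, frequencies x time points.
#' @slot freq frequency axis in Hz (strictly increasing).
#' @slot time time axis in milliseconds.
#' @export
setClass("TFMap",
  representation(power = "matrix", freq = "numeric", time = "numeric"))

setValidity("TFMap", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@freq))
    msg <- c(msg, "freq axis must match power rows")
  if (ncol(object@power) != length(object@time))
    msg <- c(msg, "time axis must match power columns")
  if (any(object@power < -1e-12)) msg <- c(msg, "power must be non-negative")
  if (length(object@freq) > 1L && any(diff(object@freq) <= 0))
    msg <- c(msg, "freq axis must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Band-split scalogram stacks (network input)
#'
#' A set of 177-plane stacks, one per epoch. Plane index convention:
#' `plane = electrode_index * 3 + band_index` (0-based; band 0 = 0-15 Hz,
#' 1 = 15-30 Hz, 2 = 30-45 Hz), so each electrode contributes three
#' consecutive planes. Each plane is 60 x 100 and min-max normalised to
#' [0, 1]. Internally stored as a height x width x plane x epoch array.
#'
#' @slot stacks numeric array, 60 x 100 x 177 x n.
#' @slot labels integer state indices 0-3, one per epoch.
#' @slot montage the source [EEGMontage-class].
#' @slot freqGrid the CWT frequency grid in Hz.
#' @slot subject subject identifier.
#' @export
setClass("TFStackSet",
  representation(stacks = "array", labels = "integer",
    montage = "EEGMontage", freqGrid = "numeric", subject = "character"))

setValidity("TFStackSet", function(object) {
  msg <- character()
  d <- dim(object@stacks)
  if (length(d) != 4L || !all(d[1:3] == c(60L, 100L, 177L)))
    msg <- c(msg, "stacks must be 60 x 100 x 177 x n")
  else if (d[4] != length(object@labels))
    msg <- c(msg, "labels must match stack count")
  rng <- suppressWarnings(range(object@stacks))
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    msg <- c(msg, "stack values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Trained network (weights plus architecture description)
#'
#' @slot weights named list of numeric weight matrices/vectors.
#' @slot spec the architecture description from [networkSpec()].
#' @export
setClass("CNNModel", representation(weights = "list", spec = "list"))

#' Cross-validated evaluation report
#'
#' @slot confusion 4 x 4 pooled count matrix (rows = true, cols = predicted).
#' @slot perFold data.frame of per-fold metrics.
#' @slot summary data.frame with mean and sd per metric.
#' @export
setClass("CNNEvalReport",
  representation(confusion = "matrix", perFold = "data.frame",
    summary = "data.frame"))

#' Electrode x band attention topography
#'
#' @slot weights 59 x 3 matrix of mean attention weights, min-max normalised
#'   to [0, 1] across all entries.
#' @slot montage an [EEGMontage-class].
#' @slot bands band labels.
#' @export
setClass("AttentionTopography",
  representation(weights = "matrix", montage = "EEGMontage",
    bands = "character"))

setValidity("AttentionTopography", function(object) {
  msg <- character()
  if (!all(dim(object@weights) == c(length(object@montage@labels), 3L)))
    msg <- c(msg, "weights must be n_electrodes x 3")
  if (any(object@weights < -1e-9) || any(object@weights > 1 + 1e-9))
    msg <- c(msg, "normalised weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
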