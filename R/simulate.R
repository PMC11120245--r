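# Synthetic multi-subject EEG with class-dependent spatial-spectral
# signatures on top of 1/f^alpha background noise. The generator is fully
# seeded: identical (params, subject) yields bit-identical recordings.

BAND_RANGES <- list(low = c(0, 15), mid = c(15, 30), high = c(30, 45))

#' Default per-state spatial-spectral signatures
#'
#' Each cognitive state is given a band-limited oscillation on a small
#' electrode set: posterior alpha-range activity for rest, frontal mid-band
#' activity for memory recall, right-temporal high-band activity for mental
#' singing, and parietal mid-band activity for serial subtraction. The
#' electrode/band assignments are chosen to be spatially and spectrally
#' distinct so that an attention mechanism can in principle recover them;
#' they are not claims about real cortical sources.
#'
#' @param amplitude common signature RMS amplitude in microvolts.
#' @return Named list of signatures (band, electrodes, amplitude).
#' @export
defaultSignatures <- function(amplitude = 5) {
  list(
    resting     = list(band = "low",  electrodes = c("POz", "Oz", "O1", "O2"),
                       amplitude = amplitude),
    memory      = list(band = "mid",  electrodes = c("Fz", "F1", "F2"),
                       amplitude = amplitude),
    music       = list(band = "high", electrodes = c("C4", "C6", "T8"),
                       amplitude = amplitude),
    subtraction = list(band = "mid",  electrodes = c("Pz", "P3", "P4"),
                       amplitude = amplitude))
}

#' Construct simulation parameters
#'
#' Defaults describe the package's scaled-down study fixture: 2 subjects,
#' 180 s of imagery per state at 250 Hz. The full acquisition protocol
#' (7 subjects, 900 s per state at 1000 Hz) is obtained by overriding
#' `nSubjects`, `stateDuration` and `rate`.
#'
#' @param nSubjects number of subjects.
#' @param stateDuration seconds of imagery per state per subject.
#' @param rate sampling rate in Hz.
#' @param signatures per-state signature list, see [defaultSignatures()].
#' @param noiseExponent slope alpha of the 1/f^alpha background noise.
#' @param noiseScale background noise RMS in microvolts per channel.
#' @param includeTiming emit the block structure (6 s cue, 60 s imagery,
#'   24 s rest per state, 60 s between blocks); if FALSE, each state is one
#'   contiguous interval preceded by a 6 s rest lead-in.
#' @param subjectJitter relative per-subject perturbation of signature
#'   amplitude and centre frequency.
#' @param seed integer base seed.
#' @return A [SimParams-class] object.
#' @export
simParams <- function(nSubjects = 2L, stateDuration = 180, rate = 250,
                      signatures = defaultSignatures(),
                      noiseExponent = 1, noiseScale = 10,
                      includeTiming = TRUE, subjectJitter = 0.1,
                      seed = 1L) {
  new("SimParams", nSubjects = as.integer(nSubjects),
      stateDuration = stateDuration, rate = rate, signatures = signatures,
      noiseExponent = noiseExponent, noiseScale = noiseScale,
      includeTiming = includeTiming, subjectJitter = subjectJitter,
      seed = as.integer(seed))
}

#' High signal-to-noise simulation fixture
#'
#' The default fixture used by the package's pipeline-recovery checks:
#' strong signatures (8 uV RMS) over weak background noise (4 uV RMS),
#' contiguous state intervals. Chosen once as an easy, clearly separable
#' regime; see the methods vignette.
#'
#' @param ... overrides passed to [simParams()].
#' @export
highSNRParams <- function(...) {
  args <- list(signatures = defaultSignatures(amplitude = 8),
               noiseScale = 4, includeTiming = FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(simParams, args)
}

# Evaluate expr with a private, deterministic RNG stream; restores the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Protocol annotation timeline
#'
#' Builds the cue/imagery/rest annotation structure for one subject without
#' generating any signal, so that sample bookkeeping over the full
#' acquisition protocol stays cheap. With `includeTiming`, each block holds
#' the four states (resting first, the other three rotated across blocks),
#' each as 6 s cue + up to 60 s imagery + 24 s rest, with 60 s between
#' blocks. Without it, states are contiguous intervals with 6 s lead-ins.
#'
#' @param params a [SimParams-class].
#' @param subject 1-based subject index (rotations differ across subjects).
#' @return list with `annotations` (data.frame onset/duration/label) and
#'   `totalDuration` (s).
#' @export
protocolTimeline <- function(params, subject = 1L) {
  states <- COG_STATES
  ann <- list()
  t0 <- 0
  if (params@includeTiming) {
    remaining <- rep(params@stateDuration, 4)
    names(remaining) <- states
    block <- 0L
    while (any(remaining > 1e-9)) {
      # resting always first; remaining task order rotated per block/subject
      rot <- (block + subject - 1L) %% 3L
      order4 <- c("resting", states[-1][((seq_len(3) - 1L + rot) %% 3L) + 1L])
      for (st in order4) {
        im <- min(60, remaining[[st]])
        if (im <= 1e-9) next
        ann[[length(ann) + 1L]] <- data.frame(
          onset = t0, duration = 6, label = "cue")
        ann[[length(ann) + 1L]] <- data.frame(
          onset = t0 + 6, duration = im, label = st)
        ann[[length(ann) + 1L]] <- data.frame(
          onset = t0 + 6 + im, duration = 24, label = "rest")
        t0 <- t0 + 6 + im + 24
        remaining[[st]] <- remaining[[st]] - im
      }
      block <- block + 1L
      if (any(remaining > 1e-9)) t0 <- t0 + 60  # inter-block break
    }
  } else {
    for (st in states) {
      ann[[length(ann) + 1L]] <- data.frame(
        onset = t0, duration = 6, label = "rest")
      ann[[length(ann) + 1L]] <- data.frame(
        onset = t0 + 6, duration = params@stateDuration, label = st)
      t0 <- t0 + 6 + params@stateDuration
    }
  }
  list(annotations = do.call(rbind, ann), totalDuration = t0)
}

# 1/f^alpha noise, one channel, unit RMS, via spectral shaping of white
# Gaussian noise.
.pinkNoise <- function(n, alpha) {
  x <- rnorm(n)
  if (alpha == 0) return(x / max(sd(x), 1e-12))
  X <- fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)          # two-sided frequency index
  g <- ifelse(f == 0, 0, f^(-alpha / 2))
  y <- Re(fft(X * g, inverse = TRUE)) / n
  s <- sd(y)
  if (s < 1e-12) y else y / s
}

#' Generate one subject's synthetic recording
#'
#' All channels carry independent 1/f^alpha noise at `noiseScale` uV RMS.
#' During each state's imagery intervals, the state's signature electrodes
#' additionally carry an amplitude-modulated sinusoid whose frequency is
#' drawn inside the signature band (low 0-15 Hz, mid 15-30 Hz, high
#' 30-45 Hz), scaled to the signature RMS, with half-amplitude spill-over
#' onto the two nearest neighbouring electrodes.
#'
#' @param params a [SimParams-class].
#' @param subject 1-based subject index (must be <= `nSubjects`).
#' @return An [EEGRecording-class].
#' @export
simulateRecording <- function(params, subject = 1L) {
  stopifnot(is(params, "SimParams"))
  if (subject < 1L || subject > params@nSubjects)
    stop("subject index out of range")
  montage <- standardMontage()
  for (sg in params@signatures) {
    bad <- setdiff(sg$electrodes, montage@labels)
    if (length(bad))
      stop("signature references unknown electrode(s): ",
           paste(bad, collapse = ", "))
  }
  tl <- protocolTimeline(params, subject)
  n <- round(tl$totalDuration * params@rate)
  nch <- length(montage@labels)

  .withSeed(params@seed * 7919L + subject, {
    sig <- matrix(0, nch, n)
    if (params@noiseScale > 0) {
      for (ch in seq_len(nch))
        sig[ch, ] <- params@noiseScale *
          .pinkNoise(n, params@noiseExponent)
    }
    # per-subject signature perturbation
    jit <- params@subjectJitter
    ampMult <- pmax(0.2, 1 + jit * rnorm(4))
    freqShift <- jit * 4 * rnorm(4)
    names(ampMult) <- names(freqShift) <- COG_STATES

    ann <- tl$annotations
    task <- ann[ann$label %in% COG_STATES, , drop = FALSE]
    for (i in seq_len(nrow(task))) {
      st <- task$label[i]
      sg <- params@signatures[[st]]
      if (sg$amplitude <= 0) next
      band <- BAND_RANGES[[sg$band]]
      bw <- diff(band)
      i0 <- round(task$onset[i] * params@rate) + 1L
      len <- round(task$duration[i] * params@rate)
      tt <- (seq_len(len) - 1L) / params@rate
      f <- runif(1, band[1] + 0.25 * bw, band[2] - 0.25 * bw) +
        freqShift[[st]]
      f <- min(max(f, band[1] + 0.05 * bw), band[2] - 0.05 * bw)
      env <- 1 + 0.3 * sin(2 * pi * runif(1, 0.3, 1) * tt +
                           runif(1, 0, 2 * pi))
      wave <- env * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
      wave <- wave / max(sqrt(mean(wave^2)), 1e-12) *
        sg$amplitude * ampMult[[st]]
      idx <- match(sg$electrodes, montage@labels)
      cols <- i0:(i0 + len - 1L)
      for (e in idx) {
        sig[e, cols] <- sig[e, cols] + wave
        for (nb in .nearestNeighbours(montage, montage@labels[e], 2L))
          sig[nb, cols] <- sig[nb, cols] + 0.5 * wave
      }
    }
    new("EEGRecording", signals = sig, rate = params@rate,
        montage = montage, annotations = ann,
        subject = sprintf("S%02d", subject))
  })
}

#' @describeIn simulateRecording Sampling rate accessor.
#' @param x an object with a sampling rate.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname simulateRecording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)

#' @rdname simulateRecording
#' @export
setMethod("samplingRate", "EEGEpochs", function(x) x@rate)

#' Annotations accessor
#' @param x an [EEGRecording-class].
#' @export
annotations <- function(x) {
  stopifnot(is(x, "EEGRecording"))
  x@annotations
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording %s: %d channels x %d samples (%.1f s at %g Hz), %d annotations\n",
    object@subject, nrow(object@signals), ncol(object@signals),
    ncol(object@signals) / object@rate, object@rate,
    nrow(object@annotations)))
})
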