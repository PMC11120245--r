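# Continuous wavelet scalograms and the 177-plane band-split stack that is
# the network input.

#' Default CWT frequency grid: 1-45 Hz in 0.5 Hz steps (89 bins)
#'
#' 0 Hz is unattainable by a wavelet transform; the grid starts at 1 Hz and
#' the 0-45 Hz display convention of scalogram figures is treated as the
#' plot axis, not the analysis grid.
#' @export
defaultFreqGrid <- function() seq(1, 45, by = 0.5)

#' Morlet scalogram of a single channel
#'
#' Complex Morlet continuous wavelet transform implemented as a bank of
#' analytic Gaussian filters in the frequency domain: at centre frequency f
#' the filter has standard deviation f / nCycles (nCycles = 6 gives the
#' classic 6-cycle Morlet time-frequency trade-off). The map holds power
#' (squared magnitude), scaled so that a unit-amplitude sinusoid at a grid
#' frequency yields power ~1 at its ridge.
#'
#' @param x numeric vector, one epoch of one channel.
#' @param rate sampling rate in Hz.
#' @param freqs centre-frequency grid in Hz, inside (0, rate/2).
#' @param nCycles wavelet width in cycles.
#' @return A [TFMap-class] (frequencies x time).
#' @export
cwtPowerMap <- function(x, rate, freqs = defaultFreqGrid(), nCycles = 6) {
  if (!length(x)) stop("empty signal")
  if (any(!is.finite(x))) stop("non-finite values in signal")
  if (any(freqs <= 0 | freqs >= rate / 2))
    stop("freqs must lie strictly inside (0, rate/2)")
  W <- .cwtComplex(x, rate, freqs, nCycles)
  new("TFMap", power = abs(W)^2, freq = freqs,
      time = (seq_along(x) - 1L) / rate * 1000)
}

# Analytic Gaussian filter bank for a given signal length/rate/grid,
# memoised: it is reused across the 59 channels and all epochs of a run.
.cwtCache <- new.env(parent = emptyenv())

.cwtFilterBank <- function(n, rate, freqs, nCycles) {
  key <- paste(n, rate, nCycles, length(freqs),
               freqs[1], freqs[length(freqs)], sep = "|")
  bank <- .cwtCache[[key]]
  if (!is.null(bank)) return(bank)
  m <- 2^ceiling(log2(max(2 * n, 64)))
  nu <- (seq_len(m) - 1L) * rate / m
  pos <- nu <= rate / 2 & seq_len(m) > 1L   # analytic: positive freqs only
  H <- matrix(0, m, length(freqs))
  for (j in seq_along(freqs)) {
    sf <- freqs[j] / nCycles
    H[pos, j] <- 2 * exp(-((nu[pos] - freqs[j])^2) / (2 * sf^2))
  }
  bank <- list(H = H, m = m)
  .cwtCache[[key]] <- bank
  bank
}

# Complex CWT coefficients (freq x time) for one channel.
.cwtComplex <- function(x, rate, freqs, nCycles) {
  n <- length(x)
  bank <- .cwtFilterBank(n, rate, freqs, nCycles)
  X <- fft(c(x, rep(0, bank$m - n)))
  Z <- mvfft(X * bank$H, inverse = TRUE) / bank$m
  t(Z[seq_len(n), , drop = FALSE])
}

#' Split a scalogram into low/mid/high band maps
#'
#' Partitions the frequency rows into the three canonical planes: low
#' (0-15 Hz), mid (15-30 Hz) and high (30-45 Hz). Bands are half-open
#' `[lo, hi)` except the last, which includes its upper edge, so the
#' partition is exhaustive and disjoint.
#'
#' @param map a [TFMap-class].
#' @param edges band edges (4 increasing values).
#' @return Named list of three [TFMap-class] objects (`low`, `mid`, `high`).
#' @export
bandSplit <- function(map, edges = BAND_EDGES) {
  stopifnot(is(map, "TFMap"), length(edges) == 4L)
  out <- list()
  for (b in 1:3) {
    sel <- if (b < 3) map@freq >= edges[b] & map@freq < edges[b + 1]
           else map@freq >= edges[b] & map@freq <= edges[b + 1]
    if (!any(sel)) stop("grid error: band ", BAND_NAMES[b],
                        " holds no frequency rows")
    out[[BAND_NAMES[b]]] <- new("TFMap",
      power = map@power[sel, , drop = FALSE],
      freq = map@freq[sel], time = map@time)
  }
  out
}

# Bilinear interpolation matrix mapping nIn grid points onto nOut points
# (align-corners convention: endpoints map to endpoints, so identity when
# nIn == nOut and constants are preserved exactly).
.interpMatrix <- function(nIn, nOut) {
  A <- matrix(0, nOut, nIn)
  if (nIn == 1L) { A[, 1] <- 1; return(A) }
  src <- if (nOut == 1L) (nIn - 1) / 2 else
    (seq_len(nOut) - 1L) * (nIn - 1) / (nOut - 1)
  lo <- pmin(floor(src), nIn - 2)
  w <- src - lo
  A[cbind(seq_len(nOut), lo + 1L)] <- 1 - w
  A[cbind(seq_len(nOut), lo + 2L)] <- A[cbind(seq_len(nOut), lo + 2L)] + w
  A
}

.bilinearResize <- function(mat, height, width) {
  A <- .interpMatrix(nrow(mat), height)
  B <- .interpMatrix(ncol(mat), width)
  A %*% mat %*% t(B)
}

#' Resample a time-frequency map to a fixed size
#'
#' Separable bilinear interpolation to `height` x `width` (default the
#' 60 x 100 plane size consumed by the network). Constant maps stay
#' constant; a map already at the target size is returned unchanged.
#'
#' @param map a [TFMap-class].
#' @param height,width target dimensions.
#' @return A [TFMap-class] of the requested size.
#' @export
resizeMap <- function(map, height = 60, width = 100) {
  stopifnot(is(map, "TFMap"))
  p <- .bilinearResize(map@power, height, width)
  p[p < 0] <- 0  # clip tiny negative round-off
  new("TFMap", power = p,
      freq = as.vector(.interpMatrix(length(map@freq), height) %*% map@freq),
      time = as.vector(.interpMatrix(length(map@time), width) %*% map@time))
}

# Min-max normalise a plane to [0,1]; constant planes map to 0.
.minmax01 <- function(p) {
  r <- range(p)
  if (r[2] - r[1] < 1e-12) return(p * 0)
  (p - r[1]) / (r[2] - r[1])
}

#' Build the 177-plane stack for one epoch
#'
#' For each electrode: Morlet scalogram, band split into low/mid/high, each
#' band plane bilinearly resized to 60 x 100 and min-max normalised to
#' `[0, 1]` (constant planes map to 0). Planes are stacked in the
#' convention `plane = electrode_index * 3 + band_index` (0-based).
#'
#' @param epoch numeric matrix, 59 channels x samples.
#' @param rate sampling rate in Hz.
#' @param freqs CWT frequency grid.
#' @param nCycles wavelet width in cycles.
#' @param normalize min-max normalise each plane (the network input
#'   convention); set FALSE to keep raw power for energy diagnostics.
#' @return numeric array 60 x 100 x 177.
#' @export
buildStack <- function(epoch, rate, freqs = defaultFreqGrid(), nCycles = 6,
                       normalize = TRUE) {
  if (nrow(epoch) != 59L) stop("epoch must have 59 channels")
  n <- ncol(epoch)
  Bt <- t(.interpMatrix(n, 100))
  bandSel <- lapply(1:3, function(b) {
    if (b < 3) freqs >= BAND_EDGES[b] & freqs < BAND_EDGES[b + 1]
    else freqs >= BAND_EDGES[b] & freqs <= BAND_EDGES[b + 1]
  })
  if (any(!vapply(bandSel, any, logical(1))))
    stop("grid error: empty band")
  Ab <- lapply(bandSel, function(sel) .interpMatrix(sum(sel), 60))
  out <- array(0, dim = c(60, 100, 177))
  for (e in seq_len(59)) {
    P <- abs(.cwtComplex(epoch[e, ], rate, freqs, nCycles))^2
    if (any(!is.finite(P))) stop("numeric error: non-finite scalogram")
    Tm <- P %*% Bt                      # time axis to 100 bins
    for (b in 1:3) {
      plane <- Ab[[b]] %*% Tm[bandSel[[b]], , drop = FALSE]
      plane[plane < 0] <- 0
      out[, , (e - 1L) * 3L + b] <- if (normalize) .minmax01(plane)
                                    else plane
    }
  }
  out
}

#' Build stacks for a whole epoch set
#'
#' @param epochs an [EEGEpochs-class].
#' @param freqs,nCycles passed to [buildStack()].
#' @param verbose print progress.
#' @return A [TFStackSet-class].
#' @export
buildStacks <- function(epochs, freqs = defaultFreqGrid(), nCycles = 6,
                        verbose = FALSE) {
  stopifnot(is(epochs, "EEGEpochs"))
  n <- nEpochs(epochs)
  stacks <- array(0, dim = c(60, 100, 177, n))
  for (i in seq_len(n)) {
    stacks[, , , i] <- buildStack(epochs@epochs[, , i], epochs@rate,
                                  freqs, nCycles)
    if (verbose && i %% 50 == 0)
      message("  stacked ", i, "/", n, " epochs")
  }
  new("TFStackSet", stacks = stacks, labels = epochs@labels,
      montage = standardMontage(), freqGrid = freqs,
      subject = epochs@subject)
}

#' Extract one stack in the (177, 60, 100) plane-first layout
#'
#' @param x a [TFStackSet-class].
#' @param i epoch index.
#' @return numeric array 177 x 60 x 100.
#' @export
getStack <- function(x, i) {
  stopifnot(is(x, "TFStackSet"))
  aperm(x@stacks[, , , i], c(3, 1, 2))
}

setMethod("show", "TFStackSet", function(object) {
  cat(sprintf(
    "TFStackSet %s: %d stacks of 177 x 60 x 100; labels: %s\n",
    object@subject, nEpochs(object),
    paste(table(factor(object@labels, 0:3, COG_STATES)), collapse = "/")))
})
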