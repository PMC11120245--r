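# A bare recording with chosen signals/annotations, for arithmetic oracles.
makeRec <- function(signals, rate = 250, ann = NULL) {
  if (is.null(ann))
    ann <- data.frame(onset = numeric(), duration = numeric(),
                      label = character())
  new("EEGRecording", signals = signals, rate = rate,
      montage = standardMontage(), annotations = ann, subject = "T")
}

test_that("band-pass filter rejects DC, keeps 10 Hz, removes 60 Hz", {
  n <- 2500; rate <- 250
  tt <- (seq_len(n) - 1) / rate
  # DC rejection: gain at 0 Hz is zero, so away from the filtfilt edge
  # transients a 10 uV offset vanishes (120 s signal, middle half checked)
  nDC <- 120 * 100
  const <- makeRec(matrix(10, 59, nDC), 100)
  outDC <- bandpassFilter(const, 0.1, 45)
  midDC <- (nDC %/% 4):(3 * nDC %/% 4)
  expect_lt(max(abs(rowMeans(outDC@signals[, midDC]))), 1e-6)

  tone <- makeRec(matrix(sin(2 * pi * 10 * tt), 59, n, byrow = TRUE), rate)
  out <- bandpassFilter(tone, 0.1, 45)
  mid <- 500:2000   # avoid filter edges
  rmsRatio <- sqrt(mean(out@signals[1, mid]^2)) /
    sqrt(mean(tone@signals[1, mid]^2))
  expect_lt(abs(rmsRatio - 1), 0.05)

  hum <- makeRec(matrix(sin(2 * pi * 60 * tt), 59, n, byrow = TRUE), rate)
  out <- bandpassFilter(hum, 0.1, 45)
  expect_lt(sqrt(mean(out@signals[1, mid]^2)) /
            sqrt(mean(hum@signals[1, mid]^2)), 0.10)

  expect_error(bandpassFilter(tone, 0.1, 130), "Nyquist")
  expect_error(bandpassFilter(tone, 50, 45), "low < high")
})

test_that("filtering is near-idempotent on band-limited signals", {
  n <- 2500; rate <- 250
  tt <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * 8 * tt) + 0.5 * sin(2 * pi * 22 * tt)
  rec <- makeRec(matrix(x, 59, n, byrow = TRUE), rate)
  once <- bandpassFilter(rec)
  twice <- bandpassFilter(once)
  mid <- 500:2000
  expect_lt(max(abs(once@signals[1, mid] - twice@signals[1, mid])), 0.02)
})

test_that("average reference zeroes the channel mean at every sample", {
  set.seed(3)
  rec <- makeRec(matrix(rnorm(59 * 100, mean = 5), 59, 100))
  out <- averageReference(rec)
  expect_lt(max(abs(colMeans(out@signals))), 1e-12)
  again <- averageReference(out)
  expect_equal(again@signals, out@signals, tolerance = 1e-12)
  # hand arithmetic on a single sample
  one <- makeRec(matrix(as.numeric(1:59), 59, 1))
  expect_equal(averageReference(one)@signals[, 1], 1:59 - mean(1:59))
})

test_that("baseline correction subtracts the pre-task mean", {
  rate <- 100
  sig <- matrix(2, 59, 20 * rate)          # baseline level 2 uV
  sig[, (10 * rate + 1):(16 * rate)] <- 5  # task at 5 uV
  ann <- data.frame(onset = 10, duration = 6, label = "memory")
  out <- baselineCorrect(makeRec(sig, rate, ann), 6)
  task <- out@signals[, (10 * rate + 1):(16 * rate)]
  expect_true(all(abs(task - 3) < 1e-12))
  # segment equal to the baseline mean everywhere becomes zero
  sig2 <- matrix(2, 59, 20 * rate)
  out2 <- baselineCorrect(makeRec(sig2, rate, ann), 6)
  expect_true(all(abs(out2@signals[, (10 * rate + 1):(16 * rate)]) < 1e-12))
  # insufficient pre-task signal
  annBad <- data.frame(onset = 3, duration = 6, label = "memory")
  expect_error(baselineCorrect(makeRec(sig, rate, annBad), 6), "annotation")
  # default baseline length is 6 s
  expect_equal(formals(baselineCorrect)$baselineLen, 6)
})

test_that("segmentation uses per-interval floor semantics without overlap", {
  rate <- 100
  sig <- matrix(rnorm(59 * 40 * rate), 59, 40 * rate)
  ann <- data.frame(onset = c(1, 12, 22, 31),
                    duration = c(7, 6, 8, 3),
                    label = c("resting", "memory", "music", "subtraction"))
  rec <- makeRec(sig, rate, ann)
  ep <- segmentEpochs(rec, 3)
  expect_equal(nEpochs(ep), sum(floor(ann$duration / 3)))  # 2+2+2+1
  expect_equal(as.integer(table(factor(epochLabels(ep), 0:3))),
               c(2L, 2L, 2L, 1L))
  # first epoch of each interval starts exactly at the interval onset
  expect_equal(ep@epochs[, , 1], sig[, 101:400])
  expect_equal(ep@epochs[, , 3], sig[, 1201:1500])
  # duration exactly L gives one epoch
  ep1 <- segmentEpochs(makeRec(sig, rate, data.frame(
    onset = 0, duration = 3, label = "resting")), 3)
  expect_equal(nEpochs(ep1), 1L)
  # epoch counts are monotone non-increasing in L
  counts <- vapply(c(1, 1.5, 2, 3, 5), function(L)
    nEpochs(segmentEpochs(rec, L)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(segmentEpochs(makeRec(sig, rate), 3), "no task annotations")
  expect_error(segmentEpochs(rec, 0), "windowLen")
})

test_that("decimation preserves in-band content at the lower rate", {
  rate <- 1000
  tt <- (seq_len(4 * rate) - 1) / rate
  rec <- makeRec(matrix(sin(2 * pi * 10 * tt), 59, 4 * rate, byrow = TRUE),
                 rate)
  out <- decimateRecording(rec, 250)
  expect_equal(samplingRate(out), 250)
  expect_equal(ncol(out@signals), ncol(rec@signals) / 4)
  mid <- 300:700
  ref <- sin(2 * pi * 10 * (seq_len(1000) - 1) / 250)
  expect_lt(max(abs(out@signals[1, mid] - ref[mid])), 0.05)
})
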