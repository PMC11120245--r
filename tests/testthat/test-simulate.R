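test_that("identical parameters and subject give bit-identical recordings", {
  p <- simParams(nSubjects = 1L, stateDuration = 8, rate = 100,
                 includeTiming = FALSE, seed = 7L)
  r1 <- simulateRecording(p, 1L)
  r2 <- simulateRecording(p, 1L)
  expect_identical(r1@signals, r2@signals)
  expect_identical(r1@annotations, r2@annotations)
  p2 <- simParams(nSubjects = 2L, stateDuration = 8, rate = 100,
                  includeTiming = FALSE, seed = 7L)
  r3 <- simulateRecording(p2, 2L)
  expect_false(identical(r1@signals, r3@signals))
})

test_that("per-state annotated imagery time equals stateDuration", {
  for (timing in c(TRUE, FALSE)) {
    p <- simParams(stateDuration = 150, includeTiming = timing)
    tl <- protocolTimeline(p, 1L)
    ann <- tl$annotations
    for (st in c("resting", "memory", "music", "subtraction"))
      expect_equal(sum(ann$duration[ann$label == st]), 150)
  }
})

test_that("block timing follows the 6 s cue / 60 s imagery / 24 s rest template", {
  p <- simParams(stateDuration = 120, includeTiming = TRUE)
  tl <- protocolTimeline(p, 1L)
  ann <- tl$annotations
  task <- ann[!ann$label %in% c("cue", "rest"), ]
  # every imagery interval is a full 60 s block here (120 = 2 blocks)
  expect_true(all(task$duration == 60))
  expect_equal(nrow(task), 8L)   # 4 states x 2 blocks
  for (i in seq_len(nrow(task))) {
    cue <- ann[ann$label == "cue" & abs(ann$onset + 6 - task$onset[i]) < 1e-9, ]
    expect_equal(nrow(cue), 1L)
    post <- ann[ann$label == "rest" &
                abs(ann$onset - (task$onset[i] + 60)) < 1e-9, ]
    expect_equal(post$duration, 24)
  }
  # resting is always the first task of each block
  expect_identical(task$label[c(1, 5)], c("resting", "resting"))
})

test_that("zero noise and zero amplitudes give an all-zero recording", {
  p <- simParams(nSubjects = 1L, stateDuration = 5, rate = 100,
                 signatures = defaultSignatures(amplitude = 0),
                 noiseScale = 0, includeTiming = FALSE, seed = 1L)
  rec <- simulateRecording(p, 1L)
  expect_true(all(rec@signals == 0))
})

test_that("signature electrodes carry band power during their state", {
  # mid-band signature on C4 for music, nothing else: C4 during music
  # imagery must hold > 5x the 15-30 Hz power of C4 during resting.
  sig <- defaultSignatures(amplitude = 0)
  sig$music <- list(band = "mid", electrodes = "C4", amplitude = 5)
  p <- simParams(nSubjects = 1L, stateDuration = 20, rate = 250,
                 signatures = sig, noiseScale = 1, includeTiming = FALSE,
                 seed = 21L)
  rec <- simulateRecording(p, 1L)
  ann <- annotations(rec)
  c4 <- match("C4", channelNames(rec))
  seg <- function(state) {
    a <- ann[ann$label == state, ]
    i0 <- round(a$onset * rec@rate)
    rec@signals[c4, (i0 + 1):(i0 + round(a$duration * rec@rate))]
  }
  pMusic <- bandPower(seg("music"), 250, 15, 30)
  pRest <- bandPower(seg("resting"), 250, 15, 30)
  expect_gt(pMusic / pRest, 5)
})

test_that("with noise off, signature spectra peak inside the signature band", {
  p <- simParams(nSubjects = 1L, stateDuration = 16, rate = 250,
                 noiseScale = 0, includeTiming = FALSE, seed = 5L)
  rec <- simulateRecording(p, 1L)
  ann <- annotations(rec)
  m <- standardMontage()
  bands <- list(low = c(0, 15), mid = c(15, 30), high = c(30, 45))
  for (st in names(defaultSignatures())) {
    sg <- defaultSignatures()[[st]]
    a <- ann[ann$label == st, ]
    i0 <- round(a$onset * rec@rate)
    x <- rec@signals[match(sg$electrodes[1], channelNames(m)),
                     (i0 + 1):(i0 + round(a$duration * rec@rate))]
    inBand <- bandPower(x, 250, bands[[sg$band]][1], bands[[sg$band]][2])
    total <- bandPower(x, 250, 0, 125)
    expect_gt(inBand / total, 0.9)
  }
})

test_that("unknown signature electrodes are rejected", {
  sig <- defaultSignatures()
  sig$music$electrodes <- c("C4", "NOPE")
  p <- simParams(signatures = sig, stateDuration = 5, rate = 100,
                 includeTiming = FALSE)
  expect_error(simulateRecording(p, 1L), "unknown electrode")
  expect_error(simulateRecording(simParams(nSubjects = 1L), 2L),
               "out of range")
})
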