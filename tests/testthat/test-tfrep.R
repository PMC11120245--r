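test_that("scalogram of a pure tone peaks at the nearest grid frequency", {
  rate <- 250
  tt <- (0:749) / rate
  tf <- cwtPowerMap(sin(2 * pi * 10 * tt), rate)
  interior <- 200:550
  peaks <- apply(tf@power[, interior], 2, which.max)
  expect_true(all(tf@freq[peaks] == 10))
  # two tones give two local maxima near 10 and 35 Hz
  tf2 <- cwtPowerMap(sin(2 * pi * 10 * tt) + sin(2 * pi * 35 * tt), rate)
  prof <- rowMeans(tf2@power[, interior])
  locmax <- which(diff(sign(diff(prof))) == -2) + 1L
  expect_true(any(abs(tf2@freq[locmax] - 10) <= 1))
  expect_true(any(abs(tf2@freq[locmax] - 35) <= 1))
})

test_that("scalogram is linear in the zero signal and rejects bad input", {
  tf <- cwtPowerMap(rep(0, 500), 250)
  expect_true(all(tf@power == 0))
  expect_error(cwtPowerMap(numeric(0), 250), "empty")
  expect_error(cwtPowerMap(c(1, NA, 2), 250), "non-finite")
  expect_error(cwtPowerMap(rnorm(100), 250, freqs = c(10, 200)), "rate/2")
})

test_that("band split partitions the default grid into 28/30/31 rows", {
  tf <- cwtPowerMap(rnorm(500), 250)
  bands <- bandSplit(tf)
  expect_equal(vapply(bands, function(b) nrow(b@power), numeric(1)),
               c(low = 28, mid = 30, high = 31))
  # partition is exhaustive and disjoint
  expect_equal(sort(c(bands$low@freq, bands$mid@freq, bands$high@freq)),
               tf@freq)
  # a 20 Hz tone deposits > 80% of total power in the mid band
  tone <- cwtPowerMap(sin(2 * pi * 20 * (0:749) / 250), 250)
  tb <- bandSplit(tone)
  tot <- sum(tone@power)
  expect_gt(sum(tb$mid@power) / tot, 0.8)
})

test_that("bilinear resize preserves constants, identity and peak location", {
  const <- new("TFMap", power = matrix(3.5, 20, 40),
               freq = seq(1, 20, length.out = 20),
               time = seq(0, 1000, length.out = 40))
  r <- resizeMap(const)
  expect_equal(dim(r@power), c(60L, 100L))
  expect_true(all(abs(r@power - 3.5) < 1e-9))
  # 60 x 100 input is unchanged
  set.seed(8)
  exact <- new("TFMap", power = matrix(runif(6000), 60, 100),
               freq = seq(1, 45, length.out = 60),
               time = seq(0, 1000, length.out = 100))
  expect_equal(resizeMap(exact)@power, exact@power, tolerance = 1e-12)
  # delta at the centre maps to the centre within one bin
  delta <- matrix(0, 21, 51); delta[11, 26] <- 1
  rd <- resizeMap(new("TFMap", power = delta,
                      freq = seq_len(21), time = seq_len(51)))
  pk <- which(rd@power == max(rd@power), arr.ind = TRUE)[1, ]
  expect_lt(abs(pk[1] - 30.5), 2)
  expect_lt(abs(pk[2] - 50.5), 2)
})

test_that("stacks have the contracted shape, range and plane order", {
  rate <- 250
  epoch <- matrix(0, 59, 750)
  st0 <- buildStack(epoch, rate)
  expect_equal(dim(st0), c(60L, 100L, 177L))
  expect_true(all(st0 == 0))          # constant planes normalise to 0

  # 20 Hz tone only on C4: its mid-band plane carries the top raw energy
  c4 <- match("C4", channelNames(standardMontage()))
  epoch[c4, ] <- sin(2 * pi * 20 * (0:749) / rate)
  raw <- buildStack(epoch, rate, normalize = FALSE)
  energies <- apply(raw, 3, sum)
  expect_equal(which.max(energies), (c4 - 1L) * 3L + 2L)
  st <- buildStack(epoch, rate)
  expect_true(all(st >= 0 & st <= 1))
})

test_that("injecting band power raises that plane's raw energy monotonically", {
  rate <- 250
  set.seed(4)
  base <- matrix(rnorm(59 * 500, sd = 0.5), 59, 500)
  c3 <- match("C3", channelNames(standardMontage()))
  tone <- sin(2 * pi * 35 * (0:499) / rate)
  eHigh <- function(a) {
    ep <- base; ep[c3, ] <- ep[c3, ] + a * tone
    sum(buildStack(ep, rate, normalize = FALSE)[, , (c3 - 1L) * 3L + 3L])
  }
  e <- vapply(c(0, 1, 2, 4), eHigh, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("permuting electrodes permutes stack planes accordingly", {
  rate <- 250
  set.seed(5)
  epoch <- matrix(rnorm(59 * 400), 59, 400)
  perm <- sample(59)
  s1 <- buildStack(epoch, rate)
  s2 <- buildStack(epoch[perm, ], rate)
  planePerm <- as.vector(t(outer((perm - 1L) * 3L, 1:3, `+`)))
  expect_equal(s2, s1[, , planePerm])
})

test_that("whole-epoch-set stacking matches per-epoch stacking and labels", {
  rec <- tinyRecording()
  ep <- segmentEpochs(rec, 3)
  st <- buildStacks(ep)
  expect_s4_class(st, "TFStackSet")
  expect_equal(nEpochs(st), nEpochs(ep))
  expect_identical(epochLabels(st), epochLabels(ep))
  expect_equal(st@stacks[, , , 2], buildStack(ep@epochs[, , 2], ep@rate))
  # plane-first accessor
  one <- getStack(st, 1)
  expect_equal(dim(one), c(177L, 60L, 100L))
  expect_equal(one[5, , ], st@stacks[, , 5, 1])
})
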