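# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A short two-state-cycle recording for preprocessing/EDF tests.
tinyRecording <- function() {
  fixture("tinyRec", function() {
    p <- simParams(nSubjects = 1L, stateDuration = 12, rate = 250,
                   includeTiming = FALSE, seed = 11L)
    simulateRecording(p, 1L)
  })
}

# Small random stack batch for network-level tests.
randomStacks <- function(n, seed = 99L) {
  r <- paste0("stacks", n, "_", seed)
  fixture(r, function() {
    set.seed(seed)
    array(runif(60 * 100 * 177 * n), c(60, 100, 177, n))
  })
}

# RMS band power of one channel via Welch-free direct periodogram:
# independent oracle used against the generator and the CWT.
bandPower <- function(x, rate, lo, hi) {
  n <- length(x)
  sp <- abs(fft(x))^2 / n
  f <- (seq_len(n) - 1L) * rate / n
  sel <- f >= lo & f <= hi & f <= rate / 2
  sum(sp[sel])
}
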