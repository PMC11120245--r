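---
title: "Decoding cognitive states from EEG scalograms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cognitive states from EEG scalograms: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A cognitive brain-computer interface asks whether self-paced, high-level
mental activity — resting with a wandering mind, recalling the day's events,
mentally singing a song, counting down from 5000 in steps of 3 — leaves a
decodable trace in scalp EEG. `CogStateCNN` implements a subject-dependent
four-class decoder for this task: 59-channel EEG is transformed into
time-frequency images and classified by a convolutional network with a
channel-and-frequency attention (CFA) block. Because recordings from such
experiments are typically private, the package ships a seeded synthetic
generator that emulates the acquisition protocol, so the entire pipeline is
testable end to end without any data download.

# Pipeline

1. **Acquisition model.** 59 electrodes (10-20/10-10 positions, Fpz ... O2),
   block design: within each block the subject performs the four states in
   sequence (resting always first), each as a 6 s fixation cue, 60 s of
   imagery and 24 s of rest, with 60 s between blocks. A full session gives
   15 min of imagery per state per subject.
2. **Preprocessing** (`bandpassFilter`, `averageReference`,
   `baselineCorrect`, `segmentEpochs`): zero-phase Butterworth band-pass
   0.1-45 Hz, common average reference, subtraction of the mean over the 6 s
   preceding each task onset, and segmentation of each imagery interval into
   non-overlapping windows of length `L` (default 3 s), labelled by state.
   Partial tails are discarded (`floor(D / L)` windows per interval).
3. **Time-frequency representation** (`cwtPowerMap`, `bandSplit`,
   `resizeMap`, `buildStacks`): per channel, a complex Morlet continuous
   wavelet transform (6 cycles) on a linear 1-45 Hz grid in 0.5 Hz steps;
   the power map is split into low (0-15 Hz), mid (15-30 Hz) and high
   (30-45 Hz) bands; each band plane is bilinearly resized to 60 x 100 and
   min-max normalised to [0, 1]. The 59 electrodes x 3 bands give a
   177-plane stack per window — the network input.
4. **Network** (`networkSpec`, `initNetwork`): conv 3x3 (177->177), CFA,
   max-pool 5x5/5, conv 5x5 (->128), pool 2x2/2, conv 5x5 (->128),
   conv 5x5 (->64), dropout 0.5, pool 2x2/2, flatten (960), linear to 4
   classes; ReLU after every convolution. The CFA block computes per-plane
   global max- and average-pooled statistics, sums them, passes them through
   a 177->59->177 perceptron (ReLU after each layer) and a sigmoid, and
   rescales each plane by its weight.
5. **Training and evaluation** (`trainSubject`, `computeMetrics`): per
   subject, a stratified 80/20 train/test split; the training portion is cut
   into K = 5 folds; each fold's model trains on the other four folds with
   Adam (learning rate 1e-3) on softmax cross-entropy, batch size 32, and is
   evaluated on the fixed test set. Reported metrics: accuracy, macro
   precision/recall/F-score, Cohen's kappa, macro one-vs-rest AUC, as
   per-fold values and mean +/- sd.
6. **Attention topography** (`attentionTopography`, `renderTopomap`): mean
   CFA weights over folds and probe stacks, reshaped to electrodes x bands
   and drawn as scalp maps.

# The synthetic generator

`simulateRecording` produces, per subject, independent 1/f^alpha background
noise (alpha = 1, spectral shaping of white Gaussian noise) on every channel
at 10 uV RMS by default, plus one spatial-spectral signature per state: an
amplitude-modulated sinusoid whose frequency is drawn inside the signature
band, scaled to the signature RMS on the listed electrodes with
half-amplitude spill-over onto each electrode's two nearest neighbours.
Defaults place posterior low-band activity for resting, frontal mid-band for
memory, right-temporal high-band for music and parietal mid-band for
subtraction — mutually distinct in space or frequency so that attention can
in principle recover them; they are caricatures, not claims about cortical
sources. A `subjectJitter` knob perturbs per-subject amplitude and centre
frequency, standing in for inter-subject variability that the underlying
experiment does not characterise.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction from realistic head geometry, non-stationary state dynamics
within an imagery interval, or electrode drift. Passing the package's
recovery tests therefore shows that the pipeline can extract planted
spatial-spectral structure at realistic amplitudes — not that the published
real-data accuracies are reproduced. Those require the original private
recordings.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| band edges | 0/15/30/45 Hz | the three scalogram planes per electrode |
| CWT grid | 1-45 Hz, 0.5 Hz steps | 0 Hz is unreachable by a wavelet; 89 rows split 28/30/31 across bands |
| wavelet width | 6 cycles | standard EEG trade-off between time and frequency resolution |
| window length L | 3 s | the protocol's default epoch; sweeps use 1.5-5 s |
| plane size | 60 x 100 | fixed network input; flatten length 960 follows from it |
| dropout | 0.5 | regularisation after conv4 |
| learning rate | 1e-3 | Adam default; no scheduler, no early stopping |
| batch size | 32 | training protocol |
| folds K | 5 | cross-validation protocol |
| noise / amplitude | 10 / 5 uV RMS | realistic background-to-signature ratio; `highSNRParams()` uses 4 / 8 uV for the easy regime |

# Numerical and design choices

* **Filter realisation.** The 0.1-45 Hz band-pass is a cascade of a
  2nd-order high-pass and a 4th-order low-pass Butterworth, each applied
  forward-backward (zero phase). A single band-pass with a 0.1 Hz edge is
  numerically fragile in transfer-function form; the cascade is stable at
  both 250 and 1000 Hz.
* **Wavelet realisation.** The Morlet CWT is computed as a bank of analytic
  Gaussian filters in the frequency domain (sd = f/6 at centre frequency f),
  scaled so a unit-amplitude tone yields ridge power ~1. Signals are
  zero-padded to twice the next power of two, which exceeds the wavelet
  support at the lowest analysed frequency (1 Hz) and avoids circular
  wrap-around.
* **Order of operations.** Band splitting happens **before** resizing, so
  each band plane is independently 60 x 100 — required for a 177 x 60 x 100
  stack. Resizing first and slicing afterwards would yield 20-row bands and
  cannot produce the stated input shape.
* **Normalisation.** Per-plane min-max to [0, 1]; constant planes map to 0.
  Grayscale power planes are used throughout; colormap rendering of
  scalograms is a display convention and never enters the computation.
* **Attention tail as specified.** The CFA block applies ReLU *before* the
  sigmoid, which confines all attention weights to [0.5, 1). This follows
  the published layer table as printed; a conventional sigmoid-only tail
  would allow (0, 1). The property suite asserts the [0.5, 1) interval.
* **Pooled-vector fusion.** The global max- and average-pooled vectors are
  summed before the shared perceptron, matching the single fc1 path of the
  layer table.
* **Paddings and pooling.** Conv paddings (1 for 3x3, 2 for 5x5) are forced
  by shape preservation in the layer table; pooling is max pooling.
* **Initialisation.** Uniform fan-in, U(-1/sqrt(fan_in), +1/sqrt(fan_in)),
  fully seeded. Training is bit-deterministic on a given platform: one
  private Mersenne Twister drives initialisation, shuffling and dropout.
* **Chance agreement.** Kappa uses marginal chance agreement (Cohen's
  convention) by default; on the balanced protocol this coincides with the
  fixed P0 = 1/4 used in the published worked examples. The published kappa
  values are truncated rather than rounded at the fourth decimal, so
  checks against them allow one unit in the last printed digit.
* **Undefined precision.** A class never predicted leaves precision
  undefined; macro averages skip such classes with a warning.
* **Engine.** No deep-learning framework is available in the target
  R environment, so the conv/pool/attention/linear layers, softmax
  cross-entropy, backpropagation and Adam are implemented in C++
  (single precision, im2col + BLAS gemm). Gradients are verified against
  central finite differences in the development history; eval-mode forward
  passes are deterministic.

# Problem sizes used by the test suite

The published protocol (7 subjects x 15 min per state at 1000 Hz, 50 epochs
per fold) is far beyond a desk-scale test budget: one forward+backward pass
of the network costs ~0.1-0.2 CPU-seconds, dominated by the 177->177
convolution at 60 x 100 resolution. The package therefore fixes these
scaled-down problem sizes for its own verification runs:

* **Sample bookkeeping** uses the full protocol's annotation timeline (no
  signal is generated), reproducing the published train/test count table
  exactly, including the 3.5 s row once segmentation is done per 60 s
  imagery block. The published 4.5 s row (4436/1108) is not divisible into
  the protocol's 420 blocks and is excluded as an inconsistency of the
  source table.
* **Recovery runs** use the high-SNR fixture at 90 s per state and 250 Hz
  (120 windows per subject, 96 train / 24 test), K = 5 folds, batch 16 with
  8 epochs (about 40 Adam steps per fold) for the genuine-label run and
  2 epochs for the label-shuffled control. These sizes were chosen from the
  step-count arithmetic above — roughly matching the per-fold update count
  at which the engine was observed to converge on this fixture — and are
  stated here as the package's reference problem sizes.
* The window-length sweep utility runs the same protocol per length; its
  unit test uses a 12 s-per-state fixture with 2 folds and 1 epoch purely
  as a bookkeeping and plumbing check.

# Known limitations

* Subject-dependent decoding only; no cross-subject transfer or alignment.
* ICA artifact removal and bad-channel interpolation are exposed only as a
  pass-through hook (`artifactHook`): synthetic data needs neither, and both
  are standard library operations on real data.
* The EDF writer targets the package's own 59-channel recordings (16-bit,
  1 s records, EDF+ annotations); it is not a general-purpose EDF library,
  though files are readable by standard tools.
* Accuracy claims transfer to real EEG only to the extent that real class
  signatures resemble stable band-limited, spatially localised power
  differences.
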