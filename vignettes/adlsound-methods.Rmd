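---
title: "Methods: from ambient sound to activity logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ambient sound to activity logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adlsound)
```

`adlsound` models a household acoustic monitoring system as a chain of small,
individually testable stages. This vignette explains each stage's model and
assumptions, the parameters that matter, the numerical conventions, and what
the synthetic experiments do and do not establish.

## Signal model and capture gating

All audio is mono 16 kHz PCM in [-1, 1]; the WAV reader deliberately rejects
any other rate, bit depth or channel count rather than resampling, because
every downstream shape (512-sample buffers, 1024-point FFT frames, 48x32
features) is derived from that one format.

The capture stage emulates an event-driven node. Energy is the mean absolute
amplitude of a 512-sample buffer (a deliberately cheap statistic an always-on
low-power core can afford), a segment opens at the first buffer at or above
`wake_threshold` and closes when sub-threshold buffers persist beyond
`stop_silence_s`. Defaults: `wake_threshold = 0.01` (mean-abs units,
full scale 1.0) and `stop_silence_s = 5` seconds. The wake threshold has no
canonical published value; 0.01 sits roughly 20 dB below the nominal event
level of the synthesizer (RMS 0.05) and safely above its quiet-room floor, so
gating neither chatters on silence nor clips event onsets by more than one
buffer (32 ms). A single supra-threshold buffer resets the silence counter —
"low energy maintained" is read as a *consecutive* run. A trailing partial
buffer is dropped, mirroring buffer-granularity hardware.

## Windowless streaming features

The spectrogram is hop-synchronous: buffer size equals hop (512), each
arriving buffer is concatenated with its predecessor into a rectangular
(unwindowed) 1024-sample frame, and the 1024-point DFT's power |X_k|^2 is
kept for k = 0..511. Three conventions pin the exact 512x32 / 48x32
geometry for one second of audio:

* the first frame uses 512 zeros of prehistory — at stream start there is no
  "previous buffer";
* the final partial hop is zero-padded, so 16000 samples always yield
  ceil(16000/512) = 32 frames;
* bins k = 0..511 of the one-sided spectrum are kept (the Nyquist bin is
  dropped) — the only reading that gives exactly 512 rows.

The Mel stage uses 48 triangular filters with centers equally spaced on the
HTK scale `m = 2595 log10(1 + f/700)` between 0 and 8 kHz, evaluated on the
512 bin frequencies, unnormalized. 48 bands rather than the speech-standard
40 keeps resolution in the bands where appliance noise lives, and divides
cleanly under the network's three 2x poolings. The log transform is decibels
referenced to the matrix maximum with an `-80` dB floor (`amin = 1e-10`
guards the log). dB rather than natural log is chosen for parity with the
widely used reference mel-spectrogram extraction; the test suite checks the
whole chain against an independently implemented NumPy oracle to 1e-4. A
fully silent input returns a matrix filled with the floor value (the
referenced transform is otherwise undefined at zero power). All of
`n_fft = 1024`, `hop = 512`, `n_mels = 48`, `db_floor = -80` are arguments,
not constants.

Feature quantization is affine int8, `q = clamp(round(x/s) + z, -128, 127)`,
with `(s, z)` calibrated once from the min/max of a calibration collection —
global (training-set) calibration rather than per-clip, mirroring fixed-scale
deployment where the parameters are frozen into the exported model. A
degenerate calibration range falls back to `s = 1e-8`. One second of features
is 6144 bytes in float32 and 1536 bytes in int8; `write_feature_bin()`
serializes exactly those payloads.

## Dataset construction

Sounds divide into *continuous* (water, hums, speech: they dominate many
consecutive frames) and *instant* (impacts, flushes: they complete within a
frame or two). The default map assigns `hitting` and `flushing` to instant
and everything else to continuous. Continuous recordings are cut into
non-overlapping one-second clips (trailing remainder dropped); a short event
is placed at a seeded random offset inside a zero one-second buffer and
yields exactly one training clip.

Balancing resamples each label to `balance_target = 1500` base clips (plus
`domain_target = 250` site-specific clips where available; a site never
records every label). Oversampling repeats the whole set floor(target/n)
times and draws the remainder without replacement, so each original appears
either floor or ceiling many times; over-represented labels are subsampled
without replacement. Augmentation *follows* resampling — it is what
diversifies the oversampled repeats — and produces two masked copies per
clip: each copy erases 1-2 contiguous time bands (width <= 8 frames) and 1-2
contiguous Mel bands (height <= 8 bands) to the dB floor. The mask geometry
is not canonical; the defaults follow the usual spectrogram-masking
augmentation style and are config arguments. The resulting per-label totals
are 1500 x 3 = 4500 (base-only labels) or 1750 x 3 = 5250. The 1500:250
ratio is applied per label; whether it was ever meant as an aggregate ratio
is ambiguous, but per-label is the only reading consistent with resampling
the domain pool "based on 250 samples". Train/test splits are stratified at
the *source clip* level so an original and its oversampled or augmented
derivatives never straddle the split.

## The classifier

The network is a deliberately small residual CNN over 48x32x1 inputs: a 3x3
stem of width 8 with batch norm and ReLU, three residual stages of widths
8/16/32 (each one block of two 3x3 convolutions with a 1x1 stride-2
projection skip, downsampling at stage entry), global average pooling and a
softmax layer. With 12 classes this is 19,956 parameters — the low tens of
thousands a microcontroller budget implies. Published edge models of this
family land in the same range but differ in per-layer details, so the widths
here are configurable and matching any particular parameter count was not a
goal. Training is
mini-batch Adam (lr 1e-3, batch 64, up to 30 epochs, early stopping with
patience 5 on validation loss when a validation set is supplied); no
optimizer or schedule is canonical for this architecture, so the defaults are
the field's adaptive-moment defaults. Inputs are mapped from dB to roughly
[-1, 1] by the fixed affine (x + 40)/40. Everything (initialization,
shuffling) is seeded; two builds or runs with the same seed are bit
identical. The convolution/batch-norm kernel is implemented in
RcppArmadillo (im2col + GEMM) because no deep-learning framework is part of
this package's dependency footprint and the numerical content is small
enough to own.

Quantized inference is emulated in-process rather than through a specific
embedded runtime; the contract is the arithmetic, not the file format. Batch
norm is folded into the convolutions (weights scaled per out-channel, means
and betas folded into biases), folded weights are quantized per-tensor
symmetric int8 (scale max|w|/127), biases stay float (standing in for the
int32 bias path of integer runtimes), and activations are quantized
per-tensor affine int8 at the block boundaries (network input is covered by
the feature quantization; each ReLU output and the pooled vector carry
calibrated scales from min/max over a calibration set). The logit/softmax
stage stays float, as it does in practice.

## Voting and activity assembly

Predictions arrive every 0.5 s. Windows of 7 frames (3.5 s) slide by one
frame; a window is only evaluated once full. Per label, independently:

* continuous: occurred iff strictly more than `window_size/2` frames exceed
  the probability threshold (with the odd default 7 a tie is impossible; the
  strict inequality is kept for even windows); confidence is the mean
  probability over the whole buffer.
* instant: occurred iff any frame exceeds the threshold; confidence is the
  mean of the supra-threshold probabilities only, so a single strong frame
  is not diluted by six empty ones.

Labels are never exclusive — water can run while a cup clinks — which is the
reason for per-label counting instead of hard or soft voting over a single
winner. The probability threshold defaults to 0.5 (no canonical value
exists; it is a per-config argument).

Because consecutive windows overlap, one physical supra-threshold frame of an
instant label would be re-counted in up to 7 windows. The stream-level voter
attributes an instant occurrence once, at the first window containing the
frame (tracked by frame index), then suppresses it. The single-window
`vote()` operation has no cross-window state and performs no deduplication.

Activity assembly follows the occurred/tolerance automaton: open at the
first occurred window (start time = that window's time), accumulate count
and confidence on occurrences and reset the tolerance counter, decrement on
every non-occurred window, close when the counter goes below zero (end time
= last occurred window). Tolerances are counted in windows: 10 (= 5 s) for
continuous labels, 4 for instant ones. Stream end flushes open activities.
Confidence of an activity is the mean of its constituent occurred-window
confidences; duration is exactly end - start. A consequence worth naming: an
activity with a single occurrence has start == end and duration 0 — the
strict start < end expectation holds only from two occurrences up, and the
`min_duration` filter is the natural way to drop such records when they are
unwanted.

Window and frame time bases: a frame's time is the *center* of its
one-second clip, and a window's time is its newest frame's time. The center
convention keeps logged intervals aligned with ground-truth intervals for
transients (a start-of-clip convention would systematically place a
transient's activity half a second before the event).

Log filtering drops records below `min_duration` or `min_confidence`
(defaults 0 — filtering is opt-in) and records whose label is excluded at
the node's location; the shipped exclusion table (bathroom: tv, microwave,
cooking) is an editable example, not a claim about all homes.

## The hub and scoring

The hub is in-process/file plumbing, not a daemon: `run_node()` chains
gate -> frame -> features -> predict -> vote -> accumulate -> filter per
active segment (the voting buffer starts empty in each segment, as a
wake-from-sleep node's buffer would), and `merge_logs()` is a stable
chronological merge with (location, label) tie-breaking. Timestamps are
stream-relative seconds; wall-clock anchoring is the caller's business.

Event-level scoring is artifact-defined (the reference system reports no
event metric): a truth interval is detected if a same-label activity
overlaps it by at least `overlap_fraction = 0.5` of the truth duration,
matched one-to-one greedily by overlap; precision/recall/F1 follow. The
`background` class is ignored by default since scripts never contain it.

## What the synthesizer does and does not establish

Each class has a fixed parametric recipe (band-shaped noise with distinct
passbands for the two water classes, ~4 Hz amplitude-modulated noise for
brushing, crackle + hiss for cooking, mains-harmonic stacks with fan noise
for microwave/airutils, syllabically modulated formant tones for speech/tv,
narrow-band trickle for peeing, a <= 0.3 s decaying broadband transient for
hitting, a rise-sustain-fall flush, pink-noise background). Nominal level is
RMS 0.05 full scale with per-call gain; sessions mix entries sample-wise
over a pink noise floor and peak-normalize only if the mix clips, preserving
transient crest factors. One master seed splits into independent per-entry
streams, so editing one script entry never changes another's noise.
Generation is bit-reproducible.

The recipes were chosen once so that classes are mutually separable (a
nearest-centroid baseline on mean log-Mel vectors exceeds 80%; the CNN is
expected to do much better) — there is deliberately learnable structure, as
the pipeline's correctness is the thing under test. No claim is made that
absolute accuracies transfer to real recordings: the synthesizer has no room
acoustics, no reverberation, no microphone coloring, and its amplitude
statistics are calibrated only for mutual separability (no published
amplitude statistics exist for the original recordings to match). What the
synthetic experiments *do* establish is relational: the pipeline's shapes
and payloads are exact, voting equals its brute-force definition, smoothing
beats raw frames under injected label noise, balancing/augmentation help
under class imbalance in the expected order, and int8 inference tracks the
float path.

## Problem sizes and numerical choices in the shipped experiments

The test suite trains the shared 12-class model on 500 clips per label and
evaluates on 100 per label (6 epochs); the imbalanced-data ablation uses 4
classes at 120/12/8/6 clips against a 120-clip balance target over 3 seeds;
the smoothing experiment uses 120-frame streams over 20 seeds with 10%
argmax flips; end-to-end evaluation uses three 10-minute scripted bathroom
sessions over a -10 dB noise floor (which keeps the energy gate open — a
ventilated bathroom rather than a silent one — so segmentation does not
truncate the 3.5 s flush events below the voting buffer length). These sizes
were chosen as the smallest at which each effect is comfortably away from
its decision boundary. Numerical guards: batch-norm epsilon 1e-5, softmax
computed with max subtraction, cross-entropy clamped at 1e-12, quantization
scales floored at 1e-8, batches of fewer than two samples skipped (batch
statistics are undefined).

## Known limitations

* No open-set/outlier rejection: an unknown sound is forced into the nearest
  known class (a gargle will log as speech).
* The int8 path is an emulation of integer arithmetic in float (fake-quant);
  bit-exactness with any particular embedded runtime is not claimed.
* Session scripts are ground truth by construction; there is no labeling
  noise model.
* The hub's chronological merge assumes nodes share a time base.
* Synthetic separability means reported accuracies are upper bounds on what
  comparable real data would give.
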