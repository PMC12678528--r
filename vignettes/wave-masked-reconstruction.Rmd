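---
title: "Wave-masked linear ECG lead reconstruction: methods and design"
author: "wmlr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-masked linear ECG lead reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmlr)
```

## The reconstruction model

ECG leads measure projections of one underlying cardiac source onto
different electrode configurations, so to a first approximation any lead
is a linear function of a few others, applied sample by sample:

$$y_t = A\,x_t + C,$$

with $x_t$ the vector of available channel values at time $t$, $A$ an
outputs × inputs coefficient matrix and $C$ an intercept. The four limb
leads never need fitting: $III = II - I$, $aVR = -(I+II)/2$,
$aVL = I - II/2$, $aVF = II - I/2$ hold exactly
(`derive_limb_leads()`), so reconstruction targets the precordial
leads only.

The package fits this transform in two interchangeable ways:

* `fit_ols()` — the SVD-based closed form. For a rank-deficient design
  it returns the minimum-norm solution with a warning; this matters in
  practice because highly collinear lead sets are common.
* `fit_sgd()` — minibatch stochastic gradient descent on channels
  standardized by training statistics, started from zero coefficients.
  Starting at zero keeps the iterates inside the row space of the
  design, so on rank-deficient data SGD converges to the same
  minimum-norm solution as the closed form *in the standardized space*;
  coefficients are mapped back to raw millivolts before the model is
  returned, and the scaling state is stored so predictions are invariant
  to the internal scaling choice (checked to 1e-9 in the tests).

SGD defaults are learning rate 0.05, batch 1024, at most 300 epochs with
early stop when an epoch improves the standardized loss by less than
1e-12. The rate sits well under the stability limit (the standardized
Hessian has eigenvalues of order the channel count), and the epoch cap is
sized for the worst case of one batch per epoch on tiny fixtures; on
cohort-sized data the early stop ends training within a handful of
epochs. An epoch whose standardized loss exceeds 1e8 raises a divergence
error naming the epoch rather than returning garbage. Correctness is
anchored by equivalence tests against `fit_ols()` (coefficients within
1e-2 on standardized channels, prediction RMSE within 1e-3 mV).

## Wave masking

Healthy ECG activity is a sequence of compact waves — the P wave, the
QRS complex, the T wave — separated by near-isoelectric gaps. A single
linear map on raw per-sample inputs must apply the *same* gains to every
wave; if the waves project to the output leads with different relative
amplitudes, no such map is exact. Wave masking works around this while
staying linear: for each wave, everything outside the wave's delineated
segments is replaced by zeros (`mask_wave()`, half-open `[on, off)`
intervals, exact pass-through inside). The augmented input
(`build_augmented_input()`) stacks six channels in a fixed order:

1. P wave masked from lead II,
2. QRS complex masked from lead V3,
3. T wave masked from lead I,
4. raw leads I, II and V3.

Because the three masked channels are nonzero on disjoint supports, the
fitted transform can give each wave its own effective gain. The default
wave-to-lead mapping is configurable; the channel order is fixed and
recorded so that model coefficients remain comparable across runs. Only
zero padding is supported — softer or tapered masks would break the exact
complementarity property (P + QRS + T masks reconstruct the signal on the
segment union, bit-exactly) that the test suite relies on.

## Delineation

Masking needs fiducials from only the available leads. The delineator is
deliberately classical:

* **R peaks**: zero-phase band-pass 5–15 Hz, derivative, squaring,
  150 ms moving-window integration, adaptive threshold (half the 99th
  percentile of the envelope) with a 200 ms refractory period, then
  refinement to the absolute extremum of the raw signal.
* **QRS bounds**: outward scan from R until the rectified signal stays
  below 0.05 % of the R amplitude for 6 ms. The dwell requirement stops
  the scan from ending at the instantaneous zero crossings between Q, R
  and S.
* **P and T**: dominant extremum in a 200 ms window before QRS onset
  (P) and in up to 60 % of the RR interval after QRS offset (T); a wave
  whose peak is below 2 % of the R amplitude is reported ABSENT rather
  than invented. Boundaries use 0.05 % of the wave's own peak.
* **Baseline**: the mode of the amplitude histogram, not the median — at
  high heart rates waves occupy most of the record and the median drifts
  off the isoelectric line.
* **Fusion**: leads I, II, V3 are delineated independently, beats are
  matched by nearest R peak within 150 ms, and each fiducial is the
  across-lead median. QRS has priority in overlap repair (P offsets clip
  to QRS onset, T onsets to QRS offset), and consecutive beats are
  clipped so their segments never overlap.

The boundary fractions are far smaller than the 5 % used by bedside
delineators on purpose. The synthetic generator defines wave truth as the
±4σ truncation of Gaussian components; a 5 % crossing of a Gaussian sits
about 1.5σ inside that support (≈ 30 ms for a 20 ms-wide P wave), which
would be a systematic bias, not noise. A 0.05 % crossing sits at ≈ 3.9σ,
within 10 ms of truth across the generator's width jitter. On real,
noisy recordings these deep thresholds would chase noise — there the
import path (`import_fiducials()`, a 0-based CSV dialect with empty
fields for absent waves) lets users bring boundaries from any external
delineator, and all fiducial invariants are validated on import.

## The synthetic cohort generator

`generate_cohort()` emulates 10 s, 500 Hz, 12-lead records in millivolts
with known ground truth. Design choices:

* **Beat model**: sums of Gaussians per deflection (P, Q, R, S, T), each
  truncated at ±4σ. Defaults: P(−160 ms, σ 20 ms, 0.15 mV),
  Q(−25, 8, −0.10), R(0, 10, 1.00), S(25, 8, −0.20),
  T(240, 30, 0.35) relative to the R peak — amplitudes and timings of a
  normal adult beat. Truncation makes wave supports *exact*, so masking
  complementarity and fiducial recovery can be tested with zero
  tolerance. A dynamical-system beat model would look more organic but
  has no provable supports; exactness won.
* **Mixing**: one source, three wave components, projected onto the
  eight independent leads through per-wave gain vectors; limb leads are
  derived from I and II so Einthoven/Goldberger identities hold by
  construction. In `global` mode all waves share one gain vector. In
  `per_wave` mode a disparity `d` scales the QRS gain by `1 + d` and the
  P/T gains by `1 − d` on the reconstructed leads V1, V2, V4, V5, V6,
  while the input leads I, II, V3 keep the shared gains. Keeping the
  input gains shared is the crucial construction: every raw input sample
  then lies on a single line regardless of which wave produced it, so
  raw inputs carry no wave identity and the three-lead transform is
  provably misspecified, while the masked channels separate the waves
  and make the six-channel transform exact (to the noise floor). The
  energy-weighted residual algebra of this construction predicts a mean-r
  advantage of roughly 0.015 at `d = 0.2` under 20 dB noise, which is
  what the acceptance script measures.
* **Patient variability**: heart rate uniform in 50–90 bpm, per-patient
  multiplicative jitter of ±20 % on amplitudes and ±10 % on widths, RR
  jitter ±5 % per beat, seeded hierarchically (cohort → patient →
  record), every derived seed kept below 2³¹. The width jitter is
  deliberately half the amplitude jitter: wider T waves at the fastest
  heart rates would otherwise let the T support of one beat collide with
  the next beat's P support, which the generator treats as a morphology
  error.
* **Noise**: white Gaussian noise per core lead at a configured SNR
  (dB), added before limb-lead derivation so the limb identities hold
  for the noisy signals too. 20 dB corresponds to clearly visible but
  benign baseline noise.
* **Default gains** `(I 0.6, II 1.0, V1 0.4, V2 0.7, V3 1.1, V4 1.3,
  V5 1.0, V6 0.8)`: positive (R upright everywhere), distinct, and with
  `g_I ≠ g_II/2` so the derived aVL is not identically zero.

What the generator does *not* emulate: pathological morphologies, P/T
overlap at extreme rates, electrode motion artifacts, mains
interference, inter-lead noise correlation beyond the limb-lead algebra,
or torso volume-conductor physics. Tests passing on this generator show
the pipeline machinery is correct and that masking captures wave-specific
structure when present; they do not certify clinical accuracy on real
recordings, where the masking advantage must be re-measured (the
HDF5/metadata adapter exists for exactly that).

## Evaluation protocol

Performance is scored per record and per lead over all samples: Pearson
correlation (undefined correlations from constant signals are excluded
from aggregates and counted) and RMSE in millivolts. Records are
assigned to 5 folds *by patient* — all records of a patient share a
fold, fold sizes differ by at most one, assignment is deterministic per
seed — and each fold's model trains on the pooled samples of all
out-of-fold records. Aggregate tables report median/mean/SD per lead
plus an unweighted `Average` row; SD defaults to the population
convention (divide by n; configurable) purely so results are
reproducible to the last digit. Pipelines are compared with classical
paired t-tests on per-record RMSE matched by record id, two-sided, with
significance marked at p < 0.05 and no multiple-testing correction;
p-values are reported raw and flagged when the difference distribution
is degenerate.

## Numerical conventions and limits

* Sample indices are 1-based inside the package (native R); intervals
  are half-open `[on, off)`. The fiducial CSV dialect on disk is 0-based
  for interoperability with external tools; conversion happens at
  import/export.
* Amplitudes are millivolts everywhere; readers convert via WFDB gain
  and the HDF5 `scale` attribute. WFDB round trips are exact to half an
  ADC quantization step (format 16 stores 16-bit counts); CSV round
  trips are bit-exact (`%.17g`).
* Resampling is polyphase rational (`signal::resample`) with the ratio
  reduced to small integers; a 5 Hz sine resampled 400→500 Hz stays
  within 1e-3 mV of the analytic signal away from the edges.
* Denoising is zero-phase (forward–backward) 4th-order Butterworth,
  highpass 0.3 Hz and lowpass 100 Hz, optional 50/60 Hz notch, chosen as
  standard conditioning for a 500 Hz target rate. Zero-phase filtering
  leaves fiducials unshifted. The 0.3 Hz highpass has poles within
  ~1e-3 of the unit circle, so double-precision filtering is linear only
  to ≈ 1e-6 relative — an arithmetic limit, not a property of the
  filter, and the linearity test asserts exactly that.
* A lead is "blank" iff its maximum absolute amplitude is below
  1e-6 mV: detects dead channels without flagging genuinely
  low-amplitude leads.
* The deep baselines (a 2-layer tanh LSTM with linear head; a committee
  of five 3-layer tanh feed-forward networks whose predictions are
  averaged) are trained by backpropagation with the Adam update on
  standardized channels, deterministic per seed, committee members
  seeded individually. They are reduced-scale comparison scaffolding:
  hidden widths default to 64 (LSTM) and 32 (FFN) so training runs in
  seconds to minutes on one CPU, and no claim is made that they match
  any published architecture's capacity.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run cohorts of 2–50 patients
(10 s records at 500 Hz, i.e. 5 000 samples × 12 leads each). These
sizes were chosen so that the closed-form properties (exactness,
min-norm recovery, masking complementarity) are tested at full strength
— they are size-independent — while the stochastic quantities (CV mean
r, delineation rates) stabilize to two to three decimals, which is the
precision at which the package makes claims about them.
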