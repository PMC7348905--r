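---
title: "Decoding sub-second timing prediction from single-trial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sub-second timing prediction from single-trial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timingbci)
```

## The decoding problem

When a subject covertly predicts *when* an event will occur — here, whether
a second flash will follow a first one after 400 ms (condition T400) or
600 ms (T600) — the anticipatory EEG carries two distinct single-trial
signatures:

* **A low-frequency ERP pattern.** After the flash-evoked N1, a contingent
  negative variation (CNV) develops: a slow negative drift over central
  electrodes. About 200 ms after the predicted moment the drift is
  terminated by a positive-going deflection, so the T400 and T600
  waveforms separate from roughly 600 ms onward. This pattern lives below
  4 Hz.
* **A high-frequency power pattern.** Power in the 20–60 Hz range (beta
  and mid-gamma) is suppressed during timing maintenance, and the
  suppression sets in earlier and more deeply when the predicted moment is
  earlier (T400 before T600).

`timingbci` decodes the two signatures with two deliberately different
classifiers and fuses them at the decision level:

1. **DCPM** (discriminative canonical pattern matching) for the ERP
   pattern, on delta-band (0–4 Hz) data in the 500–850 ms window
   (70 samples at 200 Hz).
2. **CSP** (common spatial patterns) for the power pattern, on 20–60 Hz
   data in the 100–800 ms window.
3. **Fisher-discriminant decision fusion**: each classifier's feature
   vector is projected to a scalar decision value (`F1`, `F2`) by its own
   Fisher read-out, and the trial label is `sign(F1 + F2)` — `+1` for
   T400, `-1` for T600, with exact ties resolved to `+1`.

## The DCPM model

With class templates $\hat X_k$ (the per-class trial means, channels ×
samples), DCPM builds:

* **DSP projection.** The between-class scatter
  $S_B = (\hat X_1 - \hat X_2)(\hat X_1 - \hat X_2)^\top$ and the
  within-class scatter $S_w = \sigma_1^2 + \sigma_2^2$, with
  $\sigma_k^2 = \frac1M \sum_i (X_{k,i} - \hat X_k)(X_{k,i} - \hat X_k)^\top$,
  define the generalized eigenproblem $S_w^{-1} S_B U = U \Lambda$. Because
  the templates are matrices, $S_B$ has rich rank and yields several useful
  filters; we keep the eigenvectors whose eigenvalues are at least 1% of
  the largest (capped at 10) — the reduced projection $\hat U$. $S_w$ is
  ridge-regularized by $10^{-6}\,\mathrm{tr}(S_w)/N_c$ since 18 channels
  estimated from ≤40 trials can be ill-conditioned.
* **Per-class CCA.** For class $k$, canonical projections $(P_k, Q_k)$ are
  fitted between the DSP-projected template (tiled across the class's
  training trials) and the DSP-projected training trials themselves. This
  keeps the model strictly training-only; at test time the same $Q_k$
  rotates both template and trial.
* **Pattern-matching features.** For a test trial $Y$:
  $\rho_{1k} = \mathrm{corr2}(\hat X_k^\top \hat U, Y^\top \hat U)$,
  $\rho_{2k} = \mathrm{corr2}(\hat X_k^\top \hat U Q_k, Y^\top \hat U Q_k)$,
  $\rho_{3k} = -\lVert \hat X_k^\top \hat U Q_k - Y^\top \hat U Q_k \rVert_F$,
  where corr2 is the Pearson coefficient over the flattened matrices. The
  feature vector is the class difference
  $f_1 = (\rho_{11}-\rho_{12},\, \rho_{21}-\rho_{22},\, \rho_{31}-\rho_{32})$,
  read out by a Fisher discriminant fitted on the training trials'
  features. The read-out training uses templates built from the full
  training fold (no inner cross-fitting): slightly optimistic, but stable
  at small $n$.

The reduced $\hat U$ is used in all three features; the full-rank variant
is available via `use_full_u = TRUE` for comparison.

## The CSP model

Per trial, the trace-normalized covariance $R = XX^\top/\mathrm{tr}(XX^\top)$;
per class, the mean $\bar R_k$. The composite $\bar R_1 + \bar R_2 = U\Lambda U^\top$
gives the whitening matrix $P = \Lambda^{-1/2} U^\top$ (so that
$P(\bar R_1+\bar R_2)P^\top = I$ — the identity the whole construction
relies on; a variant with exponent $-1$ is kept behind a flag for
auditability but does not whiten). Eigendecomposing
$S_1 = P\bar R_1 P^\top = B\Lambda_1 B^\top$ diagonalizes $S_2$ in the same
basis with $\Lambda_2 = I - \Lambda_1$, so the class-2 filter bank is the
class-1 bank in reverse eigenvalue order. The two leading filters of each
bank project the trial, and the features are
$c_i = \log\{v_i / \sum_j v_j\}$ over the four projected (population)
variances — scale-invariant by construction. A Fisher read-out maps the
4-vector to $F_2$.

Shrinkage of the composite covariance toward the scaled identity is applied
*only* when it is numerically rank-deficient: an unconditional ridge would
visibly break the whitening identity that we verify to $10^{-8}$ in the
tests, while a conditional one preserves both robustness and the identity.

## Cross-validation and the evaluation harness

Folds are stratified per class with seeded shuffling; the assignment
depends only on the label vector, the fold count and the seed, never on
the data, so different bands and methods can be compared on literally the
same partitions (`band_sweep()` does this explicitly). Every model
component — templates, DSP, CCA, CSP filters, both read-outs — is refitted
on each training fold; nothing crosses the fold boundary. With 35–40
trials per class folds can differ by one trial, so the mean accuracy is
weighted by fold size. `compare_methods()` evaluates DCPM, CSP and fusion
per subject on shared folds and emits the familiar per-subject accuracy
table with `Mean`/`Std` rows.

## What the synthetic generator emulates

No public recordings accompany this paradigm, so the package ships a
generator whose defaults encode the assumed data structure: 200 Hz epochs
from −500 to 2500 ms around the first flash, 21 channels (the 18 central
classification electrodes at unit spatial gain plus FP1/FP2/OZ at 0.3), a
class-independent N1 at 160 ms, a CNV of −10 µV/s from 200 ms terminated
by a 2 µV smooth positive deflection starting 200 ms after the predicted
moment (600 ms for T400, 800 ms for T600), a second-flash response at
900 ms in every condition (all analysis windows end before it, and the
tests confirm it does not leak into features), and 20–60 Hz suppression
with onset 100/220/300 ms for T400/T600/NT and depth scaled 1/0.8/0.7.

Noise is built in the frequency domain as a pink (1/f) plus white mixture
with 8 µV RMS per channel. Each draw's spectrum is split into its 20–60 Hz
component and the remainder; only the in-band component is multiplied by
the suppression gain envelope, so the planted in-band power change at a
unit-gain channel is exactly $20\log_{10}(1-d)$ dB for depth $d$ while the
out-of-band background is untouched.

Two structural choices deserve emphasis:

* **Suppression must have spatial structure.** Trace-normalized
  covariances divide out any gain common to all channels, so a spatially
  uniform power suppression is mathematically invisible to CSP. The
  generator therefore scales the suppression depth by the central spatial
  profile, concentrating it over the classification electrodes — which is
  also where the real effect is strongest.
* **Effect sizes are free parameters.** The source phenomenology is
  qualitative (no µV amplitudes are published), so the defaults were
  chosen once to place single-method cross-validated accuracies in the
  65–85% range typical of this paradigm — far from both chance and
  ceiling — and are documented here rather than treated as measured
  values. Setting `erp_amp_uv = 0` removes the entire ERP timing effect
  (the CNV then runs identically in all conditions); `supp_depth = 0`
  removes the power effect; both at zero give an exactly exchangeable
  null.

What the generator does *not* emulate: volume-conducted channel
correlations (noise is channel-independent), eye blinks and other
artifacts, line noise, button-press potentials, and any biophysical
forward model. Passing tests on this generator therefore demonstrate the
correctness and calibration of the algorithms under the assumed signal
structure, not performance on real recordings.

## Descriptive metrics

* **SNR**: $10\log_{10}\left(\overline{a}^2 / (\overline{a^2} - \overline{a}^2)\right)$
  over per-trial window amplitudes, with population (1/N) moments.
* **FDR** (Fisher discriminative ratio, not false-discovery rate):
  $(\tilde m_1 - \tilde m_2)^2 / (\tilde S_1^2 + \tilde S_2^2)$; population
  variances by default for consistency with the SNR, switchable to
  1/(N−1).
* **Fractional-area latency**: the time before which 50% of the rectified
  component area in the window has accumulated, with trapezoidal
  integration and exact interpolation inside the crossing segment.
  Rectification handles biphasic windows; signed-positive area is
  available as an option.
* **ERSP**: 7-cycle complex Morlet wavelets, trial-averaged power,
  divisive baseline (the 100 ms before the first flash) per frequency and
  channel, expressed in dB, then averaged over channels. Frequencies whose
  wavelet support exceeds the epoch raise an error; values within half a
  support of the epoch edges are distorted and analysis windows should
  avoid them.

## Numerical conventions

* Time: 0 ms = first-flash onset; sample $i$ (1-based) of an epoch lies at
  $t_0 + 1000 (i-1)/f_s$ ms; windows are half-open $[a, b)$, which makes
  "500–850 ms at 200 Hz" exactly 70 samples and makes adjacent windows
  tile. After `select_epochs()` the new `t0_ms` is the time of the first
  retained sample (identical to the window start whenever the start lies
  on the sample grid).
* Labels: `+1` = T400, `-1` = T600, `0` = NT (metrics only); decision
  values map to labels by sign with ties to `+1`.
* Filters: Butterworth order 4 applied forward–backward (zero phase,
  effective order 8), after odd-reflection padding of at least 0.5 s. The
  delta band "0–4 Hz" is a 4 Hz low-pass; DC is handled by baseline
  correction rather than a high-pass edge.
* Eigenvector sign convention everywhere: the largest-magnitude entry is
  made positive, so fitted models are reproducible across linear-algebra
  backends.
* Bundles store the payload as little-endian float32 (adequate for µV EEG,
  and byte-reproducible); metadata travels as JSON.

## Problem sizes used by the test-suite

The packaged tests exercise the full pipeline on generated data: 40 trials
per class and 21 channels for calibration checks (20 independent seeds for
the null-calibration and band-ordering properties), an 18-subject cohort
for the fusion comparison, and smaller 20-trial subjects for unit-level
checks. These sizes mirror the paradigm's own design (35–40 retained
trials per condition, 18 subjects) while keeping a full run lightweight.

## Known limitations

* Two-class only; the no-timing condition participates in metrics but not
  in classification.
* CSP windows are used at full resolution (140 samples for 100–800 ms at
  200 Hz); no additional decimation is applied inside the classifier.
* The DCPM read-out's training features are computed against templates
  from the same training fold, a mildly optimistic convention chosen for
  small-sample stability; the cross-validated accuracies it reports remain
  honest because test folds never contribute to any component.
* Rational (non-integer) resampling is not implemented; `downsample()`
  requires an integer decimation factor.
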