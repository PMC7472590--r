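---
title: "Stopping-time delineation of ECG waveforms and STEMI screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stopping-time delineation of ECG waveforms and STEMI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stecg)
```

## The problem

ST-elevation myocardial infarction (STEMI) is read off a 12-lead ECG as an
amplitude difference: the J point (the junction between the QRS complex and
the ST segment) rising above the isoelectric baseline beyond a lead-, sex-
and age-specific threshold. Automating that reading requires delineating
each heartbeat — R peak, S point, J point, T wave — and estimating the
baseline level, on signals that wander, carry muscle noise, and are
sometimes wholly inverted (lead avR, reversed electrodes, or
infarction-related repolarization changes). A positive STEMI call in leads
II, III and avF together additionally raises the possibility of
right-ventricle infarction, which contraindicates nitroglycerin.

`stecg` implements a delineation scheme built from *stopping times*: each
landmark is the first index at which a windowed objective over the amplitude
sequence attains its maximum. The objectives are deterministic, so every
decision can be audited; around them sits a light value-bookkeeping
formalism (action values, softmax policies, updated state values) that
carries amplitudes and differences between stages and supplies the
arbitration machinery for the waveform-direction decision.

## The downhill U-turn score

All post-R landmarks derive from one primitive. For a forward search from an
anchor $a$ with range $R$,

$$\mathrm{score}(i) \;=\; \sum_{j=0}^{R}\bigl[d(a+i) - d(a+i+R+j)\bigr],
\qquad i = 0,\dots,R,$$

and the stopping time is $\omega = a + \arg\max_i \mathrm{score}(i)$ (ties
to the smallest $i$; backward searches negate every offset). The score
contrasts a sample against a trailing window of equal length, so it is
maximized where a descending trajectory is about to turn upward — hence
"downhill U-turn". Because the score looks ahead two ranges, the stages
that target the turn itself (J point, T end, and the two backward baseline
searches) displace the stopping time by half the range. The cumulative form
makes the decision robust to locally extreme slopes that would trap a
greedy gradient rule.

Out-of-record indices are clipped to the borders and the result is flagged
truncated; 10-s records routinely end mid-beat.

### Indexing convention

Every index the package exposes is a **0-based sample index** (time =
index / fs). This keeps the window arithmetic exactly as the score formulas
read; the R-internal one-based access is confined to a single helper.

## The annotation cascade

1. **QRS peaks.** The record is cut into consecutive 300-sample subsets
   (one subset holds at most one QRS at 500 Hz). Per subset the stopping
   time is the argmax of the neighboring-sample slope (interval 2 samples),
   taken over rising slopes only; the candidate is then refined to the
   amplitude maximum over the 600 surrounding samples. The stage runs
   twice — second-pass windows anchor on first-pass peaks, which makes the
   result translation-equivariant — and peaks closer than 300 samples merge,
   keeping the larger amplitude.
2. **Minimum after R.** Argmin over the 50 samples on each side of the R
   peak.
3. **S point.** A forward U-turn from the QRS slope point with range 24
   (two 25-term windows over 50 samples) gives the QRS downhill point; the
   *temporarily lower point* is whichever of it and the minimum-after-R
   carries the lower updated value; a ±150-sample search around it for the
   amplitude closest to its own then fixes the S point. The two candidate
   slopes from the R peak and from the downhill point to the temporarily
   lower point decide which anchor the S point pairs with.
4. **J point.** Forward U-turn from the S point with range
   $1.5\times$ the record's mean R-to-S interval, plus half the range.
   The resulting index deliberately sits at the ST-deviation measurement
   range past the anatomical QRS end — elevation is read there clinically,
   and the synthetic ground truth marks the same anchor (QRS end + 0.04 s).
5. **T wave.** The T peak is the amplitude argmax over a window after the J
   point whose length is the record mean of $300 + \omega_{QRS} - \omega_S$
   minus 50; the T-end U-turn repeats the forward search with the
   $1.5\times$ interval range clamped into $[25, 100]$ samples for
   stability across heart rates.

The record's mean R-to-S interval is recomputed per record and taken as a
magnitude; on heavily distorted signals a signed mean can become negative,
which would invalidate every later window.

## Baseline approximation and ST evaluation

Two backward U-turns before the QRS locate a representative point on the PR
segment: first from the QRS slope point with the clamped T-stage range, then
from that point with the mean R-to-S interval as range, each displaced
backward by half its range. A 21-weight sweep ($w = 0.1, \dots, 2.1$)
follows: the weighted last amplitude of the baseline interval is fed
through a sigmoid, a squared-difference loss against the representative
amplitude is evaluated, and the weight with the smallest absolute
finite-difference loss gradient is kept (ties to the smaller weight). As
printed, the weighted form cancels its amplitude ($w/1.1$), so the
adjustment contributes at most half a count; it is retained for
auditability and the cancellation is documented rather than "fixed".

Elevation is the J-point amplitude minus the adjusted baseline amplitude,
in ADC counts with a linear calibration of 17 counts per 0.10 mV
(configurable). Thresholds: 0.25 mV for V2/V3 in males under 40, 0.20 mV
for V2/V3 in males 40 and over, 0.15 mV for V2/V3 in females, 0.10 mV
elsewhere; unknown sex or age on V2/V3 falls back to the largest applicable
threshold and is flagged — a deliberate bias toward specificity that is
surfaced in the report rather than hidden. A beat is STEMI-positive when
elevation *strictly* exceeds the threshold; the record is MI when the
flagged fraction strictly exceeds 39.9999 %. A single representative beat
therefore yields a ratio of exactly 0 or 1. MI in II, III and avF together
raises the RV-infarction flag (indeterminate — never silently false — when
a lead is missing).

## Waveform direction

Two independent stages decide whether the record is inverted.

**Least-first-power stage.** Per beat, the segment from the J point across
the T search window is summarized by its standard deviation about the
J amplitude $p$, signed so that a segment lying above $p$ (an upright T)
gives $\beta < 0$: the side point $p - \beta$ then falls closer to the
first T-peak amplitude than $p + \beta$, and the direction is upward.
The segment spans the full T search range rather than stopping at the
T-peak argmax — an amplitude argmax can never fall below $p$, so a
peak-bounded segment would be structurally blind to inverted T waves.
A flat segment ties to upward and is flagged low-confidence.

**Approximate-entropy stage.** Per beat, two slope sets are taken over
windows of twice the mean R-to-minimum interval: the descent after the R
peak (entering with signs, so their negated mean is a positive magnitude)
and the ascent after the minimum. Each yields a reward
$(\mathrm{slope}_{\max} + \mathrm{avg}(-\mathrm{slope}))/2$ with the shared
absolute-maximum slope, and an approximate-entropy next state
$\log(c)/\tfrac{R}{2}$ where $c$ counts slope magnitudes strictly below
that maximum (a zero count guards to 0). The coefficient $\gamma$ is
searched over $\{0, 0.5, \dots, 2.5\}$ by minimizing the product of the
pairwise softmax outputs — steering away from a $\gamma$ at which one
abruptly large action value dominates — and the softmax temperature
$\alpha$ over $\{0.5, \dots, 100.5\}$ by the first updated value to exceed
the smaller action value (0, treated as policy 1, when none does). A third
state counts, across beats, appearances of longer intervals before and
after the T wave ($\gamma = 10$, policy floored at $10^{-4}$, $\alpha = 1$);
its updated value adds to the per-beat value and the record value is the
per-beat sum. The record and its amplitude-inverted, re-annotated copy are
both evaluated; the higher value wins. The wiring of the third state is
prose-level in its source and is recorded here as this package's reading:
the two increment counters are the third-state rewards, the two
approximate-entropy values are its next states, and the first-state value
is the second-state reward.

**Arbitration.** Agreement passes through. On conflict, each stage's
contrast ratio $|sv_{non} - sv_{inv}| / \max(sv) \times 100$ decides, the
larger ratio winning. Finally a STEMI beat ratio above 20.0 % overrides to
non-inversed: elevation itself builds an upright impulsive wave from the S
point to the T peak, which is exactly the situation in which the
direction stages are least trustworthy.

## Data input

The noise-compensation loop shrinks a multiplier (start 3.0, step 0.1,
floor 0.1) on the mean absolute amplitude until fewer than 3000 samples lie
below the bound, then clips samples at or above it, preserving the sample
grid — clipping, never deletion, because every later stage addresses
absolute indices. Applied literally to a clean record, the count criterion
only triggers once the bound has fallen into the physiologic range, and
committing the clip would flatten the QRS. The pipeline therefore commits
clipping only when at most 5 % of samples are affected (sparse
large-oscillation artifacts, the situation the rule is for); otherwise the
record passes through unchanged with the diagnostics still reported. The
literal behavior remains available (`maxClipFrac = 1`) and unit-tested.
The nonnegative shift (add $|\min|$ when the minimum is negative) runs
afterward and is idempotent.

## The synthetic generator

`synthConfig()`/`generateRecord()` build records from compact-support
raised-cosine kernels on an explicitly flat baseline: P (20 counts, center
R−110), R (170 counts ≈ 1.0 mV, half-width 25), S (depth 25, center R+20),
T (51 counts ≈ 0.3 mV, center R+150), QRS end at R+33, at 500 Hz with 10
beats at 60 bpm by default — about 5000 samples per record, the duration
the method is designed around. Compact support keeps the ground-truth J
amplitude exactly `base + stOffset`: the injected ST plateau is exactly
`stOffset` at the truth J index (QRS end + 0.04 s, the ST measurement
anchor). Ground-truth S and T indices are the extrema of the noiseless
waveform, since kernel superposition shifts them off the kernel centers.
Inversion reflects the pre-noise train about the baseline; wander (sinusoid)
and white muscle noise are added last, under a locally scoped RNG stream so
the generator never perturbs the caller's seed.

Cohorts (`generateCohort()`) vary heart rate over 55–75 bpm and use mild
noise (sd 2 counts) and wander (5 counts at 0.3 Hz) — a monitored but
non-ideal strip; positives inject at least threshold + 10 counts of
elevation, negatives at most threshold − 10. What the generator does *not*
emulate: vectorcardiographic 12-lead projection, rhythm disturbances,
variable beat morphology within a record, and electrode artifacts beyond
white noise and sinusoidal wander. Passing tests therefore demonstrate that
the decision logic is implemented faithfully and behaves correctly on
signals matching its design assumptions — not clinical performance on
hospital data.

## Numerical choices

* Ties in every argmax/argmin break toward the smallest index; the
  $\gamma$ and weight grids tie toward the smaller grid value; the
  $\alpha$ search is first-hit so ties cannot arise.
* Softmax policies are computed with max-subtraction; amplitude-scale
  action values at small $\alpha$ overflow naive exponentials.
* "Exceeds" is strict everywhere (elevation vs threshold, 39.9999 % rule,
  20.0 % override, $v' > Q$ in the $\alpha$ search).
* Degenerate inputs: all-zero records pass preprocessing unchanged; a flat
  record yields an empty peak list; zero-width slope denominators discard
  that candidate; direction ties default to non-inversed and are flagged.
* Problem sizes in the tests and the acceptance script — 1000 random arrays
  for the stopping-time oracles, 100 records for landmark recovery, 100+100
  cohorts for STEMI and inversion — are the package's chosen verification
  scale; each runs in well under two minutes on one core.

## Worked example

```{r example}
g <- generateRecord(synthConfig(seed = 7, stOffset = 30, noiseSd = 2))
report <- runPipeline(g$record)
report
head(beatTable(annotateBeats(g$record))[, c("r_peak_idx", "omega_s",
                                            "omega_j", "omega_tmax")])
```

## Known limitations

* The delineator assumes an R-dominant upright QRS for its primary
  annotation; on inverted records the landmarks are surrogates anchored on
  the most prominent upright deflection, sufficient for the direction
  decision but not for clinical delineation of inverted beats.
* The baseline weight adjustment is near-vacuous by construction (the
  printed weighted form cancels its amplitude); it is kept for fidelity
  and auditability.
* P-wave delineation, ST-depression grading and reciprocal-change scoring
  are out of scope.
* Threshold calibration (17 counts per 0.10 mV) is linear and
  configurable; acquisition chains with nonlinear gain need their own
  constant.
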