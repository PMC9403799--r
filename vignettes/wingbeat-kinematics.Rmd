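---
title: "Wingbeat kinematics from body-mounted biologgers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wingbeat kinematics from body-mounted biologgers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeatr)
```

## The scientific problem

The mechanical power of flapping flight is governed by two kinematic
parameters: wingbeat frequency $f$ and wingbeat amplitude $A$. Because the
aerodynamic forces on a wing section scale with the square of the local flow
speed, and power with its cube, power scales as

$$P \propto A^3 f^3,$$

so a body-mounted accelerometer — which senses the body's reaction to the
flapping wings — can in principle track both parameters. In practice three
questions arise: does the dorsoventral ("heave") acceleration amplitude
actually track wing amplitude; can individual wingbeats be segmented reliably
from tag data sampled at 40–180 Hz; and do birds modulate frequency or
amplitude when flight demands change (climbing, speeding up), possibly as a
function of morphology (wing loading)?

`wingbeatr` implements this analysis chain as a tested pipeline. Because
per-bird field recordings are rarely shareable, the package includes a
forward simulator that generates every sensor stream from known kinematics,
so each downstream stage can be validated against ground truth.

## The forward model

### Wing motion

Wing elevation is modelled on the cycle phase $u \in [0, 1)$: a half-cosine
downstroke from $+A/2$ to $-A/2$ over $u \in [0, d)$ and a half-cosine
upstroke back over $u \in [d, 1)$, where $d$ is the downstroke fraction. The
phase advances at the instantaneous wingbeat frequency (constant, linear
ramp, or an arbitrary function of time) and pauses during glide bouts.

Two conventions are worth stating explicitly:

* **Downstroke fraction defaults to 0.5.** Stroke asymmetry in cruising
  flight is rarely quantified; the symmetric default makes the heave waveform
  exactly sinusoidal, which is also the least structured assumption for
  detector validation. Asymmetric strokes (`downstroke_fraction != 0.5`) are
  fully supported and tested.
* **Glides begin at the end of the stroke in progress.** A glide bout
  configured as `c(start, end)` takes effect at the next cycle boundary,
  where the wing's angular velocity is zero. This keeps the heave signal
  smooth across glide boundaries (a bird does not freeze its wing
  mid-stroke) and lets the ground-truth cycle table tile the flapping bouts
  exactly.

### Body reaction (heave)

The dynamic heave component is modelled as proportional to the downward wing
angular velocity, with a single calibration gain:

$$a_z(t) = 1\,\mathrm{g} - k\,\dot\theta(t) + \varepsilon(t),
\qquad \varepsilon \sim N(0, \sigma^2)\ \text{i.i.d.}$$

This is a linearized quasi-steady lift response: at cruising airspeed the
oscillatory lift on the wing is dominated by the term linear in the flapping
velocity, and lift peaks where the wing traverses the body at maximal speed.
The model reproduces the phase relations observed with synchronized video
and wing-mounted magnets: the heave maximum falls exactly at the downstroke
midpoint, and the peak-to-peak heave grows linearly with both $A$ and $f$
(for symmetric strokes, $\Delta a_z = k \cdot (A/2) \cdot 2\pi f$ with $A$ in
radians).

A model with heave proportional to wing angular *acceleration* was
considered and rejected: for any stroke whose angular speed peaks mid-stroke
the angular acceleration is zero there, so such a model necessarily puts
heave extrema at the stroke reversals, contradicting the observed mid-
downstroke heave peak. The default gain `heave_gain = 0.04` g/(rad/s) yields
a peak-to-peak heave of about 2 g at the default kinematics (5 Hz, 90
degrees peak-to-peak), the signal size typical of back-mounted tags on
mid-sized birds. No aerodynamic force model is attempted; the simulator's
purpose is kinematic ground truth, not aerodynamics.

### Magnetometer with a wing-mounted magnet

A small magnet on the leading edge of the wing modulates the field at a
back-mounted magnetometer as the wing moves. The sensed field is

$$\mathbf{B}(t) = \mathbf{E} + \frac{m}{r(t)^3}\,\hat{\mathbf{e}},$$

with $\mathbf{E}$ the constant geomagnetic vector, $m$ the magnet moment and
$r(t)$ the magnet–sensor distance, mapped linearly from the wing elevation
over its anatomical range ($+90^\circ \to$ minimum distance, $-90^\circ \to$
maximum). Only the inverse-cube magnitude law and the monotone
elevation-to-distance map matter for the analysis; the true field geometry
of a taped-on magnet is not modelled. The per-sample Euclidean norm of the
three channels (the "vector sum") is then a pure function of wing elevation:
it peaks at the start of the downstroke and bottoms out at its end, and its
per-cycle maximum increases monotonically with true wing amplitude — the
property that makes it an amplitude proxy. The dipole direction must not
oppose $\mathbf{E}$ (enforced at configuration time) or the vector sum would
not be monotone in the dipole term.

### Track, pressure, wind

The track is a sequence of constant-groundspeed, constant-climb-rate
segments. Barometric pressure follows the standard-atmosphere (ISA
troposphere) formula; the same closed form is used in both directions
(simulation and altitude retrieval), so the round trip is exact. Wind is
constant per record. Sensor streams are sampled at their own rates, with an
optional true-rate offset of a few Hz relative to nominal (a known artefact
of commercial loggers) and optional timestamp jitter.

## Wingbeat detection

Detection follows the second-derivative turning-point algorithm used for
field data:

1. smooth the raw heave with a centered moving average (`smooth_signal`;
   window truncated at the edges, window 1 = no smoothing);
2. mark positive-to-negative turning points of the first difference
   (plateaus take the sign of the next nonzero difference);
3. accept a turning point when $|\Delta^2 a_z|$ exceeds a threshold within
   `search_radius` samples; resolve accepted peaks closer together than
   `min_separation` samples to the larger heave value;
4. segment cycles between consecutive peaks, with frequency computed from
   actual timestamps (robust to nominal-rate error);
5. compute per-cycle heave amplitude as max − min of the *raw* heave over
   the half-open cycle window (the raw signal preserves amplitude; the
   smoothed one attenuates it);
6. drop cycles with implausible frequencies (default band: 0.5–2 times the
   bout median) and average the survivors over fixed blocks of
   `block_size` cycles (10 for field-style data, 5 for short bouts).

### Numerical choices

* **Threshold automation.** Field practice selects the derivative threshold
  manually per bout. The automated default (`auto_threshold`) is the 0.90
  quantile of $|\Delta^2 a_z|$, a scale-equivariant, deterministic rule that
  suits recordings where flapping is a minority of samples. Within a pure
  flapping bout, however, the $|\Delta^2|$ distribution of a near-sinusoidal
  signal is arcsine-like — concentrated near its maximum — and a 0.90
  quantile can sit above what a true peak attains at an unlucky sampling
  offset; under strong noise the 0.90 quantile is noise-dominated instead.
  `suggest_detection_params()` therefore uses the bout median.
* **Windows matched to the cycle.** A smoothing window of about one third of
  the expected period attenuates the wingbeat by under ~20% while averaging
  noise; signals with fewer than ~8 samples per cycle are left unsmoothed
  (high-frequency species produce clean signals at these rates). The minimum
  peak separation is 60% of the expected period — the same idea as the
  plausible-frequency band, applied at the sample level.
* **Tie-breaks.** Two accepted candidates closer than the separation radius
  resolve to the larger (smoothed) heave value, deterministically.
* **Cycle convention.** Cycles are half-open peak-to-peak intervals
  $[p_i, p_{i+1})$; a flapping bout with $n$ detected peaks therefore yields
  $n - 1$ cycles. Round-trip tests assert peak count = true cycle count and
  cycle count = true count minus the number of bouts.
* **Frequency estimators.** Per-cycle frequency is $1/\text{period}$; block
  means of it feed the statistical layer. For bout-level summaries,
  `summary.wingbeats` also reports cycles per unit flapping time, which is
  immune to the small upward Jensen bias that the arithmetic mean of
  $1/\text{period}$ acquires when peak times are quantized to very few
  samples per cycle (visible only near ~3 samples/cycle).
* **Undersampled magnetometers.** Magnetometer samples are assigned to
  cycles by timestamp membership; no interpolation is performed. A cycle
  without a magnetometer sample gets `NA` and is excluded from proxy fits.

## Flight state

Altitude comes from the ISA inversion of barometric pressure (reference
pressure adjustable to the daily sea-level value); climb rate $V_z$ is the
first difference of altitude smoothed over a centered 2-s window; airspeed
is the horizontal wind-triangle magnitude $|\mathbf{v}_g - \mathbf{v}_w|$.
Flight-state values are joined onto kinematic intervals by time-weighted
means over the interval span.

Filter semantics follow the field definitions exactly and are
boundary-tested: level flight is the strict open interval
$-0.2 < V_z < 0.2$ m/s; an interval qualifies when at least 80% of its span
is level flapping flight (inclusive); the airspeed window retains values
within the overall mean ± 1 sample (n−1) standard deviation, inclusive on
both edges.

## Statistical layer

* `fit_amplitude_frequency()`: OLS of heave amplitude on wingbeat frequency
  per dataset, with two-sided slope p-value — the cross-species summary
  table layout (mean ± sd amplitude and frequency, slope, intercept, p,
  $R^2$, total wingbeats) is emitted per species by `run_pipeline()`.
* `fit_lmm_interaction()`: amplitude ~ WBF + WBF:$V_z$ (or WBF:airspeed)
  with a random intercept per individual and a continuous-time AR(1)
  (`corCAR1`) residual correlation indexed by interval start time, fitted by
  REML via `nlme`. A positive interaction indicates amplitude is modulated
  more than frequency as the covariate rises. Marginal and conditional
  $R^2$ use the variance-partition formula
  ($R^2_m = \sigma_f^2 / (\sigma_f^2 + \sigma_u^2 + \sigma_e^2)$, $R^2_c$
  adds $\sigma_u^2$ to the numerator), so $R^2_m \le R^2_c$ always, with
  equality at zero random-effect variance. An exactly collinear response
  (zero residual variance) is a degenerate case: the fit falls back to OLS
  with zero variance components and is flagged, rather than failing inside
  the optimizer. Near-zero estimated random-intercept variance is reported
  with a warning, not silently accepted.
* `species_cv()` and `correlate_cv_morphology()`: the coefficient of
  variation of wingbeat frequency, pooled across individuals of a species
  (per-interval means by default; per-cycle pooling is available by passing
  cycle-level frequencies), correlated with mass, wingspan or residual wing
  loading (Pearson, two-sided). Wing loading is mass per wing area; the
  residual is taken from the log–log OLS of wing loading on mass and is
  invariant to unit changes (property-tested), so the unit convention is
  irrelevant.
* `power_proxy()`: $(A f)^3$, for relative comparisons only.
* p-values are two-sided Wald t throughout; no multiple-testing correction
  is applied.

### The bundled species tables and the CV analysis

`morphometrics_table()` (14 species: mass, wingspan, wing area) and
`kinematics_summary_table()` (per-species mean ± sd of amplitude and
frequency, regression summaries, total wingbeats; wild and wind-tunnel
rows) ship with the package. `cv_wing_loading_correlation()` reconstructs
the species-level analysis from them: CVs from the summary columns (wild
datasets plus the wind-tunnel dunlin, which has no wild dataset) against
residual wing loading. The pigeon has both a wild and a wind-tunnel
dataset; the wild one is used by default, matching how the original
analysis was described.

This reconstruction has a sharp caveat, verified quantitatively in the
package's tests: the published coefficient was computed from per-bird data,
while the summary columns are rounded to one decimal. A frequency sd of
"0.5" at a mean of "5.2" pins the species CV only to within ~10%, and
propagating the rounding envelope through the correlation moves $\rho$ over
a range of order ±0.2 — the pigeon row alone moves it by ~0.15 (the
wind-tunnel pigeon row gives $\rho \approx -0.465$, the wild row
$\rho \approx -0.316$, with the published value in between). The
reconstruction therefore reproduces the analysis and its qualitative
conclusion (a negative, non-significant correlation: birds with high
residual wing loading vary frequency less), not the third decimal of the
published statistic. Both pigeon variants are exposed
(`pigeon = "wild"` / `"wind_tunnel"`) and both are reported by the
acceptance script.

## What the simulator does and does not emulate

Emulated: flapping bouts with known per-cycle frequency and amplitude
(constant, ramped or arbitrary profiles), glide gaps, climb/level/descent
track segments, multi-rate sampling with nominal-rate error and timestamp
jitter, i.i.d. Gaussian sensor noise per channel, the magnet-on-wing
magnetometer signal, barometric pressure and constant wind.

Not emulated: aerodynamic forces and body-pitch dynamics, centripetal
accelerations of turning or dynamic-soaring flight (which blur wingbeat
peaks in real albatross data), 1/f sensor noise and temperature drift,
GPS error, spatially varying wind, and behavioural correlations between
kinematics and flight state other than the configurable amplitude–climb
coupling in `run_pipeline()`. Passing tests therefore demonstrate
correctness of the algorithms under the stated signal model, not detector
performance on every real-world recording.

## Problem sizes and reproducibility

The test-suite simulations use 10–60 s bouts at 40–200 Hz (a few thousand
cycles overall), and the mixed-model recovery study uses 100 replicates of
10 individuals × 200 intervals — sizes at which every check runs in minutes
on a laptop while keeping Monte Carlo error well below the asserted
tolerances. All randomness flows from explicit seeds: identical
configuration plus seed reproduces every trace, table and model fit
bit-for-bit.

## Known limitations

* The detector assumes one dominant heave peak per wingbeat; strongly
  multi-peaked waveforms (e.g. pronounced wing-tip reversal spikes) would
  need a stricter separation radius or per-species tuning, as in field
  practice.
* The CAR1 mixed model assumes stationary within-individual autocorrelation;
  regime switching (e.g. alternating flap–glide cycles) is not modelled.
* Residual wing loading is fitted across whatever species set is supplied;
  with few species the residuals are sensitive to influential points, which
  is intrinsic to the analysis, not to the implementation.
* Absolute altitudes depend on the atmosphere model and the reference
  pressure; climb rates, being differences, are insensitive to both.
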