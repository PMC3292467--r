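---
title: "Methods: kinetic, fractal and statistical analysis of dynamic small-animal PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic, fractal and statistical analysis of dynamic small-animal PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

petkin analyses dynamic PET studies of the kind used to compare two
receptor tracers in small groups of tumor-bearing animals: a 60-minute
acquisition on a 28-frame schedule (ten 30 s, five 60 s, five 120 s and
eight 300 s frames), an image-derived blood input function from a heart
VOI, and one tumor TAC per animal. This vignette documents the model,
the conventions the package had to fix where the underlying methods
leave them open, the synthetic-data design, and what the test suite does
and does not establish.

## The kinetic model

The reversible two-tissue compartment model describes free (`C1`) and
bound/internalised (`C2`) tracer:

$$\dot C_1 = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2,\qquad
  \dot C_2 = k_3 C_1 - k_4 C_2,$$

with the measured VOI signal
$C_{PET}(t) = (1 - V_B)\,(C_1 + C_2)(t) + V_B\,C_p(t)$. For receptor
peptides the conventional reading is K1 receptor binding, k2
displacement, k3 internalisation, k4 externalisation; `VB` is the
fractional blood volume ("vessel density"). All rates are in 1/min;
time is handled in minutes internally and in seconds in all files.

The impulse response has the closed form implemented in
`impulse_response()`; both eigenvalue rates are nonnegative for any
nonnegative rate constants, so the response is a sum of two decaying
exponentials with $h(0) = K_1$. Numerical conventions:

* **Confluent eigenvalues.** When $\alpha_2 - \alpha_1 <
  10^{-9}(\alpha_1+\alpha_2)$ (plus an additive floor so all-zero rates
  qualify) the limit form $K_1 e^{-\alpha t}(1 + (k_3+k_4-\alpha)t)$ is
  used, keeping the response continuous in the parameters.
* **Analytic convolution.** With the input modelled as exponentials, the
  convolution is expanded term-by-term into exponential basis functions;
  `simulate_tac()` integrates these in closed form over every frame and
  reports frame *means*, never midpoint samples. In the forward
  simulation, near-confluent eigenvalues are nudged apart by a relative
  $10^{-7}$ instead of adding a confluent integration branch; the induced
  error is $O(10^{-7} t^2)$, far below the 0.1% tolerance at which the
  simulator is verified against an independent RK4/quadrature oracle.
* **Colliding rates.** If an input decay rate coincides with an
  eigenvalue, the $s\,e^{-\alpha s}$ term is integrated with a
  cancellation-safe routine (series expansion for small exponents).

### Estimation

The original analysis used a proprietary machine-learning fitter; petkin
replaces it with bounded multi-start weighted nonlinear least squares,
which is reproducible from first principles. The objective is the
frame-duration-weighted residual sum of squares between the
frame-averaged model and the data (longer frames carry proportionally
more weight because their values are less noisy), normalised by the data
scale. Parameters are bounded in $[0,1)^4 \times (0,1)$, matching the
published plausibility rule that a fit is accepted when every rate is
below 1/min and `VB` is positive; `fit_2tcm()` reports that flag rather
than silently discarding animals.

Starting points come from a deterministic Halton sequence (32 by
default), log-spaced over the rate box. All starts are screened by
objective value, the best 10 are polished with L-BFGS-B, and the winner
is refined at tight tolerance. Screening-then-polishing is an efficiency
choice, not a statistical one: the search space and the
best-converged-minimum semantics are those of plain multi-start, and
noiseless round trips recover all five parameters to better than 0.5%.
An optional seed applies a random shift to the Halton points; the
default is fully deterministic.

### Macro-parameters

The influx (trapping) rate is $K_i = K_1 k_3 / (k_2 + k_3)$. The
"receptor binding potential" reported alongside the rate constants in
this literature is not given a formula in the source material; petkin
adopts $RBP := K_i$. The numerical case: the published group-mean rates
reproduce the published group-mean RBP within 2.4% under this reading
(B: 0.0760 computed vs 0.0765 printed; R: 0.0464 vs 0.0453), while the
classical binding ratio $k_3/k_4$ is off by a factor of ~20. The
classical ratio remains available as `bp_alt`. Exact equality is not
expected — a mean of per-animal ratios is not the ratio of means — and
the acceptance suite checks the 5% consistency band, not equality.

## Input-function model

The blood curve is fitted by 1–3 decaying exponentials
(`fit_input_exponentials()`). Conventions chosen where the tooling being
emulated is silent:

* **Window.** The fit starts at the peak frame (frame of maximum value);
  a rise phase is not modelled. Pre-peak frames are preserved: the
  returned object linearly interpolates the measured pre-peak values
  when evaluated there.
* **Frame-mean fitting.** The model prediction for a frame is the
  analytic mean of $C_p$ over the frame, not a midpoint sample. With
  300 s frames and slow rates the midpoint bias would be ~1%, which
  would defeat sub-percent round-trip recovery.
* **Estimation.** Variable projection: for fixed rates the amplitudes
  solve a nonnegative weighted linear least-squares problem, so the
  nonlinear search runs only over the 1–3 rates (multi-start over
  geometric ladders anchored at the tail slope, L-BFGS-B, rates bounded
  at 0 so the fitted curve never grows; a clamped rate on non-decaying
  data raises a warning).
* **Order selection.** Small-sample AIC (AICc) with duration weights; an
  extra term is kept only when it strictly lowers AICc, so ties resolve
  toward fewer terms. A floor on the weighted RSS (`1e-12` of the data
  scale) keeps the criterion finite on noiseless data and prevents
  overfitting a perfect fit with redundant terms.

## Quantification and partial-volume correction

`SUV = concentration × weight / dose`. The late SUV is the
duration-weighted mean of frames fully inside 3300–3600 s — on the
28-frame schedule exactly the final 300 s frame, which reconciles the
"55 to 60 min" and "56 to 60 min" phrasings that both denote that frame.

Recovery coefficients are anchored at phantom measurements
(0.32 at 3 mm, 0.85 at 8 mm) and interpolated linearly; outside the
anchors they are extrapolated linearly, capped at 1 (a large object
recovers everything) and floored at 0.01 (with a warning, since a
correction factor of 100 is no longer physical). Correction is division
of the VOI value by the coefficient, applied to both the tumor and the
blood curve before any model fitting, each with its own configured
diameter (defaults: tumor 8 mm, heart 10 mm — the latter extrapolates
above the 8 mm anchor and caps at RC = 1).

## Fractal dimension

The heterogeneity index is the box-counting dimension of the time–SUV
curve: time normalised to [0, 1] over the schedule span, SUV divided by
a fixed ceiling of 20 (values above are clipped, not rejected), the
piecewise-linear curve through the frame midpoints rasterised at step
$1/(10g)$ and counted on $g \times g$ grids for $g = 1..7$; the
dimension is the least-squares slope of $\ln N(g)$ vs $\ln g$, clipped
to [0, 2].

Two conventions fixed here: the "7 × 7 subdivision" is read as grid
levels $g = 1..7$, and the *curve*, not the 28 isolated frame points, is
counted — 28 points would saturate at 28 boxes and bias the slope low.
Under these conventions a smooth shallow uptake curve (the realistic
case: SUV ≪ 20, so the normalised curve is nearly horizontal) gives
values near 1, consistent with the published group medians of ~1.0–1.14,
and an exactly diagonal curve gives 1. A full-range straight ramp
sampled at only 28 frames overshoots to ~1.3 (the $g=1$ anchor plus the
$\approx 2g$ crossed cells tilt the log–log slope); densely sampled it
is 1 within 10%. The bounds 0 and 2 are attained by a single point and
approached by space-filling noise respectively.

## Statistics

**Rank-sum convention.** The two-sided Wilcoxon rank-sum test uses the
normal approximation with *no* continuity correction and *no* tie
correction by default: $W$ is the rank sum of the smaller group,
$z = (W - m(N+1)/2)/\sqrt{mn(N+1)/12}$, $p = 2\Phi(-|z|)$. At group
sizes 4 and 5 this exactly reproduces all four distinct p-values the
reference analysis prints (0.0275, 0.05, 0.4624, 0.8065), which
identifies the convention of the original software; both corrections are
available as flags. The exact variant enumerates all
$\binom{m+n}{m}$ assignments and returns the symmetric tail mass
$P(|W - E W| \ge |w_{obs} - E W|)$ — one of several defensible two-sided
conventions, chosen because it makes the complete-separation case
$2/126$ rather than $1/126$.

A caveat the test suite documents deliberately: the uncorrected normal
approximation and the exact tail mass do *not* agree to 0.02 across the
$|z| < 1$ region at these sample sizes — enumeration shows differences
up to 0.106 (e.g. $W = 18$: exact 0.7302 vs normal 0.6242), because the
approximation excludes the observed point mass that the exact tail
includes. The acceptance test asserting the 0.02 band is kept at its
stated bound and fails honestly; the agreement that *does* hold is in
the far tails, which is where the published significance calls live.

**SVM-RFE.** Features are z-scored, a soft-margin linear classifier is
trained (L2-regularised *squared* hinge loss, C = 1 — smooth and convex,
so deterministic BFGS from zero suffices without a QP solver), and the
feature with the smallest squared weight is eliminated each round; the
ranking is the reverse elimination order. The reference analysis reports
no numeric SVM output, so this is a fidelity feature with
property-level tests (symmetry for duplicated features, recovery of a
separating feature) rather than an acceptance surface.

## Synthetic cohorts: the stated world

`generate_cohort()` emulates the study the analysis assumes:

* **Group structure.** B: n = 5, R: n = 4. Kinetic parameters are drawn
  log-normally (median-preserving) around the published group medians
  with relative SDs equal to the published SD/mean per group; draws
  violating the acceptance box are resampled (at most 100 times, then a
  typed error).
* **Doses and weights.** Uniform within the study protocol: 20–40 MBq
  (B), 10–30 MBq (R); body weight 250–350 g, a typical adult nude-rat
  range.
* **Blood curve.** Three decaying exponentials with rates (6, 0.4,
  0.02)/min and amplitude proportions 12 : 2.5 : 0.9 — a fast
  distribution phase, intermediate clearance and a slow terminal phase,
  with the peak at t = 0 since only decaying terms are modelled. The
  per-group amplitude scales (2.394891 for B, 1.454849 for R) were
  calibrated once, before any acceptance measurement, so that a tumor
  curve simulated from each group's median parameters lands exactly on
  that group's published median late SUV (1.1865, 0.9886); two different
  peptides clearing differently from blood is precisely what a
  group-specific input scale represents. Amplitudes are in SUV units and
  scaled to Bq/g by dose/weight per animal.
* **Noise.** Zero-mean Gaussian, SD = `noise_level` × value ×
  $\sqrt{30\,\mathrm{s}/\Delta t}$, clipped at zero: proportional noise
  whose variance falls with frame duration, the standard first-order
  model for reconstructed frames. Default `noise_level` 0.05.
* **Partial-volume loss.** Observed curves are multiplied by the
  recovery coefficients of the configured diameters so the pipeline's
  correction stage is a true inverse; without this the end-to-end
  noiseless round trip could not be exact.
* **Decay.** Generated activities are decay-corrected (standard for
  reconstructed PET); `apply_physical_decay()` / `decay_correct()`
  expose the ⁶⁸Ga half-life (67.71 min) path for testing.
* **Blood vs plasma.** The heart VOI is treated as both whole blood and
  plasma; no metabolite or hematocrit correction is modelled.

What the generator does *not* emulate — and hence what a green test does
not establish: inter-parameter correlation within an animal (parameters
are drawn independently, so synthetic SUV spreads are wider than the
published ranges), reconstruction artefacts, motion, scanner dead time,
or any spatial structure (the recovery-coefficient scalar is the entire
partial-volume abstraction). Published animal-level numbers (group
means/medians) are generator inputs and consistency anchors, not
reproducible outputs: the real per-animal data are not public.

## Pipeline

`run_study()` chains, per animal: partial-volume correction → input
fit → compartment fit → macro-parameters → SUV curve → late SUV →
fractal dimension, then builds the per-group descriptive block and the
eight-parameter rank-sum table. Failures are per-animal: an animal whose
stage errors or whose fit fails acceptance is recorded and (by default)
excluded from the statistics, never silently dropped; the policy is
switchable to `keep` or `fail`. Reports carry provenance (config,
package version) and a content hash; a fixed cohort and config reproduce
the hash bit-for-bit. `simulate_and_run()` additionally returns the
generator truth and per-animal recovery errors.

## Known limitations

* The 2TCM fitter assumes a noise-free input function; input noise
  propagates into the kinetic estimates un-modelled (no errors-in-
  variables treatment).
* At 5% frame noise the influx macro-parameter is only as robust as K1
  for the B-group parameter regime (reversible binding, k4 ≈ 0.1/min);
  its robustness advantage is clear in the R-group regime (k4 ≈
  0.04/min). The acceptance suite checks the pooled fraction.
* The exact Wilcoxon variant is limited to 12 observations total; the
  normal approximation has no such limit but inherits the small-sample
  caveat above.
* Fractal dimensions of 28-frame curves are convention-dependent
  (grid levels, rasterisation step, midpoint interpolation); values are
  comparable within this package, not across implementations.
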