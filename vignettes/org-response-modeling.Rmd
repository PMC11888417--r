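---
title: "Modeling optoretinographic cone responses with coneorg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling optoretinographic cone responses with coneorg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneorg)
```

## The response model and its assumptions

When a cone photoreceptor absorbs a visible flash, its outer segment
(OS) contracts within milliseconds, then elongates over hundreds of
milliseconds, then relaxes back toward baseline over seconds.
Phase-sensitive OCT observes this as a change in optical path length
(ΔOPL) between the inner/outer segment junction (ISOS) and the cone
outer segment tip (COST). `coneorg`'s primary model is a biexponential
with a step onset,

$$\Delta OPL(t) = u(t)\left[A_0 + A_1\left(-e^{-\tau_a t} + e^{-\tau_b t}\right)\right],$$

which is the response of an overdamped second-order system with an
offset. Its assumptions, and their practical consequences:

* **The contraction is a step.** At a 400 Hz volume rate the 5–8 ms
  contraction spans only 2–3 samples, so no attempt is made to model
  its kinetics; `u(t)` switches on at onset with $u(0) = 1$, and the
  model equals $A_0$ at $t = 0$. The model therefore cannot describe
  the negative-going samples *during* the contraction, only its
  amplitude.
* **Amplitudes of the two exponentials are equal and opposite.** This
  makes the fit a four-parameter problem and ties the elongation and
  recovery phases together; responses to very strong stimuli (≥ 32%
  bleach) depart from this form and are out of scope.
* **The parameterization is degenerate**: $(A_1, \tau_a, \tau_b)$ and
  $(-A_1, \tau_b, \tau_a)$ describe the same curve. All reported fits
  use the canonical orientation $\tau_a \ge \tau_b$ (hence $A_1 \ge 0$
  for elongation-type responses); `canonicalize_params()` applies the
  identity explicitly.

Closed forms for the derived figures of merit follow from the
derivative: $t_{max} = -\log(\tau_b/\tau_a)/(\tau_a - \tau_b)$, the
maximum ΔOPL as the model value there, and the elongation rate at any
$t > 0$. Two numerical choices deserve note. First, the onset-step
impulse in the formal derivative is excluded: `eval_rate()` is defined
only for $t > 0$, and the conventional "early elongation slope" is
reported as the rate at a caller-chosen time (default 0.05 s), since a
rate *at* the discontinuity is not well defined. Second,
$\tau_a = \tau_b$ makes $t_{max}$ a 0/0 form; because an optimizer can
pass through that point, `derived_metrics()` returns the analytic limit
$1/\tau_a$ with a `degenerate` flag rather than an error.

Variants reuse the single-flash core: paired flashes as a time-shifted
sum of two responses; pulse trains as longer shifted sums; adapting
backgrounds as the flash response plus an *ungated* linear ramp
$m\,t$ (the background bleaches steadily before and after the flash, so
the ramp is not switched by the flash onset); and an en-face intensity
model in which OS elongation modulates cone brightness through the
interference phase $n\,(4\pi/\lambda)\,\Delta OPL_{elong}(t)$. The
en-face model's phase argument carries the elongation term only — the
contraction offset does not enter — and is implemented exactly in that
printed form.

### Alternative single-flash parameterizations

Five parameterizations, named by convention after plot colors, are
available for model comparison: **magenta** (the primary model),
**green** (an onset-shifted two-exponential that represents the
contraction by its duration $t_0$ and converges to 0 at late times),
**red** (saturating elongation only), **blue** (offset-free
two-exponential; its exact printed form appears only in supplementary
material, so the implementation here is the natural offset-free reading
and is flagged provisional), and **cyan** (a pair of saturating
exponentials with independent amplitudes, which nests red). Because
red, blue and cyan do not represent the contraction, `compare_models()`
applies contraction weighting only to magenta and green and reports a
late-window RMS ($t \ge 0.5$ s) alongside the full-window RMS for fair
comparison.

## Fitting: tunable parameters and numerical choices

All fits minimize a weighted residual sum of squares with a bounded
Levenberg–Marquardt (trust-region) algorithm (`minpack.lm::nls.lm`,
`ftol = ptol = 1e-14`, up to 1000 iterations).

* **Rate constants** are constrained to $(10^{-6}, \infty)$ s⁻¹ so the
  response cannot diverge as $t \to \infty$; amplitudes are
  unconstrained.
* **Contraction weighting.** Squared residuals in
  $[\mathrm{onset}, \mathrm{onset} + w]$ are multiplied by a factor
  (default 10). The window $w$ defaults to 25 ms — 10 samples at
  400 Hz, covering the 5–8 ms negative-going segment with margin — and
  both factor and window are arguments. Without this, the contraction
  contributes only 1–3% of the objective and is fitted poorly. In
  paired-flash fits the weighting is applied after *both* onsets (an
  assumption: the convention for the second contraction is not
  prescribed anywhere, and symmetry is the natural default).
* **Initialization** is scale-aware and deliberately simple: $A_0$ from
  the minimum of the first 50 ms after onset, $A_1$ from the maximum
  excursion minus $A_0$, $\tau_a = 5$ s⁻¹, $\tau_b = 0.1$ s⁻¹ (mid-range
  physiological values). Round-trip tests show this basin is wide
  enough that noiseless 3 s/400 Hz traces are recovered to relative
  error $< 10^{-3}$ across the full physiological parameter ranges.
* **Confidence bounds** are 95% intervals from the linearization at the
  optimum using a Student-$t$ quantile with $n - p$ degrees of freedom.
  Because the contraction weights are *emphasis* weights — they do not
  describe the noise variance, which is homoscedastic — the parameter
  covariance uses the sandwich form
  $\sigma^2 (J^\top W J)^{-1} J^\top W^2 J (J^\top W J)^{-1}$ with
  $\sigma^2$ estimated from the unweighted residuals. (The naive
  weighted-least-squares covariance undercovers badly here: in a
  200-seed simulation at $\sigma = 10$ nm its nominal-95% intervals for
  $A_0$ covered the truth barely half the time, while the sandwich form
  covers at ~95%.)
* **Baseline convention.** Traces are zero-referenced to the mean of
  the pre-onset window before fitting — except in `fit_background()`,
  where the ramp is active before onset and pre-onset referencing would
  alias part of it into an un-modeled offset; there the trace is taken
  as already referenced (its generator produces $m\,t$ with $t = 0$ at
  onset) and referencing is opt-in.
* **Failure policy.** Non-convergence and degenerate cases (constant
  traces, singular Jacobians) yield flagged results, never exceptions,
  so batch processing over hundreds of cones continues.
* **Reliability flags.** Slow parameters need long observation windows
  (see below). Estimates are flagged unreliable when the post-onset
  window is shorter than per-parameter thresholds (defaults: 1.0 s for
  $A_1$ and $\tau_a$, 2.85 s for $\tau_b$, none for $A_0$ — approximate
  values read from the window analysis, configurable). In paired-flash
  fits, the first flash's window is the inter-stimulus interval and the
  second's is the remainder of the record.

Ratios of second-flash to first-flash parameters propagate uncertainty
with the independence variance formula, recovering each parameter's
standard error from its 95% interval width divided by $2 \times 1.96$.
Monte-Carlo sampling confirms the propagated sigma within 10% for
relative uncertainties up to 0.1.

## Radiometry and dose-response

Corneal power converts to retinal photon flux density as
$\Phi = T P / (hc/\lambda) / (\pi (d/2)^2)$ assuming uniform
illumination of a circular spot (default transmission $T = 1$). The
bleach fraction uses single-hit fluence bleaching without regeneration,
$p = 1 - e^{-Q s}$ with fluence $Q = \Phi \cdot \Delta t$: pigment
regeneration has a time constant of minutes and is negligible over
sub-10 s exposures. The photosensitivity default
$s = 2.95 \times 10^{-8}\ \mu m^2 \approx 10^{-7.53}\ \mu m^2$ is the
literature cone value at 555 nm; it simultaneously reproduces, at
printed precision, the 4% bleach of a 10 ms/5.05 μW flash and the
60%/85% bleaches of 10 s backgrounds at $3.1$ and
$6.5 \times 10^6$ photons s⁻¹ μm⁻² — a triple consistency check that is
part of the test suite. Dose is expressed throughout as *percent
bleached*, the unit in which the dose–response constants are quoted,
with $\log_{10}$ in the log-linear form. The Michaelis–Menten form
$y = b\,v_m/(b + b_0)$ constrains $b_0 > 0$ but leaves $v_m$ free in
sign, since contraction amplitudes saturate at negative values.

## Phase extraction

The per-cone observable is a pair of complex samples (ISOS and COST)
over nine A-scans spanning the cone center. Per timepoint, the phase
difference is the angle of the vector sum
$\sum_i A_i B_i^*$ (COST times conjugate ISOS): summing before taking
the angle weights each A-scan by its magnitude and cancels phase common
to both surfaces (common-path rejection, verified as an invariance
test). Timepoints whose vector sum is numerically null (magnitude below
$10^{-12}$ of the series mean) have undefined phase and are flagged.

A temporal unwrapping step is inserted between the phase difference and
the OPL conversion: elongations routinely exceed the unambiguous
$\lambda/4 \approx 212.5$ nm half-range, and at 400 Hz the true
frame-to-frame phase change stays far below $\pi$, so mapping
successive differences into $(-\pi, \pi]$ and accumulating recovers the
full excursion. This step is an implementation necessity of the
representation, not a claim about any particular instrument's
processing. Flagged samples stay `NA`; the unwrap offset is carried
across them. The OPL conversion is
$\Delta OPL = \Delta\Phi\,\lambda/(4\pi)$ (double pass), with
$\lambda$ defaulting to 850 nm — the center of a typical 825–875 nm
swept source — and configurable. All upstream volume processing
(demodulation, flattening, segmentation, registration, cone detection)
is out of scope: the package consumes already-segmented per-cone
samples.

## Observation-window sensitivity

`truncation_sweep()` refits truncated copies of a trace (default grid:
0.3 s to the full post-onset duration in 0.05 s steps) and expresses
each parameter's deviation from the full-window estimate as a
percentage error. `minimum_window()` reports the smallest window from
which PE stays below a threshold (default 10%) *through the reference*
— a sustained criterion, chosen over first-crossing because PE
necessarily converges to zero at the reference window (it is defined
against that estimate), which makes late dips uninformative;
first-crossing would systematically flatter slow parameters. On noisy
ensembles the analysis reproduces the expected ordering: the
contraction amplitude is stable from very short windows, while the
recovery rate $\tau_b$ — whose time constant is comparable to the whole
record — demands the longest observation. The specific minimum-window
durations depend on the data's noise level and bleach range and are not
fixed constants of the method.

## Synthetic data: what it emulates, and what it does not

The generators emulate the acquisition conditions the analysis assumes:
400 Hz sampling, 1 s or 3 s records, stimulus onset 200 ms after record
start, additive i.i.d. Gaussian OPL noise (default $\sigma = 10$ nm),
and — for the complex-field generator — static per-A-scan phases with
circular complex Gaussian noise at a stated amplitude SNR. The
paired-flash generator attenuates the second response by a default rule
(contraction ratio $\min(1,\ 2.3\,t_{isi} + 0.31)$, reaching unity near
$t_{isi} = 0.3$ s; elongation ratio 0.85, within the observed 0.75–1
band); the pulse-train generator applies that rule cumulatively down
the train. These constants parameterize the generator and are
configurable; they are conventions consistent with observed trends, not
claims. All generators are bit-reproducible under a fixed seed.

What the generators do **not** model: eye motion, speckle
decorrelation, photon-noise-accurate OCT statistics, inter-cone
variability, or high-bleach nonlinearity. Passing round-trip tests
therefore demonstrates the *estimator's* correctness under the model's
own assumptions — identifiability, calibrated intervals, pipeline
inversion — not robustness to every artifact of real recordings.

Problem sizes used by the test suite (chosen to exercise each property
at desk scale): 50 random draws for noiseless recovery, 100 draws for
the closed-form-vs-grid oracle (coarse 10 ms pass plus 10 μs refinement
around the maximum, equivalent to a flat 10 μs grid), 120–200 seeds for
interval-coverage checks, 50 seeds each for the phase-pipeline noise
budget and the window-ordering ensemble, and $2 \times 10^5$
Monte-Carlo draws for ratio-uncertainty validation.

## Known limitations

* The model family is phenomenological: parameters summarize the OS
  deformation, they do not resolve biophysical mechanism.
* High-bleach (≥ 32%) responses are outside the model's validity; no
  extended form is provided.
* Confidence bounds are linearized (Wald-type); they are approximate
  for strongly correlated parameters such as $\tau_b$ on short windows
  (the reliability flags exist precisely for that case).
* The paired-flash reliability thresholds are approximations;
  applications with different noise levels should recalibrate them via
  `truncation_sweep()`.
* The blue alternative model's form is provisional (see above).
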