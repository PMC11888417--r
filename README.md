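# coneorg

Quantitative modeling of optoretinographic (ORG) cone photoreceptor
responses.

Phase-sensitive OCT can resolve nanometer-scale, light-evoked changes in
the optical path length (ΔOPL) of cone outer segments — a rapid
contraction at flash onset followed by a slower elongation and a still
slower recovery to baseline. `coneorg` provides the model suite and
estimation machinery needed to turn such measurements into comparable,
physiologically meaningful parameters: for clinicians and vision
scientists quantifying photoreceptor function, and for instrument
builders validating an ORG processing pipeline against synthetic data.

## The model

The single-flash response is described by a four-parameter biexponential
with a step onset:

    ΔOPL(t) = u(t) · [ A₀ + A₁ · ( −e^(−τₐ·t) + e^(−τᵦ·t) ) ]

where `u(t)` is the Heaviside step (1 for t ≥ 0), `A₀` (nm, negative) is
the contraction amplitude, `A₁` (nm) the elongation amplitude, and `τₐ`,
`τᵦ` (s⁻¹) the elongation and recovery rate constants. Derived figures
of merit (time of maximum elongation, maximum ΔOPL, elongation rate at
any time) follow in closed form. Variants cover paired flashes (a
time-shifted sum of two single-flash responses), pulse trains, flashes
on adapting backgrounds (an added linear ramp `m·t`), five alternative
single-flash parameterizations, and an en-face interference intensity
forward model.

Around the model sit:

- a constrained, contraction-weighted trust-region fitting engine with
  95% confidence bounds, parameter-ratio error propagation, and
  alternative-model comparison;
- stimulus radiometry: corneal power → retinal photon flux density →
  photopigment bleach fraction (`p = 1 − exp(−Q·s)`), plus log-linear
  and Michaelis–Menten dose–response fits;
- phase extraction: complex ISOS/COST cone subvolume samples →
  vector-sum phase difference → temporal unwrapping → ΔOPL trace;
- observation-window sensitivity analysis (truncation sweeps, minimum
  windows at a percentage-error threshold);
- synthetic-data generators for all of the above, for round-trip and
  Monte-Carlo validation.

## Worked example

```r
library(coneorg)

## exemplary single-flash parameters (8% bleach)
p <- response_params(a0 = -36.4, a1 = 200.8, tau_a = 9.5, tau_b = 0.07)

## simulate a 3 s, 400 Hz measurement (onset 0.2 s, sigma = 10 nm) and refit
trace <- simulate_single_flash_trace(p, sim_config(noise_sigma_nm = 10, seed = 42))
fit <- fit_single_flash(trace)
print(fit)
#> ORG model fit (single_flash), 1200 points
#>         estimate    ci_low   ci_high
#> a0    -32.512000 -39.55600 -25.46800
#> a1    196.570000 189.77000 203.37000
#> tau_a   9.225300   8.65810   9.79250
#> tau_b   0.071945   0.06521   0.07868
#> R^2 = 0.9446, RMS = 10.001 nm, late RMS = 10.086 nm (weights: x10 in [onset, onset+0.025 s])
```

All four generating parameters are recovered within their 95% bounds,
and the RMS residual matches the injected 10 nm noise floor. Derived
figures of merit and stimulus radiometry:

```r
m <- derived_metrics(p)
#> t_max = 0.521 s, dOPL_max = 155.8 nm, early rate = 1172 nm/s

spec <- radiometry_spec(power_w = 5.05e-6, duration_s = 0.010,
                        wavelength_nm = 555, spot_diameter_um = 360)
photon_flux_density(spec)   # 1.39e8 photons s^-1 um^-2
bleach_fraction(spec)       # 0.040 -> a 4% bleach flash
```

A command-line wrapper is installed at `inst/exec/coneorg`
(subcommands `fit`, `simulate`, `radiometry`, `dose-fit`, `window`,
`compare-models`, `extract`); see `?run_cli`.

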