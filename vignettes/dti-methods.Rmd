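---
title: "Models and design choices in dtikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in dtikin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtikin)
```

`dtikin` covers the quantitative chain of a direct-thrombin-inhibitor
characterisation campaign: enzyme assays, plasma traces, rodent
dose–response, and biosensor kinetics. This vignette explains the models,
the parameters that matter, the numerical choices, and what the synthetic
data generators do and do not emulate.

## Tight-binding enzyme kinetics

For an inhibitor whose Ki is far below the enzyme concentration, free and
total inhibitor differ materially and the classical Michaelis–Menten
inhibition expressions fail. The steady-state velocity instead follows the
Morrison quadratic,

$$v_s = \frac{v_o}{2E_t}\left(\sqrt{(K_i' + I_t - E_t)^2 + 4K_i'E_t}
 - (K_i' + I_t - E_t)\right),$$

which `morrison_velocity()` evaluates and `fit_morrison()` inverts by
nonlinear least squares. Key choices:

- **Units.** `morrison_velocity()` takes all three concentrations in one
  common unit (the expression is scale-invariant); the fitting layer works
  in nM internally and reports Ki′ in pM, the unit in which picomolar
  inhibitors are quoted. Conversions happen only at interfaces.
- **Velocity estimation.** Fast-binding inhibitors give linear progress
  curves, so the steady-state velocity is the OLS slope over a
  configurable window (default: the whole 10-minute read), with r² as the
  linearity diagnostic. No burst-phase model is fitted — slow-binding
  onset kinetics are out of scope.
- **vo handling.** The uninhibited velocity is measured directly (the
  It = 0 well), so the default fit fixes vo and estimates only Ki′; a
  fitted-vo mode exists for robustness checks.
- **Parameterisation.** Ki′ is fitted on the log scale, which enforces
  positivity and makes the standard error (delta method) meaningful across
  the pM–nM range. Starting values come from exact inversion of the
  Morrison expression at the half-inhibition point.
- **Titration design.** Identifiability of Ki′ ≪ Et rests on points near
  the stoichiometric equivalence I_t ≈ E_t; the bundled designs use a
  10-point titration of 0–2× Et, densified around the knee, with
  triplicate reads — the standard layout for tight-binding titrations.

The competitive mechanism is resolved through the substrate dependence
K′i(S) = K_i(1 + S/K_m): `ki_from_substrate_series()` regresses K′i on S
(inverse-variance weighted when standard errors are available — the
weighting is our choice; unweighted is used when no errors are supplied),
reports the intercept as K_i and intercept/slope as a derived K_m, and
calls the mechanism `competitive_consistent` when the linearity r² reaches
a configurable threshold (default 0.9). K_m for the chromogenic substrate
is treated purely as a diagnostic: it is a free truth parameter of the
generator, not a packaged constant.

For cleavage products inhibiting non-competitively, Ki equals the IC50 of
a logistic dose–response fit. The four-parameter logistic is parameterised
as $y = A_2 + (A_1 - A_2)/(1 + 10^{H(x - x_0)})$ with $x = \log_{10}$
concentration, so the inflection satisfies $y(x_0) = (A_1+A_2)/2$ and
IC50 = $10^{x_0}$. This is the standard, numerically well-defined form of
the "(x/x0)^H" logistic written in concentration space; a ratio of
*logarithms* raised to a power is undefined wherever the log changes sign,
so we adopt the concentration-ratio reading. Asymptotes are free by
default; a constrained mode (A1 = 0, A2 = 100) is available since percent
inhibition is bounded.

**Selectivity** is reported as a lower bound: the target is characterised
by the lowest tested concentration reaching the inhibition threshold
(default 20%), each off-target by the highest tested concentration at
which it stays below it, and the bound is the most conservative ratio
across off-targets. With a target active at 0.1 nM and every off-target
quiet at 100 µM this yields the familiar "at least 10^6-fold" statement.

## Plasma traces

**Clot waveform analysis.** The transmittance trace is differentiated with
Savitzky–Golay local-polynomial filters (order 5 by default, so a third
derivative is supported); raw finite differences amplify noise far too
much, and the clinical analyzers' internal algorithms are proprietary.
min1/min2/min3 are the minima of the first three derivatives, located
outside the filter's edge-transient region. The derivative window is the
key tuning parameter: each differentiation step multiplies noise by
roughly 1/h per order, so higher derivatives of noisy traces need windows
of several seconds (the bundled driver uses 15 s at 10 Hz sampling for a
stable min3). Clot time is defined here as the time of min1 — the point of
steepest transmittance fall; analyzers use unpublished threshold rules, so
this choice is documented rather than emulated. A trace whose total drop
is under 1% returns an explicit no-clot result.

**Thrombin generation.** `tgt_parameters()` reports peak (curve maximum),
TTpeak (arg-max), lag time (first interpolated upward crossing of a
threshold), ETP (trapezoidal area) and velocity index
VI = peak/(TTpeak − LT). Two lag definitions are offered: a fraction of
peak (default 10%) and a fixed 2 nM threshold (the thrombinogram-software
style); neither is canonical in the literature, so both are explicit
options. VI is the standard velocity-index definition; small negative
excursions around the calibrated zero baseline are integrated as measured.
An optional quadratic Savitzky–Golay pre-smoothing stabilises peak and lag
estimates on noisy traces; it is off by default so exact geometric inputs
are untouched.

**Dose–intensity gradients.** Anticoagulant intensity parameters are
fitted as $Y = 10^{m\log_{10}X + C}$ by OLS on the log–log scale ("log"
is log10 throughout, consistent with the 10^ form). Values are normalised
as fold change over vehicle before fitting; this shifts only C, never m,
so gradient comparisons between drugs are unaffected by the choice.

## Censored dose–response and the therapeutic index

Occlusion and bleeding times in the rodent models are recorded up to a
fixed observation cap (60 min) and censored there. The response-time curve
is modelled as a Hill function rising from the saline baseline to the cap,

$$RT(d) = b + \frac{c - b}{1 + (RT_{50}/d)^{h}},$$

with multiplicative log-normal residuals. The paper-style figures show the
curves and RT50 markers without naming an interpolation model; the Hill
form with censored maximum likelihood is our documented choice. Censored
observations contribute log-normal survival terms — they are neither
discarded nor treated as exact, which is what keeps RT50 estimable when
the top doses saturate. The baseline is fixed (default: the saline group
mean; the packaged constants are 8.82 min for occlusion and 4.25 min for
tail bleeding) because saline groups are measured separately in these
experiments. Uncensored data are first fitted by log-scale least squares
(which alone achieves sub-ppm recovery on clean data); the censored
likelihood refinement engages only when censored records are present.
RT50 equals the `rt50` parameter by construction — the dose at which the
latent curve crosses the midpoint of baseline and cap — and the
therapeutic index is the plain ratio RT50(bleeding)/RT50(occlusion),
computed from group-level fits (whether per-animal or group-mean fits were
used historically is unknowable; group-level is our choice). Dose units
are carried as tags and never auto-converted; heparin's activity-to-molar
conversion is a separate, opt-in step (183.5 U/mg, 10 900 g/mol).

## Biosensor kinetics

The 1:1 Langmuir interpretation of biolayer interferometry gives closed
forms: association $R(t) = R_{max}\frac{C}{C+K_D}(1-e^{-(k_{on}C+k_{off})t})$
and mono-exponential dissociation from the association end-point, with
$K_D = k_{off}/k_{on}$ identically. Rmax — the saturating response — is a
parameter the instrument software implies but rarely names; it is explicit
here. The default fit is global (one kon/koff/Rmax shared across the
dilution series, vendor practice); per-curve mode reports kobs and koff
per concentration as a heterogeneity diagnostic. Parameters are fitted on
the log scale; the design is flagged ill-conditioned when every analyte
concentration sits two orders of magnitude away from the fitted KD.
Equilibrium responses are the *fitted* plateaus of the association
exponential, not last samples — a trace ending before equilibrium
underestimates Req otherwise — and plateaus with standard errors above 50%
(or kobs·t below 1) are flagged unreliable. The steady-state isotherm
$R_{eq} = R_{max}C/(K_D + C)$ then gives a second, kinetics-free route to
KD; on clean data the two routes agree within 1%, and reporting both
mirrors how biosensor affinities are quoted.

## Synthetic data: what it emulates, and what it does not

Every generator consumes a `sim_spec` (assay kind, truth parameters,
sampling design, noise SD, seed) and emits the exact forward model of its
consuming module plus noise, alongside a truth sidecar for
parameter-recovery tests. Design decisions:

- **Noise models.** Optical read-outs (absorbance, transmittance,
  thrombin signal, biosensor response) carry additive Gaussian noise in
  native units; in-vivo response times carry multiplicative log-normal
  noise, which keeps them positive and matches the skew of biological
  timing data. No raw-trace noise magnitudes are published for these
  assays; the defaults (e.g. 2% of signal) are chosen for test power, not
  claimed realism.
- **Thrombogram shape.** A gamma-density pulse shifted by the lag time
  and rescaled to the requested peak. Real instrument output shapes are
  proprietary; the gamma pulse reproduces the lag/rise/decay structure and
  has a closed-form area, which the generator reports as the true ETP.
  There is no mechanistic coagulation-cascade model behind any trace —
  shapes are phenomenological.
- **Censoring is generator-side.** Records at or above the cap carry a
  censored flag, mirroring how the animal experiments record a capped
  observation window.
- **Seeding.** One integer seed per spec; per-replicate sub-streams are
  derived deterministically from it, so a fixed spec reproduces its output
  exactly across runs and platforms.

Because the zero-noise generators *are* the fitting modules' forward
models, passing recovery tests demonstrates the estimation machinery, the
numerics and the censoring logic — not that real plasma or animal data
follow these idealised shapes. Conclusions about instrument data require
the usual model diagnostics (linearity r², fit residuals, the
ill-conditioning and reliability flags).

## Problem sizes and numerical tolerances

The recovery suites use 100–200 seeded replicates per experiment at the
study's group sizes (4–5 dose levels, 5–8 animals per dose for the
therapeutic index; 10-point triplicate titrations for Morrison fits;
7-concentration dilution series for biosensor fits) — large enough for
stable medians while keeping the full test suite under a minute.
Nonlinear fits run Levenberg–Marquardt with tight tolerances (1e-15 on
ftol/ptol) so that noiseless round trips recover truth to machine
precision; grid-plus-golden-section and ODE oracles in the tests verify
the optima independently. Degenerate inputs (flat traces, all-censored
records, saturated isotherms, chromophore-free sequences) return explicit
flagged results or targeted errors rather than numerical garbage.

## Known limitations

- Slow-binding (onset) kinetics, mass-transport-limited or bivalent
  biosensor models, fluorogenic calibrator deconvolution, and mechanistic
  cascade models are out of scope.
- The clot-time and lag-time definitions are documented conventions, not
  reverse-engineered instrument rules; absolute values are comparable
  within this package, not across analyzers.
- The log-normal censored likelihood assumes homoscedastic log-scale
  noise across doses; strongly dose-dependent variability would bias the
  Hill slope more than RT50 itself.
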