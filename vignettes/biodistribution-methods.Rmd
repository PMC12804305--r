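---
title: "Methods: quantifying ex vivo biodistribution from weighed standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ex vivo biodistribution from weighed standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodistr)
```

## The measurement problem

An *ex vivo* biodistribution study asks how much of an injected
radiotracer ends up in each tissue. The readout is the percentage of the
injected dose per gram of tissue (%ID g⁻¹), with standardized uptake
values (SUV) and target-to-background ratios derived from it. The
awkward part is the denominator: dose calibrators are geometry-sensitive
and inaccurate at the sub-MBq doses used in mice, while gamma counters
saturate at injectable activity levels. `biodistr` implements the
weighed-standard approach: the two most precise instruments in the lab —
the analytical balance and the gamma counter — are combined so that the
injected activity of every animal is derived from the *mass* of
formulation it received and a counting standard drawn from the same
formulation.

The chain of quantities:

1. Every syringe is weighed full (before injection) and empty (after),
   so the injected mass is $m_\mathrm{inj} = m_\mathrm{full} -
   m_\mathrm{empty}$, automatically correcting for residual formulation
   left in the syringe.
2. One extra syringe (the $n{+}1$th; see `plan_formulation()`) is
   emptied into a weighed ~10 mL water stock. Aliquots of the stock
   (~1 mL, at least four) are weighed and gamma-counted next to the
   tissues. Because the dilution is tracked entirely by mass, aliquot
   $i$ of mass $m_i$ contains $m_\mathrm{std}\, m_i / m_\mathrm{stock}$
   grams of formulation, and its net CPM give a calibration factor
   $\mathrm{CF} = \mathrm{CPM}$ per gram of formulation.
3. The injected activity of animal $j$, in counter units, is then simply
   $\mathrm{CF} \cdot m_{\mathrm{inj},j}$, and for a tissue of mass $m_t$
   with net counts $C_t$,
   $$\%\mathrm{ID}\,\mathrm{g}^{-1} = 100 \cdot
     \frac{C_t}{\mathrm{CF}\, m_\mathrm{inj}} \cdot \frac{1}{m_t},
   \qquad
   \mathrm{SUV} = \%\mathrm{ID}\,\mathrm{g}^{-1} \cdot
     \frac{BW}{100}.$$

All counter CPM are decay-corrected *by the counter* to the start of the
counting protocol, so that reference time is adopted for everything:
dose-calibrator readings of the syringes are forward-corrected to it via
`decay_correct()` rather than back-correcting every tube to injection
time. Correction is multiplicative and unit-agnostic:
$A(t_\mathrm{ref}) = A(t) e^{-\lambda (t_\mathrm{ref} - t)}$.

A single study clock is assumed; timestamps are ISO 8601 and mixing
offset-aware with naive stamps is rejected outright, since their relative
offsets would be undefined.

## Parameters that matter

* **Background policy** (`study_config(background_policy=)`): mean
  (default) or median of the background tubes. The protocol counts
  background in quadruplicate but does not fix the aggregation; the mean
  is unbiased under the Poisson model, the median is available when a
  contaminated blank is suspected.
* **Negative net counts** (`negative_net_policy`): low-uptake tissues can
  fall below background. The default keeps the negative value and flags
  it (`negative_net`), so group means stay unbiased; clamping to zero is
  available but biases means upward.
* **Standard-aliquot CV warning** (`cv_warn_pct`, default 5%): a
  pipetting-quality gate, not an error — the calibration factor is still
  the mean across aliquots.
* **Counter ceiling** (`counter_ceiling_cpm`): optional linear-range
  limit; tubes above it are flagged for recounting after decay. No
  dead-time correction is attempted.
* **Manual override** (`manual_injected_activity_override_MBq`): for
  failed injections or tracers that stick to the syringe, a
  dose-calibrator-measured injected activity (MBq at the reference time)
  replaces the mass-based value, converted into counter units through the
  activity calibration factor CF·$m_\mathrm{std}$/$A_\mathrm{delivered}$
  (CPM MBq⁻¹). The calibrator-based estimate is otherwise only ever a
  cross-check reported next to the mass-based value, never a silent
  substitute.

Group statistics use the sample standard deviation (n−1); CV is reported
only for positive means. Contrast ratios are formed **per animal** and
then averaged — not as the ratio of group means — because the pairing of
target and background within an animal carries real information and the
per-animal ratio is the quantity biologically claimed. Excluded animals
(failed injections) stay in the per-animal output but leave all
summaries.

## Whole-body kinetics

Whole-body activity versus time is fitted by nonlinear least squares
(Levenberg–Marquardt) with $A(t) = A_0 e^{-\lambda t}$ or
$A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}$, initialized from
log-linear regression (the two-phase start splits the series at its
midpoint: the late half fixes the slow phase). `model = "auto"` picks by
corrected AIC but keeps the one-phase model unless the biexponential
improves AICc by more than 2 units — the simplest adequate model is the
defensible default when metabolite data are absent. Fits are unweighted
by default; 1/A (Poisson-proportional) weights are available. When a
nuclide is supplied and the fitted effective half-life is below the
physical one, the biological half-life follows from
$1/t_\mathrm{eff} = 1/t_\mathrm{phys} + 1/t_\mathrm{bio}$.

## Decay chains

For alpha emitters without usable gammas, a gamma-emitting daughter is
counted instead and the mother inferred through the Bateman equation
$$A_d(t) = A_m(0)\, \frac{\lambda_d}{\lambda_d - \lambda_m}
  \left(e^{-\lambda_m t} - e^{-\lambda_d t}\right) \mathrm{BR}.$$
`bateman_daughter()` evaluates it in the cancellation-free form
$e^{-\lambda_m t}\,(-\mathrm{expm1}(-(\lambda_d-\lambda_m)t))$, so
near-degenerate rate pairs lose no precision; at relative separation
below $10^{-12}$ it switches to the analytic limit
$\lambda t e^{-\lambda t}$. The secular limit
($\lambda_m \to 0$), the transient-equilibrium ratio
$\lambda_d/(\lambda_d-\lambda_m)\cdot\mathrm{BR}$, the
equilibrium-timing helper $t = -\ln(1-f)/\lambda_d$ and the inversion
`mother_from_daughter()` are separate, tested operations. The inversion
refuses time points where the predicted ingrowth is below $10^{-6}$ of
the achievable daughter level — dividing by a vanishing ingrowth would
amplify measurement error without bound.

Which fraction counts as "reaching" equilibrium is convention: 95%
reproduces the five-half-life rule of thumb
($\lceil -\log_2(0.05)\rceil = 5$), and 99% puts a 45.6-min daughter at
about 5 h; both fractions are exposed as arguments rather than baked in.
Only a single mother–daughter pair with an effective branching ratio is
modeled; full multi-member chains and the down-scatter of a second
daughter's gammas into the counting window are out of scope (a
user-supplied spillover fraction can be subtracted linearly upstream of
the analysis if the counter setup requires it).

## The nuclide table

Constants ship as a versioned plain-text table (119 entries) drawn from
standard nuclear-data compilations, with the decay constant always
derived as $\ln 2 / t_{1/2}$. Gamma-line intensities are per-decay photon
yields, so annihilation lines (511 keV) can exceed 100%. Decay-chain
links carry branching ratios for the chains relevant to alpha-emitter
work (Ac-225 → Fr-221 → … → Bi-213; Ra-224 → … → Pb-212 → Bi-212).
Exponents $|\lambda \Delta t| > 700$ are refused rather than silently
under- or overflowing.

## What the synthetic generator emulates — and what it does not

`generate_study()` produces a complete virtual study: syringes weighed
full/empty with a residual fraction retained, dose-calibrator readings
consistent with physical decay, the standard-stock dilution, background
and standard tubes, and tissue tubes whose expected CPM follow per-animal
true %ID g⁻¹ values. Tubes decay tube-by-tube down the counting queue
(default 60 s spacing) and the simulated counter decay-corrects them back
to the protocol start, exercising the reference-time convention end to
end. With `noise = "none"` the study is an exact fixed point of the
analysis (recovery to ~10⁻¹⁴ relative); with `noise = "poisson"` counts
are Poisson over the counting interval, masses and body weights get
Gaussian jitter and per-animal true %ID g⁻¹ is lognormal.

Defaults describe a realistic mouse study with an antibody-like tracer at
a late time point: 4 animals per group, 25 ± 2 g body weight, 0.12 ±
0.01 g injected formulation, 1% residual fraction, 5 × 10⁶ CPM per gram
of formulation at the reference time (≈6 × 10⁵ CPM injected — comfortably
inside a counter's linear range), 30 CPM background, 15% between-animal
lognormal sigma, and a ten-tissue panel whose summed %ID stays near 25%.
These are study conditions, not tuning knobs.

What the generator does **not** emulate: tracer sticking to syringes,
partial (tail-vein) injections, counter dead-time and saturation,
spillover between energy windows, tissue-collection blood contamination,
and any biology beyond a static %ID g⁻¹ per tissue. Passing the
round-trip and coverage tests therefore demonstrates the correctness of
the bookkeeping and statistics under the stated measurement model, not
robustness to those real-world failure modes — which is exactly what a
calculation pipeline can and should guarantee.

The Poisson-recovery check compares each replicate's recovered group mean
with the mean of that replicate's *realized* per-animal true values,
within three standard errors (sample sd/√n of the recovered values): the
estimator's own dispersion is the right yardstick when the truth varies
per animal. Validation uses 200 seeded replicates of the default
four-animal study, restricted to tissues with at least 10⁴ expected
counts, where counting noise is ≲1%.

## Numerical choices and degenerate inputs

* Masses are treated at face value as recorded to four decimals (g); the
  generator rounds recorded masses *before* deriving the consistent
  activities, so rounding never breaks the zero-noise fixed point.
* A tissue of exactly zero mass yields a missing %ID g⁻¹ (flagged
  `zero_mass`), never zero or infinity; %ID per organ is still defined.
* Validation is total: `validate_study()` accumulates every violation
  instead of stopping at the first, so one pass over a broken sheet set
  shows everything to fix.
* CSV output is serialized at 6 significant digits; the JSON mirror keeps
  full precision.

## Limitations

SUV is computed by body weight only (lean-mass and body-surface-area
variants are deliberately out of scope). Inferential statistics
(t-tests, ANOVA, MANOVA) are deliberately not implemented — the CSV/JSON
outputs are structured for direct import into dedicated statistics
software, and no plotting is built in for the same reason. Liquid
scintillation workflows share the weighed-standard logic but their
quench and efficiency corrections are not modeled.
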