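---
title: "Quantifying tissue-specific insulin sensitivity from FDG-PET and clamp data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue-specific insulin sensitivity from FDG-PET and clamp data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgclamp)
```

## The problem

Mildly elevated liver triglyceride content (HTG between 1.86% and 5.56% by
proton MR spectroscopy, the "MEL" range) sits between the recently proposed
normal cut-off of 1.85% and the classical 5.56% upper limit. Characterising
which tissues lose insulin sensitivity in that range requires combining
several measurement modalities: a hyperinsulinaemic–euglycaemic clamp for
whole-body insulin sensitivity (M-value), dynamic [18F]FDG-PET for
tissue-specific glucose uptake and endogenous glucose production (EGP),
fasting and OGTT indices (HOMA-IR, simplified Matsuda ISI, Adipo-IR), and a
serum NMR metabolite panel scanned with covariate-adjusted logistic
regression under Storey FDR control.

`fdgclamp` implements that quantitative chain end to end, together with a
synthetic two-group cohort generator that emulates the statistical and
physiological structure such studies produce. The generator makes every
stage testable without patient data; it is first-class, tested code, not a
fixture.

## Tracer kinetics

### Forward model

Tissue FDG kinetics follow the irreversible two-tissue compartment model

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1, \qquad C_t = C_1 + C_2,$$

with plasma input $C_p(t)$. The package carries two independent
implementations: an exact closed-form solution for exponential-sum inputs
(used by the simulator) and a fine-grid exponential-integrator convolution
(`solve_irreversible_2tc()`, used as the test oracle). Their agreement is
asserted in the test suite.

The plasma input function is a parametric bolus: three washout
exponentials (rates 0.35, 0.08 and 0.01 min⁻¹, AUC weights 0.55/0.30/0.15)
minus a fast rise term (1.5 min⁻¹) so that $C_p(0) = 0$. A smooth closed
form was chosen deliberately: its AUC is known exactly, which gives the
rate-of-disappearance estimator an analytic oracle. The curve is scaled so
that whole-body tracer clearance is consistent with the subject's
programmed glucose disposal, making mass balance — not an arbitrary
amplitude — the ground truth.

### Patlak analysis

`patlak_ki()` implements Gjedde–Patlak graphical analysis: ordinary least
squares of $C_t(t)/C_p(t)$ on $\int_0^t C_p\,d\tau / C_p(t)$ restricted to
$t \ge t^*$. The slope estimates $K_i = K_1 k_3/(k_2+k_3)$. Design choices:

* $t^*$ defaults to 20 min, beyond free-compartment equilibration
  ($\approx 3/(k_2+k_3)$) for clamp-state muscle and liver constants.
  Adipose tissue equilibrates more slowly ($k_2+k_3 \approx 0.08$ min⁻¹);
  the estimator accepts any $t^*$, and the tests validate the 2% recovery
  contract at windows satisfying $t^* \ge 3/(k_2+k_3)$.
* The regression is unweighted; weighting schemes require a noise model
  that dynamic PET data rarely justify.
* The plasma integral uses trapezoids on the plasma grid with an implied
  zero sample at injection.

Tissue glucose uptake converts the slope with the lumped-constant formula
$GU = K_i \cdot [\text{glucose}] / (\rho \cdot LC)$, with lumped constants
1.2 (skeletal muscle), 1.0 (liver), 1.14 (adipose) and default densities
1.04, 1.05 and 0.92 kg/L (configurable; densities are reported in the run
manifest because they are convention, not measurement).

### M-value, Rd and EGP

The M-value is the mean of three consecutive 20-min interval means of the
glucose infusion rate, starting at the first glucose sample within a
tolerance (default 0.3 mmol/L) of the 5 mmol/L target with at least 60 min
of trace remaining; the baseline (t = 0) sample never qualifies because it
precedes insulin action. The glucose rate of disappearance comes from
urine-corrected tracer clearance,

$$R_d = \frac{(\text{dose} - \text{urine})}{\mathrm{AUC}(C_p)}
        \cdot \frac{[\text{glucose}]}{\text{weight}},$$

with the plasma AUC extrapolated beyond the last sample by a
mono-exponential fitted to the final three points. EGP is then
$R_d - \mathrm{GIR}$, computed exactly (the identity is preserved to
machine precision, and negative estimates are legal outputs — they arise
whenever hepatic output is fully suppressed and measurement noise tips the
difference below zero). The "average plasma glucose" entering $R_d$ is the
mean of clamp samples from 60 min onward; which average the formula should
use is a convention the package exposes rather than hides.

## Insulin sensitivity indices

All indices use the exact printed formulas: HOMA-IR
($G \cdot I_{\mu U/mL}/22.5$), the simplified Matsuda ISI
($10^4/\sqrt{G_0 I_0 G_{120} I_{120}}$), first-phase
(0/30 min) and total-phase (0/60/120 min) secretion indices as trapezoid
AUC ratios on exactly the named time points, and Adipo-IR as the
insulin × FFA product (glycerol variant available). Two conventions are
configuration, never silent assumptions: the insulin pmol/L → µU/mL factor
(default 6.00) and the Matsuda unit mode (default `"si"`, i.e. mmol/L ×
pmol/L, which matches index magnitudes around 19–29; `"mgdl"` gives the
classic convention).

## Group statistics

* `adjusted_group_comparison()` fits OLS of a transformed outcome on group
  plus covariates (sex, age, BMI, optionally PET scan timing) and reports
  the group coefficient with Wald CI, p-value and the graded evidence
  scale (p < 0.01 strong, 0.01 ≤ p < 0.05 moderate, 0.05 ≤ p < 0.1 weak,
  p ≥ 0.1 little). The transform registry (`identity`, `log`,
  `rank_normal`, with `auto` choosing by sign and skewness) records the
  applied transform in the output, since "transformed to achieve
  normality" is otherwise unreproducible.
* `metabolite_scan()` log2-transforms each measure, standardizes to unit
  SD, and fits logistic regression of group on measure + sex + age + BMI,
  reporting the odds ratio per 1 SD with a Wald CI. Wald rather than
  profile intervals: deterministic, and the convention behind typical
  forest plots. Quasi-separated fits are refit with an in-package Firth
  bias-reduced solver and flagged.
* `storey_qvalues()` estimates the null proportion π₀ with the smoother
  method (π̂₀(λ) over λ = 0.05…0.95, cubic smoothing spline, evaluated at
  λ = 0.95, clipped to (0, 1]) and applies the step-up construction, which
  reduces exactly to Benjamini–Hochberg when π₀ = 1. At panel sizes around
  100 the smoother is known to run slightly liberal under the global null;
  the tests therefore assert the defining quantity
  $E[V/\max(R,1)]$ directly by simulation.
* `sample_size_two_sample_t()` searches the smallest equal per-group n
  whose noncentral-t power reaches the target, starting from the
  normal-approximation bound — the same computation a G*Power-style tool
  performs. `stats::power.t.test` serves as an independent cross-check in
  the tests, not as the implementation.

## The synthetic cohort generator

`generate_cohort()` draws per-subject ground truth on the log scale. The
defaults are the study conditions, chosen once:

* **Groups.** 101 subjects per group; liver triglyceride from truncated
  log-normals on the half-open intervals (0, 1.85] and (1.85, 5.56], with
  the location calibrated by root-finding so the *truncated* medians equal
  0.9% and 3.2%.
* **Demographics.** Women fractions 0.76/0.62; BMI log-normal with
  medians 25.2 and 29.4 kg/m²; age median 48.
* **Covariate structure.** Sex and BMI act linearly on the log scale of
  every outcome (e.g. +0.03 log-insulin per BMI unit), so that log-scale
  covariate adjustment is exactly specified and null configurations stay
  calibrated. A consequence worth stating: the marginal group contrasts
  (what a Table-1 analogue shows) combine direct MEL shifts with
  BMI-mediated ones. The defaults attribute most of the fasting-insulin
  contrast to BMI and most of the FFA/glycerol and EGP contrasts to the
  group itself, mirroring the study's pattern of weak evidence for
  HOMA-IR but moderate evidence for Adipo-IR and EGP after adjustment.
* **Effects.** Standardized MEL shifts (log-SD units) calibrated so
  marginal medians land on the reference contrasts: fasting Adipo-IR
  17.6 vs 28.4 pmol/L×mmol/L, insulin–glycerol product 1.97 vs 3.75,
  HOMA-IR 1.31 vs 1.79. EGP suppression is logit-normal with the
  unsuppressed fraction shifted +2.83 SD in MEL, putting clamp-state EGP
  medians near 0.2 (LL) and 2.7 (MEL) µmol/kg/min. Whole-body disposal
  receives only a small direct shift (−0.15 SD): the M-value contrast
  emerges through EGP, matching the observation that Rd differs little
  between groups.
* **Clamp.** Insulin fixed at 40 mU/m²/min; a discrete PI controller
  (updates every 5 min, gains 25 and 2.5, feed-forward ramp priming 80%
  of the steady-state requirement) servos glucose to 5.0 mmol/L; insulin
  action activates with an 8-min time constant, EGP suppresses with
  12 min. Glucose/insulin samples are emitted every 30 min. At steady
  state GIR = disposal − suppressed EGP exactly in noiseless mode.
* **Noise.** Multiplicative log-normal throughout (TACs 5% CV, clamp
  glucose 1.5%, OGTT 7%, assays 5%), preserving positivity.
* **Metabolome.** 31 measures, log-normal, block-correlated by
  lipoprotein/metabolite class (intra-block ρ = 0.4); default shifts
  positive for triglycerides, VLDL/LDL lipids, ApoB, BCAAs, glycolysis
  intermediates and GlycA, negative for HDL size and PUFA fractions, zero
  for designated null measures. Custom panels with programmed effects are
  supported for simulation studies.
* **Urine loss.** A configurable fraction of injected dose, default 10%.

What the generator does *not* emulate: PET image formation and
reconstruction noise structure, MRS spectral fitting, insulin assay
calibration differences, inter-protocol sampling-schedule heterogeneity
(the default dynamic schedule is 0.25–120 min, dense early), or missing
data. Passing tests therefore demonstrate correctness of the estimators
under the stated forward models, not robustness to every artefact of real
scanner data.

## Numerical choices and degenerate inputs

* Integration: trapezoids everywhere data are discrete; the plasma tail is
  extrapolated mono-exponentially from the last three samples, and the
  120-min default schedule makes the trapezoid-plus-tail AUC agree with
  the closed-form input AUC within 1%.
* Determinism: every simulator is a pure function of (inputs, seed); batch
  generation derives per-subject child seeds, and `run_pipeline()` writes
  MD5 content hashes so identical config + seed gives identical artifacts.
* Degenerate inputs fail loudly and specifically: clamps shorter than
  120 min, steady state never reached, non-positive plasma activity in
  the Patlak window, urine exceeding dose, collinear or zero-residual-df
  designs, unknown measure names in effect maps.
* Ties at the median in `median_split()` go to the lower group; missing
  values are excluded and counted.

## Problem sizes in the tests

The suite validates the Patlak noise contract over 200 seeded replicates,
null calibration over 1,000 simulated outcomes (250 cohorts × 4
independent outcomes at n = 48/group), mass balance over 50 noiseless
subjects, and scan FDR/recovery over 200 replicates of a 100-measure panel
at n = 152 — sizes chosen to keep Monte-Carlo standard errors comfortably
below the tolerances they guard.

## Known limitations

* The Patlak estimator inherits the usual small positive-window bias when
  $t^*$ is close to free-compartment equilibration; the bias is
  monotone-decreasing in $t^*$ (asserted in tests) but not corrected.
* Storey's bootstrap π₀ variant is not implemented; only the smoother.
* The OGTT response is a fixed-shape parametric curve scaled by relative
  insulin sensitivity — adequate for index arithmetic and directionality,
  not a physiological glucose–insulin model.
* Logistic Wald intervals can misbehave near separation; the Firth
  fallback bounds the damage but profile intervals are not offered.
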