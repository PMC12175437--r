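---
title: "Models and methods behind hfpefcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hfpefcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfpefcmr)
```

`hfpefcmr` quantifies four families of CMR-derived markers used to
discriminate HFpEF in obese/diabetic cohorts — myocardial perfusion, diffuse
fibrosis (ECV), left atrial mechanics, and the statistics chain that links
them to the clinical outcome — together with a synthetic-data module that
generates every input from known ground truth. This vignette describes the
models, the parameters that matter, the numerical decisions, and what the
synthetic validation does and does not establish.

## Dual-bolus Fermi-constrained deconvolution

A dilute pre-bolus (0.00375 mmol/kg gadolinium) is used to measure the
arterial input function (AIF) without T1 saturation, and a main bolus
(0.0375 mmol/kg) drives tissue enhancement; the AIF is rescaled by the
concentration ratio of the two boluses (`dose_scaling_factor()`, 10). The
measured tissue curve is modelled as the causal discrete convolution of the
rescaled AIF with a tissue impulse response constrained to the Fermi form

$$R(t) = \frac{A}{\exp\!\big((t-\mu)/k\big) + 1},$$

whose parameters are estimated by damped (Levenberg–Marquardt) nonlinear
least squares (`minpack.lm::nls.lm`). Myocardial blood flow is the initial
response value $R(0)$, and the perfusion reserve is the stress/rest MBF
ratio. Signal is assumed proportional to contrast concentration over the
fitted range — the premise of the dual-bolus design — and the
signal-to-flow conversion constant is an explicit argument
(`unit_conversion`, default 1 signal unit per mL/g/min, appropriate for
synthetic work).

**Preprocessing.** The first-pass window runs from bolus onset to the first
local minimum after the global peak (the valley before recirculation), with
ties broken toward the earliest sample; a monotone tail means the window
runs to the last sample. Onset is declared where the curve exceeds the
baseline mean by 5 baseline SDs, and then refined by walking back along a
smoothed copy to the point where the curve leaves the baseline band —
without the refinement a noisy baseline dates the onset several samples
late, which matters greatly (below). The peak/valley search also runs on a
smoothed copy (`detect_width`, default 5 samples) so that single-sample
noise dips do not truncate the window; the returned values are always the
raw ones. Smoothing is a centred moving average of odd width
(`smooth_width`, default 3). Its edges are handled asymmetrically on
purpose: the start is zero-padded, because a baseline-subtracted first-pass
curve truly vanishes before onset, while the end replicates the last
sample. Both preprocessed curves keep `(smooth_width − 1)/2` leading
baseline samples: a centred smoother leaks post-onset signal backward in
time, and the causal convolution in the model can only reproduce that leak
if those samples are part of the fitted grid. With these conventions the
noiseless round trip through the full pipeline recovers MBF to better than
0.1% (in practice ~1e-9 relative), which the test suite asserts across a
grid of Fermi shapes.

**Registration.** Temporal registration is an integer-sample shift aligning
the two detected onsets (sub-sample registration is out of scope). This is
the single most delicate step of the method: with 1-s sampling and typical
first-pass kinetics, a one-sample misregistration alone biases MBF by tens
of percent, because the fit compensates an apparent arrival shift with the
initial response value. The Monte-Carlo noise benchmark in the test suite
(Gaussian noise at 5% of tissue peak, 200 replicates, median absolute MBF
error below 10%) therefore perturbs the *preprocessed* tissue curve — it
measures the noise robustness of the deconvolution itself. End-to-end, with
noise injected before extraction, the error budget is dominated by
onset-detection jitter amplified through integer registration; this is a
genuine property of integer-shift registration, not of the optimizer, and
is the main caveat for applying the pipeline to low-SNR curves.

**Fitting.** Initialisation is `A = peak(tissue)/∫aif`, `μ = 0.25·T`,
`k = 0.1·T` for window length `T`; bounds are `A ≥ 0`, `0 ≤ μ ≤ T`,
`k ≥ dt/10`. Convergence is declared at relative parameter change below
1e-8 or the gradient criterion (`ptol = 1e-8`, `gtol = 1e-10`); hitting
`max_iter` (200) returns the fit flagged `converged = FALSE` with a
warning. A null tissue curve fits to `A → 0`, i.e. zero flow. The test
suite also cross-checks the optimizer against an exhaustive grid search on
16-sample toys: the residual sum of squares is quadratic in `A`, so the
oracle profiles `A` in closed form and grids `(μ, k)` at 0.01 resolution —
equivalent to the full three-parameter grid evaluated at the `A`-optimum.

## Extracellular volume fraction

$$\mathrm{ECV} = (1-\mathrm{HCT})\,
\frac{1/T1_{\text{myo,post}} - 1/T1_{\text{myo,native}}}
     {1/T1_{\text{blood,post}} - 1/T1_{\text{blood,native}}}$$

ECV is stored as a fraction and rendered as percent in reports. Validation
rejects non-positive T1s, hematocrit outside (0, 1), post-contrast T1
exceeding native T1, and a non-positive blood relaxation-rate change ("no
blood contrast effect"). Values outside 15–60% trigger a warning, not an
error — the plausibility gate is deliberately soft because no hard
physiologic cut-off exists. The synthetic generator inverts the equation
for the post-contrast myocardial T1, so `compute_ecv()` on a generated
panel returns the target exactly (the suite asserts 1e-12 relative), and
the equation is invariant under a common rescaling of all four T1s. Visit
averaging (both for ECV and all other repeated measurements) is the
arithmetic mean of available visits.

## Left atrial mechanics

Volumes use the biplane area–length formula
$V = \tfrac{8}{3\pi}\,A_{2ch}A_{4ch}/L$ (mm³ → mL), with the length taken
as the mean of the two view lengths; Simpson's rule is out of scope. Strain
is Lagrangian length strain referenced to LV end-diastole,
$\varepsilon(t) = 100\,(L(t)-L_{ref})/L_{ref}$, so it is unit-free and
independent of absolute atrial size. The phasic decomposition follows the
standard feature-tracking convention: reservoir = curve maximum, booster =
value at the pre-atrial-contraction frame, conduit = reservoir − booster,
which makes `reservoir = conduit + booster` an identity that the code
asserts on every output. A pre-A frame earlier than the strain peak is
physiologically inverted timing and warns. The reference-frame convention
(LV end-diastole rather than atrial minimum) was an open choice; it is the
dominant convention in feature-tracking CMR and keeps strain zero at the
volumetric reference. Frames are 1-based inside R and 0-based in trajectory
files, converted at the I/O boundary.

The trajectory generator builds a smooth periodic length curve from cosine
segments between four control points (reference length at end-diastole, the
reservoir peak at 40% of the cycle, the pre-A value at 80%, and back).
Cosine easing is monotone between control points, so the curve maximum is
exactly the reservoir control point and recovery of the phasic strains is
exact by construction; a 100-draw random sweep in the suite bounds recovery
at 0.5% absolute.

## Cohort statistics

The statistics stage works on a subject-level table obtained by averaging
all available visits. Group comparisons use classical one-way ANOVA
(`stats::aov`/`lm`) with Tukey–Kramer post hoc tests (`stats::TukeyHSD`);
the degenerate zero-within-variance case is handled explicitly (p = 1 at
equal means, p = 0 otherwise). Categorical rows use Pearson's chi-squared
without continuity correction. Correlations are Pearson product-moment with
a t-based two-sided p; skewed positive biomarkers (Pentraxin-3) enter on
the natural-log scale.

Logistic discrimination of HFpEF uses maximum-likelihood `glm` fits, odds
ratios per unit with Wald 95% CIs (profile CIs offer little at n = 35 and
Wald matches conventional reporting), and covariate adjustment for age, sex
(binary indicator) and BMI. Complete or quasi-complete separation — a real
hazard in 35-subject fits — is detected (via the fitted-probability
warning, or a coefficient/SE above 10) and flagged with a warning rather
than silently reported or auto-penalised: a separated fit has a divergent
MLE whose odds ratio carries no information. Where replicate simulations
are averaged (as in the acceptance script), separated fits are excluded
from the mean for the same reason. NT-proBNP is generated in the cohort but
deliberately left out of the default predictor set, since it defines the
HFpEF group.

ROC analysis uses `pROC` (empirical curve, trapezoid AUC, DeLong CI by
default with a bootstrap flag); the operating point maximises the Youden
index with ties broken toward higher specificity, a tie-break that matters
because physiologically interdependent LA parameters can produce identical
classifications at small n. Test–retest reliability is ICC(2,1) — two-way
random effects, absolute agreement, single measurement — computed from the
two-way ANOVA mean squares with the McGraw–Wong F-based confidence interval
and Cicchetti's interpretation bands (< 0.40 poor, 0.40–0.59 fair,
0.60–0.74 good, ≥ 0.75 excellent). Absolute agreement is the right flavour
here because a systematic day effect should count against reliability; the
suite checks that a pure additive visit shift lowers ICC(2,1) below the
consistency correlation, and that a hand-computed 4×2 table reproduces the
closed form exactly. The sensitivity analysis re-runs a supplied analysis
on the subset without arrhythmia history and fails loudly if a whole group
would vanish.

## The synthetic-data module

The generator defines the study conditions and is itself tested code:

* **AIF**: a peak-normalised gamma-variate (baseline + amplitude at
  `onset + αβ`), chosen because the measured AIF of the study is not
  public and a parametric stand-in with interpretable amplitude is needed.
  Defaults (onset 10 s, α = 3, β = 2 s, 1-s sampling over 60 s) give a
  first-pass bolus of realistic width for 3 T perfusion imaging.
* **Tissue**: the forward convolution model with the Fermi response scaled
  so `R(0)` equals the prescribed MBF, plus i.i.d. Gaussian noise. The
  study does not state the noise level of measured curves, so `noise_sd`
  is config-exposed and not asserted as study-faithful.
* **T1 panels**: anchors (myocardium 1200 ms native; blood 1800/350 ms
  native/post) are physiologic 3 T values; the post-contrast myocardial T1
  is solved from the target ECV.
* **Cohorts**: three groups (6/16/13 by default) with the reported group
  means/SDs for demographics, CMR indices and biomarkers; Pentraxin-3 is
  log-normal with moment matching (the study reports it as skewed and
  log-transforms it, naming no distribution); biomarkers are kept inside
  their assay reportable ranges (Galectin-3 3.13–100, Pentraxin-3
  0.094–192, IL1RL1 1.6–200 ng/mL) by truncation-resampling rather than
  clipping, to avoid boundary atoms. Continuous imaging variables are
  *not* truncated: they follow the reported normals faithfully, which
  means rare draws can be unphysical (a negative strain) — the pipeline's
  measurement stages clamp such values to the physical domain before
  synthesising signals. Variables are drawn independently within subject,
  so cross-variable identities that hold in real data (reservoir = conduit
  + booster per subject) hold only in expectation at the cohort level.
* **Replicates**: day-1/day-8 values are subject latent + visit noise,
  with within-subject variance `between_sd²(1 − ICC)/ICC` implied by the
  target reliability, and an optional systematic day-8 shift so that
  absolute-agreement and consistency ICCs separate. The suite checks
  empirical convergence to the target (|error| < 0.05 at n = 500). A
  consequence of this variance decomposition is that the *single-visit*
  SD of a retest variable exceeds the specified between-subject scale by
  the within-subject component; the specified scale is recovered in the
  visit-averaged latent, and exactly so as the reliability approaches 1.

Everything is deterministic given the seed; identical seeds give
byte-identical serialised output.

**What passing tests show — and don't.** Round-trip recovery on synthetic
data establishes internal consistency: the analysis inverts its own forward
model. It does not establish accuracy on scanner data, where the AIF family
is wrong in detail, noise is structured (motion, saturation, coil shading),
transit delays are real, and contours are drawn by humans. The
registration-sensitivity caveat above is the clearest instance: a method
that is exact under its own forward model can still be fragile to a
one-sample timing error.

## Numerical choices and problem sizes

Defaults live in function signatures and `pipeline_config()`: onset
threshold 5 baseline SDs; smoothing width 3; detection width 5; LM
tolerances `ptol` 1e-8 / `gtol` 1e-10, 200 iterations; ECV plausibility
gate 15–60%; two-sided tests at 0.05; natural logs throughout. The test
suite's simulation sizes — 200-replicate perfusion Monte-Carlo, 500-subject
reliability check, 2000 null cohorts for the ANOVA type-I error, 500
simulated cohorts per odds-ratio benchmark — were chosen as the smallest
sizes at which the Monte-Carlo error is comfortably below the tolerance
being asserted, and the whole suite runs in well under a minute.

## Known limitations

* One representative curve pair per subject and state; no pixel-wise or
  16-segment perfusion mapping, and no model-independent deconvolution.
* Integer-sample registration (see above); no transit-delay parameter.
* Scalar T1 inputs only — no MOLLI relaxometry or ROI handling.
* Contours/lengths are inputs; no image-based feature tracking.
* The cohort generator draws variables independently within subject; joint
  structure (correlations between strains and volumes) is not emulated.
* No multiple-testing correction beyond Tukey, matching the analysis it
  reimplements; at n = 35 the logistic and ROC estimates are fragile and
  the separation flag should be heeded.
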