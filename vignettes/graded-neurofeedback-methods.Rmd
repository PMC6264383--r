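---
title: "Models and methods behind gradnf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradnf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradnf)
```

# The experiment gradnf models

Graded real-time fMRI neurofeedback asks a participant not merely to
up-regulate a brain region, but to hit discrete target magnitudes of the BOLD
response. The paradigm gradnf implements trains kinesthetic motor imagery
against two regions of interest — the supplementary motor area (SMA), which
activates during imagery, and the hand area of primary motor cortex (M1),
which tends to deactivate — with a 15-segment thermometer display whose
*low* and *high* targets sit at 50% and 100% of each participant's
individually calibrated localizer response.

Because no subject-level data are deposited for this paradigm, gradnf pairs
the analysis chain with a synthetic-data generator whose default parameters
encode the study conditions: a 3T acquisition at TR = 1.55 s; neurofeedback
runs of 180 volumes tiling five 20-volume rest blocks around two *low* and
two *high* 20-volume task blocks (31 s each); a motor-execution localizer of
four 16-volume task blocks flanked by five rest blocks (24.8 s each); 17
subjects; five neurofeedback runs per target region with counterbalanced
region and level orders.

One printed protocol constant cannot be reconciled: the localizer's stated
total of 272 volumes does not match its stated block structure
(9 × 16 = 144). `build_localizer_run()` generates the described block
structure and exposes `pad_volumes` (default 0, appended as trailing rest)
rather than guessing where undescribed volumes sat.

# The generative model

`simulate_roi_run()` draws one region's ROI-mean series as

$$ y_t \;=\; B\,\Big(1 + \textstyle\sum_c \tfrac{\mathrm{PSC}_c}{100}\,
   (x_c * h)_t\Big) \;+\; \beta_d\, t \;+\; \varepsilon_t, $$

with raw-unit baseline $B$ (default 1000, an arbitrary scanner scale chosen
so percent changes are well conditioned), per-condition boxcars $x_c$,
a double-gamma hemodynamic kernel $h$, a linear drift $\beta_d$ (default
0.01 raw units/volume), and stationary AR(1) Gaussian noise
$\varepsilon_t$ (default marginal SD 5, lag-1 correlation 0.3). Noise is
generated at the ROI level; voxelwise noise and spatial smoothing are
deliberately out of scope because every analysis stage operates on ROI
means.

**Kernel normalization.** The double-gamma kernel (peak delay 6 s, mode at
5 s, undershoot delay 16 s, undershoot ratio 1/6, 32 s support) is sampled
on the TR grid and scaled to **unit sum**, so the response to a sustained
block plateaus at exactly the regressor amplitude. This is the calibration
that makes the simulated plateau percent signal change equal the generative
`psc_true`, ties the online thermometer to the offline estimates, and makes
the localizer task beta directly interpretable as a plateau amplitude. A
unit-peak option exists for users who want the conventional display
normalization; nothing downstream depends on it because the same kernel is
used for generation and analysis.

**Default effect structure.** SMA responds positively with a high-minus-low
difference of 0.087 PSC (the group mean difference the paradigm is designed
to detect), M1 deactivates by 0.15 PSC at both levels, and the
motor-execution localizer drives M1 at 1.48 and SMA at 1.10 PSC — the group
localizer values that also calibrate the informed priors. The low/high SMA
amplitudes (0.25/0.337) are set so responses stay in a physiologically
sensible sub-percent range; only their difference is consequential for the
level inference. Between-subject variability perturbs every true PSC entry
with independent Gaussian noise (default SD 0.10 PSC).

**Physiology.** End-tidal CO2 and heart-rate traces are simulated at TR
resolution as a subject-typical mean (38 mmHg, 65 bpm) plus a slow AR(1)
fluctuation (lag-1 0.95; SD 1 mmHg / 2 bpm) plus a task-locked component.
The default couplings (−0.18 mmHg, −0.20 bpm) were chosen once so that the
group-level Fisher-z correlations with the task predictor land in the small
negative range the paradigm reports, i.e. the confound analysis exercises a
realistic weak-coupling regime rather than a caricature. Continuous-time
physiological recording, respiration volume, and trace-specific hemodynamic
kernels are not modelled; both traces are convolved with the same canonical
kernel in the analysis.

# The online feedback computation

The engine replays the real-time computation causally, volume by volume:

* at each rest-to-task transition the **baseline** becomes the median of the
  last 10 TRs of the completed rest block;
* each task volume emits $\mathrm{PSC}_{NF} =
  (\mathit{val}-\mathit{baseline}) \times 100 / \mathit{baseline}$ with
  *val* the mean of the last three acquired volumes;
* thermometer segments are $\mathrm{PSC}_{NF}$ divided by 10% of the
  region's localizer PSC, rounded, and clamped to $[0, 15]$; targets sit at
  segments 5 (*low*) and 10 (*high*);
* rest volumes emit no feedback.

Two conventions were genuinely open and are configurable:

* **Rounding.** Only the clamping is specified. The default rounds the
  continuous segment value to the nearest integer, half away from zero
  (`round_half_up`); `rounding = "floor"` gives the "segment fills only when
  fully earned" display convention.
* **Window at block onset.** The default (`window = "straddle"`) lets the
  3-volume moving window at a task block's first two volumes include
  trailing rest volumes, which is what a causal online system sees;
  `"restart"` restricts the window to values acquired since block onset.

A design consequence worth knowing: because runs begin with a 20-volume rest
block, the 3-volume window always has three samples by the first task
volume.

# The offline GLM

The neurofeedback design matrix contains an intercept, an HRF-convolved
boxcar over all task blocks, a parametric level regressor coded
**+1/2 on high and −1/2 on low blocks** on the same convolved support (so
its coefficient is directly the high-minus-low amplitude difference), and
one unconvolved indicator per task block spanning the 10 pre-onset volumes,
mirroring the online baseline window. No drift term is included — the
counterbalanced level orders are what protects the level contrast from the
(simulated and real) scanner drift, and the package's counterbalancing
guarantees the low-first/high-first run counts differ by at most one per
region, with the odd run's direction alternating between regions within
subject. The localizer model is intercept + convolved task + mean-centred
linear drift.

The pre-onset predictors are implemented as one indicator **per task block**
rather than one shared regressor; with four task blocks per run either
reading of "separate pre-onset baseline period predictors" is
rank-admissible, and the per-block version nests the shared one.

**Prewhitening** is iterated Cochrane–Orcutt: starting at $\rho = 0$, each
pass estimates the lag-1 autocorrelation of the current whitened residuals,
accumulates it into $\rho$, and refits on quasi-differenced data (first
observation scaled by $\sqrt{1-\rho^2}$). Three passes are the default: the
single-pass estimate is noticeably attenuated by the projection onto this
rich design (about −0.05 at $\rho = 0.4$, 180 volumes), and iterating to the
fixed point where whitened residuals are serially uncorrelated removes most
of that attenuation at the cost of two extra least-squares solves.

Percent signal change mirrors the online definition: the level response is
$\hat\beta_{task} \pm \tfrac12 \hat\beta_{level}$, the baseline is the
intercept plus the mean of the pre-onset coefficients, and PSC is their
ratio × 100. For the localizer the baseline is the intercept alone. Both
are invariant to rescaling the raw series, and on noiseless runs they
recover the generative values exactly; the online block average is lower
than the offline estimate because the hemodynamic ramp dilutes the block
mean, so the online/offline consistency check compares plateau volumes
(last 5 of each block) and holds within 5%.

# Group inference

Per subject, region, condition (*active* = feedback came from that region)
and level, the **median** PSC across runs feeds a fully within-subject
2 × 2 ANOVA (level × condition) fit with `stats::aov()` `Error()` strata,
so each effect is tested against its own subject-by-effect interaction.
Omega squared uses
$\hat\omega^2 = (SS_{eff} - df_{eff}\,MS_{err}) / (SS_{total} +
MS_{subjects})$, clipped at 0 — the standard within-subject estimator; the
exact variant used by point-and-click software is unpublished, which is why
the package prints the formula it uses rather than mimicking a black box.
For a two-level within factor the main-effect F equals the squared paired t
on the cell means, and the suite pins that identity to 1e-8.

Directional hypotheses follow the paradigm: M1 tests are one-sided *less*
(deactivation), the SMA level test one-sided *greater* (high > low). Paired
and one-sample t-tests are delegated to `stats::t.test()` and augmented with
the paired effect size $d = t/\sqrt{n}$.

**Informed Bayes factors.** The directed Bayes factor integrates the
noncentral-t likelihood over a half-normal prior on the standardized effect
$\delta$, truncated to the hypothesized direction:

$$ \mathrm{BF} = \frac{\int_0^{\infty} f_{nct}\!\big(t \mid \delta\sqrt{n},\,
   n-1\big)\, \tfrac{2}{\sigma}\varphi(\delta/\sigma)\, d\delta}
   {f_{nct}(t \mid 0,\, n-1)}. $$

The prior scale $\sigma$ is a fixed fraction of the group localizer PSC —
75% of the M1 value (1.48 → 1.11) for deactivation tests, 50% of the SMA
value (1.10 → 0.55) for the level test, echoing the 50% *low* target.
Integration substitutes $\delta = \sigma u$ so the mass is well scaled for
any prior width, and runs adaptive quadrature at relative tolerance 1e-6; a
brute-force Riemann sum over a fine $\delta$ grid serves as the independent
oracle in the tests (agreement within 1e-4). The implementation reproduces
the directed Bayes factors for the two M1 deactivation tests to within 0.1%
from their printed t statistics; for the SMA level test the printed t and
printed Bayes factor are mutually inconsistent under any prior in this
family (the printed BF corresponds to t ≈ 2.91, not 3.006), and the package
reports the value implied by the stated inputs.

**Physiological confounds.** Per run, the demeaned trace is convolved with
the hemodynamic kernel and Pearson-correlated with the convolved task
predictor; demeaning before convolution avoids a spurious onset-ramp
correlation that the raw-mean convolution would inject. Correlations are
Fisher-z transformed *before* averaging across runs, tested against zero per
region × trace with one-sample t-tests — two-sided by default, since the
observed directions are part of what is being tested — and
Benjamini–Hochberg corrected across the four combinations
(`stats::p.adjust`). Both Bonferroni-style reasoning (via one-sided tests)
and FDR are available because the inference layer mixes the two in
different places.

# Numerical and testing choices

* **Determinism.** Every stochastic stage takes an explicit seed; cohort
  stages derive per-subject and per-run seeds from a single root via a
  documented 32-bit fold (`child_seed()`), so any run can be regenerated in
  isolation. Library calls never disturb the caller's RNG stream.
* **Degenerate inputs.** Zero-variance differences raise errors rather than
  returning NaN t statistics; an ANOVA stratum whose effect variance is
  numerically zero reports F = 0, p = 1 ("no trend") instead of 0/0; a
  perfect GLM fit short-circuits the autocorrelation estimate to 0; constant
  physiological traces are dropped with a warning.
* **Problem sizes.** The Monte-Carlo properties run at sizes chosen to make
  their expectations sharp but cheap: AR(1) recovery at 10,000 samples
  (±0.05), GLM rho recovery over 300 replicate runs, unbiasedness of PSC
  recovery over 120 counterbalanced run pairs, and the type-I error of the
  level test over 1000 replicate null cohorts of 6 subjects with one run
  per region — the nominal-rate property does not depend on cohort size, so
  small cohorts are simulated through the full
  simulate → GLM → median → ANOVA path.
* **What passing tests do not show.** The generator draws Gaussian AR(1)
  noise on ROI means under an exactly known hemodynamic kernel. Real data
  add motion, kernel mismatch, non-stationary physiology-coupled noise, and
  voxel-selection effects; recovering the generative parameters here
  validates the arithmetic and the inferential identities, not robustness
  to those violations.

# Worked example

```{r, eval = FALSE}
report <- run_full_study(study_config(n_subjects = 17, seed = 42))
print(report)
report$physio
```

# Known limitations

* The analysis operates exclusively on ROI-mean series; voxel selection,
  motion correction and smoothing are out of scope by design.
* The hemodynamic kernel family is fixed (double-gamma); region- or
  trace-specific kernels are not implemented.
* Feedback-display latency and behavioural delay are not modelled; the
  engine emits per-TR states.
* The drift model is linear only; slow nonlinear scanner drift is not
  simulated.
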