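---
title: "Methods: from gas traces to sex-stratified response tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gas traces to sex-stratified response tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calorest)
library(dplyr)
```

`calorest` implements the full analysis chain of a paired caloric-restriction
(CR) experiment in a small nocturnal mammal (~100 g, long-day photoperiod):
six females and six males, each measured first under a control ration (CTL)
and again after a 60% ration cut, with open-flow respirometry, an
extracellular-flux mito-stress assay on cultured fibroblasts, urinary and
blood biomarker panels, and qPCR-based mitochondrial DNA quantification. This
vignette explains the models and procedures, the tunable parameters and their
defaults, what the synthetic-cohort generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open.

## Respirometry

Gas exchange is computed per timestamp from a pull-mode, flow-through system
with a water-vapour-scrubbed excurrent stream:

$$\dot V O_2 = \frac{FR_i\left[(F_iO_2 - F_e'O_2) - F_e'O_2\,(F_e'CO_2 - F_iCO_2)\right]}{(1 - F_e'O_2)\; m}$$

$$\dot V CO_2 = \frac{FR_i\left[(F_e'CO_2 - F_iCO_2) - F_e'CO_2\,(F_iO_2 - F_e'O_2)\right]}{(1 - F_e'CO_2)\; m}$$

with $FR_i$ the incurrent flow (mL h^-1^, STP-corrected upstream by the
instrument) and $m$ the body mass in kg, so both rates are mass-specific
(mL kg^-1^ h^-1^). Two conventions deserve note:

* **Sign orientation.** The CO~2~ equation is written
  excurrent-minus-incurrent so that net CO~2~ production by the animal is
  positive; the mirrored ordering sometimes seen in print yields negative
  values under the same physiology.
* **Shift structure.** VO~2~ depends on the CO~2~ fractions only through
  their difference, so a common additive offset in the CO~2~ channel cancels
  exactly in VO~2~ (but not in VCO~2~, which carries $F_e'CO_2$ alone in both
  the interference term and the denominator). The tests assert this algebra.

RER is the element-wise ratio VCO~2~/VO~2~; values outside the physiological
[0.7, 1.0] band (pure lipid to pure carbohydrate oxidation) are flagged, not
clipped, and timestamps with zero VO~2~ carry an explicit undefined marker.
Energy expenditure uses the oxycaloric form

$$EE = (3.815 + 1.232\,\mathrm{RER}) \cdot \dot VO_2\,[\mathrm{L\,kg^{-1}h^{-1}}] \cdot m\,[\mathrm{kg}] \quad [\mathrm{kcal\,h^{-1}}]$$

The unit contract matters: the pipeline carries VO~2~ in mL kg^-1^ h^-1^ and
the EE formula converts to L kg^-1^ h^-1^ internally — only that pairing
yields the ~1 kcal h^-1^ magnitudes expected for a 100 g animal, and a
unit-sanity guard warns when EE falls outside (0.01, 100) kcal h^-1^ for a
50–150 g subject.

Day/night aggregation uses unweighted sample means within each photoperiod
phase (default: lights off 17:00, lights on 03:00, i.e. 14 h light). Means
are unweighted because the instrument's multiplexing gaps are modest and no
time-weighting convention is defensible without the raw duty cycle; the
weighted recombination of phase means still reproduces the whole-trace mean
exactly, which is tested.

## Circadian extrema by changepoint segmentation

Daily maxima and minima are not raw extremes (too noise-sensitive at a 10-min
cadence) but plateau means found by segmentation: an exact optimal partition
under a Gaussian change-in-mean cost with a linear per-changepoint penalty,
solved with the PELT pruned dynamic program. Choices, all configurable:

* **Penalty** `3 * log(n)` per cycle — an MBIC-flavoured default strict
  enough not to shatter a 144-sample day into noise segments.
* **Cost normalization** divides the RSS cost by a noise-variance estimate so
  the penalty has a stable meaning across variables with different units. The
  estimator is the *robust* first-difference form
  $\hat\sigma = \mathrm{mad}(\Delta x)/\sqrt 2$: a plain
  $\mathrm{var}(\Delta x)/2$ is inflated by the handful of genuine level
  shifts and can mask a small night peak sitting on a large day/night step.
* **Minimum segment length** 3 samples (30 min), below which a "plateau" is
  indistinguishable from a transient.
* **Pruning under a minimum segment length** must be delayed: a candidate
  dominated at position $s$ is provably dispensable only from position
  $s + \ell_{\min}$ onward, because for nearer positions the dominating path
  would need an over-short segment. The implementation keeps dominated
  candidates alive for $\ell_{\min}-1$ extra steps; an exhaustive-search
  oracle over hundreds of random series verifies exact equivalence.

The daily maximum (`Max`) is the highest segment mean among segments
overlapping the *night* window and the minimum (`Min`) the lowest among
segments overlapping the *day* window — the layout used for a nocturnal
species whose activity peak is dark-phase. `hMax`/`hMin` are the clock times
of the first in-window sample of the winning segment ("the time at which the
change is achieved"); equal-mean ties go to the earliest segment. Multi-day
recordings are split into 24 h cycles anchored at lights-off, each cycle is
segmented independently, and values are averaged arithmetically while clock
times are averaged circularly.

Clock times live on the 24 h circle: $\theta = 2\pi\,t/1440$. The circular
mean is the resultant direction of unit vectors, with
$SD = \sqrt{-2\ln \bar R}$ converted to minutes; a near-zero resultant
(uniformly spread times) yields an explicit undefined marker. Note the
circular mean equals the ordinary mean only for tightly clustered times —
for wide asymmetric spreads they differ by minutes, which is why summary
times are reported at minute resolution and the equivalence is only asserted
on clusters. CTL→CR time shifts are signed shortest arcs in (−720, 720]
minutes, negative for phase advances.

## Mito-stress metrics

Per well, with three measurement cycles per protocol phase:

* **OxCR** (oxidative coupling rate) = 100 · (mean baseline OCR − min
  post-oligomycin OCR) / mean baseline OCR;
* **MtRC** (mitochondrial reserve capacity) = 100 · (max post-FCCP OCR −
  mean baseline OCR) / mean baseline OCR;
* **GlcP** (glycolytic potential) = 100 · (mean post-FCCP ECAR − mean
  baseline ECAR) / mean baseline ECAR.

The min/max-versus-mean asymmetry between stressed OCR and stressed ECAR is
kept exactly as the assay defines it. All metrics are percentages of the
well's own baseline, which cancels cell-count bias — they are invariant to
rescaling a whole well, and that invariance is tested. Wells are normalized
first and averaged second within a sample; wells failing QC (missing phase,
nonpositive baseline) are excluded with a logged reason, and a sample with no
valid well is reported missing, never zero. A rotenone/antimycin phase is
accepted and ignored.

The **metabolic potential** is the displacement from the basal phenotype
(100%, 100%) to the stressed phenotype on (OCR%, ECAR%) axes. The assay
literature describes it as a two-dimensional "gap" without a scalar formula;
we retain the raw displacement and also report its Euclidean magnitude
$\sqrt{\mathrm{MtRC}^2 + \mathrm{GlcP}^2}$. The choice is consequential: under
restriction the glycolytic component typically rises while the oxidative
reserve falls, so the Euclidean magnitude can *increase* even when the
oxidative reserve contracts — a scalarization-dependent verdict, which is why
the components are always exported alongside the magnitude.

## Biomarkers

Urinary analytes (cortisol, 8-OHdG, 17β-estradiol, testosterone) are divided
by creatinine (mg mL^-1^) to correct urine dilution; nonpositive creatinine
produces an explicit missing value. The mtDNA/nuDNA ratio uses the
efficiency-power ΔCt model $E^{\overline{Ct}_{nu} - \overline{Ct}_{mt}}$
with replicate means over up to two triplicate runs per target and default
$E = 2$ (perfect doubling); $E$ is configurable and a standard-curve mode is
deliberately out of scope. Glycaemia follows the bedside repeat rule: a first
reading inside the normal range stands; an out-of-range first reading
triggers repeats and the mean of all readings is reported, flagged. The
normal range defaults to (50, 150) mg dL^-1^ — an explicit, documented
convention, since "normal range" has no universal bounds for this species.

## Cohort statistics

The response statistic is the per-individual percent change
$V = 100\,(x_{CR} - x_{CTL})/x_{CTL}$, summarised per sex as mean ± SD. The
mean of per-individual changes and the change of group means agree only when
all individuals share the same baseline; both are available, and the report
uses the per-individual convention.

With n = 6 per sex, contrasts use **exact enumeration** rank tests rather
than asymptotic approximations or parametric mixed models: the paired CR
effect by the exact Wilcoxon signed-rank distribution over all $2^m$ sign
assignments (midranks for ties, zeros dropped, two-sided p doubled from the
smaller tail), and sex contrasts by the exact rank-sum distribution over all
$\binom{n_1+n_2}{n_1}$ arrangements. At these sample sizes full enumeration
is cheap and makes no distributional assumptions; the tests are verified
against independent brute-force enumerations for every size up to 8, and
against the reference distribution-free implementation on untied data.
Report annotations use the conventional ladder `***` < 0.001, `**` < 0.01,
`*` < 0.05, `°` < 0.1. No multiplicity correction is applied to the
correlation network or PCA descriptions; the report exposes raw p-values.

**Dixon's Q** screens each variable × sex × condition cell (n = 6) for a
single outlier at α = 0.05, using the gap/range variant recommended for the
sample size (r10 for n ≤ 7, r11 for 8–10, r22 for 11–13) against the
standard two-tailed critical table; both extremes are tested and the larger
ratio is the suspect.

**Correlation networks** pool CTL and CR rows within each sex and keep edges
with $|r| \ge 0.5$ (Pearson by default, Spearman available), retaining the
sign. **PCA** standardizes the animal-condition × variable matrix after
simple column-mean imputation (a deliberate simplification of iterative-PCA
imputation; with ~5% missingness from culture attrition the difference is
immaterial for the leading components), drops zero-variance columns with a
notice, and describes components by each variable's correlation with the
scores (with two-sided p) and each category's v-statistic
$v = (\bar x_{cat} - \bar x)/\sqrt{\tfrac{N-n}{N-1}\,\tfrac{\sigma^2}{n}}$.

## The synthetic cohort

No animal data ship with the package; a deterministic generator reproduces
the statistical structure the pipeline assumes, parameterised by the
published group means and SDs for every variable (body mass, biomarkers,
flux metrics, mtDNA/nuDNA ratios, and the day/night structure of VO~2~ and
RER including extrema values and clock times).

* **Paired design.** Each animal carries a latent level ($\rho = 0.7$
  between its CTL and CR values); within a condition the calorimetry profile
  parameters share a second latent factor ($\rho = 0.8$), which keeps
  night/day/peak/trough draws ordered. Ordering guards (peak above the night
  mean, trough below the day mean, positivity floors) repair the rare deep
  tail draw; they are part of the generative model, and the recorded ground
  truth is always the post-guard value.
* **Gas traces** are built by *inverting* the gas-exchange equations: target
  VO~2~ and RER circadian profiles are converted to excurrent fractions at
  fixed incurrent composition (20.95% O~2~, 0.04% CO~2~), flow
  (30 L h^-1^) and body mass, by a fixed-point solve that round-trips
  through the forward equations to machine precision. The circadian shape is
  a two-plateau square wave (night/day) with a 2 h peak plateau in the night
  window and a 2 h trough plateau in the day window — the simplest shape
  with unambiguous ground-truth extrema and transition times — optionally
  smoothed by a short circular moving-average ramp (default 3 samples).
  Plateau base levels are solved from the programmed phase means over the
  actual sample counts, so phase means are recovered exactly at zero noise;
  plateau starts sit at least 3 samples inside their window so every flanking
  segment is detectable at the minimum segment length. Measurement noise is
  multiplicative and per-sample (CV 5% on VO~2~, 2% on RER).
* **Flux plates** encode each sample's programmed OxCR/MtRC/GlcP exactly in
  the decisive statistics (baseline mean, oligomycin minimum, FCCP maximum,
  FCCP ECAR mean): cycle jitter (CV 2%) is injected orthogonally to those
  statistics — baseline noise is mean-centred, the non-extreme cycles are
  jittered away from the extreme — and each well carries a lognormal
  cell-count scale factor that the %-baseline metrics cancel by
  construction. A naive independent per-cycle noise would bias max-of-3 /
  min-of-3 statistics upward/downward by ~1.7% of their level, which for a
  300% reserve is a 5-point systematic error; the structured noise keeps
  programmed metrics recoverable while plates still look realistic. Optional
  well dropout emulates culture contamination.
* **qPCR** records place the nuclear target near Ct 25 and offset the
  mitochondrial target by $\log_E(\text{ratio})$, with mean-centred replicate
  jitter so the replicate-mean ratio is exactly the programmed one.
* **Biomarkers** draw from per-group normals, or moment-matched lognormals
  for right-skewed hormones (cortisol, testosterone, estradiol — their
  published SDs approach or exceed their means, which no positive-support
  normal can produce). Urinary raw values are reconstructed as
  normalized × creatinine with lognormal creatinine, so normalization
  round-trips. Out-of-range glycaemia draws get two repeat readings.

What the generator does **not** emulate: instrument drift and washout lag,
torpor bouts and thermoregulatory transients, multiplexing gaps, plate
background wells, assay-plate edge effects, or any mechanistic link between
the biomarker families (they are drawn independently given the group
structure). Passing round-trip tests therefore demonstrates that the
pipeline computes its defined quantities correctly under the assumed data
model — not that the model captures every feature of real traces.

## Problem sizes and verification

The test suite verifies, among others: equation agreement with independent
brute-force transcriptions on 1000 random inputs (1e-12 relative); PELT
equal to exhaustive-search dynamic programming on hundreds of random short
series; exact test p-values equal to independent enumerations for all group
sizes up to 8; noise-free cohort round-trips exact to 1e-9 (values) and to
the 10-min sampling interval (times); and, across 100 default-noise cohorts,
recovered per-group means within 2 SEM of the programmed targets for well
over 90% of variable × group cells. Default verification sizes (2–4
recording days, 100 seeds) were chosen so the whole suite runs in a few
minutes on one core while keeping Monte-Carlo error far below the asserted
margins.
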