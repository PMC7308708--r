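# calorest

Bioenergetics of caloric restriction, end to end: from raw open-flow
respirometry gas traces, extracellular-flux plate traces, qPCR Ct tables and
biomarker panels to a sex-stratified, paired response report.

The package is written for comparative physiologists running paired
food-restriction experiments in small mammals (the motivating design: six
females and six males of a ~100 g nocturnal primate, each its own control
across a two-week 60% ration cut under a 14 h photoperiod). Its core
computations:

* **Indirect calorimetry.** Per-timestamp mass-specific rates from
  incurrent/excurrent fractional gas concentrations in a pull-mode,
  scrubbed-stream system:

  VO₂ = FRᵢ[(FᵢO₂ − Fₑ′O₂) − Fₑ′O₂(Fₑ′CO₂ − FᵢCO₂)] / [(1 − Fₑ′O₂)·m]

  with the mirrored VCO₂ form oriented so CO₂ production is positive, RER =
  VCO₂/VO₂ (flagged outside [0.7, 1.0]), and energy expenditure
  EE = (3.815 + 1.232·RER)·VO₂[L·kg⁻¹·h⁻¹]·m[kg] in kcal·h⁻¹, plus
  unweighted day/night phase means.
* **Circadian extrema.** Changepoint segmentation (an exact PELT dynamic
  program under a Gaussian change-in-mean cost, penalty 3·log n, minimum
  segment 30 min) finds each day's maximum plateau in the night window and
  minimum plateau in the day window, with clock times summarised by circular
  statistics and CTL→CR shifts as signed shortest arcs.
* **Mito stress test.** Per-well OxCR, MtRC and GlcP as percentages of the
  well's own baseline OCR/ECAR (cancelling cell-count bias), the
  basal→stressed metabolic-potential displacement, and QC-aware triplicate
  aggregation.
* **Biomarkers.** Creatinine normalization of urinary analytes, the
  efficiency-power ΔCt mtDNA/nuDNA ratio, and the glycaemia repeat rule.
* **Cohort statistics.** Per-individual percent change V° = 100·(CR −
  CTL)/CTL with per-sex summaries; exact-enumeration Wilcoxon signed-rank
  and rank-sum contrasts (no asymptotics at n = 6); Dixon's Q outlier
  screening; signed correlation networks; PCA with variable correlations and
  category v-statistics.
* **Synthetic cohort.** A deterministic generator that reproduces the whole
  design — paired animals, circadian gas traces built by inverting the
  calorimetry equations, triplicate flux wells, replicated Cts, biomarker
  panels — with recorded ground truth, so the entire pipeline is testable
  without animal data.

## Worked example

```r
library(calorest)
library(dplyr)

cohort <- gen_cohort(cohort_design(seed = 42))      # 6F + 6M, CTL then CR
res    <- run_pipeline(run_config(seed = 42), cohort = cohort)

res$report |>
  filter(variable %in% c("body_mass", "rer_night", "oxcr")) |>
  transmute(variable,
    ctl_f = sprintf("%.2f ± %.2f", ctl_f_mean, ctl_f_sd),
    cr_f  = sprintf("%.2f ± %.2f", cr_f_mean,  cr_f_sd),
    v_f   = sprintf("%+.1f ± %.1f", v_f_mean, v_f_sd),
    v_m   = sprintf("%+.1f ± %.1f", v_m_mean, v_m_sd),
    sig_cr_f)
#>   variable        ctl_f         cr_f         v_f         v_m sig_cr_f
#>  body_mass 98.75 ± 3.28 83.40 ± 5.74 -15.6 ± 3.6 -12.9 ± 4.1        *
#>       oxcr 62.41 ± 5.78 68.91 ± 1.70 +11.0 ± 8.1  -6.6 ± 9.9        °
#>  rer_night  0.98 ± 0.08  0.89 ± 0.09  -9.1 ± 6.0  +0.5 ± 9.0        *
```

Read across a row: females entered at 98.75 ± 3.28 g and lost 15.6% of body
mass under restriction (males 12.9%), an exact paired signed-rank test
marking the within-sex effect at p < 0.05 (`*`). Nocturnal RER falls from
0.98 toward lipid oxidation in females, and the fibroblast oxidative
coupling rate rises ~11% in females while dipping in males — the
sex-by-treatment patterns the report is built to expose.

Single operations work on plain tibbles and chain with the pipe:

```r
vo2_rate(30000, 0.2095, 0.2000, 0.0004, 0.0100, 0.1)
#> [1] 2842.5      # mL O2 kg^-1 h^-1 for a 100 g animal at 30 L/h flow

cohort$gas_traces |>
  derive_metabolic_series() |>
  aggregate_by_phase()

exact_rank_sum(1:6, 7:12)$p.value
#> [1] 0.002164502  # 2 / choose(12, 6)
```

`plot_metabolic_series()`, `plot_polar_times()`, `plot_energy_phenotype()`
and `autoplot()` on a PCA result give the standard figures;
`tidy()`/`glance()` tidiers cover the fitted objects. A thin command-line
wrapper lives at `inst/scripts/run_pipeline.R`, and `write_config_template()`
emits a YAML config documenting every pipeline default.

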