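# dtiwmh

Simulation and analysis toolkit for a methodological question in diffusion
tensor imaging (DTI): **how much of a between-group difference in
tract-averaged MD/FA is driven by unequal white matter hyperintensity (WMH)
load rather than by disease-specific change in normal-appearing white
matter (NAWM)?**

WMH — FLAIR-bright small-vessel lesions common in the elderly — locally
raise mean diffusivity (MD) and lower fractional anisotropy (FA). If a
patient group carries more WMH than its control group, a tract-based DTI
comparison mixes two signals. `dtiwmh` builds the full chain needed to
study this on synthetic data with known ground truth, for methods
researchers and pipeline developers:

* **Phantoms** — tensor-field bundles (straight/arc), a ventricular region,
  and WMH-like lesions (elevated MD, reduced FA) placed preferentially
  near the ventricles; Rician-noise DWI simulation (b = 0 + 64 directions,
  2 mm isotropic by default).
* **Tensor model** — heteroscedasticity-corrected (weighted) linear least
  squares: OLS on log-signals, then a reweighted pass with weights equal to
  the squared predicted signals; eigenvalue maps of MD and FA.
* **Tractography** — deterministic FACT-style streamline tracking (FA
  threshold 0.2, turning-angle threshold 30°, bidirectional Euler, 1 mm
  steps).
* **Tract segmentation** — atlas-style AND-ROIs and 5-voxel dilated
  NOT-shells; tract means over unique visited voxels.
* **Cohort statistics** — WMH/ventricle load as % of intracranial volume;
  matched lower-load (≤ 0.5 %ICV) vs higher-load (≥ 1 %ICV) subgroups with
  pooled-variance t-tests and Cohen's
  *d* = (m₂ − m₁)/s_pooled; and nested regression per tract×metric:
  model 1 `metric ~ group + ventricle load`, model 2 adds WMH load, with
  standardized β, R², ΔR² and the R²-change F test.

A summary-level cohort generator (default n = 132 controls + 83 prodromal
AD) draws each tract metric as
`μ_t + γ·s_t·L + a_t·AD + b_v·VV + ε`, combining a WMH-load pathway
(susceptibility s_t: high for the superior longitudinal fasciculus, medium
for the dorsal cingulum, low for the corticospinal tract, none for the
ventral cingulum) with a disease-specific NAWM pathway — so adjustment
behavior can be validated against known generative truth.

## Worked example

Checking a published effect size from printed summaries (lower- vs
higher-load subgroups, n = 21 + 21, MD 0.73 ± 0.03 vs 0.79 ± 0.06 µm²/ms):

```r
library(dtiwmh)
cohens_d_pooled(0.73, 0.03, 21, 0.79, 0.06, 21)
#> [1] 1.264911
```

A full simulated analysis — cohort, covariate-matched WMH-load subgroups,
effect sizes, and WMH-adjusted nested regression:

```r
co    <- simulate_cohort(cohort_spec(seed = 42))
pairs <- match_subgroups(co)           # 21 matched lower/higher-load pairs
t2    <- run_table2(co, pairs)
subset(t2, metric == "MD", c(tract, mean_low, mean_high, cohens_d, p))
#>    tract mean_low mean_high cohens_d        p
#> 1   dc_r    0.746     0.749    0.091 7.70e-01
#> 3   dc_l    0.743     0.758    0.366 2.42e-01
#> 5   vc_r    0.711     0.699   -0.212 4.96e-01
#> 7   vc_l    0.722     0.699   -0.500 1.13e-01
#> 9  slf_r    0.757     0.825    1.941 1.85e-07
#> 11 slf_l    0.745     0.789    1.582 7.95e-06
#> 13 cst_r    0.707     0.714    0.107 7.31e-01
#> 15 cst_l    0.680     0.713    0.758 1.85e-02
```

Higher WMH load elevates MD most in the susceptible SLF, not at all in the
ventral cingulum — the generative susceptibility ordering surfaces as the
effect-size ranking. The nested regression then separates the pathways:

```r
t3 <- run_table3(co)
subset(t3, metric == "MD" & tract %in% c("slf_l", "vc_l"),
       c(tract, beta_group_m1, p_group_m1, beta_group_m2, beta_wmh_m2, delta_r2))
#>    tract beta_group_m1 p_group_m1 beta_group_m2 beta_wmh_m2 delta_r2
#> 7   vc_l          0.24    7.1e-04         0.201        0.11   0.0096
#> 11 slf_l          0.35    3.4e-07         0.014        0.91   0.7147
```

The SLF group effect (β = 0.35, unadjusted) vanishes once WMH load enters
the model (β = 0.014) while the WMH coefficient is large — the difference
was load-driven. The ventral-cingulum effect survives adjustment — a
genuine NAWM difference. `run_demo(seed, out_dir)` writes this analysis,
plus an image-level lesion mechanism check on twin phantoms, as TSV tables
with a JSON manifest.

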