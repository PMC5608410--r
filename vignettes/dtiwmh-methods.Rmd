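---
title: "Methods: simulating and adjusting for WMH load in tract-based DTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and adjusting for WMH load in tract-based DTI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

White matter hyperintensities (WMH) — T2/FLAIR-bright lesions attributed to
small-vessel disease — exhibit elevated mean diffusivity (MD) and reduced
fractional anisotropy (FA). When two groups differ in WMH load, a
tract-averaged DTI comparison can attribute lesion-driven signal to the
disease under study: differences in normal-appearing white matter (NAWM) and
differences in lesion load are conflated. `dtiwmh` provides a fully synthetic
test bench for this confound: image-level diffusion phantoms with known
tensor fields and lesions, the standard tract-analysis pipeline (tensor fit,
deterministic tractography, atlas-style ROI segmentation), WMH-load
quantification, and the two statistical designs used to separate the
pathways — a matched-subgroup contrast with Cohen's *d*, and nested
regression in which the group effect is estimated before and after adding
WMH load as a covariate, summarized by standardized coefficients and the
R²-change F test.

No clinical data ship with the package; every analysis runs on data the
package generates itself, with ground truth known by construction.

## Units and coordinate conventions

Diffusivities are in µm²/ms and b-values in ms/µm², so b = 1000 s/mm² is
stored as 1.0 and MD maps come out in the customary µm²/ms scale. Distances
are in mm. Voxel indices are 0-based; world coordinates follow a NIfTI-style
voxel-to-world affine; a voxel owns the half-open cube around its centre
(membership by rounding). These conventions are implemented once
(`vox_affine()`, `world_to_voxel()`, `containing_voxel()`) and used
everywhere.

## Tensor estimation

Per voxel, the log-signal is linear in the seven parameters
$(\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz})$ through the
design row $[1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z,
-2b g_y g_z]$. Taking logs distorts the noise variance by a factor
$1/S^2$, so `fit_wlls()` is heteroscedasticity-corrected: pass 1 solves
ordinary least squares on the logs; pass 2 re-solves each voxel with weights
equal to the squared pass-1 *predicted* signals. Exactly one reweighting
pass is the default (`weighting_passes = 1`); iterating further is possible
but changes nothing on noise-free data and little at SNR ≥ 20. On noise-free
data both passes solve a consistent system, so truth tensors are recovered
to numerical precision regardless of weights — the pipeline's strongest
self-check (observed agreement ~1e-14 on the default 40³ phantom).

Numerical choices: signals ≤ 0 (possible under magnitude noise) are clamped
to a machine-epsilon-scaled floor before the log; a voxel with more than
half its measurements clamped, or a non-finite solution, is marked invalid
rather than raising an error. Negative eigenvalues are clamped to zero for
MD/FA map computation only; raw eigenvalues are retained in the eigen
field. FA is defined 0 when all eigenvalues are 0.

## Tractography

`track_whole_brain()` is deterministic streamline tracking over the
principal eigenvector field: a seed in every voxel with FA ≥ 0.2 (the
threshold is a parameter), bidirectional fixed-step Euler integration
(default step 1 mm = half a voxel), step-to-step sign alignment of the
eigenvector, and stopping when the containing voxel leaves the volume or
falls below the FA threshold, when the turn between consecutive steps
exceeds 30°, or at a maximum length. Halves are concatenated; streamlines
shorter than 10 mm (configurable; no length filter is claimed by the
original pipeline, so this is an explicit default) are discarded.

**Direction sampling.** The default samples the principal direction of the
*containing voxel* (the classical fibre-assignment-by-continuous-tracking
scheme). A trilinear mode — interpolate the six tensor components, then
re-extract the principal eigenvector — is available via
`tracking_params(interpolation = "trilinear")`. Nearest-voxel is the default
deliberately: the turning-angle criterion is only meaningful if a sharp
fibre-direction change appears as a sharp turn. With trilinear sampling a
60° interface is rotated through in ≤30° increments across one voxel of
support, so the angle rule never fires and streamlines leak across
interfaces the threshold is supposed to block. With nearest-voxel sampling
the turn presents at full magnitude in a single step and propagation halts
at the interface, which the kink-phantom tests assert. Within coherent
bundles (the phantoms' straight and arc geometries) the two modes agree.

## Phantoms

`make_phantom()` builds an ellipsoidal "brain", a central box-shaped
"ventricular" region with CSF-like isotropic diffusivity (3.0 µm²/ms),
tube-shaped tract bundles (straight or arc) carrying NAWM eigenvalues
(default (1.4, 0.45, 0.45) µm²/ms → MD 0.77, FA 0.62; single-fibre voxels
are more anisotropic than the tract-averaged FA ≈ 0.44 typical of cohort
tables, which reflects partial voluming), and an isotropic background
(0.8 µm²/ms, FA 0 — so only bundles seed streamlines). Lesions carry
eigenvalues (1.6, 1.0, 0.85) µm²/ms (MD 1.15, FA 0.33) in the local fibre
frame — elevated MD, reduced FA, validated at spec construction — and are
placed as small blobs with centre probability proportional to
$\exp(-d/\tau)$ of the Chebyshev distance $d$ to the ventricular region
(τ = `lesion_site_bias`, default 4 voxels), emulating the periventricular
preference of real lesions without anatomy. The achieved lesion voxel count
is trimmed to the target exactly, and `lesion_within` can confine lesions
to named bundles for mechanism experiments.

`simulate_dwi()` evaluates $S = S_0 \exp(-b\, g^\top D g)$ for one b = 0
volume plus 64 directions (spherical Fibonacci point set) at 2 mm isotropic
resolution by default, then applies Rician noise $|S + n_1 + i n_2|$ with
$\sigma = \bar S_0 / \mathrm{SNR}_{b0}$ (default SNR 30, a typical DTI
acquisition); `snr_b0 = Inf` returns exact model signals.

What the phantoms do **not** emulate: anatomy, crossing fibres, partial
voluming, motion/eddy artefacts, spatially varying coil sensitivity, and
FLAIR image formation (lesions exist as masks, not segmented images).
Passing the image-level tests therefore demonstrates correctness of the
algorithms under their stated model, not robustness to real-data nuisances.

## Tract segmentation

Atlas labels are projected to the subject grid by nearest-neighbour
resampling through an invertible affine (`build_and_roi()`; in the synthetic
setting the transform is identity or a known affine — estimating nonlinear
warps is out of scope). The exclusion region is a shell: the tract mask
dilated by 5 voxels minus the tract (`build_not_shell()`). "Approximately
five voxels" is realized as 5 iterations of 26-connected dilation (a
Chebyshev ball, giving the exactly enumerable 11³ − 1 = 1330 single-voxel
shell); a Euclidean-ball dilation is available via `metric = "euclidean"`.
A streamline is retained iff it has ≥1 vertex in the AND-ROI and none in
the shell; exclusion removes whole streamlines (not truncation — an open
choice, resolved toward the simpler semantics). The tract mean of MD/FA is
taken over the set of *unique visited voxels*, not over vertices: it is
then invariant to seed density and duplicated streamlines. Manual tract
editing is replaced by a QC report (`tract_qc()`): counts plus a
visitation map, no automatic editing.

## Subject metrics and subgroups

WMH and ventricle volumes are voxel counts × voxel volume (ml), normalized
as percent of intracranial volume (`percent_of_icv()`). Load classes use
closed thresholds: lower ≤ 0.5 %ICV, higher ≥ 1 %ICV, intermediate
excluded. Fazekas grades are treated as commentary anchoring those
quantitative thresholds and are not implemented.

`match_subgroups()` pairs higher- with lower-load controls greedily by
standardized Euclidean distance over (age, MMSE, ventricle %ICV), within
exact sex × cardiovascular-disease strata where possible (relaxed when a
class runs out), keeping the `target_n = 21` closest pairs; the balance
report gives post-match Mann-Whitney p-values (continuous) and
two-proportion tests (binary).

## Cohort simulation

The summary-level generator draws, per subject, covariates matching typical
control / prodromal-AD cohort tables (group sizes 132/83; age ≈ 71.5 ± 5;
MMSE on 27–30 vs 24–30; gamma-distributed, hence right-skewed and
non-negative, WMH loads 0.70 ± 0.91 vs 1.17 ± 1.38 %ICV and ventricle loads
2.18 ± 1.00 vs 2.65 ± 1.20 %ICV), then per tract *t* and subject *j*:

$$\mathrm{MD}_{jt} = \mu_t + \gamma_{MD}\, s_t L_j + a_t\, \mathrm{AD}_j +
b_v (VV_j - \overline{VV}) + \varepsilon_{jt},$$

and analogously for FA. $L_j$ is WMH load (%ICV), $s_t \ge 0$ the tract's
susceptibility to WMH, $a_t$ a disease-specific NAWM effect, $VV_j$ the
ventricle load (atrophy proxy). Baseline means/SDs come from the lower-load
column of the matched-subgroup table; susceptibilities (SLF 1, dorsal
cingulum 0.35, corticospinal tract 0.2, ventral cingulum 0) and
$\gamma_{MD} = 0.04$ µm²/ms per %ICV are calibrated so the implied
matched-subgroup effect sizes reproduce the anchor ordering (SLF ≈ 1.25,
DC ≈ 0.6, CST ≈ 0.4, VC ≈ 0); $\gamma_{FA} = -0.02$. The per-tract lesion
overlap is not quantified in cohort tables, so the susceptibilities are
qualitative weights anchored to where WMH are anatomically common.

Two tiers are deliberate: image-level simulation for a few subjects (the
mechanism), summary-level simulation for full cohorts (the statistics) —
full image simulation of 215 subjects buys nothing for the statistical
questions.

Setting all of $\gamma$, $a_t$, $b_v$ to zero (`null_cohort_spec()`) makes
the groups exchangeable on tract metrics while covariates still differ;
this is the type-I-error bench: at n = 132+83, both the model-1 group test
and the model-2 WMH test hold their nominal 5% size (verified at 1000 and,
as a development cross-check, 5000 replicates).

## The confound-recovery scenario

`confound_scenario_spec()` encodes the central qualitative claim as a
testable pattern: make the SLF-analog group difference *purely*
WMH-mediated ($a_{SLF} = 0$, $s_{SLF} = 1$) and the VC-analog difference
*purely* NAWM-driven ($s_{VC} = 0$, $a_{VC} = 0.04$). Then, per replicate,
the nested table should show: SLF group effect significant in model 1 but
not model 2, with significant WMH coefficient and positive ΔR²; VC group
effect significant in both models.

A power note explains the scenario's amplified parameters. The model-1
significance of a purely mediated effect is bounded by the group separation
in load itself: with the default load distributions that ceiling is ≈85%
power, so a ≥90% joint detection rate is arithmetically out of reach no
matter how strong $\gamma$ is. The scenario therefore widens the load
separation (0.5 ± 0.5 vs 1.5 ± 1.0 %ICV) and sizes $a_{VC}$ at d ≈ 0.8 so
every component of the joint pattern has ≥98% power — except the model-2
SLF non-significance, which is a true null and caps at 95% by construction.
The expected joint rate is ≈0.93; the suite requires ≥0.90 over 200
replicates. The scenario validates the mechanism and the inference
machinery, not observed effect sizes.

## Statistics: implementation notes

* **Mann-Whitney U**: midranks for ties; exact two-sided p by full
  enumeration of group assignments when both groups have ≤ 8 observations
  (ties included); otherwise normal approximation with tie-corrected
  variance and continuity correction. Degenerate all-tied input returns
  p = 1 with a warning.
* **Cohen's d**: pooled-SD formula, sign = higher-load minus lower-load
  group mean; `cohens_d_pooled()` also accepts printed summary statistics,
  so published tables can be checked directly (0.73 ± 0.03 vs 0.79 ± 0.06
  at n = 21 + 21 gives d = 1.2649).
* **Standardized OLS**: *all* variables — outcome, continuous predictors
  and 0/1 dummies alike — are z-scored before an ordinary LS fit (the
  common statistics-package convention for standardized β of a binary
  predictor); collinear or constant predictors raise errors naming the
  columns.
* **ΔR² significance**: the nested-model F-change test,
  $F = (\Delta R^2/q)\,/\,((1-R^2_2)/(n-p_2-1))$ — the natural test where a
  published "ΔR² was significant" does not name one. Identical models give
  F = 0, p = 1.
* **Model covariates**: model 1 = group + ventricle %ICV; model 2 adds WMH
  %ICV. MMSE and amyloid ratio are *excluded* by default even when they
  differ between groups — both are definitionally entangled with the
  diagnosis (conditioning on them absorbs the group effect) — but can be
  added via `extra_covariates`.
* **Multiplicity**: none by default, matching exploratory practice;
  `p_adjust = "holm"` is available. α = 0.05 two-sided throughout.

## Problem sizes and determinism

Default test-bench sizes: 40³ voxels (2 mm) for the exactness phantom; a
30×24×24 grid for the tracking bundle; 1000 replicates for null
calibration; 200 for the confound-recovery scenario; 100–200 seeds for
matching/ordering properties. These sizes make the full suite run in a few
minutes while leaving Monte-Carlo bands comfortably inside the asserted
tolerances. Every random draw descends from an explicit seed through a
fixed child-seed derivation; identical seeds give byte-identical outputs
(`run_demo()` asserts this).

## Known limitations

* Geometry is schematic: no gyral anatomy, no crossing fibres, no partial
  voluming; FA inside bundles is single-fibre-high rather than
  tract-average-realistic.
* Registration is assumed known (identity/affine); nonlinear warp
  estimation and motion/eddy correction are out of scope.
* The summary-level generator is linear with Gaussian residuals; real
  tract metrics have heavier tails and spatially correlated noise.
* Lesion masks are inputs or simulations; FLAIR segmentation is not
  modelled, so segmentation error in WMH load is absent.
* The matched-subgroup selector is greedy 1:1 nearest-neighbour, adequate
  for simulated cohorts; it is not an optimal-matching implementation.
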