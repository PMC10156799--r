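# fontanflow

Quantitative hemodynamics of the Fontan total cavopulmonary connection
(TCPC) from 4D flow MRI, for imaging scientists and cardiovascular
researchers who need the full measurement chain — phase-contrast
preprocessing, vessel geometry, pathline-based caval flow distribution,
voxel-wise flow energetics, and small-cohort longitudinal statistics — as
reusable, tested R code. Because patient 4D flow data are not publicly
depositable, the package ships a synthetic phantom generator with analytic
ground truth for every stage, and its entire verification is oracle-based.

## What it computes

In a Fontan circulation the IVC and SVC drain directly into the left and
right pulmonary arteries. From a time-resolved velocity field `v(x, t)`
on a voxel grid, the package measures:

- **Caval flow distribution** — pathlines are emitted at 30 per cm³ from
  the caval volumes and advected through the field (RK4, trilinear
  interpolation); with `N_LPA`, `N_RPA` the first-crossing counts at the
  arterial entrance planes,

  `FD_LPA = N_LPA / (N_LPA + N_RPA)`,

  and flow is *unequal* when `FD_LPA < 30%` or `> 70%` (strict).
- **Voxel-wise maps** (after truncation to a common cardiac-cycle
  fraction and 1 mm isotropic resampling): peak velocity (regional 98th
  percentile), stasis (% of frames below 0.1 m/s), kinetic energy
  `KE = ½ ρ V_vox |v|²` summed over frames, and viscous energy loss from
  the dissipation function

  `φ_v = ½ Σᵢⱼ [ (∂vⱼ/∂xᵢ + ∂vᵢ/∂xⱼ) − ⅔ (∇·V) δᵢⱼ ]²`,

  as a rate `μ V_vox φ_v` (W), time-integrated (`EL_tot`, J) and
  time-averaged (`EL_mean`, W), with ρ = 1060 kg/m³ and μ = 3.2 cP.
- **Longitudinal statistics** — annualized changes, exact small-sample
  rank-sum / signed-rank tests, Spearman correlation with permutation
  p-values, OLS, and Monte-Carlo post-hoc power.

The phantom generator provides uniform flow, solid-body rotation and a
Poiseuille tube (closed-form KE and dissipation), plus a streamfunction
TCPC junction whose caval flow split is exact by construction, with MRI
corruption models (noise, eddy-current phase offsets, venc aliasing).

## Worked example

Recover a prescribed 80/20 caval split from pathline counting:

```r
library(fontanflow)

ph <- make_tcpc_phantom(split_ivc_to_lpa = 0.8, pulsatility = 0.3,
                        n_frames = 12)
em <- seed_emitters(ph$regions, "IVC", density = 30, seed = 2)
pl <- trace_pathlines(ph$series, em,
                      entrance_planes = ph$regions$boundary_planes[c("lpa", "rpa")])
flow_distribution(count_crossings(pl,
                                  ph$regions$boundary_planes$lpa,
                                  ph$regions$boundary_planes$rpa))
#> flow distribution: LPA 261 / RPA 64  (LPA fraction 0.803, unequal; validity 1.00)
```

The phantom's ground truth is 0.8; counting 325 pathlines recovers 0.803,
and the strict 30/70 rule classifies the case as unequal. The
energetics are checked the same way, against the Poiseuille closed form:

```r
pz <- make_poiseuille_tube(1, radius = 8, length = 60, mean_velocity = 0.3)
maps <- hemodynamic_maps(pz$series)
sum(maps$el_mean) / pz$truth$analytic_el_rate - 1   # total dissipation error
#> [1] 0.026
```

i.e. the voxel-wise dissipation total lands within 2.6% of the analytic
`8 μ L Q² / (π R⁴)` at 1 mm resolution.

The `analysis/` directory holds the numbered workflow drivers
(`01_make_phantoms.R` … `06_longitudinal_stats.R`); each is a thin
narrative script over the package functions and writes its tables under
`results/`. The methods vignette
(`vignettes/fontan-4dflow-methods.Rmd`) documents the models, parameter
choices and numerical conventions.

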