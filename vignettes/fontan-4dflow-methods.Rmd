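---
title: "Quantifying TCPC hemodynamics from 4D flow MRI: models, phantoms and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TCPC hemodynamics from 4D flow MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontanflow)
```

## The problem

In the Fontan circulation, systemic venous return is routed passively
through the total cavopulmonary connection (TCPC): the inferior and
superior vena cava (IVC, SVC) join directly onto the left and right
pulmonary arteries (LPA, RPA), with no sub-pulmonary ventricle. Because
the circuit is passive, fluid-mechanical inefficiency — kinetic energy
that is dissipated by viscous shear instead of delivered to the lungs,
regions of stasis, unbalanced caval flow routing — is believed to
contribute to the long-term attrition of these patients. Time-resolved
three-directional phase-contrast MRI ("4D flow") measures the velocity
field `v(x, t)` over the whole connection through the cardiac cycle, and
from that single acquisition every quantity this package computes can be
derived.

`fontanflow` implements the full measurement chain — phase-contrast
preprocessing, lumen geometry, pathline-based caval flow distribution,
voxel-wise flow energetics, and the longitudinal statistics used to follow
the metrics over years — together with a synthetic phantom generator that
provides analytic ground truth for every stage. Patient data for studies
of this kind are not publicly depositable, so the package's verification
strategy is entirely phantom- and oracle-based: each stage is tested
against closed forms, enumeration, or constructions whose answer is known
exactly.

## The quantities

All fields live on a regular voxel grid (spacing in mm, velocity in m/s).
Blood is treated as Newtonian and incompressible with density
$\rho = 1060\ \mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 3.2\ \mathrm{cP}$.

**Caval flow distribution.** Massless particles are released at 30
emitters per cm$^3$ from the segmented IVC (and SVC) volume and advected
through the time-resolved field. With $N_\mathrm{LPA}$ and
$N_\mathrm{RPA}$ the numbers of pathlines whose *first* entrance-plane
crossing is the LPA or RPA plane,

$$\mathrm{FD}_\mathrm{LPA} = \frac{N_\mathrm{LPA}}{N_\mathrm{LPA}+N_\mathrm{RPA}},
\qquad \mathrm{FD}_\mathrm{RPA} = 1 - \mathrm{FD}_\mathrm{LPA}.$$

Unequal distribution is defined by the strict rule
$\mathrm{FD}_\mathrm{LPA} < 0.30$ or $> 0.70$; the boundary values count
as equal. Because many pathlines terminate before reaching either artery,
the fraction of pathlines with more than 3 time points that reach a plane
is reported alongside (the validity fraction).

**Voxel-wise maps.** After truncating all series to the shortest covered
cycle fraction and resampling to 1 mm isotropic resolution:

* *peak velocity* — per-voxel maximum speed over frames; regions report
  the 98th percentile (linear interpolation between order statistics);
* *stasis* — percentage of frames with speed below 0.1 m/s; regions
  report the mean;
* *kinetic energy* — $\tfrac12\,\rho\,V_\mathrm{vox}\,|v|^2$ per voxel
  and frame, summed over frames (J);
* *viscous energy loss* — the dissipation function
  $$\phi_v = \tfrac12 \sum_{i}\sum_{j}
  \Big[\Big(\frac{\partial v_j}{\partial x_i} +
  \frac{\partial v_i}{\partial x_j}\Big) -
  \tfrac23 (\nabla\!\cdot\!V)\,\delta_{ij}\Big]^2,$$
  converted to an energy-loss rate $\mu V_\mathrm{vox} \phi_v$ (W).
  `el_tot` integrates the rate over the covered cycle (trapezoidal rule);
  `el_mean` is its frame average. The $\tfrac23\,\nabla\!\cdot\!V$ term is
  retained even though the continuum field is divergence-free, because
  measured fields are not.

## The phantom generator: what it emulates, and what it does not

The generator is first-class, tested code; its defaults are the study
conditions every verification below runs under.

**Analytic fields.** Uniform flow (any dissipation estimate must vanish),
solid-body rotation (antisymmetric velocity gradient, so $\phi_v \equiv 0$
and pathlines are exact circles of period $2\pi/\omega$), and a steady
Poiseuille tube with radius $R = 8$ mm, length 60 mm and mean velocity
0.3 m/s, whose total dissipation rate $8\mu L Q^2/(\pi R^4)$ and kinetic
energy $(2\pi/3)\rho \bar V^2 R^2 L$ are closed forms.

**The TCPC junction.** A planar cross — IVC entering from below, SVC from
above, LPA leaving left, RPA right, channels 16 mm wide — extruded over a
20 mm slab. The in-plane velocity is derived from a streamfunction
$\psi$, so the continuous field is exactly divergence-free and streamlines
are level sets of $\psi$. Limb profiles are plug flow, which makes three
quantities coincide exactly: the flux fraction of IVC flow leaving through
the LPA, the $\psi$-level fraction, and the fraction of uniformly seeded
IVC particles whose streamline exits the LPA. The junction interior is a
transfinite (Coons) patch blending the four limb profiles with a
smoothstep weight. In such a 4-way junction the flow split is governed by
the $\psi$ value at the interior stagnation point, so a plain blend does
not realise a requested split; the generator therefore adds a closed-form,
compactly supported correction that pins a stagnation point at the
junction centre with $\psi^\ast = (1 - f)\,q_\mathrm{IVC}$, which realises
the requested split $f$ exactly in the continuous field. An independent
fine-step streamline tracer over the analytic $\psi$ confirms the
partition in the test suite.

Voxel values are obtained by *discrete* central differencing of $\psi$, so
the sampled in-plane field has identically zero discrete divergence at
interior voxels. The voxel lattice is offset half a voxel from the
geometry's symmetry axes: centres never sit exactly on walls or on the
mirror plane, and the discrete lumen is exactly mirror-symmetric.

Pulsatility is a global sinusoidal scale factor
$v(t) = v_0\,(1 + p \sin 2\pi t/T)$; it changes speeds but not
streamlines, which is deliberate — the flow-split ground truth survives
modulation. Real caval waveforms (respiratory variation, Womersley
profiles, secondary helical flow) are *not* emulated, so passing the
phantom tests demonstrates correctness of the numerics, not robustness to
physiological complexity. Phantom dimensions give caval emitter volumes of
about 10–11 cm$^3$, in the range of segmented caval volumes in adolescent
and adult Fontan patients.

**Corruption models.** `corrupt()` adds i.i.d. Gaussian velocity noise,
per-component spatial polynomial phase offsets evaluated in world mm
coordinates, and venc wrap-around
$v \mapsto v - 2\,\mathrm{venc}\cdot\mathrm{round}(v/2\,\mathrm{venc})$,
all behind one explicit seed (default 1).

**The Poiseuille lattice offset.** The tube axis is placed at a fixed
generic sub-voxel offset (spacing/6, spacing/3) from the voxel lattice.
With the axis exactly on voxel centres and $R$ a multiple of the spacing,
lattice points fall exactly on the lumen boundary circle and the discrete
volume integrals stop converging first-order — a measure-zero degenerate
alignment that no acquisition would produce. Any generic offset restores
the documented convergence; the default is fixed once and used everywhere.

## Preprocessing conventions

The in-house tools used in practice for phase-contrast preprocessing do
not document their exact models, so this package fixes explicit,
deterministic substitutes:

* **Static tissue** = temporal standard deviation of every component
  below a threshold (default 0.01 m/s — raise it above the noise floor
  for noisy data) *and* time-mean magnitude above the 5th percentile.
* **Phase offsets** are fitted per component as an order-1 or order-2
  spatial polynomial to the *time-averaged* velocity over static voxels
  (eddy-current offsets are temporally static) and subtracted everywhere.
  On noiseless data the fit is exact least squares, recovered to machine
  precision, and re-correction is idempotent.
* **Anti-aliasing** compares each value with the median of its
  6-neighbourhood and shifts by the multiple of $2\,\mathrm{venc}$ that
  brings it closest, sweeping to a fixed point (cap 10). This is chosen
  over 4D Laplacian unwrapping for determinism and testability. Its
  capture range is a real limitation: a wrapped voxel is only corrected
  when four of its six neighbours are unwrapped, so small pockets (a
  fast-jet core a voxel or two across) are restored exactly, while
  extended wrapped slabs — e.g. a whole lumen wrapped along its axis —
  are left untouched. Acquisitions should set the venc above the bulk
  velocity; the corrector is for localized jets.
* **PC-MRA** is the time-mean of magnitude-weighted speed, a common
  convention where the operative definition is not otherwise fixed; with
  the package's Otsu threshold it segments the phantom lumen with Dice
  above 0.98.

## Geometry

Centerlines are minimal-cost paths on the voxel adjacency graph
(26-connectivity) with edge cost equal to step length divided by the
squared distance-to-wall, which pins the path to the medial ridge — a
deterministic stand-in for skeletonisation (no 3-D thinning is available
in the R package stack used). Endpoints snap to the *nearest* in-mask
voxel (depth breaks near-ties only): at open vessel ends the distance
transform is dominated by the artificial end cap, and a depth-first snap
would drift the endpoint inward, shortening the centerline. Paths are
smoothed with a window-5 moving average and resampled at 1 mm.

Region partitions cut a one-voxel slab on the distal side of each
boundary plane (within the plane's radius, so distant limbs are never
severed), label the connected components by their seeds, and then assign
the cut-band voxels to neighbouring labels with ties resolved towards the
connection — a conservative-connection convention; the band is one voxel
thick, so limb summaries shift by at most that band.

## Pathline integration

Classical RK4 on `dx/dt = V(x, t)` with trilinear spatial interpolation
and linear temporal interpolation between frames; time wraps periodically
over the cardiac cycle (default horizon 3 cycles, default step
frame_duration/5). Termination: leaving the lumen, speed below
$10^{-3}$ m/s for 5 consecutive steps, crossing an entrance plane, or the
horizon. Emitters are released once at $t = 0$; per-frame release is out
of scope, and the single-release convention is what the split-recovery
tolerance of ±0.05 is stated for. On solid-body rotation — where
trilinear interpolation is exact because the field is linear in position —
the orbit-closure error falls by a factor of about 16 per halving of the
step, the RK4 signature; on the phantom, halving the step moves recovered
splits by well under 0.01.

A note on counting statistics: a jittered-grid seeding at 30 emitters per
cm$^3$ in a ~10 cm$^3$ source yields roughly 300 pathlines, so a single
seeding realisation of the symmetric phantom carries a standard error of
about 0.015 in the recovered fraction. Verifications of the symmetric
case therefore average the estimate over several independent emitter
seedings (each at the study density); per-split recovery checks use a
single realisation against the looser ±0.05 band.

## Numerical choices in the maps

* **Gradients** are central differences at interior lumen voxels;
  where only one along-axis neighbour is in the lumen, a second-order
  one-sided (3-point) stencil is used, falling back to 2-point only for
  single-voxel spans. Out-of-mask neighbours are excluded rather than
  read as zero, so wall voxels never see artificial shear against the
  background. The 3-point one-sided stencil is exact for the parabolic
  Poiseuille profile, which is what brings the total dissipation within
  5% of the closed form at 1 mm.
* **Per-voxel sums vs. the continuum**: with a binary lumen mask the
  discrete volume integral carries an O(h) partial-volume error
  concentrated at the wall (where $\phi_v$ peaks); at 4/2/1 mm on the
  R = 8 mm tube the total-dissipation error falls monotonically
  (≈14%, 6%, 3%) and the kinetic-energy error likewise (≈6%, 3%, 2%).
* **Time integral**: trapezoid over frame onset times; the covered
  duration is (n_frames − 1) frame durations (one frame duration for a
  single frame), and `el_mean` is the plain frame average — for steady
  fields the identity `el_mean × duration = el_tot` holds exactly and is
  asserted in the tests.
* **Percentile**: linear interpolation between order statistics
  (`quantile` type 7).
* **Regional KE** averages the time-summed map over the region (sum over
  time first, then mean over ROI); the alternative reading
  (time-average first) differs only by the fixed factor n_frames and is
  not used.

## Longitudinal statistics

Changes are annualized: (follow-up − baseline) / follow-up years. With
cohorts of ten subjects, asymptotic null distributions are dubious, so
rank-sum and signed-rank tests use exact small-sample distributions
(enumeration-equivalent) up to n = 10 per group / n = 15 pairs, with the
tie-corrected normal approximation beyond. Spearman correlation uses
average ranks and a permutation p-value (exact for n ≤ 8, else $10^5$
seeded permutations). Simple OLS supplies slope and $R^2$ for the
association between annualized changes in energy loss and peak velocity.
No multiple-testing correction is applied, matching common practice in
small descriptive cohorts; the number of tests run is reported so a
reader can apply one. Post-hoc power is Monte-Carlo under a normal model
with plug-in moments — a documented convention, chosen because no
standard power model exists for these nonparametric tests; its numbers
are not comparable across software that assumes different models.

The cohort simulator produces a *stable* cohort by default (zero annual
drift, 8% measurement noise, follow-up 4.4 ± 2.6 years floored at 0.6),
so the stability tests are expected non-significant; induced drifts are
detected (see `analysis/06_longitudinal_stats.R`).

## Problem sizes used in the shipped analyses and tests

Phantoms are generated at 1 mm isotropic spacing on grids of roughly
90 × 90 × 31 voxels with 2–12 cardiac frames; emitter counts are ~320 per
caval source; null-calibration runs use 2000 simulated datasets. These
sizes make every stage's error measurable against its oracle while the
whole verification cycle stays interactive on a laptop-class machine.

## Known limitations

* The junction phantom is planar and orthogonal; curved, offset or
  patient-specific TCPC geometries are out of scope, as are CFD solvers.
* Sinusoidal pulsatility is a stand-in — nothing here claims fidelity to
  patient caval waveforms.
* The anti-aliasing capture range excludes extended wrapped regions (see
  above).
* Passing phantom recovery does not bound errors on patient data, where
  segmentation error, noise and unresolved near-wall shear dominate;
  the resolution-dependence of the energetics (the 4/2/1 mm table) is a
  reminder that absolute energy-loss values are acquisition-dependent.
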