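---
title: "Quantitative T1 mapping for gadolinium retention: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T1 mapping for gadolinium retention: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1retain)
```

## The scientific problem

Gadolinium-based contrast agents shorten the longitudinal relaxation time T1
of the tissue they occupy. If gadolinium is retained in brain tissue weeks
after an administration, a prospective T1-mapping protocol should see it: T1
measured before and four weeks after exposure should be shorter in regions
that retain the agent. `t1retain` implements that computational chain for a
3D inversion-recovery Look-Locker acquisition, together with the synthetic
cohort machinery needed to exercise and validate every stage without access
to patient data, and a small pharmacokinetic module that puts intravenous
and intrathecal dosing on the same concentration scale.

The chain is: simulate (or load) 4-D magnitude Look-Locker data →
voxelwise T1 estimation (polarity recovery, three-parameter fit,
Look-Locker correction, validity clamping) → rigid co-registration of the
two sessions via synthetic T1-weighted images, with region volumes as an
alignment diagnostic → region-wise longitudinal statistics (paired and
one-sample t-tests on percent change, a ±3% safety margin, age
correlations, forest-plot data).

## Signal model

During a Look-Locker readout the magnetization recovers with an apparent
time constant $T_1^*$ shorter than the true $T_1$, because the train of
small-flip-angle pulses (angle $\alpha$, one per phase interval $\tau$)
keeps tipping magnetization away:

$$\frac{1}{T_1^*} = \frac{1}{T_1} - \frac{\ln \cos \alpha}{\tau}.$$

The sampled signed signal follows the classic three-parameter model

$$S(\mathrm{TI}) = A - B\,e^{-\mathrm{TI}/T_1^*},$$

and the acquisition records only $|S|$: early samples, where magnetization
is still negative, appear flipped. The default protocol is the scanner
protocol the pipeline targets: first inversion time 19.6 ms, 12 phases
spaced 400.3 ms, cycle duration 4815 ms. Two timing caveats are deliberate:
the printed cycle duration is slightly shorter than twelve full intervals
and is treated as metadata only, and the readout excitation angle is not
part of the printed protocol — the 8° default is an assumption (it is the
flip angle of the accompanying 3D T1-weighted scan) and is exposed
prominently in `llProtocol()`.

The simulator uses $A = m_0$ and $B = m_0(1+\epsilon)$ with inversion
efficiency $\epsilon \in (0,1]$; the three-parameter fit treats $A$, $B$,
$T_1^*$ as free, so imperfect inversion is absorbed by $B$ and never biases
$T_1$. Noise is applied to the magnitude, either Gaussian (floored at zero)
or proper two-channel Rician; `noiseSd` is a fraction of $m_0$.

## Fitting

`fitCurve()` tries every polarity index $k \in \{0,\dots,n\}$ (negate the
first $k$ samples), fits each signed candidate by Levenberg-Marquardt, and
keeps the pair with the smallest residual norm; equal residuals resolve to
the smaller index, which makes the estimator deterministic. Starting
values follow a zero-crossing heuristic ($A_0$ = last magnitude,
$B_0 = A_0$ + first magnitude, $T_1^{*}{}_0$ from the TI at the magnitude
minimum, floored at 50 ms). Because a cheap heuristic start can
occasionally strand the optimizer in a local minimum, the fit is guarded by
a coarse grid search over $T_1^*$ — the model is linear in $A, B$ at fixed
$T_1^*$, so each grid point is an exact least-squares solve — and restarts
from the grid optimum when that is better. Convergence tolerances are
relative 1e-8 on parameters with at most 200 iterations; non-convergence is
flagged in the result, never raised.

Two Look-Locker corrections are implemented. The primary one inverts the
flip-angle relation above. The classical alternative
$T_1 = T_1^*(B/A - 1)$ is available via `correction = "b_over_a"` for
cross-checks; which variant an external reconstruction used is generally
not documented, so both are kept.

Fitted T1 outside (0, 10000) ms is treated as artifact. The choice here is
*exclusion* (a validity mask consumed by all region statistics), not value
clipping: artifacts are unrealistic values to be discarded, and clipping
them to the boundary would bias region means.

## The phantom and what it does (not) emulate

`makePhantom()` builds a label volume plus ground-truth T1: an outer
cortex-like shell around a white-matter-like core with embedded deep-gray
blobs (or an axial slab stack), on a grid with 1.39 × 1.39 × 4 mm voxels by
default. The region dictionary carries the pre-contrast region means and
between-subject SDs of a 76-participant 3T cohort (cortex 1479.3 ± 61.2 ms,
subcortical white matter 1082.1 ± 46.7 ms, basal ganglia 1274.3 ± 55.0 ms,
pallidum 1030.6 ± 60.6 ms, and ten lobar sub-regions), so simulated
cohorts have the same statistical structure the analysis assumes. Voxel
noise within a region is Gaussian truncated at 1 ms, 60 ms SD by default
(a typical single-tissue spread at 3T). Gadolinium exposure enters through
relaxation-rate additivity, $1/T_1^{post} = 1/T_1^{pre} + r_1 C$, with a
default relaxivity $r_1 = 4.0\ \mathrm{L\,mmol^{-1}\,s^{-1}}$ (typical for
a macrocyclic agent at 3T; the value is configurable because no single
published number applies universally).

Two optional realism switches exist because registration needs them:
`shadingAmp` adds a smooth world-coordinate T1 modulation (emulating
cortical-depth gradients and receive-field shading), and `psfBlurVox`
band-limits the scene with a Gaussian point-spread function. Both default
to 0 so that the arithmetic invariants (region voxels exactly at the
dictionary mean in the zero-noise case) hold exactly.

The phantom is deliberately not anatomical: no surfaces, no partial-volume
mixture model at borders, no posterior fossa. Passing tests therefore
demonstrate the correctness of the estimation and inference machinery
under the cohort's statistical structure — not robustness to segmentation
error or anatomy-specific artifacts.

## Registration

Sessions are aligned by 6-DOF rigid registration of synthetic T1-weighted
images (intensity a strictly decreasing function of fitted T1, so white
matter is bright as in a clinical scan), minimizing mean squared intensity
difference with a three-level Gaussian pyramid (6, 3, 0 mm by default),
deterministic multi-start Nelder-Mead with self-restarts, and a decimated
grid at the coarsest level. Two numerical choices matter and were found the
hard way:

* **Halfway-space metric.** The moving image has typically been resampled
  once already, the fixed image not; comparing them directly makes the
  interpolation blur asymmetric and biases the optimum near sharp edges.
  The cost therefore resamples the moving image by half the candidate
  transform and the fixed image by the inverse half, so both are
  interpolated exactly once per evaluation, plus a small constant
  compensation blur (0.41 voxel sigma) on the fixed side for the
  resampling the moving volume has already been through.
* **Band-limited scenes.** Registering a phantom whose edges are perfect
  steps is unrepresentative of acquired data and biases out-of-plane
  rotations on anisotropic (4 mm slice) grids; registration experiments
  should switch on `psfBlurVox` (≈ 0.7) and `shadingAmp` (≈ 0.06), which
  brings recovery of a 3°/2 mm misalignment to about 0.1° / 0.1 mm, well
  inside the 0.5°/0.5 mm tolerance used in the tests.

Labels are brought across sessions by nearest-neighbour resampling, which
never invents labels but does change voxel counts of thin structures —
each output voxel carries one label. Between-session region-volume change
is therefore mostly a by-product of resampling and co-registration, which
is exactly why the pipeline reports it as an alignment diagnostic rather
than biology. One simplification relative to a full surface-based stream:
the session-2 synthetic T1w is registered directly to session 1's,
collapsing the intermediate hop via a separately acquired anatomical scan;
an external label volume plus transform can be supplied instead.

## Longitudinal statistics

The primary per-region statistic is the **mean of per-subject percent
changes**, tested against zero with a two-tailed one-sample t-test; the
session difference is additionally tested with a paired t-test. The
percent change of the session means (ratio of means) is reported as a
diagnostic column — the two aggregations agree only when all subjects
share the same pre value, and conflating them changes the third decimal of
cohort-level summaries. A mean percent change within the pre-defined
safety margin (±3%, boundary inclusive — conservative toward the null) is
classified `within_margin`; shortening beyond it, the signature retention
would produce, is `exceeds_margin_shortening`. No multiple-testing
correction is applied across the 14 regions in the primary output, matching
standard practice for this design; a Holm-adjusted column is emitted as
clearly-secondary extra output. Age associations use Pearson correlation
with the two-tailed t transform. Normality is assumed throughout;
significance is 0.05 two-tailed. No between-session physiologic drift is
modelled (the generator's null is exactly zero true change), because no
diurnal T1 model is available to calibrate one.

The regional cohort simulator (`simulateCohortMeans()`) is the scalable
counterpart of the voxel chain: subject region means are drawn from the
between-subject distribution and the 4-week value perturbed on the percent
scale with each region's observed percent-change SD (2.9% in subcortical
white matter up to 6.9% in pallidum). Large simulation studies (10,000
cohorts of n = 76 for the type-I error of the margin procedure; 2,000
cohorts for retention sensitivity at 0.05 mM cortical gadolinium) run at
this level; the voxelwise chain is validated separately end to end at
small n (the test suite uses 3-4 subjects on 24 × 24 × 16 grids), because a
voxel-level rerun of every cohort would add nothing statistically — the
voxel chain's output *is* region means, whose distribution the regional
simulator reproduces by construction.

## Pharmacokinetic comparison

The PK module quantifies the Discussion-level question: how does the brain
load of a standard intravenous dose compare with an intrathecal one?
Plasma concentration after IV injection follows a dose-scaled
biexponential (default amplitudes 3.99 and 4.78 kg/L, decay rates 0.144
and 0.0111 min⁻¹ — the classic plasma parameters for an extracellular
gadolinium agent; an optional gamma-variate first-pass bolus is available
but off by default because the uptake integral is dominated by the slow
tail). Transfer into tissue uses a leakage coefficient
$K_i = 10^{-3}\ \mathrm{min^{-1}}$ (a hippocampal literature value), by
default bidirectional, $dC_t/dt = K_i (C_p - C_t)$; the unidirectional
(Patlak) limit $dC_t/dt = K_i C_p$ has the closed form peak
$K_i D (a_1/m_1 + a_2/m_2)$, which serves as the analytic oracle for the
fixed-step 4th-order Runge-Kutta integrator (0.1 min steps over 72 h).
With these defaults the computed IV brain peak is ≈ 0.04 mM against the
0.1 mM literature estimate for a 0.5 mmol intrathecal dose — the same
order of magnitude, which is the only claim this module is built to
support; the assembled route-comparison ledger (`table5Report()`) marks
every literature cell as an input and only the IV brain peak as computed.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; the workflow fans a
single global seed out to per-subject seeds drawn once from the manifest,
so any subject can be regenerated in isolation, and reruns of the same
configuration produce byte-identical reports (checksummed in the run
manifest). Test problem sizes were chosen as the smallest that exercise
each property: 24-32 voxel grids for phantoms, 200 curves for the
polarity-oracle comparison, 500 replicates per T1 for noise robustness,
10,000 regional cohorts for test size. Known limitations: no multi-
component T1 or B1 mapping, no saturation modelling of long-T1 voxels
(cycle time 4815 ms is short for CSF-contaminated voxels), no deformable
registration, no CSF/glymphatic compartment in the PK model, and
order-of-magnitude-only PK claims.
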