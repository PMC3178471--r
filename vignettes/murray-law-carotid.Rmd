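---
title: "Testing the principle of minimum work at arterial bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the principle of minimum work at arterial bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifex)
```

## The model

Murray's principle of minimum work balances two costs for a vessel
segment of radius $r$, length $l$ carrying steady flow $Q$: the
Poiseuille pumping power $8 \mu l Q^2 / (\pi r^4)$ and a metabolic cost
$b \pi r^2 l$ proportional to the blood volume being maintained. The
total is strictly convex in $r$ with minimum at

$$ r^{*} = \left( \frac{16 \mu Q^2}{\pi^2 b} \right)^{1/6},
   \qquad\text{so}\qquad Q \propto r^{*3}. $$

With flow conserved at a bifurcation ($Q_{CCA} = Q_{ICA} + Q_{ECA}$),
cubing-and-summing gives the cube law $r_{CCA}^3 = r_{ICA}^3 +
r_{ECA}^3$. More generally one asks which exponent $n$ satisfies

$$ r_{CCA}^n = r_{ICA}^n + r_{ECA}^n \tag{power law} $$

for measured radii: $n = 2$ preserves cross-sectional area (constant
mean velocity through the junction), $n = 3$ is the energy optimum, and
$n < 2$ implies accelerating flow out of the bifurcation.
`murray_bifurcation()` closes the theoretical loop numerically: it
minimizes the segment cost per branch by 1-D search (Brent bracketing
plus Newton polishing of the stationarity condition, agreeing with the
closed form to $10^{-8}$ relative) and recovers $n = 3$ from the optimal
triple via the root finder, for any flows and parameters. The default
viscosity is $3.5\times 10^{-3}$ Pa s; the metabolic coefficient
defaults to $10^3\,\mathrm{W\,m^{-3}}$ (Murray's order of magnitude for
blood), and cancels out of the exponent.

Murray's assumptions — steady laminar flow, straight rigid tubes — are
what motivate the tortuosity filter below.

## Estimating the exponent from data

For one bifurcation, the power law in ratio form
$a^n + b^n = 1$ with $a = r_{ICA}/r_{CCA}$, $b = r_{ECA}/r_{CCA}$ has a
strictly decreasing left side when $a, b < 1$, so the root is unique;
`solve_exponent()` brackets it in $[0.05, 50]$ and solves with
`stats::uniroot` (Brent/zeroin) to $10^{-10}$. When a daughter is at
least as large as the parent no positive root exists and the record is
flagged `no_root` rather than forced; such records are excluded from
means with a logged count, since there is no defensible value to impute.

For a cohort, `fit_cohort_exponent()` estimates a single $n$ by
Gauss-Newton iteration with step halving (start $n_0 = 2$, step
tolerance $10^{-8}$, at most 50 iterations). Two model forms are
tagged, because nonlinear least squares answers depend on where the
residual is taken:

* `parent-response`: $r_{CCA,i} = (r_{ICA,i}^n + r_{ECA,i}^n)^{1/n} +
  \varepsilon_i$, residuals in mm. Large bifurcations carry more
  weight; this is the form cross-checked against `stats::nls` in the
  test suite.
* `daughter-sum`: residuals on the power scale of the plotted
  representation, normalized per bifurcation,
  $(a_i^n + b_i^n) - 1$. The unnormalized power-scale objective
  $\sum_i ((r_{ICA,i}^n + r_{ECA,i}^n) - r_{CCA,i}^n)^2$ is degenerate
  for mm-scale radii — every term vanishes as $n \to -\infty$ and a
  barrier separates the spurious valley from the true minimum — so the
  package fits the normalized form, which has the same zero set on
  noiseless data and weights bifurcations equally.

`mean_individual_exponent()` averages the per-bifurcation roots
instead. On noiseless cohorts all three estimators agree with the
generating exponent to $10^{-6}$; on noisy cohorts they differ
(a Jensen-type gap plus the weighting differences above), which is why
cohort-level and individual-level estimates of carotid exponents are
reported separately in the literature. The 95% CI is linearized
($\hat n \pm t_{0.975, N-1}\,\widehat{se}$) by default; with 5%
relative radius noise on all three radii the interval covers the true
exponent in about 93% of replicates (the mild undercoverage is the
errors-in-variables effect of noise on the daughter radii, which the
linearization ignores). A seeded nonparametric bootstrap (percentile,
2000 resamples by default) is available where the linearization is not
trusted.

`ica_adjustment()` reports the percent change in the ICA radius that
would make a triple satisfy the law at a given $n$ with CCA and ECA
held fixed: for the cohort mean ratios (0.67, 0.61) it is +18.3% at
$n = 2$ and +37.0% at $n = 3$ — the scale of anatomical change the
cube law would demand. `summarize_ratios()` reports means and SDs of
per-record ratios (mean of ratios, not ratio of means) and the
bifurcation area ratio under two labelled definitions, (i)
$(r_{ICA}^2 + r_{ECA}^2)/r_{CCA}^2$ and (ii)
$(r_{ICA} + r_{ECA})/r_{CCA}$, since both conventions appear in the
carotid literature.

## Measuring radii from masks

The imaging chain consumes binary masks (the output of any segmentation
tool) plus marker points near the three branch ends.

**Distance transform.** `distance_map()` is an exact anisotropic
Euclidean distance transform (separable lower-envelope algorithm,
implemented in C++): the value at a vessel voxel is the radius of the
maximally inscribed sphere centred there, in mm.

**Centerlines.** `minimal_cost_path()` runs Dijkstra on the
26-connected voxel graph with edge cost
$\text{step length} / (1 + DT)$ — a standard medialness weighting that
pulls the path onto the lumen centre; step lengths use the physical
spacing. The voxel path is resampled at half the smallest voxel,
smoothed by a 5-point moving average, snapped to the sub-voxel ridge of
the interpolated distance map, and smoothed again (refinement corrects
the half-voxel bias of discrete paths whose corridor straddles voxel
rows, but adds transverse jitter that would otherwise inflate arc
lengths — and hence tortuosity, which is computed on this final curve).

**Bifurcation point.** The paths from the CCA end to the two daughter
ends merge smoothly through the junction, so their last common point
(common meaning within one voxel diagonal: equal-cost discrete paths
may occupy adjacent rows) lies a little downstream of the anatomical
apex, by roughly half a parent radius. The package therefore
reconstructs the apex by fitting a straight axis to each branch over a
window 3–9 mm clear of the junction and taking the least-squares point
nearest the three lines; the reconstruction is accepted only if it
stays within the junction bulb (1.5 inscribed radii of the preliminary
split), falling back to the path-based point for strongly curved
branches. On phantoms this localizes the junction to about a quarter
voxel.

**Method A.** The inscribed-sphere radius at each centerline point.
Plain trilinear sampling of the distance map reads up to half a voxel
low whenever the axis runs between voxel rows (linear interpolation
flattens the tent-shaped peak of the field), so the profile uses a
tent-peak reconstruction: along each perpendicular direction $e$,
$\hat r = (D(p + \delta e) + D(p - \delta e))/2 + \delta$ with
$\delta$ half a voxel, taking the binding (smaller) of the two
directions. For an exactly tent-shaped field this is exact regardless
of where the axis falls.

**Method B.** The equivalent radius $\sqrt{A/\pi}$ from the lumen area
in the plane perpendicular to the flow axis: tangents by central
differences on the smoothed curve, the mask sampled on a 2D grid of
pitch $0.2 \times$ the smallest voxel and extent 4 unit radii with
trilinear interpolation at threshold 0.5. The two methods agree on
circular sections; on elliptical sections A returns the minor semi-axis
while B returns $\sqrt{ab}$, so B > A — the reason both are carried
through the pipeline (A mimics clinical calliper practice but
underestimates non-circular lumens).

**Windows.** `measure_triple()` takes the CCA radius at 2 unit radii
upstream of the bifurcation point, the ICA radius as the median between
6 and 12 unit radii (the carotid sinus, when present, dilates the
proximal ICA — in phantoms it is placed within 5 radii, so the window
clears it), and the ECA radius as the median between 2 and 7 unit radii
(medians shrug off localized artifacts such as the ECA's own side
branches; perturbation tests confirm a localized dilation narrower than
half the window moves the estimate by under 5%). The "unit radius" that
scales these windows is itself circular as usually stated; the package
resolves it as the median method-A radius over the whole branch,
computed once before windowing — stable because medians ignore both the
junction bulb and a sinus bulge. Medians over an even count are the
mean of the middle two.

## The phantom generator

Phantoms replace patient scans, so their defaults state the conditions
the pipeline is meant to handle. Tubes are voxelized by the
voxel-centre rule (a voxel is vessel iff its centre lies within the
local radius of the centerline), deterministic and faithful to the
binary-mask input contract; the default grid is 0.5 mm isotropic, and
CT-angiography anisotropy (2 × 0.5 × 0.5 mm) is exercised in the tests.
Daughter tubes are straight constant-radius capsules joined by plain
union (no fillet) — legitimate because every measurement window stays
clear of the junction by construction. A radius below two voxels is
refused as under-resolved. The carotid-sinus bulge scales the ICA
radius by a $\sin^2$ window over arc $[0, 5 r_{ICA}]$; centerline
curvature is a single-period sinusoid whose amplitude for a target
tortuosity is solved by quadrature
(`tube_amplitude_for_tortuosity`). Daughters that fail to separate
beyond the junction region (branch angles too small) are rejected.

`sample_cohort()` draws ICA/CCA and ECA/CCA ratios from truncated
normals on (0, 1) with means/SDs 0.67/0.074 and 0.61/0.087 — values
representative of inscribed-sphere measurements in adult carotid
cohorts — uncorrelated by default (no reliable joint estimate exists;
the latent correlation is exposed as a parameter). Absolute scale is
not identified by ratio data, so the CCA radius is lognormal with
median 4 mm, a typical adult CCA lumen radius; only ratios enter the
power law, so this choice is cosmetic for exponent work. With
`exact_exponent = n*` the daughters are rescaled by a common factor so
the law holds at $n^*$ to machine precision (preserving ECA/ICA);
relative Gaussian jitter is applied afterwards. Each subject
contributes independent left and right bifurcations.

What the phantoms do *not* emulate: greyscale CT physics (contrast,
noise, partial volume), segmentation errors, non-circular diseased
lumens beyond the elliptical test fixtures, and walls that taper. A
passing phantom suite therefore validates the geometry-processing and
estimation chain, not any claim about real arteries.

## Tortuosity and the straight-vessel subset

Tortuosity is $(L/D) - 1$: arc length along the centerline over the
endpoint chord, minus one — 0 for a straight vessel, $\pi/2 - 1$ for a
semicircle, invariant under rigid motion and uniform scaling. Because
Murray's derivation assumes straight tubes, cohort analyses are run
both on all records and on the subset with ICA tortuosity strictly
below 0.1 (`filter_low_tortuosity`; the inequality is strict, and
records with missing tortuosity are dropped from the subset). $L$ is
computed on the smoothed, resampled, refined curve, so the junction
bend contributes a small positive bias (about 0.01 on straight
phantoms) relative to the analytic centerline.

## Pipeline, determinism and problem sizes

`run_study()` accepts either a cohort CSV (radius triples go straight
to estimation) or imaging cases (mask + markers per bifurcation) and
writes per-record tables, ratio summaries, exponent tables (regression
with CI and mean of individual roots, for all records and the
low-tortuosity subset), power-scale plot data, and a run log with the
package version, seed and exclusion counts. Identical seeds give
byte-identical CSVs; randomness enters only through bootstrap CIs.
Masks travel as NIfTI (via RNifti) or MetaImage (a minimal uncompressed
MET_UCHAR reader/writer, which also round-trips a nonzero origin);
configs are YAML or plain R lists.

The test suite is sized for a single CPU: phantoms of roughly
$200 \times 100 \times 35$ voxels at 0.5 mm (a second or two each
through the full chain), 20 randomized phantom-recovery runs, 300
replicates for CI calibration, a $10^6$-point grid-scan oracle for the
root finder on 100 random triples, and exhaustive-Dijkstra oracle
comparison (via igraph) on masks of about $18^3$ voxels.

## Known limitations

* The bifurcation point of strongly curved junctions falls back to the
  path-based split, which sits downstream of the apex by up to half a
  parent radius; window medians make the radius triple robust to this,
  but single-point CCA measurements inherit a small shift.
* Method B assumes a locally planar, simply connected cross-section;
  at the junction itself (inside the windows' exclusion zones) the
  plane cuts both daughters and the area is not meaningful.
* The energy model is Murray's original two-term cost: no pulsatility,
  wall elasticity or reflection losses. Exponents measured in large
  elastic arteries are routinely below 3, and this package measures —
  it does not explain.
* The linearized CI slightly undercovers under radius noise (see
  above); use the bootstrap for reporting.
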