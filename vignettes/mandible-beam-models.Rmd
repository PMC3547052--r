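---
title: "Beam-theory models of the crocodilian mandible"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-theory models of the crocodilian mandible}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandibeam)
```

## The scientific problem

Crocodilian snouts range from short and robust (brevirostrine) to long and
slender (longirostrine), and the proportional length of the mandibular
symphysis — the fused midline segment of the lower jaw — tracks that
spectrum, from about 10% of mandible length up to about 50%. Long
symphyses correlate with feeding on small agile prey; short ones with
feeding on large prey, which demands vigorous lateral shaking and
long-axis rolling ("death roll") in addition to plain biting. `mandibeam`
implements the structural side of this question: if the mandible is
idealized as a 'Y'-shaped arrangement of beams, which simple measurement
should govern its strain under each feeding load, and does a statistical
comparison of candidate predictors bear the beam-theory expectation out?

## The structural idealization

A mandible is reduced to four linear measurements: overall length $L$,
symphyseal length $SL$, posterior width $W$, and the inter-rami angle $A$.
`build_beam_frame()` places the anterior tip at the origin, a symphysis
beam along the longitudinal ($Z$) axis to the junction at $(0, 0, SL)$,
and two ramus beams to fully restrained posterior nodes at
$(\pm W/2, 0, L)$. All sections are solid circles: symphysis diameter
0.069054 mm and rami 0.05 mm by default, chosen (in the source data
convention we replicate) so that mass, width and overall length are
conserved between a zero-length-symphysis frame and one whose symphysis
is 37.5% of overall length. The material is structural steel
($E = 200000$ MPa, $\nu = 0.25$, $\rho = 7.87$ g/cm$^3$); the choice is
arbitrary because the analysis is linear and comparative — strains for any
other modulus follow by scaling. Units are mm, N and MPa throughout
(MPa = N/mm$^2$), so strains are dimensionless.

The three feeding load cases, built by `make_load_case()`, all restrain
both posterior nodes in all six degrees of freedom:

* **bite** — unit force along $-Y$ (dorso-ventral, out of the frame
  plane), the jaw-adduction direction;
* **shake** — unit force along $+X$ (transverse, in the frame plane);
* **twist** — unit moment about $+Z$ (the longitudinal axis).

Two published descriptions of the bite/shake axes conflict; we follow the
assignment above (bite out-of-plane, shake in-plane) because it is the one
whose mechanics reproduce the published regressions and rankings — under
it, bite strain tracks overall length and shake strain tracks symphyseal
length, which the opposite assignment cannot produce.

### The solver

`solve_frame()` is a conventional linear-elastic 3D space-frame solver:
12-degree-of-freedom Euler–Bernoulli elements (axial, torsion, bending in
two planes; no shear deformation — the slenderness ratios of these beams
are at least ~7, and transverse-shear compliance is negligible at that
slenderness, though a solver that includes it could differ in the third
decimal). Local element axes put $x$ along the element and $y$ in the
global $XZ$ plane wherever possible (for vertical elements, $y$ is derived
from global $Z$); this makes end-force signs reproducible. Systems here
have at most a few dozen degrees of freedom, so the reduced system is
solved densely; a near-singular reduced stiffness (under-restrained frame)
is reported as a rigid-body-mode error naming the free node and degree of
freedom. A zero-length symphysis degenerates cleanly to a two-element 'V'
frame rather than a zero-length element.

Stress recovery follows the total-fibre-stress convention at element ends
only (moments vary linearly between end loads, so interior maxima cannot
occur):

$$\sigma = \frac{|N|}{A_s} + \frac{\sqrt{M_y^2 + M_z^2}\,(d/2)}{I},
\qquad \varepsilon = \sigma / E .$$

Torsion produces shear rather than fibre stress; a von-Mises-style
combined measure that folds in torsional and transverse shear is reported
alongside each element (`max_fibre_stress()`), but all headline statistics
use fibre stress only. The axial term matters: it is what makes the shake
response of the seven-taxon models an imperfect power law of symphyseal
length (log-likelihood ≈ 32 rather than a degenerate perfect fit), and it
is why strain across sweeps that hold symphyseal length constant is flat
only to within a few percent rather than exactly — the residual variation
is the angle-dependent axial force in the rami, two orders of magnitude
smaller than the variation along each load case's driving variable.

## Load magnitudes

Unit loads are the default everywhere: the solve is linear and the
statistics operate on log strain, so magnitudes shift regression
intercepts only — slopes, log-likelihoods, AICc differences, Akaike
weights and rankings are invariant (the test suite asserts this by running
the pipeline at two magnitudes). Physically motivated magnitudes are
available for scenario work:

* `shake_force()` — harmonic head shaking: prey of mass $m$ (by
  convention three skull masses) held at outlever $r$ and oscillated at
  frequency $f$ (default 4 Hz) with angular amplitude $\theta_0$ gives
  $F = m\,\theta_0 (2\pi f)^2 r$. No published value of $\theta_0$
  exists, so it is a required parameter; the function refuses to run
  without it rather than defaulting silently (0.5 rad is used as a worked
  example in the documentation only).
* `twist_torque()` — long-axis roll from a standing start: a body of mass
  $m$ (fifty skull masses by convention) at radius $r$ (skull width)
  turning through $\theta$ (default $2\pi$) in $t$ (default 0.5 s) gives
  $T = m r^2 \cdot 2\theta/t^2$.
* `muscle_group_force()` — the dry-skull method: adductor-chamber
  cross-sectional area times a 0.3 MPa specific tension, divided evenly
  over the trusses representing the group (packaged counts: 138 temporal,
  160 pterygoid). `volume_scale_force()` applies the $2/3$-power
  area–volume scaling; `tet_scale_factor()` rescales a model's loads so
  its bite force matches a reference ("tooth equals tooth").

## Morphometrics

`procrustes_align()` implements generalized Procrustes superimposition:
centre, scale to unit centroid size, then iteratively rotate each
configuration to the evolving consensus (SVD-based orthogonal Procrustes,
rotations only) until the consensus changes by less than $10^{-10}$.
Size correction is by centroid size; no tangent-space refinement beyond
the standard orthogonal projection is applied (the conventional choice,
and the simplest). `shape_pca()` decomposes the aligned coordinates with
`stats::prcomp`; PC1 is sign-fixed so that longer symphyses score higher
(via the S1–S4 chord), and remaining axes so their largest loading is
positive — signs are otherwise arbitrary and this makes runs comparable.

The 22-landmark scheme enumerates S1–S21 explicitly plus S22, which we
take as the right-side partner of S21 (the published list names only the
left); readers accept 21- or 22-landmark files. `landmarks_to_linear()`
defines measurement recipes (documented in its help page) that recover
$(L, SL, A, W)$ exactly from the package's own landmark template; real
measurements were taken interactively in a 3D viewer, so these recipes
are package conventions pinned by tests, not reconstructions.

## Statistics

Responses are peak fibre strain for beam models and, for externally
supplied element-strain fields (`read_strain_field()`), the robust 95%
quantile (`strain_percentile()`; linear interpolation between order
statistics at positions $1 + (n-1)q$ — the R type-7 convention, fixed and
documented because no convention is named in the source material). The
robust quantile exists because maxima of high-resolution FE strain exports
are typically restraint and point-load artifacts; the synthetic
`generate_strain_field()` reproduces exactly this regime.

`fit_log_model()` is ordinary least squares on natural logs of strain and
of linear measurements (PC scores enter raw — they can be negative), with
the Gaussian maximum-likelihood log-likelihood
$\log L = -\tfrac{n}{2}(\ln(2\pi\,\mathrm{RSS}/n) + 1)$. The MLE variance
$\mathrm{RSS}/n$ (not $\mathrm{RSS}/(n-p)$) is required to reproduce the
published log-likelihood/AICc pairs exactly. The parameter count includes
the variance, so one-predictor fits have $k = 3$ and the two-PC fit
$k = 4$. `aicc()` applies the small-sample correction
$-2\log L + 2k + 2k(k+1)/(n-k-1)$; `compare_models()` ranks fits, forms
$\Delta$AICc and Akaike weights $w_i \propto e^{-\Delta_i/2}$, and refuses
to compare fits made to different response data. A perfect fit
($\mathrm{RSS} = 0$) has unbounded likelihood and is flagged as degenerate
rather than returned as a number. Rankings (`rank_performance()`) place
rank 1 at the lowest strain; exact ties are broken alphabetically and
flagged.

## What the generators emulate — and what they do not

The synthetic module makes the package self-contained:

* `generate_sweep()` completes two held constants plus one varied grid to
  full measurement rows via $W = 2(L-SL)\tan(A/2)$; the four packaged
  presets reproduce the published sweep blocks (the shipped fixture keeps
  the printed, 1-decimal rows; the generator recomputes the derived
  variable at full precision so geometry is exactly self-consistent).
* `generate_taxa()` spans symphysis proportions 0.13–0.52 of length and
  lengths 2.3–3.7 mm — the ranges of the seven-taxon comparative set —
  with log-normal jitter (default scale 0.05, a realistic measurement
  and individual-variation scatter for linear skull measurements).
* `generate_landmark_population()` deforms a parametric landmark template
  along a symphysis-elongation mode and a dorso-ventral robustness mode
  plus isotropic noise. The packaged calibration (elongation 0.35,
  robustness 0.50 on the log scale, noise 0.004 of length) was set, once,
  so the two leading PCs of the aligned population carry on the order of
  two thirds and one quarter of shape variance — the dominance structure
  reported for real mandible landmarks. The robustness mode varies
  vertical relief rather than width because in unit-size shape space a
  width mode is strongly correlated with the elongation mode and the two
  would merge into a single PC.
* `generate_strain_field()` draws log-normal baseline strains around
  $10^{-4}$ (a physiological bone-strain order) with a 2%, ×100 artifact
  tail by default.

Every generator is a pure function of its parameters and an explicit
integer seed, and restores the caller's RNG state.

What passing tests on these populations show is that the pipeline's
machinery — superimposition, PCA, regression, model selection — recovers
known structure; they do not show that real crocodilian landmark data has
that structure, since the real configurations are not distributable. The
same limit applies to the high-resolution FE strains: the multi-million
element models behind the published FE columns are out of reach at desk
scale, so the package reproduces their comparison arithmetic from shipped
printed values and accepts external per-element strain CSVs for new data.

## Conventions for awkward inputs

Published measurement tables are internally inconsistent in two ways the
package handles explicitly. First, angle conventions differ: the sweep
dimensions are consistent with $A$ as the **full** inter-rami angle
($W = 2(L-SL)\tan(A/2)$, the package's canonical convention), while the
seven-taxon beam dimensions are consistent with the printed angle being
the **half** angle of each ramus to the midline. `linear_measurements()`
takes an `angle_convention` argument; the taxa fixture is read as
half-angle. Regressions always use the angle column as printed, which is
what was regressed originally; node coordinates are always built from
$(L, SL, W)$, so the convention affects only the consistency check.
Second, widths measured on real (curved) mandibles do not satisfy the
straight-rami relation at all, so the full-size specimen table is shipped
as plain data without frame validation. Consistency is checked against a
loose 15% relative tolerance (warning) and a hard 50% tolerance
(rejection), reflecting 1-decimal rounding in the printed values.

## Problem sizes in the test suite

The suite solves frames of 3–30 elements, uses landmark populations of
4–60 specimens and strain fields of up to 5000 elements, and runs the full
seven-taxon study several times; these sizes keep every statistical check
well-conditioned while the whole suite completes in seconds. The
acceptance script re-runs the seven-taxon study from the packaged fixture
and reports the shake and twist regression statistics.

## Known limitations

* Prismatic circular sections only: no taper, no vertical-plane geometry
  variation — deliberately, to isolate in-plane shape effects, but it is
  exactly the simplification that makes torsional behaviour of real
  mandibles (where section varies along the jaw) diverge from these
  models.
* Euler–Bernoulli kinematics: no shear deformation or warping torsion.
* The morphometric pipeline assumes complete, commonly-labelled landmark
  sets; there is no missing-landmark estimation.
* AICc comparison assumes the usual Gaussian OLS setting; with $n = 7$
  the weights are evidence summaries, not significance tests.
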