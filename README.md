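# mandibeam

Beam-theory biomechanics of the crocodilian mandible.

Crocodilian lower jaws span a spectrum from short, robust (brevirostrine)
to long, slender (longirostrine) shapes, and the length of the mandibular
symphysis — the fused midline segment — tracks that spectrum. Feeding on
large prey loads the mandible three ways: **biting** (dorso-ventral jaw
adduction), **shaking** (lateral head sweeps with prey gripped at the jaw
tips), and **twisting** (the long-axis "death roll"). `mandibeam` asks,
and answers statistically, which simple measurement of mandible shape
should control peak strain under each load when the mandible is idealized
as a 'Y'-shaped frame of beams.

The package provides, end to end:

* **Geometry** — `linear_measurements()`, `build_beam_frame()`: a
  four-node, three-element 'Y' frame built from overall length L,
  symphyseal length SL, and width W (with the inter-rami angle A as the
  consistency-checked fourth variable), circular sections, steel-like
  material.
* **Solver** — `solve_frame()`, `max_fibre_stress()`: a 12-DOF
  Euler–Bernoulli space-frame core with total fibre stress recovery
  (σ = |N|/A + √(My² + Mz²)·(d/2)/I) and strain ε = σ/E.
* **Load cases** — `make_load_case()` (bite = −Y force, shake = +X force,
  twist = +Z moment at the tip; posterior nodes fully fixed), plus the
  feeding-load physics: harmonic shake forces (`shake_force()`),
  rigid-body twist torque (`twist_torque()`), dry-skull muscle forces
  (`muscle_group_force()`, `volume_scale_force()`, `tet_scale_factor()`).
* **Morphometrics** — `procrustes_align()` (generalized Procrustes),
  `shape_pca()`, `landmarks_to_linear()` on a 22-landmark scheme.
* **Model selection** — `fit_log_model()` (OLS on ln strain vs ln
  measurement, Gaussian-MLE log-likelihood), `aicc()` with the
  small-sample correction −2 logL + 2k + 2k(k+1)/(n−k−1),
  `compare_models()` (ΔAICc, Akaike weights), `strain_percentile()`
  (robust 95% strain), `rank_performance()`.
* **Synthetic data** — seeded generators for measurement sweeps,
  pseudo-taxa, landmark populations and artifact-tailed strain fields.
* **Pipeline** — `run_beam_study()` and `run_sweep_study()`, plus a thin
  CLI (`exec/mandibeam`) with `study`, `sweep` and `simulate` subcommands.

## Worked example

The packaged seven-taxon measurement set drives the whole comparative
study:

```r
library(mandibeam)
study <- run_beam_study(packaged_measurements("taxa"))
print(study)
#> beam study: 7 taxa, cases bite/shake/twist
#>   bite: AICc-best ln(Length) (AICc -39.60, weight 1.00)
#>   shake: AICc-best ln(Symphyseal L.) (AICc -50.25, weight 1.00)
#>   twist: AICc-best ln(Angle) (AICc -29.63, weight 1.00)
```

Each load case is explained best by the variable beam theory predicts:
overall length for biting, symphyseal length for shaking, inter-rami
angle for twisting. The shake comparison in full:

```r
print(study$comparisons$shake, digits = 3)
#>               model intercept length_mm symphysis_mm angle_deg df logLik  AICc dAICc akaike_weight          support
#> 1 ln(Symphyseal L.)     -1.55        NA        0.974        NA  3 32.124 -50.2   0.0      1.00e+00 nearly identical
#> 2        ln(Length)     -4.81       2.6           NA        NA  3 -0.208  14.4  64.7      9.08e-15             poor
#> 3         ln(Angle)     -3.64        NA           NA      0.61  3 -5.067  24.1  74.4      7.05e-17             poor
```

The symphyseal-length model has slope 0.974 (peak shake strain very
nearly proportional to symphysis length), log-likelihood 32.12, and all
the Akaike weight; the length-only alternative trails by ΔAICc ≈ 65.
Rankings put the short-symphysis taxa on top under shaking:

```r
subset(study$rankings, load_case == "shake")
#>    load_case rank           taxon     strain  tied
#> 8      shake    1    C. moreletii 0.07814107 FALSE
#> 9      shake    2    O. tetraspis 0.08668215 FALSE
#> 10     shake    3 C. novaeguineae 0.11435068 FALSE
#> 11     shake    4  C. intermedius 0.15129566 FALSE
#> 12     shake    5 M. cataphractus 0.16966793 FALSE
#> 13     shake    6    C. johnstoni 0.17720087 FALSE
#> 14     shake    7   T. schlegelii 0.40340885 FALSE
```

(Strains are for unit loads on the mm-scale models; only relative values
matter, and slopes, likelihoods, weights and rankings are invariant to
the load magnitude.)

The same machinery runs on synthetic inputs — for instance a sweep that
varies angle and width at constant length and symphyseal length
(`run_sweep_study()`), or a seeded pseudo-taxon population
(`generate_taxa(20, seed = 42)`).

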