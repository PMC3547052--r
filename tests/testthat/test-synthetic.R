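# Generators: determinism, sweep structure, recovery properties.

test_that("all generators are pure functions of spec + seed", {
  expect_identical(generate_taxa(8, seed = 42), generate_taxa(8, seed = 42))
  expect_identical(generate_landmark_population(5, seed = 42),
                   generate_landmark_population(5, seed = 42))
  expect_identical(generate_strain_field(100, seed = 42),
                   generate_strain_field(100, seed = 42))
  expect_false(identical(generate_strain_field(100, seed = 1),
                         generate_strain_field(100, seed = 2)))
  expect_error(generate_taxa(5, seed = NULL), "seed")
  # the caller's RNG stream is not consumed
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_taxa(5, seed = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("sweep presets reproduce the published block structure", {
  sw <- generate_sweep(sweep_preset("CL-CSL-VA-VW"))
  expect_equal(sw$width_mm, c(0.44, 0.88, 1.34, 1.82, 2.33),
               tolerance = 5e-3)
  expect_true(all(sw$length_mm == 4.0) && all(sw$symphysis_mm == 1.5))

  one <- generate_sweep(sweep_spec("single",
                                   constants = list(length_mm = 4,
                                                    symphysis_mm = 1.5),
                                   vary = list(angle_deg = 30)))
  expect_equal(nrow(one), 1L)

  # constant-angle block: L - SL identical on every row
  sw3 <- generate_sweep(sweep_preset("CA-CW-VSL-VL"))
  gap <- sw3$length_mm - sw3$symphysis_mm
  expect_equal(gap, rep(gap[1], 5), tolerance = 1e-12)
  expect_equal(gap[1], 2.5, tolerance = 0.05)

  # the shipped fixture carries the printed rows verbatim
  fix <- packaged_measurements("sweeps")
  expect_equal(nrow(fix), 20L)
  expect_equal(fix$width_mm[fix$block == "CA-CW-VSL-VL"], rep(2.0, 5))
  expect_equal(fix$length_mm[fix$block == "CL-CSL-VA-VW"], rep(4.0, 5))
})

test_that("inadmissible sweep points are named", {
  # at a 30 degree angle a 1.3 mm width implies a negative symphysis on a
  # 2 mm mandible; the offending grid point is named
  bad <- sweep_spec("bad", constants = list(length_mm = 2, width_mm = 1.3),
                    vary = list(angle_deg = c(30, 150)))
  expect_error(generate_sweep(bad), "angle_deg = 30")
})

test_that("pseudo-taxa span the requested symphysis spectrum", {
  tx <- generate_taxa(5, sl_ratio = c(0.15, 0.5), noise = 0, seed = 1)
  expect_equal(tx$symphysis_mm / tx$length_mm,
               seq(0.15, 0.5, length.out = 5), tolerance = 1e-12)
  grid <- c(0.15, 0.3, 0.5)
  tx2 <- generate_taxa(3, sl_ratio = grid, noise = 0, seed = 1)
  expect_equal(tx2$symphysis_mm / tx2$length_mm, grid, tolerance = 1e-12)
  expect_error(generate_taxa(3, sl_ratio = c(0.5, 1.2), seed = 1), "\\(0, 1\\)")
  expect_error(generate_taxa(3, length_range = c(3, 2), seed = 1),
               "impossible")
  # jittered taxa still satisfy measurement invariants (validated on build)
  tx3 <- generate_taxa(20, noise = 0.08, seed = 5)
  expect_s3_class(tx3, "linear_measurements")
})

test_that("regression recovers a slope of 1 from strain proportional to SL", {
  tx <- generate_taxa(7, noise = 0, seed = 2)
  y <- 3.7e-4 * tx$symphysis_mm    # exact power law, exponent 1
  fit <- fit_log_model(y, data.frame(sl = tx$symphysis_mm))
  expect_equal(unname(fit$coefficients[2]), 1, tolerance = 1e-10)
  # with mild noise, recovery within 0.02
  set.seed(31)
  y2 <- y * exp(rnorm(7, 0, 0.005))
  fit2 <- fit_log_model(y2, data.frame(sl = tx$symphysis_mm))
  expect_equal(unname(fit2$coefficients[2]), 1, tolerance = 0.02)
})

test_that("landmark population modes behave as specified", {
  # zero amplitudes + zero noise: all configurations identical
  pop0 <- generate_landmark_population(4, elongation_sd = 0,
                                       robustness_sd = 0, noise = 0,
                                       seed = 1)
  expect_equal(pop0[, , 1], pop0[, , 3], tolerance = 1e-15)

  # template is bilaterally symmetric before noise
  tpl <- mandible_template()
  sch <- landmark_scheme()
  left <- sch$landmark[sch$side == "left"]
  right <- sch$landmark[sch$side == "right"]
  expect_equal(unname(tpl[left, ] %*% diag(c(-1, 1, 1))),
               unname(tpl[right, ]), tolerance = 1e-12)

  # dominant mode ordering: mode-1 >> mode-2 >> noise shows in the PCs
  pop <- generate_landmark_population(40, elongation_sd = 0.4,
                                      robustness_sd = 0.1, noise = 0.001,
                                      seed = 6)
  p <- shape_pca(procrustes_align(pop))
  expect_gt(p$variance_fraction[1], p$variance_fraction[2])
  expect_gt(p$variance_fraction[2], p$variance_fraction[3])
  expect_error(generate_landmark_population(5, noise = -1, seed = 1),
               ">= 0")
})

test_that("packaged calibration yields two dominant PCs near 66/26", {
  pop <- generate_landmark_population(60, seed = 1)
  p <- shape_pca(procrustes_align(pop))
  expect_equal(100 * p$variance_fraction[1], 66, tolerance = 10 / 66)
  expect_equal(100 * p$variance_fraction[2], 26, tolerance = 10 / 26)
})

test_that("strain fields have the constructed artifact structure", {
  pure <- generate_strain_field(4000, artifact_fraction = 0, seed = 12)
  expect_lt(max(pure) / strain_percentile(pure, 0.95), 3)
  expect_error(generate_strain_field(100, artifact_fraction = 1, seed = 1),
               "artifact_fraction")
  expect_error(generate_strain_field(100, artifact_multiplier = -1,
                                     seed = 1), "positive")
})

test_that("measurements -> frame -> re-measurement round-trip is exact", {
  tx <- generate_taxa(6, noise = 0, seed = 8)
  for (i in seq_len(nrow(tx))) {
    fr <- build_beam_frame(tx[i, ])
    back <- frame_measurements(fr)
    expect_equal(back$length_mm, tx$length_mm[i], tolerance = 1e-9)
    expect_equal(back$symphysis_mm, tx$symphysis_mm[i], tolerance = 1e-9)
    expect_equal(back$width_mm, tx$width_mm[i], tolerance = 1e-9)
    expect_equal(back$angle_deg, tx$angle_deg[i], tolerance = 1e-9)
  }
})
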