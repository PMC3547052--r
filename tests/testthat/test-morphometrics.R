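# Procrustes superimposition, shape PCA, and landmark measurement recipes.

rot3 <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

test_that("superimposition removes similarity transforms", {
  a <- mandible_template(3, 0.8, 1.35, 0.45)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  b <- 2.7 * a %*% rot3(0.3, -0.8, 1.2) +
    matrix(c(5, -2, 11), nrow(a), 3, byrow = TRUE)
  expect_equal(procrustes_distance(a, b), 0, tolerance = 1e-9)

  # GPA output invariant under similarity transform of any input
  pop <- generate_landmark_population(6, seed = 11)
  g1 <- procrustes_align(pop)
  pop2 <- unclass(pop)
  pop2[, , 3] <- 0.5 * pop2[, , 3] %*% rot3(1.1, 0.2, -0.7) +
    matrix(c(-4, 1, 9), dim(pop)[1], 3, byrow = TRUE)
  g2 <- procrustes_align(landmark_set(pop2))
  # consensus may differ by a global rotation; compare via distances
  expect_equal(procrustes_distance(g1$consensus, g2$consensus), 0,
               tolerance = 1e-8)
  for (i in seq_len(dim(pop)[3])) {
    expect_equal(procrustes_distance(g1$aligned[, , i], g2$aligned[, , i]),
                 0, tolerance = 1e-8)
  }
})

test_that("GPA consensus sides with the duplicated pair against an outlier", {
  base <- mandible_template(3, 0.8, 1.35, 0.45)
  outlier <- mandible_template(3, 2.4, 0.7, 0.9)
  g <- procrustes_align(landmark_set(list(a = base, b = base, c = outlier)))
  d_pair <- procrustes_distance(g$consensus, base)
  d_out <- procrustes_distance(g$consensus, outlier)
  expect_lt(d_pair, d_out)
  # brute-force pairwise check: the outlier is farther from either copy
  # than the copies are from each other
  expect_lt(procrustes_distance(base, base),
            procrustes_distance(base, outlier))
})

test_that("GPA agrees with an independent pairwise superimposition", {
  skip_if_not_installed("vegan")
  a <- mandible_template(3, 0.8, 1.35, 0.45)
  set.seed(5)
  b <- (a + matrix(rnorm(length(a), 0, 0.02), nrow(a), 3)) %*%
    rot3(0.4, -0.2, 0.9)
  ca <- scale(a, scale = FALSE); ca <- ca / sqrt(sum(ca^2))
  cb <- scale(b, scale = FALSE); cb <- cb / sqrt(sum(cb^2))
  v <- vegan::procrustes(ca, cb, scale = FALSE)
  mine <- cb %*% mandibeam:::procrustes_rotation(cb, ca)
  expect_equal(unclass(v$Yrot), unname(mine), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate and mismatched landmark inputs are refused", {
  flat <- matrix(1, 4, 3, dimnames = list(c("S1", "S4", "S15", "S16"), NULL))
  expect_error(landmark_set(list(a = flat, b = flat)), "degenerate")
  a <- mandible_template()
  b <- a[-3, ]
  expect_error(landmark_set(list(a = a, b = b)), "S3")
  expect_error(procrustes_align(landmark_set(list(a = a))), "at least two")
})

test_that("shape PCA satisfies its basic identities", {
  pop <- generate_landmark_population(12, seed = 3)
  p <- shape_pca(procrustes_align(pop))
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(colMeans(p$scores), rep(0, ncol(p$scores)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # two specimens: a single axis carries all variance
  two <- landmark_set(list(a = mandible_template(3, 0.6, 1.35, 0.45),
                           b = mandible_template(3, 1.6, 1.35, 0.45)))
  p2 <- shape_pca(procrustes_align(two))
  expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-9)

  # duplicating every specimen leaves variance fractions unchanged
  dup <- unclass(pop)[, , rep(seq_len(dim(pop)[3]), 2)]
  dimnames(dup)[[3]] <- sprintf("s%d", seq_len(dim(dup)[3]))
  pd <- shape_pca(procrustes_align(landmark_set(dup)))
  k <- min(length(p$variance_fraction), length(pd$variance_fraction))
  expect_equal(pd$variance_fraction[1:3], p$variance_fraction[1:3],
               tolerance = 1e-8)
})

test_that("PCA recovers a single generating mode", {
  pop <- generate_landmark_population(40, elongation_sd = 0.3,
                                      robustness_sd = 0, noise = 0.0005,
                                      seed = 21)
  p <- shape_pca(procrustes_align(pop))
  expect_gt(p$variance_fraction[1], 0.95)

  # PC1 axis within 5 degrees of the finite-difference generating mode
  tpl_shape <- function(slf) {
    m <- mandible_template(3, 0.8 * slf, 1.35, 0.45)
    m <- scale(m, scale = FALSE)
    m <- m / sqrt(sum(m^2))
    m %*% mandibeam:::procrustes_rotation(m, p$consensus)
  }
  d <- as.vector(tpl_shape(1.2) - tpl_shape(1 / 1.2))
  d <- d / sqrt(sum(d^2))
  cosang <- abs(sum(d * p$loadings[, 1]))
  expect_gt(cosang, cos(5 * pi / 180))

  # sign convention: longer symphysis scores higher on PC1
  sl <- landmarks_to_linear(pop)$symphysis_mm
  expect_gt(cor(p$scores[, 1], sl), 0.9)
})

test_that("landmark measurement recipes recover the generating geometry", {
  L <- 3.4; SL <- 1.1; W <- 1.25; h <- 0.5
  m <- landmarks_to_linear(mandible_template(L, SL, W, h))
  expect_equal(m$length_mm, L, tolerance = 1e-9)
  expect_equal(m$symphysis_mm, SL, tolerance = 1e-9)
  expect_equal(m$width_mm, W, tolerance = 1e-9)
  expect_equal(m$angle_deg, angle_from_geometry(L, SL, W), tolerance = 1e-9)

  # isotropic scaling scales lengths, leaves the angle unchanged
  sc <- landmarks_to_linear(2.5 * mandible_template(L, SL, W, h))
  expect_equal(sc$length_mm, 2.5 * L, tolerance = 1e-9)
  expect_equal(sc$angle_deg, m$angle_deg, tolerance = 1e-9)

  # reflection gives identical measurements
  refl <- mandible_template(L, SL, W, h) %*% diag(c(-1, 1, 1))
  mr <- landmarks_to_linear(refl)
  expect_equal(mr$length_mm, m$length_mm, tolerance = 1e-9)
  expect_equal(mr$angle_deg, m$angle_deg, tolerance = 1e-9)

  # missing landmarks are named
  expect_error(landmarks_to_linear(mandible_template()[-4, ]), "S4")
})

test_that("landmark CSV IO round-trips and validates", {
  pop <- generate_landmark_population(4, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(pop, path)
  back <- read_landmarks(path)
  expect_equal(unclass(back), unclass(pop), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a file missing one landmark for one taxon is refused with its name
  d <- utils::read.csv(path)
  d <- d[!(d$taxon == "specimen_01" & d$landmark == "S7"), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path2, row.names = FALSE)
  expect_error(read_landmarks(path2), "S7")
})

test_that("GPA+PCA is invariant to specimen input order", {
  pop <- generate_landmark_population(8, seed = 9)
  p1 <- shape_pca(procrustes_align(pop))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  shuffled <- landmark_set(unclass(pop)[, , perm])
  p2 <- shape_pca(procrustes_align(shuffled))
  expect_equal(p2$variance_fraction, p1$variance_fraction, tolerance = 1e-8)
  expect_equal(abs(p2$scores[dimnames(pop)[[3]][perm], 1]),
               abs(p1$scores[dimnames(pop)[[3]][perm], 1]), tolerance = 1e-6)
})
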