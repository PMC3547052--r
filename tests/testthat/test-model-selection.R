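# Regression likelihoods, AICc arithmetic, weights, quantiles, rankings.

test_that("OLS fit matches a normal-equations oracle to 1e-10", {
  set.seed(4)
  x <- seq(0.5, 3.5, length.out = 7)
  eps <- c(0.11, -0.23, 0.05, 0.18, -0.09, 0.02, -0.04)
  y <- exp(2 * log(x) + eps)  # ln y = 2 ln x + eps
  fit <- fit_log_model(y, data.frame(x = x))

  # oracle: closed-form normal equations on the logged data
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% X, t(X) %*% log(y))
  rss <- sum((log(y) - X %*% beta)^2)
  n <- length(y)
  ll <- -(n / 2) * (log(2 * pi * rss / n) + 1)
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-10)
  expect_equal(fit$rss, rss, tolerance = 1e-10)
  expect_equal(fit$logLik, ll, tolerance = 1e-10)
  # and the Gaussian-MLE formula agrees with stats::logLik on the same lm
  expect_equal(fit$logLik, as.numeric(stats::logLik(fit$lm)),
               tolerance = 1e-10)
  expect_identical(fit$k, 3L)
})

test_that("degenerate perfect fits are flagged, not returned as numbers", {
  fit <- fit_log_model(rep(2.5, 6), log_y = FALSE)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$logLik))
  expect_true(is.na(fit$aicc))
  expect_error(compare_models(list(fit)), "degenerate")
  # exact linear relation with a predictor is degenerate too
  x <- 1:6
  fit2 <- fit_log_model(exp(1 + 2 * log(x)), data.frame(x = x))
  expect_true(fit2$degenerate)
})

test_that("log transforms guard their domains", {
  expect_error(fit_log_model(c(-1, 2, 3), data.frame(x = 1:3)), "positive")
  expect_error(fit_log_model(c(1, 2, 3), data.frame(x = c(-1, 1, 2))),
               "positive")
  # raw (PC-like) predictors may be negative when log_x = FALSE
  f <- fit_log_model(c(1, 2, 3, 4), data.frame(pc = c(-2, -1, 1, 2)),
                     log_x = FALSE)
  expect_false(f$degenerate)
})

test_that("AICc arithmetic reproduces the printed comparison tables", {
  expect_equal(aicc(32.12, 3, 7), -50.24, tolerance = 1e-6)
  expect_equal(aicc(5.52, 3, 7), 2.96, tolerance = 1e-6)
  expect_error(aicc(1, 3, 4), "undefined")
  # large-n limit approaches AIC
  expect_equal(aicc(10, 3, 1e8), -2 * 10 + 6, tolerance = 1e-4)

  # every printed AICc in the shipped comparison tables is reproduced from
  # its printed logLik within printed-rounding tolerance
  pub <- published_comparisons()
  recomputed <- aicc(pub$logLik, pub$df, 7)
  expect_true(all(abs(recomputed - pub$AICc) <= 0.02 + 1e-9))
  # and the printed deltas follow from the printed AICc columns
  for (an in unique(pub$analysis)) {
    d <- pub[pub$analysis == an, ]
    expect_equal(d$dAICc, d$AICc - min(d$AICc), tolerance = 0.015)
  }
})

test_that("Akaike weights match a brute-force softmax oracle to 1e-12", {
  set.seed(8)
  for (rep in 1:5) {
    a <- sort(rnorm(6, sd = 5))
    w <- akaike_weights(a)$weight
    oracle <- exp(-(a - min(a)) / 2)
    oracle <- oracle / sum(oracle)
    expect_equal(w, oracle, tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  # printed delta columns reproduce the printed best-model weights
  expect_lt(abs(akaike_weights(c(0, 0.17, 6.47, 8.66, 13.74))$weight[1] -
                  0.51), 0.005)
  expect_lt(abs(akaike_weights(c(0, 1.69, 3.19, 4.11, 16.92))$weight[1] -
                  0.57), 0.005)
})

test_that("compare_models sorts, labels support, and guards responses", {
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1, 6.3, 6.8)
  x1 <- 1:7; x2 <- c(2, 1, 4, 3, 6, 5, 7)
  f1 <- fit_log_model(y, data.frame(a = x1))
  f2 <- fit_log_model(y, data.frame(b = x2))
  cmp <- compare_models(list(f1, f2))
  expect_equal(cmp$dAICc[1], 0)
  expect_true(all(diff(cmp$AICc) >= 0))
  expect_equal(sum(cmp$akaike_weight), 1, tolerance = 1e-12)
  expect_identical(cmp$support[1], "nearly identical")

  single <- compare_models(f1)
  expect_equal(single$akaike_weight, 1)
  expect_equal(single$dAICc, 0)

  f3 <- fit_log_model(rev(y), data.frame(a = x1))
  expect_error(compare_models(list(f1, f3)), "different response")
})

test_that("strain quantile uses the documented interpolation convention", {
  expect_equal(strain_percentile(1:100, 0.95), 95.05, tolerance = 1e-12)
  expect_equal(strain_percentile(rep(7, 50), 0.3), 7)
  expect_error(strain_percentile(numeric(0)), "empty")
  expect_error(strain_percentile(1:5, 1.2), "0, 1")
  s <- strain_summary(c(1:99, 1000))
  expect_true(all(diff(s[-1]) >= 0))
})

test_that("a 95% quantile ignores an artifact tail that dominates the max", {
  f <- generate_strain_field(5000, artifact_fraction = 0.02,
                             artifact_multiplier = 100, seed = 17)
  base <- generate_strain_field(5000, artifact_fraction = 0, seed = 17)
  expect_gte(strain_percentile(f, 1), 50 * strain_percentile(f, 0.95))
  # the robust value stays within the uncontaminated baseline's support
  expect_lt(strain_percentile(f, 0.95), max(base))
})

test_that("rank_performance ranks ascending strain and handles ties", {
  tab <- data.frame(
    taxon = rep(c("a", "b", "c"), 2),
    load_case = rep(c("bite", "shake"), each = 3),
    peak_strain = c(3, 1, 2, 5, 5, 4))
  expect_warning(r <- rank_performance(tab), "tied")
  bite <- r[r$load_case == "bite", ]
  expect_identical(bite$taxon, c("b", "c", "a"))
  shake <- r[r$load_case == "shake", ]
  expect_identical(shake$taxon[1], "c")
  expect_true(all(shake$tied[2:3]))
  expect_error(rank_performance(tab[-1, ]), "missing")
  tab$peak_strain[2] <- NA
  expect_error(rank_performance(tab), "missing strain")
})

test_that("external strain fields round-trip through CSV", {
  f <- generate_strain_field(200, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(element_id = seq_along(f), strain = f), path,
                   row.names = FALSE)
  back <- read_strain_field(path)
  expect_equal(unname(back), f, tolerance = 1e-12)
  expect_equal(strain_percentile(back, 0.95), strain_percentile(f, 0.95))
})
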