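test_that("slope is exact on identity and exact-scaling inputs", {
  pairs <- tibble::tibble(x = c(0.1, 0.25, 0.4, -0.2),
                          y = c(0.1, 0.25, 0.4, -0.2),
                          se_y = c(0.05, 0.04, 0.08, 0.06))
  fit <- ivw_slope(pairs)
  expect_identical(fit$slope, 1)
  expect_identical(fit$dispersion_scale, 1)

  pairs$y <- 0.5 * pairs$x
  fit2 <- ivw_slope(pairs)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-12)
  # zero residual dispersion clamps the scale at 1
  expect_identical(fit2$dispersion_scale, 1)
})

test_that("worked three-variant example matches the closed form", {
  pairs <- tibble::tibble(x = c(0.1, 0.2, 0.4),
                          y = c(0.05, 0.12, 0.25),
                          se_y = c(0.05, 0.04, 0.05))
  fit <- ivw_slope(pairs)
  # w = (400, 625, 400); sum(wxy) = 57; sum(wx^2) = 93
  expect_equal(fit$slope, 57 / 93, tolerance = 1e-12)
  expect_equal(fit$slope, lm_origin_slope(pairs), tolerance = 1e-10)
  expect_equal(fit$n_variants, 3L)
})

test_that("closed form equals the WLS-through-origin oracle on random instances", {
  for (i in 1:100) {
    pairs <- random_pairs(n = sample(3:40, 1), rng_seed = 1000 + i)
    expect_equal(ivw_slope(pairs)$slope, lm_origin_slope(pairs),
                 tolerance = 1e-10)
  }
})

test_that("slope is equivariant under rescaling of y and of x", {
  pairs <- random_pairs(12, rng_seed = 5)
  base <- ivw_slope(pairs)$slope
  for (c_ in c(0.2, 3)) {
    scaled_y <- dplyr::mutate(pairs, y = y * c_, se_y = se_y * c_)
    expect_equal(ivw_slope(scaled_y)$slope, c_ * base, tolerance = 1e-12)
    scaled_x <- dplyr::mutate(pairs, x = x * c_)
    expect_equal(ivw_slope(scaled_x)$slope, base / c_, tolerance = 1e-12)
  }
})

test_that("inflating the SE of a discordant pair moves the slope toward the rest", {
  pairs <- tibble::tibble(x = c(0.1, 0.2, 0.3, 0.4),
                          y = c(0.05, 0.10, 0.15, 0.80),  # last pair discordant
                          se_y = c(0.05, 0.05, 0.05, 0.05))
  slope_without <- ivw_slope(pairs[1:3, ])$slope
  slopes <- vapply(c(0.05, 0.2, 1, 10, 100), function(s) {
    p <- pairs; p$se_y[4] <- s; ivw_slope(p)$slope
  }, numeric(1))
  # distance to the 3-pair fit shrinks monotonically as the outlier is down-weighted
  expect_true(all(diff(abs(slopes - slope_without)) < 0))
  expect_equal(slopes[5], slope_without, tolerance = 1e-3)
})

test_that("confidence intervals are symmetric normal-quantile intervals", {
  pairs <- random_pairs(10, rng_seed = 9)
  fit <- ivw_slope(pairs)
  expect_lte(fit$ci_lo, fit$slope)
  expect_gte(fit$ci_hi, fit$slope)
  expect_equal(fit$ci_hi - fit$ci_lo, 2 * qnorm(0.975) * fit$se)
  expect_equal(unname(slope_ci(fit, 0.95)), c(fit$ci_lo, fit$ci_hi))

  # 1.96-style arithmetic on a stated example
  fake <- fit
  fake$slope <- 0.5
  fake$se <- 0.1
  expect_equal(unname(slope_ci(fake, 0.95)), c(0.304, 0.696),
               tolerance = 1e-4)
  # a wide-CI fit crosses 1, as seen for very small cohorts
  fake$slope <- 0.818
  fake$se <- 0.103
  ci <- slope_ci(fake, 0.95)
  expect_lt(ci["lo"], 1)
  expect_gt(ci["hi"], 1)
  # degenerate zero-SE interval collapses to the slope
  fake$se <- 0
  expect_equal(unname(slope_ci(fake, 0.95)), c(0.818, 0.818))

  expect_error(slope_ci(fit, 1.2), class = "minppv_invalid_level")
})

test_that("degenerate inputs raise classed errors", {
  expect_error(ivw_slope(tibble::tibble(x = 0.1, y = 0.1, se_y = 0.05)),
               class = "minppv_insufficient_data")
  expect_error(
    ivw_slope(tibble::tibble(x = c(0, 0), y = c(0.1, 0.2),
                             se_y = c(0.05, 0.05))),
    class = "minppv_degenerate_regressor")
  expect_error(
    ivw_slope(tibble::tibble(x = c(0.1, 0.2), y = c(0.1, 0.2),
                             se_y = c(0.05, -1))),
    class = "minppv_invalid_se")
})

test_that("overdispersion never shrinks the SE below the fixed-weight value", {
  for (i in 1:20) {
    pairs <- random_pairs(15, rng_seed = 300 + i)
    fit <- ivw_slope(pairs)
    fixed_se <- sqrt(1 / sum(pairs$x^2 / pairs$se_y^2))
    expect_gte(fit$dispersion_scale, 1)
    expect_gte(fit$se, fixed_se - 1e-12)
  }
})

test_that("tidy, glance and autoplot expose the fit", {
  pairs <- random_pairs(8, rng_seed = 2)
  fit <- ivw_slope(pairs)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$slope)
  expect_equal(td$conf.low, fit$ci_lo)
  gl <- glance(fit)
  expect_equal(gl$n_variants, 8L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("joint weighting by both SEs behaves sensibly", {
  pairs <- random_pairs(10, rng_seed = 11)
  pairs$se_x <- 1e-8
  # negligible reference error: both-SE fit equals the candidate-only fit
  expect_equal(ivw_slope(pairs, weights = "both")$slope,
               ivw_slope(pairs)$slope, tolerance = 1e-6)
  pairs$se_x <- NULL
  expect_error(ivw_slope(pairs, weights = "both"),
               class = "minppv_invalid_se")
})
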