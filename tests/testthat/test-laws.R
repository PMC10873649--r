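# Fairness-law fitting, interpolation, Gaussian CIs, Welch tests,
# balanced-composition disparity and fairest-composition search.

test_that("an exact line is recovered with slope, intercept and r = 1", {
  sw <- synthetic_sweep(seq(0, 1, 0.1), seeds = 1:3,
                        f_g0 = function(p) 0.60 + 0.10 * (1 - p),
                        f_g1 = function(p) 0.60 + 0.10 * p)
  f <- fit_law(sw, "g1")
  expect_equal(f$slope, 0.10, tolerance = 1e-10)
  expect_equal(f$intercept, 0.60, tolerance = 1e-10)
  expect_equal(f$pearson_r, 1.0, tolerance = 1e-10)
  expect_false(f$degenerate)
  expect_equal(f$interpolation_mae, 0, tolerance = 1e-12)
  # g0's law on its own representation axis has the same positive slope
  f0 <- fit_law(sw, "g0")
  expect_equal(f0$slope, 0.10, tolerance = 1e-10)
  # fitted line at 0 and 1 equals intercept and intercept + slope
  expect_equal(interpolate_from_extremes(f$intercept,
                                         f$intercept + f$slope, 0),
               f$intercept)
})

test_that("a flat response is reported as degenerate with r = 0, not an error", {
  sw <- synthetic_sweep(seq(0, 1, 0.25), seeds = 1:2,
                        f_g0 = function(p) 0.7 + 0 * p,
                        f_g1 = function(p) 0.7 + 0 * p)
  f <- fit_law(sw, "g1")
  expect_true(f$degenerate)
  expect_equal(f$pearson_r, 0)
  expect_equal(f$slope, 0, tolerance = 1e-12)
})

test_that("fit_law is invariant to the ordering of sweep rows", {
  set.seed(8)
  sw <- synthetic_sweep(seq(0, 1, 0.1), seeds = 1:5,
                        f_g0 = function(p) 0.65 + 0.08 * (1 - p),
                        f_g1 = function(p) 0.62 + 0.11 * p,
                        noise_sd = 0.01)
  perm <- sample(nrow(sw))
  sw2 <- composition_sweep(as.data.frame(sw)[perm, ],
                           attr(sw, "categories"))
  for (field in c("slope", "intercept", "pearson_r", "interpolation_mae"))
    expect_equal(fit_law(sw2, "g1")[[field]], fit_law(sw, "g1")[[field]],
                 tolerance = 1e-12)
})

test_that("interpolation from the extremes is the stated linear form", {
  expect_equal(interpolate_from_extremes(0.60, 0.70, 0.5), 0.65)
  expect_equal(interpolate_from_extremes(0.60, 0.70, 0.0), 0.60)
  expect_equal(interpolate_from_extremes(0.60, 0.70, 0.3), 0.63)
  expect_error(interpolate_from_extremes(0.6, 0.7, 1.2), "extrapolation")
  expect_error(interpolate_from_extremes(0.6, 0.7, -0.1), "extrapolation")
})

test_that("interpolation MAE counts only intermediate proportions", {
  # line y = 0.6 + 0.1 r with one of 5 intermediates displaced by +0.02
  props <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)
  rows <- data.frame(category = "g1", proportion = props, seed = 1,
                     sauroc = 0.6 + 0.1 * props)
  rows$sauroc[rows$proportion == 0.5] <- rows$sauroc[rows$proportion == 0.5] + 0.02
  rows0 <- data.frame(category = "g0", proportion = props, seed = 1,
                      sauroc = 0.6 + 0.1 * (1 - props))
  sw <- composition_sweep(rbind(rows, rows0), c("g0", "g1"))
  m <- interpolation_mae(sw, "g1")
  expect_equal(m$mean, 0.02 / 5, tolerance = 1e-12)  # 0.004
  expect_equal(interpolation_mae(sw, "g0")$mean, 0, tolerance = 1e-12)

  # endpoints are reproduced exactly, so they contribute no error
  sw_trunc <- composition_sweep(
    rbind(rows[rows$proportion > 0, ], rows0[rows0$proportion > 0, ]),
    c("g0", "g1"))
  expect_error(interpolation_mae(sw_trunc, "g1"), "endpoint")
})

test_that("a noisy true line is recovered within the stated bands", {
  set.seed(19)
  sw <- synthetic_sweep(seq(0, 1, 0.1), seeds = 1:10,
                        f_g0 = function(p) 0.60 + 0.09 * (1 - p),
                        f_g1 = function(p) 0.60 + 0.09 * p,
                        noise_sd = 0.005)
  f <- fit_law(sw, "g1")
  expect_lt(abs(f$slope - 0.09), 0.01)
  expect_lte(f$interpolation_mae, 2 * 0.005)
  expect_true(f$ci$slope["low"] <= 0.09 && 0.09 <= f$ci$slope["high"])
})

test_that("the Gaussian CI follows mean +/- z * sd / sqrt(n)", {
  # {0, 2}: mean 1, sample sd sqrt(2), half-width 1.96 * sqrt(2)/sqrt(2)
  ci <- gaussian_ci(c(0, 2), level = 0.95)
  z <- qnorm(0.975)
  expect_equal(unname(ci), c(1 - z, 1 + z), tolerance = 1e-12)
  expect_equal(gaussian_ci(rep(0.4, 5)), c(low = 0.4, high = 0.4))
  set.seed(2)
  v <- rnorm(9)
  ci2 <- gaussian_ci(v, 0.9)
  expect_true(ci2["low"] <= mean(v) && mean(v) <= ci2["high"])
  expect_equal(mean(ci2), mean(v))            # symmetric about the mean
  expect_error(gaussian_ci(1), "at least 2")
})

test_that("Welch's test matches the hand-computed statistic and conventions", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w <- welch_test(a, b)
  # independent hand computation of the Welch formula
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  dof_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$statistic, t_hand, tolerance = 1e-12)
  expect_equal(round(w$statistic, 4), -3.6742)
  expect_equal(w$dof, 4, tolerance = 1e-9)
  expect_equal(round(w$p_value, 4), 0.0213)

  # antisymmetry
  w2 <- welch_test(b, a)
  expect_equal(w2$statistic, -w$statistic)
  expect_equal(w2$p_value, w$p_value)

  # identical groups and degenerate conventions
  expect_equal(welch_test(a, a)$statistic, 0)
  expect_equal(welch_test(a, a)$p_value, 1)
  d <- welch_test(c(1, 1), c(1, 1))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  d2 <- welch_test(c(2, 2), c(1, 1))
  expect_true(d2$degenerate)
  expect_equal(d2$p_value, 0)
})

test_that("the balanced-composition report reproduces its own means exactly", {
  set.seed(27)
  sw <- synthetic_sweep(c(0, 0.5, 1), seeds = 1:10,
                        f_g0 = function(p) 0.70 + 0 * p,
                        f_g1 = function(p) 0.66 + 0 * p,
                        noise_sd = 0.004)
  rep <- balanced_disparity_report(sw, alpha = 0.01)
  at_half <- sw[abs(sw$proportion - 0.5) < 1e-9, ]
  expect_equal(rep$difference,
               mean(at_half$sauroc[at_half$category == "g1"]) -
                 mean(at_half$sauroc[at_half$category == "g0"]))
  expect_true(rep$significant)               # 0.04 gap at sd 0.004, n = 10
  sw_no_half <- synthetic_sweep(c(0, 1), seeds = 1:3,
                                f_g0 = function(p) 0.7 + 0 * p,
                                f_g1 = function(p) 0.7 + 0 * p)
  expect_error(balanced_disparity_report(sw_no_half), "0.5 proportion")
})

test_that("the fairest composition sits at the crossing of the two laws", {
  # g1 mean: 0.6 + 0.1 p; g0 mean: 0.76 - 0.1 p -> crossing at p = 0.8
  sw <- synthetic_sweep(seq(0, 1, 0.1), seeds = 1,
                        f_g0 = function(p) 0.76 - 0.1 * p,
                        f_g1 = function(p) 0.60 + 0.1 * p)
  expect_equal(fairest_composition(sw), 0.8)  # grid point at the crossing
  # identical category curves: tie broken toward balance
  sw2 <- synthetic_sweep(seq(0, 1, 0.25), seeds = 1,
                         f_g0 = function(p) 0.7 + 0 * p,
                         f_g1 = function(p) 0.7 + 0 * p)
  expect_equal(fairest_composition(sw2), 0.5)
})

test_that("sweep tables round-trip through their long CSV format", {
  set.seed(4)
  sw <- synthetic_sweep(seq(0, 1, 0.5), seeds = 1:2,
                        f_g0 = function(p) 0.7 - 0.05 * p,
                        f_g1 = function(p) 0.6 + 0.05 * p,
                        noise_sd = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_table(sw, path)
  back <- read_sweep_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sw))
  expect_identical(attr(back, "categories"), attr(sw, "categories"))
})
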