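make_flat_dataset <- function(values, conc = 1e-7) {
  conc_response("a", "x", replicate = seq_along(values),
                conc_M = rep(conc, length(values)), response = values)
}

test_that("leave-one-out outlier rule flags only gross deviations", {
  # hand oracle: others of the 5th are {10,11,9,10}: mean 10, SD 0.816,
  # |500-10| >> 3 x 0.816
  d <- exclude_outliers(make_flat_dataset(c(10, 11, 9, 10, 500)))
  expect_equal(d$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  d2 <- exclude_outliers(make_flat_dataset(c(10, 10, 10, 10, 10)))
  expect_false(any(d2$excluded))

  expect_warning(d3 <- exclude_outliers(make_flat_dataset(c(10, 500))),
                 "fewer than 3")
  expect_false(any(d3$excluded))
})

test_that("outlier rule is applied per concentration", {
  d <- conc_response("a", "x", replicate = rep(1:4, 2),
                     conc_M = rep(c(1e-8, 1e-6), each = 4),
                     response = c(5, 5, 5, 80, 90, 91, 89, 90))
  d <- exclude_outliers(d)
  expect_equal(which(d$excluded), 4L)
})

test_that("noiseless four-parameter data are recovered exactly", {
  x <- seq(-9, -5, by = 0.5)
  d <- conc_response("a", "x", replicate = rep(1, length(x)),
                     conc_M = 10^x,
                     response = logistic_response(x, -7, 100, 1, 0))
  f <- fit_logistic(d, "four_param", bottom_fixed_at_zero = TRUE)
  expect_equal(f$log_ec50, -7, tolerance = 1e-6)
  expect_equal(f$e_max, 100, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)

  f3 <- fit_logistic(d, "three_param_hill1", bottom_fixed_at_zero = TRUE)
  expect_identical(f3$hill, 1)
  expect_equal(f3$log_ec50, -7, tolerance = 1e-6)
})

test_that("steep curves match a brute-force grid oracle", {
  x <- seq(-9, -5, by = 0.5)
  y <- logistic_response(x, -7.2, 85, 2, 0)
  d <- conc_response("a", "x", replicate = rep(1, length(x)), conc_M = 10^x,
                     response = y)
  f <- fit_logistic(d, "four_param", bottom_fixed_at_zero = TRUE)
  oracle <- grid_logistic(x, y, centre = c(-7, 80, 1.5),
                          widths = c(1.5, 30, 1.4))
  expect_equal(f$pooled[["log_ec50"]], oracle[["log_ec50"]],
               tolerance = 1e-3)
  expect_equal(f$pooled[["e_max"]], oracle[["e_max"]], tolerance = 1e-3)
  expect_equal(f$pooled[["hill"]], oracle[["hill"]], tolerance = 1e-3)
})

test_that("fits are equivariant under response and concentration scaling", {
  x <- seq(-9, -5, by = 0.5)
  y <- logistic_response(x, -7, 100, 1.3, 5)
  base <- conc_response("a", "x", replicate = rep(1, length(x)),
                        conc_M = 10^x, response = y)
  f0 <- fit_logistic(base)
  # responses scaled by c: e_max and bottom scale, shape unchanged
  f_scaled <- fit_logistic(
    conc_response("a", "x", replicate = rep(1, length(x)), conc_M = 10^x,
                  response = 3 * y))
  expect_equal(f_scaled$e_max, 3 * f0$e_max, tolerance = 1e-6)
  expect_equal(f_scaled$bottom, 3 * f0$bottom, tolerance = 1e-5)
  expect_equal(f_scaled$log_ec50, f0$log_ec50, tolerance = 1e-6)
  expect_equal(f_scaled$hill, f0$hill, tolerance = 1e-6)
  # concentrations scaled by 10: log EC50 shifts by exactly +1
  f_shift <- fit_logistic(
    conc_response("a", "x", replicate = rep(1, length(x)),
                  conc_M = 10 * 10^x, response = y))
  expect_equal(f_shift$log_ec50, f0$log_ec50 + 1, tolerance = 1e-6)
  expect_equal(f_shift$e_max, f0$e_max, tolerance = 1e-6)
})

test_that("pooled fit agrees with per-replicate mean for identical replicates", {
  x <- seq(-9, -5, by = 0.5)
  y <- logistic_response(x, -6.5, 90, 1, 0)
  d <- conc_response("a", "x", replicate = rep(1:3, each = length(x)),
                     conc_M = rep(10^x, 3), response = rep(y, 3))
  f <- fit_logistic(d, bottom_fixed_at_zero = TRUE)
  expect_equal(f$log_ec50, f$pooled[["log_ec50"]], tolerance = 1e-6)
  expect_equal(f$e_max, f$pooled[["e_max"]], tolerance = 1e-6)
  expect_equal(f$sem_log_ec50, 0, tolerance = 1e-6)
})

test_that("non-convergent replicates are dropped, all-failure is an error", {
  # replicate 2 has < 4 distinct concentrations and cannot be fitted
  x <- seq(-9, -5, by = 0.5)
  y <- logistic_response(x, -7, 100, 1, 0)
  d <- conc_response("a", "x",
                     replicate = c(rep(1, length(x)), rep(2, 3)),
                     conc_M = c(10^x, 1e-8, 1e-7, 1e-6),
                     response = c(y, 1, 2, 3))
  f <- fit_logistic(d, bottom_fixed_at_zero = TRUE)
  expect_equal(nrow(f$per_replicate), 1)
  d_bad <- conc_response("a", "x", replicate = rep(1, 3),
                         conc_M = c(1e-8, 1e-7, 1e-6), response = c(1, 2, 3))
  expect_error(fit_logistic(d_bad), "no replicate")
})

test_that("fold potency follows the log EC50 difference", {
  expect_equal(fold_potency_value(-7, -7), 1)
  expect_equal(fold_potency_value(-8.11, -6.48), 10^1.63, tolerance = 1e-12)
  x <- seq(-10, -5, by = 0.5)
  mk <- function(le, id) {
    d <- conc_response("a", id, replicate = rep(1, length(x)), conc_M = 10^x,
                       response = logistic_response(x, le, 100, 1, 0))
    fit_logistic(d, bottom_fixed_at_zero = TRUE)
  }
  fp <- fold_potency(mk(-8.11, "carfentanil"), mk(-6.48, "DAMGO"))
  expect_equal(fp$fold, 10^1.63, tolerance = 1e-4)
  # assay mismatch refused
  d_other <- conc_response("b", "x", replicate = rep(1, length(x)),
                           conc_M = 10^x,
                           response = logistic_response(x, -7, 100, 1, 0))
  expect_error(fold_potency(fit_logistic(d_other, bottom_fixed_at_zero = TRUE),
                            mk(-6.48, "DAMGO")), "same assay")
})
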