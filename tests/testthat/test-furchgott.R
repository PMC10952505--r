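curve4 <- function(log_ec50, e_max, hill = 1, bottom = 0) {
  c(log_ec50 = log_ec50, e_max = e_max, hill = hill, bottom = bottom)
}

test_that("equieffective pairing inverts the fitted curves", {
  # pure 1-log right shift: depleted concentration is 10x at every level
  ep <- equieffective_pairs(curve4(-7, 100), curve4(-6, 100))
  expect_equal(nrow(ep), 20)
  expect_equal(ep$a_depleted / ep$a_control, rep(10, 20), tolerance = 1e-9)
  expect_true(all(diff(ep$response_level) > 0))
  # identical curves: identical concentrations
  ep2 <- equieffective_pairs(curve4(-7, 100), curve4(-7, 100))
  expect_equal(ep2$a_depleted, ep2$a_control, tolerance = 1e-12)
  # non-overlapping response ranges refused
  expect_error(equieffective_pairs(curve4(-7, 10), curve4(-6, 100)),
               "overlap")
})

test_that("pairs from operational-model curves satisfy the inactivation relation", {
  # forward-simulate control and depleted (tau -> q tau) responses, invert
  # numerically (uniroot, independent of the analytic inversion), and check
  # the pairs against the generating K_A
  k_a <- 1e-6; tau <- 30; q <- 0.1
  resp_c <- function(a) evaluate_operational(0, 100, tau, 1, k_a, a)
  resp_d <- function(a) evaluate_operational(0, 100, q * tau, 1, k_a, a)
  levels <- seq(0.1, 0.9, length.out = 9) * resp_d(1)  # within depleted range
  invert <- function(f, level) 10^stats::uniroot(
    function(lx) f(10^lx) - level, c(-14, 1), tol = 1e-13)$root
  a_c <- vapply(levels, function(l) invert(resp_c, l), numeric(1))
  a_d <- vapply(levels, function(l) invert(resp_d, l), numeric(1))
  predicted <- a_d * q * k_a / (k_a + (1 - q) * a_d)
  expect_equal(a_c, predicted, tolerance = 0.01)
})

test_that("noiseless pairs recover K_A and q exactly", {
  k_a <- 5.596e-6; q <- 0.06
  a_d <- 10^seq(-7, -4, length.out = 20)
  pairs <- data.frame(a_control = a_d * q * k_a / (k_a + (1 - q) * a_d),
                      a_depleted = a_d)
  f <- fit_furchgott(pairs)
  expect_equal(f$k_a, k_a, tolerance = 1e-4)
  expect_equal(f$q, q, tolerance = 1e-4)
  expect_true(f$k_a_ci[1] <= k_a && k_a <= f$k_a_ci[2])
})

test_that("the inactivation relation has the right limits", {
  # saturating depleted concentration: a_control -> q K_A / (1 - q)
  k_a <- 1e-7; q <- 0.5
  lim <- q * k_a / (1 - q)
  a_big <- 1e3
  expect_equal(a_big * q * k_a / (k_a + (1 - q) * a_big), lim,
               tolerance = 1e-8)
  # small concentrations: a_control ~ q a_depleted
  a_small <- k_a * 1e-6
  expect_equal(a_small * q * k_a / (k_a + (1 - q) * a_small) / a_small, q,
               tolerance = 1e-5)
})

test_that("insufficient depletion is refused", {
  a_d <- 10^seq(-8, -5, length.out = 10)
  pairs <- data.frame(a_control = a_d, a_depleted = a_d)
  expect_error(fit_furchgott(pairs), "depletion insufficient")
  expect_error(fit_furchgott(data.frame(a_control = a_d[1:3],
                                        a_depleted = a_d[1:3])),
               "at least 5")
})

test_that("fitted results reproduce their own pairs (self-consistency)", {
  set.seed(7)
  k_a <- 7.5e-7; q <- 0.15
  a_d <- 10^seq(-8, -4.5, length.out = 20)
  a_c <- a_d * q * k_a / (k_a + (1 - q) * a_d) * 10^rnorm(20, sd = 0.02)
  f <- fit_furchgott(data.frame(a_control = a_c, a_depleted = a_d))
  back <- a_d * f$q * f$k_a / (f$k_a + (1 - f$q) * a_d)
  rms <- sqrt(mean((log10(a_c) - log10(back))^2))
  expect_lt(rms, 3 * sqrt(f$ssr / f$n_pairs) + 0.05)
})

test_that("occupancy follows the law of mass action", {
  expect_identical(occupancy(1e-7, 1e-7), 0.5)
  expect_identical(occupancy(0, 1e-7), 0)
  expect_equal(occupancy(9e-7, 1e-7), 0.9)
  p <- occupancy(10^seq(-12, -3), 1e-7)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) > 0))
})

test_that("reserve summary matches the hyperbolic closed form", {
  # Hill slope 1, bottom 0: occupancy at half-max = 100 / (1 + K_A/EC50)
  fitc <- curve4(-7, 100)
  furch <- list(k_a = 35.2 * 1e-7)
  rs <- reserve_summary(fitc, furch)
  expect_equal(rs$ka_over_ec50, 35.2, tolerance = 1e-9)
  expect_equal(rs$occupancy_at_half_max, 100 / 36.2, tolerance = 1e-9)
  # no reserve: occupancy tracks response
  rs1 <- reserve_summary(fitc, list(k_a = 1e-7))
  expect_equal(rs1$occupancy_at_half_max, 50, tolerance = 1e-9)
  # occupancy at half max strictly decreases with increasing reserve
  ratios <- c(1, 2, 5, 10, 50, 200)
  occ <- vapply(ratios, function(r)
    reserve_summary(fitc, list(k_a = r * 1e-7))$occupancy_at_half_max,
    numeric(1))
  expect_true(all(diff(occ) < 0))
  expect_lt(occ[length(occ)], 1)
})

test_that("the full round trip recovers K_A and q from simulated arms", {
  truth <- ground_truth(tau = 30, k_a = 5.596e-6, q = 0.06, noise_cv = 0)
  arms <- simulate_depletion_arm(truth, seed = 21)
  fc <- fit_logistic(arms$control, bottom_fixed_at_zero = TRUE)
  fd <- fit_logistic(arms$depleted, bottom_fixed_at_zero = TRUE)
  f <- fit_furchgott(equieffective_pairs(fc, fd))
  expect_equal(f$k_a, 5.596e-6, tolerance = 5e-3)
  expect_equal(f$q, 0.06, tolerance = 0.02 / 0.06)
})
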