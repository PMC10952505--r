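test_that("operational model evaluates to its algebraic values", {
  # conc = K_A, tau = 1: numerator K_A, denominator 3 K_A
  expect_equal(evaluate_operational(0, 100, 1, 1, 1e-7, 1e-7), 100 / 3)
  # saturating concentration: basal + span * tau / (tau + 1)
  expect_equal(evaluate_operational(0, 100, 1, 1, 1e-7, 1e3), 50,
               tolerance = 1e-6)
  expect_equal(evaluate_operational(10, 110, 2, 1, 1e-7, 1e-7), 60)
  expect_equal(evaluate_operational(0, 100, 5, 1, 1e-7, 0), 0)
})

test_that("noiseless transduction ratios are recovered", {
  tr <- ground_truth(tau = 10, k_a = 1e-6, noise_cv = 0, n_replicates = 2)
  d <- simulate_assay(tr, seed = 1)
  f <- fit_operational(d, e_max_system = 100, se_method = "asymptotic")
  expect_equal(f$log_tau_over_ka, 7, tolerance = 1e-6)
  expect_equal(f$tau, 10, tolerance = 1e-4)
})

test_that("tau/K_A composite is stable along the likelihood ridge", {
  # free (tau, K_A, e_max) vs e_max fixed at truth: the identifiable
  # composite must agree even though tau itself wanders the ridge
  tr <- ground_truth(tau = 8, k_a = 5e-7, noise_cv = 0, n_replicates = 2)
  d <- simulate_assay(tr, seed = 3)
  f_free <- fit_operational(d, se_method = "asymptotic")
  f_fix <- fit_operational(d, e_max_system = 100, se_method = "asymptotic")
  expect_equal(f_free$log_tau_over_ka, f_fix$log_tau_over_ka,
               tolerance = 5e-3)
  expect_equal(f_fix$log_tau_over_ka, tr$log_tau_over_ka, tolerance = 1e-6)
})

test_that("the fitter matches an exhaustive grid oracle on a 5-point dataset", {
  conc <- 10^seq(-8, -6, by = 0.5)
  y <- evaluate_operational(0, 100, 10^0.9, 1, 10^-6.1, conc)
  d <- conc_response("a", "x", replicate = rep(1, 5), conc_M = conc,
                     response = y)
  f <- fit_operational(d, e_max_system = 100, se_method = "asymptotic")
  oracle <- grid_operational(conc, y, lt_range = c(0.5, 1.3),
                             lka_range = c(-6.5, -5.7),
                             em_range = c(100, 100), em_step = 1)
  fitter_sse <- sse_operational(conc, y, f$tau, f$k_a, 100)
  expect_lte(fitter_sse, oracle$sse + 1e-9)
  expect_equal(log10(f$tau), oracle$log_tau, tolerance = 0.02)
  expect_equal(log10(f$tau) - f$log_tau_over_ka, oracle$log_ka,
               tolerance = 0.02)
})

test_that("full-agonist data still yield a finite SE for the composite", {
  tr <- ground_truth(tau = 100, k_a = 1e-6, noise_cv = 0.03)
  d <- simulate_assay(tr, seed = 5)
  f <- fit_operational(d, e_max_system = 100, n_boot = 100, seed = 2)
  expect_true(is.finite(f$se_log_tau_over_ka))
  expect_gt(f$se_log_tau_over_ka, 0)
})

test_that("flat data are refused as signal-free", {
  d <- conc_response("a", "x", replicate = rep(1:3, each = 4),
                     conc_M = rep(10^seq(-9, -6), 3), response = rep(5, 12))
  expect_error(fit_operational(d), "no signal")
})

test_that("DeltaLog and DeltaDeltaLog propagate in quadrature", {
  mk <- function(lr, se, assay = "a", ag = "x") {
    structure(list(assay_id = assay, agonist_id = ag, log_tau_over_ka = lr,
                   se_log_tau_over_ka = se), class = "operational_fit")
  }
  self <- delta_log(mk(7, 0.1), mk(7, 0.1))
  expect_equal(self$value, 0)
  expect_equal(self$se, 0.1 * sqrt(2))
  dl <- delta_log(mk(7, 0.1, ag = "y"), mk(6, 0.1))
  expect_equal(dl$value, 1)
  expect_equal(dl$se, sqrt(0.02))
  expect_error(delta_log(mk(7, 0.1, assay = "b"), mk(6, 0.1)), "same assay")

  dl2 <- delta_log(mk(5.5, 0.1, assay = "p2", ag = "y"),
                   mk(6, 0.1, assay = "p2"))
  dd <- delta_delta_log(dl, dl2)
  expect_equal(dd$value, 1.5)
  expect_equal(dd$se, sqrt(dl$se^2 + dl2$se^2))
  # antisymmetry under pathway swap
  dd_swap <- delta_delta_log(dl2, dl)
  expect_identical(dd_swap$value, -dd$value)
  # mismatched reference refused
  dl_bad <- delta_log(mk(5.5, 0.1, assay = "p2", ag = "y"),
                      mk(6, 0.1, assay = "p2", ag = "other_ref"))
  expect_error(delta_delta_log(dl, dl_bad), "same reference")
})

test_that("differences are invariant to a constant shift of all ratios", {
  mk <- function(lr, assay, ag) {
    structure(list(assay_id = assay, agonist_id = ag, log_tau_over_ka = lr,
                   se_log_tau_over_ka = 0.1), class = "operational_fit")
  }
  for (shift in c(0, 2.5)) {
    dl1 <- delta_log(mk(7.3 + shift, "p1", "x"), mk(6.1 + shift, "p1", "ref"))
    dl2 <- delta_log(mk(5.0 + shift, "p2", "x"), mk(5.9 + shift, "p2", "ref"))
    dd <- delta_delta_log(dl1, dl2)
    expect_equal(dl1$value, 1.2, tolerance = 1e-12)
    expect_equal(dd$value, 1.2 - (-0.9), tolerance = 1e-12)
  }
})

test_that("a two-agonist assay recovers a known 100-fold ratio difference", {
  # truth: tau/K_A differs 100-fold => DeltaLog = 2
  covered <- 0L
  n_runs <- 25
  for (s in seq_len(n_runs)) {
    d_ref <- simulate_assay(ground_truth(tau = 10, k_a = 1e-6,
                                         noise_cv = 0.05),
                            agonist_id = "ref", seed = 100 + s)
    d_a <- simulate_assay(ground_truth(tau = 10, k_a = 1e-8,
                                       noise_cv = 0.05),
                          agonist_id = "a", seed = 500 + s)
    f_ref <- fit_operational(d_ref, e_max_system = 100, n_boot = 100,
                             seed = s)
    f_a <- fit_operational(d_a, e_max_system = 100, n_boot = 100, seed = s)
    dl <- delta_log(f_a, f_ref)
    ci <- dl$value + c(-1.96, 1.96) * dl$se
    if (ci[1] <= 2 && 2 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, ceiling(0.8 * n_runs))
})

test_that("reference comparison gates Dunnett on the ANOVA F test", {
  # degenerate: identical constants -> not tested
  g <- list(ref = c(1, 1, 1), a = c(1, 1, 1), b = c(1, 1, 1))
  out <- compare_to_reference(g, "ref")
  expect_false(out$tested)
  expect_true(all(is.na(out$comparisons$p_adjusted)))

  # a strongly shifted group is detected, and agrees with a permutation oracle
  set.seed(11)
  g2 <- list(ref = rnorm(5), a = rnorm(5), b = rnorm(5) + 10)
  out2 <- compare_to_reference(g2, "ref")
  expect_true(out2$tested)
  p_b <- out2$comparisons$p_adjusted[out2$comparisons$group == "b"]
  expect_lt(p_b, 0.001)
  expect_lt(perm_maxt_p(g2, "ref", n_perm = 10000), 0.001)

  expect_error(compare_to_reference(list(ref = 1:3, a = 1:3), "ref"),
               "at least 2 groups")
  expect_error(compare_to_reference(list(ref = 1, a = 1:3, b = 1:3), "ref"),
               "at least 2 values")
})
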