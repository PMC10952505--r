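#' Equieffective concentrations from control and depleted curves
#'
#' Implements the horizontal-line step of the Furchgott irreversible-antagonist
#' method: `n_levels` response levels are spaced evenly over the central 5-95%
#' of the depleted curve's span, and each level is inverted analytically
#' through both fitted logistic curves to give the pair of concentrations
#' (`a_control`, `a_depleted`) producing the same absolute response before and
#' after receptor inactivation. Levels are read from the fitted curves, not
#' raw points, because replicate noise would make raw inversion ill-defined.
#'
#' @param fit_control,fit_depleted [fit_logistic()] results (their pooled
#'   curves are used), or named lists/vectors with `log_ec50`, `e_max`,
#'   `hill`, `bottom`.
#' @param n_levels number of horizontal lines (default 20).
#' @return An `equieffective_pairs` object: data frame `response_level`,
#'   `a_control`, `a_depleted` with curve metadata attributes.
#' @export
equieffective_pairs <- function(fit_control, fit_depleted, n_levels = 20) {
  pc <- curve_params(fit_control)
  pd <- curve_params(fit_depleted)
  span_d <- pd[["e_max"]] - pd[["bottom"]]
  if (span_d <= 0) stop("depleted curve has non-positive span")
  lo <- pd[["bottom"]] + 0.05 * span_d
  hi <- pd[["bottom"]] + 0.95 * span_d
  ctrl_lo <- min(pc[["bottom"]], pc[["e_max"]])
  ctrl_hi <- max(pc[["bottom"]], pc[["e_max"]])
  if (lo <= ctrl_lo || hi >= ctrl_hi)
    stop(sprintf(paste0("curves do not overlap across the requested levels; ",
                        "usable response range is (%.4g, %.4g)"),
                 max(lo, ctrl_lo), min(hi, ctrl_hi)))
  levels <- seq(lo, hi, length.out = n_levels)
  a_c <- 10^logistic_inverse(levels, pc[["log_ec50"]], pc[["e_max"]],
                             pc[["hill"]], pc[["bottom"]])
  a_d <- 10^logistic_inverse(levels, pd[["log_ec50"]], pd[["e_max"]],
                             pd[["hill"]], pd[["bottom"]])
  out <- data.frame(response_level = levels, a_control = a_c,
                    a_depleted = a_d)
  structure(out, class = c("equieffective_pairs", "data.frame"),
            control = pc, depleted = pd)
}

curve_params <- function(x) {
  if (inherits(x, "logistic_fit")) {
    p <- x$pooled
    c(log_ec50 = unname(p[["log_ec50"]]), e_max = unname(p[["e_max"]]),
      hill = unname(p[["hill"]]), bottom = unname(p[["bottom"]]))
  } else {
    x <- unlist(x)
    needed <- c("log_ec50", "e_max", "hill", "bottom")
    if (!all(needed %in% names(x)))
      stop("curve must provide log_ec50, e_max, hill, bottom")
    x[needed]
  }
}

# Furchgott relation: concentration on the control curve equieffective with
# a_depleted on the depleted curve, for dissociation constant k_a and
# surviving-receptor fraction q.
furchgott_control_conc <- function(a_depleted, k_a, q) {
  a_depleted * q * k_a / (k_a + (1 - q) * a_depleted)
}

#' Fit the Furchgott relation to equieffective pairs
#'
#' Least-squares fit (in log10 concentration, so pairs spanning orders of
#' magnitude weigh equally) of
#' `a_control = a_depleted * q * K_A / (K_A + (1 - q) * a_depleted)`
#' to estimate the agonist equilibrium dissociation constant `K_A` and the
#' fraction `q` of receptors left functional by the irreversible antagonist.
#' 95% confidence intervals are asymptotic from the fit covariance, with a
#' profile-likelihood fallback when the asymptotic interval crosses a
#' parameter bound.
#'
#' @param pairs an [equieffective_pairs()] object, or a data frame with
#'   columns `a_control` and `a_depleted` (molar).
#' @return A `furchgott_fit` object: `k_a` (molar), `q` in (0, 1], their
#'   95% CIs (`k_a_ci`, `q_ci`), and the residual sum of squares in log10
#'   concentration units.
#' @export
fit_furchgott <- function(pairs) {
  a_c <- pairs$a_control
  a_d <- pairs$a_depleted
  if (length(a_c) < 5) stop("need at least 5 equieffective pairs")
  if (any(a_c <= 0 | a_d <= 0)) stop("concentrations must be positive")
  if (min(a_c / a_d) > 0.99)
    stop("depletion insufficient: q ~ 1, K_A is unidentifiable")
  q0 <- min(1, max(1e-4, min(a_c / a_d)))
  ka0 <- if (q0 < 1) max(a_c) * (1 - q0) / max(q0, 1e-4) else max(a_d)
  dat <- data.frame(y = log10(a_c), ad = a_d)
  fit <- minpack.lm::nlsLM(
    y ~ log10(10^lka * q * ad / (10^lka + (1 - q) * ad)),
    data = dat, start = list(lka = log10(ka0), q = q0),
    lower = c(-14, 1e-8), upper = c(2, 1),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  q_hat <- unname(cf[["q"]])
  lka_hat <- unname(cf[["lka"]])
  if (q_hat > 0.99)
    stop("depletion insufficient: q ~ 1, K_A is unidentifiable")
  n <- length(a_c)
  ssr <- sum(stats::resid(fit)^2)
  tcrit <- stats::qt(0.975, df = n - 2)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  lka_ci <- q_ci <- c(NA_real_, NA_real_)
  need_profile <- is.null(V)
  if (!is.null(V)) {
    se_lka <- sqrt(V["lka", "lka"]); se_q <- sqrt(V["q", "q"])
    lka_ci <- lka_hat + c(-1, 1) * tcrit * se_lka
    q_ci <- q_hat + c(-1, 1) * tcrit * se_q
    if (!all(is.finite(c(lka_ci, q_ci))) || q_ci[1] <= 0 || q_ci[2] > 1)
      need_profile <- TRUE
  }
  if (need_profile) {
    prof <- furchgott_profile_ci(dat, lka_hat, q_hat, ssr, n)
    lka_ci <- prof$lka_ci
    q_ci <- prof$q_ci
  }
  q_ci <- pmin(pmax(q_ci, 0), 1)
  structure(list(k_a = 10^lka_hat, q = q_hat,
                 k_a_ci = 10^lka_ci, q_ci = q_ci,
                 ssr = ssr, n_pairs = n), class = "furchgott_fit")
}

# profile-likelihood 95% CI: SSR threshold from the F(1, n-2) distribution
furchgott_profile_ci <- function(dat, lka_hat, q_hat, ssr_min, n) {
  thresh <- ssr_min * (1 + stats::qf(0.95, 1, n - 2) / (n - 2))
  prof_ss <- function(fix, value) {
    ss_of <- function(other) {
      lka <- if (fix == "lka") value else other
      q <- if (fix == "q") value else other
      pred <- log10(10^lka * q * dat$ad / (10^lka + (1 - q) * dat$ad))
      sum((dat$y - pred)^2)
    }
    int <- if (fix == "lka") c(1e-8, 1) else c(-14, 2)
    stats::optimize(ss_of, interval = int)$objective
  }
  bound <- function(fix, hat, dir, lim) {
    f <- function(v) prof_ss(fix, v) - thresh
    lo <- hat; hi <- hat + dir * 1e-4
    while (f(hi) < 0 && (dir > 0) == (hi < lim)) {
      lo <- hi
      hi <- hat + (hi - hat) * 2
      if ((dir > 0 && hi >= lim) || (dir < 0 && hi <= lim)) { hi <- lim; break }
    }
    if (f(hi) < 0) return(lim)
    stats::uniroot(f, sort(c(lo, hi)))$root
  }
  list(lka_ci = c(bound("lka", lka_hat, -1, -14),
                  bound("lka", lka_hat, +1, 2)),
       q_ci = c(bound("q", q_hat, -1, 1e-8),
                bound("q", q_hat, +1, 1)))
}

#' @export
print.furchgott_fit <- function(x, ...) {
  cat(sprintf("<furchgott_fit> K_A = %.4g M (95%% CI [%.3g, %.3g])\n",
              x$k_a, x$k_a_ci[1], x$k_a_ci[2]))
  cat(sprintf("  q = %.3f (95%% CI [%.3f, %.3f]), %d pairs, SSR(log10) = %.3g\n",
              x$q, x$q_ci[1], x$q_ci[2], x$n_pairs, x$ssr))
  invisible(x)
}

#' Fractional receptor occupancy
#'
#' Law-of-mass-action occupancy `p = [A] / ([A] + K_A)`.
#'
#' @param conc agonist concentration(s), molar, >= 0.
#' @param k_a equilibrium dissociation constant, molar, > 0.
#' @return Fractional occupancy in \[0, 1).
#' @export
#' @examples
#' occupancy(1e-7, 1e-7)  # 0.5 at conc = K_A
occupancy <- function(conc, k_a) {
  stopifnot(k_a > 0, all(conc >= 0))
  conc / (conc + k_a)
}

#' Receptor-reserve summary
#'
#' Combines the control-arm logistic fit with the Furchgott `K_A` estimate to
#' give the receptor-reserve index `K_A/EC50` (> 1 indicates reserve) and the
#' fractional occupancy (in percent) at which the response reaches 50% of the
#' agonist's own maximum: the fitted control curve is inverted at half-maximal
#' response and the corresponding occupancy is read from the occupancy curve.
#' An `occupancy_curve` over the curve's central range is attached for
#' plotting occupancy against response.
#'
#' @param fit_control control-arm [fit_logistic()] result (or curve parameter
#'   list as in [equieffective_pairs()]).
#' @param furch a [fit_furchgott()] result.
#' @return List `ka_over_ec50`, `occupancy_at_half_max` (percent),
#'   `occupancy_curve` (data frame `conc_M`, `p`, `response`).
#' @export
reserve_summary <- function(fit_control, furch) {
  pc <- curve_params(fit_control)
  k_a <- furch$k_a
  ec50 <- 10^pc[["log_ec50"]]
  half <- pc[["bottom"]] + 0.5 * (pc[["e_max"]] - pc[["bottom"]])
  lc_half <- tryCatch(
    logistic_inverse(half, pc[["log_ec50"]], pc[["e_max"]], pc[["hill"]],
                     pc[["bottom"]]),
    error = function(e)
      stop("response never reaches 50% of maximum within the curve range"))
  occ_half <- 100 * occupancy(10^lc_half, k_a)
  grid <- 10^seq(pc[["log_ec50"]] - 3, pc[["log_ec50"]] + 3,
                 length.out = 121)
  curve <- data.frame(
    conc_M = grid,
    p = occupancy(grid, k_a),
    response = logistic_response(log10(grid), pc[["log_ec50"]],
                                 pc[["e_max"]], pc[["hill"]],
                                 pc[["bottom"]]))
  list(ka_over_ec50 = k_a / ec50, occupancy_at_half_max = occ_half,
       occupancy_curve = curve)
}
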