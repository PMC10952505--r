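#' Black-Leff operational model
#'
#' Response of a transduction system to agonist concentration `conc` (molar):
#' `basal + (e_max - basal) * tau^n [A]^n / (tau^n [A]^n + ([A] + K_A)^n)`,
#' where `tau` is the operational efficacy (a composite of receptor density,
#' intrinsic efficacy and coupling efficiency), `K_A` the agonist equilibrium
#' dissociation constant, `n_slope` the transducer-function slope and `e_max`
#' the maximal response the system can produce.
#'
#' @param basal response without agonist (assay units).
#' @param e_max maximal system response (assay units).
#' @param tau operational efficacy, > 0.
#' @param n_slope transducer slope, > 0.
#' @param k_a equilibrium dissociation constant, molar, > 0.
#' @param conc agonist concentration(s), molar, >= 0.
#' @return Response(s) in assay units.
#' @export
#' @examples
#' evaluate_operational(0, 100, tau = 1, n_slope = 1, k_a = 1e-7,
#'                      conc = 1e-7)  # 33.33: numerator K_A, denominator 3 K_A
evaluate_operational <- function(basal, e_max, tau, n_slope, k_a, conc) {
  stopifnot(tau > 0, n_slope > 0, k_a > 0, all(conc >= 0))
  ta <- (tau * conc)^n_slope
  basal + (e_max - basal) * ta / (ta + (conc + k_a)^n_slope)
}

# internal predictor in the (log_tau, log_R) parameterisation where
# R = tau / K_A is the transduction ratio; the composite log10(R) is the
# identifiable quantity even when tau and K_A 'ride' a likelihood ridge.
op_predict <- function(conc, basal, e_max, n_slope, log_tau, log_r) {
  tau <- 10^log_tau
  k_a <- tau / 10^log_r
  evaluate_operational(basal, e_max, tau, n_slope, k_a, conc)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

# starts from a pooled logistic fit
op_start <- function(log_conc, response, basal, e_max_system, n_slope) {
  lf <- fit_logistic_one(log_conc, response, "four_param",
                         bottom_fixed_at_zero = TRUE)
  top <- max(lf[["e_max"]], max(response), basal + 1e-6)
  emax0 <- if (is.null(e_max_system)) 1.2 * top else e_max_system
  f <- min((top - basal) / (emax0 - basal), 0.99)
  f <- max(f, 0.01)
  n0 <- if (is.null(n_slope)) 1 else n_slope
  tau0 <- (f / (1 - f))^(1 / n0)
  ec50 <- 10^lf[["log_ec50"]]
  ka0 <- ec50 * ((2 + tau0^n0)^(1 / n0) - 1)
  list(log_tau = log10(tau0), log_r = log10(tau0 / ka0), e_max = emax0,
       n = n0)
}

# core least-squares fit for one dataset; returns list(par, ss, convergence)
op_fit_core <- function(log_conc, response, basal, e_max_system, n_slope,
                        start = NULL) {
  conc <- 10^log_conc
  free_emax <- is.null(e_max_system)
  free_n <- is.null(n_slope)
  st <- if (is.null(start))
    op_start(log_conc, response, basal, e_max_system, n_slope) else start
  p0 <- c(st$log_tau, st$log_r)
  lower <- c(-4, st$log_r - 6)
  upper <- c(7, st$log_r + 6)
  if (free_emax) {
    p0 <- c(p0, st$e_max)
    lower <- c(lower, max(basal + 1e-9, max(response) * 0.999))
    upper <- c(upper, max(response) * 100 + abs(basal) + 1)
  }
  if (free_n) {
    p0 <- c(p0, st$n); lower <- c(lower, 0.2); upper <- c(upper, 5)
  }
  res_fn <- function(p) {
    lt <- p[1]; lr <- p[2]
    em <- if (free_emax) p[3] else e_max_system
    nn <- if (free_n) p[[length(p)]] else n_slope
    response - op_predict(conc, basal, em, nn, lt, lr)
  }
  best <- NULL
  offsets <- if (is.null(start)) c(0, -1, 1, 2) else 0  # warm start: one run
  for (off in offsets) {
    p <- p0; p[1] <- min(max(p0[1] + off, lower[1]), upper[1])
    ans <- tryCatch(
      minpack.lm::nls.lm(p, lower = lower, upper = upper, fn = res_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(ans)) {
      val <- sum(ans$fvec^2)
      if (is.null(best) || val < best$value)
        best <- list(par = ans$par, value = val,
                     convergence = ans$info)
    }
  }
  if (is.null(best)) stop("operational fit failed to start")
  best$free_emax <- free_emax
  best$free_n <- free_n
  best
}

#' Fit the operational model to a concentration-response dataset
#'
#' Least-squares fit of the operational model in the
#' `(log10 tau, log10(tau/K_A))` parameterisation, so the identifiable
#' transduction ratio `Log(tau/K_A)` is always reported with a standard error
#' even when `tau` and `K_A` are individually poorly determined (full
#' agonists). The standard error is obtained by bootstrap over replicates
#' (default, 200 resamples) or from the asymptotic curvature of the
#' least-squares surface.
#'
#' @param dataset a [conc_response()] object (after [exclude_outliers()]).
#' @param e_max_system maximal system response; `NULL` to estimate it from
#'   the data, or a number to fix it (e.g. from a joint fit across agonists,
#'   see [fit_operational_assay()]).
#' @param n_slope transducer slope; a number to fix it (default 1) or `NULL`
#'   to estimate.
#' @param basal response without agonist; fixed, default 0 for
#'   background-subtracted assay data.
#' @param se_method `"bootstrap"` (replicate resampling) or `"asymptotic"`.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed integer seed for the bootstrap stream.
#' @return An `operational_fit` object: list with `tau`, `k_a`,
#'   `log_tau_over_ka`, `se_log_tau_over_ka`, `e_max_system`, `n_slope`,
#'   `basal`, residual sum of squares `ss`, and identifiers.
#' @export
fit_operational <- function(dataset, e_max_system = NULL, n_slope = 1,
                            basal = 0,
                            se_method = c("bootstrap", "asymptotic"),
                            n_boot = 200, seed = 1L) {
  stopifnot(is_conc_response(dataset))
  se_method <- match.arg(se_method)
  d <- included_rows(dataset)
  span <- diff(range(tapply(d$response, d$conc_M, mean)))
  if (!is.finite(span) || span <= 1e-10 * max(1, max(abs(d$response))))
    stop("no signal: responses show no concentration dependence")
  lc <- log10(d$conc_M)
  fit <- op_fit_core(lc, d$response, basal, e_max_system, n_slope)
  p <- fit$par
  lt <- p[1]; lr <- p[2]
  em <- if (fit$free_emax) p[3] else e_max_system
  nn <- if (fit$free_n) p[[length(p)]] else n_slope
  se <- switch(se_method,
    asymptotic = op_se_asymptotic(fit, lc, d$response, basal, e_max_system,
                                  n_slope),
    bootstrap = op_se_bootstrap(d, basal, e_max_system, n_slope, fit, n_boot,
                                seed))
  structure(list(
    assay_id = attr(dataset, "assay_id"),
    agonist_id = attr(dataset, "agonist_id"),
    basal = basal, e_max_system = em, n_slope = nn,
    tau = 10^lt, k_a = 10^(lt - lr),
    log_tau_over_ka = lr, se_log_tau_over_ka = se,
    ss = fit$value, n_obs = nrow(d),
    n_replicates = length(unique(d$replicate))), class = "operational_fit")
}

#' Confidence interval for the transduction ratio
#'
#' Interval for `Log(tau/K_A)` built from the fit's standard error with a
#' Student-t quantile on the replicate degrees of freedom (replicates - 1),
#' the appropriate small-sample reference for bootstrap-over-replicates SEs.
#'
#' @param object an `operational_fit`.
#' @param parm ignored (only the composite ratio has an interval).
#' @param level confidence level (default 0.95).
#' @param ... ignored.
#' @return Length-2 numeric vector (lower, upper).
#' @export
confint.operational_fit <- function(object, parm, level = 0.95, ...) {
  df <- max(object$n_replicates - 1, 1)
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  object$log_tau_over_ka + c(-1, 1) * tcrit * object$se_log_tau_over_ka
}

op_se_asymptotic <- function(fit, log_conc, response, basal, e_max_system,
                             n_slope) {
  conc <- 10^log_conc
  obj <- function(p) {
    em <- if (fit$free_emax) p[3] else e_max_system
    nn <- if (fit$free_n) p[[length(p)]] else n_slope
    sum((response - op_predict(conc, basal, em, nn, p[1], p[2]))^2)
  }
  p <- fit$par
  k <- length(p)
  h <- 1e-4
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ei <- ej <- rep(0, k); ei[i] <- h; ej[j] <- h
    H[i, j] <- (obj(p + ei + ej) - obj(p + ei - ej) -
                obj(p - ei + ej) + obj(p - ei - ej)) / (4 * h * h)
  }
  dof <- max(length(response) - k, 1)
  sigma2 <- fit$value / dof
  V <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(V) || !is.finite(V[2, 2]) || V[2, 2] < 0) return(NA_real_)
  sqrt(V[2, 2])
}

op_se_bootstrap <- function(d, basal, e_max_system, n_slope, fit, n_boot,
                            seed) {
  reps <- sort(unique(d$replicate))
  if (length(reps) < 2) return(NA_real_)
  st <- list(log_tau = fit$par[1], log_r = fit$par[2],
             e_max = if (fit$free_emax) fit$par[3] else e_max_system,
             n = if (fit$free_n) fit$par[[length(fit$par)]] else n_slope)
  with_seed(seed, {
    vals <- vapply(seq_len(n_boot), function(b) {
      take <- sample(reps, length(reps), replace = TRUE)
      db <- do.call(rbind, lapply(take, function(r)
        d[d$replicate == r, , drop = FALSE]))
      ans <- tryCatch(
        op_fit_core(log10(db$conc_M), db$response, basal, e_max_system,
                    n_slope, start = st),
        error = function(e) NULL)
      if (is.null(ans)) NA_real_ else ans$par[2]
    }, numeric(1))
    stats::sd(vals, na.rm = TRUE)
  })
}

#' @export
print.operational_fit <- function(x, ...) {
  cat(sprintf("<operational_fit> %s / %s\n", x$assay_id, x$agonist_id))
  cat(sprintf("  Log(tau/KA) = %.3f +/- %.3f   tau = %.3g   KA = %.3g M\n",
              x$log_tau_over_ka, x$se_log_tau_over_ka, x$tau, x$k_a))
  cat(sprintf("  e_max_system = %.3g  n = %.2f  basal = %.3g  SS = %.3g\n",
              x$e_max_system, x$n_slope, x$basal, x$ss))
  invisible(x)
}

#' Joint operational fit of all agonists within an assay
#'
#' Fits the operational model to every agonist in one assay simultaneously
#' with a single shared `e_max_system` and transducer slope `n_slope` (the
#' transducer function is a property of the pathway, not the agonist), and
#' per-agonist `(tau, K_A)`. Standard errors of each `Log(tau/K_A)` come from
#' replicate bootstrap of the joint fit.
#'
#' @param datasets list of [conc_response()] objects, all from the same assay.
#' @param n_slope fix the shared slope at a value, or `NULL` to estimate it.
#' @param basal shared fixed basal (default 0).
#' @param se_method,n_boot,seed as in [fit_operational()].
#' @return List with `fits` (named list of `operational_fit`),
#'   `e_max_system`, `n_slope`.
#' @export
fit_operational_assay <- function(datasets, n_slope = NULL, basal = 0,
                                  se_method = c("bootstrap", "asymptotic"),
                                  n_boot = 200, seed = 1L) {
  se_method <- match.arg(se_method)
  stopifnot(length(datasets) >= 1)
  assay <- attr(datasets[[1]], "assay_id")
  for (d in datasets)
    if (!identical(attr(d, "assay_id"), assay))
      stop("all datasets must come from the same assay")
  dl <- lapply(datasets, included_rows)
  free_n <- is.null(n_slope)
  starts <- lapply(seq_along(datasets), function(i)
    op_start(log10(dl[[i]]$conc_M), dl[[i]]$response, basal, NULL,
             if (free_n) NULL else n_slope))
  emax0 <- max(vapply(starts, `[[`, numeric(1), "e_max"))
  k <- length(datasets)
  # parameter vector: emax, [n], (log_tau_i, log_r_i) x k
  res_make <- function(data_list) {
    function(p) {
      em <- p[1]
      nn <- if (free_n) p[2] else n_slope
      off <- if (free_n) 2L else 1L
      unlist(lapply(seq_len(k), function(i) {
        g <- data_list[[i]]
        g$response - op_predict(g$conc_M, basal, em, nn,
                                p[off + 2 * i - 1], p[off + 2 * i])
      }), use.names = FALSE)
    }
  }
  p0 <- c(emax0, if (free_n) 1)
  lower <- c(max(basal + 1e-9,
                 0.999 * max(vapply(dl, function(g) max(g$response),
                                    numeric(1)))),
             if (free_n) 0.2)
  upper <- c(emax0 * 100 + 1, if (free_n) 5)
  for (s in starts) {
    p0 <- c(p0, s$log_tau, s$log_r)
    lower <- c(lower, -4, s$log_r - 6)
    upper <- c(upper, 7, s$log_r + 6)
  }
  solve_joint <- function(data_list, p_init) {
    fn <- res_make(data_list)
    ans <- minpack.lm::nls.lm(p_init, lower = lower, upper = upper, fn = fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 1000, ftol = 1e-13, ptol = 1e-13))
    list(par = ans$par, value = sum(ans$fvec^2))
  }
  fit <- solve_joint(dl, p0)
  # one refinement pass from the solution guards against early termination
  fit2 <- solve_joint(dl, fit$par)
  if (fit2$value < fit$value) fit <- fit2
  em <- fit$par[1]
  nn <- if (free_n) fit$par[2] else n_slope
  off <- if (free_n) 2L else 1L
  lrs <- fit$par[off + 2 * seq_len(k)]
  lts <- fit$par[off + 2 * seq_len(k) - 1]
  ses <- rep(NA_real_, k)
  if (se_method == "bootstrap") {
    reps_list <- lapply(dl, function(g) sort(unique(g$replicate)))
    boot_vals <- with_seed(seed, {
      sapply(seq_len(n_boot), function(b) {
        data_b <- lapply(seq_len(k), function(i) {
          reps <- reps_list[[i]]
          take <- sample(reps, length(reps), replace = TRUE)
          do.call(rbind, lapply(take, function(r)
            dl[[i]][dl[[i]]$replicate == r, , drop = FALSE]))
        })
        ans <- tryCatch(solve_joint(data_b, fit$par),
                        error = function(e) NULL)
        if (is.null(ans)) rep(NA_real_, k) else
          ans$par[off + 2 * seq_len(k)]
      })
    })
    boot_vals <- matrix(boot_vals, nrow = k)
    ses <- apply(boot_vals, 1, stats::sd, na.rm = TRUE)
  } else {
    # per-agonist asymptotic SE with shared parameters held fixed
    for (i in seq_len(k)) {
      g <- dl[[i]]
      core <- list(par = c(lts[i], lrs[i]),
                   value = sum((g$response - op_predict(
                     g$conc_M, basal, em, nn, lts[i], lrs[i]))^2),
                   free_emax = FALSE, free_n = FALSE)
      ses[i] <- op_se_asymptotic(core, log10(g$conc_M), g$response, basal,
                                 em, nn)
    }
  }
  fits <- lapply(seq_len(k), function(i) {
    structure(list(
      assay_id = assay, agonist_id = attr(datasets[[i]], "agonist_id"),
      basal = basal, e_max_system = em, n_slope = nn,
      tau = 10^lts[i], k_a = 10^(lts[i] - lrs[i]),
      log_tau_over_ka = lrs[i], se_log_tau_over_ka = ses[i],
      ss = NA_real_, n_obs = nrow(dl[[i]]),
      n_replicates = length(unique(dl[[i]]$replicate))),
      class = "operational_fit")
  })
  names(fits) <- vapply(datasets, attr, character(1), "agonist_id")
  list(fits = fits, e_max_system = em, n_slope = nn, ss = fit$value)
}

#' Transduction-ratio difference against a reference agonist
#'
#' `DeltaLog(tau/K_A) = Log(tau/K_A)_agonist - Log(tau/K_A)_reference`
#' within one pathway; standard errors propagate in quadrature.
#'
#' @param fit_a,fit_ref `operational_fit` objects from the same assay.
#' @return List `value`, `se`, plus identifiers.
#' @export
delta_log <- function(fit_a, fit_ref) {
  stopifnot(inherits(fit_a, "operational_fit"),
            inherits(fit_ref, "operational_fit"))
  if (!identical(fit_a$assay_id, fit_ref$assay_id))
    stop("DeltaLog requires fits from the same assay")
  list(agonist_id = fit_a$agonist_id, reference_id = fit_ref$agonist_id,
       assay_id = fit_a$assay_id,
       value = fit_a$log_tau_over_ka - fit_ref$log_tau_over_ka,
       se = sqrt(fit_a$se_log_tau_over_ka^2 + fit_ref$se_log_tau_over_ka^2))
}

#' Bias factor between two pathways
#'
#' `DeltaDeltaLog(tau/K_A) = DeltaLog(pathway 1) - DeltaLog(pathway 2)`; a
#' positive value means bias toward pathway 1 relative to the reference
#' agonist. Both inputs must be computed against the same reference.
#'
#' @param dl_p1,dl_p2 results of [delta_log()] for the same agonist in two
#'   pathways.
#' @return List `value`, `se`, `pathway_pair`, plus identifiers.
#' @export
delta_delta_log <- function(dl_p1, dl_p2) {
  if (!identical(dl_p1$reference_id, dl_p2$reference_id))
    stop("both DeltaLog values must use the same reference agonist")
  list(agonist_id = dl_p1$agonist_id, reference_id = dl_p1$reference_id,
       pathway_pair = c(dl_p1$assay_id, dl_p2$assay_id),
       value = dl_p1$value - dl_p2$value,
       se = sqrt(dl_p1$se^2 + dl_p2$se^2))
}
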