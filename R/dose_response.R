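#' Flag outlying replicate values
#'
#' Applies the study-wide exclusion rule per concentration: a replicate value
#' is flagged when it differs from the mean of the *other* replicate values at
#' that concentration by more than three times the standard deviation of those
#' other values (leave-one-out mean and SD). The rule needs at least three
#' replicate values at a concentration; with fewer it is skipped there and a
#' warning is issued. Flagged points are retained in the record but ignored by
#' all fits.
#'
#' @param dataset a [conc_response()] object.
#' @return The dataset with its `excluded` column updated.
#' @export
#' @examples
#' d <- conc_response("a", "x", replicate = 1:5,
#'                    conc_M = rep(1e-7, 5),
#'                    response = c(10, 11, 9, 10, 500))
#' exclude_outliers(d)$excluded
exclude_outliers <- function(dataset) {
  stopifnot(is_conc_response(dataset))
  excl <- dataset$excluded
  skipped <- FALSE
  for (conc in unique(dataset$conc_M)) {
    idx <- which(dataset$conc_M == conc)
    if (length(idx) < 3L) {
      skipped <- TRUE
      next
    }
    vals <- dataset$response[idx]
    for (j in seq_along(idx)) {
      others <- vals[-j]
      s <- stats::sd(others)
      if (is.finite(s) && abs(vals[j] - mean(others)) > 3 * s)
        excl[idx[j]] <- TRUE
    }
  }
  if (skipped)
    warning("outlier rule skipped at concentration(s) with fewer than 3 ",
            "replicate values", call. = FALSE)
  dataset$excluded <- excl
  dataset
}

#' Logistic concentration-response function
#'
#' Evaluates the four-parameter logistic on the log10-concentration scale:
#' `bottom + (e_max - bottom) / (1 + 10^(hill * (log_ec50 - x)))` with
#' `x = log10(conc)`.
#'
#' @param log_conc log10 molar concentration(s).
#' @param log_ec50 log10 molar EC50.
#' @param e_max upper asymptote (assay units).
#' @param hill Hill slope.
#' @param bottom lower asymptote (assay units).
#' @return Numeric response(s).
#' @export
logistic_response <- function(log_conc, log_ec50, e_max, hill = 1, bottom = 0) {
  bottom + (e_max - bottom) / (1 + 10^(hill * (log_ec50 - log_conc)))
}

# invert the logistic: log10 concentration giving `response`
logistic_inverse <- function(response, log_ec50, e_max, hill = 1, bottom = 0) {
  f <- (response - bottom) / (e_max - bottom)
  if (any(f <= 0 | f >= 1)) stop("response level outside the curve's range")
  log_ec50 - log10(1 / f - 1) / hill
}

# Single-curve logistic fit. Grid over (log_ec50, hill) with conditionally
# linear (bottom, e_max) solved by least squares, then nlsLM polish.
# Deterministic: fixed grid, no randomness.
fit_logistic_one <- function(log_conc, response, model_kind = "four_param",
                             bottom_fixed_at_zero = FALSE) {
  hill_grid <- if (model_kind == "three_param_hill1") 1 else
    c(0.3, 0.5, 0.7, 1, 1.5, 2, 3)
  le_grid <- seq(min(log_conc) - 1, max(log_conc) + 1, by = 0.1)
  best <- NULL
  for (h in hill_grid) {
    for (le in le_grid) {
      f <- 1 / (1 + 10^(h * (le - log_conc)))
      if (bottom_fixed_at_zero) {
        emax <- sum(f * response) / sum(f * f)
        pred <- emax * f
        bot <- 0
      } else {
        X <- cbind(1 - f, f)
        cf <- tryCatch(stats::lm.fit(X, response)$coefficients,
                       error = function(e) c(NA, NA))
        if (any(!is.finite(cf))) next
        bot <- cf[1]; emax <- cf[2]
        pred <- bot * (1 - f) + emax * f
      }
      ss <- sum((response - pred)^2)
      if (is.null(best) || ss < best$ss)
        best <- list(ss = ss, log_ec50 = le, hill = h, e_max = emax,
                     bottom = bot)
    }
  }
  if (is.null(best)) stop("logistic grid search failed")
  dat <- data.frame(x = log_conc, y = response)
  st <- best
  fit <- tryCatch({
    if (model_kind == "three_param_hill1" && bottom_fixed_at_zero) {
      minpack.lm::nlsLM(y ~ e_max / (1 + 10^(log_ec50 - x)), data = dat,
                        start = list(log_ec50 = st$log_ec50, e_max = st$e_max),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else if (model_kind == "three_param_hill1") {
      minpack.lm::nlsLM(y ~ bottom + (e_max - bottom) /
                          (1 + 10^(log_ec50 - x)), data = dat,
                        start = list(log_ec50 = st$log_ec50, e_max = st$e_max,
                                     bottom = st$bottom),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else if (bottom_fixed_at_zero) {
      minpack.lm::nlsLM(y ~ e_max / (1 + 10^(hill * (log_ec50 - x))),
                        data = dat,
                        start = list(log_ec50 = st$log_ec50, e_max = st$e_max,
                                     hill = st$hill),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ bottom + (e_max - bottom) /
                          (1 + 10^(hill * (log_ec50 - x))), data = dat,
                        start = list(log_ec50 = st$log_ec50, e_max = st$e_max,
                                     hill = st$hill, bottom = st$bottom),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(log_ec50 = st$log_ec50, e_max = st$e_max,
            hill = if (model_kind == "three_param_hill1") 1 else st$hill,
            bottom = if (bottom_fixed_at_zero) 0 else unname(st$bottom))
  } else {
    cf0 <- stats::coef(fit)
    cf <- c(log_ec50 = unname(cf0["log_ec50"]),
            e_max = unname(cf0["e_max"]),
            hill = if (model_kind == "three_param_hill1") 1 else
              unname(cf0["hill"]),
            bottom = if (bottom_fixed_at_zero) 0 else unname(cf0["bottom"]))
  }
  cf
}

#' Fit a logistic model to a concentration-response dataset
#'
#' Fits curves on the log10-concentration scale. Each replicate (independent
#' experiment) is fitted individually and the per-replicate log EC50 and E_max
#' values are summarised as mean and SEM, mirroring the study's
#' per-experiment-then-combine convention; a pooled fit over all included
#' points is returned alongside for the stages (operational and Furchgott
#' analyses) that need a single curve. Excluded points are ignored.
#'
#' @param dataset a [conc_response()] object, normally after
#'   [exclude_outliers()].
#' @param model_kind `"four_param"` (log EC50, E_max, Hill, bottom) or
#'   `"three_param_hill1"` (Hill slope fixed at 1).
#' @param bottom_fixed_at_zero constrain the lower asymptote to 0 (the
#'   convention for background-subtracted assay data).
#' @return A `logistic_fit` object: list with `log_ec50`, `e_max`, `hill`,
#'   `bottom` (per-replicate means), `sem_log_ec50`, `sem_e_max`,
#'   `per_replicate` (data frame), `pooled` (named vector from the pooled
#'   fit), `model_kind`, and the dataset's identifiers.
#' @export
fit_logistic <- function(dataset, model_kind = c("four_param",
                                                 "three_param_hill1"),
                         bottom_fixed_at_zero = FALSE) {
  stopifnot(is_conc_response(dataset))
  model_kind <- match.arg(model_kind)
  d <- included_rows(dataset)
  if (nrow(d) == 0) stop("no included observations")
  per_rep <- list()
  for (r in sort(unique(d$replicate))) {
    g <- d[d$replicate == r, , drop = FALSE]
    if (length(unique(g$conc_M)) < 4L) next
    cf <- tryCatch(
      fit_logistic_one(log10(g$conc_M), g$response, model_kind,
                       bottom_fixed_at_zero),
      error = function(e) {
        message("replicate ", r, " did not converge; dropped from summary")
        NULL
      })
    if (!is.null(cf))
      per_rep[[length(per_rep) + 1L]] <- c(replicate = r, cf)
  }
  if (!length(per_rep))
    stop("no replicate produced a convergent logistic fit")
  per_rep <- as.data.frame(do.call(rbind, per_rep))
  pooled <- fit_logistic_one(log10(d$conc_M), d$response, model_kind,
                             bottom_fixed_at_zero)
  n <- nrow(per_rep)
  sem <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else 0
  structure(list(
    assay_id = attr(dataset, "assay_id"),
    agonist_id = attr(dataset, "agonist_id"),
    treatment_arm = attr(dataset, "treatment_arm"),
    model_kind = model_kind,
    bottom_fixed_at_zero = bottom_fixed_at_zero,
    log_ec50 = mean(per_rep$log_ec50),
    e_max = mean(per_rep$e_max),
    hill = mean(per_rep$hill),
    bottom = mean(per_rep$bottom),
    sem_log_ec50 = sem(per_rep$log_ec50),
    sem_e_max = sem(per_rep$e_max),
    per_replicate = per_rep,
    pooled = pooled), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %s / %s (%s, %s)\n", x$assay_id, x$agonist_id,
              x$treatment_arm, x$model_kind))
  cat(sprintf("  log EC50 = %.3f +/- %.3f  E_max = %.2f +/- %.2f  Hill = %.2f  bottom = %.2f\n",
              x$log_ec50, x$sem_log_ec50, x$e_max, x$sem_e_max, x$hill,
              x$bottom))
  cat(sprintf("  (%d replicate fits; pooled log EC50 = %.3f)\n",
              nrow(x$per_replicate), x$pooled[["log_ec50"]]))
  invisible(x)
}

#' Fold-potency ratio between two fitted curves
#'
#' Computes `10^(log_ec50_reference - log_ec50_agonist)` from the mean
#' per-replicate log EC50s, so a value above 1 means the agonist is more
#' potent than the reference.
#'
#' @param fit_a,fit_ref `logistic_fit` objects from the same assay.
#' @return A `fold_potency` list: `agonist_id`, `reference_id`, `fold`.
#' @export
#' @examples
#' fold_potency_value(-8.11, -6.48)  # carfentanil vs DAMGO, ~43-fold
fold_potency <- function(fit_a, fit_ref) {
  stopifnot(inherits(fit_a, "logistic_fit"), inherits(fit_ref, "logistic_fit"))
  if (!identical(fit_a$assay_id, fit_ref$assay_id))
    stop("fold potency requires fits from the same assay")
  structure(list(agonist_id = fit_a$agonist_id,
                 reference_id = fit_ref$agonist_id,
                 fold = fold_potency_value(fit_a$log_ec50, fit_ref$log_ec50)),
            class = "fold_potency")
}

#' @rdname fold_potency
#' @param log_ec50_a,log_ec50_ref mean log10 EC50 values (log molar).
#' @export
fold_potency_value <- function(log_ec50_a, log_ec50_ref) {
  10^(log_ec50_ref - log_ec50_a)
}

#' @export
print.fold_potency <- function(x, ...) {
  cat(sprintf("%s is %.3g-fold %s potent than %s\n", x$agonist_id,
              max(x$fold, 1 / x$fold),
              if (x$fold >= 1) "more" else "less", x$reference_id))
  invisible(x)
}
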