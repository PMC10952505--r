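# Brute-force oracles, independent of the package's fitting code paths.

# sum of squares of a 4PL at given parameters
sse_logistic <- function(log_conc, response, log_ec50, e_max, hill, bottom) {
  pred <- bottom + (e_max - bottom) / (1 + 10^(hill * (log_ec50 - log_conc)))
  sum((response - pred)^2)
}

# coarse-to-fine grid search over (log_ec50, e_max, hill), bottom fixed 0
grid_logistic <- function(log_conc, response, centre, widths, steps = 21,
                          refinements = 4) {
  best <- c(centre, sse = Inf)
  for (it in seq_len(refinements)) {
    le <- seq(centre[1] - widths[1], centre[1] + widths[1],
              length.out = steps)
    em <- seq(centre[2] - widths[2], centre[2] + widths[2],
              length.out = steps)
    hi <- seq(max(centre[3] - widths[3], 0.05), centre[3] + widths[3],
              length.out = steps)
    for (a in le) for (b in em) for (h in hi) {
      s <- sse_logistic(log_conc, response, a, b, h, 0)
      if (s < best["sse"]) best <- c(a, b, h, sse = s)
    }
    centre <- best[1:3]
    widths <- widths / 5
  }
  names(best) <- c("log_ec50", "e_max", "hill", "sse")
  best
}

# operational-model sum of squares in (tau, k_a, e_max), basal 0, n 1
sse_operational <- function(conc, response, tau, k_a, e_max) {
  ta <- tau * conc
  pred <- e_max * ta / (ta + conc + k_a)
  sum((response - pred)^2)
}

# exhaustive grid over (log tau, log KA, e_max) at 0.01 log-unit resolution
grid_operational <- function(conc, response, lt_range, lka_range, em_range,
                             em_step = 0.25) {
  lts <- seq(lt_range[1], lt_range[2], by = 0.01)
  lkas <- seq(lka_range[1], lka_range[2], by = 0.01)
  ems <- seq(em_range[1], em_range[2], by = em_step)
  best <- list(sse = Inf)
  for (em in ems) for (lt in lts) {
    tau <- 10^lt
    for (lka in lkas) {
      s <- sse_operational(conc, response, tau, 10^lka, em)
      if (s < best$sse)
        best <- list(log_tau = lt, log_ka = lka, e_max = em, sse = s)
    }
  }
  best
}

# permutation max-|t| adjusted p-value for comparisons against a reference
perm_maxt_p <- function(values_by_group, reference_id, n_perm = 10000,
                        seed = 42) {
  groups <- rep(names(values_by_group), lengths(values_by_group))
  values <- unlist(values_by_group, use.names = FALSE)
  others <- setdiff(names(values_by_group), reference_id)
  tstat <- function(g) {
    ref <- values[g == reference_id]
    max(vapply(others, function(o) {
      x <- values[g == o]
      abs(mean(x) - mean(ref)) /
        sqrt(stats::var(x) / length(x) + stats::var(ref) / length(ref))
    }, numeric(1)))
  }
  obs <- tstat(groups)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_perm), function(i)
    tstat(sample(groups)) >= obs, logical(1)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  (exceed + 1) / (n_perm + 1)
}

# one-phase decay SSE for the grid oracle
sse_decay <- function(t, y, peak, plateau, k) {
  sum((y - (plateau + (peak - plateau) * exp(-k * t)))^2)
}
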