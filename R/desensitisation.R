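#' GIRK current trace
#'
#' Container for a whole-cell recording of agonist-evoked GIRK current from
#' one neurone: sampled current versus time, the peak current evoked by the
#' noradrenaline reference application in the same cell (used to normalise
#' away cell-to-cell variability in channel expression), and labelled drug
#' application events.
#'
#' @param cell_id,drug_id character labels.
#' @param time_s sample times, seconds, strictly increasing.
#' @param current_pA sampled current, pA (same length as `time_s`).
#' @param na_peak_pA peak noradrenaline-evoked current in the same cell, > 0.
#' @param events data frame with columns `label`, `time` marking drug
#'   applications; the event labelled `"drug"` (or the first event) starts the
#'   analysed application.
#' @return A `current_trace` object.
#' @export
current_trace <- function(cell_id, drug_id, time_s, current_pA, na_peak_pA,
                          events = data.frame(label = "drug",
                                              time = min(time_s))) {
  stopifnot(length(time_s) == length(current_pA))
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (!is.finite(na_peak_pA) || na_peak_pA <= 0)
    stop("na_peak_pA must be positive")
  if (!all(c("label", "time") %in% names(events)))
    stop("events needs columns label, time")
  structure(list(cell_id = cell_id, drug_id = drug_id,
                 samples = data.frame(time_s = time_s,
                                      current_pA = current_pA),
                 na_peak_pA = na_peak_pA, events = events),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> cell=%s drug=%s: %d samples over %.0f s, NA peak %.3g pA\n",
              x$cell_id, x$drug_id, nrow(x$samples),
              diff(range(x$samples$time_s)), x$na_peak_pA))
  invisible(x)
}

#' Normalise a trace to the noradrenaline reference current
#'
#' Divides every current sample (and the reference itself) by the cell's
#' noradrenaline peak current, so currents become fractions of the maximal
#' GIRK conductance available in that neurone. Applying it to an
#' already-normalised trace (reference = 1) leaves the trace unchanged.
#'
#' @param trace a [current_trace()].
#' @return The normalised `current_trace` (reference peak becomes 1).
#' @export
normalise_to_na <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(trace$na_peak_pA) || !is.finite(trace$na_peak_pA))
    stop("missing noradrenaline reference current")
  trace$samples$current_pA <- trace$samples$current_pA / trace$na_peak_pA
  trace$na_peak_pA <- 1
  trace
}

# peak of the 5-sample moving average after the application event,
# on the baseline-subtracted current
trace_peak <- function(trace) {
  ev <- trace$events
  t_app <- if ("drug" %in% ev$label) ev$time[match("drug", ev$label)] else
    min(ev$time)
  s <- trace$samples
  pre <- s$current_pA[s$time_s < t_app & s$time_s >= t_app - 30]
  baseline <- if (length(pre)) mean(pre) else 0
  post <- s[s$time_s >= t_app, , drop = FALSE]
  y <- post$current_pA - baseline
  if (nrow(post) >= 5) {
    sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- -Inf
  } else sm <- y
  i0 <- which.max(sm)
  # raw maximum within the smoothing window around the smoothed argmax
  win <- max(1, i0 - 2):min(length(y), i0 + 2)
  i <- win[which.max(y[win])]
  list(peak = y[i], peak_time = post$time_s[i], baseline = baseline,
       t_app = t_app)
}

#' Fit a one-phase decay to the post-peak current
#'
#' Subtracts the pre-application baseline (30 s mean), locates the evoked
#' current's peak (maximum of a 5-sample moving average after the drug
#' application, which resists single-sample noise spikes), and fits
#' `I(t) = peak + (plateau - peak) * (1 - exp(-k * t))` to the segment from
#' the peak onwards with all three parameters (`peak` = the fitted current at
#' the peak, `plateau`, rate `k >= 0`) free, so sample noise at the detected
#' peak does not bias the decay. The extent of desensitisation at 10 min is
#' evaluated on the fitted decay at `t = 600 s` post peak. A post-peak
#' current that does not decline yields `k = 0` and 0% desensitisation with a
#' warning.
#'
#' @param trace a [current_trace()], normally after [normalise_to_na()].
#' @return A `desens_fit` object: `normalised_peak` (peak as fraction of the
#'   reference current), `plateau`, `rate_k` (1/s), `percent_desens_10min`,
#'   `peak_time`, and the fitted post-peak segment.
#' @export
fit_decay <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  pk <- trace_peak(trace)
  s <- trace$samples
  seg <- s[s$time_s >= pk$peak_time, , drop = FALSE]
  t_rel <- seg$time_s - pk$peak_time
  if (max(t_rel) < 600)
    stop("need at least 600 s of post-peak recording")
  y <- seg$current_pA - pk$baseline
  peak0 <- pk$peak
  late <- mean(y[t_rel >= 0.75 * max(t_rel)])
  early <- mean(y[t_rel <= 0.1 * max(t_rel)])
  if (peak0 <= 0 || late >= early * (1 - 1e-9)) {
    warning("post-peak current does not decline; k clamped at 0",
            call. = FALSE)
    cf <- c(peak = peak0, plateau = peak0, k = 0)
  } else {
    dat <- data.frame(t = t_rel, y = y)
    # coarse grid over the rate with (peak, plateau) solved linearly,
    # then Levenberg-Marquardt polish of all three parameters
    kg <- 10^seq(-5, 0, by = 0.25)
    ssg <- vapply(kg, function(k) {
      e <- exp(-k * t_rel)
      cfk <- tryCatch(stats::lm.fit(cbind(e, 1 - e), y)$coefficients,
                      error = function(err) c(NA, NA))
      if (any(!is.finite(cfk))) return(Inf)
      sum((y - (cfk[1] * e + cfk[2] * (1 - e)))^2)
    }, numeric(1))
    k0 <- kg[which.min(ssg)]
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ plateau + (peak - plateau) * exp(-k * t), data = dat,
      start = list(peak = peak0, plateau = min(y), k = k0),
      lower = c(0, -abs(peak0), 0), upper = c(2 * peak0, 2 * peak0, 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    cf <- if (is.null(fit)) c(peak = peak0, plateau = min(y), k = k0) else
      stats::coef(fit)
  }
  peak <- unname(cf[["peak"]])
  plateau <- unname(cf[["plateau"]])
  k <- unname(cf[["k"]])
  if (plateau > peak) {  # fitted drift upward: report no desensitisation
    warning("post-peak current does not decline; k clamped at 0",
            call. = FALSE)
    plateau <- peak; k <- 0
  }
  i600 <- plateau + (peak - plateau) * exp(-k * 600)
  pct <- if (peak > 0) 100 * (peak - i600) / peak else 0
  pct <- min(max(pct, 0), 100)
  structure(list(cell_id = trace$cell_id, drug_id = trace$drug_id,
                 normalised_peak = peak / trace$na_peak_pA,
                 plateau = plateau, rate_k = k,
                 percent_desens_10min = pct,
                 peak_time = pk$peak_time,
                 segment = data.frame(t = t_rel, current = y)),
            class = "desens_fit")
}

#' @export
print.desens_fit <- function(x, ...) {
  cat(sprintf("<desens_fit> cell=%s drug=%s\n", x$cell_id, x$drug_id))
  cat(sprintf("  peak = %.3g (of NA ref), plateau = %.3g, k = %.4g /s, desensitisation at 10 min = %.1f%%\n",
              x$normalised_peak, x$plateau, x$rate_k,
              x$percent_desens_10min))
  invisible(x)
}

#' Compare desensitisation across drugs
#'
#' One-way ANOVA with Dunnett post hoc comparisons of per-cell
#' desensitisation percentages against a reference drug; delegates to
#' [compare_to_reference()].
#'
#' @param groups named list of per-cell `percent_desens_10min` vectors.
#' @param reference_id name of the reference drug.
#' @param alpha ANOVA gate (default 0.05).
#' @return See [compare_to_reference()].
#' @export
compare_desens <- function(groups, reference_id, alpha = 0.05) {
  compare_to_reference(groups, reference_id, alpha)
}

#' Read a per-cell trace file
#'
#' Plain-text format: leading header lines `# key: value` (keys `cell_id`,
#' `drug`, `na_peak_pA`, `application_time_s`), then a CSV body with columns
#' `time_s`, `current_pA`.
#'
#' @param path path to the trace file.
#' @return A [current_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^#\\s*", "", l), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  need <- c("cell_id", "drug", "na_peak_pA", "application_time_s")
  if (!all(need %in% names(meta)))
    stop("trace header must provide: ", paste(need, collapse = ", "))
  body <- utils::read.csv(text = paste(lines[-hdr], collapse = "\n"))
  current_trace(meta$cell_id, meta$drug, body$time_s, body$current_pA,
                as.numeric(meta$na_peak_pA),
                events = data.frame(
                  label = "drug",
                  time = as.numeric(meta$application_time_s)))
}

#' Write a per-cell trace file
#'
#' @param trace a [current_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  ev <- trace$events
  t_app <- if ("drug" %in% ev$label) ev$time[match("drug", ev$label)] else
    min(ev$time)
  hdr <- c(paste0("# cell_id: ", trace$cell_id),
           paste0("# drug: ", trace$drug_id),
           paste0("# na_peak_pA: ", format(trace$na_peak_pA, digits = 12)),
           paste0("# application_time_s: ", format(t_app, digits = 12)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(trace$samples, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
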