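#' Per-replicate transduction ratios
#'
#' Fits the operational model to each replicate separately with the shared
#' system parameters (`e_max_system`, `n_slope`, `basal`) held fixed at their
#' joint-fit values, yielding one `Log(tau/K_A)` per independent experiment
#' for the reference-comparison statistics.
#'
#' @param dataset a [conc_response()] object.
#' @param e_max_system,n_slope,basal shared system parameters (fixed).
#' @return Data frame `replicate`, `log_r`.
#' @export
op_per_replicate_logr <- function(dataset, e_max_system, n_slope,
                                  basal = 0) {
  d <- included_rows(dataset)
  reps <- sort(unique(d$replicate))
  vals <- vapply(reps, function(r) {
    g <- d[d$replicate == r, , drop = FALSE]
    ans <- tryCatch(
      op_fit_core(log10(g$conc_M), g$response, basal, e_max_system, n_slope),
      error = function(e) NULL)
    if (is.null(ans)) NA_real_ else ans$par[2]
  }, numeric(1))
  data.frame(replicate = reps, log_r = vals)
}

#' Assemble the bias table
#'
#' Builds the transduction-ratio bias ledger: per agonist and pathway pair,
#' `DeltaLog(tau/K_A)` in each pathway against the reference agonist and their
#' difference `DeltaDeltaLog(tau/K_A)` with quadrature standard error. When
#' per-replicate transduction ratios are supplied, per-experiment
#' `DeltaDeltaLog` values (each replicate's ratio centred on the reference
#' agonist's mean ratio) feed a one-way ANOVA with Dunnett comparisons
#' against the reference.
#'
#' @param assay_fits named list: for each assay, the result of
#'   [fit_operational_assay()] (or a named list of `operational_fit`s).
#' @param reference_id reference agonist.
#' @param pairs list of length-2 character vectors `(pathway1, pathway2)`;
#'   positive bias means toward pathway 1.
#' @param per_replicate optional data frame `assay_id`, `agonist_id`,
#'   `replicate`, `log_r` from [op_per_replicate_logr()].
#' @param alpha ANOVA gate for the Dunnett stage.
#' @return A `bias_table` data frame: `agonist_id`, `pathway1`, `pathway2`,
#'   `delta_log_p1`, `delta_log_p2`, `delta_delta_log`, `se`, `p_adjusted`,
#'   `tested`.
#' @export
bias_table <- function(assay_fits, reference_id, pairs,
                       per_replicate = NULL, alpha = 0.05) {
  get_fits <- function(x) if (!is.null(x$fits)) x$fits else x
  rows <- list()
  for (pair in pairs) {
    p1 <- pair[[1]]; p2 <- pair[[2]]
    if (!p1 %in% names(assay_fits) || !p2 %in% names(assay_fits))
      stop("pathway pair references unknown assay: ", p1, ":", p2)
    f1 <- get_fits(assay_fits[[p1]])
    f2 <- get_fits(assay_fits[[p2]])
    if (!reference_id %in% names(f1) || !reference_id %in% names(f2))
      stop("reference agonist '", reference_id, "' missing from assay pair ",
           p1, ":", p2)
    shared <- intersect(names(f1), names(f2))
    # per-replicate DeltaDeltaLog lists for the Dunnett stage
    rep_lists <- NULL
    if (!is.null(per_replicate)) {
      rep_lists <- list()
      ref_mean <- function(assay) {
        v <- per_replicate$log_r[per_replicate$assay_id == assay &
                                   per_replicate$agonist_id == reference_id]
        mean(v, na.rm = TRUE)
      }
      m1 <- ref_mean(p1); m2 <- ref_mean(p2)
      for (ag in shared) {
        v1 <- per_replicate[per_replicate$assay_id == p1 &
                              per_replicate$agonist_id == ag, ]
        v2 <- per_replicate[per_replicate$assay_id == p2 &
                              per_replicate$agonist_id == ag, ]
        common <- intersect(v1$replicate, v2$replicate)
        dd <- (v1$log_r[match(common, v1$replicate)] - m1) -
          (v2$log_r[match(common, v2$replicate)] - m2)
        dd <- dd[is.finite(dd)]
        if (length(dd) >= 2) rep_lists[[ag]] <- dd
      }
    }
    p_adj <- stats::setNames(rep(NA_real_, length(shared)), shared)
    tested <- FALSE
    if (!is.null(rep_lists) && length(rep_lists) >= 3 &&
        reference_id %in% names(rep_lists)) {
      cmp <- compare_to_reference(rep_lists, reference_id, alpha)
      tested <- cmp$tested
      p_adj[cmp$comparisons$group] <- cmp$comparisons$p_adjusted
    }
    for (ag in shared) {
      dl1 <- delta_log(f1[[ag]], f1[[reference_id]])
      dl2 <- delta_log(f2[[ag]], f2[[reference_id]])
      dd <- delta_delta_log(dl1, dl2)
      rows[[length(rows) + 1L]] <- data.frame(
        agonist_id = ag, pathway1 = p1, pathway2 = p2,
        delta_log_p1 = dl1$value, delta_log_p2 = dl2$value,
        delta_delta_log = dd$value, se = dd$se,
        p_adjusted = unname(p_adj[ag]), tested = tested)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bias_table", "data.frame")
  attr(out, "reference_id") <- reference_id
  out
}

#' Pipeline configuration
#'
#' @param input path to an interchange CSV ([read_dataset()]), a list of
#'   [conc_response()] datasets, or `NULL` to simulate the study-like
#'   scenario with [simulate_scenario()].
#' @param reference_id reference agonist for all comparisons.
#' @param pairs list of pathway pairs for the bias stage (positive =
#'   toward the first pathway); empty list skips the bias stage.
#' @param model_kind logistic model for the empirical fits.
#' @param bottom_fixed_at_zero constrain logistic bottoms to 0.
#' @param run_furchgott run the receptor-inactivation stage for every
#'   agonist/assay with both treatment arms present.
#' @param n_levels horizontal lines for the Furchgott stage.
#' @param alpha significance threshold.
#' @param seed master seed (simulation and bootstrap).
#' @param n_boot bootstrap resamples for transduction-ratio SEs.
#' @param out_dir directory for report tables, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, reference_id = "DAMGO",
                            pairs = list(c("arrestin", "gprot")),
                            model_kind = "four_param",
                            bottom_fixed_at_zero = TRUE,
                            run_furchgott = TRUE, n_levels = 20,
                            alpha = 0.05, seed = 1L, n_boot = 200,
                            out_dir = NULL) {
  structure(list(input = input, reference_id = reference_id, pairs = pairs,
                 model_kind = model_kind,
                 bottom_fixed_at_zero = bottom_fixed_at_zero,
                 run_furchgott = run_furchgott, n_levels = n_levels,
                 alpha = alpha, seed = as.integer(seed), n_boot = n_boot,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages in the study's analysis order: outlier exclusion,
#' per-replicate and pooled logistic fits, joint operational fits per assay,
#' the transduction-ratio bias ledger with Dunnett comparisons, and, for any
#' agonist/assay with a depleted arm, the Furchgott efficacy stage. Tables
#' (potency, bias, Furchgott) and a run log are written to
#' `config$out_dir` when set. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return A report list: `datasets`, `logistic_fits`, `potency_table`,
#'   `assay_fits`, `bias`, `furchgott`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("opbias %s", as.character(utils::packageVersion("opbias"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("R: %s", R.version.string))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  datasets <- stage("input", {
    if (is.null(config$input)) simulate_scenario(seed = config$seed)
    else if (is.character(config$input)) read_dataset(config$input)
    else config$input
  })
  datasets <- stage("exclude_outliers",
                    suppressWarnings(lapply(datasets, exclude_outliers)))
  is_control <- vapply(datasets, function(d)
    identical(attr(d, "treatment_arm"), "control"), logical(1))
  controls <- datasets[is_control]
  lfits <- stage("fit_logistic", lapply(controls, function(d)
    fit_logistic(d, config$model_kind, config$bottom_fixed_at_zero)))
  potency <- do.call(rbind, lapply(lfits, function(f)
    data.frame(assay_id = f$assay_id, agonist_id = f$agonist_id,
               log_ec50 = f$log_ec50, sem_log_ec50 = f$sem_log_ec50,
               e_max = f$e_max, sem_e_max = f$sem_e_max)))
  rownames(potency) <- NULL
  bias <- NULL
  assay_fits <- NULL
  if (length(config$pairs)) {
    assays_needed <- unique(unlist(config$pairs))
    assay_fits <- stage("fit_operational", {
      out <- list()
      for (assay in assays_needed) {
        ds <- controls[vapply(controls, function(d)
          identical(attr(d, "assay_id"), assay), logical(1))]
        if (!length(ds)) stop("no control datasets for assay ", assay)
        out[[assay]] <- fit_operational_assay(
          ds, se_method = "bootstrap", n_boot = config$n_boot,
          seed = config$seed)
      }
      out
    })
    per_rep <- stage("per_replicate_logr", {
      do.call(rbind, lapply(assays_needed, function(assay) {
        af <- assay_fits[[assay]]
        ds <- controls[vapply(controls, function(d)
          identical(attr(d, "assay_id"), assay), logical(1))]
        do.call(rbind, lapply(ds, function(d) {
          pr <- op_per_replicate_logr(d, af$e_max_system, af$n_slope)
          cbind(assay_id = assay, agonist_id = attr(d, "agonist_id"), pr)
        }))
      }))
    })
    bias <- stage("bias_table",
                  bias_table(assay_fits, config$reference_id, config$pairs,
                             per_replicate = per_rep, alpha = config$alpha))
  } else {
    log_lines <- c(log_lines, "bias stage skipped: no pathway pairs")
  }
  furch <- NULL
  if (isTRUE(config$run_furchgott)) {
    depleted <- datasets[!is_control]
    if (length(depleted)) {
      furch <- stage("furchgott", {
        rows <- list()
        for (d in depleted) {
          assay <- attr(d, "assay_id"); ag <- attr(d, "agonist_id")
          ctrl_idx <- which(vapply(controls, function(x)
            identical(attr(x, "assay_id"), assay) &&
              identical(attr(x, "agonist_id"), ag), logical(1)))
          if (!length(ctrl_idx)) next
          fit_c <- lfits[[ctrl_idx[1]]]
          fit_d <- fit_logistic(d, config$model_kind,
                                config$bottom_fixed_at_zero)
          pr <- equieffective_pairs(fit_c, fit_d, config$n_levels)
          ff <- fit_furchgott(pr)
          rs <- reserve_summary(fit_c, ff)
          rows[[paste(assay, ag, sep = "/")]] <- list(
            assay_id = assay, agonist_id = ag, pairs = pr, fit = ff,
            reserve = rs)
        }
        rows
      })
    } else log_lines <- c(log_lines, "furchgott stage skipped: no depleted arms")
  }
  report <- list(datasets = datasets, logistic_fits = lfits,
                 potency_table = potency, assay_fits = assay_fits,
                 bias = bias, furchgott = furch, log = log_lines)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# render report tables as delimited text
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$potency_table,
                   file.path(out_dir, "potency_table.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$bias))
    utils::write.csv(as.data.frame(report$bias),
                     file.path(out_dir, "bias_table.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(report$furchgott) && length(report$furchgott)) {
    tab <- do.call(rbind, lapply(report$furchgott, function(r)
      data.frame(assay_id = r$assay_id, agonist_id = r$agonist_id,
                 k_a_nM = r$fit$k_a * 1e9,
                 k_a_ci_lo_nM = r$fit$k_a_ci[1] * 1e9,
                 k_a_ci_hi_nM = r$fit$k_a_ci[2] * 1e9,
                 ka_over_ec50 = r$reserve$ka_over_ec50,
                 occupancy_at_half_max = r$reserve$occupancy_at_half_max,
                 q = r$fit$q, q_ci_lo = r$fit$q_ci[1],
                 q_ci_hi = r$fit$q_ci[2])))
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(out_dir, "furchgott_table.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
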