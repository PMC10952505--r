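#' Ground truth for a synthetic concentration-response assay
#'
#' Records the operational-model parameters, noise level and design from
#' which a synthetic dataset is generated, so recovery can be checked against
#' truth. Defaults emulate the study conditions: 5 independent replicates,
#' a 9-point half-log concentration grid centred on the expected EC50, and
#' additive Gaussian noise with SD equal to 5% of the system maximum
#' (BRET-style error bars are roughly constant across the response range).
#'
#' @param tau operational efficacy, > 0.
#' @param k_a equilibrium dissociation constant, molar, > 0.
#' @param basal response without agonist (default 0, background-subtracted).
#' @param e_max_system maximal system response (default 100, percent scale).
#' @param n_slope transducer slope (default 1).
#' @param q fraction of receptors left functional in the depleted arm
#'   (default `NA`; required by [simulate_depletion_arm()]).
#' @param noise_cv noise SD as a fraction of `e_max_system` (default 0.05).
#' @param n_replicates independent experiments (default 5).
#' @param conc_M concentration grid, molar; default 9 half-log steps spanning
#'   two decades either side of the predicted EC50.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(tau, k_a, basal = 0, e_max_system = 100,
                         n_slope = 1, q = NA_real_, noise_cv = 0.05,
                         n_replicates = 5, conc_M = NULL) {
  stopifnot(tau > 0, k_a > 0, n_slope > 0, noise_cv >= 0,
            n_replicates >= 1)
  if (!is.na(q) && (q <= 0 || q > 1)) stop("q must lie in (0, 1]")
  if (is.null(conc_M)) {
    ec50 <- k_a / ((2 + tau^n_slope)^(1 / n_slope) - 1)
    conc_M <- ec50 * 10^seq(-2, 2, by = 0.5)
  }
  if (any(conc_M <= 0)) stop("concentrations must be positive")
  structure(list(tau = tau, k_a = k_a, basal = basal,
                 e_max_system = e_max_system, n_slope = n_slope, q = q,
                 noise_cv = noise_cv, n_replicates = n_replicates,
                 conc_M = sort(conc_M),
                 log_tau_over_ka = log10(tau) - log10(k_a)),
            class = "ground_truth")
}

#' Simulate a concentration-response dataset from operational-model truth
#'
#' Responses are the operational-model mean plus independent Gaussian noise
#' with SD `noise_cv * e_max_system`, drawn per replicate and concentration.
#' Deterministic given `seed`.
#'
#' @param truth a [ground_truth()].
#' @param assay_id,agonist_id labels for the generated dataset.
#' @param treatment_arm `"control"` or `"depleted"` (the latter scales `tau`
#'   by `q`).
#' @param seed integer seed.
#' @return A [conc_response()] dataset.
#' @export
simulate_assay <- function(truth, assay_id = "assay", agonist_id = "drug",
                           treatment_arm = "control", seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  tau <- truth$tau
  if (treatment_arm == "depleted") {
    if (is.na(truth$q)) stop("truth$q required for a depleted arm")
    tau <- truth$q * tau
  }
  mu <- evaluate_operational(truth$basal, truth$e_max_system, tau,
                             truth$n_slope, truth$k_a, truth$conc_M)
  nrep <- truth$n_replicates
  nconc <- length(truth$conc_M)
  resp <- with_seed(seed, {
    rep(mu, nrep) + stats::rnorm(nrep * nconc,
                                 sd = truth$noise_cv * truth$e_max_system)
  })
  conc_response(assay_id, agonist_id, treatment_arm,
                replicate = rep(seq_len(nrep), each = nconc),
                conc_M = rep(truth$conc_M, nrep),
                response = resp)
}

#' Simulate a paired control/depleted experiment
#'
#' Models irreversible-antagonist pretreatment as pure receptor loss: the
#' depleted arm uses `q * tau` with `K_A`, `basal`, system maximum and
#' concentration grid unchanged, consistent with the Furchgott assumption
#' that the antagonist removes receptors without altering agonist affinity.
#'
#' @inheritParams simulate_assay
#' @return List with elements `control` and `depleted`, both
#'   [conc_response()] datasets (independent noise; seeds derived from
#'   `seed`).
#' @export
simulate_depletion_arm <- function(truth, assay_id = "assay",
                                   agonist_id = "drug", seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.na(truth$q)) stop("truth$q must be set for a depletion experiment")
  list(control = simulate_assay(truth, assay_id, agonist_id, "control",
                                seed = seed),
       depleted = simulate_assay(truth, assay_id, agonist_id, "depleted",
                                 seed = seed + 1000003L))
}

#' Ground truth for a synthetic GIRK current trace
#'
#' @param peak_fraction_of_na opioid peak current as a fraction of the
#'   noradrenaline reference peak.
#' @param plateau_fraction fitted-decay plateau, same units, <= peak.
#' @param decay_k one-phase decay rate, 1/s, >= 0.
#' @param sampling_rate Hz (default 1).
#' @param noise_sd Gaussian sample noise as a fraction of the reference peak.
#' @param na_peak_pA reference current amplitude in pA (default 100).
#' @param post_peak_s recording length after the peak, seconds (default 660).
#' @return A `girk_truth` list.
#' @export
girk_truth <- function(peak_fraction_of_na = 0.8, plateau_fraction = 0.4,
                       decay_k = 0.005, sampling_rate = 1, noise_sd = 0,
                       na_peak_pA = 100, post_peak_s = 660) {
  stopifnot(plateau_fraction <= peak_fraction_of_na, decay_k >= 0,
            sampling_rate > 0, noise_sd >= 0, na_peak_pA > 0)
  structure(list(peak_fraction_of_na = peak_fraction_of_na,
                 plateau_fraction = plateau_fraction, decay_k = decay_k,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 na_peak_pA = na_peak_pA, post_peak_s = post_peak_s),
            class = "girk_truth")
}

#' Simulate a GIRK current trace
#'
#' Builds a trace with 60 s of baseline, a 30 s saturating-exponential rise
#' to the peak after drug application, then a one-phase decay to the plateau,
#' plus Gaussian sample noise; the noradrenaline reference peak is recorded
#' in the metadata. Deterministic given `seed`.
#'
#' @param truth a [girk_truth()].
#' @param cell_id,drug_id labels.
#' @param seed integer seed.
#' @return A [current_trace()] in pA.
#' @export
simulate_girk_trace <- function(truth, cell_id = "cell1", drug_id = "drug",
                                seed = 1L) {
  stopifnot(inherits(truth, "girk_truth"))
  dt <- 1 / truth$sampling_rate
  t_app <- 60
  rise_s <- 30
  t_peak <- t_app + rise_s
  time <- seq(0, t_peak + truth$post_peak_s, by = dt)
  peak <- truth$peak_fraction_of_na * truth$na_peak_pA
  plateau <- truth$plateau_fraction * truth$na_peak_pA
  current <- numeric(length(time))
  rising <- time >= t_app & time < t_peak
  # saturating rise scaled to hit the peak exactly at t_peak
  rise_tau <- rise_s / 4
  scale <- 1 - exp(-rise_s / rise_tau)
  current[rising] <- peak * (1 - exp(-(time[rising] - t_app) / rise_tau)) /
    scale
  post <- time >= t_peak
  current[post] <- plateau + (peak - plateau) *
    exp(-truth$decay_k * (time[post] - t_peak))
  if (truth$noise_sd > 0)
    current <- current + with_seed(seed, stats::rnorm(
      length(time), sd = truth$noise_sd * truth$na_peak_pA))
  current_trace(cell_id, drug_id, time, current, truth$na_peak_pA,
                events = data.frame(label = "drug", time = t_app))
}

#' Study-like ground truths for the full bias scenario
#'
#' Six agonists by four assays (G-protein activation BRET and GIRK current on
#' the G-protein side; arrestin recruitment BRET and cell-surface receptor
#' loss on the arrestin side), with dissociation constants spanning the
#' potency range of the study's drug panel and a shared within-assay
#' transducer. One agonist, carfentanil, carries a 30-fold higher
#' transduction ratio in the two arrestin-side assays, so the generating
#' truth has `DeltaDeltaLog = log10(30) ~ 1.48` for carfentanil in every
#' arrestin-versus-G-protein pathway pair and 0 for all other agonists.
#'
#' @param noise_cv noise level passed to every [ground_truth()]
#'   (default 0.05).
#' @param n_replicates replicates per dataset (default 5).
#' @return Data frame with columns `assay_id`, `agonist_id` and a list-column
#'   `truth` of [ground_truth()] objects.
#' @export
paper_like_truths <- function(noise_cv = 0.05, n_replicates = 5) {
  agonists <- c("DAMGO", "morphine", "fentanyl", "carfentanil", "alfentanil",
                "sufentanil")
  k_a <- c(DAMGO = 1e-6, morphine = 2e-6, fentanyl = 3e-7,
           carfentanil = 2e-8, alfentanil = 1.5e-6, sufentanil = 1e-7)
  assays <- c(gprot = 10, girk = 10, arrestin = 3, surface_loss = 3)
  arrestin_side <- c("arrestin", "surface_loss")
  rows <- list()
  for (assay in names(assays)) {
    for (ag in agonists) {
      tau <- assays[[assay]]
      if (ag == "carfentanil" && assay %in% arrestin_side)
        tau <- tau * 30
      rows[[length(rows) + 1L]] <- list(assay_id = assay, agonist_id = ag,
        truth = ground_truth(tau = tau, k_a = k_a[[ag]],
                             noise_cv = noise_cv,
                             n_replicates = n_replicates))
    }
  }
  out <- data.frame(assay_id = vapply(rows, `[[`, character(1), "assay_id"),
                    agonist_id = vapply(rows, `[[`, character(1),
                                        "agonist_id"))
  out$truth <- lapply(rows, `[[`, "truth")
  out
}

#' Simulate the full study-like scenario
#'
#' Generates one [conc_response()] dataset per agonist/assay combination from
#' [paper_like_truths()], with dataset seeds derived deterministically from
#' `seed`.
#'
#' @param seed integer master seed.
#' @param noise_cv,n_replicates forwarded to [paper_like_truths()].
#' @return Named list of [conc_response()] datasets (`"assay/agonist"`), with
#'   the truth table attached as attribute `truths`.
#' @export
simulate_scenario <- function(seed = 1L, noise_cv = 0.05, n_replicates = 5) {
  truths <- paper_like_truths(noise_cv, n_replicates)
  datasets <- vector("list", nrow(truths))
  for (i in seq_len(nrow(truths))) {
    datasets[[i]] <- simulate_assay(truths$truth[[i]], truths$assay_id[i],
                                    truths$agonist_id[i],
                                    seed = seed + 7919L * i)
  }
  names(datasets) <- paste(truths$assay_id, truths$agonist_id, sep = "/")
  attr(datasets, "truths") <- truths
  datasets
}
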