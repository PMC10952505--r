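#' Concentration-response dataset
#'
#' A `conc_response` object holds replicate-resolved concentration-response
#' observations for a single agonist in a single assay and treatment arm
#' (control, or receptor-depleted after irreversible-antagonist pretreatment).
#' Responses are in whatever units the assay reports (e.g. % change from basal
#' for a G-protein BRET assay, background-subtracted BRET ratio for arrestin
#' recruitment, fraction of the noradrenaline reference current for GIRK
#' recordings); concentrations are molar.
#'
#' @param assay_id,agonist_id character scalars naming the assay and agonist.
#' @param treatment_arm `"control"` or `"depleted"`.
#' @param replicate integer vector of replicate (independent experiment)
#'   indices, contiguous from 1.
#' @param conc_M numeric vector of agonist concentrations in molar, > 0.
#' @param response numeric vector of responses, same length.
#' @param excluded logical vector flagging points excluded from fitting
#'   (default all `FALSE`; see [exclude_outliers()]).
#'
#' @return An object of class `conc_response`: a data frame with columns
#'   `replicate`, `conc_M`, `response`, `excluded` and attributes `assay_id`,
#'   `agonist_id`, `treatment_arm`.
#' @export
#' @examples
#' d <- conc_response("gprot", "DAMGO", "control",
#'                    replicate = rep(1:2, each = 3),
#'                    conc_M = rep(10^c(-8, -7, -6), 2),
#'                    response = c(5, 40, 95, 6, 42, 93))
#' d
conc_response <- function(assay_id, agonist_id, treatment_arm = "control",
                          replicate, conc_M, response,
                          excluded = rep(FALSE, length(conc_M))) {
  stopifnot(is.character(assay_id), length(assay_id) == 1L,
            is.character(agonist_id), length(agonist_id) == 1L)
  treatment_arm <- match.arg(treatment_arm, c("control", "depleted"))
  n <- length(conc_M)
  if (length(replicate) != n || length(response) != n || length(excluded) != n)
    stop("replicate, conc_M, response and excluded must have equal length")
  if (any(!is.finite(conc_M)) || any(conc_M <= 0))
    stop("concentrations must be finite and strictly positive (molar)")
  replicate <- as.integer(replicate)
  reps <- sort(unique(replicate))
  if (!identical(reps, seq_along(reps)))
    stop("replicate indices must be contiguous from 1")
  out <- data.frame(replicate = replicate, conc_M = as.numeric(conc_M),
                    response = as.numeric(response),
                    excluded = as.logical(excluded))
  structure(out, class = c("conc_response", "data.frame"),
            assay_id = assay_id, agonist_id = agonist_id,
            treatment_arm = treatment_arm)
}

#' @export
print.conc_response <- function(x, ...) {
  cat(sprintf("<conc_response> assay=%s agonist=%s arm=%s\n",
              attr(x, "assay_id"), attr(x, "agonist_id"),
              attr(x, "treatment_arm")))
  cat(sprintf("  %d observations, %d replicates, %d distinct concentrations",
              nrow(x), length(unique(x$replicate)),
              length(unique(x$conc_M))))
  if (any(x$excluded)) cat(sprintf(", %d excluded", sum(x$excluded)))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @rdname conc_response
#' @param x object to test or print.
#' @param ... passed on.
#' @export
is_conc_response <- function(x) inherits(x, "conc_response")

# rows usable for fitting
included_rows <- function(dataset) {
  as.data.frame(dataset)[!dataset$excluded, , drop = FALSE]
}

#' Read a long-format concentration-response file
#'
#' Reads the package interchange format: comma-separated text with a mandatory
#' header `assay_id,agonist_id,treatment_arm,replicate,conc_M,response`.
#' Concentrations are molar (scientific notation accepted). Each
#' assay/agonist/arm combination becomes one [conc_response()] object.
#'
#' @param path path to a CSV file.
#' @return A list of `conc_response` objects, named
#'   `"assay/agonist/arm"`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("assay_id", "agonist_id", "treatment_arm", "replicate",
                "conc_M", "response")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_conc <- !is.finite(df$conc_M) | df$conc_M <= 0
  if (any(bad_conc))
    stop("non-positive or unparseable conc_M at line(s): ",
         paste(line[bad_conc], collapse = ", "))
  key <- paste(df$assay_id, df$agonist_id, df$treatment_arm, df$replicate,
               df$conc_M, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (assay, agonist, arm, replicate, conc) rows at line(s): ",
         paste(line[duplicated(key)], collapse = ", "))
  groups <- split(seq_len(nrow(df)),
                  paste(df$assay_id, df$agonist_id, df$treatment_arm,
                        sep = "/"))
  out <- lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    rep_map <- match(g$replicate, sort(unique(g$replicate)))
    conc_response(g$assay_id[1], g$agonist_id[1], g$treatment_arm[1],
                  replicate = rep_map, conc_M = g$conc_M,
                  response = g$response)
  })
  out[order(names(out))]
}

#' Write concentration-response datasets to the interchange format
#'
#' @param datasets a single `conc_response` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(datasets, path) {
  if (is_conc_response(datasets)) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    data.frame(assay_id = attr(d, "assay_id"),
               agonist_id = attr(d, "agonist_id"),
               treatment_arm = attr(d, "treatment_arm"),
               replicate = d$replicate, conc_M = d$conc_M,
               response = d$response)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
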