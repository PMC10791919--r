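## CSV interchange. All writers emit one header row, UTF-8, '.' decimal;
## readers restore column types so that write -> read round-trips.

#' @rdname trial-io
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trial-record CSV
#'
#' Columns: `observer_id, protocol, trial, level, unit, site_stim,
#' site_resp, correct, rt_ms, censored`.
#'
#' @param trials trial-record data frame.
#' @param path file path.
#' @name trial-io
#' @return `read_trials` returns the trial data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(observer_id = "character",
                                 protocol = "character",
                                 trial = "integer", level = "numeric",
                                 unit = "character",
                                 site_stim = "character",
                                 site_resp = "character",
                                 correct = "logical", rt_ms = "numeric",
                                 censored = "logical"))
}

#' @rdname outcome-io
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write scored-outcome CSV
#'
#' @param outcomes a [score_battery()] table.
#' @param path file path.
#' @name outcome-io
#' @return `read_outcomes` returns the outcomes data frame.
#' @export
read_outcomes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(observer_id = "character",
                                 protocol = "character",
                                 outcome_kind = "character",
                                 outcome = "numeric", unit = "character",
                                 n_trials_used = "integer",
                                 flagged_scoring = "logical",
                                 flagged_outlier = "logical"))
}

#' @rdname cohort-io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cohort covariate CSV
#'
#' @param cohort cohort data frame (`observer_id`, `diagnosis`, `sex`,
#'   numeric covariates).
#' @param path file path.
#' @name cohort-io
#' @return `read_cohort` returns the cohort data frame (class `cohort`).
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$observer_id <- as.character(out$observer_id)
  class(out) <- c("cohort", "data.frame")
  out
}
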