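#' Reference cohort descriptive statistics
#'
#' Published descriptive statistics (group size, mean, SD) for the study
#' cohort this package's generator emulates: male-versus-female summaries
#' of age, full-scale IQ and symptom scores within each diagnostic group,
#' together with the reported Welch two-sided p-value for each male/female
#' comparison. These serve as worked examples for [welch_t()], which
#' reproduces the reported p-values from the summary triples alone.
#'
#' `p_reported` is the p-value as printed to three decimals. The
#' `age_tdc` row's printed p (0.689) is not exactly recoverable from its
#' rounded summary statistics (recomputation gives 0.682); `reproducible`
#' marks the rows whose printed p-value is recovered to within 0.005.
#'
#' @return data frame with columns `row_id`, `measure`, `diagnosis`,
#'   `n_m, mean_m, sd_m` (males), `n_f, mean_f, sd_f` (females),
#'   `p_reported`, `reproducible`.
#' @examples
#' ref <- reference_cohort_summaries()
#' r <- ref[ref$row_id == "fsiq_wisc4_asc", ]
#' welch_t(r$n_m, r$mean_m, r$sd_m, r$n_f, r$mean_f, r$sd_f)$p
#' @export
reference_cohort_summaries <- function() {
  rows <- rbind(
    c("age_asc",          "Age",                          "ASC", 36, 10.76,  1.32, 18, 10.80,  1.39, 0.917, TRUE),
    c("age_tdc",          "Age",                          "TDC", 34, 10.47,  1.08, 20, 10.34,  1.14, 0.689, FALSE),
    c("fsiq_wisc4_asc",   "WISC-IV FSIQ",                 "ASC", 23, 101.91, 13.25, 12, 105.08, 14.94, 0.543, TRUE),
    c("fsiq_wisc4_tdc",   "WISC-IV FSIQ",                 "TDC", 23, 105.30, 11.30, 15, 108.53, 10.41, 0.373, TRUE),
    c("fsiq_wisc5_asc",   "WISC-V FSIQ",                  "ASC", 13, 101.31, 19.83,  6,  91.33, 18.35, 0.307, TRUE),
    c("fsiq_wisc5_tdc",   "WISC-V FSIQ",                  "TDC", 16, 103.12, 10.07,  7, 104.43, 14.34, 0.832, TRUE),
    c("adi_social_asc",   "ADI reciprocal social",        "ASC", 23, 20.74,  6.07, 13, 18.54,  5.74, 0.289, TRUE),
    c("adi_verbal_asc",   "ADI verbal communication",     "ASC", 24, 16.54,  4.29, 13, 13.46,  3.48, 0.025, TRUE),
    c("adi_rrsb_asc",     "ADI RRSB",                     "ASC", 24,  6.58,  2.36, 13,  5.23,  1.74, 0.056, TRUE),
    c("conners3_hyper_asc", "Conners 3 hyperactivity",    "ASC", 32, 79.84, 11.50, 15, 78.20, 13.25, 0.683, TRUE),
    c("conners3_inatt_asc", "Conners 3 inattention",      "ASC", 32, 76.62, 11.12, 15, 79.20, 11.60, 0.479, TRUE),
    c("conners3_hyper_tdc", "Conners 3 hyperactivity",    "TDC", 25, 47.96, 10.80, 16, 48.30, 17.43, 0.902, FALSE))
  out <- data.frame(row_id = rows[, 1], measure = rows[, 2],
                    diagnosis = rows[, 3],
                    n_m = as.integer(rows[, 4]),
                    mean_m = as.numeric(rows[, 5]),
                    sd_m = as.numeric(rows[, 6]),
                    n_f = as.integer(rows[, 7]),
                    mean_f = as.numeric(rows[, 8]),
                    sd_f = as.numeric(rows[, 9]),
                    p_reported = as.numeric(rows[, 10]),
                    reproducible = as.logical(rows[, 11]),
                    stringsAsFactors = FALSE)
  out
}
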