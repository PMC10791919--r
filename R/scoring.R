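#' Mean response time by the median-six rule
#'
#' Sorts the usable RTs ascending and averages the six central values: for
#' `n` usable values, positions `floor((n - 6) / 2) + 1` through
#' `floor((n - 6) / 2) + 6`. With fewer than six usable values all are
#' averaged and the result is flagged.
#'
#' @param trials trial-record data frame (needs `rt_ms` and `correct`).
#' @param correct_only drop incorrect trials first (used for CRT).
#' @return list with `outcome` (ms), `n_trials_used`, and logical `flagged`
#'   (fewer than six usable trials).
#' @examples
#' tr <- data.frame(rt_ms = 1:20, correct = TRUE)
#' mean_rt(tr)$outcome  # 10.5
#' @export
mean_rt <- function(trials, correct_only = FALSE) {
  rts <- trials$rt_ms
  if (correct_only) rts <- rts[trials$correct]
  n <- length(rts)
  if (n == 0) stop("no usable trials for mean RT")
  rts <- sort(rts)
  if (n < 6) return(list(outcome = mean(rts), n_trials_used = n,
                         flagged = TRUE))
  lo <- floor((n - 6) / 2) + 1
  list(outcome = mean(rts[lo:(lo + 5)]), n_trials_used = n, flagged = FALSE)
}

#' Staircase threshold: mean level of the final trials
#'
#' @param trials trial-record data frame for one observer and protocol,
#'   ordered by `trial`.
#' @param k number of final trials to average (default 5).
#' @return the arithmetic mean of the last `k` tracked levels, in the
#'   protocol's unit.
#' @examples
#' tr <- data.frame(trial = 1:24, level = c(rep(20, 19), 10, 11, 10, 11, 10))
#' staircase_threshold(tr)  # 10.4
#' @export
staircase_threshold <- function(trials, k = 5L) {
  trials <- trials[order(trials$trial), , drop = FALSE]
  n <- nrow(trials)
  if (n < k) stop("need at least ", k, " trials, got ", n)
  mean(utils::tail(trials$level, k))
}

#' Dynamic-detection threshold: mean recorded amplitude
#'
#' Averages the recorded ramp amplitudes over all uncensored trials.
#'
#' @param trials DDT trial records (columns `level`, `censored`).
#' @return list with `outcome` (um), `n_trials_used` and `flagged` (TRUE
#'   when censored trials were dropped).
#' @export
dynamic_threshold <- function(trials) {
  cens <- if ("censored" %in% names(trials)) trials$censored else
    rep(FALSE, nrow(trials))
  ok <- !cens
  if (!any(ok)) stop("all dynamic-detection trials censored at the device bound")
  if (any(cens))
    warning(sum(cens), " censored dynamic-detection trial(s) excluded")
  list(outcome = mean(trials$level[ok]), n_trials_used = sum(ok),
       flagged = any(cens))
}

.PAIRS <- list(
  SDT_DDT   = c(first = "SDT",  second = "DDT"),
  ADT_ADTssa = c(first = "ADT", second = "ADTssa"),
  SQFD_SMFD = c(first = "SQFD", second = "SMFD"),
  TOJ_TOJwc = c(first = "TOJ",  second = "TOJwc"))

## printed-formula ratio orientation per pair: which member is the numerator
.PAIR_NUMERATOR <- c(SDT_DDT = "second", ADT_ADTssa = "first",
                     SQFD_SMFD = "second", TOJ_TOJwc = "second")

#' Percent-change index for a protocol pair
#'
#' Computes `100 * (numerator / denominator) - 100`. Three of the published
#' pair indices put the second (harder) condition in the numerator
#' (DDT/SDT, SMFD/SQFD, TOJwc/TOJ); the amplitude-discrimination index as
#' printed inverts the ratio (ADT/ADTssa). The default reproduces each
#' printed formula; `consistent_orientation = TRUE` computes every pair as
#' second/first instead.
#'
#' @param first threshold from the pair's first condition (> 0 when it is
#'   the denominator).
#' @param second threshold from the pair's second condition.
#' @param pair_id one of `"SDT_DDT"`, `"ADT_ADTssa"`, `"SQFD_SMFD"`,
#'   `"TOJ_TOJwc"`.
#' @param consistent_orientation force the second/first orientation for all
#'   pairs.
#' @return percent change (may be negative).
#' @examples
#' percent_change(10, 25, "SDT_DDT")      # 150
#' percent_change(20, 40, "ADT_ADTssa")   # -50 (printed orientation)
#' @export
percent_change <- function(first, second, pair_id = "SDT_DDT",
                           consistent_orientation = FALSE) {
  if (!pair_id %in% names(.PAIRS)) stop("unknown pair_id: ", pair_id)
  num_is_second <- consistent_orientation ||
    .PAIR_NUMERATOR[[pair_id]] == "second"
  num <- if (num_is_second) second else first
  den <- if (num_is_second) first else second
  if (any(den <= 0)) stop("percent_change denominator must be > 0")
  100 * (num / den) - 100
}

#' Median-absolute-deviation outlier mask
#'
#' Keeps a value iff its robust z-score,
#' `|x - median| / (constant * MAD)`, does not exceed `threshold`, where
#' `MAD` is the median of absolute deviations from the median and the
#' consistency `constant` 1.4826 puts the denominator on the SD scale for
#' Gaussian data. If the MAD is zero, values equal to the median are kept
#' and a warning is emitted.
#'
#' @param values numeric vector, length >= 3.
#' @param threshold robust z cutoff (default 2.5).
#' @param constant consistency constant (default 1.4826).
#' @return logical mask, `TRUE` = keep.
#' @examples
#' mad_outlier_filter(c(1, 2, 3, 4, 100))  # TRUE TRUE TRUE TRUE FALSE
#' @export
mad_outlier_filter <- function(values, threshold = 2.5, constant = 1.4826) {
  if (length(values) < 3) stop("need at least 3 values")
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) {
    warning("MAD is zero; keeping only values equal to the median")
    return(values == med)
  }
  abs(values - med) / (constant * mad_raw) <= threshold
}

protocol_outcome_kind <- function(protocol_id) {
  switch(protocol_id,
         SRT = , CRT = "mean_rt",
         SDT = "static_threshold",
         DDT = "dynamic_threshold",
         ADT = , ADTssa = "discrimination_threshold",
         SQFD = , SMFD = "discrimination_threshold",
         TOJ = , TOJwc = "toj_threshold",
         stop("unknown protocol: ", protocol_id))
}

#' Score a battery's trial records into outcome measures
#'
#' Applies the per-protocol extraction rules: median-six mean RT for
#' SRT/CRT (correct responses only for CRT), final-five staircase means for
#' the tracked protocols, and the all-trial mean for dynamic detection.
#'
#' @param trials trial records for any number of observers/protocols (the
#'   [run_battery()] format).
#' @param k number of final staircase trials averaged (default 5).
#' @return data frame of threshold records: `observer_id, protocol,
#'   outcome_kind, outcome, unit, n_trials_used, flagged_outlier` (the
#'   outlier flag is `FALSE` until [flag_outliers()] is applied; scoring
#'   flags, e.g. censored ramp trials, are carried in `flagged_scoring`).
#' @export
score_battery <- function(trials, k = 5L) {
  split_by <- interaction(trials$observer_id, trials$protocol, drop = TRUE)
  pieces <- split(trials, split_by)
  rows <- lapply(pieces, function(tr) {
    pid <- tr$protocol[1]
    kind <- protocol_outcome_kind(pid)
    flagged <- FALSE
    if (kind == "mean_rt") {
      r <- mean_rt(tr, correct_only = pid == "CRT")
      outcome <- r$outcome; used <- r$n_trials_used; flagged <- r$flagged
      unit <- "ms_rt"
    } else if (kind == "dynamic_threshold") {
      r <- dynamic_threshold(tr)
      outcome <- r$outcome; used <- r$n_trials_used; flagged <- r$flagged
      unit <- tr$unit[1]
    } else {
      outcome <- staircase_threshold(tr, k)
      used <- nrow(tr); unit <- tr$unit[1]
    }
    data.frame(observer_id = tr$observer_id[1], protocol = pid,
               outcome_kind = kind, outcome = outcome, unit = unit,
               n_trials_used = used, flagged_scoring = flagged,
               flagged_outlier = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derived percent-change indices for the four protocol pairs
#'
#' @param outcomes a [score_battery()] table.
#' @param consistent_orientation see [percent_change()].
#' @return data frame `observer_id, pair_id, first, second, percent_change`;
#'   observers missing either member of a pair are omitted.
#' @export
derive_indices <- function(outcomes, consistent_orientation = FALSE) {
  rows <- list()
  for (pid in names(.PAIRS)) {
    pr <- .PAIRS[[pid]]
    a <- outcomes[outcomes$protocol == pr[["first"]],
                  c("observer_id", "outcome")]
    b <- outcomes[outcomes$protocol == pr[["second"]],
                  c("observer_id", "outcome")]
    m <- merge(a, b, by = "observer_id", suffixes = c("_first", "_second"))
    if (!nrow(m)) next
    rows[[pid]] <- data.frame(
      observer_id = m$observer_id, pair_id = pid,
      first = m$outcome_first, second = m$outcome_second,
      percent_change = percent_change(m$outcome_first, m$outcome_second,
                                      pid, consistent_orientation),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag outliers in an outcome table by the MAD rule
#'
#' Applies [mad_outlier_filter()] within groups and sets the
#' `flagged_outlier` column. Grouping `"cell"` filters within each protocol
#' by diagnosis-by-sex cell (requires `cohort`); `"protocol"` filters each
#' protocol globally.
#'
#' @param outcomes a [score_battery()] table.
#' @param cohort cohort data frame with `observer_id`, `diagnosis`, `sex`
#'   (needed for `grouping = "cell"`).
#' @param threshold,constant passed to [mad_outlier_filter()].
#' @param grouping `"cell"` (default) or `"protocol"`.
#' @return `outcomes` with `flagged_outlier` updated. Groups with fewer
#'   than 3 values are left unflagged.
#' @export
flag_outliers <- function(outcomes, cohort = NULL, threshold = 2.5,
                          constant = 1.4826, grouping = c("cell",
                                                          "protocol")) {
  grouping <- match.arg(grouping)
  if (grouping == "cell") {
    if (is.null(cohort))
      stop("grouping = \"cell\" requires a cohort table")
    idx <- match(outcomes$observer_id, cohort$observer_id)
    grp <- paste(outcomes$protocol, cohort$diagnosis[idx],
                 cohort$sex[idx], sep = ".")
  } else {
    grp <- outcomes$protocol
  }
  outcomes$flagged_outlier <- FALSE
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) < 3) next
    keep <- suppressWarnings(
      mad_outlier_filter(outcomes$outcome[sel], threshold, constant))
    outcomes$flagged_outlier[sel] <- !keep
  }
  outcomes
}
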