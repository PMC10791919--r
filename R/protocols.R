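#' Protocol descriptions for the nine-task battery
#'
#' Each protocol is an immutable list of stimulus constants and staircase
#' parameters. [default_specs()] returns the battery as published: trial
#' counts, intertrial intervals, standard/comparison values, step sizes, the
#' rule switch after trial 10, and device limits (amplitudes 0-350 um,
#' frequencies 0-50 Hz).
#'
#' @param protocol_id one of SRT, CRT, SDT, DDT, ADT, ADTssa, SQFD, SMFD,
#'   TOJ, TOJwc.
#' @param ... overrides for any field of the default spec.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol_id, ...) {
  specs <- default_specs()
  if (!protocol_id %in% names(specs))
    stop("unknown protocol: ", protocol_id)
  spec <- specs[[protocol_id]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown protocol_spec field(s): ",
                        paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  validate_protocol_spec(spec)
  spec
}

validate_protocol_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$protocol_id))
  if (spec$n_trials < 1) stop("n_trials must be >= 1")
  if (spec$kind == "staircase") {
    if (spec$step <= 0) stop("step must be > 0")
    if (spec$lower_bound <= 0 || spec$upper_bound <= spec$lower_bound)
      stop("bounds must satisfy 0 < lower < upper")
    if (spec$start < spec$lower_bound || spec$start > spec$upper_bound)
      stop("starting level outside bounds")
  }
  invisible(spec)
}

#' The battery's nine protocols with published constants
#'
#' @return named list of `protocol_spec` objects: SRT, CRT, SDT, DDT, ADT,
#'   ADTssa, SQFD, SMFD, TOJ, TOJwc (the dynamic-detection DDT is a ramp,
#'   not a staircase).
#' @examples
#' specs <- default_specs()
#' specs$SDT$n_trials   # 24
#' specs$TOJ$start      # 150 ms initial ISI
#' @export
default_specs <- function() {
  sc <- function(protocol_id, n_trials, iti, start, step, step_type,
                 lower, upper, unit, pair_id, condition_index, stimulus) {
    structure(list(protocol_id = protocol_id, kind = "staircase",
                   n_trials = n_trials, iti = iti, start = start,
                   step = step, step_type = step_type,
                   rule_switch_trial = 10L,
                   lower_bound = lower, upper_bound = upper, unit = unit,
                   pair_id = pair_id, condition_index = condition_index,
                   stimulus = stimulus),
              class = "protocol_spec")
  }
  rt <- function(protocol_id, condition_index) {
    structure(list(protocol_id = protocol_id, kind = "rt", n_trials = 20L,
                   iti = 3, start = 300, step = NA_real_,
                   step_type = "none", rule_switch_trial = NA_integer_,
                   lower_bound = 0, upper_bound = 350, unit = "um",
                   pair_id = "SRT_CRT", condition_index = condition_index,
                   stimulus = list(duration_ms = 40, frequency_hz = 25,
                                   amplitude_um = 300)),
              class = "protocol_spec")
  }
  list(
    SRT = rt("SRT", 1L),
    CRT = rt("CRT", 2L),
    SDT = sc("SDT", 24L, 3, start = 20, step = 1, "additive",
             lower = 1, upper = 350, unit = "um", "SDT_DDT", 1L,
             list(duration_ms = 500, frequency_hz = 25)),
    DDT = structure(list(protocol_id = "DDT", kind = "ramp", n_trials = 7L,
                         iti = 3, start = 0, step = NA_real_,
                         step_type = "none", rule_switch_trial = NA_integer_,
                         lower_bound = 0, upper_bound = 350, unit = "um",
                         pair_id = "SDT_DDT", condition_index = 2L,
                         stimulus = list(frequency_hz = 25,
                                         ramp_rate_um_s = 2,
                                         delay_range_ms = c(0, 2500))),
                    class = "protocol_spec"),
    ADT = sc("ADT", 24L, 3, start = 100, step = 10, "additive",
             lower = 10, upper = 250, unit = "um", "ADT_ADTssa", 1L,
             list(duration_ms = 500, frequency_hz = 25,
                  standard_amplitude_um = 100,
                  comparison_start_um = 200)),
    ADTssa = sc("ADTssa", 24L, 3, start = 100, step = 10, "additive",
                lower = 10, upper = 250, unit = "um", "ADT_ADTssa", 2L,
                list(duration_ms = 500, frequency_hz = 25,
                     standard_amplitude_um = 100,
                     comparison_start_um = 200,
                     adapter = list(duration_ms = 1000, frequency_hz = 25,
                                    amplitude_um = 100, lead_ms = 500))),
    SQFD = sc("SQFD", 20L, 5, start = 10, step = 1, "additive",
              lower = 1, upper = 20, unit = "Hz", "SQFD_SMFD", 1L,
              list(duration_ms = 500, standard_frequency_hz = 30,
                   comparison_start_hz = 40, amplitude_um = 200,
                   isi_ms = 500)),
    SMFD = sc("SMFD", 20L, 5, start = 10, step = 1, "additive",
              lower = 1, upper = 20, unit = "Hz", "SQFD_SMFD", 2L,
              list(duration_ms = 500, standard_frequency_hz = 30,
                   comparison_start_hz = 40, amplitude_um = 200)),
    TOJ = sc("TOJ", 20L, 5, start = 150, step = 0.10, "proportional",
             lower = 1, upper = 1000, unit = "ms", "TOJ_TOJwc", 1L,
             list(duration_ms = 40, frequency_hz = 25, amplitude_um = 200)),
    TOJwc = sc("TOJwc", 20L, 5, start = 150, step = 0.10, "proportional",
               lower = 1, upper = 1000, unit = "ms", "TOJ_TOJwc", 2L,
               list(duration_ms = 40, frequency_hz = 25, amplitude_um = 200,
                    carrier = list(frequency_hz = 25, amplitude_um = 20,
                                   duration_s = 1))))
}

## Core staircase transition. Phase 1 (trials 1..rule_switch): one-up
## one-down. Phase 2: one incorrect steps the level up; two consecutive
## correct responses step it down and reset the counter (Levitt transformed
## track converging to sqrt(0.5) ~ 70.7% correct). Additive tracks move by
## `step`; proportional tracks (TOJ) by 10% of the current level.
staircase_next <- function(level, trial_index, correct, consecutive_correct,
                           spec, rule2 = c("two_correct_down",
                                           "two_wrong_up")) {
  rule2 <- match.arg(rule2)
  up <- function(x) if (spec$step_type == "proportional")
    x * (1 + spec$step) else x + spec$step
  down <- function(x) if (spec$step_type == "proportional")
    x * (1 - spec$step) else x - spec$step

  phase1 <- trial_index <= spec$rule_switch_trial
  cc <- consecutive_correct
  if (phase1) {
    new <- if (correct) down(level) else up(level)
    cc <- 0L
  } else if (rule2 == "two_correct_down") {
    if (correct) {
      cc <- cc + 1L
      if (cc >= 2L) { new <- down(level); cc <- 0L } else new <- level
    } else { new <- up(level); cc <- 0L }
  } else { # two consecutive wrong to move up, one correct moves down
    if (correct) { new <- down(level); cc <- 0L }
    else {
      cc <- cc - 1L
      if (cc <= -2L) { new <- up(level); cc <- 0L } else new <- level
    }
  }
  list(level = min(max(new, spec$lower_bound), spec$upper_bound), cc = cc)
}

#' Initialise a staircase
#'
#' @param spec a staircase `protocol_spec`.
#' @return a `staircase_state` list with `trial_index` (the next trial to be
#'   run, starting at 1), `current_level`, `consecutive_correct` and a
#'   `history` data frame of `(level, correct)`.
#' @export
staircase_state <- function(spec) {
  structure(list(trial_index = 1L, current_level = spec$start,
                 consecutive_correct = 0L,
                 history = data.frame(level = numeric(0),
                                      correct = logical(0))),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Applies the adaptive tracking rule: one-up one-down on trials 1-10, then
#' (by default) one step easier after any incorrect response and one step
#' harder only after two consecutive correct responses. Levels are clamped
#' to the spec's bounds. The trial being answered is `state$trial_index`;
#' the returned state holds the level for the next trial.
#'
#' @param state a `staircase_state`.
#' @param correct logical response for the current trial.
#' @param spec the protocol's `protocol_spec`.
#' @param rule2 phase-2 rule variant: `"two_correct_down"` (default; two
#'   consecutive correct for a step down, any error steps up) or
#'   `"two_wrong_up"` (any correct steps down, two consecutive errors step
#'   up).
#' @return the updated `staircase_state`.
#' @examples
#' st <- staircase_state(default_specs()$SDT)
#' update_staircase(st, TRUE, default_specs()$SDT)$current_level  # 19
#' @export
update_staircase <- function(state, correct, spec,
                             rule2 = "two_correct_down") {
  if (state$trial_index > spec$n_trials)
    stop("staircase already has ", spec$n_trials, " responses")
  nxt <- staircase_next(state$current_level, state$trial_index, correct,
                        state$consecutive_correct, spec, rule2)
  state$history <- rbind(state$history,
                         data.frame(level = state$current_level,
                                    correct = correct))
  state$trial_index <- state$trial_index + 1L
  state$current_level <- nxt$level
  state$consecutive_correct <- nxt$cc
  state
}

new_trial_df <- function(observer_id, protocol_id, n, level, unit,
                         site_stim, site_resp, correct, rt,
                         censored = FALSE) {
  data.frame(observer_id = observer_id, protocol = protocol_id,
             trial = seq_len(n), level = level, unit = unit,
             site_stim = site_stim, site_resp = site_resp,
             correct = correct, rt_ms = rt, censored = censored,
             stringsAsFactors = FALSE)
}

#' Run one staircase or response-time protocol against an observer
#'
#' Simulates the practice phase (trials at the starting level until three
#' consecutive correct responses, capped at 50 attempts; practice trials are
#' not returned) and then exactly `spec$n_trials` test trials. Staircase
#' protocols track the tested quantity through [update_staircase()]'s rule;
#' SRT/CRT deliver a fixed suprathreshold stimulus.
#'
#' @param observer one row of an `observer_params` data frame.
#' @param spec a `protocol_spec` of kind `"staircase"` or `"rt"` (use
#'   [run_dynamic_detection()] for DDT).
#' @param rule2 phase-2 staircase rule, see [update_staircase()].
#' @return data frame of trial records: `observer_id, protocol, trial,
#'   level, unit, site_stim, site_resp, correct, rt_ms, censored`.
#' @export
run_protocol <- function(observer, spec, rule2 = "two_correct_down") {
  if (spec$kind == "ramp")
    stop("use run_dynamic_detection() for the DDT protocol")
  run_practice(observer, spec)

  n <- spec$n_trials
  levels_out <- numeric(n); correct_out <- logical(n); rt_out <- numeric(n)
  sites <- sample(c("D2", "D3"), n, replace = TRUE)
  level <- spec$start; cc <- 0L
  for (i in seq_len(n)) {
    levels_out[i] <- level
    resp <- simulate_trial_response(observer, spec$protocol_id, level)
    correct_out[i] <- resp$correct
    rt_out[i] <- resp$rt
    if (spec$kind == "staircase") {
      nxt <- staircase_next(level, i, resp$correct, cc, spec, rule2)
      level <- nxt$level; cc <- nxt$cc
    }
  }
  site_resp <- if (spec$protocol_id == "SRT") rep("any", n) else
    ifelse(correct_out, sites, ifelse(sites == "D2", "D3", "D2"))
  new_trial_df(observer$observer_id, spec$protocol_id, n, levels_out,
               spec$unit, sites, site_resp, correct_out, rt_out)
}

run_practice <- function(observer, spec, required = 3L, cap = 50L) {
  streak <- 0L
  for (attempt in seq_len(cap)) {
    resp <- simulate_trial_response(observer, spec$protocol_id, spec$start)
    streak <- if (resp$correct) streak + 1L else 0L
    if (streak >= required) return(invisible(attempt))
  }
  stop("practice cap exceeded for ", spec$protocol_id, ", observer ",
       observer$observer_id, ": ", cap,
       " attempts without 3 consecutive correct responses")
}

#' Run the dynamic-detection ramp protocol
#'
#' Each of the 7 trials starts with a variable silent delay (0-2500 ms, not
#' contributing to the recorded amplitude) after which the stimulus ramps
#' from zero at 2 um/s. The observer responds when the ramp crosses their
#' momentary detection threshold (the static threshold times the DDT
#' condition multiplier, perturbed by per-trial log-normal noise); the
#' recorded amplitude is the ramp value at the button press, i.e. the
#' crossing amplitude plus `ramp_rate * motor_latency`. Trials whose ramp
#' would exceed the device limit before a response are recorded at the
#' bound and flagged `censored`.
#'
#' @param observer one row of an `observer_params` data frame.
#' @param spec the DDT `protocol_spec`.
#' @return data frame of trial records as in [run_protocol()].
#' @export
run_dynamic_detection <- function(observer, spec) {
  if (spec$protocol_id != "DDT") stop("spec must be the DDT protocol")
  n <- spec$n_trials
  rate <- spec$stimulus$ramp_rate_um_s
  theta_eff <- observer$theta_detect * observer$mult_ddt
  noise <- stats::rlnorm(n, 0, observer$ddt_noise_sd)
  crossing <- theta_eff * noise
  recorded <- crossing + rate * observer$motor_latency / 1000
  censored <- recorded > spec$upper_bound
  recorded[censored] <- spec$upper_bound
  rt <- crossing / rate * 1000 + observer$motor_latency  # ms from ramp onset
  sites <- sample(c("D2", "D3"), n, replace = TRUE)
  new_trial_df(observer$observer_id, "DDT", n, recorded, spec$unit,
               sites, sites, correct = TRUE, rt = rt, censored = censored)
}

#' Run the full battery for a cohort
#'
#' Runs every protocol in `specs` for every observer, in the published
#' fixed order (SRT, CRT, SDT, DDT, ADT, ADTssa, SMFD, SQFD, TOJ, TOJwc as
#' far as present in `specs`).
#'
#' @param params `observer_params` data frame.
#' @param specs named list of `protocol_spec`s, default [default_specs()].
#' @param rule2 phase-2 staircase rule, see [update_staircase()].
#' @param seed optional integer seed set before simulation.
#' @return one data frame of trial records for all observers and protocols.
#' @export
run_battery <- function(params, specs = default_specs(),
                        rule2 = "two_correct_down", seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vector("list", nrow(params) * length(specs))
  k <- 0L
  for (i in seq_len(nrow(params))) {
    obs <- params[i, , drop = FALSE]
    for (spec in specs) {
      k <- k + 1L
      out[[k]] <- if (spec$kind == "ramp")
        run_dynamic_detection(obs, spec)
      else run_protocol(obs, spec, rule2)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
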