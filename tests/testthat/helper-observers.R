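# shared fixtures built in code

# one observer row with explicit overrides on top of zero-noise defaults
make_observer <- function(...) {
  cg <- generate_cohort(
    effect_spec(sd = c(theta_detect = 0, theta_amp = 0, theta_freq = 0,
                       theta_toj = 0, rt_location = 0)),
    n_per_group = c(1, 1, 1, 1), seed = 7L)
  obs <- cg$params[1, , drop = FALSE]
  dots <- list(...)
  for (nm in names(dots)) obs[[nm]] <- dots[[nm]]
  obs
}

# deterministic (step-function) observer: always correct above theta,
# always at chance below
step_observer <- function(theta = 10, ...) {
  make_observer(theta_detect = theta, slope = 1e6, lapse = 0, ...)
}

# minimal trial-record table for scoring tests
fake_trials <- function(levels, correct = TRUE, rt = 400,
                        protocol = "SDT", unit = "um",
                        observer_id = "OBSX") {
  n <- length(levels)
  data.frame(observer_id = observer_id, protocol = protocol,
             trial = seq_len(n), level = levels, unit = unit,
             site_stim = "D2", site_resp = "D2",
             correct = rep_len(correct, n), rt_ms = rep_len(rt, n),
             censored = FALSE, stringsAsFactors = FALSE)
}
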