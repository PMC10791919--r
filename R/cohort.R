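#' Latent observer parameters drawn by the cohort generator
#'
#' @name observer-params
#' @details
#' An `observer_params` object is a data frame with one row per simulated
#' observer and columns for every latent quantity the battery engine needs:
#' `observer_id`, `diagnosis` (ASC/TDC), `sex` (M/F), the four sensory
#' thresholds `theta_detect` (static detection, um), `theta_amp`
#' (amplitude-difference JND, um), `theta_freq` (frequency-difference JND,
#' Hz), `theta_toj` (order-judgement JND, ms), the psychometric `slope` and
#' `lapse`, the shifted log-normal response-time parameters `rt_location`,
#' `rt_scale`, `rt_shift` (ms), the additive `choice_cost` (ms) for
#' site-specific responding, `motor_latency` (ms), the per-trial noise SD of
#' the dynamic-detection momentary threshold `ddt_noise_sd` (log scale), and
#' the four condition multipliers `mult_ddt`, `mult_adtssa`, `mult_smfd`,
#' `mult_tojwc` applied to the relevant threshold in the second condition of
#' each protocol pair.
NULL

.GROUPS <- c("ASC_M", "ASC_F", "TDC_M", "TDC_F")

.LATENT_PARAMS <- c("theta_detect", "theta_amp", "theta_freq", "theta_toj",
                    "slope", "lapse", "rt_location", "rt_scale", "rt_shift",
                    "choice_cost", "motor_latency", "ddt_noise_sd",
                    "mult_ddt", "mult_adtssa", "mult_smfd", "mult_tojwc")

#' Specify the generative model for a synthetic cohort
#'
#' Defines baseline values, between-observer variation and additive group
#' effects for every latent observer parameter, plus the covariate
#' distributions of the four demographic cells (ASC male, ASC female,
#' TDC male, TDC female). With all effect arguments at their defaults the
#' spec encodes a null model: the four cells differ only by sampling noise.
#'
#' Group effects are additive on the parameter's natural scale:
#' \deqn{x = baseline + d\,[\mathrm{ASC}] + s\,[\mathrm{F}] +
#'       ds\,[\mathrm{ASC\ and\ F}] + \epsilon,\qquad
#'       \epsilon \sim N(0, sd^2)}
#' truncated below at `1e-6 * baseline` so thresholds stay strictly positive
#' (`lapse` is additionally clamped to `[0, 0.1]`).
#'
#' @param baseline named numeric vector of baseline parameter values;
#'   entries override the built-in defaults (see Details).
#' @param sd named numeric vector of between-observer standard deviations
#'   (same units as the parameter); unnamed parameters default to 0 except
#'   the four thresholds, which get the built-in defaults.
#' @param diagnosis_effect,sex_effect,interaction_effect named numeric
#'   vectors of additive offsets applied, respectively, to ASC observers,
#'   to female observers, and to ASC females on top of both main offsets.
#' @param covariates list of per-covariate specifications. Each element is a
#'   list with `mean` and `sd`, either scalars or named vectors over the four
#'   cells `ASC_M`, `ASC_F`, `TDC_M`, `TDC_F`.
#' @param seed optional integer seed stored with the spec and used by
#'   [generate_cohort()] when no explicit seed is passed.
#'
#' @details Built-in baselines describe a typically developing male child on
#' this battery: detection threshold 10 um, amplitude JND 40 um, frequency
#' JND 4 Hz, order-judgement JND 40 ms, Weibull slope 6, lapse 0.02,
#' response times shifted log-normal with location `log(150)`, scale 0.3 and
#' shift 200 ms, choice cost 150 ms, motor latency 200 ms, and second-condition
#' multipliers 1.8 (dynamic detection), 1.5 (adaptation, simultaneous
#' frequency, carrier order judgement).
#'
#' @return an object of class `effect_spec` (a validated list).
#' @examples
#' spec <- effect_spec(sex_effect = c(theta_amp = 20))
#' spec$sex_effect[["theta_amp"]]
#' @export
effect_spec <- function(baseline = NULL, sd = NULL,
                        diagnosis_effect = NULL, sex_effect = NULL,
                        interaction_effect = NULL,
                        covariates = NULL, seed = NULL) {
  base_default <- c(theta_detect = 10, theta_amp = 40, theta_freq = 4,
                    theta_toj = 40, slope = 6, lapse = 0.02,
                    rt_location = log(150), rt_scale = 0.3, rt_shift = 200,
                    choice_cost = 150, motor_latency = 200,
                    ddt_noise_sd = 0.15,
                    mult_ddt = 1.8, mult_adtssa = 1.5, mult_smfd = 1.5,
                    mult_tojwc = 1.5)
  sd_default <- c(theta_detect = 3, theta_amp = 15, theta_freq = 1.5,
                  theta_toj = 15, rt_location = 0.15)

  merge_named <- function(default, user, what) {
    out <- default
    if (!is.null(user)) {
      if (is.null(names(user)) || any(!nzchar(names(user))))
        stop("'", what, "' must be a fully named numeric vector")
      bad <- setdiff(names(user), .LATENT_PARAMS)
      if (length(bad))
        stop("unknown latent parameter(s) in '", what, "': ",
             paste(bad, collapse = ", "))
      out[names(user)] <- user
    }
    full <- stats::setNames(numeric(length(.LATENT_PARAMS)), .LATENT_PARAMS)
    full[names(out)] <- out
    full
  }

  spec <- list(
    baseline = merge_named(base_default, baseline, "baseline"),
    sd = merge_named(sd_default, sd, "sd"),
    diagnosis_effect = merge_named(numeric(0), diagnosis_effect,
                                   "diagnosis_effect"),
    sex_effect = merge_named(numeric(0), sex_effect, "sex_effect"),
    interaction_effect = merge_named(numeric(0), interaction_effect,
                                     "interaction_effect"),
    covariates = covariates %||% list(
      age = list(mean = 10.6, sd = 1.2),
      fsiq = list(mean = 104, sd = 12)),
    seed = seed)
  class(spec) <- "effect_spec"
  validate_effect_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_effect_spec <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  if (any(spec$sd < 0)) stop("between-observer SDs must be >= 0")
  thetas <- c("theta_detect", "theta_amp", "theta_freq", "theta_toj")
  if (any(spec$baseline[thetas] <= 0))
    stop("baseline thresholds must be strictly positive")
  if (spec$baseline[["lapse"]] < 0 || spec$baseline[["lapse"]] > 0.1)
    stop("baseline lapse must lie in [0, 0.1]")
  mults <- c("mult_ddt", "mult_adtssa", "mult_smfd", "mult_tojwc")
  if (any(spec$baseline[mults] <= 0))
    stop("condition multipliers must be positive")
  for (nm in names(spec$covariates)) {
    cv <- spec$covariates[[nm]]
    if (!is.list(cv) || !all(c("mean", "sd") %in% names(cv)))
      stop("covariate '", nm, "' must be a list with 'mean' and 'sd'")
    if (any(cv$sd < 0)) stop("covariate '", nm, "' has negative sd")
  }
  if (!is.null(spec$seed) && (!is.numeric(spec$seed) || length(spec$seed) != 1))
    stop("seed must be a single integer")
  invisible(spec)
}

cell_value <- function(x, group) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!is.null(names(x))) {
    if (!group %in% names(x))
      stop("per-cell covariate parameter missing cell '", group, "'")
    return(unname(x[[group]]))
  }
  stop("covariate parameters must be scalar or named by cell")
}

#' Generate a synthetic cohort of observers
#'
#' Draws demographics and latent sensory parameters for the four
#' diagnosis-by-sex cells. The default cell sizes are the study's matched
#' sample: 36 ASC males, 18 ASC females, 34 TDC males, 20 TDC females.
#'
#' @param spec an [effect_spec()].
#' @param n_per_group integer vector of cell counts, named or in the order
#'   `ASC_M`, `ASC_F`, `TDC_M`, `TDC_F`.
#' @param seed integer seed; defaults to `spec$seed`. Identical seeds give
#'   byte-identical cohorts.
#' @return a list with `cohort` (data frame of class `cohort`:
#'   `observer_id`, `diagnosis`, `sex`, one column per covariate) and
#'   `params` (data frame of class `observer_params`, see
#'   [observer-params]).
#' @examples
#' cg <- generate_cohort(effect_spec(), seed = 1)
#' table(cg$cohort$diagnosis, cg$cohort$sex)
#' @export
generate_cohort <- function(spec, n_per_group = c(ASC_M = 36, ASC_F = 18,
                                                  TDC_M = 34, TDC_F = 20),
                            seed = spec$seed) {
  validate_effect_spec(spec)
  if (length(n_per_group) != 4L)
    stop("n_per_group must have four entries (ASC_M, ASC_F, TDC_M, TDC_F)")
  if (is.null(names(n_per_group))) names(n_per_group) <- .GROUPS
  n_per_group <- n_per_group[.GROUPS]
  if (any(is.na(n_per_group)) || any(n_per_group < 1))
    stop("all cell counts must be >= 1")
  if (is.null(seed)) stop("a seed is required (in the spec or as an argument)")
  set.seed(as.integer(seed))

  rows <- list()
  for (g in .GROUPS) {
    n <- n_per_group[[g]]
    diagnosis <- sub("_.*", "", g)
    sex <- sub(".*_", "", g)
    eff <- spec$diagnosis_effect * (diagnosis == "ASC") +
      spec$sex_effect * (sex == "F") +
      spec$interaction_effect * (diagnosis == "ASC" && sex == "F")
    draw <- sapply(.LATENT_PARAMS, function(p) {
      mu <- spec$baseline[[p]] + eff[[p]]
      x <- stats::rnorm(n, mu, spec$sd[[p]])
      pmax(x, 1e-6 * abs(spec$baseline[[p]]))
    })
    draw <- matrix(draw, nrow = n,
                   dimnames = list(NULL, .LATENT_PARAMS))
    draw[, "lapse"] <- pmin(pmax(draw[, "lapse"], 0), 0.1)
    covs <- lapply(spec$covariates, function(cv) {
      pmax(stats::rnorm(n, cell_value(cv$mean, g), cell_value(cv$sd, g)),
           1e-6)
    })
    rows[[g]] <- list(diagnosis = rep(diagnosis, n), sex = rep(sex, n),
                      covs = covs, params = draw)
  }

  n_total <- sum(n_per_group)
  ids <- sprintf("OBS%03d", seq_len(n_total))
  diagnosis <- unlist(lapply(rows, `[[`, "diagnosis"), use.names = FALSE)
  sex <- unlist(lapply(rows, `[[`, "sex"), use.names = FALSE)
  cohort <- data.frame(observer_id = ids, diagnosis = diagnosis, sex = sex,
                       stringsAsFactors = FALSE)
  for (nm in names(spec$covariates))
    cohort[[nm]] <- unlist(lapply(rows, function(r) r$covs[[nm]]),
                           use.names = FALSE)
  params <- as.data.frame(do.call(rbind, lapply(rows, `[[`, "params")))
  params <- cbind(data.frame(observer_id = ids, diagnosis = diagnosis,
                             sex = sex, stringsAsFactors = FALSE), params)
  rownames(cohort) <- rownames(params) <- NULL
  class(cohort) <- c("cohort", "data.frame")
  class(params) <- c("observer_params", "data.frame")
  list(cohort = cohort, params = params)
}

#' Probability of a correct 2AFC response
#'
#' Weibull-family psychometric function for two-alternative forced choice:
#' \deqn{\Psi(\Delta) = guess + (1 - guess - lapse)
#'       \left(1 - e^{-(\Delta/\theta)^{slope}}\right)}
#' so that performance is at `guess` for a zero stimulus difference,
#' saturates at `1 - lapse`, and passes the fixed point
#' \eqn{\Psi(\theta) = guess + (1 - guess - lapse)(1 - e^{-1})}.
#'
#' @param delta non-negative stimulus difference (same units as `theta`).
#' @param theta threshold parameter, strictly positive.
#' @param slope Weibull shape, strictly positive.
#' @param lapse lapse probability, `0 <= lapse <= 1 - guess`.
#' @param guess guessing rate, `0 <= guess < 1` (0.5 for 2AFC).
#' @return probability of a correct response, vectorised over `delta`.
#' @examples
#' psychometric_correct_prob(0, theta = 10)          # chance
#' psychometric_correct_prob(10, theta = 10, lapse = 0)  # 0.5 + 0.5*(1-exp(-1))
#' @export
psychometric_correct_prob <- function(delta, theta, slope = 6,
                                      lapse = 0.02, guess = 0.5) {
  if (any(delta < 0)) stop("delta must be >= 0")
  if (theta <= 0) stop("theta must be > 0")
  if (slope <= 0) stop("slope must be > 0")
  if (guess < 0 || guess >= 1) stop("guess must lie in [0, 1)")
  if (lapse < 0 || lapse > 1 - guess)
    stop("lapse must lie in [0, 1 - guess]")
  guess + (1 - guess - lapse) * (1 - exp(-(delta / theta)^slope))
}

## protocol -> which latent threshold and condition multiplier apply
protocol_theta <- function(observer, protocol_id) {
  map <- switch(protocol_id,
    SDT    = c("theta_detect", NA),
    DDT    = c("theta_detect", "mult_ddt"),
    ADT    = c("theta_amp", NA),
    ADTssa = c("theta_amp", "mult_adtssa"),
    SQFD   = c("theta_freq", NA),
    SMFD   = c("theta_freq", "mult_smfd"),
    TOJ    = c("theta_toj", NA),
    TOJwc  = c("theta_toj", "mult_tojwc"),
    SRT    = c("theta_detect", NA),
    CRT    = c("theta_detect", NA),
    stop("unknown protocol: ", protocol_id))
  theta <- observer[[map[1]]]
  if (!is.na(map[2])) theta <- theta * observer[[map[2]]]
  theta
}

#' Simulate one trial's response
#'
#' Draws correctness from the psychometric model (with the
#' protocol-appropriate threshold and condition multiplier) and a response
#' time from the observer's shifted log-normal distribution. Protocols that
#' require responding with the finger matching the stimulated site (every
#' protocol except SRT) add the observer's `choice_cost` to the RT mean.
#' For SRT and CRT the stimulus is suprathreshold (300 um), so `delta` is
#' the stimulus amplitude itself; SRT correctness is always `TRUE` because
#' any-finger responses cannot be wrong.
#'
#' @param observer one row of an `observer_params` data frame (or a list
#'   with the same fields).
#' @param protocol_id one of SRT, CRT, SDT, ADT, ADTssa, SQFD, SMFD, TOJ,
#'   TOJwc.
#' @param level the current tracked stimulus value (amplitude, amplitude
#'   difference, frequency difference, or ISI depending on protocol).
#' @return list with logical `correct` and numeric `rt` (ms). Uses R's
#'   global RNG stream.
#' @export
simulate_trial_response <- function(observer, protocol_id, level) {
  if (level < 0) stop("level must be >= 0")
  site_specific <- protocol_id != "SRT"
  if (protocol_id == "SRT") {
    correct <- TRUE
  } else {
    theta <- protocol_theta(observer, protocol_id)
    p <- psychometric_correct_prob(level, theta, observer$slope,
                                   observer$lapse, guess = 0.5)
    correct <- stats::runif(1) < p
  }
  rt <- observer$rt_shift +
    stats::rlnorm(1, observer$rt_location, observer$rt_scale) +
    if (site_specific) observer$choice_cost else 0
  list(correct = correct, rt = rt)
}

#' Draw observer-level outcome tables straight from the latent model
#'
#' For calibration studies it is convenient to skip the trial-by-trial
#' battery and treat the latent thresholds themselves (plus optional
#' log-normal measurement noise) as the measured outcomes: condition 1 is
#' the latent parameter, condition 2 the parameter times its condition
#' multiplier. The result has the long format consumed by
#' [factorial_lm()].
#'
#' @param params an `observer_params` data frame.
#' @param dv which dependent variable: one of `"theta_detect"`,
#'   `"theta_amp"`, `"theta_freq"`, `"theta_toj"`.
#' @param measurement_cv coefficient of variation of multiplicative
#'   log-normal measurement noise (0 = none). Uses the global RNG.
#' @return data frame with columns `observer_id`, `condition` (factor
#'   `cond1`/`cond2`), `diagnosis`, `sex`, `outcome`.
#' @export
latent_outcome_table <- function(params, dv = "theta_detect",
                                 measurement_cv = 0) {
  mult_name <- switch(dv, theta_detect = "mult_ddt", theta_amp = "mult_adtssa",
                      theta_freq = "mult_smfd", theta_toj = "mult_tojwc",
                      stop("unknown dv: ", dv))
  n <- nrow(params)
  base <- params[[dv]]
  second <- base * params[[mult_name]]
  if (measurement_cv > 0) {
    sdl <- sqrt(log(1 + measurement_cv^2))
    base <- base * stats::rlnorm(n, -sdl^2 / 2, sdl)
    second <- second * stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  out <- data.frame(
    observer_id = rep(params$observer_id, 2L),
    condition = factor(rep(c("cond1", "cond2"), each = n)),
    diagnosis = factor(rep(params$diagnosis, 2L), levels = c("ASC", "TDC")),
    sex = factor(rep(params$sex, 2L), levels = c("M", "F")),
    outcome = c(base, second),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
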