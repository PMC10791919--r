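#' Default run configuration
#'
#' Encodes the study conditions end to end: the original recruitment-sized
#' cohort (112 ASC males, 18 ASC females, 137 TDC males, 55 TDC females)
#' with modest diagnosis effects on response time and detection and sex
#' effects on the discrimination and order-judgement thresholds; the
#' published battery constants; MAD outlier filtering at 2.5 within
#' protocol-by-cell; the three default matching passes on age and FSIQ;
#' and type III factorial models with Zellner-Siow Bayes factors.
#'
#' @param seed integer seed (mandatory for a valid config).
#' @return a nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = seed,
    cohort = list(
      n_per_group = c(ASC_M = 112, ASC_F = 18, TDC_M = 137, TDC_F = 55),
      effects = list(
        diagnosis_effect = c(theta_detect = 2, rt_shift = 25),
        sex_effect = c(theta_amp = 8, theta_freq = 0.8, theta_toj = 8))),
    battery = list(rule2 = "two_correct_down", overrides = list()),
    scoring = list(mad_threshold = 2.5, mad_constant = 1.4826,
                   mad_grouping = "cell", consistent_orientation = FALSE,
                   final_k = 5L),
    matching = list(enabled = TRUE, covariates = c("age", "fsiq"),
                    ratio = c(2L, 2L, 1L), caliper = NULL),
    stats = list(ss_type = "III", compute_bf = TRUE,
                 prior_scale = sqrt(2) / 2)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every block against its module's constraints before any stage
#' runs; called by [run_pipeline()].
#'
#' @param config a `run_config` (or plain nested list, e.g. parsed YAML).
#' @return the normalised config, invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed))
    stop("configuration error: a seed is mandatory")
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("configuration error: seed must be a single integer")
  defaults <- default_config(config$seed)
  for (block in c("cohort", "battery", "scoring", "matching", "stats")) {
    if (is.null(config[[block]])) config[[block]] <- defaults[[block]]
    miss <- setdiff(names(defaults[[block]]), names(config[[block]]))
    for (m in miss) config[[block]][[m]] <- defaults[[block]][[m]]
  }
  n <- unlist(config$cohort$n_per_group)
  if (length(n) != 4 || any(n < 1))
    stop("configuration error: cohort$n_per_group needs four counts >= 1")
  eff <- config$cohort$effects
  spec <- do.call(effect_spec, c(eff[intersect(names(eff),
    c("baseline", "sd", "diagnosis_effect", "sex_effect",
      "interaction_effect", "covariates"))], list(seed = config$seed)))
  if (!config$scoring$mad_grouping %in% c("cell", "protocol"))
    stop("configuration error: scoring$mad_grouping must be 'cell' or 'protocol'")
  if (config$scoring$mad_threshold <= 0)
    stop("configuration error: scoring$mad_threshold must be > 0")
  if (!config$stats$ss_type %in% c("I", "II", "III"))
    stop("configuration error: stats$ss_type must be I, II or III")
  if (!config$battery$rule2 %in% c("two_correct_down", "two_wrong_up"))
    stop("configuration error: unknown battery$rule2")
  for (nm in names(config$battery$overrides))
    do.call(protocol_spec, c(list(nm), config$battery$overrides[[nm]]))
  attr(config, "effect_spec") <- spec
  class(config) <- "run_config"
  invisible(config)
}

#' Hash of the canonical configuration
#'
#' MD5 of the canonical JSON serialisation; changes iff any configuration
#' value changes.
#'
#' @param config a `run_config`.
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  attr(config, "effect_spec") <- NULL
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

dv_pairs <- function() list(
  mean_rt = c("SRT", "CRT"),
  detection = c("SDT", "DDT"),
  amplitude = c("ADT", "ADTssa"),
  frequency = c("SQFD", "SMFD"),
  toj = c("TOJ", "TOJwc"))

#' Assemble long outcome tables for the factorial models
#'
#' Builds one two-condition long table per dependent variable (mean RT,
#' detection, amplitude discrimination, frequency discrimination, temporal
#' order judgement) from a scored outcome table, dropping outlier-flagged
#' records and, if given, restricting to the matched analysis set.
#'
#' @param outcomes a [score_battery()] table (after [flag_outliers()]).
#' @param cohort cohort data frame supplying `diagnosis` and `sex`.
#' @param retained_ids optional character vector of observer ids to keep.
#' @param drop_outliers drop records with `flagged_outlier` (default TRUE).
#' @return named list of long data frames (`observer_id, condition,
#'   diagnosis, sex, outcome`), `condition` coded `cond1`/`cond2` by pair
#'   membership.
#' @export
build_outcome_tables <- function(outcomes, cohort, retained_ids = NULL,
                                 drop_outliers = TRUE) {
  if (!is.null(retained_ids))
    outcomes <- outcomes[outcomes$observer_id %in% retained_ids, ,
                         drop = FALSE]
  if (drop_outliers)
    outcomes <- outcomes[!outcomes$flagged_outlier, , drop = FALSE]
  idx <- match(outcomes$observer_id, cohort$observer_id)
  outcomes$diagnosis <- cohort$diagnosis[idx]
  outcomes$sex <- cohort$sex[idx]
  lapply(dv_pairs(), function(pair) {
    sel <- outcomes$protocol %in% pair
    d <- outcomes[sel, , drop = FALSE]
    data.frame(observer_id = d$observer_id,
               condition = factor(ifelse(d$protocol == pair[1], "cond1",
                                         "cond2"),
                                  levels = c("cond1", "cond2")),
               diagnosis = factor(d$diagnosis, levels = c("ASC", "TDC")),
               sex = factor(d$sex, levels = c("M", "F")),
               outcome = d$outcome, stringsAsFactors = FALSE)
  })
}

stage_seed <- function(seed, k) (as.integer(seed) + 97L * k) %% 2147483647L

#' Run the full pipeline: simulate, test, score, match, analyze
#'
#' Executes the whole chain under one configuration and writes every
#' intermediate table as CSV plus a manifest and a plain-text report to
#' `out_dir`. Deterministic for a fixed seed.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory (created if missing).
#' @param verbose print per-stage progress.
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `params`, `trials`, `outcomes`, `indices`, `matching`, `effects`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  counts <- list()

  ## stage 1: cohort
  say("stage cohort")
  spec <- attr(config, "effect_spec")
  cg <- generate_cohort(spec, unlist(config$cohort$n_per_group),
                        seed = stage_seed(config$seed, 1L))
  write_cohort(cg$cohort, file.path(out_dir, "cohort.csv"))
  utils::write.csv(cg$params, file.path(out_dir, "latent_params.csv"),
                   row.names = FALSE, quote = FALSE)
  counts$cohort <- nrow(cg$cohort)

  ## stage 2: battery
  say("stage battery")
  specs <- default_specs()
  for (nm in names(config$battery$overrides))
    specs[[nm]] <- do.call(protocol_spec,
                           c(list(nm), config$battery$overrides[[nm]]))
  trials <- run_battery(cg$params, specs, rule2 = config$battery$rule2,
                        seed = stage_seed(config$seed, 2L))
  write_trials(trials, file.path(out_dir, "trials.csv"))
  counts$trials <- nrow(trials)

  ## stage 3: scoring
  say("stage scoring")
  outcomes <- score_battery(trials, k = config$scoring$final_k)
  outcomes <- flag_outliers(outcomes, cg$cohort,
                            threshold = config$scoring$mad_threshold,
                            constant = config$scoring$mad_constant,
                            grouping = config$scoring$mad_grouping)
  indices <- derive_indices(outcomes,
                            config$scoring$consistent_orientation)
  write_outcomes(outcomes, file.path(out_dir, "outcomes.csv"))
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE, quote = FALSE)
  counts$outcomes <- nrow(outcomes)
  counts$outcomes_flagged <- sum(outcomes$flagged_outlier)

  ## stage 4: matching
  matching <- NULL
  retained <- cg$cohort$observer_id
  if (isTRUE(config$matching$enabled)) {
    say("stage matching")
    passes <- default_match_passes(config$matching$covariates)
    for (i in seq_along(passes)) {
      passes[[i]]$ratio <- as.integer(config$matching$ratio[
        min(i, length(config$matching$ratio))])
      passes[[i]]$caliper <- config$matching$caliper
    }
    matching <- run_matching_passes(cg$cohort, passes)
    retained <- matching$retained_ids
    utils::write.csv(data.frame(observer_id = sort(retained)),
                     file.path(out_dir, "matched_ids.csv"),
                     row.names = FALSE, quote = FALSE)
    balance <- do.call(rbind, lapply(seq_along(matching$passes), function(i)
      cbind(pass = i, matching$passes[[i]]$balance)))
    utils::write.csv(balance, file.path(out_dir, "balance.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  counts$retained <- length(retained)

  ## stage 5: inference
  say("stage stats")
  tables <- build_outcome_tables(outcomes, cg$cohort, retained)
  effects <- list()
  report <- character(0)
  for (dv in names(tables)) {
    et <- factorial_lm(tables[[dv]], ss_type = config$stats$ss_type,
                       compute_bf = config$stats$compute_bf,
                       prior_scale = config$stats$prior_scale)
    effects[[dv]] <- et
    utils::write.csv(as.data.frame(et),
                     file.path(out_dir, paste0("effects_", dv, ".csv")),
                     row.names = FALSE, quote = FALSE)
    report <- c(report, format_effect_report(et, dv), "")
  }
  writeLines(report, file.path(out_dir, "report.txt"))

  manifest <- list(package = "tactsim",
                   version = as.character(utils::packageVersion("tactsim")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   config = unclass(config),
                   row_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cg$cohort, params = cg$params, trials = trials,
                 outcomes = outcomes, indices = indices,
                 matching = matching, effects = effects,
                 manifest = manifest))
}

#' Write small fixture files for tests and examples
#'
#' @param kind one of `"toy_trials"` (a two-observer, two-protocol battery
#'   run under a fixed seed), `"toy_cohort"` (eight observers, two per
#'   cell), `"reference_summaries"` (the published descriptive statistics
#'   from [reference_cohort_summaries()]).
#' @param dir directory to write into.
#' @return path of the written file.
#' @export
make_fixtures <- function(kind = c("toy_trials", "toy_cohort",
                                   "reference_summaries"),
                          dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "toy_trials") {
    cg <- generate_cohort(effect_spec(),
                          n_per_group = c(1, 1, 1, 1), seed = 42L)
    specs <- default_specs()[c("SRT", "SDT")]
    trials <- run_battery(cg$params[1:2, ], specs, seed = 43L)
    return(write_trials(trials, file.path(dir, "toy_trials.csv")))
  }
  if (kind == "toy_cohort") {
    cg <- generate_cohort(effect_spec(),
                          n_per_group = c(2, 2, 2, 2), seed = 42L)
    return(write_cohort(cg$cohort, file.path(dir, "toy_cohort.csv")))
  }
  path <- file.path(dir, "reference_summaries.csv")
  utils::write.csv(reference_cohort_summaries(), path, row.names = FALSE)
  path
}
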