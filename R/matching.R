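#' Specify one propensity-matching pass
#'
#' @param treatment_label,control_label values of the grouping variable
#'   matched in this pass (treated units keep all their members; controls
#'   are selected).
#' @param covariates covariate column names used in the propensity model
#'   (default age and FSIQ).
#' @param ratio number of controls matched to each treated unit.
#' @param caliper maximum allowed propensity distance in SDs of the logit
#'   of the score (`NULL` = no caliper).
#' @param order processing order of treated units: `"descending_score"`
#'   (default) or `"data_order"`.
#' @return an object of class `match_spec`.
#' @export
match_spec <- function(treatment_label, control_label,
                       covariates = c("age", "fsiq"), ratio = 1L,
                       caliper = NULL,
                       order = c("descending_score", "data_order")) {
  order <- match.arg(order)
  if (ratio < 1) stop("ratio must be >= 1")
  structure(list(treatment_label = treatment_label,
                 control_label = control_label,
                 covariates = covariates, ratio = as.integer(ratio),
                 caliper = caliper, order = order),
            class = "match_spec")
}

#' Estimate propensity scores by logistic regression
#'
#' Fits group membership on the spec's covariates with a binomial GLM
#' (iteratively reweighted least squares, convergence tolerance 1e-8,
#' at most 100 iterations) and returns the fitted probabilities of being
#' in the treatment group.
#'
#' @param cohort cohort data frame restricted or not; only rows whose
#'   `group` value equals one of the two labels are used.
#' @param spec a [match_spec()].
#' @param group_var column of `cohort` holding the group labels (default
#'   `"group"`; a `diagnosis`-by-`sex` label column is built by
#'   [run_matching_passes()]).
#' @return numeric vector of scores in (0, 1), one per used row, with the
#'   used row indices in attribute `"rows"` and the fitted model in
#'   attribute `"fit"`.
#' @export
estimate_propensity <- function(cohort, spec, group_var = "group") {
  labs <- c(spec$control_label, spec$treatment_label)
  rows <- which(cohort[[group_var]] %in% labs)
  if (!any(cohort[[group_var]] == spec$treatment_label) ||
      !any(cohort[[group_var]] == spec$control_label))
    stop("both group labels must be present in the cohort")
  dat <- cohort[rows, , drop = FALSE]
  miss <- setdiff(spec$covariates, names(dat))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (anyNA(dat[spec$covariates]))
    stop("covariates must be complete (no NA)")
  dat$.treated <- as.integer(dat[[group_var]] == spec$treatment_label)
  form <- stats::as.formula(paste(".treated ~",
                                  paste(spec$covariates, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  p <- stats::fitted(fit)
  if (!fit$converged || any(p < 1e-8) || any(p > 1 - 1e-8))
    stop("propensity model shows (near-)perfect separation; ",
         "consider fewer covariates or a caliper")
  structure(as.numeric(p), rows = rows, fit = fit)
}

smd <- function(x, treated, denom_sd) {
  (mean(x[treated]) - mean(x[!treated])) / denom_sd
}

#' Greedy nearest-neighbour matching on propensity scores
#'
#' Processes treated units (by default from highest score down), giving
#' each its `ratio` nearest unused controls by absolute score difference,
#' without replacement. Ties are broken by the lower observer id. With a
#' caliper, candidate controls farther than `caliper` SDs of the logit
#' score are unavailable and treated units with no candidate are dropped.
#'
#' @param scores propensity scores for all units in this pass.
#' @param labels group labels aligned with `scores`.
#' @param spec the [match_spec()].
#' @param ids unit identifiers aligned with `scores` (default indices).
#' @param covariate_data optional data frame (aligned with `scores`) of the
#'   spec's covariates, used for the balance table.
#' @return an object of class `match_result`: list with `pairs` (data frame
#'   `treated_id, control_id, distance`), `retained_ids` (matched treated
#'   plus their controls), `scores`, and `balance` (per-covariate
#'   standardized mean difference before and after matching, standardized
#'   by the pre-match pooled SD).
#' @export
greedy_match <- function(scores, labels, spec, ids = seq_along(scores),
                         covariate_data = NULL) {
  stopifnot(length(scores) == length(labels), length(ids) == length(scores))
  treated_idx <- which(labels == spec$treatment_label)
  control_idx <- which(labels == spec$control_label)
  if (!length(control_idx)) stop("no controls available")
  if (!length(treated_idx)) stop("no treated units available")

  cal_dist <- if (!is.null(spec$caliper)) {
    sd_logit <- stats::sd(stats::qlogis(pmin(pmax(scores, 1e-12),
                                             1 - 1e-12)))
    spec$caliper * sd_logit
  } else Inf

  ord <- if (spec$order == "descending_score")
    treated_idx[order(scores[treated_idx], decreasing = TRUE)] else
      treated_idx
  available <- rep(TRUE, length(scores))
  pairs <- list()
  for (t in ord) {
    got <- character(0)
    for (r in seq_len(spec$ratio)) {
      cand <- control_idx[available[control_idx]]
      if (!length(cand)) break
      d <- abs(scores[cand] - scores[t])
      dl <- abs(stats::qlogis(pmin(pmax(scores[cand], 1e-12), 1 - 1e-12)) -
                stats::qlogis(pmin(pmax(scores[t], 1e-12), 1 - 1e-12)))
      cand <- cand[dl <= cal_dist]
      d <- d[dl <= cal_dist]
      if (!length(cand)) break
      best <- cand[order(d, as.character(ids[cand]))][1]
      available[best] <- FALSE
      pairs[[length(pairs) + 1L]] <-
        data.frame(treated_id = as.character(ids[t]),
                   control_id = as.character(ids[best]),
                   distance = abs(scores[best] - scores[t]),
                   stringsAsFactors = FALSE)
      got <- c(got, as.character(ids[best]))
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated_id = character(0), control_id = character(0),
               distance = numeric(0))
  matched_treated <- unique(pairs$treated_id)
  retained <- c(matched_treated, pairs$control_id)

  balance <- NULL
  if (!is.null(covariate_data)) {
    treated_all <- labels == spec$treatment_label
    keep <- as.character(ids) %in% retained
    balance <- do.call(rbind, lapply(names(covariate_data), function(cv) {
      x <- covariate_data[[cv]]
      denom <- sqrt((stats::var(x[treated_all]) +
                     stats::var(x[!treated_all])) / 2)
      data.frame(covariate = cv,
                 smd_before = smd(x, treated_all, denom),
                 smd_after = if (any(keep & treated_all) &&
                                 any(keep & !treated_all))
                   smd(x[keep], treated_all[keep], denom) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(pairs = pairs, retained_ids = retained, scores = scores,
                 balance = balance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("greedy propensity match:", nrow(x$pairs), "pairs,",
      length(unique(x$retained_ids)), "units retained\n")
  if (!is.null(x$balance)) {
    cat("balance (SMD before -> after):\n")
    for (i in seq_len(nrow(x$balance)))
      cat(sprintf("  %-8s %6.3f -> %6.3f\n", x$balance$covariate[i],
                  x$balance$smd_before[i], x$balance$smd_after[i]))
  }
  invisible(x)
}

default_match_passes <- function(covariates = c("age", "fsiq")) {
  list(match_spec("ASC_F", "ASC_M", covariates, ratio = 2L),
       match_spec("ASC_F", "TDC_M", covariates, ratio = 2L),
       match_spec("ASC_F", "TDC_F", covariates, ratio = 1L))
}

#' Sequential matching passes building the analysis cohort
#'
#' Runs a list of matching passes against the diagnosis-by-sex cells
#' (labels `ASC_M`, `ASC_F`, `TDC_M`, `TDC_F`). The default three passes
#' anchor on the smallest cell (autistic females, all retained) and match
#' it 2:1 against autistic males, 2:1 against typically developing males
#' and 1:1 against typically developing females. The retained analysis set
#' is the union of the treated cell and all matched controls.
#'
#' @param cohort cohort data frame with `observer_id`, `diagnosis`, `sex`
#'   and the covariates.
#' @param passes list of [match_spec()]s; default as described.
#' @return list with `retained_ids`, `passes` (per-pass `match_result`s)
#'   and `scores` (per-pass propensity scores).
#' @export
run_matching_passes <- function(cohort, passes = default_match_passes()) {
  cohort$group <- paste(cohort$diagnosis, cohort$sex, sep = "_")
  retained <- character(0)
  results <- list()
  for (i in seq_along(passes)) {
    spec <- passes[[i]]
    p <- estimate_propensity(cohort, spec)
    rows <- attr(p, "rows")
    res <- greedy_match(p, cohort$group[rows], spec,
                        ids = cohort$observer_id[rows],
                        covariate_data = cohort[rows, spec$covariates,
                                                drop = FALSE])
    results[[i]] <- res
    retained <- union(retained, res$retained_ids)
  }
  treated_cells <- unique(vapply(passes, `[[`, "", "treatment_label"))
  retained <- union(retained,
                    cohort$observer_id[cohort$group %in% treated_cells])
  list(retained_ids = retained, passes = results)
}
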