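#' Welch's unequal-variance t-test from summary statistics
#'
#' Computes the two-sided Welch test from group sizes, means and standard
#' deviations:
#' \deqn{t = \frac{m_1 - m_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with Welch-Satterthwaite degrees of freedom.
#'
#' @param n1,m1,s1 size, mean and SD of group 1 (`n1 >= 2`).
#' @param n2,m2,s2 size, mean and SD of group 2.
#' @return object of class `welch_result`: list with `t`, `df`
#'   (non-integer), `p` (two-sided), `mean_diff` and `se`.
#' @examples
#' welch_t(23, 101.91, 13.25, 12, 105.08, 14.94)$p  # ~0.543
#' @export
welch_t <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("both group sizes must be >= 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0")
  if (s1 == 0 && s2 == 0) stop("both group variances are zero")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 mean_diff = m1 - m2, se = se),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t(%.2f) = %.3f, p = %.4g (diff = %.3f, SE = %.3f)\n",
              x$df, x$t, x$p, x$mean_diff, x$se))
  invisible(x)
}

#' Partial eta-squared
#'
#' @param ss_effect,ss_residual sums of squares, both non-negative and not
#'   both zero (both zero returns 0 with a warning, for the degenerate
#'   constant-outcome model).
#' @return `ss_effect / (ss_effect + ss_residual)`, in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_residual) {
  if (any(ss_effect < 0) || any(ss_residual < 0))
    stop("sums of squares must be >= 0")
  tot <- ss_effect + ss_residual
  out <- ifelse(tot == 0, 0, ss_effect / tot)
  if (any(tot == 0)) warning("both sums of squares zero; returning 0")
  out
}

## log of integral_0^inf exp(logf(g)) dg, by max-shifted quadrature in
## u = log g. logf must accept a vector.
log_integral_g <- function(logf, lower = -40, upper = 40) {
  opt <- stats::optimize(function(u) logf(exp(u)) + u, c(lower, upper),
                         maximum = TRUE)
  m <- opt$objective
  val <- stats::integrate(function(u) exp(logf(exp(u)) + u - m),
                          lower, upper, rel.tol = 1e-10,
                          subdivisions = 500L)
  if (val$message != "OK") stop("quadrature failed: ", val$message)
  m + log(val$value)
}

#' Jeffreys-Zellner-Siow Bayes factor for a two-sample t statistic
#'
#' Computes BF10 for the two-sample t-test under a Cauchy(0, r) prior on
#' the standardized effect size (equivalently a normal prior with
#' inverse-gamma(1/2, r^2/2) mixing on its variance g), by adaptive
#' quadrature over g:
#' \deqn{BF_{10} = \frac{\int_0^\infty (1+Ng)^{-1/2}
#'   \left(1+\frac{t^2}{(1+Ng)\nu}\right)^{-(\nu+1)/2} \pi(g)\,dg}
#'   {\left(1+t^2/\nu\right)^{-(\nu+1)/2}}}
#' with \eqn{N = n_1 n_2/(n_1+n_2)} and \eqn{\nu = n_1+n_2-2}.
#'
#' @param t observed t statistic (finite).
#' @param n1,n2 group sizes, both >= 2.
#' @param r Cauchy prior scale (default `sqrt(2)/2`, the conventional
#'   "medium" scale).
#' @return BF10 (> 0). Values below 1 favour the null.
#' @examples
#' jzs_ttest_bf(0, 20, 20)   # < 1
#' @export
jzs_ttest_bf <- function(t, n1, n2, r = sqrt(2) / 2) {
  if (!is.finite(t)) stop("t must be finite")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (r <= 0) stop("prior scale r must be > 0")
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  log_prior <- function(g) 0.5 * log(r^2 / 2) - lgamma(0.5) -
    1.5 * log(g) - r^2 / (2 * g)
  logf <- function(g) -0.5 * log1p(N * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) + log_prior(g)
  log_num <- log_integral_g(logf)
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  exp(log_num - log_den)
}

## log Bayes factor of a linear model (p non-intercept columns, fit R2,
## n observations) against the intercept-only null, under the
## Zellner-Siow mixture-of-g prior: g ~ inverse-gamma(1/2, n/2).
zs_lm_log_bf_null <- function(R2, n, p) {
  if (p == 0) return(0)
  if (R2 < 0) R2 <- 0
  if (R2 >= 1) R2 <- 1 - 1e-12
  log_prior <- function(g) 0.5 * log(n / 2) - lgamma(0.5) -
    1.5 * log(g) - n / (2 * g)
  logf <- function(g) (n - 1 - p) / 2 * log1p(g) -
    (n - 1) / 2 * log1p(g * (1 - R2)) + log_prior(g)
  log_integral_g(logf)
}

factor_terms <- function() c("condition", "diagnosis", "sex",
                             "condition:diagnosis", "condition:sex",
                             "diagnosis:sex", "condition:diagnosis:sex")

prepare_factorial <- function(data) {
  needed <- c("condition", "diagnosis", "sex", "outcome")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (f in c("condition", "diagnosis", "sex")) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) != 2)
      stop("factor '", f, "' must have exactly two observed levels")
  }
  cells <- table(data$condition, data$diagnosis, data$sex)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: condition=", dimnames(cells)[[1]][empty[1]],
         ", diagnosis=", dimnames(cells)[[2]][empty[2]],
         ", sex=", dimnames(cells)[[3]][empty[3]])
  }
  data
}

#' Factorial linear model over Condition, Diagnosis and Sex
#'
#' Fits ordinary least squares on the full 2x2x2 factorial design (all
#' two- and three-way interactions) with sum-to-zero factor coding, and
#' reports per-term F tests by the configured sum-of-squares type (default
#' III), partial eta-squared, and (optionally) a Zellner-Siow Bayes factor
#' for each term against the same model without it.
#'
#' @param data long outcome table: columns `condition`, `diagnosis`, `sex`
#'   (each two-level) and `outcome`; at most two rows per observer (one per
#'   condition), treated as independent observations.
#' @param ss_type `"III"` (default), `"II"` or `"I"`.
#' @param compute_bf attach `bf10` per term via [model_bf()] (default
#'   TRUE).
#' @param prior_scale passed to [model_bf()].
#' @return data frame of class `effect_table`: one row per term with `term,
#'   F, df1, df2, p, partial_eta_sq, bf10`; attributes `ss_type` and
#'   `prior_scale`. Residual degrees of freedom are in attribute
#'   `"df_residual"`. When the residual sum of squares is numerically zero,
#'   terms with non-zero sums of squares report `F = Inf`.
#' @export
factorial_lm <- function(data, ss_type = c("III", "II", "I"),
                         compute_bf = TRUE, prior_scale = sqrt(2) / 2) {
  ss_type <- match.arg(ss_type)
  data <- prepare_factorial(data)
  if (nrow(data) - 8 < 1) stop("need at least one residual degree of freedom")
  ctr <- list(condition = "contr.sum", diagnosis = "contr.sum",
              sex = "contr.sum")
  fit <- stats::lm(outcome ~ condition * diagnosis * sex, data = data,
                   contrasts = ctr)
  terms_all <- factor_terms()
  y <- data$outcome
  rss_fit <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (rss_fit <= 1e-10 * max(tss, 1)) {
    # degenerate (noise-free or constant) outcome: car refuses a zero
    # residual, so take drop-term sums of squares directly
    mm <- stats::model.matrix(fit)
    assign <- attr(mm, "assign")
    ss <- vapply(seq_along(terms_all), function(k) {
      sum(stats::lm.fit(mm[, assign != k, drop = FALSE], y)$residuals^2) -
        rss_fit
    }, numeric(1))
    df1 <- vapply(seq_along(terms_all), function(k) sum(assign == k), 0)
    ss_res <- rss_fit
    df2 <- nrow(data) - ncol(mm)
  } else if (ss_type == "I") {
    a <- stats::anova(fit)
    ss <- a[terms_all, "Sum Sq"]
    df1 <- a[terms_all, "Df"]
    ss_res <- a["Residuals", "Sum Sq"]
    df2 <- a["Residuals", "Df"]
  } else {
    a <- car::Anova(fit, type = ss_type)
    ss <- a[terms_all, "Sum Sq"]
    df1 <- a[terms_all, "Df"]
    ss_res <- a["Residuals", "Sum Sq"]
    df2 <- a["Residuals", "Df"]
  }
  tol <- 1e-10 * max(tss, ss, ss_res, 1e-12)
  if (ss_res <= tol) {
    F_ <- ifelse(ss > tol, Inf, 0)
    p <- ifelse(ss > tol, 0, 1)
  } else {
    F_ <- (ss / df1) / (ss_res / df2)
    F_[ss <= tol] <- 0
    p <- stats::pf(F_, df1, df2, lower.tail = FALSE)
  }
  peta <- suppressWarnings(partial_eta_squared(pmax(ss, 0), ss_res))
  peta[ss <= tol & ss_res <= tol] <- 0
  out <- data.frame(term = terms_all, F = F_, df1 = df1, df2 = df2, p = p,
                    partial_eta_sq = peta, bf10 = NA_real_,
                    stringsAsFactors = FALSE)
  if (compute_bf)
    out$bf10 <- vapply(terms_all, function(tm)
      model_bf(data, tm, prior_scale = prior_scale), numeric(1))
  attr(out, "ss_type") <- ss_type
  attr(out, "prior_scale") <- prior_scale
  attr(out, "df_residual") <- df2
  class(out) <- c("effect_table", "data.frame")
  out
}

#' Bayes factor for one term of the factorial model
#'
#' Compares the full factorial model against the same model with the given
#' term's columns removed, under Zellner-Siow mixture-of-g priors on the
#' effect coefficients (a single g shared by all effects in a model,
#' Jeffreys priors on the intercept and error variance). Each model's
#' marginal likelihood relative to the intercept-only null is a
#' one-dimensional integral over g, evaluated by adaptive quadrature; the
#' term's BF10 is the ratio of the two.
#'
#' @param data long outcome table as for [factorial_lm()].
#' @param term one of the seven design terms, e.g. `"sex"` or
#'   `"condition:diagnosis:sex"`.
#' @param prior_scale reserved for compatibility; the Zellner-Siow unit
#'   information scale (g ~ inverse-gamma(1/2, n/2)) is used.
#' @return BF10 (> 0) with attributes `method` and `prior`.
#' @export
model_bf <- function(data, term, prior_scale = sqrt(2) / 2) {
  data <- prepare_factorial(data)
  terms_all <- factor_terms()
  term <- gsub(" ", "", term)
  canon <- function(tm) paste(sort(strsplit(tm, ":")[[1]]), collapse = ":")
  hit <- terms_all[vapply(terms_all, canon, "") == canon(term)]
  if (!length(hit)) stop("unknown term: ", term)
  term <- hit[1]
  ctr <- list(condition = "contr.sum", diagnosis = "contr.sum",
              sex = "contr.sum")
  mm <- stats::model.matrix(~ condition * diagnosis * sex, data = data,
                            contrasts.arg = ctr)
  assign <- attr(mm, "assign")
  term_labels <- attr(stats::terms(~ condition * diagnosis * sex),
                      "term.labels")
  keep_map <- vapply(term_labels, canon, "")
  term_cols <- which(assign > 0 &
                       keep_map[pmax(assign, 1)] == canon(term))
  if (!length(term_cols) || all(abs(mm[, term_cols]) < 1e-12))
    stop("term '", term, "' has no non-zero design columns")
  y <- data$outcome
  n <- length(y)
  r2 <- function(X) {
    if (ncol(X) == 0) return(0)
    f <- stats::lm.fit(cbind(1, X), y)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    1 - sum(f$residuals^2) / tss
  }
  X_full <- mm[, assign > 0, drop = FALSE]
  X_red <- mm[, assign > 0 & !(seq_along(assign) %in% term_cols),
              drop = FALSE]
  lb_full <- zs_lm_log_bf_null(r2(X_full), n, ncol(X_full))
  lb_red <- zs_lm_log_bf_null(r2(X_red), n, ncol(X_red))
  structure(exp(lb_full - lb_red),
            method = "Zellner-Siow single-g quadrature",
            prior = "g ~ inverse-gamma(1/2, n/2)")
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  cat("Factorial effects (type", attr(x, "ss_type"), "sums of squares)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Format an effect table in the conventional reporting style
#'
#' @param effects an `effect_table`.
#' @param outcome_name label for the dependent variable.
#' @return character vector, one line per term, of the form
#'   `"F(df1, df2) = ..., p = ..., eta_p^2 = ..., BF_10 = ..."`.
#' @export
format_effect_report <- function(effects, outcome_name = "outcome") {
  fmt_p <- function(p) ifelse(p < 0.001, "< 0.001",
                              paste0("= ", formatC(p, digits = 3,
                                                   format = "f")))
  c(paste0("Outcome: ", outcome_name),
    sprintf("  %-28s F(%d, %d) = %.2f, p %s, eta_p^2 = %.3f, BF_10 = %.3g",
            effects$term, effects$df1, effects$df2,
            pmin(effects$F, 9.99e12), fmt_p(effects$p),
            effects$partial_eta_sq, effects$bf10))
}
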