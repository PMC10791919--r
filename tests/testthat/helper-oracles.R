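# sequential greedy oracle: literal re-implementation by exhaustive search
# over the remaining controls at each step
greedy_oracle <- function(scores, labels, spec, ids) {
  tr <- which(labels == spec$treatment_label)
  co <- which(labels == spec$control_label)
  if (spec$order == "descending_score")
    tr <- tr[order(scores[tr], decreasing = TRUE)]
  used <- logical(length(scores))
  pairs <- NULL
  for (t in tr) {
    for (r in seq_len(spec$ratio)) {
      cand <- co[!used[co]]
      if (!length(cand)) break
      d <- abs(scores[cand] - scores[t])
      best <- cand[d == min(d)]
      best <- best[order(as.character(ids[best]))][1]
      used[best] <- TRUE
      pairs <- rbind(pairs, data.frame(treated_id = as.character(ids[t]),
                                       control_id = as.character(ids[best])))
    }
  }
  pairs
}


# dense-grid brute-force integration over the prior on g, independent of
# the quadrature path used by jzs_ttest_bf()
jzs_grid_oracle <- function(t, n1, n2, r = sqrt(2) / 2) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  u <- seq(-25, 25, length.out = 200001)    # trapezoid in log g
  g <- exp(u)
  logf <- -0.5 * log1p(N * g) -
    (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
    0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g) + u
  m <- max(logf)
  num <- exp(m) * sum(exp(logf - m)) * (u[2] - u[1])
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# per-term sums of squares by explicit nested-model comparison:
# SS(term) = RSS(model without the term's columns) - RSS(full model)
ss3_oracle <- function(data) {
  ctr <- list(condition = "contr.sum", diagnosis = "contr.sum",
              sex = "contr.sum")
  mm <- model.matrix(~ condition * diagnosis * sex, data = data,
                     contrasts.arg = ctr)
  assign <- attr(mm, "assign")
  y <- data$outcome
  rss <- function(X) sum(lm.fit(X, y)$residuals^2)
  full <- rss(mm)
  sapply(seq_len(max(assign)), function(k)
    rss(mm[, assign != k, drop = FALSE]) - full)
}

make_long <- function(n_cell = 6, effects = c(condition = 0, diagnosis = 0,
                                              sex = 0), sd = 1,
                      unbalance = 0) {
  cells <- expand.grid(condition = c("cond1", "cond2"),
                       diagnosis = c("ASC", "TDC"), sex = c("M", "F"),
                       stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- n_cell + sample(0:unbalance, 1)
    mu <- effects[["condition"]] * (cells$condition[i] == "cond2") +
      effects[["diagnosis"]] * (cells$diagnosis[i] == "ASC") +
      effects[["sex"]] * (cells$sex[i] == "F")
    data.frame(observer_id = NA, condition = cells$condition[i],
               diagnosis = cells$diagnosis[i], sex = cells$sex[i],
               outcome = mu + rnorm(n, 0, sd), stringsAsFactors = FALSE)
  }))
  rows$observer_id <- sprintf("O%03d", seq_len(nrow(rows)))
  rows
}

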