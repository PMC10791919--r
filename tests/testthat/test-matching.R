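test_that("propensity scores reduce to the treated fraction for constant covariates", {
  cohort <- data.frame(observer_id = sprintf("O%d", 1:10),
                       group = rep(c("A", "B"), c(4, 6)),
                       age = 10, fsiq = 100, stringsAsFactors = FALSE)
  spec <- match_spec("A", "B")
  p <- estimate_propensity(cohort, spec)
  expect_equal(as.numeric(p), rep(0.4, 10), tolerance = 1e-8)
})

test_that("complete separation is signalled", {
  cohort <- data.frame(observer_id = sprintf("O%d", 1:10),
                       group = rep(c("A", "B"), each = 5),
                       age = c(1:5, 101:105), fsiq = 100,
                       stringsAsFactors = FALSE)
  expect_error(estimate_propensity(cohort, match_spec("A", "B")),
               "separation")
})

test_that("propensity scores agree with a grid-search maximum likelihood oracle", {
  cohort <- data.frame(observer_id = sprintf("O%d", 1:6),
                       group = c("A", "A", "A", "B", "B", "B"),
                       age = c(9.1, 11.4, 10.2, 10.9, 9.8, 12.0),
                       stringsAsFactors = FALSE)
  spec <- match_spec("A", "B", covariates = "age")
  p <- estimate_propensity(cohort, spec)

  y <- as.integer(cohort$group == "A")
  x <- cohort$age
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  # coarse-to-fine grid search, refined 6 times
  lo <- c(-40, -5); hi <- c(40, 5)
  for (it in 1:6) {
    g1 <- seq(lo[1], hi[1], length.out = 41)
    g2 <- seq(lo[2], hi[2], length.out = 41)
    val <- outer(g1, g2, Vectorize(function(a, b) nll(c(a, b))))
    ix <- which(val == min(val), arr.ind = TRUE)[1, ]
    best <- c(g1[ix[1]], g2[ix[2]])
    span <- (hi - lo) / 8
    lo <- best - span; hi <- best + span
  }
  oracle_p <- plogis(best[1] + best[2] * x)
  expect_equal(as.numeric(p), oracle_p, tolerance = 1e-4)
})

test_that("greedy matching takes nearest unused controls in score order", {
  scores <- c(0.8, 0.6, 0.79, 0.61, 0.2)
  labels <- c("T", "T", "C", "C", "C")
  ids <- c("t1", "t2", "c1", "c2", "c3")
  res <- greedy_match(scores, labels, match_spec("T", "C"), ids = ids)
  expect_equal(res$pairs$treated_id, c("t1", "t2"))
  expect_equal(res$pairs$control_id, c("c1", "c2"))
  expect_setequal(res$retained_ids, c("t1", "t2", "c1", "c2"))
})

test_that("identical score vectors match perfectly with zero residual imbalance", {
  scores <- rep(c(0.3, 0.5, 0.7), 2)
  labels <- rep(c("T", "C"), each = 3)
  covs <- data.frame(age = rep(c(9, 10, 11), 2))
  res <- greedy_match(scores, labels, match_spec("T", "C"),
                      ids = sprintf("u%d", 1:6), covariate_data = covs)
  expect_equal(nrow(res$pairs), 3)
  expect_equal(res$pairs$distance, rep(0, 3))
  expect_equal(res$balance$smd_after, 0)
})

test_that("a zero caliper with no exact ties yields an empty match set", {
  scores <- c(0.8, 0.6, 0.75, 0.55)
  labels <- c("T", "T", "C", "C")
  res <- greedy_match(scores, labels,
                      match_spec("T", "C", caliper = 0),
                      ids = sprintf("u%d", 1:4))
  expect_equal(nrow(res$pairs), 0)
  expect_equal(length(res$retained_ids), 0)
})

test_that("greedy matching equals the sequential exhaustive oracle on small problems", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(4:10, 1)
    n_t <- sample(1:(n - 1), 1)
    labels <- sample(rep(c("T", "C"), c(n_t, n - n_t)))
    scores <- round(runif(n, 0.05, 0.95), 3)
    ids <- sprintf("u%02d", 1:n)
    spec <- match_spec("T", "C", ratio = sample(1:2, 1),
                       order = sample(c("descending_score", "data_order"),
                                      1))
    res <- greedy_match(scores, labels, spec, ids = ids)
    orc <- greedy_oracle(scores, labels, spec, ids)
    if (is.null(orc)) {
      expect_equal(nrow(res$pairs), 0)
    } else {
      expect_equal(res$pairs[c("treated_id", "control_id")],
                   orc, ignore_attr = TRUE)
    }
    # matching without replacement
    expect_false(any(duplicated(res$pairs$control_id)))
  }
})

test_that("matching improves covariate balance on overlapping cohorts", {
  set.seed(15)
  worse <- 0
  for (rep in 1:100) {
    n_t <- 20; n_c <- 60
    cohort <- data.frame(
      observer_id = sprintf("u%03d", 1:(n_t + n_c)),
      group = rep(c("T", "C"), c(n_t, n_c)),
      age = c(rnorm(n_t, 11, 1.2), rnorm(n_c, 10, 1.2)),
      fsiq = c(rnorm(n_t, 100, 10), rnorm(n_c, 106, 10)),
      stringsAsFactors = FALSE)
    spec <- match_spec("T", "C")
    p <- estimate_propensity(cohort, spec)
    res <- greedy_match(p, cohort$group, spec, ids = cohort$observer_id,
                        covariate_data = cohort[c("age", "fsiq")])
    if (any(abs(res$balance$smd_after) >
            abs(res$balance$smd_before) + 1e-9)) worse <- worse + 1
  }
  expect_lte(worse, 10)   # balance may tick up only in rare draws
})

test_that("sequential passes retain the anchor cell and the matched controls", {
  cg <- generate_cohort(effect_spec(), c(30, 10, 30, 12), seed = 16L)
  res <- run_matching_passes(cg$cohort)
  asc_f <- cg$cohort$observer_id[cg$cohort$diagnosis == "ASC" &
                                   cg$cohort$sex == "F"]
  expect_true(all(asc_f %in% res$retained_ids))
  # 10 treated, ratio 2, 2, 1 -> 20 + 20 + 10 controls + 10 anchors
  expect_equal(length(res$retained_ids), 10 + 20 + 20 + 10)
  for (pass in res$passes)
    expect_false(any(duplicated(pass$pairs$control_id)))
})
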