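test_that("default protocol specs carry the published constants", {
  sp <- default_specs()
  expect_setequal(names(sp), c("SRT", "CRT", "SDT", "DDT", "ADT", "ADTssa",
                               "SQFD", "SMFD", "TOJ", "TOJwc"))
  expect_equal(sp$SDT$n_trials, 24L)
  expect_equal(sp$SDT$start, 20)
  expect_equal(sp$SDT$step, 1)
  expect_equal(sp$DDT$n_trials, 7L)
  expect_equal(sp$DDT$stimulus$ramp_rate_um_s, 2)
  expect_equal(sp$DDT$stimulus$delay_range_ms, c(0, 2500))
  expect_equal(sp$ADT$step, 10)
  expect_equal(sp$ADT$stimulus$standard_amplitude_um, 100)
  expect_equal(sp$ADT$stimulus$comparison_start_um, 200)
  expect_equal(sp$ADTssa$stimulus$adapter$duration_ms, 1000)
  expect_equal(sp$SQFD$step, 1)
  expect_equal(sp$SQFD$stimulus$standard_frequency_hz, 30)
  expect_equal(sp$SQFD$stimulus$comparison_start_hz, 40)
  expect_equal(sp$SQFD$stimulus$isi_ms, 500)
  expect_equal(sp$TOJ$start, 150)
  expect_equal(sp$TOJ$step, 0.10)
  expect_equal(sp$TOJwc$stimulus$carrier$amplitude_um, 20)
  for (p in c("SRT", "CRT", "SQFD", "SMFD", "TOJ", "TOJwc"))
    expect_equal(sp[[p]]$n_trials, 20L)
  for (p in c("ADT", "ADTssa")) expect_equal(sp[[p]]$n_trials, 24L)
  # device envelope: amplitudes 0-350 um, frequency differences 0-20 Hz
  expect_lte(sp$SDT$upper_bound, 350)
  expect_lte(sp$SQFD$upper_bound, 50 - 30)
  expect_equal(sp$SRT$stimulus$amplitude_um, 300)
  expect_error(protocol_spec("SDT", bogus = 1), "unknown")
  expect_error(protocol_spec("SDT", step = -1), "step")
})

test_that("staircase follows one-up one-down then two-correct one-wrong", {
  sp <- default_specs()$SDT
  st <- staircase_state(sp)
  st <- update_staircase(st, TRUE, sp)
  expect_equal(st$current_level, 19)           # phase 1, one step down
  st <- update_staircase(st, FALSE, sp)
  expect_equal(st$current_level, 20)           # phase 1, one step up

  # drive to phase 2 at level 15 by construction
  st <- staircase_state(sp)
  seq1 <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  for (r in seq1) st <- update_staircase(st, r, sp)
  expect_equal(st$trial_index, 11L)
  expect_equal(st$current_level, 16)
  # two consecutive correct: hold, then one step down
  st2 <- update_staircase(st, TRUE, sp)
  expect_equal(st2$current_level, 16)
  st2 <- update_staircase(st2, TRUE, sp)
  expect_equal(st2$current_level, 15)
  expect_equal(st2$consecutive_correct, 0L)
  # correct then incorrect: hold, then one step up
  st3 <- update_staircase(st, TRUE, sp)
  st3 <- update_staircase(st3, FALSE, sp)
  expect_equal(st3$current_level, 17)
  # history bookkeeping
  expect_equal(nrow(st3$history), 12)
  expect_error({
    stx <- st3
    for (i in 1:30) stx <- update_staircase(stx, TRUE, sp)
  }, "already has")
})

test_that("order-judgement staircase steps by 10% of the current ISI", {
  tj <- default_specs()$TOJ
  st <- staircase_state(tj)
  st <- update_staircase(st, FALSE, tj)
  expect_equal(st$current_level, 165)          # +10% of 150
  st <- update_staircase(st, TRUE, tj)
  expect_equal(st$current_level, 148.5)        # -10% of 165
})

test_that("k consecutive correct responses lower the level by k steps in phase 1", {
  for (sp in list(default_specs()$SDT, default_specs()$ADT,
                  default_specs()$SQFD)) {
    for (k in c(1, 4, 7)) {
      st <- staircase_state(sp)
      for (i in seq_len(k)) st <- update_staircase(st, TRUE, sp)
      expect_equal(st$current_level,
                   max(sp$start - k * sp$step, sp$lower_bound))
    }
  }
})

test_that("levels never leave the protocol bounds", {
  set.seed(7)
  for (pid in c("SDT", "ADT", "SQFD", "TOJ")) {
    sp <- default_specs()[[pid]]
    for (rep in 1:25) {
      st <- staircase_state(sp)
      for (i in seq_len(sp$n_trials)) {
        st <- update_staircase(st, runif(1) < 0.35, sp)
        expect_gte(st$current_level, sp$lower_bound)
        expect_lte(st$current_level, sp$upper_bound)
      }
    }
  }
})

test_that("run_protocol produces the full trial record", {
  obs <- step_observer(theta = 10)
  set.seed(11)
  srt <- run_protocol(obs, default_specs()$SRT)
  expect_equal(nrow(srt), 20)
  expect_true(all(srt$correct))                 # any-finger responses
  expect_true(all(srt$site_resp == "any"))
  expect_true(all(srt$rt_ms > 0))

  set.seed(12)
  a <- run_protocol(obs, default_specs()$SDT)
  set.seed(12)
  b <- run_protocol(obs, default_specs()$SDT)
  expect_identical(a, b)                        # determinism under a seed
  expect_equal(a$trial, 1:24)
  # incorrect 2AFC responses point at the other digit
  wrong <- !a$correct
  if (any(wrong)) expect_true(all(a$site_stim[wrong] != a$site_resp[wrong]))
})

test_that("a deterministic observer's staircase descends to and brackets theta", {
  obs <- step_observer(theta = 10)
  set.seed(13)
  tr <- run_protocol(obs, default_specs()$SDT)
  last5 <- tail(tr$level, 5)
  expect_true(all(last5 >= 8 & last5 <= 13))
  expect_lt(abs(staircase_threshold(tr) - 10), 2)
})

test_that("practice gating rejects a chance-level observer", {
  obs <- make_observer(theta_detect = 1e6, slope = 1e6, lapse = 0)
  set.seed(8)   # a run in which no three consecutive correct occur
  expect_error(run_protocol(obs, default_specs()$SDT), "practice cap")
})

test_that("dynamic detection implements the ramp arithmetic", {
  sp <- default_specs()$DDT
  # crossing at 15 um, 300 ms motor latency, 2 um/s: recorded 15.6
  obs <- make_observer(theta_detect = 15, mult_ddt = 1, ddt_noise_sd = 0,
                       motor_latency = 300)
  tr <- run_dynamic_detection(obs, sp)
  expect_equal(nrow(tr), 7)
  expect_equal(tr$level, rep(15.6, 7))
  expect_false(any(tr$censored))

  obs0 <- make_observer(theta_detect = 15, mult_ddt = 1, ddt_noise_sd = 0,
                        motor_latency = 0)
  expect_equal(run_dynamic_detection(obs0, sp)$level, rep(15, 7))

  # Monte-Carlo mean against the closed form theta*mult*E[noise] + rate*lat
  obs2 <- make_observer(theta_detect = 10, mult_ddt = 1.8,
                        ddt_noise_sd = 0.15, motor_latency = 200)
  sp_big <- protocol_spec("DDT", n_trials = 4000L)
  set.seed(21)
  m <- mean(run_dynamic_detection(obs2, sp_big)$level)
  expect_equal(m, 10 * 1.8 * exp(0.15^2 / 2) + 2 * 0.2, tolerance = 0.1)

  # ramp hitting the device bound is censored and clamped
  obs3 <- make_observer(theta_detect = 400, mult_ddt = 1, ddt_noise_sd = 0)
  tr3 <- run_dynamic_detection(obs3, sp)
  expect_true(all(tr3$censored))
  expect_equal(tr3$level, rep(350, 7))
})

test_that("dynamic estimates exceed static estimates when the pair multiplier >= 1", {
  set.seed(31)
  cg <- generate_cohort(effect_spec(), c(5, 5, 5, 5), seed = 31L)
  for (i in seq_len(nrow(cg$params))) {
    obs <- cg$params[i, ]
    sdt_est <- staircase_threshold(run_protocol(obs, default_specs()$SDT))
    ddt_est <- dynamic_threshold(run_dynamic_detection(
      obs, default_specs()$DDT))$outcome
    expect_gt(ddt_est, sdt_est)
  }
})

test_that("the alternative phase-2 rule converges near 70.7% from the easy side", {
  # two_wrong_up variant: any correct steps down, two errors step up;
  # its equilibrium sits at 29.3% correct, i.e. tracks a much harder level
  obs <- make_observer(theta_detect = 10, lapse = 0)
  sp <- protocol_spec("SDT", n_trials = 2000L)
  set.seed(41)
  tr <- run_protocol(obs, sp, rule2 = "two_wrong_up")
  pc <- mean(tr$correct[tr$trial > 10])
  expect_lt(pc, 0.60)   # tracks below the two-correct-down equilibrium
})

test_that("run_battery covers every observer and protocol", {
  cg <- generate_cohort(effect_spec(), c(1, 1, 1, 1), seed = 51L)
  tr <- run_battery(cg$params, seed = 52L)
  expect_equal(sort(unique(tr$protocol)),
               sort(names(default_specs())))
  counts <- table(tr$observer_id)
  expect_true(all(counts == sum(vapply(default_specs(), `[[`, 0,
                                       "n_trials"))))
})
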