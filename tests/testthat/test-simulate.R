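test_that("simulate_* are deterministic given the seed and leave RNG alone", {
  m <- make_montage()
  d <- tiny_design(2)
  spec <- amp_only_spec(0.5)
  spec$noise_sd <- 0.2
  r1 <- simulate_subject_fnirs(m, d, spec, seed = 42)
  r2 <- simulate_subject_fnirs(m, d, spec, seed = 42)
  expect_identical(r1$data, r2$data)
  rr1 <- simulate_rr(120, seed = 7)
  rr2 <- simulate_rr(120, seed = 7)
  expect_identical(rr1$rr, rr2$rr)
  s1 <- simulate_scr(d, seed = 3)
  s2 <- simulate_scr(d, seed = 3)
  expect_identical(s1$samples, s2$samples)
  # caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_rr(60, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null effect spec produces an all-zero recording", {
  m <- make_montage()
  d <- tiny_design(2)
  rec <- simulate_subject_fnirs(m, d, null_effect_spec(), seed = 1)
  expect_true(all(rec$data == 0))
})

test_that("response prolongation increases post-offset area", {
  m <- make_montage()
  d <- tiny_design(3)
  fs <- d$sampling_rate
  rec0 <- simulate_subject_fnirs(m, d, amp_only_spec(1, tau_ot = 0),
                                 seed = 1, group = "PLC")
  spec8 <- amp_only_spec(1, tau_ot = 8)
  spec8$subject_tau_sd <- 0
  rec8 <- simulate_subject_fnirs(m, d, spec8, seed = 1,
                                 group = "intranasal_OT")
  # numeric integration of the block-averaged curves after block offset
  ba0 <- block_average(rec0, d, "gentle_touch", window = c(30, 45))
  ba8 <- block_average(rec8, d, "gentle_touch", window = c(30, 45))
  area0 <- sum(ba0[13, ]) / fs
  area8 <- sum(ba8[13, ]) / fs
  expect_gt(area8, area0)
  # placebo recordings identical whether or not prolongation is configured
  rec0b <- simulate_subject_fnirs(m, d, spec8, seed = 1, group = "PLC")
  expect_identical(rec0$data, rec0b$data)
})

test_that("RR simulation hits closed-form means and spectral targets", {
  rr_const <- simulate_rr(60, mean_hr_bpm = 75, lf_amp = 0, hf_amp = 0,
                          jitter_sd = 0, seed = 1)
  expect_true(all(abs(rr_const$rr - 800) < 1e-9))
  rr_hf <- simulate_rr(300, mean_hr_bpm = 70, lf_amp = 0, hf_amp = 30,
                       hf_freq = 0.25, jitter_sd = 0, seed = 2)
  # spectral oracle: power concentrated in the HF band
  hf <- hf_power(rr_hf, band = c(0.15, 0.40))
  lf <- hf_power(rr_hf, band = c(0.04, 0.15))
  expect_gt(hf, lf)
})

test_that("SCR simulation produces the configured base-to-peak amplitude", {
  d <- tiny_design(4)
  flat <- simulate_scr(d, event_amplitude = 0, noise_sd = 0, seed = 1)
  expect_true(all(abs(flat$samples - flat$samples[1]) < 1e-12))
  tr <- simulate_scr(d, event_amplitude = 1.2, noise_sd = 0, seed = 1)
  onsets <- d$events$onset[d$events$condition == "gentle_touch"]
  amp <- scr_event_amplitude(tr, onsets, window_s = 15)
  expect_lt(abs(amp - 1.2), 0.02)
})

test_that("cohort generator enforces sizes, exclusions and reproducibility", {
  cfg <- cohort_config(group_sizes = c(intranasal_OT = 8, oral_OT = 9,
                                       PLC = 10),
                       n_incomplete = 2, n_technical = 1,
                       components = character(0))
  ch <- simulate_cohort(cfg, seed = 11)
  acc <- exclusion_accounting(ch$subjects)
  expect_equal(acc$enrolled, 30)
  expect_equal(acc$analyzed, 27)
  expect_equal(acc$incomplete, 2)
  expect_equal(acc$technical, 1)
  tab <- table(analyzed_subjects(ch)$group)
  expect_equal(as.integer(tab[c("intranasal_OT", "oral_OT", "PLC")]),
               c(8L, 9L, 10L))
  expect_true(!anyDuplicated(ch$subjects$id))
  # ratings respect their scales, plasma positive
  rt <- cohort_ratings(ch)
  expect_true(all(rt$rating >= 1 & rt$rating <= 9))
  expect_true(all(cohort_plasma(ch)$pg_ml > 0))
  # reproducible and extensible: first subjects unchanged when cohort grows
  ch2 <- simulate_cohort(cfg, seed = 11)
  expect_identical(ch$subjects$plasma_baseline, ch2$subjects$plasma_baseline)
  cfg_big <- cfg
  cfg_big$group_sizes <- c(intranasal_OT = 8, oral_OT = 9, PLC = 12)
  ch3 <- simulate_cohort(cfg_big, seed = 11)
  shared <- seq_len(nrow(ch$subjects))
  expect_identical(ch$subjects$mediator[shared][order(ch$subjects$id[shared])][1:5],
                   ch3$subjects$mediator[match(sort(ch$subjects$id[shared])[1:5],
                                               ch3$subjects$id)])
})

test_that("null mediation paths give null group differences", {
  cfg <- cohort_config(group_sizes = c(intranasal_OT = 40, oral_OT = 40,
                                       PLC = 40),
                       n_incomplete = 0, n_technical = 0,
                       paths = list(
                         intranasal_OT = list(a = 0, b = 0, c_prime = 0),
                         oral_OT = list(a = 0, b = 0, c_prime = 0)),
                       components = character(0))
  means <- replicate(40, {
    ch <- simulate_cohort(cfg, seed = sample.int(1e6, 1))
    s <- analyzed_subjects(ch)
    diff(tapply(s$pleasantness_gentle_touch,
                s$group == "PLC", mean))
  })
  # Monte-Carlo mean difference ~ N(0, sigma_y^2 * (1/80 + 1/40) / 40)
  expect_lt(abs(mean(means)), 3 * sqrt(1 * (1 / 80 + 1 / 40) / 40))
})

test_that("OLS on replicate generated cohorts recovers the configured a path", {
  set.seed(31)
  a_hat <- replicate(200, {
    d <- simulate_mediation_data(n_treat = 56, n_control = 58,
                                 seed = sample.int(1e6, 1))
    coef(lm(m ~ x, d))[["x"]]
  })
  mc_se <- sd(a_hat) / sqrt(length(a_hat))
  expect_lt(abs(mean(a_hat) - 6.57), 2 * mc_se)
})
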