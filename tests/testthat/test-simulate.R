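# Synthetic episode generator: contracts, determinism, fault injection.

test_that("baseline episodes have the configured geometry and a stable timeline", {
  cfg <- episode_config(duration = 60, sampling_rate = 256, seed = 42)
  ep <- generate_baseline(cfg)
  expect_equal(dim(ep$signal), c(4, 15360))
  expect_equal(length(ep$behavior), 15360)
  expect_true(all(ep$behavior >= 0))
  expect_true(all(ep$behavior < ep$config$calibration$error_threshold))
  expect_identical(ep$truth$state_timeline$state, "stable")
  expect_equal(ep$truth$state_timeline$t_end, 60)
  expect_null(ep$truth$fault_onset)
  # dominant alpha: the 8-12 Hz band carries most of the 1-45 Hz power
  ev <- detect_events(ep)
  expect_gt(mean(ev$alpha_power), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(episode_config(duration = 0), "duration")
  expect_error(episode_config(sampling_rate = 0), "sampling_rate")
  expect_error(episode_config(n_channels = 0), "n_channels")
  expect_error(fault_spec("gradual_drift", onset_sigma = -1), "onset_sigma")
  expect_error(fault_spec("gradual_drift", drift_start = 50, drift_end = 40),
               "drift_start")
  expect_error(generate_baseline(task_scenario("inhibition", seed = 1)),
               "none")
})

test_that("episodes are a pure function of their configuration", {
  cfg <- task_scenario("overload", seed = 77, duration = 20)
  a <- simulate_episode(cfg)
  b <- simulate_episode(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_episode(task_scenario("overload", seed = 78, duration = 20))
  expect_false(identical(a$signal, c2$signal))
})

test_that("state timelines partition the episode exactly", {
  for (task in c("motor_control", "inhibition", "overload")) {
    for (seed in c(3, 11, 29)) {
      ep <- simulate_episode(quick_config(task, seed = seed, duration = 30))
      tl <- ep$truth$state_timeline
      expect_equal(tl$t_start[1], 0)
      expect_equal(tl$t_end[nrow(tl)], 30)
      if (nrow(tl) > 1)
        expect_equal(tl$t_start[-1], tl$t_end[-nrow(tl)], tolerance = 1e-12)
      expect_true(all(tl$t_end > tl$t_start))
    }
  }
})

test_that("zero-amplitude drift is a no-op on signal and behaviour", {
  cfg <- episode_config(seed = 5, duration = 20)
  base <- generate_baseline(cfg)
  ep <- inject_fault(base, fault_spec("gradual_drift", drift_amplitude = 0))
  expect_equal(ep$signal, base$signal)
  expect_equal(ep$behavior, base$behavior)
  expect_null(ep$truth$error_onset)
  expect_identical(ep$truth$fault_kind, "gradual_drift")
})

test_that("inject_fault enforces its contracts", {
  cfg <- episode_config(seed = 5, duration = 20)
  base <- generate_baseline(cfg)
  expect_error(inject_fault(base, fault_spec("none")), "kind")
  faulted <- inject_fault(base, fault_spec("gradual_drift"))
  expect_error(inject_fault(faulted, fault_spec("gradual_drift")),
               "already carries")
})

test_that("fault onsets beyond the episode are clamped with a warning record", {
  cfg <- episode_config(seed = 8, duration = 8)
  base <- generate_baseline(cfg)
  ep <- inject_fault(base, fault_spec("gradual_drift", onset_mu = 40,
                                      onset_sigma = 0.1))
  expect_equal(ep$truth$fault_onset, 8)
  expect_match(ep$warnings, "clamped", all = FALSE)
})

test_that("faulted episodes record onset, error onset, and matching states", {
  ep <- fixture_episode("motor_control", 21)
  expect_identical(ep$truth$fault_kind, "gradual_drift")
  expect_true(is.numeric(ep$truth$fault_onset))
  expect_true("drift" %in% ep$truth$state_timeline$state)
  expect_gte(ep$truth$error_onset, ep$truth$fault_onset)

  ep2 <- fixture_episode("inhibition", 21)
  expect_identical(ep2$truth$fault_kind, "decision_reversal")
  expect_true(all(c("conflict", "reversal") %in%
                    ep2$truth$state_timeline$state))

  ep3 <- fixture_episode("overload", 21)
  expect_true(all(c("drift", "overload") %in%
                    ep3$truth$state_timeline$state))
  # ambiguity crossing: overload state entered tau*log(1/0.3) after onset
  amb <- ep3$truth$ambiguity_cross - ep3$truth$fault_onset
  expect_equal(amb, 2.2 * log(1 / 0.3), tolerance = 1e-8)
})

test_that("decision delays lie in the configured range for every seed", {
  for (seed in 1:40) {
    ep <- simulate_episode(quick_config("inhibition", seed = seed,
                                        duration = 20))
    if (is.null(ep$truth$fault_onset)) next
    d <- ep$truth$fault_onset - ep$truth$entropy_cross
    expect_gte(d, 0.3)
    expect_lte(d, 0.5)
    expect_equal(d, ep$truth$decision_delay, tolerance = 1e-10)
  }
})

test_that("behavioural lag between fault and error matches its calibration", {
  lags <- vapply(1:150, function(seed) {
    ep <- simulate_episode(quick_config("motor_control", seed = seed,
                                        duration = 20,
                                        behavior_lag_mean = 3.0,
                                        behavior_lag_sd = 0.25))
    ep$truth$error_onset - ep$truth$fault_onset
  }, numeric(1))
  # debounced threshold crossing adds a small fixed offset (< 40 ms)
  expect_lt(abs(mean(lags) - 3.0), 3 * 0.25 / sqrt(150) + 0.05)
  expect_lt(abs(sd(lags) - 0.25), 0.08)
})

test_that("error_onset implements the debounced threshold crossing", {
  fs <- 256
  b <- c(rep(0, 5 * fs), rep(2, 5 * fs))
  expect_equal(error_onset(b, 1, fs), 5.0)
  expect_null(error_onset(rep(0, 1000), 1, fs))
  # a blip shorter than the debounce window does not count
  blip <- rep(0, 1000); blip[100:130] <- 2  # ~120 ms at 256 Hz
  expect_null(error_onset(blip, 1, fs))
  expect_error(error_onset(numeric(0), 1, fs), "non-empty")
  expect_error(error_onset(b, 0, fs), "positive")
})
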