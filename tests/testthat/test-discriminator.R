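# Event detection: pseudocode fidelity, lifecycle, calibration gates.

test_that("drift/conflict branching equals the pseudocode oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 40
    div <- runif(n, 0, 0.7)
    cr <- runif(n, 0, 1)
    ev <- classify_windows(feature_stream(div, cr), discriminator_params())
    expect_identical(ev$type, pseudocode_oracle(div, cr))
  }
})

test_that("published threshold examples behave as printed", {
  p <- discriminator_params()
  one <- function(div, cr) classify_windows(feature_stream(div, cr), p)$type
  expect_identical(one(0.40, 0.0), "DriftEvent")
  expect_identical(one(0.20, 0.60), "ConflictEscalate")
  # elif precedence: drift wins when both exceed their thresholds
  expect_identical(one(0.40, 0.60), "DriftEvent")
  expect_identical(one(0.35, 0.50), "NoEvent")  # strict inequalities
})

test_that("raising the drift threshold never increases drift emissions", {
  set.seed(23)
  div <- runif(60, 0, 0.8); cr <- runif(60, 0, 1)
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    p <- discriminator_params(threshold_drift = th)
    sum(classify_windows(feature_stream(div, cr), p)$type == "DriftEvent")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hypothesis lifecycle: one commitment, rejection only afterwards", {
  set.seed(31)
  for (rep in 1:15) {
    n <- 30
    f <- data.frame(divergence = runif(n, 0, 0.6),
                    conflict_ratio = runif(n),
                    spectral_entropy = runif(n, 0.3, 0.8),
                    confidence = runif(n, 0.4, 1),
                    leading = sample(c("intent_a", "intent_b"), n, TRUE),
                    t_end = seq_len(n), stringsAsFactors = FALSE)
    ev <- classify_windows(f, discriminator_params())
    expect_lte(sum(ev$type == "Sigma1"), 1)
    expect_lte(sum(ev$type == "RejectH1"), 1)
    expect_lte(sum(ev$type == "AcceptH1"), 1)
    i_s <- which(ev$type == "Sigma1")
    for (ty in c("RejectH1", "AcceptH1")) {
      i_t <- which(ev$type == ty)
      if (length(i_t)) expect_gt(i_t, i_s)
    }
    expect_true(!is.unsorted(ev$t))
  }
})

test_that("a committed hypothesis is rejected on an entropy spike", {
  f <- data.frame(divergence = 0.1, conflict_ratio = 0.1,
                  spectral_entropy = c(0.4, 0.4, 0.7, 0.7),
                  confidence = 0.9, leading = "intent_a",
                  t_end = 1:4, stringsAsFactors = FALSE)
  ev <- classify_windows(f, discriminator_params())
  expect_identical(ev$type, c("Sigma1", "NoEvent", "RejectH1", "NoEvent"))
})

test_that("a change of leading hypothesis triggers rejection", {
  f <- data.frame(divergence = 0.1, conflict_ratio = 0.1,
                  spectral_entropy = 0.4, confidence = 0.9,
                  leading = c("intent_a", "intent_a", "intent_b"),
                  t_end = 1:3, stringsAsFactors = FALSE)
  ev <- classify_windows(f, discriminator_params())
  expect_identical(ev$type[3], "RejectH1")
})

test_that("detect_events on an episode commits immediately and stays ordered", {
  ep <- fixture_episode("motor_control", 33)
  ev <- detect_events(ep)
  expect_identical(ev$type[1], "Sigma1")
  expect_true(!is.unsorted(ev$t))
  # timestamps are window end times: first window ends at 512/256 = 2 s
  expect_equal(ev$t[1], 2)
  expect_error(detect_events(ep$signal[, 1:1000, drop = FALSE]),
               "baseline")
})

test_that("a stationary baseline episode emits no warning events", {
  ep <- fixture_episode("motor_control", 101, faulted = FALSE)
  ev <- detect_events(ep)
  expect_false(any(ev$type %in% c("DriftEvent", "ConflictEscalate",
                                  "RejectH1")))
})

test_that("warning events are rare across fault-free episodes", {
  # calibration gate: warning-class events in at most 5% of clean episodes
  n <- 200
  hits <- vapply(seq_len(n), function(i) {
    ep <- simulate_episode(task_scenario(
      c("motor_control", "inhibition", "overload")[1 + i %% 3],
      seed = 5000 + i, faulted = FALSE, duration = 30))
    ev <- detect_events(ep)
    any(ev$type %in% c("DriftEvent", "ConflictEscalate", "RejectH1"))
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("drift faults are detected between fault onset and error onset", {
  # detection gate on gradual drift with published fault parameters
  n <- 60
  ok <- vapply(seq_len(n), function(i) {
    ep <- simulate_episode(task_scenario("motor_control", seed = 7000 + i))
    ev <- detect_events(ep)
    d <- ev$t[ev$type == "DriftEvent"]
    length(d) > 0 && any(d > ep$truth$fault_onset &
                           d < ep$truth$error_onset)
  }, logical(1))
  expect_gte(mean(ok), 0.75)
})

test_that("ablation flags disable the corresponding branches", {
  ep <- fixture_episode("motor_control", 33)
  ev <- detect_events(ep, discriminator_params(disable = "drift"))
  expect_false(any(ev$type == "DriftEvent"))
  ev2 <- detect_events(ep, discriminator_params(disable = c("drift",
                                                            "conflict")))
  expect_false(any(ev2$type %in% c("DriftEvent", "ConflictEscalate")))
})
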