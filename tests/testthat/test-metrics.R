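# Trace scoring: traceability, anticipation, per-marker statistics,
# bootstrap intervals, condition comparisons.

fixture_truth <- function() {
  list(fault_kind = "gradual_drift", fault_onset = 5, error_onset = 9,
       true_intent = "intent_a",
       state_timeline = data.frame(
         t_start = c(0, 5, 10), t_end = c(5, 10, 60),
         state = c("stable", "drift", "stable"), stringsAsFactors = FALSE))
}

test_that("traceability counts type-consistent markers within tolerance", {
  truth <- fixture_truth()
  # 10 markers, 9 interpretable by hand count: sigma1 always; drift markers
  # at 5.5..10.9 inside drift +/- 1 s; the drift marker at 30 is not
  tr <- make_trace(c(2, 5.5, 6, 7, 8, 9, 10, 10.9, 30, 44),
                   c("Sigma1", rep("DriftEvent", 8), "AcceptH1"))
  expect_equal(as.numeric(traceability_score(tr, truth, 1.0)), 0.9)
  # all inside a matching interval
  tr2 <- make_trace(c(2, 6, 7), c("Sigma1", "DriftEvent", "DriftEvent"))
  expect_equal(as.numeric(traceability_score(tr2, truth)), 1.0)
  # empty trace: 1.0 by convention, flagged
  e <- traceability_score(make_trace(numeric(0), character(0)), truth)
  expect_equal(as.numeric(e), 1.0)
  expect_true(attr(e, "empty"))
  expect_error(traceability_score(tr2, truth, tolerance = -1), "tolerance")
})

test_that("marker/state consistency map follows the marker semantics", {
  truth <- list(fault_kind = "decision_reversal", fault_onset = 7,
                error_onset = 10, true_intent = "intent_b",
                state_timeline = data.frame(
                  t_start = c(0, 6, 7, 9), t_end = c(6, 7, 9, 60),
                  state = c("stable", "conflict", "reversal", "stable"),
                  stringsAsFactors = FALSE))
  ok <- function(ty, t) cogtrace:::.interpretable(ty, t, truth, 1.0)
  expect_true(ok("ConflictEscalate", 6.5))
  expect_false(ok("ConflictEscalate", 20))
  expect_true(ok("RejectH1", 8))     # reversal interval
  expect_true(ok("RejectH1", 30))    # any post-fault time
  expect_false(ok("RejectH1", 3))    # pre-fault
  expect_true(ok("AcceptH1", 4))
  expect_false(ok("AcceptH1", 7.9))  # > 1 s from both stable intervals
  expect_true(ok("Sigma1", 59))
  expect_false(ok("DriftEvent", 8))  # no drift state in a reversal episode
})

test_that("anticipation latency is the first-warning lead over error onset", {
  truth <- fixture_truth()
  tr <- make_trace(c(2, 6.7, 8, 12),
                   c("Sigma1", "DriftEvent", "ConflictEscalate",
                     "DriftEvent"))
  expect_equal(anticipation_latency(tr, truth), 9 - 6.7)
  # warning at t=3.0 with error at 5.3 -> 2.3 s
  expect_equal(anticipation_latency(
    make_trace(3, "DriftEvent"), list(error_onset = 5.3)), 2.3)
  expect_null(anticipation_latency(make_trace(3, "DriftEvent"),
                                   list(error_onset = NULL)))
  expect_null(anticipation_latency(make_trace(12, "DriftEvent"), truth))
  expect_null(anticipation_latency(make_trace(2, "Sigma1"), truth))
  # non-negative whenever defined (property over generated episodes)
  for (seed in c(2, 9, 23)) {
    ep <- fixture_episode("motor_control", seed)
    tr <- emit_trace(detect_events(ep))
    l <- anticipation_latency(tr, ep$truth)
    if (!is.null(l)) expect_gte(l, 0)
  }
})

test_that("marker_stats equals a brute-force recount on mixed fixtures", {
  traces <- list(); truths <- list()
  k <- 0
  for (task in c("motor_control", "inhibition", "overload")) {
    for (seed in c(4, 15)) {
      for (faulted in c(TRUE, FALSE)) {
        k <- k + 1
        ep <- fixture_episode(task, seed, faulted)
        traces[[k]] <- emit_trace(detect_events(ep),
                                  sprintf("%s-%d-%d", task, seed, faulted))
        truths[[k]] <- ep$truth
      }
    }
  }
  ms <- marker_stats(traces, truths)
  oracle <- recount_marker_stats(traces, truths)
  for (ty in ms$marker) {
    row <- ms[ms$marker == ty, ]
    expect_equal(row$activation_frequency, oracle[[ty]]$activation,
                 info = ty)
    expect_equal(row$correct_prediction_rate, oracle[[ty]]$correct,
                 info = ty)
    expect_equal(row$false_positive_rate, oracle[[ty]]$fp, info = ty)
    expect_equal(row$mean_lead_time, oracle[[ty]]$lead, info = ty)
  }
  expect_error(marker_stats(traces, truths[-1]), "aligned")
})

test_that("rates and scores are bounded for arbitrary generated traces", {
  set.seed(53)
  types <- c("Sigma1", "DriftEvent", "ConflictEscalate", "RejectH1",
             "AcceptH1")
  truth <- fixture_truth()
  for (rep in 1:15) {
    n <- sample(1:15, 1)
    tr <- make_trace(sort(runif(n, 0, 60)), sample(types, n, TRUE),
                     hypothesis = sample(c("intent_a", "intent_b", NA),
                                         n, TRUE))
    ts <- as.numeric(traceability_score(tr, truth))
    expect_gte(ts, 0); expect_lte(ts, 1)
    ms <- marker_stats(list(tr), list(truth))
    rates <- c(ms$activation_frequency, ms$correct_prediction_rate,
               ms$false_positive_rate)
    rates <- rates[!is.na(rates)]
    expect_true(all(rates >= 0 & rates <= 1))
  }
})

test_that("bootstrap intervals are deterministic, degenerate-safe, and shrink", {
  expect_error(bootstrap_ci(numeric(0)), "non-empty")
  expect_error(bootstrap_ci(1:5, level = 1.2), "level")
  ci <- bootstrap_ci(rep(3, 20), seed = 1)
  expect_equal(unname(ci), c(3, 3))
  x <- rnorm(100)
  expect_identical(bootstrap_ci(x, seed = 9), bootstrap_ci(x, seed = 9))
  set.seed(61)
  big <- rnorm(400); small <- big[1:40]
  w <- function(ci) ci[["high"]] - ci[["low"]]
  expect_lt(w(bootstrap_ci(big, seed = 2, n_resamples = 800)),
            w(bootstrap_ci(small, seed = 2, n_resamples = 800)))
})

test_that("bootstrap coverage of the mean is near nominal", {
  set.seed(71)
  n_rep <- 250
  cover <- vapply(seq_len(n_rep), function(i) {
    x <- rnorm(40)
    ci <- bootstrap_ci(x, n_resamples = 400)
    ci[["low"]] <= 0 && 0 <= ci[["high"]]
  }, logical(1))
  # percentile bootstrap at n=40 undercovers slightly; allow [0.88, 0.99]
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 0.99)
})

test_that("condition comparison gates on normality and reports effect sizes", {
  set.seed(83)
  a <- rnorm(30); b <- a + 1
  res <- compare_conditions(a, b, paired = TRUE)
  expect_identical(res$test, "paired t-test")
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$effect_size_type, "cohens_d")
  # identical paired samples: zero effect
  same <- compare_conditions(a, a, paired = TRUE)
  expect_equal(same$effect_size, 0)
  # shifted normal pairs (delta = 1, sd = 1): d within sampling error of 1
  d <- replicate(20, {
    x <- rnorm(50); y <- x + rnorm(50, 1, 1)
    compare_conditions(y, x)$effect_size
  })
  expect_lt(abs(mean(d) - 1), 0.15)
  # heavily skewed: Wilcoxon branch
  sk <- rexp(40)^3
  res2 <- compare_conditions(sk, sk + rexp(40), paired = TRUE)
  expect_match(res2$test, "wilcoxon")
  expect_identical(res2$effect_size_type, "rank_biserial")
  expect_gte(abs(res2$effect_size), 0); expect_lte(abs(res2$effect_size), 1)
  expect_error(compare_conditions(1:2, 1:2), "insufficient")
})
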