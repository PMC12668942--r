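# Window extraction and spectral features.

test_that("sliding window counts match an enumeration oracle", {
  count_oracle <- function(n, size, step) {
    k <- 0; s <- 1
    while (s + size - 1 <= n) { k <- k + 1; s <- s + step }
    k
  }
  cases <- expand.grid(n = c(511, 512, 1024, 1500, 4096),
                       size = c(512, 256), step = c(512, 256, 128, 1))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      sig <- matrix(0, 1, n)
      w <- sliding_windows(sig, size, step, sampling_rate = 256)
      expect_equal(w$n_windows, count_oracle(n, size, step),
                   info = sprintf("n=%d size=%d step=%d", n, size, step))
    })
  }
  expect_equal(sliding_windows(matrix(0, 1, 1024), 512, 512)$n_windows, 2)
  expect_equal(sliding_windows(matrix(0, 1, 511), 512, 512)$n_windows, 0)
  expect_equal(sliding_windows(matrix(0, 1, 1024), 512, 256)$n_windows, 3)
  expect_error(sliding_windows(matrix(0, 1, 100), 512, step = 0), "step")
  expect_error(sliding_windows(matrix(0, 1, 100), 1), "window_size")
})

test_that("windows start at zero, advance by step, and carry end times", {
  w <- sliding_windows(matrix(seq_len(2048), 2, byrow = TRUE), 512, 256, 256)
  expect_equal(w$starts, c(1, 257, 513))
  expect_equal(w$t_end, c(512, 768, 1024) / 256)
  expect_equal(dim(w$get(2)), c(2, 512))
  expect_equal(w$get(2)[1, 1], 257)
})

test_that("Jensen-Shannon divergence has its defining properties", {
  set.seed(7)
  for (rep in 1:25) {
    p <- runif(30); p <- p / sum(p)
    q <- runif(30); q <- q / sum(q)
    d <- js_divergence(p, q)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, js_divergence(q, p), tolerance = 1e-12)
  }
  p <- runif(20); p <- p / sum(p)
  expect_equal(js_divergence(p, p), 0)
  # maximal for disjoint supports under base-2 normalisation
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  expect_error(js_divergence(c(0.5, 0.5), c(0.7, 0.4)), "sum to 1")
  expect_error(js_divergence(c(1, 0), c(0.5, 0.5, 0)), "length")
})

test_that("spectral entropy is normalized to [0, 1]", {
  expect_equal(spectral_entropy(rep(1 / 10, 10)), 1)
  expect_equal(spectral_entropy(c(1, rep(0, 9))), 0)
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(45)
    h <- spectral_entropy(p)
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("a pure 10 Hz window maximises alpha power among canonical bands", {
  fs <- 256
  t <- (0:511) / fs
  w <- matrix(sin(2 * pi * 10 * t), 1)
  psd <- cogtrace:::.window_psd(w, fs)
  bandpow <- function(lo, hi) sum(psd$avg[psd$bins >= lo & psd$bins <= hi])
  alpha <- bandpow(8, 12)
  expect_gt(alpha, bandpow(1, 4))    # delta
  expect_gt(alpha, bandpow(4, 8))    # theta
  expect_gt(alpha, bandpow(13, 30))  # beta
  f <- extract_features(w, rep(1 / 45, 45), fs)
  expect_gt(f$alpha_power, 0.9)
})

test_that("divergence is zero against the window's own spectrum", {
  set.seed(11)
  w <- matrix(rnorm(2048), 4)
  psd <- cogtrace:::.window_psd(w, 256)
  f <- extract_features(w, psd$norm, 256)
  expect_equal(f$divergence, 0, tolerance = 1e-12)
  expect_error(extract_features(w, psd$norm * 2, 256), "normalized")
})

test_that("hypothesis evidence separates clean spatial patterns", {
  fs <- 256; t <- (0:511) / fs
  tpl <- intent_templates(4)
  # alpha only on the first template's channels, silence elsewhere
  w <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 1),
             0 * t, 0 * t)
  h <- hypothesis_evidence(w, tpl, fs)
  expect_identical(h$leading, "intent_a")
  expect_equal(h$confidence, 1)
  expect_equal(h$conflict_ratio, 0)
  # symmetric pattern: equal evidence, full conflict
  w2 <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t),
              sin(2 * pi * 10 * t), sin(2 * pi * 10 * t))
  h2 <- hypothesis_evidence(w2, tpl, fs)
  expect_equal(h2$conflict_ratio, 1, tolerance = 1e-6)
  expect_error(hypothesis_evidence(w, list()), "non-empty|>= 2")
})

test_that("template argmax matches a direct dot-product oracle", {
  fs <- 256; t <- (0:511) / fs
  tpl <- list(a = c(1, 0, 0) , b = c(0, 1, 0), c = c(0, 0, 1))
  set.seed(13)
  for (rep in 1:10) {
    amps <- runif(3, 0.2, 2)
    w <- do.call(rbind, lapply(1:3, function(ch)
      amps[ch] * sin(2 * pi * 10 * t + ch)))
    h <- hypothesis_evidence(w, tpl, fs)
    # oracle: project per-channel alpha residual onto each template directly
    psd <- cogtrace:::.window_psd(w, fs)
    resid <- cogtrace:::.alpha_residual(psd)
    oracle_scores <- vapply(tpl, function(wt) sum(wt * resid), numeric(1))
    expect_identical(h$leading, names(which.max(oracle_scores)))
    expect_equal(unname(h$scores), unname(oracle_scores), tolerance = 1e-9)
  }
})

test_that("synchrony is the mean pairwise alpha-band phase locking", {
  fs <- 256; t <- (0:511) / fs
  # identical phase: full locking
  w <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t))
  expect_equal(cogtrace:::.plv(w, fs), 1, tolerance = 1e-6)
  # constant phase offset still locks
  w2 <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 2))
  expect_equal(cogtrace:::.plv(w2, fs), 1, tolerance = 1e-6)
  # single channel: defined as 1
  f <- extract_features(matrix(rnorm(512), 1), rep(1 / 45, 45), fs)
  expect_equal(f$synchrony, 1)
})
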