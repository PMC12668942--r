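# Synthetic cognitive-episode generator.
#
# An episode is a multichannel EEG-like signal (pink background noise plus a
# dominant alpha-band oscillation whose spatial distribution expresses the
# agent's intent), a non-negative behavioural-error series, and a ground-truth
# timeline. Faults perturb the spectral content and/or the intent expression
# and, after a behavioural lag, degrade performance.

# --- spectral primitives ----------------------------------------------------

# 1/f amplitude profile over the rFFT frequencies of an n-sample series
# (flat below 1 Hz to avoid the DC blow-up). Deterministic given (n, fs).
.pink_profile <- function(n, fs) {
  freq <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  amp <- 1 / sqrt(pmax(freq, 1))
  amp[1] <- 0
  amp
}

# Pink noise with unit variance, drawn from the current RNG state.
.pink_noise <- function(n, fs) {
  m <- floor(n / 2) + 1
  amp <- .pink_profile(n, fs)
  phase <- stats::runif(m, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(m - 1L + n %% 2)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slowly varying unit-variance noise (spectral content below `cutoff` Hz);
# used for phase wander and input-locked amplitude jitter.
.slow_noise <- function(n, fs, cutoff = 1) {
  m <- floor(n / 2) + 1
  freq <- seq(0, fs / 2, length.out = m)
  amp <- as.numeric(freq > 0 & freq <= cutoff)
  phase <- stats::runif(m, 0, 2 * pi)
  if (!any(amp > 0)) return(numeric(n))
  spec <- amp * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(m - 1L + n %% 2)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Fraction of pink-noise variance per 1 Hz bin over `band` (used by the
# generative entropy model of the reversal trigger).
.pink_band_shape <- function(n, fs, band = c(1, 45)) {
  amp <- .pink_profile(n, fs)
  freq <- seq(0, fs / 2, length.out = length(amp))
  pow <- amp^2
  bins <- band[1]:band[2]
  mass <- vapply(bins, function(b)
    sum(pow[freq > b - 0.5 & freq <= b + 0.5]), numeric(1))
  list(bins = bins, mass = mass / sum(pow))
}

# Normalized spectral entropy of the generative model spectrum at broadband
# noise scale `s` (alpha mass fixed; optional extra component masses).
.model_entropy <- function(s, alpha_mass, noise_mass_shape, extra = NULL) {
  m <- noise_mass_shape$mass * s^2
  p <- m
  ia <- match(9:11, noise_mass_shape$bins)
  p[ia] <- p[ia] + alpha_mass * c(0.15, 0.7, 0.15)
  if (!is.null(extra)) {
    ie <- match(extra$bin, noise_mass_shape$bins)
    p[ie] <- p[ie] + extra$mass
  }
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(noise_mass_shape$mass))
}

# --- intent templates -------------------------------------------------------

#' Intent templates
#'
#' Spatial templates of the two intent classes: each template is a
#' non-negative per-channel weighting of alpha-band power (class A loads the
#' first half of the channels, class B the second half). Used both by the
#' generator (to express the agent's intent) and by the matched-filter
#' hypothesis bank of the discriminator.
#'
#' @param n_channels number of channels (>= 2 for a two-class bank).
#' @return Named list of per-channel weight vectors summing to one.
#' @examples
#' intent_templates(4)
#' @export
intent_templates <- function(n_channels) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 2L)
    stop_contract("intent templates require >= 2 channels")
  g1 <- seq_len(ceiling(n_channels / 2))
  w1 <- numeric(n_channels); w1[g1] <- 1 / length(g1)
  w2 <- numeric(n_channels); w2[-g1] <- 1 / (n_channels - length(g1))
  list(intent_a = w1, intent_b = w2)
}

# per-channel alpha power share given mixing m of the non-expressed template
.alpha_share <- function(expressed, m, n_channels) {
  if (n_channels < 2L) return(1)  # no spatial intent expression possible
  tpl <- intent_templates(n_channels)
  we <- tpl[[expressed]]
  wo <- tpl[[setdiff(names(tpl), expressed)]]
  (1 - m) * we * sum(we > 0) + m * wo * sum(wo > 0)
}

# --- baseline ---------------------------------------------------------------

#' Generate a fault-free baseline episode
#'
#' Produces a stationary episode: per channel, pink (1/f) background noise
#' plus a dominant alpha-band (8-12 Hz) oscillation whose spatial pattern
#' expresses the agent's intent class. Behaviour stays below the error
#' threshold throughout and the ground-truth timeline is a single `stable`
#' interval.
#'
#' @param config an [episode_config()] whose fault kind is `"none"`.
#' @return A `cog_episode`: list with `signal` (channels x samples matrix),
#'   `behavior` (length-`n_samples` non-negative vector), `truth` (ground
#'   truth), and `config`.
#' @examples
#' ep <- generate_baseline(episode_config(seed = 1, duration = 8))
#' dim(ep$signal)
#' @export
generate_baseline <- function(config) {
  if (!inherits(config, "cog_episode_config"))
    stop_config("config must be an episode_config()")
  if (config$fault$kind != "none")
    stop_contract("generate_baseline requires fault kind \"none\"")
  cal <- config$calibration
  fs <- config$sampling_rate
  n <- round_samples(config$duration, fs)
  if (n < 2L) stop_config("episode too short: fewer than 2 samples")
  nc <- config$n_channels
  t <- (seq_len(n) - 1) / fs

  intent <- with_seed(derive_seed(config$seed, "intent"), {
    true_intent <- if (stats::runif(1) < 0.5) "intent_a" else "intent_b"
    confused <- stats::runif(1) < cal$confusion_rate
    expressed <- if (confused) setdiff(c("intent_a", "intent_b"), true_intent)
                 else true_intent
    m0 <- cal$intent_mix_cap *
      stats::rbeta(1, cal$intent_mix_shape1, cal$intent_mix_shape2)
    jit <- exp(stats::rnorm(nc, 0, cal$amp_jitter_sd))
    phi0 <- stats::runif(nc, 0, 2 * pi)
    list(true_intent = true_intent, expressed = expressed, m0 = m0,
         jit = jit, phi0 = phi0)
  })

  noise <- with_seed(derive_seed(config$seed, "noise"), {
    pink <- vapply(seq_len(nc), function(ch) .pink_noise(n, fs),
                   numeric(n))
    pj <- vapply(seq_len(nc), function(ch)
      cal$phase_jitter_sd * .slow_noise(n, fs, cutoff = 0.5), numeric(n))
    bnoise <- abs(stats::rnorm(n, 0, cal$behavior_base_sd))
    list(pink = pink, phase_jitter = pj, behavior = bnoise)
  })

  share <- .alpha_share(intent$expressed, intent$m0, nc)
  sig <- matrix(0, nrow = nc, ncol = n)
  for (ch in seq_len(nc)) {
    a <- cal$alpha_amp * sqrt(share[ch]) * intent$jit[ch]
    sig[ch, ] <- a * sin(2 * pi * cal$alpha_freq * t + intent$phi0[ch] +
                           noise$phase_jitter[, ch]) +
      config$noise_sd * noise$pink[, ch]
  }

  truth <- list(
    fault_kind = "none", fault_onset = NULL, error_onset = NULL,
    state_timeline = data.frame(t_start = 0, t_end = config$duration,
                                state = "stable",
                                stringsAsFactors = FALSE),
    true_intent = intent$true_intent)

  structure(list(signal = sig, behavior = noise$behavior, truth = truth,
                 config = config,
                 internals = list(intent = intent, noise = noise, t = t),
                 warnings = character()),
            class = "cog_episode")
}

# --- fault injection --------------------------------------------------------

# behaviour series with degradation starting at error time `e`
.degraded_behavior <- function(base_behavior, t, e, cal) {
  rise <- stats::plogis((t - e) / cal$behavior_rise)
  recover <- ifelse(t > e + cal$behavior_hold,
                    exp(-(t - e - cal$behavior_hold) / 3), 1)
  base_behavior + cal$behavior_level * rise * recover
}

.draw_lag <- function(config, seed_label = "lag") {
  with_seed(derive_seed(config$seed, seed_label),
            max(0.3, stats::rnorm(1, config$behavior_lag_mean,
                                  config$behavior_lag_sd)))
}

#' Inject a fault into a baseline episode
#'
#' Returns a new episode in which the configured fault regime perturbs the
#' signal, the ground-truth timeline records the fault phases, and behaviour
#' degrades after a lag drawn from
#' `Normal(behavior_lag_mean, behavior_lag_sd)`.
#'
#' @param base a fault-free `cog_episode` from [generate_baseline()].
#' @param fault a [fault_spec()] with `kind != "none"`; defaults to the
#'   fault in the base episode's configuration when that is set.
#' @param seed optional integer overriding the fault RNG sub-stream derived
#'   from the episode seed.
#' @return A new `cog_episode` with fault, behaviour and ground truth.
#' @examples
#' cfg <- episode_config(seed = 3)
#' ep <- inject_fault(generate_baseline(cfg), fault_spec("gradual_drift"))
#' ep$truth$fault_kind
#' @export
inject_fault <- function(base, fault, seed = NULL) {
  if (!inherits(base, "cog_episode"))
    stop_contract("base must be a cog_episode")
  if (base$truth$fault_kind != "none")
    stop_contract("base episode already carries a fault")
  if (!inherits(fault, "cog_fault_spec") || fault$kind == "none")
    stop_contract("fault must be a fault_spec() with kind != \"none\"")
  if (is.null(base$internals))
    stop_contract("base episode lacks generator internals; regenerate it")
  config <- base$config
  cal <- config$calibration
  fs <- config$sampling_rate
  dur <- config$duration
  t <- base$internals$t
  n <- length(t)
  seed0 <- if (is.null(seed)) config$seed else as.integer(seed)
  warnings <- base$warnings

  onset <- with_seed(derive_seed(seed0, "fault.onset"),
                     stats::rnorm(1, fault$onset_mu, fault$onset_sigma))
  if (onset < 0 || onset > dur) {
    warnings <- c(warnings,
                  sprintf("fault onset %.2f s clamped to [0, %g]", onset, dur))
    onset <- min(max(onset, 0), dur)
  }
  expr <- with_seed(derive_seed(seed0, "fault.expr"), list(
    gain = exp(stats::rnorm(1, 0, cal$drift_expr_sd)),
    theta = exp(stats::rnorm(1, 0, cal$theta_expr_sd)),
    mix = cal$overload_mix_gain * exp(stats::rnorm(1, 0, cal$overload_mix_sd)),
    ngain = cal$overload_noise_gain *
      exp(stats::rnorm(1, 0, cal$overload_noise_sd)),
    nmult = cal$reversal_noise_mult *
      exp(stats::rnorm(1, 0, cal$reversal_mult_sd)),
    rmix = cal$reversal_mix_peak *
      exp(stats::rnorm(1, 0, cal$reversal_mix_sd)),
    phase = stats::runif(2, 0, 2 * pi),
    delay = stats::runif(1, fault$decision_delay[1], fault$decision_delay[2]),
    amp_jit = .slow_noise(n, fs, cutoff = 2)))

  ep <- switch(fault$kind,
    gradual_drift = .inject_drift(base, fault, onset, expr, cal, t),
    decision_reversal = .inject_reversal(base, fault, onset, expr, cal, t),
    schema_collapse = .inject_collapse(base, fault, onset, expr, cal, t))
  ep$warnings <- c(warnings, ep$warnings)
  ep$config$fault <- fault
  ep
}

# rebuild the alpha component for a time-varying mixing / expression schedule
.alpha_signal <- function(base, m_t, expressed_t) {
  cal <- base$config$calibration
  nc <- base$config$n_channels
  t <- base$internals$t
  intent <- base$internals$intent
  if (nc < 2L) {
    a <- cal$alpha_amp * intent$jit[1]
    return(matrix(a * sin(2 * pi * cal$alpha_freq * t + intent$phi0[1] +
                            base$internals$noise$phase_jitter[, 1]),
                  nrow = 1))
  }
  tpl <- intent_templates(nc)
  we <- tpl[[intent$expressed]]
  wo <- tpl[[setdiff(names(tpl), intent$expressed)]]
  ne <- sum(we > 0); no <- sum(wo > 0)
  sig <- matrix(0, nrow = nc, ncol = length(t))
  # expressed_t: 0 = original expressed pattern, 1 = flipped pattern;
  # fractional values crossfade the two patterns in power
  for (ch in seq_len(nc)) {
    share <- (1 - m_t) * ((1 - expressed_t) * we[ch] * ne +
                            expressed_t * wo[ch] * no) +
      m_t * ((1 - expressed_t) * wo[ch] * no + expressed_t * we[ch] * ne)
    a <- cal$alpha_amp * sqrt(pmax(share, 0)) * intent$jit[ch]
    sig[ch, ] <- a * sin(2 * pi * cal$alpha_freq * t + intent$phi0[ch] +
                           base$internals$noise$phase_jitter[, ch])
  }
  sig
}

.assemble_episode <- function(base, alpha_sig, noise_scale, extra_sig,
                              behavior, truth) {
  config <- base$config
  nc <- config$n_channels
  sig <- alpha_sig
  for (ch in seq_len(nc))
    sig[ch, ] <- sig[ch, ] + config$noise_sd * noise_scale *
      base$internals$noise$pink[, ch] + extra_sig
  structure(list(signal = sig, behavior = behavior, truth = truth,
                 config = config, internals = base$internals,
                 warnings = character()),
            class = "cog_episode")
}

.state_timeline <- function(dur, ...) {
  iv <- list(...)  # named list state -> c(start, end); in order
  rows <- list()
  cursor <- 0
  for (nm in names(iv)) {
    s <- max(cursor, iv[[nm]][1]); e <- min(dur, iv[[nm]][2])
    if (e <= s) next
    if (s > cursor)
      rows[[length(rows) + 1L]] <- data.frame(t_start = cursor, t_end = s,
                                              state = "stable")
    rows[[length(rows) + 1L]] <- data.frame(t_start = s, t_end = e,
                                            state = nm)
    cursor <- e
  }
  if (cursor < dur)
    rows[[length(rows) + 1L]] <- data.frame(t_start = cursor, t_end = dur,
                                            state = "stable")
  tl <- do.call(rbind, rows)
  tl$state <- sub("[0-9]+$", "", tl$state)  # allow drift2 etc. if ever needed
  rownames(tl) <- NULL
  tl
}

.inject_drift <- function(base, fault, onset, expr, cal, t) {
  config <- base$config
  dur <- config$duration
  # zero-amplitude faults are no-ops on signal and behaviour
  if (fault$drift_amplitude == 0) {
    ep <- base
    ep$truth$fault_kind <- "gradual_drift"
    ep$truth$fault_onset <- onset
    return(ep)
  }
  peak <- onset + cal$drift_peak_delay
  env <- fault$drift_amplitude * cal$drift_gain * expr$gain *
    exp(-(t - peak)^2 / (2 * cal$drift_width^2))
  env[t < onset | t > fault$drift_end] <- 0
  extra <- env * sin(2 * pi * cal$drift_freq * t + expr$phase[1])

  lag <- .draw_lag(config)
  e <- onset + lag
  behavior <- .degraded_behavior(base$internals$noise$behavior, t, e, cal)
  # ground-truth drift phase: onset to where the excursion has subsided
  drift_end_state <- min(onset + cal$drift_peak_delay +
                           cal$drift_state_margin * cal$drift_width,
                         fault$drift_end, dur)
  truth <- list(
    fault_kind = "gradual_drift", fault_onset = onset,
    error_onset = error_onset(behavior, cal$error_threshold,
                              config$sampling_rate, cal$error_debounce),
    state_timeline = .state_timeline(dur, drift = c(onset, drift_end_state)),
    true_intent = base$truth$true_intent)

  m0 <- base$internals$intent$m0
  alpha_sig <- .alpha_signal(base, rep(m0, length(t)), rep(0, length(t)))
  .assemble_episode(base, alpha_sig, 1, extra, behavior, truth)
}

.inject_reversal <- function(base, fault, onset, expr, cal, t) {
  config <- base$config
  dur <- config$duration
  fs <- config$sampling_rate
  n <- length(t)
  shape <- .pink_band_shape(n, fs)
  alpha_mass <- cal$alpha_amp^2 / 4
  noise_mass <- shape
  noise_mass$mass <- noise_mass$mass * config$noise_sd^2
  s_max <- expr$nmult

  # smallest broadband scale whose model entropy reaches the cutoff
  h_at <- function(s) .model_entropy(s, alpha_mass, noise_mass)
  s_star <- if (h_at(s_max) < fault$entropy_cutoff) NA_real_ else {
    if (h_at(1) >= fault$entropy_cutoff) 1 else
      stats::uniroot(function(s) h_at(s) - fault$entropy_cutoff,
                     c(1, s_max), tol = 1e-4)$root
  }

  ramp <- cal$reversal_ramp_len
  if (is.na(s_star)) {
    # destabilisation never crosses the cutoff: no reversal is enacted
    scale_t <- 1 + (s_max - 1) *
      pmax(0, pmin(1, (t - onset) / ramp)) *
      pmax(0, pmin(1, (onset + ramp + 3 + cal$reversal_settle - t) /
                     cal$reversal_settle))
    alpha_sig <- .alpha_signal(base, rep(base$internals$intent$m0, n),
                               rep(0, n))
    truth <- list(fault_kind = "decision_reversal", fault_onset = NULL,
                  error_onset = NULL,
                  state_timeline = .state_timeline(dur),
                  true_intent = base$truth$true_intent)
    ep <- .assemble_episode(base, alpha_sig, scale_t, 0,
                            base$internals$noise$behavior, truth)
    ep$warnings <- "entropy cutoff never crossed; reversal not enacted"
    return(ep)
  }

  t_cross <- onset + ramp * (s_star - 1) / (s_max - 1)
  t_flip <- t_cross + expr$delay
  settle <- cal$reversal_settle
  up <- pmax(0, pmin(1, (t - onset) / ramp))
  down <- pmax(0, pmin(1, (t - t_flip) / settle))
  scale_t <- 1 + (s_max - 1) * pmin(up, 1 - down)

  fade <- 0.15  # s, crossfade of the intent flip
  expressed_t <- pmax(0, pmin(1, (t - t_flip) / fade))
  # residual competition from the superseded schema, decaying after the flip
  m_t <- pmin(0.49, base$internals$intent$m0 +
                expr$rmix * exp(-pmax(0, t - t_flip) / cal$reversal_mix_tau) *
                (t >= t_flip))
  alpha_sig <- .alpha_signal(base, m_t, expressed_t)

  lag <- .draw_lag(config)
  e <- t_flip + lag
  behavior <- .degraded_behavior(base$internals$noise$behavior, t, e, cal)
  truth <- list(
    fault_kind = "decision_reversal", fault_onset = t_flip,
    error_onset = error_onset(behavior, cal$error_threshold, fs,
                              cal$error_debounce),
    state_timeline = .state_timeline(dur,
                                     conflict = c(t_cross, t_flip),
                                     reversal = c(t_flip, t_flip + settle)),
    true_intent = base$truth$true_intent,
    entropy_cross = t_cross, decision_delay = expr$delay)
  .assemble_episode(base, alpha_sig, scale_t, 0, behavior, truth)
}

.inject_collapse <- function(base, fault, onset, expr, cal, t) {
  config <- base$config
  dur <- config$duration
  fs <- config$sampling_rate
  n <- length(t)
  tau <- fault$precision_decay_tau
  stream_len <- fault$drift_end - fault$drift_start
  stream_end <- min(onset + stream_len, dur)
  in_stream <- t >= onset & t <= stream_end
  precision <- ifelse(t >= onset, exp(-(t - onset) / tau), 1)
  ambiguity <- 1 - precision
  t_amb <- onset + tau * log(1 / (1 - fault$ambiguity_threshold))

  theta_amp <- ifelse(in_stream,
                      cal$theta_gain * expr$theta * precision, 0)
  extra <- theta_amp * sin(2 * pi * fault$input_rate * t + expr$phase[2]) *
    (1 + 0.5 * ambiguity * expr$amp_jit)

  settle_down <- pmax(0, pmin(1, (t - stream_end) / cal$reversal_settle))
  amb_eff <- ambiguity * ifelse(t <= stream_end, 1, 1 - settle_down) *
    (t >= onset)
  scale_t <- 1 + expr$ngain * amb_eff
  m_t <- pmin(0.49, base$internals$intent$m0 + expr$mix * amb_eff)
  alpha_sig <- .alpha_signal(base, m_t, rep(0, n))

  lag <- .draw_lag(config)
  e <- onset + lag
  behavior <- .degraded_behavior(base$internals$noise$behavior, t, e, cal)
  truth <- list(
    fault_kind = "schema_collapse", fault_onset = onset,
    error_onset = error_onset(behavior, cal$error_threshold, fs,
                              cal$error_debounce),
    state_timeline = .state_timeline(dur,
                                     drift = c(onset, min(t_amb, stream_end)),
                                     overload = c(min(t_amb, stream_end),
                                                  stream_end)),
    true_intent = base$truth$true_intent,
    ambiguity_cross = t_amb)
  .assemble_episode(base, alpha_sig, scale_t, extra, behavior, truth)
}

#' Simulate a complete episode
#'
#' Single entry point composing [generate_baseline()] and, when the
#' configuration carries a fault, [inject_fault()]. A pure function of the
#' configuration (including its seed): identical configs give bit-identical
#' episodes.
#'
#' @param config an [episode_config()].
#' @param keep_internals keep generator internals on the returned episode
#'   (needed only if you want to re-inject a different fault).
#' @return A `cog_episode`.
#' @examples
#' ep <- simulate_episode(task_scenario("motor_control", seed = 11))
#' ep$truth$fault_kind
#' @export
simulate_episode <- function(config, keep_internals = FALSE) {
  fault <- config$fault
  base_config <- config
  base_config$fault <- fault_spec("none")
  ep <- generate_baseline(base_config)
  if (fault$kind != "none") ep <- inject_fault(ep, fault)
  ep$config <- config
  if (!keep_internals) ep$internals <- NULL
  ep
}

#' Behavioural error onset
#'
#' Time of the first sample at which the behavioural-error series exceeds
#' `threshold` and remains above it for at least `debounce` seconds.
#'
#' @param behavior non-negative behavioural-error series.
#' @param threshold positive error threshold.
#' @param sampling_rate Hz.
#' @param debounce seconds of sustained excess required (default 0.25).
#' @return Onset time in seconds, or `NULL` if never reached.
#' @examples
#' b <- c(rep(0, 1280), rep(2, 1280))
#' error_onset(b, 1, 256)
#' @export
error_onset <- function(behavior, threshold, sampling_rate, debounce = 0.25) {
  if (!length(behavior)) stop_contract("behavior must be non-empty")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_contract("threshold must be a positive scalar")
  k <- max(1L, as.integer(ceiling(debounce * sampling_rate)))
  above <- behavior > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= k)
  if (!length(ok)) return(NULL)
  (starts[ok[1]] - 1L) / sampling_rate
}

#' @export
print.cog_episode <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cog_episode> %s, %g s @ %g Hz, %d channel(s)\n",
              cfg$task_type, cfg$duration, cfg$sampling_rate, cfg$n_channels))
  cat(sprintf("  fault: %s", x$truth$fault_kind))
  if (!is.null(x$truth$fault_onset))
    cat(sprintf(" (onset %.2f s)", x$truth$fault_onset))
  if (!is.null(x$truth$error_onset))
    cat(sprintf(", error onset %.2f s", x$truth$error_onset))
  cat("\n  states:", paste(x$truth$state_timeline$state, collapse = " > "),
      "\n")
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}

#' @export
plot.cog_episode <- function(x, channel = 1, ...) {
  t <- (seq_len(ncol(x$signal)) - 1) / x$config$sampling_rate
  graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1.5, 1))
  graphics::plot(t, x$signal[channel, ], type = "l",
                 xlab = "time (s)", ylab = sprintf("channel %d", channel),
                 main = sprintf("%s (%s)", x$config$task_type,
                                x$truth$fault_kind), ...)
  if (!is.null(x$truth$fault_onset))
    graphics::abline(v = x$truth$fault_onset, col = "red3", lty = 2)
  graphics::plot(t, x$behavior, type = "l", xlab = "time (s)",
                 ylab = "behavioural error")
  graphics::abline(h = x$config$calibration$error_threshold,
                   col = "grey50", lty = 3)
  if (!is.null(x$truth$error_onset))
    graphics::abline(v = x$truth$error_onset, col = "red3", lty = 2)
  invisible(x)
}
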