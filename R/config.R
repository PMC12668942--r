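#' Fault specification
#'
#' Describes the destabilising dynamic injected into a synthetic episode.
#' Three fault regimes are supported, mirroring the three task paradigms:
#'
#' * `gradual_drift` — a transient Gaussian-profile low-frequency excursion of
#'   abstract amplitude `drift_amplitude`, beginning at an onset drawn from
#'   `Normal(onset_mu, onset_sigma)` (truncated to the episode).
#' * `decision_reversal` — broadband destabilisation until the model spectral
#'   entropy exceeds `entropy_cutoff`, then an abrupt intent flip enacted after
#'   a delay drawn uniformly from `decision_delay`.
#' * `schema_collapse` — a `input_rate` Hz input-locked component whose
#'   precision (inverse variance) decays with time constant
#'   `precision_decay_tau`; the `overload` state is entered when the ambiguity
#'   index `1 - precision(t)/precision(0)` exceeds `ambiguity_threshold`.
#'
#' Only the fields relevant to `kind` are consulted; the others are ignored.
#'
#' @param kind one of `"gradual_drift"`, `"decision_reversal"`,
#'   `"schema_collapse"`, `"none"`.
#' @param drift_amplitude dimensionless drift amplitude (default 0.12).
#' @param onset_mu,onset_sigma seconds; Gaussian fault-onset model
#'   (defaults 5.5 and 1.0).
#' @param entropy_cutoff normalized spectral entropy triggering the intent
#'   flip (default 0.6).
#' @param decision_delay length-2 range, seconds, of the uniform
#'   entropy-crossing-to-enactment delay (default `c(0.3, 0.5)`).
#' @param input_rate Hz, rate of the input-locked stream (default 5).
#' @param precision_decay_tau seconds, precision decay constant (default 2.2).
#' @param ambiguity_threshold ambiguity index entering the overload state
#'   (default 0.7).
#' @param drift_start,drift_end seconds; generic perturbation window bounding
#'   the drift support (defaults 20 and 40).
#' @return An object of class `cog_fault_spec`.
#' @examples
#' fault_spec("gradual_drift")
#' @export
fault_spec <- function(kind = c("none", "gradual_drift", "decision_reversal",
                                "schema_collapse"),
                       drift_amplitude = 0.12,
                       onset_mu = 5.5, onset_sigma = 1.0,
                       entropy_cutoff = 0.6,
                       decision_delay = c(0.3, 0.5),
                       input_rate = 5,
                       precision_decay_tau = 2.2,
                       ambiguity_threshold = 0.7,
                       drift_start = 20, drift_end = 40) {
  kind <- match.arg(kind)
  check_scalar_num(drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar_num(onset_mu, "onset_mu")
  check_scalar_num(onset_sigma, "onset_sigma", lower = 0)
  check_scalar_num(entropy_cutoff, "entropy_cutoff", lower = 0, upper = 1)
  if (!is.numeric(decision_delay) || length(decision_delay) != 2L ||
      any(!is.finite(decision_delay)) || decision_delay[1] > decision_delay[2] ||
      decision_delay[1] < 0)
    stop_config("decision_delay must be an increasing non-negative range")
  check_scalar_num(input_rate, "input_rate", lower = 0, strict_lower = TRUE)
  check_scalar_num(precision_decay_tau, "precision_decay_tau",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(ambiguity_threshold, "ambiguity_threshold",
                   lower = 0, upper = 1)
  check_scalar_num(drift_start, "drift_start", lower = 0)
  check_scalar_num(drift_end, "drift_end")
  if (drift_start >= drift_end)
    stop_config("drift_start must be < drift_end")
  structure(list(kind = kind, drift_amplitude = drift_amplitude,
                 onset_mu = onset_mu, onset_sigma = onset_sigma,
                 entropy_cutoff = entropy_cutoff,
                 decision_delay = decision_delay,
                 input_rate = input_rate,
                 precision_decay_tau = precision_decay_tau,
                 ambiguity_threshold = ambiguity_threshold,
                 drift_start = drift_start, drift_end = drift_end),
            class = "cog_fault_spec")
}

#' Episode configuration
#'
#' A full scenario description for one synthetic episode. The seed fully
#' determines the episode: identical configurations produce bit-identical
#' episodes.
#'
#' @param task_type cognitive paradigm: `"motor_control"` (gradual intent
#'   drift), `"inhibition"` (late decision reversal) or `"overload"`
#'   (rapid-serial-presentation schema collapse).
#' @param duration episode length in seconds (default 60).
#' @param sampling_rate samples per second (default 256).
#' @param n_channels number of signal channels (default 4).
#' @param fault a [fault_spec()]; `NULL` selects the task-appropriate fault
#'   with its defaults for non-"none" behaviour via [task_scenario()].
#' @param noise_sd broadband (pink) noise amplitude, arbitrary units
#'   (default 0.45, calibrated; see [generator_calibration()]).
#' @param behavior_lag_mean,behavior_lag_sd seconds; Gaussian lag between
#'   fault onset and behavioural error onset (frozen calibrated defaults,
#'   task-dependent when built through [task_scenario()]).
#' @param seed integer RNG seed.
#' @param calibration generator calibration constants,
#'   see [generator_calibration()].
#' @return An object of class `cog_episode_config`.
#' @examples
#' cfg <- episode_config("motor_control", fault = fault_spec("gradual_drift"),
#'                       seed = 1)
#' @export
episode_config <- function(task_type = c("motor_control", "inhibition",
                                         "overload"),
                           duration = 60, sampling_rate = 256, n_channels = 4,
                           fault = fault_spec("none"),
                           noise_sd = 0.45,
                           behavior_lag_mean = 4.13, behavior_lag_sd = 0.28,
                           seed = 1L,
                           calibration = generator_calibration()) {
  task_type <- match.arg(task_type)
  check_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar_num(sampling_rate, "sampling_rate", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(n_channels, "n_channels", lower = 1)
  if (!inherits(fault, "cog_fault_spec"))
    stop_config("fault must be a fault_spec()")
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  check_scalar_num(behavior_lag_mean, "behavior_lag_mean", lower = 0)
  check_scalar_num(behavior_lag_sd, "behavior_lag_sd", lower = 0)
  check_scalar_num(seed, "seed")
  if (fault$kind != "none" && fault$drift_end > duration)
    fault$drift_end <- duration
  structure(list(task_type = task_type, duration = duration,
                 sampling_rate = sampling_rate,
                 n_channels = as.integer(n_channels),
                 fault = fault, noise_sd = noise_sd,
                 behavior_lag_mean = behavior_lag_mean,
                 behavior_lag_sd = behavior_lag_sd,
                 seed = as.integer(seed), calibration = calibration),
            class = "cog_episode_config")
}

#' Task scenario presets
#'
#' Builds the episode configuration for one of the three task paradigms with
#' its calibrated fault parameters and behavioural lag: motor control pairs
#' with gradual intent drift, inhibition with late decision reversal, and
#' overload with schema collapse.
#'
#' @param task_type task paradigm.
#' @param seed integer RNG seed.
#' @param faulted logical; `FALSE` produces a fault-free control episode.
#' @param ... passed on to [episode_config()].
#' @return A `cog_episode_config`.
#' @examples
#' cfg <- task_scenario("inhibition", seed = 7)
#' cfg$fault$kind
#' @export
task_scenario <- function(task_type = c("motor_control", "inhibition",
                                        "overload"),
                          seed = 1L, faulted = TRUE, ...) {
  task_type <- match.arg(task_type)
  kind <- switch(task_type, motor_control = "gradual_drift",
                 inhibition = "decision_reversal",
                 overload = "schema_collapse")
  lag <- .task_lags(task_type)
  args <- list(...)
  if (is.null(args$fault))
    args$fault <- fault_spec(if (faulted) kind else "none")
  if (is.null(args$behavior_lag_mean)) args$behavior_lag_mean <- lag[["mean"]]
  if (is.null(args$behavior_lag_sd)) args$behavior_lag_sd <- lag[["sd"]]
  do.call(episode_config,
          c(list(task_type = task_type, seed = seed), args))
}

#' Discriminator parameters
#'
#' Sliding-window detection parameters. Windows of `window_size` samples are
#' advanced by `step` samples; the spectral baseline reference is the mean
#' normalized power spectrum of the first `baseline_windows` windows. Per
#' window, in a single precedence chain: the initial hypothesis is committed
#' (Sigma1) at the first window whose matched-filter confidence reaches
#' `commit_confidence`; after commitment the hypothesis is rejected (RejectH1)
#' on an entropy spike above `reject_entropy_spike` or a change of leading
#' hypothesis, or confirmed (AcceptH1) after `accept_windows` consecutive
#' stable windows; otherwise divergence above `threshold_drift` emits
#' DriftEvent, else conflict ratio above `threshold_conflict` emits
#' ConflictEscalate, else NoEvent.
#'
#' @param window_size samples per analysis window (default 512).
#' @param step hop between windows in samples (default `window_size / 2`,
#'   the standard half-overlap choice).
#' @param threshold_drift divergence trigger for DriftEvent (default 0.35).
#' @param threshold_conflict conflict-ratio trigger for ConflictEscalate
#'   (default 0.5).
#' @param commit_confidence hypothesis confidence required to commit
#'   (default 0.75).
#' @param reject_entropy_spike normalized spectral entropy triggering
#'   rejection (default 0.6).
#' @param alpha_band Hz interval of the dominant band (default `c(8, 12)`).
#' @param baseline_windows windows used for the spectral baseline (default 3).
#' @param accept_windows consecutive stable windows before AcceptH1
#'   (default 4).
#' @param disable character vector of disabled branches, subset of
#'   `c("drift", "conflict")`, for ablation runs.
#' @return An object of class `cog_discriminator_params`.
#' @examples
#' discriminator_params()
#' @export
discriminator_params <- function(window_size = 512, step = window_size / 2,
                                 threshold_drift = 0.35,
                                 threshold_conflict = 0.5,
                                 commit_confidence = 0.75,
                                 reject_entropy_spike = 0.6,
                                 alpha_band = c(8, 12),
                                 baseline_windows = 3,
                                 accept_windows = 4,
                                 disable = character()) {
  check_scalar_num(window_size, "window_size", lower = 2)
  check_scalar_num(step, "step", lower = 1, upper = window_size)
  check_scalar_num(threshold_drift, "threshold_drift", lower = 0, upper = 1)
  check_scalar_num(threshold_conflict, "threshold_conflict",
                   lower = 0, upper = 1)
  check_scalar_num(commit_confidence, "commit_confidence",
                   lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_num(reject_entropy_spike, "reject_entropy_spike",
                   lower = 0, upper = 1)
  if (!is.numeric(alpha_band) || length(alpha_band) != 2L ||
      alpha_band[1] >= alpha_band[2] || alpha_band[1] <= 0)
    stop_config("alpha_band must be an increasing positive Hz interval")
  check_scalar_num(baseline_windows, "baseline_windows", lower = 1)
  check_scalar_num(accept_windows, "accept_windows", lower = 1)
  if (length(disable) && !all(disable %in% c("drift", "conflict")))
    stop_config("disable must be a subset of c(\"drift\", \"conflict\")")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 threshold_drift = threshold_drift,
                 threshold_conflict = threshold_conflict,
                 commit_confidence = commit_confidence,
                 reject_entropy_spike = reject_entropy_spike,
                 alpha_band = alpha_band,
                 baseline_windows = as.integer(baseline_windows),
                 accept_windows = as.integer(accept_windows),
                 disable = as.character(disable)),
            class = "cog_discriminator_params")
}

#' Study configuration
#'
#' Configuration for a batch simulation study across the task paradigms.
#'
#' @param n_episodes_per_task episodes simulated per task (default 300).
#' @param tasks subset of the three task paradigms.
#' @param fault_rate fraction of episodes receiving a fault (default 0.8; the
#'   remainder are fault-free controls).
#' @param discriminator a [discriminator_params()].
#' @param ablation disabled components, subset of
#'   `c("discriminator_drift", "discriminator_conflict", "emitter")`.
#' @param tolerance seconds; temporal tolerance used when scoring traces
#'   (default 1.0).
#' @param root_seed integer; fully determines the study.
#' @return An object of class `cog_study_config`.
#' @examples
#' study_config(n_episodes_per_task = 5, root_seed = 42)
#' @export
study_config <- function(n_episodes_per_task = 300,
                         tasks = c("motor_control", "inhibition", "overload"),
                         fault_rate = 0.8,
                         discriminator = discriminator_params(),
                         ablation = character(),
                         tolerance = 1.0,
                         root_seed = 1L) {
  check_scalar_num(n_episodes_per_task, "n_episodes_per_task", lower = 1)
  tasks <- unique(match.arg(tasks, several.ok = TRUE))
  if (!length(tasks)) stop_config("tasks must be non-empty")
  check_scalar_num(fault_rate, "fault_rate", lower = 0, upper = 1)
  if (!inherits(discriminator, "cog_discriminator_params"))
    stop_config("discriminator must be a discriminator_params()")
  allowed <- c("discriminator_drift", "discriminator_conflict", "emitter")
  if (length(ablation) && !all(ablation %in% allowed))
    stop_config("ablation must be a subset of ",
                paste(allowed, collapse = ", "))
  check_scalar_num(tolerance, "tolerance", lower = 0)
  check_scalar_num(root_seed, "root_seed")
  structure(list(n_episodes_per_task = as.integer(n_episodes_per_task),
                 tasks = tasks, fault_rate = fault_rate,
                 discriminator = discriminator,
                 ablation = as.character(ablation),
                 tolerance = tolerance,
                 root_seed = as.integer(root_seed)),
            class = "cog_study_config")
}

#' @export
print.cog_fault_spec <- function(x, ...) {
  cat("<fault_spec>", x$kind, "\n")
  if (x$kind == "gradual_drift")
    cat(sprintf("  amplitude %.3g, onset ~ N(%.3g, %.3g) s\n",
                x$drift_amplitude, x$onset_mu, x$onset_sigma))
  if (x$kind == "decision_reversal")
    cat(sprintf("  entropy cutoff %.2f, decision delay %.0f-%.0f ms\n",
                x$entropy_cutoff, 1000 * x$decision_delay[1],
                1000 * x$decision_delay[2]))
  if (x$kind == "schema_collapse")
    cat(sprintf("  input rate %g Hz, precision decay tau %.2g s, ambiguity > %.2g\n",
                x$input_rate, x$precision_decay_tau, x$ambiguity_threshold))
  invisible(x)
}

#' @export
print.cog_episode_config <- function(x, ...) {
  cat(sprintf("<episode_config> %s: %gs @ %g Hz, %d channel(s), fault=%s, seed=%d\n",
              x$task_type, x$duration, x$sampling_rate, x$n_channels,
              x$fault$kind, x$seed))
  invisible(x)
}

#' @export
print.cog_study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d episode(s)/task x {%s}, fault rate %.2f, seed %d\n",
              x$n_episodes_per_task, paste(x$tasks, collapse = ", "),
              x$fault_rate, x$root_seed))
  if (length(x$ablation))
    cat("  ablation:", paste(x$ablation, collapse = ", "), "\n")
  invisible(x)
}
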