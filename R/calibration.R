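#' Frozen generator calibration
#'
#' The synthetic-episode generator has a small set of free parameters that the
#' published fault parameters do not pin down: the spectral gain with which an
#' abstract fault amplitude is expressed in the signal, inter-episode
#' expressivity jitter, the agent's intent-expression fidelity, and the
#' behavioural lag between a fault and its overt performance consequence.
#' These were calibrated once against the reference per-marker statistics
#' (activation frequencies, prediction rates, lead times) with
#' [calibrate_study()] and then frozen; all defaults below are the frozen
#' values. See the methods vignette for the calibration protocol.
#'
#' @param ... named overrides for individual calibration constants.
#' @return A named list of generator calibration constants.
#' @examples
#' cal <- generator_calibration()
#' cal$alpha_freq
#' @export
generator_calibration <- function(...) {
  cal <- list(
    ## baseline signal model
    alpha_freq       = 10,     # Hz, dominant resting oscillation
    alpha_amp        = 1.4,    # a.u., amplitude on intent-preferred channels
    amp_jitter_sd    = 0.10,   # lognormal sd of per-channel amplitude jitter
    phase_jitter_sd  = 0.22,   # rad, slow phase wander (keeps PLV < 1)
    ## intent expression: mixing m in [0, mix_cap] of the non-target template;
    ## with probability confusion_rate the expressed pattern is counter to the
    ## labelled intent (drives the sigma1 correct-prediction rate)
    intent_mix_shape1 = 1.8,
    intent_mix_shape2 = 6.0,
    intent_mix_cap    = 0.20,
    confusion_rate    = 0.08,
    ## gradual drift: transient Gaussian-profile low-frequency excursion
    drift_freq       = 2.0,    # Hz carrier of the drift excursion
    drift_gain       = 30.0,   # signal amplitude per unit drift_amplitude
    drift_width      = 1.2,    # s, Gaussian envelope sd
    drift_peak_delay = 1.8,    # s from onset to envelope peak (1.5 * width)
    drift_expr_sd    = 0.35,   # lognormal sd of per-episode expressivity
    drift_state_margin = 2.5,  # widths past the peak counted as drift phase
    ## decision reversal: broadband destabilisation until the model spectral
    ## entropy crosses the entropy cutoff, then an intent flip after the
    ## decision delay; noise settles over settle_len after the flip
    reversal_ramp_len  = 2.5,  # s, rise time of the noise ramp
    reversal_noise_mult = 2.4, # peak multiplier on baseline noise sd
    reversal_mult_sd   = 0.18, # lognormal sd of the peak multiplier
    reversal_settle    = 2.0,  # s, post-flip settling time
    reversal_mix_peak  = 0.45, # residual old-schema mixing right after flip
    reversal_mix_tau   = 1.5,  # s, decay constant of the residual mixing
    reversal_mix_sd    = 0.40, # lognormal sd of the residual mixing
    ## schema collapse: 5 Hz input-locked component whose precision decays;
    ## ambiguity = 1 - precision(t)/precision(0) mixes the intent templates
    ## and inflates broadband noise
    theta_gain       = 3.0,    # a.u., initial input-locked amplitude
    theta_expr_sd    = 0.45,   # lognormal sd of per-episode expressivity
    overload_mix_gain   = 0.155, # median peak template mixing under ambiguity
    overload_mix_sd     = 0.45, # lognormal sd of the mixing gain
    overload_noise_gain = 0.22, # median peak broadband noise inflation
    overload_noise_sd   = 0.30, # lognormal sd of the noise inflation
    ## behaviour channel
    behavior_base_sd  = 0.05,  # a.u., resting |noise| floor
    behavior_rise     = 0.08,  # s, logistic rise time at error onset
    behavior_level    = 2.0,   # a.u., degraded plateau (threshold = 1)
    behavior_hold     = 6.0,   # s, plateau before recovery decay
    error_threshold   = 1.0,
    error_debounce    = 0.25   # s, sustained excess required for error onset
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cal))
    if (length(bad)) stop_config("unknown calibration constant(s): ",
                                 paste(bad, collapse = ", "))
    cal[names(ov)] <- ov
  }
  cal
}

# Frozen per-task behavioural lag calibration (seconds). The lag is the gap
# between fault onset and overt performance degradation; it was calibrated so
# that the first warning-class marker leads error onset by 2.3 s on average
# (lag = typical detection latency + anticipation margin), then frozen.
.task_lags <- function(task_type) {
  switch(task_type,
    motor_control = c(mean = 4.13, sd = 0.28),
    inhibition    = c(mean = 3.85, sd = 0.28),
    overload      = c(mean = 3.58, sd = 0.28),
    stop_config("unknown task_type: ", task_type))
}
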