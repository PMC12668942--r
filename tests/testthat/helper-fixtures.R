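# Shared fixtures and independent oracles for the test suite.

# Small fast episode: short duration, low rate. Enough windows for the
# detector (baseline needs 3): 20 s at 256 Hz with 512/256 windows -> 19.
quick_config <- function(task = "motor_control", seed = 1, faulted = TRUE,
                         duration = 20, sampling_rate = 256, ...) {
  task_scenario(task, seed = seed, faulted = faulted, duration = duration,
                sampling_rate = sampling_rate, ...)
}

# memoised full-length episodes reused across tests in one run
.fixture_env <- new.env(parent = emptyenv())
fixture_episode <- function(task, seed, faulted = TRUE) {
  key <- paste(task, seed, faulted, sep = "|")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_episode(
      task_scenario(task, seed = seed, faulted = faulted))
  .fixture_env[[key]]
}

# Independent re-implementation of the published sliding-window decision
# rule (drift check, else conflict check), used as the oracle for
# classify_windows on feature streams that never trigger the hypothesis
# lifecycle.
pseudocode_oracle <- function(divergence, conflict_ratio,
                              threshold_drift = 0.35,
                              threshold_conflict = 0.5) {
  out <- character(length(divergence))
  for (i in seq_along(divergence)) {
    if (divergence[i] > threshold_drift) out[i] <- "DriftEvent"
    else if (conflict_ratio[i] > threshold_conflict)
      out[i] <- "ConflictEscalate"
    else out[i] <- "NoEvent"
  }
  out
}

# feature stream that keeps the hypothesis lifecycle inert (confidence below
# the commit threshold) so only the drift/conflict branches can fire
feature_stream <- function(divergence, conflict_ratio) {
  n <- length(divergence)
  data.frame(divergence = divergence, conflict_ratio = conflict_ratio,
             spectral_entropy = rep(0.4, n), confidence = rep(0.1, n),
             leading = rep("intent_a", n), t_end = seq_len(n) + 1,
             stringsAsFactors = FALSE)
}

# Brute-force recount oracle for marker_stats: direct loops written
# independently of the implementation.
recount_marker_stats <- function(traces, truths, tolerance = 1.0) {
  interp1 <- function(type, t, truth) {
    tl <- truth$state_timeline
    within <- function(states) any(tl$state %in% states &
                                     t >= tl$t_start - tolerance &
                                     t <= tl$t_end + tolerance)
    switch(type,
      Sigma1 = TRUE,
      DriftEvent = within("drift"),
      ConflictEscalate = within(c("conflict", "overload")),
      AcceptH1 = within("stable"),
      RejectH1 = within("reversal") ||
        (!is.null(truth$fault_onset) && t >= truth$fault_onset - tolerance))
  }
  warn <- c("DriftEvent", "ConflictEscalate", "RejectH1")
  res <- list()
  for (ty in c("Sigma1", "AcceptH1", "RejectH1", "DriftEvent",
               "ConflictEscalate")) {
    act <- 0; nm <- 0; nc <- 0; nfp <- 0; leads <- c()
    for (k in seq_along(traces)) {
      tr <- traces[[k]]; truth <- truths[[k]]
      rows <- which(tr$type == ty)
      if (length(rows) > 0) act <- act + 1
      for (i in rows) {
        nm <- nm + 1
        ok <- interp1(ty, tr$t[i], truth)
        corr <- if (ty == "Sigma1")
          isTRUE(tr$hypothesis[i] == truth$true_intent)
        else if (ty %in% warn)
          ok && !is.null(truth$error_onset) && tr$t[i] < truth$error_onset
        else ok
        if (corr) {
          nc <- nc + 1
          if (ty %in% warn) leads <- c(leads, truth$error_onset - tr$t[i])
        }
        if ((is.null(truth$fault_onset) && ty %in% warn) || !ok)
          nfp <- nfp + 1
      }
    }
    res[[ty]] <- list(activation = act / length(traces),
                      correct = if (nm) nc / nm else NA_real_,
                      fp = if (nm) nfp / nm else NA_real_,
                      lead = if (length(leads)) mean(leads) else NA_real_)
  }
  res
}

# hand-built trace helper
make_trace <- function(t, type, hypothesis = NA_character_, id = "fixture") {
  emit_trace(data.frame(t = t, type = type,
                        hypothesis = rep_len(hypothesis, length(t)),
                        stringsAsFactors = FALSE), episode_id = id)
}
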