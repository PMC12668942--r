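# Sliding-window cognitive event detection with hypothesis lifecycle.

#' Classify a feature stream into cognitive events
#'
#' Applies the detection rules to an already-extracted feature sequence, one
#' window per row, maintaining the hypothesis lifecycle across windows. Per
#' window a single event is emitted by precedence:
#'
#' 1. `Sigma1` at the first window whose hypothesis confidence reaches
#'    `commit_confidence` (at most once per stream);
#' 2. after commitment, `RejectH1` when spectral entropy exceeds
#'    `reject_entropy_spike` or the leading hypothesis changes (at most once);
#' 3. `AcceptH1` once the leading hypothesis has been unchanged for
#'    `accept_windows` consecutive windows (at most once, only while H1
#'    stands);
#' 4. `DriftEvent` when divergence exceeds `threshold_drift`, else
#'    `ConflictEscalate` when the conflict ratio exceeds `threshold_conflict`
#'    (this if/else precedence is deliberate);
#' 5. otherwise `NoEvent`.
#'
#' @param features data.frame with columns `divergence`, `conflict_ratio`,
#'   `spectral_entropy`, `confidence`, `leading`, `t_end` (one row per
#'   window, in order).
#' @param params a [discriminator_params()].
#' @return A `cog_events` data.frame: `window`, `t`, `type`, `hypothesis`
#'   plus the feature columns.
#' @examples
#' f <- data.frame(divergence = c(.1, .4), conflict_ratio = 0,
#'                 spectral_entropy = .5, confidence = .9,
#'                 leading = "intent_a", t_end = c(2, 3))
#' classify_windows(f, discriminator_params())$type
#' @export
classify_windows <- function(features, params = discriminator_params()) {
  need <- c("divergence", "conflict_ratio", "spectral_entropy",
            "confidence", "leading", "t_end")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop_contract("features lacks column(s): ", paste(miss, collapse = ", "))
  nw <- nrow(features)
  type <- character(nw)
  committed <- NA_character_
  rejected <- FALSE
  accepted <- FALSE
  stable_run <- 0L
  drift_on <- !("drift" %in% params$disable)
  conflict_on <- !("conflict" %in% params$disable)
  for (i in seq_len(nw)) {
    fv <- features[i, ]
    if (is.na(committed)) {
      if (!is.na(fv$confidence) && !is.na(fv$leading) &&
          fv$confidence >= params$commit_confidence) {
        committed <- fv$leading
        stable_run <- 0L
        type[i] <- "Sigma1"
        next
      }
    } else if (!rejected) {
      if (fv$spectral_entropy > params$reject_entropy_spike ||
          (!is.na(fv$leading) && fv$leading != committed)) {
        rejected <- TRUE
        type[i] <- "RejectH1"
        next
      }
      stable_run <- stable_run + 1L
      if (!accepted && stable_run >= params$accept_windows) {
        accepted <- TRUE
        type[i] <- "AcceptH1"
        next
      }
    }
    if (drift_on && fv$divergence > params$threshold_drift) {
      type[i] <- "DriftEvent"
    } else if (conflict_on && fv$conflict_ratio > params$threshold_conflict) {
      type[i] <- "ConflictEscalate"
    } else {
      type[i] <- "NoEvent"
    }
  }
  out <- data.frame(window = seq_len(nw), t = features$t_end, type = type,
                    hypothesis = ifelse(type == "Sigma1",
                                        features$leading, NA_character_),
                    stringsAsFactors = FALSE)
  out <- cbind(out, features[setdiff(names(features), c("t_end"))])
  class(out) <- c("cog_events", "data.frame")
  out
}

#' Detect cognitive events in a signal
#'
#' Runs the full sliding-window pipeline: windowing, spectral baseline
#' estimation from the first `baseline_windows` windows, feature extraction,
#' and classification (see [classify_windows()] for the event rules).
#'
#' @param signal channels x samples matrix, or a `cog_episode`.
#' @param params a [discriminator_params()].
#' @param sampling_rate Hz (taken from the episode when one is given).
#' @return A `cog_events` data.frame with one row per window.
#' @examples
#' ep <- simulate_episode(task_scenario("motor_control", seed = 5))
#' ev <- detect_events(ep)
#' table(ev$type)
#' @export
detect_events <- function(signal, params = discriminator_params(),
                          sampling_rate = 256) {
  if (inherits(signal, "cog_episode")) {
    sampling_rate <- signal$config$sampling_rate
    signal <- signal$signal
  }
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.matrix(signal) || ncol(signal) == 0)
    stop_contract("signal must be a non-empty channels x samples matrix")
  win <- sliding_windows(signal, params$window_size, params$step,
                         sampling_rate)
  if (win$n_windows < params$baseline_windows)
    stop_config("signal shorter than baseline_windows x window_size: ",
                "cannot calibrate the spectral baseline")
  nc <- nrow(signal)
  templates <- if (nc >= 2) intent_templates(nc) else NULL

  psds <- lapply(seq_len(win$n_windows),
                 function(i) .window_psd(win$get(i), sampling_rate))
  ref <- rowMeans(vapply(psds[seq_len(params$baseline_windows)],
                         function(p) p$norm, numeric(length(psds[[1]]$norm))))
  ref <- ref / sum(ref)

  nw <- win$n_windows
  divergence <- conflict_ratio <- entropy <- synchrony <- numeric(nw)
  alpha_power <- confidence <- numeric(nw)
  leading <- character(nw)
  ia <- psds[[1]]$bins >= params$alpha_band[1] &
    psds[[1]]$bins <= params$alpha_band[2]
  for (i in seq_len(nw)) {
    w <- win$get(i)
    psd <- psds[[i]]
    hyp <- if (!is.null(templates))
      .hypothesis_from_psd(psd, templates, params$alpha_band)
    else list(confidence = 0, leading = NA_character_, conflict_ratio = 0)
    divergence[i] <- js_divergence(psd$norm, ref)
    conflict_ratio[i] <- hyp$conflict_ratio
    entropy[i] <- .entropy_norm(psd$norm)
    synchrony[i] <- .plv(w, sampling_rate, params$alpha_band)
    alpha_power[i] <- if (sum(psd$avg) > 0) sum(psd$avg[ia]) / sum(psd$avg)
                      else 0
    confidence[i] <- hyp$confidence
    leading[i] <- hyp$leading
  }
  features <- data.frame(
    divergence = divergence, conflict_ratio = conflict_ratio,
    spectral_entropy = entropy, synchrony = synchrony,
    alpha_power = alpha_power, confidence = confidence, leading = leading,
    t_center = win$t_center, t_end = win$t_end, stringsAsFactors = FALSE)
  ev <- classify_windows(features, params)
  attr(ev, "baseline_reference") <- ref
  attr(ev, "params") <- params
  ev
}

#' @export
print.cog_events <- function(x, ...) {
  tab <- table(factor(x$type, levels = c("Sigma1", "AcceptH1", "RejectH1",
                                         "DriftEvent", "ConflictEscalate",
                                         "NoEvent")))
  cat(sprintf("<cog_events> %d window(s): ", nrow(x)))
  cat(paste(names(tab)[tab > 0], tab[tab > 0], sep = "=", collapse = ", "),
      "\n")
  cols <- intersect(c("window", "t", "type", "hypothesis"), names(x))
  sub <- as.data.frame(x)[x$type != "NoEvent", cols, drop = FALSE]
  if (nrow(sub)) print.data.frame(utils::head(sub, 20), row.names = FALSE)
  invisible(x)
}
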