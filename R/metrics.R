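# Trace evaluation: traceability, anticipation latency, per-marker
# statistics, bootstrap intervals, and condition comparisons.

# states consistent with each marker type; RejectH1 additionally accepts any
# post-fault time (handled separately), Sigma1 is always interpretable
.marker_state_map <- list(
  DriftEvent = "drift",
  ConflictEscalate = c("conflict", "overload"),
  RejectH1 = "reversal",
  AcceptH1 = "stable",
  Sigma1 = NULL)

.warning_types <- c("DriftEvent", "ConflictEscalate", "RejectH1")

# is marker (type, t) interpretable against a ground-truth timeline?
.interpretable <- function(type, t, truth, tolerance) {
  if (type == "Sigma1") return(TRUE)
  tl <- truth$state_timeline
  states <- .marker_state_map[[type]]
  if (is.null(states)) return(FALSE)
  hit <- any(tl$state %in% states &
               t >= tl$t_start - tolerance & t <= tl$t_end + tolerance)
  if (!hit && type == "RejectH1" && !is.null(truth$fault_onset))
    hit <- t >= truth$fault_onset - tolerance
  hit
}

#' Traceability score of a symbolic trace
#'
#' Fraction of markers that are semantically interpretable against the
#' ground-truth state timeline: a marker is interpretable iff its timestamp
#' falls within `tolerance` seconds of a state interval consistent with its
#' type (DriftEvent with `drift`, ConflictEscalate with `conflict` or
#' `overload`, RejectH1 with `reversal` or any post-fault time, AcceptH1 with
#' `stable`; the initial commitment marker is always interpretable). An empty
#' trace scores 1.0 by convention (no uninterpretable emissions) and is
#' flagged via the `"empty"` attribute.
#'
#' @param trace a `cog_trace`.
#' @param truth episode ground truth (`$truth` of a `cog_episode`).
#' @param tolerance seconds, non-negative (default 1.0).
#' @return Fraction in \[0, 1\] with attribute `empty`.
#' @examples
#' ep <- simulate_episode(task_scenario("motor_control", seed = 2))
#' tr <- emit_trace(detect_events(ep))
#' traceability_score(tr, ep$truth)
#' @export
traceability_score <- function(trace, truth, tolerance = 1.0) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop_contract("tolerance must be a non-negative scalar")
  if (!nrow(trace))
    return(structure(1.0, empty = TRUE))
  ok <- vapply(seq_len(nrow(trace)), function(i)
    .interpretable(trace$type[i], trace$t[i], truth, tolerance), logical(1))
  structure(mean(ok), empty = FALSE)
}

#' Anticipation latency of a trace
#'
#' Lead time of the first warning-class marker (DriftEvent, ConflictEscalate
#' or RejectH1) over behavioural error onset: `error_onset - t_marker`.
#' `NULL` when the episode has no error onset or no warning marker precedes
#' it.
#'
#' @param trace a `cog_trace`.
#' @param truth episode ground truth.
#' @return Latency in seconds, or `NULL`.
#' @examples
#' tr <- emit_trace(data.frame(t = 3, type = "DriftEvent",
#'                             hypothesis = NA_character_))
#' anticipation_latency(tr, list(error_onset = 5.3))
#' @export
anticipation_latency <- function(trace, truth) {
  e <- truth$error_onset
  if (is.null(e) || !nrow(trace)) return(NULL)
  w <- trace$t[trace$type %in% .warning_types & trace$t < e]
  if (!length(w)) return(NULL)
  e - min(w)
}

#' Per-marker statistics over a collection of episodes
#'
#' For each marker type: activation frequency (fraction of episodes with at
#' least one such marker), correct-prediction rate, false-positive rate, and
#' lead-time statistics over correct warning-class markers. A warning marker
#' is correct iff it is interpretable and precedes error onset; the initial
#' commitment marker is correct iff its committed hypothesis matches the
#' episode's true intent; AcceptH1 is correct iff interpretable. A marker is
#' a false positive iff it occurs in a fault-free episode or is not
#' interpretable. Underlying counts are retained for audit.
#'
#' @param traces list of `cog_trace` objects.
#' @param truths index-aligned list of ground truths.
#' @param tolerance seconds (default 1.0).
#' @return A `cog_marker_stats` data.frame, one row per marker type, with
#'   columns `marker`, `activation_frequency`, `correct_prediction_rate`,
#'   `false_positive_rate`, `mean_lead_time`, `sd_lead_time` and the
#'   underlying counts.
#' @examples
#' eps <- lapply(1:3, function(s)
#'   simulate_episode(task_scenario("motor_control", seed = s)))
#' trs <- lapply(eps, function(e) emit_trace(detect_events(e)))
#' marker_stats(trs, lapply(eps, `[[`, "truth"))
#' @export
marker_stats <- function(traces, truths, tolerance = 1.0) {
  if (length(traces) != length(truths))
    stop_contract("traces and truths must be index-aligned (equal length)")
  types <- c("Sigma1", "AcceptH1", "RejectH1", "DriftEvent",
             "ConflictEscalate")
  n_ep <- length(traces)
  rows <- lapply(types, function(ty) {
    n_marker <- 0L; n_correct <- 0L; n_fp <- 0L; n_ep_active <- 0L
    leads <- numeric(0)
    for (k in seq_len(n_ep)) {
      tr <- traces[[k]]; truth <- truths[[k]]
      sel <- which(tr$type == ty)
      if (length(sel)) n_ep_active <- n_ep_active + 1L
      faultfree <- is.null(truth$fault_onset)
      for (i in sel) {
        n_marker <- n_marker + 1L
        interp <- .interpretable(ty, tr$t[i], truth, tolerance)
        correct <- if (ty == "Sigma1") {
          !is.na(tr$hypothesis[i]) &&
            identical(tr$hypothesis[i], truth$true_intent)
        } else if (ty %in% .warning_types) {
          interp && !is.null(truth$error_onset) &&
            tr$t[i] < truth$error_onset
        } else interp
        if (correct) {
          n_correct <- n_correct + 1L
          if (ty %in% .warning_types)
            leads <- c(leads, truth$error_onset - tr$t[i])
        }
        # a false positive is a spurious alarm: a warning marker in a
        # fault-free episode, or any marker outside a consistent interval
        # (lifecycle markers legitimately appear in fault-free episodes)
        if ((faultfree && ty %in% .warning_types) || !interp)
          n_fp <- n_fp + 1L
      }
    }
    data.frame(
      marker = ty,
      activation_frequency = n_ep_active / n_ep,
      correct_prediction_rate = if (n_marker) n_correct / n_marker else NA_real_,
      false_positive_rate = if (n_marker) n_fp / n_marker else NA_real_,
      mean_lead_time = if (length(leads)) mean(leads) else NA_real_,
      sd_lead_time = if (length(leads) > 1) stats::sd(leads) else NA_real_,
      n_markers = n_marker, n_correct = n_correct, n_false_positive = n_fp,
      n_episodes_active = n_ep_active, n_episodes = n_ep,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cog_marker_stats", "data.frame")
  out
}

#' Percentile bootstrap confidence interval
#'
#' @param values non-empty numeric sample.
#' @param statistic function of a sample (default `mean`).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param n_resamples bootstrap resamples (default 2000).
#' @param seed optional integer; makes the interval deterministic.
#' @return Named numeric `c(low, high)`.
#' @examples
#' bootstrap_ci(rnorm(50), seed = 1)
#' @export
bootstrap_ci <- function(values, statistic = mean, level = 0.95,
                         n_resamples = 2000, seed = NULL) {
  if (!length(values)) stop_contract("sample must be non-empty")
  if (level <= 0 || level >= 1) stop_contract("level must be in (0, 1)")
  draw <- function() {
    boots <- vapply(seq_len(n_resamples), function(i)
      statistic(sample(values, replace = TRUE)), numeric(1))
    stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE, type = 7)
  }
  q <- if (is.null(seed)) draw() else with_seed(seed, draw())
  c(low = q[1], high = q[2])
}

#' Compare two conditions with normality-gated tests
#'
#' Assesses each sample with a Shapiro-Wilk test; if both pass at the 0.05
#' level a (paired) t-test is used, otherwise the Wilcoxon test. Reports the
#' test statistic, p-value and effect size (Cohen's d for the t branch,
#' rank-biserial correlation for the Wilcoxon branch).
#'
#' @param samples_a,samples_b numeric samples (equal length when paired).
#' @param paired logical (default TRUE).
#' @return List with `test`, `statistic`, `p_value`, `effect_size`,
#'   `effect_size_type`, `shapiro_p`.
#' @examples
#' compare_conditions(rnorm(20), rnorm(20, 1))
#' @export
compare_conditions <- function(samples_a, samples_b, paired = TRUE) {
  if (length(samples_a) < 3 || length(samples_b) < 3)
    stop_contract("insufficient data: need n >= 3 per condition")
  if (paired && length(samples_a) != length(samples_b))
    stop_contract("paired comparison requires equal-length samples")
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(samples_a); pb <- sw(samples_b)
  normal <- pa > 0.05 && pb > 0.05
  if (paired && stats::sd(samples_a - samples_b) <
        1e-10 * (abs(mean(samples_a - samples_b)) + 1)) {
    # degenerate: constant difference (t-test undefined)
    dd <- mean(samples_a - samples_b)
    return(list(test = "paired t-test",
                statistic = if (dd == 0) 0 else sign(dd) * Inf,
                p_value = if (dd == 0) 1 else 0,
                effect_size = if (dd == 0) 0 else sign(dd) * Inf,
                effect_size_type = "cohens_d",
                shapiro_p = c(a = pa, b = pb)))
  }
  if (normal) {
    ht <- stats::t.test(samples_a, samples_b, paired = paired)
    d <- if (paired) {
      dd <- samples_a - samples_b
      if (stats::sd(dd) == 0) 0 else mean(dd) / stats::sd(dd)
    } else {
      sp <- sqrt((stats::var(samples_a) + stats::var(samples_b)) / 2)
      if (sp == 0) 0 else (mean(samples_a) - mean(samples_b)) / sp
    }
    list(test = if (paired) "paired t-test" else "t-test",
         statistic = unname(ht$statistic), p_value = ht$p.value,
         effect_size = d, effect_size_type = "cohens_d",
         shapiro_p = c(a = pa, b = pb))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(samples_a, samples_b, paired = paired))
    es <- if (paired) {
      dd <- samples_a - samples_b
      dd <- dd[dd != 0]
      if (!length(dd)) 0 else {
        rk <- rank(abs(dd))
        wp <- sum(rk[dd > 0]); wt <- sum(rk)
        2 * wp / wt - 1                    # paired rank-biserial
      }
    } else {
      nx <- length(samples_a); ny <- length(samples_b)
      u <- unname(ht$statistic)
      2 * u / (nx * ny) - 1                # rank-biserial from U
    }
    list(test = if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum",
         statistic = unname(ht$statistic), p_value = ht$p.value,
         effect_size = es, effect_size_type = "rank_biserial",
         shapiro_p = c(a = pa, b = pb))
  }
}

#' Holm-adjusted p-values
#'
#' Convenience wrapper applying the Holm step-down correction across a set of
#' condition comparisons.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values.
#' @examples
#' adjust_pvalues(c(0.01, 0.04, 0.2))
#' @export
adjust_pvalues <- function(p) stats::p.adjust(p, method = "holm")

#' @export
print.cog_marker_stats <- function(x, digits = 3, ...) {
  cat("<marker statistics over", x$n_episodes[1], "episode(s)>\n")
  df <- data.frame(
    marker = x$marker,
    activation = sprintf("%.1f%%", 100 * x$activation_frequency),
    correct = ifelse(is.na(x$correct_prediction_rate), "-",
                     sprintf("%.1f%%", 100 * x$correct_prediction_rate)),
    false_pos = ifelse(is.na(x$false_positive_rate), "-",
                       sprintf("%.1f%%", 100 * x$false_positive_rate)),
    lead_s = ifelse(is.na(x$mean_lead_time), "-",
                    sprintf("%.2f\u00b1%.2f", x$mean_lead_time,
                            ifelse(is.na(x$sd_lead_time), 0, x$sd_lead_time))))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
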