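# Sliding-window spectral features for the discriminator.

#' Sliding windows over a multichannel signal
#'
#' Consecutive windows starting at sample 1, advanced by `step` samples; a
#' trailing fragment shorter than `window_size` is discarded. Windows are
#' labelled by their end time (a detection cannot precede the data it used).
#'
#' @param signal channels x samples matrix (a plain vector is treated as one
#'   channel).
#' @param window_size samples per window (>= 2).
#' @param step hop in samples (>= 1).
#' @param sampling_rate Hz, used for the time labels.
#' @return A list with `starts` (1-based start indices), `t_end` and
#'   `t_center` (seconds), and `get(i)` returning window `i` as a
#'   channels x window_size matrix.
#' @examples
#' w <- sliding_windows(matrix(rnorm(2048), 2), 512, 256, sampling_rate = 256)
#' length(w$starts)
#' @export
sliding_windows <- function(signal, window_size, step = window_size,
                            sampling_rate = 256) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_contract("signal must be a numeric matrix (channels x samples)")
  if (window_size < 2) stop_contract("window_size must be >= 2")
  if (step < 1) stop_contract("step must be >= 1")
  n <- ncol(signal)
  starts <- seq.int(1L, by = as.integer(step),
                    length.out = max(0L, (n - as.integer(window_size)) %/%
                                       as.integer(step) + 1L))
  if (n < window_size) starts <- integer(0)
  ends <- starts + as.integer(window_size) - 1L
  list(starts = starts,
       t_end = ends / sampling_rate,
       t_center = (starts + ends - 1) / 2 / sampling_rate,
       n_windows = length(starts),
       get = function(i) signal[, starts[i]:ends[i], drop = FALSE])
}

# Hann-tapered channel-averaged power spectrum of one window, aggregated into
# 1 Hz bins over `band`. Returns the *unnormalized* per-channel band matrix
# too (used by the hypothesis bank).
.window_psd <- function(window, sampling_rate, band = c(1, 45)) {
  nc <- nrow(window); len <- ncol(window)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
  w <- sweep(window, 2, taper, `*`)
  sp <- stats::mvfft(t(w))
  pow <- Mod(sp)^2                       # len x nc
  freq <- (seq_len(len) - 1) * sampling_rate / len
  bins <- band[1]:band[2]
  idx <- findInterval(freq, c(bins - 0.5, bins[length(bins)] + 0.5))
  keep <- freq >= band[1] - 0.5 & freq < band[2] + 0.5 & freq <= sampling_rate / 2
  binned <- rowsum(pow[keep, , drop = FALSE], idx[keep])  # nbins x nc
  if (nrow(binned) < length(bins)) {     # pad bins absent at low resolution
    full <- matrix(0, length(bins), nc)
    full[as.integer(rownames(binned)), ] <- binned
    binned <- full
  }
  avg <- rowMeans(binned)
  list(bins = bins, per_channel = binned, avg = avg,
       norm = if (sum(avg) > 0) avg / sum(avg) else
         rep(1 / length(bins), length(bins)))
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 JSD, bounded in \[0, 1\]; symmetric and zero iff the distributions
#' are equal.
#'
#' @param p,q non-negative vectors of equal length summing to one.
#' @return JSD in bits.
#' @examples
#' js_divergence(c(.5, .5), c(.5, .5))
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop_contract("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop_contract("p and q must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop_contract("p and q must each sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  max(0, min(1, (kl(p, m) + kl(q, m)) / 2))
}

#' Normalized spectral entropy
#'
#' Shannon entropy of a normalized power spectrum divided by the log of the
#' bin count, giving a disorder index in \[0, 1\].
#'
#' @param p normalized spectral distribution.
#' @return Entropy in \[0, 1\].
#' @examples
#' spectral_entropy(rep(1 / 10, 10))
#' @export
spectral_entropy <- function(p) {
  if (any(p < 0)) stop_contract("spectrum must be non-negative")
  s <- sum(p)
  if (s == 0) return(1)
  nb <- length(p)
  if (nb < 2) return(0)
  p <- p / s
  p <- p[p > 0]
  min(1, -sum(p * log(p)) / log(nb))
}

#' Matched-filter hypothesis evidence
#'
#' Scores each intent template against a window: per channel, alpha-band
#' power above the local broadband noise floor (estimated from the 13-17 Hz
#' flank) is projected onto each template's spatial weights. Confidence is
#' `max(score) / sum(scores)`.
#'
#' @param window channels x samples matrix.
#' @param templates named list of non-negative per-channel weight vectors
#'   (see [intent_templates()]); at least two.
#' @param sampling_rate Hz.
#' @param alpha_band Hz interval (default `c(8, 12)`).
#' @return List with `scores` (named, non-negative), `confidence`,
#'   `leading` (template name) and `conflict_ratio` (second-best / best).
#' @examples
#' w <- matrix(rnorm(2048), 4)
#' hypothesis_evidence(w, intent_templates(4))$confidence
#' @export
hypothesis_evidence <- function(window, templates, sampling_rate = 256,
                                alpha_band = c(8, 12)) {
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  if (!length(templates)) stop_contract("template set must be non-empty")
  if (length(templates) < 2) stop_contract("need >= 2 intent templates")
  psd <- .window_psd(window, sampling_rate)
  .hypothesis_from_psd(psd, templates, alpha_band)
}

# hypothesis scoring from a precomputed window PSD (shared with the
# detection loop, which reuses its PSDs)
.hypothesis_from_psd <- function(psd, templates, alpha_band = c(8, 12)) {
  resid <- .alpha_residual(psd, alpha_band)
  scores <- vapply(templates, function(w) {
    if (length(w) != length(resid))
      stop_contract("template length must equal channel count")
    sum(w * resid)
  }, numeric(1))
  scores <- pmax(scores, 0)
  tot <- sum(scores)
  ord <- order(scores, decreasing = TRUE)
  conf <- if (tot > 0) scores[ord[1]] / tot else 1 / length(scores)
  ratio <- if (scores[ord[1]] > 0) scores[ord[2]] / scores[ord[1]] else 1
  list(scores = scores, confidence = unname(conf),
       leading = names(templates)[ord[1]],
       conflict_ratio = unname(ratio))
}

# per-channel alpha-band power above the 13-17 Hz noise-floor estimate
.alpha_residual <- function(psd, alpha_band = c(8, 12)) {
  ia <- psd$bins >= alpha_band[1] & psd$bins <= alpha_band[2]
  iflank <- psd$bins >= 13 & psd$bins <= 17
  alpha <- colSums(psd$per_channel[ia, , drop = FALSE])
  floor_rate <- colMeans(psd$per_channel[iflank, , drop = FALSE])
  pmax(alpha - floor_rate * sum(ia), 0)
}

# mean pairwise phase-locking value across channels in `band`
.plv <- function(window, sampling_rate, band = c(8, 12)) {
  nc <- nrow(window)
  if (nc < 2) return(1)
  len <- ncol(window)
  sp <- stats::mvfft(t(window))
  freq <- (seq_len(len) - 1) * sampling_rate / len
  mask <- as.numeric(freq >= band[1] & freq <= band[2] &
                       freq <= sampling_rate / 2)
  analytic <- stats::mvfft(sp * (2 * mask), inverse = TRUE) / len
  ph <- Arg(analytic)                    # len x nc
  plvs <- c()
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc)
    plvs <- c(plvs, Mod(mean(exp(1i * (ph[, i] - ph[, j])))))
  mean(plvs)
}

#' Extract discriminator features from a window
#'
#' Computes the feature vector driving event detection: `divergence`
#' (base-2 Jensen-Shannon divergence between the window's channel-averaged
#' normalized power spectrum and `baseline_reference`), `spectral_entropy`
#' (normalized Shannon entropy of the window spectrum), `alpha_power`
#' (alpha-band fraction of total band power), `synchrony` (mean pairwise
#' alpha-band phase-locking value; 1 for single-channel input), and
#' `conflict_ratio` with hypothesis `confidence`/`leading` from the
#' matched-filter bank.
#'
#' @param window channels x samples matrix (>= 2 samples per channel).
#' @param baseline_reference normalized baseline spectral distribution over
#'   the same 1 Hz bins (must sum to 1).
#' @param sampling_rate Hz.
#' @param templates intent template bank; defaults to
#'   [intent_templates()] for the window's channel count (single-channel
#'   windows get a degenerate two-template bank with zero scores).
#' @param alpha_band Hz interval (default `c(8, 12)`).
#' @param t_center,t_end seconds, optional time labels copied to the output.
#' @return A one-row data.frame feature vector.
#' @examples
#' w <- matrix(rnorm(2048), 4)
#' ref <- rep(1 / 45, 45)
#' extract_features(w, ref)$divergence
#' @export
extract_features <- function(window, baseline_reference, sampling_rate = 256,
                             templates = NULL, alpha_band = c(8, 12),
                             t_center = NA_real_, t_end = NA_real_) {
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  if (ncol(window) < 2) stop_contract("window needs >= 2 samples per channel")
  psd <- .window_psd(window, sampling_rate)
  if (length(baseline_reference) != length(psd$norm))
    stop_contract("baseline_reference has wrong length (expected ",
                  length(psd$norm), " bins)")
  if (abs(sum(baseline_reference) - 1) > 1e-6)
    stop_contract("baseline_reference must be normalized (sum to 1)")
  nc <- nrow(window)
  divergence <- js_divergence(psd$norm, baseline_reference)
  ent <- .entropy_norm(psd$norm)
  ia <- psd$bins >= alpha_band[1] & psd$bins <= alpha_band[2]
  alpha_power <- if (sum(psd$avg) > 0) sum(psd$avg[ia]) / sum(psd$avg) else 0
  synchrony <- .plv(window, sampling_rate, alpha_band)
  if (is.null(templates) && nc >= 2) templates <- intent_templates(nc)
  hyp <- if (!is.null(templates))
    hypothesis_evidence(window, templates, sampling_rate, alpha_band)
  else list(confidence = 0, leading = NA_character_, conflict_ratio = 0)
  data.frame(divergence = divergence, conflict_ratio = hyp$conflict_ratio,
             spectral_entropy = ent, synchrony = synchrony,
             alpha_power = alpha_power, confidence = hyp$confidence,
             leading = hyp$leading, t_center = t_center, t_end = t_end,
             stringsAsFactors = FALSE)
}

.entropy_norm <- function(p) {
  nb <- length(p)
  p <- p[p > 0]
  if (!length(p)) return(1)
  min(1, -sum(p * log(p)) / log(nb))
}
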