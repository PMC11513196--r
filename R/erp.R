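#' Trial-level windowed mean amplitudes
#'
#' For every subject, the mean signal value inside `window` is computed per
#' trial. These trial scores are the raw material for the mean amplitude,
#' variability and dependability measures.
#'
#' @param epochs an [make_epochs()] / [read_epoch_set()] result.
#' @param window length-2 ms pair inside the epoch time axis.
#' @return Named list of numeric vectors (one trial score per trial).
#' @export
trial_amplitudes <- function(epochs, window = c(0, 100)) {
  stopifnot(inherits(epochs, "epoch_set"), length(window) == 2,
            window[1] >= min(epochs$time), window[2] <= max(epochs$time))
  sel <- epochs$time >= window[1] & epochs$time <= window[2]
  if (!any(sel)) stop("window contains no samples")
  lapply(epochs$epochs, function(m) {
    if (is.null(m) || nrow(m) == 0L)
      stop("subject with no trials; exclude upstream")
    rowMeans(m[, sel, drop = FALSE])
  })
}

#' Per-subject mean amplitude in a window
#'
#' Average over trials of each trial's windowed mean — the standard mean
#' amplitude score (e.g. ERN as mean activity 0-100 ms post-response).
#'
#' @inheritParams trial_amplitudes
#' @return Named numeric vector (uV), one value per subject.
#' @export
mean_amplitude <- function(epochs, window = c(0, 100)) {
  vapply(trial_amplitudes(epochs, window), mean, numeric(1))
}

#' Fractional-area latency of a component
#'
#' The earliest time at which the cumulative rectified area of the
#' polarity-consistent signal, accumulated from the window start, reaches
#' `fraction` of the total area in the window. Area is accumulated by the
#' trapezoid rule with linear interpolation between samples. For negative
#' components only the negative-going part of the waveform contributes.
#'
#' @param waveform numeric vector of signal values (uV).
#' @param time matching time axis (ms).
#' @param window length-2 ms analysis window.
#' @param fraction area fraction in (0, 1); default 0.5.
#' @param polarity `"negative"` or `"positive"`.
#' @return Latency in ms, or `NA` (with a warning) when the window holds no
#'   polarity-consistent area.
#' @export
fractional_area_latency <- function(waveform, time, window = c(0, 100),
                                    fraction = 0.5,
                                    polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(length(waveform) == length(time), fraction > 0, fraction < 1,
            window[1] >= min(time), window[2] <= max(time))
  sel <- time >= window[1] & time <= window[2]
  t <- time[sel]
  y <- waveform[sel]
  y <- if (polarity == "negative") pmax(-y, 0) else pmax(y, 0)
  if (length(t) < 2L || all(y == 0)) {
    warning("no polarity-consistent area in window; latency undefined")
    return(NA_real_)
  }
  dt <- diff(t)
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dt))
  target <- fraction * cum[length(cum)]
  k <- which(cum >= target)[1]
  if (k == 1L) return(t[1])
  t[k - 1] + (target - cum[k - 1]) / (cum[k] - cum[k - 1]) * (t[k] - t[k - 1])
}

#' Within- and between-subject trial variability
#'
#' Within-subject SD is the standard deviation of the trial-level windowed
#' means per subject; between-subject SD is the standard deviation of the
#' subject-level means.
#'
#' @inheritParams trial_amplitudes
#' @return List with `within_sd` (named vector, `NA` for single-trial
#'   subjects) and `between_sd` (scalar).
#' @export
trial_variability <- function(epochs, window = c(0, 100)) {
  scores <- trial_amplitudes(epochs, window)
  within <- vapply(scores, function(s)
    if (length(s) >= 2L) sd(s) else NA_real_, numeric(1))
  list(within_sd = within,
       between_sd = sd(vapply(scores, mean, numeric(1))))
}

#' Subject-level dependability of averaged ERP scores
#'
#' One-way random-effects variance decomposition: the between-subject
#' variance is estimated as the variance of subject means minus the average
#' error variance of a mean (`mean(v_i / n_i)`), and each subject's
#' dependability is `sigma2_b / (sigma2_b + v_i / n_i)` where `v_i` is that
#' subject's trial variance and `n_i` their trial count. Values are clipped
#' to [0, 1]; a non-positive between-subject variance estimate yields 0 for
#' everyone, with a warning.
#'
#' @inheritParams trial_amplitudes
#' @return Named numeric vector of per-subject dependability coefficients.
#' @export
dependability <- function(epochs, window = c(0, 100)) {
  scores <- trial_amplitudes(epochs, window)
  n_i <- lengths(scores)
  if (any(n_i < 2L))
    stop("dependability requires >= 2 trials per subject")
  m_i <- vapply(scores, mean, numeric(1))
  v_i <- vapply(scores, var, numeric(1))
  sigma2_b <- var(m_i) - mean(v_i / n_i)
  if (sigma2_b <= 0) {
    warning("non-positive between-subject variance estimate; dependability set to 0")
    return(stats::setNames(rep(0, length(m_i)), names(scores)))
  }
  dep <- sigma2_b / (sigma2_b + v_i / n_i)
  pmin(pmax(dep, 0), 1)
}

#' Per-subject ERP metrics table
#'
#' Combines windowed mean amplitude, fractional-area latency (computed on
#' the subject-average waveform), trial counts, within-subject SD and
#' dependability into one row per subject.
#'
#' @inheritParams trial_amplitudes
#' @param latency_window window for the latency measure; defaults to
#'   `window`.
#' @param polarity component polarity for the latency measure.
#' @return Data frame of class `erp_metrics`.
#' @export
erp_metrics <- function(epochs, window = c(0, 100), latency_window = window,
                        polarity = "negative") {
  scores <- trial_amplitudes(epochs, window)
  vb <- trial_variability(epochs, window)
  dep <- tryCatch(dependability(epochs, window), error = function(e) {
    stats::setNames(rep(NA_real_, length(scores)), names(scores))
  })
  lat <- vapply(names(epochs$epochs), function(id) {
    avg <- colMeans(epochs$epochs[[id]])
    suppressWarnings(
      fractional_area_latency(avg, epochs$time, latency_window,
                              polarity = polarity))
  }, numeric(1))
  out <- data.frame(subject_id = names(scores),
                    mean_amplitude = vapply(scores, mean, numeric(1)),
                    latency = lat, n_trials = lengths(scores),
                    within_sd = vb$within_sd, dependability = dep,
                    row.names = NULL)
  class(out) <- c("erp_metrics", "data.frame")
  out
}

#' Apply trial-count and dependability exclusion rules
#'
#' Subjects with fewer than `min_trials` trials or dependability strictly
#' below `min_dependability` are removed; both thresholds are inclusive on
#' the boundary (exactly 5 trials or exactly .70 is kept).
#'
#' @param metrics an [erp_metrics()] data frame.
#' @param min_trials minimum trial count (default 5).
#' @param min_dependability minimum dependability (default 0.70).
#' @return List with `kept` (filtered metrics) and `log` (data frame of
#'   subject_id, rule, value for every exclusion).
#' @export
apply_exclusions <- function(metrics, min_trials = 5,
                             min_dependability = 0.70) {
  stopifnot(is.data.frame(metrics),
            all(c("subject_id", "n_trials", "dependability") %in%
                  names(metrics)))
  log <- data.frame(subject_id = character(), rule = character(),
                    value = numeric())
  few <- metrics$n_trials < min_trials
  lowdep <- !is.na(metrics$dependability) &
    metrics$dependability < min_dependability
  if (any(few))
    log <- rbind(log, data.frame(subject_id = metrics$subject_id[few],
                                 rule = "min_trials",
                                 value = metrics$n_trials[few]))
  if (any(lowdep))
    log <- rbind(log, data.frame(subject_id = metrics$subject_id[lowdep],
                                 rule = "min_dependability",
                                 value = metrics$dependability[lowdep]))
  list(kept = metrics[!(few | lowdep), , drop = FALSE], log = log)
}
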