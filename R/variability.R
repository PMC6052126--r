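# Spike-train variability statistics.
#
# The local irregularity measure CV2 is built from m-values: for any two
# consecutive ISIs, m = 2|ISI - ISI'| / (ISI + ISI'), bounded in [0, 2],
# anchored at the middle spike of the three spikes involved. Averaging all
# m-values whose anchor falls inside the analysis window gives the CV2,
# which is robust against slow rate changes where the classical CV is not.
# Count variability across trials is the Fano factor FF = var(n_i)/mean(n_i);
# a stationary renewal process predicts FF ~ CV^2, and a Poisson process
# gives CV = CV2 = FF = 1.

#' Inter-spike intervals
#'
#' @param spike_times Strictly increasing spike-time vector (ms).
#' @return Numeric vector of ISI durations, length `n - 1` (empty for fewer
#'   than two spikes).
#' @export
compute_isis <- function(spike_times) {
  if (length(spike_times) < 2) return(numeric(0))
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  diff(spike_times)
}

#' Coefficient of variation of ISIs
#'
#' CV = SD(ISI)/mean(ISI). Meaningful only for stationary firing: rate
#' changes within the observation inflate the CV, which is why the local
#' CV2 is preferred for task epochs.
#'
#' @param isis Numeric vector of ISIs.
#' @return CV, or `NA_real_` when fewer than two ISIs are available.
#' @export
compute_cv <- function(isis) {
  if (length(isis) < 2) return(NA_real_)
  stats::sd(isis) / mean(isis)
}

#' Local irregularity m-values of an aligned spike train set
#'
#' One m-value per pair of consecutive ISIs: `m = 2|ISI - ISI'|/(ISI + ISI')`,
#' anchored at the time of the middle spike. An m-value is retained when its
#' anchor lies inside the half-open analysis window; the first or third spike
#' may fall outside the window. m-values never cross trial boundaries, and
#' values from all trials are pooled.
#'
#' @param aligned An `aligned_trains` object from [align_spikes()] (its
#'   `window` is used), or a plain list of aligned spike-time vectors if
#'   `window` is supplied.
#' @param window Optional [epoch_window()] overriding `aligned$window`.
#' @return Data frame with columns `value` (in `[0, 2]`), `anchor_time` (ms,
#'   aligned clock) and `trial_id`.
#' @export
compute_m_values <- function(aligned, window = NULL) {
  if (inherits(aligned, "aligned_trains")) {
    window <- window %||% aligned$window
    trains <- aligned$trains
  } else {
    stopifnot(!is.null(window))
    trains <- aligned
    if (is.null(names(trains))) names(trains) <- seq_along(trains)
  }
  out <- lapply(names(trains), function(tid) {
    st <- trains[[tid]]
    n <- length(st)
    if (n < 3) return(NULL)
    isi <- diff(st)
    i1 <- isi[-length(isi)]
    i2 <- isi[-1]
    m <- 2 * abs(i1 - i2) / (i1 + i2)
    anchor <- st[2:(n - 1)]
    keep <- in_window(anchor, window)
    if (!any(keep)) return(NULL)
    data.frame(value = m[keep], anchor_time = anchor[keep], trial_id = tid)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(value = numeric(0), anchor_time = numeric(0),
                      trial_id = character(0))
  }
  rownames(out) <- NULL
  out
}

#' CV2 from pooled m-values
#'
#' Arithmetic mean of the m-values pooled over all trials of one epoch and
#' trial type. Estimates from fewer than `min_m` m-values are unreliable and
#' reported as undefined.
#'
#' @param m_values Data frame from [compute_m_values()], or a bare numeric
#'   vector of m-values.
#' @param min_m Minimum number of m-values required (default 20).
#' @return List with `cv2` (`NA_real_` if undefined), `n_m`, and `reason`
#'   (`""` when defined, `"insufficient m-values"` otherwise).
#' @export
compute_cv2 <- function(m_values, min_m = 20) {
  m <- if (is.data.frame(m_values)) m_values$value else m_values
  n <- length(m)
  if (n < min_m) {
    return(list(cv2 = NA_real_, n_m = n, reason = "insufficient m-values"))
  }
  list(cv2 = mean(m), n_m = n, reason = "")
}

#' Local variation (LV) of a single-trial ISI sequence
#'
#' `LV = 1/(n-1) * sum_i 3 (ISI_i - ISI_{i+1})^2 / (ISI_i + ISI_{i+1})^2`
#' over the `n - 1` consecutive ISI pairs of one trial; 0 for a perfectly
#' regular train, about 1 for Poisson. ISIs are never pooled across trial
#' boundaries; use [lv_across_trials()] to average per-trial values.
#'
#' @param isis Numeric ISI vector from one trial.
#' @return LV, or `NA_real_` for fewer than two ISIs.
#' @export
compute_lv <- function(isis) {
  n <- length(isis)
  if (n < 2) return(NA_real_)
  i1 <- isis[-n]
  i2 <- isis[-1]
  sum(3 * (i1 - i2)^2 / (i1 + i2)^2) / (n - 1)
}

#' Trial-averaged LV inside a window
#'
#' Computes [compute_lv()] per trial from the ISIs between in-window spikes
#' and averages the defined per-trial values.
#'
#' @param aligned An `aligned_trains` object.
#' @return Mean per-trial LV, or `NA_real_` when no trial has two ISIs in
#'   the window.
#' @export
lv_across_trials <- function(aligned) {
  vals <- vapply(aligned$trains, function(st) {
    stw <- st[in_window(st, aligned$window)]
    compute_lv(compute_isis(stw))
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Fano factor of in-window spike counts across trials
#'
#' `FF = var(n_i)/mean(n_i)` over per-trial counts inside the half-open
#' window, with the unbiased (n-1) sample variance. To limit the downward
#' finite-window estimation bias, samples whose mean rate is below
#' `min_rate` are reported as undefined.
#'
#' @param aligned An `aligned_trains` object.
#' @param min_rate Minimum trial-averaged firing rate in spikes/s
#'   (default 5).
#' @return List with `ff` (`NA_real_` if undefined), `counts` (per-trial
#'   in-window counts), `rate` (trial-averaged rate, spikes/s), `n_trials`,
#'   and `reason`.
#' @export
compute_ff <- function(aligned, min_rate = 5) {
  counts <- window_counts(aligned)
  n_trials <- length(counts)
  win_s <- (aligned$window$end_offset - aligned$window$start_offset) / 1000
  rate <- mean(counts) / win_s
  if (n_trials < 2) {
    return(list(ff = NA_real_, counts = counts, rate = rate,
                n_trials = n_trials, reason = "fewer than 2 trials"))
  }
  if (mean(counts) == 0) {
    return(list(ff = NA_real_, counts = counts, rate = rate,
                n_trials = n_trials, reason = "zero mean count"))
  }
  if (rate < min_rate) {
    return(list(ff = NA_real_, counts = counts, rate = rate,
                n_trials = n_trials, reason = "rate below minimum"))
  }
  list(ff = stats::var(counts) / mean(counts), counts = counts, rate = rate,
       n_trials = n_trials, reason = "")
}

#' Waveform signal-to-noise ratio
#'
#' SNR of a unit's spike waveforms: the mean trough-to-peak amplitude over
#' snippets, divided by twice the standard deviation over all samples of all
#' snippets. Units are selected downstream with SNR strictly greater than
#' the threshold (default 2.5).
#'
#' @param waveforms Numeric matrix, one row per spike snippet.
#' @return SNR value, `NA_real_` if the overall SD is zero.
#' @export
compute_snr <- function(waveforms) {
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) < 1) stop("need at least one waveform snippet")
  amp <- apply(waveforms, 1, function(w) max(w) - min(w))
  s <- stats::sd(as.vector(waveforms))
  if (s == 0) return(NA_real_)
  mean(amp) / (2 * s)
}

#' Per-unit variability statistics for one epoch and trial type
#'
#' Computes rate, CV2, LV and FF for every unit of a session in the given
#' window, restricted to correct trials of one trial type. A unit is
#' `selected` for an epoch when both its CV2 (at least `min_m` m-values) and
#' its FF (rate at least `min_rate` spikes/s) are defined. Units whose
#' proportion of very short ISIs (<= `burst_isi_ms`) exceeds `burst_frac`
#' are flagged as bursty but kept.
#'
#' @param session A [spike_session()].
#' @param window An [epoch_window()] (typically `wait` or `movement`).
#' @param trial_type Trial type label such as `"SG-HF"`.
#' @param min_rate,min_m Selection thresholds (defaults 5 spikes/s, 20
#'   m-values).
#' @param snr_threshold Units with SNR not exceeding this are dropped before
#'   analysis (default 2.5, strict inequality).
#' @param burst_isi_ms,burst_frac Bursting flag rule: proportion of ISIs at
#'   or below `burst_isi_ms` exceeding `burst_frac` (defaults 2 ms, 1%).
#' @return Data frame, one row per unit, with columns `unit_id`, `epoch`,
#'   `trial_type`, `rate`, `cv2`, `lv`, `ff`, `n_m`, `n_trials`, `selected`,
#'   `reason`, `bursty`.
#' @export
unit_variability <- function(session, window, trial_type,
                             min_rate = 5, min_m = 20, snr_threshold = 2.5,
                             burst_isi_ms = 2, burst_frac = 0.01) {
  units <- session$units[session$units$snr > snr_threshold, , drop = FALSE]
  rows <- lapply(units$unit_id, function(uid) {
    al <- align_spikes(session, uid, window, trial_type = trial_type)
    mv <- compute_m_values(al)
    cv2 <- compute_cv2(mv, min_m = min_m)
    ff <- compute_ff(al, min_rate = min_rate)
    lv <- lv_across_trials(al)
    all_isis <- unlist(lapply(al$trains, compute_isis))
    bursty <- length(all_isis) > 0 &&
      mean(all_isis <= burst_isi_ms) > burst_frac
    reason <- paste(Filter(nzchar, c(cv2$reason, ff$reason)), collapse = "; ")
    data.frame(unit_id = uid, epoch = window$name, trial_type = trial_type,
               rate = ff$rate, cv2 = cv2$cv2, lv = lv, ff = ff$ff,
               n_m = cv2$n_m, n_trials = ff$n_trials,
               selected = !is.na(cv2$cv2) && !is.na(ff$ff),
               reason = reason, bursty = bursty)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select units by epoch-wise criteria
#'
#' `either_epoch` returns, per epoch, the units selected in that epoch (used
#' for population medians, where the population may differ between epochs).
#' `both_epochs` returns the units selected in every supplied epoch (used
#' for paired per-neuron comparisons).
#'
#' @param results Data frame combining [unit_variability()] rows for two or
#'   more epochs (same trial type).
#' @param mode `"either_epoch"` or `"both_epochs"`.
#' @return For `either_epoch`, a named list of unit-id vectors, one per
#'   epoch; for `both_epochs`, a single unit-id vector.
#' @export
select_units <- function(results, mode = c("either_epoch", "both_epochs")) {
  mode <- match.arg(mode)
  per_epoch <- lapply(split(results, results$epoch), function(df) {
    df$unit_id[df$selected]
  })
  if (mode == "either_epoch") return(per_epoch)
  Reduce(intersect, per_epoch)
}
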