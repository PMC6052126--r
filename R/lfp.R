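# Spike-to-LFP beta phase locking.
#
# To avoid trivial spike/LFP correlations from volume conduction on the
# spike's own electrode, each electrode's LFP is replaced by the trial-wise
# average of its directly neighboring channels (8-connected on the grid;
# 3 to 8 channels depending on array position, 4 to 9 when the center is
# included). The dominant beta frequency is read off the averaged power
# spectrum in 10-45 Hz during the extended wait window, the whole-trial
# signal is bandpass filtered around it with a zero-phase (forward-backward)
# 4-pole Butterworth, and the instantaneous phase comes from the analytic
# signal (Hilbert transform). Phase 0 corresponds to an oscillation peak.

#' Directly neighboring electrodes on the array grid
#'
#' 8-connected neighborhood of an electrode on the 10 x 10 grid; absent
#' sites (the unconnected corners) are skipped.
#'
#' @param electrode_id Electrode to look up.
#' @param layout Layout data frame (`electrode_id`, `row`, `col`).
#' @param include_center Also return the electrode itself (default `FALSE`).
#' @return Integer vector of electrode ids.
#' @export
grid_neighbors <- function(electrode_id, layout, include_center = FALSE) {
  i <- match(electrode_id, layout$electrode_id)
  if (is.na(i)) stop(sprintf("electrode %s not in layout", electrode_id))
  dr <- abs(layout$row - layout$row[i])
  dc <- abs(layout$col - layout$col[i])
  nb <- layout$electrode_id[dr <= 1 & dc <= 1 &
                              !(dr == 0 & dc == 0)]
  if (include_center) nb <- c(electrode_id, nb)
  sort(nb)
}

#' Neighbor-averaged LFP for one electrode
#'
#' Sample-wise mean, trial by trial, over the LFP signals of the directly
#' neighboring channels (optionally including the electrode's own channel).
#' Neighbors without an LFP channel are skipped.
#'
#' @param session A [spike_session()] with LFP data.
#' @param electrode_id Center electrode.
#' @param include_center Include the electrode's own signal (default
#'   `FALSE`; see Details in the package vignette on volume conduction).
#' @param trial_ids Trials to average for; default all trials with LFP.
#' @return Named list (by trial id) of averaged signal vectors.
#' @export
neighbor_average_lfp <- function(session, electrode_id,
                                 include_center = FALSE, trial_ids = NULL) {
  if (is.null(session$lfp)) stop("session has no LFP data")
  if (is.null(session$layout)) stop("session has no array layout")
  nb <- grid_neighbors(electrode_id, session$layout, include_center)
  nb <- nb[as.character(nb) %in% names(session$lfp)]
  if (length(nb) == 0) {
    stop(sprintf("electrode %s: no neighbor LFP channels available",
                 electrode_id))
  }
  tids <- trial_ids %||% names(session$lfp[[as.character(nb[1])]])
  tids <- as.character(tids)
  out <- lapply(tids, function(tid) {
    sigs <- lapply(as.character(nb), function(el) session$lfp[[el]][[tid]])
    rowMeans(do.call(cbind, sigs))
  })
  stats::setNames(out, tids)
}

# Cut the window's sample range out of a full-trial signal. Sample k of a
# 1 kHz trace covers trial time [k-1, k) ms, so the half-open window
# [start, end) maps onto samples (ev+start+1) .. (ev+end).
trial_segment <- function(x, event_time, window, fs = 1000) {
  i0 <- round((event_time + window$start_offset) * fs / 1000) + 1
  i1 <- round((event_time + window$end_offset) * fs / 1000)
  if (i0 < 1 || i1 > length(x)) {
    stop("analysis window extends beyond recorded trial span")
  }
  x[i0:i1]
}

#' Detect the dominant beta frequency
#'
#' Averages the periodogram of equal-length signal segments (one per trial,
#' typically the extended 1000 ms wait window of a neighbor-averaged LFP)
#' and returns the frequency of maximum power within the search band. With
#' 1000 ms segments at 1 kHz the resolution is 1 Hz. Ties break toward the
#' lower frequency.
#'
#' @param segments List of equal-length numeric vectors, or a single vector.
#' @param fs Sampling rate in Hz (default 1000).
#' @param band Search band in Hz (default `c(10, 45)`).
#' @param half_width Half bandwidth of the resulting band in Hz (default 5).
#' @return List of class `beta_band` with `peak_frequency`, `half_width`,
#'   `frequencies` and `power` (the averaged spectrum in the band).
#' @export
detect_peak_beta <- function(segments, fs = 1000, band = c(10, 45),
                             half_width = 5) {
  if (is.numeric(segments)) segments <- list(segments)
  n <- unique(lengths(segments))
  if (length(n) != 1) stop("all segments must have equal length")
  pw <- Reduce(`+`, lapply(segments, function(x) {
    Mod(stats::fft(x - mean(x)))^2 / n
  })) / length(segments)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep) || all(pw[keep] == 0)) {
    stop("flat spectrum in search band; cannot detect a beta peak")
  }
  f_band <- freqs[keep]
  p_band <- pw[keep]
  peak <- f_band[which.max(p_band)]   # first max = lowest frequency on ties
  structure(list(peak_frequency = peak, half_width = half_width,
                 frequencies = f_band, power = p_band),
            class = "beta_band")
}

#' Zero-phase bandpass filter around the beta peak
#'
#' 4-pole Butterworth bandpass at `peak +/- half_width` Hz, applied
#' forward-backward (`signal::filtfilt`) so the net phase shift is zero.
#' The filter is applied to the entire trial, not per analysis window, so
#' filter edge effects stay at the trial edges.
#'
#' @param x Full-trial signal vector.
#' @param band A `beta_band` from [detect_peak_beta()], or a numeric
#'   `c(low, high)` in Hz.
#' @param fs Sampling rate in Hz (default 1000).
#' @param order Butterworth order of the underlying one-pass design
#'   (default 4; the forward-backward application doubles the effective
#'   roll-off).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, band, fs = 1000, order = 4) {
  if (inherits(band, "beta_band")) {
    band <- band$peak_frequency + c(-1, 1) * band$half_width
  }
  stopifnot(length(band) == 2, band[1] > 0)
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Instantaneous phase via the analytic signal
#'
#' Phase angle of the analytic (Hilbert-transformed) signal, in
#' `(-pi, pi]`. For a band-limited oscillation the phase is 0 at a local
#' maximum and passes +pi/2 at the following downward zero crossing.
#'
#' @param x Band-limited real signal.
#' @return Phase vector in radians, same length as `x`.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(analytic)
  ph[ph <= -pi] <- pi  # negative-zero imaginary parts map -pi to +pi
  ph
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Resultant length `R = |sum exp(i phi)| / n`, test statistic `Z = n R^2`,
#' and the standard finite-sample-corrected p-value approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2))`,
#' clamped to `(0, 1]`.
#'
#' @param phases Numeric vector of phases in radians.
#' @return List with `n`, `resultant_length`, `mean_phase`, `z`, `p_value`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0) {
    return(list(n = 0L, resultant_length = NA_real_, mean_phase = NA_real_,
                z = NA_real_, p_value = NA_real_))
  }
  s <- sum(exp(1i * phases))
  r <- Mod(s) / n
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(n = as.integer(n), resultant_length = r, mean_phase = Arg(s),
       z = z, p_value = p)
}

#' Beta phase at each in-window spike of one unit
#'
#' Reads the instantaneous phase at each spike's sample index, for spikes
#' inside the (extended) analysis window, pooled over trials. Spikes outside
#' the recorded LFP span are skipped with a warning.
#'
#' @param session A [spike_session()].
#' @param unit_id Unit identifier.
#' @param window Extended [epoch_window()].
#' @param phase_by_trial Named list (trial id -> full-trial phase vector)
#'   from [instantaneous_phase()] of the unit's electrode's
#'   neighbor-averaged, beta-filtered LFP.
#' @param trial_type Optional trial type restriction.
#' @return Numeric vector of spike phases in radians.
#' @export
spike_phases <- function(session, unit_id, window, phase_by_trial,
                         trial_type = NULL) {
  tr <- session_trials(session, trial_type)
  ev <- tr[[window$align_event]]
  phases <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(tr))) {
    tid <- as.character(tr$trial_id[i])
    ph <- phase_by_trial[[tid]]
    if (is.null(ph)) next
    st <- session$spikes[[as.character(unit_id)]][[tid]]
    if (is.null(st) || length(st) == 0) next
    al <- st - ev[i]
    st_in <- st[in_window(al, window)]
    idx <- round(st_in) + 1  # sample k covers [k-1, k) ms at 1 kHz
    ok <- idx >= 1 & idx <= length(ph)
    n_skipped <- n_skipped + sum(!ok)
    phases <- c(phases, ph[idx[ok]])
  }
  if (n_skipped > 0) {
    warning(sprintf("unit %s: %d spike(s) outside the recorded LFP span",
                    unit_id, n_skipped))
  }
  phases
}

#' Phase locking of all units of a session
#'
#' Full phase-locking pipeline for one trial type: per electrode carrying
#' units, the neighbor-averaged LFP is computed, the beta peak is detected
#' from the extended wait window, the whole-trial signal is beta-filtered
#' with zero phase and Hilbert-transformed, and each unit's spike phases in
#' both extended windows are submitted to the Rayleigh test. A unit counts
#' as tested in a window when it has more than `min_spikes` spikes there,
#' and as locked when additionally `p < alpha`.
#'
#' @param session A [spike_session()] with LFP, layout and units.
#' @param trial_type Trial type label.
#' @param windows Named list with `wait_extended` and `movement_extended`
#'   windows; default from [default_windows()] using the session profile.
#' @param min_spikes Spikes required for testing (default 30, strict).
#' @param alpha Significance level of the Rayleigh test (default 0.05).
#' @param include_center Passed to [neighbor_average_lfp()].
#' @param snr_threshold Units at or below this SNR are skipped (default 2.5).
#' @return Data frame with one row per unit x window: `unit_id`,
#'   `electrode_id`, `window`, `n_spikes`, `resultant_length`, `mean_phase`,
#'   `rayleigh_p`, `tested`, `locked`, `beta_peak_hz`. The per-spike phases
#'   are attached as the `"phases"` attribute (a named list keyed by
#'   `unit_id.window`).
#' @export
phase_locking <- function(session, trial_type,
                          windows = NULL, min_spikes = 30, alpha = 0.05,
                          include_center = FALSE, snr_threshold = 2.5) {
  if (is.null(session$lfp)) {
    stop("phase locking requires LFP data; session has none")
  }
  windows <- windows %||%
    default_windows(session$meta$monkey_profile)[c("wait_extended",
                                                   "movement_extended")]
  fs <- session$meta$sampling_rate
  tr <- session_trials(session, trial_type)
  units <- session$units[session$units$snr > snr_threshold, , drop = FALSE]
  rows <- list()
  phase_dump <- list()
  for (el in unique(units$electrode_id)) {
    avg <- neighbor_average_lfp(session, el, include_center = include_center,
                                trial_ids = tr$trial_id)
    wwin <- windows$wait_extended
    segs <- lapply(seq_len(nrow(tr)), function(i) {
      trial_segment(avg[[as.character(tr$trial_id[i])]],
                    tr[[wwin$align_event]][i], wwin, fs)
    })
    beta <- detect_peak_beta(segs, fs = fs)
    phase_by_trial <- lapply(avg, function(x) {
      instantaneous_phase(bandpass_zero_phase(x, beta, fs = fs))
    })
    for (uid in units$unit_id[units$electrode_id == el]) {
      for (wname in names(windows)) {
        ph <- spike_phases(session, uid, windows[[wname]], phase_by_trial,
                           trial_type = trial_type)
        rt <- rayleigh_test(ph)
        tested <- rt$n > min_spikes
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, electrode_id = el, window = wname,
          n_spikes = rt$n, resultant_length = rt$resultant_length,
          mean_phase = rt$mean_phase, rayleigh_p = rt$p_value,
          tested = tested,
          locked = tested && !is.na(rt$p_value) && rt$p_value < alpha,
          beta_peak_hz = beta$peak_frequency)
        phase_dump[[paste(uid, wname, sep = ".")]] <- ph
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "phases") <- phase_dump
  out
}

#' Percentage of phase-locked units per window
#'
#' Among units tested in a window (more than the minimum spike count), the
#' percentage whose Rayleigh test is significant. The denominator is
#' per-window: the set of tested units may differ between windows.
#'
#' @param results Data frame from [phase_locking()].
#' @param window Window name, e.g. `"wait_extended"`.
#' @return Percentage in `[0, 100]`, or `NA_real_` if no unit was tested.
#' @export
locked_fraction <- function(results, window) {
  df <- results[results$window == window & results$tested, , drop = FALSE]
  if (nrow(df) == 0) return(NA_real_)
  100 * sum(df$locked) / nrow(df)
}

#' Trial-averaged LFP spectrogram (diagnostic)
#'
#' Short-time power estimate of per-trial signals, averaged across trials.
#' Intended for visual checks of the task-locked beta envelope, not for
#' quantitative claims.
#'
#' @param signals List of equal-length per-trial signal vectors.
#' @param fs Sampling rate in Hz (default 1000).
#' @param window_ms STFT window length in ms (default 256).
#' @param overlap Fractional window overlap (default 0.9).
#' @return List of class `spectrogram_grid` with `times` (ms), `frequencies`
#'   (Hz) and `power` (frequencies x times matrix, >= 0).
#' @export
lfp_spectrogram <- function(signals, fs = 1000, window_ms = 256,
                            overlap = 0.9) {
  if (is.numeric(signals)) signals <- list(signals)
  nwin <- round(window_ms * fs / 1000)
  step <- max(1, round(nwin * (1 - overlap)))
  pw <- NULL
  for (x in signals) {
    sp <- signal::specgram(x, n = nwin, Fs = fs, overlap = nwin - step)
    p <- Mod(sp$S)^2
    pw <- if (is.null(pw)) p else pw + p
  }
  structure(list(times = sp$t * 1000, frequencies = sp$f,
                 power = pw / length(signals)),
            class = "spectrogram_grid")
}
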