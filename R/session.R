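#' @keywords internal
"_PACKAGE"

# Canonical task event order within a trial.
EVENT_NAMES <- c("TS", "WS", "CueOn", "CueOff", "GO", "SR", "Rew")

GRIP_LEVELS <- c("SG", "PG")
FORCE_LEVELS <- c("LF", "HF")

#' Trial type labels
#'
#' The task crosses two grip types (side grip SG, precision grip PG) with two
#' force levels (low LF, high HF), giving exactly four trial types.
#'
#' @return Character vector of the four trial type labels,
#'   e.g. `"SG-HF"`.
#' @export
trial_types <- function() {
  as.vector(outer(GRIP_LEVELS, FORCE_LEVELS, paste, sep = "-"))
}

#' Construct an analysis epoch window
#'
#' An epoch window is an alignment event plus a half-open offset interval
#' `[start_offset, end_offset)` in milliseconds. The two main analysis epochs
#' (`wait`, `movement`) are 500 ms long; the extended windows used for phase
#' locking are 1000 ms long. Half-open intervals make adjacent windows
#' partition time, so spike counts are additive across abutting windows.
#'
#' @param name One of `"wait"`, `"movement"`, `"wait_extended"`,
#'   `"movement_extended"`.
#' @param align_event Task event name the offsets are relative to.
#' @param start_offset,end_offset Window edges in ms relative to the
#'   alignment event; the window is `[start_offset, end_offset)`.
#' @return An object of class `epoch_window`.
#' @export
epoch_window <- function(name, align_event, start_offset, end_offset) {
  name <- match.arg(name, c("wait", "movement", "wait_extended",
                            "movement_extended"))
  align_event <- match.arg(align_event, EVENT_NAMES)
  stopifnot(is.numeric(start_offset), is.numeric(end_offset),
            end_offset > start_offset)
  len <- end_offset - start_offset
  expected <- if (grepl("extended$", name)) 1000 else 500
  if (len != expected) {
    stop(sprintf("window '%s' must span %d ms, got %g ms", name, expected, len))
  }
  structure(list(name = name, align_event = align_event,
                 start_offset = start_offset, end_offset = end_offset),
            class = "epoch_window")
}

#' @export
print.epoch_window <- function(x, ...) {
  cat(sprintf("<epoch_window> %s: [%s%+g, %s%+g) ms\n", x$name,
              x$align_event, x$start_offset, x$align_event, x$end_offset))
  invisible(x)
}

#' Default analysis windows per monkey profile
#'
#' The wait epoch is the first 500 ms of the preparatory delay, starting at
#' cue offset, where firing rates are most stationary. The movement epoch is
#' centred on the peak of movement-related activity around switch release
#' (SR): animals with fast reaction times engage the movement earlier
#' relative to SR, so the `fast` profile uses `[SR-150, SR+350)` while the
#' `slow` profile uses `[SR, SR+500)`. The extended 1000 ms windows are used
#' for spike-to-LFP phase locking.
#'
#' @param monkey_profile `"fast"` or `"slow"` reaction-time profile.
#' @return Named list of [epoch_window()] objects: `wait`, `movement`,
#'   `wait_extended`, `movement_extended`.
#' @export
default_windows <- function(monkey_profile = c("fast", "slow")) {
  monkey_profile <- match.arg(monkey_profile)
  mv <- if (monkey_profile == "fast") {
    epoch_window("movement", "SR", -150, 350)
  } else {
    epoch_window("movement", "SR", 0, 500)
  }
  list(
    wait = epoch_window("wait", "CueOff", 0, 500),
    movement = mv,
    wait_extended = epoch_window("wait_extended", "CueOff", -500, 500),
    movement_extended = epoch_window("movement_extended", "SR", -400, 600)
  )
}

#' Electrode layout of a 10 x 10 array with unconnected corners
#'
#' Standard 100-site grid in which the four corner sites are not wired,
#' leaving 96 connected electrodes numbered row-wise.
#'
#' @return Data frame with columns `electrode_id`, `row`, `col`.
#' @export
grid_layout_96 <- function() {
  g <- expand.grid(col = 1:10, row = 1:10)[, c("row", "col")]
  corner <- (g$row %in% c(1, 10)) & (g$col %in% c(1, 10))
  g <- g[!corner, , drop = FALSE]
  g$electrode_id <- seq_len(nrow(g))
  rownames(g) <- NULL
  g[, c("electrode_id", "row", "col")]
}

#' Construct a trial-segmented session
#'
#' Container for one recording session: a trial table with task event times
#' (per-trial clock, 0 at trial start TS), spike times per unit and trial at
#' 1 ms resolution, optional per-electrode LFP traces at `sampling_rate`, the
#' electrode grid layout, and metadata (monkey profile, dead time).
#'
#' @param trials Data frame with columns `trial_id`, `grip`, `force`,
#'   `correct`, `duration_ms` and one column per event in
#'   `TS, WS, CueOn, CueOff, GO, SR, Rew` (ms, `NA` allowed for absent
#'   events).
#' @param units Data frame with columns `unit_id`, `electrode_id`, `snr`.
#' @param spikes Named list (by `unit_id`) of named lists (by `trial_id`) of
#'   integer spike-time vectors in ms on the trial clock.
#' @param lfp Optional named list (by `electrode_id`) of named lists (by
#'   `trial_id`) of numeric sample vectors covering the trial span.
#' @param layout Data frame as returned by [grid_layout_96()], or `NULL`.
#' @param meta List with at least `monkey_profile` (`"fast"`/`"slow"`),
#'   `sampling_rate` (Hz, default 1000) and `dead_time_ms` (default 1.3).
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(trials, units, spikes, lfp = NULL, layout = NULL,
                          meta = list(), validate = TRUE) {
  meta$sampling_rate <- meta$sampling_rate %||% 1000
  meta$dead_time_ms <- meta$dead_time_ms %||% 1.3
  meta$monkey_profile <- meta$monkey_profile %||% "fast"
  s <- structure(list(trials = trials, units = units, spikes = spikes,
                      lfp = lfp, layout = layout, meta = meta),
                 class = "spike_session")
  if (validate) validate_session(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate session invariants
#'
#' Checks event-time ordering within each trial, strict monotonicity and
#' dead-time separation of spike times, LFP coverage of the trial span, and
#' layout consistency. Stops with an informative error naming the offending
#' trial or unit on violation.
#'
#' @param session A [spike_session()].
#' @return The session, invisibly.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  need <- c("trial_id", "grip", "force", "correct", "duration_ms")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trials table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tr$trial_id)) stop("duplicated trial_id in trials table")
  if (!all(tr$grip %in% GRIP_LEVELS)) stop("invalid grip label")
  if (!all(tr$force %in% FORCE_LEVELS)) stop("invalid force label")
  ev_cols <- intersect(EVENT_NAMES, names(tr))
  for (i in seq_len(nrow(tr))) {
    ev <- unlist(tr[i, ev_cols])
    ev <- ev[!is.na(ev)]
    if (length(ev) > 1 && any(diff(ev) <= 0)) {
      stop(sprintf("trial %s: event times not strictly increasing",
                   tr$trial_id[i]))
    }
    if (!is.na(tr$GO[i]) && !is.na(tr$SR[i]) && tr$SR[i] < tr$GO[i]) {
      stop(sprintf("trial %s: negative reaction time", tr$trial_id[i]))
    }
  }
  dead <- session$meta$dead_time_ms
  for (uid in names(session$spikes)) {
    for (tid in names(session$spikes[[uid]])) {
      st <- session$spikes[[uid]][[tid]]
      if (length(st) > 1) {
        d <- diff(st)
        if (any(d <= 0)) {
          stop(sprintf("unit %s trial %s: spike times not strictly increasing",
                       uid, tid))
        }
        if (any(d < dead)) {
          stop(sprintf("unit %s trial %s: inter-spike interval below dead time",
                       uid, tid))
        }
      }
    }
  }
  if (!is.null(session$lfp)) {
    fs <- session$meta$sampling_rate
    dur <- stats::setNames(tr$duration_ms, as.character(tr$trial_id))
    for (el in names(session$lfp)) {
      for (tid in names(session$lfp[[el]])) {
        n <- length(session$lfp[[el]][[tid]])
        expect <- round(dur[[tid]] * fs / 1000)
        if (abs(n - expect) > 1) {
          stop(sprintf("electrode %s trial %s: %d LFP samples, expected %d",
                       el, tid, n, expect))
        }
      }
    }
  }
  if (!is.null(session$layout)) {
    if (anyDuplicated(session$layout$electrode_id)) {
      stop("layout: duplicated electrode_id")
    }
  }
  invisible(session)
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf(
    "<spike_session> %d trials (%d correct), %d units, %s LFP channels\n",
    nrow(x$trials), sum(x$trials$correct), nrow(x$units),
    if (is.null(x$lfp)) "no" else as.character(length(x$lfp))))
  cat(sprintf("  profile: %s, dead time %.1f ms, fs %g Hz\n",
              x$meta$monkey_profile, x$meta$dead_time_ms,
              x$meta$sampling_rate))
  invisible(x)
}

#' Subset the trial table by type and correctness
#'
#' @param session A [spike_session()].
#' @param trial_type Trial type label such as `"SG-HF"`, or `NULL` for all.
#' @param correct_only Keep only correct trials (default `TRUE`).
#' @return Subset of `session$trials`.
#' @export
session_trials <- function(session, trial_type = NULL, correct_only = TRUE) {
  tr <- session$trials
  if (correct_only) tr <- tr[tr$correct, , drop = FALSE]
  if (!is.null(trial_type)) {
    tt <- paste(tr$grip, tr$force, sep = "-")
    tr <- tr[tt == trial_type, , drop = FALSE]
  }
  tr
}

#' Align a unit's spikes to an epoch window's event
#'
#' Re-expresses each trial's spike times relative to the window's alignment
#' event. The full aligned train is kept, not clipped to the window, because
#' local-irregularity m-values anchored just inside the window may need the
#' flanking spikes outside it. In-window membership is always evaluated on
#' the half-open interval `[start_offset, end_offset)`.
#'
#' @param session A [spike_session()].
#' @param unit_id Unit identifier present in `session$units`.
#' @param window An [epoch_window()].
#' @param trial_type Optional trial type label to restrict to.
#' @param correct_only Restrict to correct trials (default `TRUE`).
#' @return Object of class `aligned_trains`: list with `trial_ids`, `trains`
#'   (list of aligned spike-time vectors, one per trial), and `window`.
#' @export
align_spikes <- function(session, unit_id, window, trial_type = NULL,
                         correct_only = TRUE) {
  stopifnot(inherits(window, "epoch_window"))
  uid <- as.character(unit_id)
  if (!uid %in% names(session$spikes)) {
    stop(sprintf("unknown unit '%s'", uid))
  }
  tr <- session_trials(session, trial_type, correct_only)
  ev <- tr[[window$align_event]]
  if (any(is.na(ev))) {
    bad <- tr$trial_id[which(is.na(ev))[1]]
    stop(sprintf("trial %s is missing align event '%s'", bad,
                 window$align_event))
  }
  tid <- as.character(tr$trial_id)
  trains <- lapply(seq_along(tid), function(i) {
    st <- session$spikes[[uid]][[tid[i]]]
    if (is.null(st)) numeric(0) else st - ev[i]
  })
  names(trains) <- tid
  structure(list(trial_ids = tr$trial_id, trains = trains, window = window),
            class = "aligned_trains")
}

# Count of spikes falling in the half-open window [start, end).
in_window <- function(x, window) {
  x >= window$start_offset & x < window$end_offset
}

#' Per-trial spike counts inside the window
#'
#' @param aligned An `aligned_trains` object from [align_spikes()].
#' @return Integer vector of in-window spike counts, one per trial.
#' @export
window_counts <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_trains"))
  vapply(aligned$trains,
         function(tr) sum(in_window(tr, aligned$window)), integer(1))
}
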