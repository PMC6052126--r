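# Plain-text session bundle: a directory holding meta.json, trials.csv,
# units.csv, layout.csv, spikes/<unit_id>.csv and lfp/<electrode_id>.csv.
# Spike times are integers in ms; LFP samples are written at full double
# precision so a write -> read round trip is lossless.

#' Write a session bundle
#'
#' Serialises a [spike_session()] to a directory of plain-text files:
#' `meta.json` (profile, sampling rate, dead time), `trials.csv`,
#' `units.csv`, `layout.csv`, one `spikes/<unit_id>.csv` per unit
#' (columns `trial_id`, `spike_time_ms`) and one `lfp/<electrode_id>.csv`
#' per channel (columns `trial_id`, `value`, samples in order within trial).
#'
#' @param session A [spike_session()].
#' @param path Directory to create (must not already contain a bundle).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(session$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(session$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  if (!is.null(session$layout)) {
    utils::write.csv(session$layout, file.path(path, "layout.csv"),
                     row.names = FALSE)
  }
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  for (uid in names(session$spikes)) {
    rows <- lapply(names(session$spikes[[uid]]), function(tid) {
      st <- session$spikes[[uid]][[tid]]
      if (length(st) == 0) return(NULL)
      data.frame(trial_id = tid, spike_time_ms = st)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(trial_id = character(0),
                                      spike_time_ms = numeric(0))
    utils::write.csv(df, file.path(path, "spikes", paste0(uid, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(session$lfp)) {
    dir.create(file.path(path, "lfp"), showWarnings = FALSE)
    for (el in names(session$lfp)) {
      rows <- lapply(names(session$lfp[[el]]), function(tid) {
        data.frame(trial_id = tid,
                   value = sprintf("%.17g", session$lfp[[el]][[tid]]))
      })
      df <- do.call(rbind, rows)
      utils::write.csv(df, file.path(path, "lfp", paste0(el, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' Read a session bundle
#'
#' Inverse of [write_session()]. A bundle without an `lfp/` directory loads
#' with `lfp = NULL`; the phase-locking stages then refuse to run. Schema
#' violations (missing columns, non-monotone spike times, dead-time
#' violations) raise errors naming the offending file, unit or trial.
#'
#' @param path Bundle directory.
#' @return A validated [spike_session()].
#' @export
read_session <- function(path) {
  req <- c("meta.json", "trials.csv", "units.csv")
  for (f in req) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("session bundle '%s' is missing '%s'", path, f))
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  units <- utils::read.csv(file.path(path, "units.csv"),
                           stringsAsFactors = FALSE)
  units$unit_id <- as.character(units$unit_id)
  layout <- NULL
  if (file.exists(file.path(path, "layout.csv"))) {
    layout <- utils::read.csv(file.path(path, "layout.csv"))
  }
  spikes <- list()
  for (uid in units$unit_id) {
    f <- file.path(path, "spikes", paste0(uid, ".csv"))
    if (!file.exists(f)) {
      stop(sprintf("session bundle '%s' is missing spike file for unit '%s'",
                   path, uid))
    }
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!all(c("trial_id", "spike_time_ms") %in% names(df))) {
      stop(sprintf("file '%s': expected columns trial_id, spike_time_ms", f))
    }
    sp <- split(df$spike_time_ms, as.character(df$trial_id))
    for (tid in names(sp)) {
      if (is.unsorted(sp[[tid]], strictly = TRUE)) {
        stop(sprintf("unit %s trial %s: spike times not strictly increasing",
                     uid, tid))
      }
    }
    # canonical form: one entry per trial, in trial-table order
    all_tid <- as.character(trials$trial_id)
    full <- stats::setNames(
      lapply(all_tid, function(tid) {
        v <- sp[[tid]]
        if (is.null(v)) numeric(0) else v
      }), all_tid)
    spikes[[uid]] <- full
  }
  lfp <- NULL
  lfp_dir <- file.path(path, "lfp")
  if (dir.exists(lfp_dir)) {
    lfp <- list()
    for (f in list.files(lfp_dir, pattern = "\\.csv$", full.names = TRUE)) {
      el <- sub("\\.csv$", "", basename(f))
      df <- utils::read.csv(f, stringsAsFactors = FALSE)
      ch <- split(df$value, as.character(df$trial_id))
      lfp[[el]] <- ch[order(match(names(ch), as.character(trials$trial_id)))]
    }
    # electrode keys in numeric order when they are numeric
    num <- suppressWarnings(as.numeric(names(lfp)))
    if (!anyNA(num)) lfp <- lfp[order(num)]
  }
  spike_session(trials = trials, units = units, spikes = spikes, lfp = lfp,
                layout = layout, meta = as.list(meta))
}
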