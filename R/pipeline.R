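# Context comparisons between the wait and movement epochs, and the
# end-to-end analysis orchestrator.

FEATURES <- c("cv2", "ff", "rate")

# Internal: wide per-unit table of one feature for both epochs, restricted
# to units selected in both epochs.
paired_feature <- function(results, feature,
                           epochs = c("wait", "movement")) {
  sel <- select_units(results, "both_epochs")
  w <- results[results$epoch == epochs[1] & results$unit_id %in% sel, ]
  m <- results[results$epoch == epochs[2] & results$unit_id %in% sel, ]
  m <- m[match(w$unit_id, m$unit_id), ]
  data.frame(unit_id = w$unit_id, wait = w[[feature]],
             movement = m[[feature]])
}

#' Population summary of a feature per epoch with rank-sum comparison
#'
#' Medians of CV2, FF and firing rate over the units selected in each epoch
#' (the `either_epoch` rule: the unit sets may differ between epochs), and a
#' two-sided Wilcoxon rank-sum test comparing the two epoch populations
#' (normal approximation with tie correction).
#'
#' @param results Combined [unit_variability()] rows for both epochs of one
#'   trial type.
#' @param features Features to summarise (default CV2, FF, rate).
#' @param epochs Epoch names, first is the reference (default wait,
#'   movement).
#' @return Data frame with one row per feature: `feature`, `median_wait`,
#'   `median_movement`, `p_value`, `n_wait`, `n_movement`.
#' @export
epoch_population_summary <- function(results, features = FEATURES,
                                     epochs = c("wait", "movement")) {
  sel <- select_units(results, "either_epoch")
  rows <- lapply(features, function(f) {
    x <- results[results$epoch == epochs[1] &
                   results$unit_id %in% sel[[epochs[1]]], f]
    y <- results[results$epoch == epochs[2] &
                   results$unit_id %in% sel[[epochs[2]]], f]
    p <- if (length(x) >= 2 && length(y) >= 2) {
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    } else {
      NA_real_
    }
    data.frame(feature = f, median_wait = stats::median(x),
               median_movement = stats::median(y), p_value = p,
               n_wait = length(x), n_movement = length(y))
  })
  do.call(rbind, rows)
}

#' Paired per-unit values across epochs with Spearman correlation
#'
#' For units selected in both epochs, pairs each feature's wait value with
#' its movement value, reports the percentage of units whose value is
#' strictly higher during movement, and the Spearman rank correlation
#' between epochs.
#'
#' @inheritParams epoch_population_summary
#' @return List with `pairs` (long data frame: `unit_id`, `feature`,
#'   `wait`, `movement`) and `summary` (per feature: `pct_higher_movement`,
#'   `rho`, `rho_p`, `n`).
#' @export
paired_scatter_table <- function(results, features = FEATURES,
                                 epochs = c("wait", "movement")) {
  pairs <- do.call(rbind, lapply(features, function(f) {
    pf <- paired_feature(results, f, epochs)
    if (nrow(pf) == 0) return(NULL)
    cbind(pf[, "unit_id", drop = FALSE], feature = f,
          pf[, c("wait", "movement")])
  }))
  summary <- do.call(rbind, lapply(features, function(f) {
    pf <- pairs[pairs$feature == f, , drop = FALSE]
    n <- nrow(pf)
    if (n < 2) {
      return(data.frame(feature = f, pct_higher_movement = NA_real_,
                        rho = NA_real_, rho_p = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      stats::cor.test(pf$wait, pf$movement, method = "spearman"))
    data.frame(feature = f,
               pct_higher_movement = 100 * mean(pf$movement > pf$wait),
               rho = unname(ct$estimate), rho_p = ct$p.value, n = n)
  }))
  list(pairs = pairs, summary = summary)
}

#' Epoch contrast of paired values
#'
#' `C = (n_wait_higher - n_movement_higher) / (n_wait_higher +
#' n_movement_higher)`, over units with paired values in both epochs; ties
#' are excluded from both counts. Positive C means a larger share of units
#' with the higher value during wait; C is antisymmetric under swapping the
#' epochs and bounded in `[-1, 1]`.
#'
#' @param pairs Data frame with columns `wait` and `movement` (e.g. one
#'   feature's rows of [paired_scatter_table()]`$pairs`).
#' @param feature Optional label stored in the result.
#' @return Data frame of class `contrast_value` with `feature`, `c`,
#'   `n_higher_wait`, `n_higher_movement` (`c = NA` if all pairs tie).
#' @export
contrast_value <- function(pairs, feature = NA_character_) {
  ok <- !is.na(pairs$wait) & !is.na(pairs$movement)
  hw <- sum(pairs$wait[ok] > pairs$movement[ok])
  hm <- sum(pairs$movement[ok] > pairs$wait[ok])
  cval <- if (hw + hm == 0) NA_real_ else (hw - hm) / (hw + hm)
  structure(data.frame(feature = feature, c = cval, n_higher_wait = hw,
                       n_higher_movement = hm),
            class = c("contrast_value", "data.frame"))
}

#' Variability comparison within rate-profile subpopulations
#'
#' Splits the both-epochs-selected units by the sign of their firing-rate
#' change (movement rate above wait rate, or the converse; exact ties go to
#' the `mvt_gt_wait` side and are reported in the result) and, within each
#' subpopulation, compares CV2 and FF between epochs with medians and
#' rank-sum tests. Demonstrates that the epoch modulation of CV2 and FF is
#' not a by-product of the rate change direction.
#'
#' @inheritParams epoch_population_summary
#' @return List with `assignment` (unit_id, subpopulation), `n_ties`, and
#'   `summaries`: per subpopulation a data frame of medians and p-values
#'   for CV2 and FF (NULL for an empty subpopulation).
#' @export
split_by_rate_profile <- function(results, epochs = c("wait", "movement")) {
  pf <- paired_feature(results, "rate", epochs)
  n_ties <- sum(pf$movement == pf$wait)
  sub <- ifelse(pf$movement >= pf$wait, "mvt_gt_wait", "wait_gt_mvt")
  assignment <- data.frame(unit_id = pf$unit_id, subpopulation = sub)
  summaries <- lapply(split(pf$unit_id, sub), function(uids) {
    rows <- lapply(c("cv2", "ff"), function(f) {
      fp <- paired_feature(results, f, epochs)
      fp <- fp[fp$unit_id %in% uids, ]
      if (nrow(fp) == 0) return(NULL)
      p <- if (nrow(fp) >= 2) {
        stats::wilcox.test(fp$wait, fp$movement, exact = FALSE,
                           correct = TRUE)$p.value
      } else {
        NA_real_
      }
      data.frame(feature = f, median_wait = stats::median(fp$wait),
                 median_movement = stats::median(fp$movement),
                 p_value = p, n = nrow(fp))
    })
    do.call(rbind, rows)
  })
  list(assignment = assignment, n_ties = n_ties, summaries = summaries)
}

#' Renewal-prediction test: FF against CV2 squared
#'
#' A stationary renewal process predicts FF ~ CV^2; the per-unit ratio
#' FF / CV2^2 measures the deviation. Computed per epoch for units selected
#' in both epochs, with per-epoch median ratio and the fraction of units
#' whose ratio is strictly below 1 (a ratio of exactly 1 counts as "not
#' below"). Units with CV2 = 0 in an epoch are excluded from that epoch's
#' ratios and reported in `n_excluded`.
#'
#' @inheritParams epoch_population_summary
#' @return List with `rows` (per unit: FF, CV2^2 and ratio per epoch) and
#'   `summary` (per epoch: `median_ratio`, `pct_ratio_below_1`, `n`,
#'   `n_excluded`).
#' @export
renewal_test <- function(results, epochs = c("wait", "movement")) {
  ff <- paired_feature(results, "ff", epochs)
  cv2 <- paired_feature(results, "cv2", epochs)
  cv2 <- cv2[match(ff$unit_id, cv2$unit_id), ]
  rows <- data.frame(unit_id = ff$unit_id,
                     ff_wait = ff$wait, cv2sq_wait = cv2$wait^2,
                     ff_movement = ff$movement,
                     cv2sq_movement = cv2$movement^2)
  rows$ratio_wait <- ifelse(rows$cv2sq_wait > 0,
                            rows$ff_wait / rows$cv2sq_wait, NA_real_)
  rows$ratio_movement <- ifelse(rows$cv2sq_movement > 0,
                                rows$ff_movement / rows$cv2sq_movement,
                                NA_real_)
  summarise <- function(r) {
    ok <- !is.na(r)
    data.frame(median_ratio = stats::median(r[ok]),
               pct_ratio_below_1 = 100 * mean(r[ok] < 1),
               n = sum(ok), n_excluded = sum(!ok))
  }
  summary <- cbind(epoch = epochs,
                   rbind(summarise(rows$ratio_wait),
                         summarise(rows$ratio_movement)))
  list(rows = rows, summary = summary)
}

#' Run the full context-dependent variability analysis
#'
#' For each requested trial type: per-unit variability in the wait and
#' movement epochs, unit selection, population summaries, paired
#' comparisons with contrasts, the rate-profile subpopulation split, the
#' FF-versus-CV2^2 renewal test, and (when LFP data are present) the beta
#' phase-locking analysis. Writes tidy CSV files, a log, and diagnostic
#' plots into `out_dir`; any stage failure aborts the run, removes partial
#' outputs and names the failing stage.
#'
#' @param session A [spike_session()] or a bundle path for [read_session()].
#' @param out_dir Output directory (created; must not exist or be empty).
#' @param trial_types Trial type labels to analyze (default all four).
#' @param windows Named list of epoch windows; default
#'   [default_windows()] for the session's monkey profile.
#' @param min_rate,min_m,snr_threshold,min_spikes_phase,alpha Selection and
#'   test thresholds (defaults 5 spikes/s, 20 m-values, SNR 2.5, 30 spikes,
#'   0.05).
#' @param include_center Passed to the phase-locking stage.
#' @param do_phase Run the phase-locking stage (default: LFP present).
#' @param plots Write diagnostic plots (default `TRUE`).
#' @return Invisibly, a named list of per-trial-type result lists
#'   (`variability`, `population`, `paired`, `contrasts`, `subpopulations`,
#'   `renewal`, `phase`).
#' @export
run_pipeline <- function(session, out_dir, trial_types = NULL,
                         windows = NULL, min_rate = 5, min_m = 20,
                         snr_threshold = 2.5, min_spikes_phase = 30,
                         alpha = 0.05, include_center = FALSE,
                         do_phase = NULL, plots = TRUE) {
  if (is.character(session)) session <- read_session(session)
  if (dir.exists(out_dir) &&
      length(list.files(out_dir, all.files = TRUE, no.. = TRUE)) > 0) {
    stop("output directory exists and is not empty: ", out_dir)
  }
  all_types <- trial_types()
  trial_types <- trial_types %||% all_types
  windows <- windows %||% default_windows(session$meta$monkey_profile)
  do_phase <- do_phase %||% !is.null(session$lfp)
  if (do_phase && is.null(session$lfp)) {
    stop("phase-locking stage requested but session has no LFP data")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
    message(msg)
  }
  stage <- "setup"
  out <- list()
  tryCatch({
    for (tt in trial_types) {
      logmsg("trial type %s", tt)
      stage <- paste0("variability[", tt, "]")
      res <- rbind(
        unit_variability(session, windows$wait, tt, min_rate = min_rate,
                         min_m = min_m, snr_threshold = snr_threshold),
        unit_variability(session, windows$movement, tt,
                         min_rate = min_rate, min_m = min_m,
                         snr_threshold = snr_threshold))
      stage <- paste0("context[", tt, "]")
      pop <- epoch_population_summary(res)
      paired <- paired_scatter_table(res)
      contrasts <- do.call(rbind, lapply(FEATURES, function(f) {
        contrast_value(paired$pairs[paired$pairs$feature == f, ,
                                    drop = FALSE], feature = f)
      }))
      subpop <- split_by_rate_profile(res)
      renew <- renewal_test(res)
      phase <- NULL
      if (do_phase) {
        stage <- paste0("phase_locking[", tt, "]")
        phase <- phase_locking(
          session, tt,
          windows = windows[c("wait_extended", "movement_extended")],
          min_spikes = min_spikes_phase, alpha = alpha,
          include_center = include_center, snr_threshold = snr_threshold)
      }
      stage <- paste0("report[", tt, "]")
      dir_tt <- file.path(out_dir, tt)
      dir.create(dir_tt, showWarnings = FALSE)
      wcsv <- function(df, name) {
        utils::write.csv(df, file.path(dir_tt, name), row.names = FALSE)
      }
      wcsv(res, "variability.csv")
      wcsv(pop, "population_summary.csv")
      wcsv(paired$pairs, "paired_values.csv")
      wcsv(paired$summary, "paired_summary.csv")
      wcsv(contrasts, "contrast.csv")
      wcsv(subpop$assignment, "subpopulation_assignment.csv")
      sub_sum <- do.call(rbind, lapply(names(subpop$summaries), function(s) {
        df <- subpop$summaries[[s]]
        if (is.null(df)) return(NULL)
        cbind(subpopulation = s, df)
      }))
      if (!is.null(sub_sum)) wcsv(sub_sum, "subpopulation_summary.csv")
      wcsv(renew$rows, "renewal_rows.csv")
      wcsv(renew$summary, "renewal_summary.csv")
      if (!is.null(phase)) {
        wcsv(phase, "phase_locking.csv")
        ph_dump <- attr(phase, "phases")
        dump_df <- do.call(rbind, lapply(names(ph_dump), function(k) {
          if (length(ph_dump[[k]]) == 0) return(NULL)
          parts <- strsplit(k, ".", fixed = TRUE)[[1]]
          data.frame(unit_id = parts[1], window = parts[2],
                     phase = ph_dump[[k]])
        }))
        if (!is.null(dump_df)) wcsv(dump_df, "spike_phases.csv")
      }
      if (plots) {
        stage <- paste0("plots[", tt, "]")
        plot_report(file.path(dir_tt, "report.pdf"), pop, paired, renew,
                    phase)
      }
      out[[tt]] <- list(variability = res, population = pop,
                        paired = paired, contrasts = contrasts,
                        subpopulations = subpop, renewal = renew,
                        phase = phase)
      logmsg("trial type %s done", tt)
    }
  }, error = function(e) {
    unlink(out_dir, recursive = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out)
}

#' Re-render the diagnostic plots of a finished pipeline run
#'
#' Reads the CSV outputs of [run_pipeline()] for one trial type and rebuilds
#' `report.pdf`. The CSVs are the contract surface; plots are regenerable.
#'
#' @param trial_dir Per-trial-type output directory of a pipeline run.
#' @param path Output PDF path (default `report.pdf` inside `trial_dir`).
#' @return `path`, invisibly.
#' @export
render_report <- function(trial_dir,
                          path = file.path(trial_dir, "report.pdf")) {
  rd <- function(name) {
    f <- file.path(trial_dir, name)
    if (file.exists(f)) utils::read.csv(f) else NULL
  }
  pop <- rd("population_summary.csv")
  pairs <- rd("paired_values.csv")
  rows <- rd("renewal_rows.csv")
  if (is.null(pop) || is.null(pairs) || is.null(rows)) {
    stop("not a pipeline output directory: ", trial_dir)
  }
  plot_report(path, pop, list(pairs = pairs), list(rows = rows),
              rd("phase_locking.csv"))
  invisible(path)
}

# Diagnostic plots: population bars, paired scatters, log-log FF vs CV2^2,
# and per-window locked fractions. Regenerable; the CSVs are the contract.
plot_report <- function(path, pop, paired, renew, phase) {
  grDevices::pdf(path, width = 9, height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  bp <- rbind(pop$median_wait, pop$median_movement)
  graphics::barplot(bp, beside = TRUE, names.arg = pop$feature,
                    col = c("black", "darkgreen"),
                    main = "population medians",
                    legend.text = c("wait", "movement"))
  for (f in unique(paired$pairs$feature)) {
    pf <- paired$pairs[paired$pairs$feature == f, ]
    graphics::plot(pf$wait, pf$movement, pch = 16, cex = 0.5,
                   xlab = "wait", ylab = "movement", main = f)
    graphics::abline(0, 1, col = "gray")
  }
  graphics::par(mfrow = c(1, 2))
  for (ep in c("wait", "movement")) {
    x <- renew$rows[[paste0("cv2sq_", ep)]]
    y <- renew$rows[[paste0("ff_", ep)]]
    ok <- x > 0 & y > 0
    graphics::plot(x[ok], y[ok], log = "xy", pch = 16, cex = 0.5,
                   col = if (ep == "wait") "black" else "darkgreen",
                   xlab = "CV2^2", ylab = "FF",
                   main = paste("renewal test,", ep))
    graphics::abline(0, 1, untf = TRUE, col = "gray")
  }
  if (!is.null(phase)) {
    graphics::par(mfrow = c(1, 1))
    lf <- vapply(c("wait_extended", "movement_extended"),
                 function(w) locked_fraction(phase, w), numeric(1))
    graphics::barplot(lf, names.arg = c("wait", "movement"),
                      col = c("black", "darkgreen"), ylab = "% locked",
                      main = "phase-locked units")
  }
  invisible(path)
}
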