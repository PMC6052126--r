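# Independent naive reference implementations used to cross-check the
# vectorised package code on tiny inputs, plus small fixture builders.

# Naive m-value enumeration: explicit loop over spike triplets.
naive_m_values <- function(trains, window) {
  out <- numeric(0)
  for (st in trains) {
    n <- length(st)
    if (n < 3) next
    for (j in 2:(n - 1)) {
      if (st[j] >= window$start_offset && st[j] < window$end_offset) {
        isi1 <- st[j] - st[j - 1]
        isi2 <- st[j + 1] - st[j]
        out <- c(out, 2 * abs(isi1 - isi2) / (isi1 + isi2))
      }
    }
  }
  out
}

# Naive Fano factor: per-trial counting loop, n-1 variance by hand.
naive_ff <- function(trains, window) {
  counts <- vapply(trains, function(st) {
    sum(st >= window$start_offset & st < window$end_offset)
  }, numeric(1))
  mu <- mean(counts)
  if (mu == 0) return(NA_real_)
  sum((counts - mu)^2) / (length(counts) - 1) / mu
}

# Von Mises sampler (Best & Fisher rejection algorithm).
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  (out + pi) %% (2 * pi) - pi
}

# Minimal hand-built session: 2 units, 3 correct SG-HF trials plus one
# error trial, optional 20 Hz LFP on a few electrodes.
make_toy_session <- function(with_lfp = FALSE, beta_hz = 20) {
  trials <- data.frame(
    trial_id = 1:4, grip = "SG", force = "HF",
    correct = c(TRUE, TRUE, TRUE, FALSE),
    TS = 0, WS = 400, CueOn = 800, CueOff = 1100, GO = 2100,
    SR = c(2300, 2320, 2280, 2400), Rew = c(3100, 3120, 3080, 3200),
    duration_ms = 3600)
  units <- data.frame(unit_id = c("u1", "u2"), electrode_id = c(12, 13),
                      snr = c(4, 3))
  mk <- function(base) {
    sp <- lapply(1:4, function(i) base + (i - 1) * 7)
    stats::setNames(sp, as.character(1:4))
  }
  spikes <- list(u1 = mk(c(1000, 1150, 1250, 1300, 1500, 1700, 2200)),
                 u2 = mk(c(900, 1200, 1400, 1450, 1650, 2000, 2500)))
  lfp <- NULL
  layout <- grid_layout_96()
  if (with_lfp) {
    els <- sort(unique(unlist(lapply(c(12, 13), function(e) {
      grid_neighbors(e, layout, include_center = TRUE)
    }))))
    tt <- (0:3599) / 1000
    lfp <- stats::setNames(lapply(els, function(e) {
      stats::setNames(lapply(1:4, function(i) cos(2 * pi * beta_hz * tt)),
                      as.character(1:4))
    }), as.character(els))
  }
  spike_session(trials = trials, units = units, spikes = spikes,
                lfp = lfp, layout = layout,
                meta = list(monkey_profile = "fast", sampling_rate = 1000,
                            dead_time_ms = 1.3))
}

# aligned_trains wrapper for bare per-trial spike lists in tests.
as_aligned <- function(trains, window) {
  if (is.null(names(trains))) names(trains) <- seq_along(trains)
  structure(list(trial_ids = names(trains), trains = trains,
                 window = window),
            class = "aligned_trains")
}
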