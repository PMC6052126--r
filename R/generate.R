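# Synthetic session generator.
#
# The base spiking model is a gamma renewal process (shape a parameterizes
# irregularity, CV = 1/sqrt(a); a = 1 is Poisson) with an optional absolute
# dead time, started in equilibrium so that windowed statistics are free of
# onset transients. Task-locked rate modulation and beta phase locking are
# produced by time-warping the stationary renewal process through
# operational time (the integral of the intensity). Trial-to-trial network
# state changes are modeled as a per-trial multiplicative log-normal gain on
# the waiting-period intensity: a doubly stochastic (Cox) modulation that
# inflates the Fano factor above CV^2 while leaving the local irregularity
# CV2 essentially untouched.

#' Equilibrium first spike of a stationary (dead-time) gamma renewal process
#'
#' Draws the forward recurrence time: the interval straddling the origin is
#' length-biased, which for an ISI `dead_time + Gamma(shape, scale)` is an
#' explicit mixture (`Gamma(shape)` with weight `dead_time/mu`,
#' `Gamma(shape+1)` with weight `1 - dead_time/mu`), and the origin falls
#' uniformly inside it.
#'
#' @param rate Mean firing rate, spikes/s.
#' @param shape Gamma shape parameter.
#' @param dead_time Absolute refractory dead time, ms.
#' @return Time of the first spike after 0, in ms.
#' @keywords internal
equilibrium_first_spike <- function(rate, shape, dead_time = 0) {
  mu <- 1000 / rate
  gmean <- mu - dead_time
  stopifnot(gmean > 0)
  sc <- gmean / shape
  v <- if (stats::runif(1) < dead_time / mu) {
    stats::rgamma(1, shape = shape, scale = sc)
  } else {
    stats::rgamma(1, shape = shape + 1, scale = sc)
  }
  stats::runif(1) * (dead_time + v)
}

#' Simulate a stationary gamma renewal spike train
#'
#' ISIs are `dead_time + Gamma(shape, scale)` with overall mean `1000/rate`
#' ms; the first interval is drawn from the stationary forward-recurrence
#' distribution so the process is in equilibrium from time 0.
#'
#' @param rate Mean firing rate, spikes/s.
#' @param shape Gamma shape (`1` = Poisson; CV of ISIs is
#'   `1/sqrt(shape)` when `dead_time = 0`).
#' @param duration_ms Train duration; spikes are returned in
#'   `[0, duration_ms)`.
#' @param dead_time Absolute dead time in ms (default 0).
#' @return Numeric vector of spike times in ms (continuous-valued).
#' @export
simulate_renewal_train <- function(rate, shape = 1, duration_ms,
                                   dead_time = 0) {
  mu <- 1000 / rate
  stopifnot(mu > dead_time, shape > 0, duration_ms >= 0)
  sc <- (mu - dead_time) / shape
  t0 <- equilibrium_first_spike(rate, shape, dead_time)
  if (t0 >= duration_ms) return(numeric(0))
  times <- t0
  last <- t0
  while (last < duration_ms) {
    n_chunk <- max(16L, ceiling((duration_ms - last) / mu * 1.4))
    isis <- dead_time + stats::rgamma(n_chunk, shape = shape, scale = sc)
    new <- last + cumsum(isis)
    times <- c(times, new)
    last <- new[length(new)]
  }
  times[times < duration_ms]
}

#' Task-locked intensity profile of one trial
#'
#' Baseline rate throughout the trial with a smooth Gaussian rate transient
#' centred on movement onset (SR), peaking at `base_rate * movement_gain`.
#' `movement_gain < 1` yields the minority profile of rate-decreasing units.
#'
#' @param events Named numeric vector or one-row data frame with at least
#'   `SR` (ms on the trial clock).
#' @param base_rate Baseline rate, spikes/s.
#' @param movement_gain Peak multiplicative rate factor at SR (default 1 =
#'   stationary).
#' @param duration_ms Trial duration.
#' @param sigma_ms Width (SD) of the movement transient (default 150 ms).
#' @param dt_ms Time step of the returned grid (default 1).
#' @return List with `time` (ms grid) and `rate` (spikes/s at each grid
#'   point).
#' @export
simulate_rate_profile <- function(events, base_rate, movement_gain = 1,
                                  duration_ms, sigma_ms = 150, dt_ms = 1) {
  tt <- seq(0, duration_ms - dt_ms, by = dt_ms)
  sr <- if (is.data.frame(events)) events$SR[1] else events[["SR"]]
  rate <- base_rate * (1 + (movement_gain - 1) *
                         exp(-(tt - sr)^2 / (2 * sigma_ms^2)))
  list(time = tt, rate = rate)
}

# Smooth weight that is 1 during the waiting period (up to GO), ramps
# linearly to 0 between GO and SR, and stays 0 afterwards. Used to confine
# the trial gain to the pre-movement period.
wait_weight <- function(time, events) {
  go <- if (is.data.frame(events)) events$GO[1] else events[["GO"]]
  sr <- if (is.data.frame(events)) events$SR[1] else events[["SR"]]
  w <- rep(0, length(time))
  w[time <= go] <- 1
  ramp <- time > go & time < sr
  w[ramp] <- (sr - time[ramp]) / (sr - go)
  w
}

# Weight confining beta phase locking to the cue/delay period: ramps up over
# 100 ms at cue onset and back to zero 300 ms before GO. The early cutoff
# mirrors beta desynchronisation around the GO signal and keeps the extended
# movement window (starting at SR - 400 ms, with reaction times of at least
# 100 ms) free of entrained spikes.
locking_weight <- function(time, events) {
  cue <- if (is.data.frame(events)) events$CueOn[1] else events[["CueOn"]]
  go <- if (is.data.frame(events)) events$GO[1] else events[["GO"]]
  knots_t <- c(0, cue, cue + 100, go - 400, go - 300, max(time))
  knots_w <- c(0, 0, 1, 1, 0, 0)
  stats::approx(knots_t, knots_w, xout = time, rule = 2, ties = "ordered")$y
}

#' Apply a per-trial multiplicative gain to an intensity profile
#'
#' Draws one log-normal gain with mean 1 and standard deviation
#' `trial_gain_sd` and multiplies the intensity by it. With
#' `scope = "wait"` the gain acts fully before GO and fades out linearly by
#' SR, so the movement period keeps near-renewal count statistics; with
#' `scope = "all"` the whole trial is scaled.
#'
#' @param intensity List with `time` and `rate` from
#'   [simulate_rate_profile()].
#' @param trial_gain_sd SD of the mean-1 log-normal gain (0 disables).
#' @param events Trial events (needed for `scope = "wait"`).
#' @param scope `"wait"` or `"all"`.
#' @return The intensity list with scaled `rate` and the drawn `gain`
#'   attached.
#' @export
apply_trial_gain <- function(intensity, trial_gain_sd, events = NULL,
                             scope = c("wait", "all")) {
  scope <- match.arg(scope)
  if (trial_gain_sd <= 0) {
    intensity$gain <- 1
    return(intensity)
  }
  sdlog <- sqrt(log(1 + trial_gain_sd^2))
  gain <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  if (scope == "all") {
    intensity$rate <- intensity$rate * gain
  } else {
    stopifnot(!is.null(events))
    w <- wait_weight(intensity$time, events)
    intensity$rate <- intensity$rate * (1 + (gain - 1) * w)
  }
  intensity$gain <- gain
  intensity
}

#' Simulate spikes from an intensity profile by operational-time warping
#'
#' Runs an equilibrium stationary gamma renewal process at unit rate in
#' operational time (the cumulative integral of the intensity) and maps the
#' spikes back to real time, giving an inhomogeneous renewal train whose
#' local statistics match the stationary process.
#'
#' @param intensity List with `time` (ms) and `rate` (spikes/s).
#' @param shape Gamma shape of the underlying renewal process.
#' @param dead_time Absolute dead time in ms applied in real time by
#'   discarding violating spikes (default 0).
#' @return Numeric vector of spike times in ms.
#' @export
simulate_inhomogeneous_train <- function(intensity, shape = 1,
                                         dead_time = 0) {
  dt <- diff(intensity$time[1:2])
  cum <- c(0, cumsum(intensity$rate) * dt / 1000)  # expected count
  total <- cum[length(cum)]
  if (total <= 0) return(numeric(0))
  # unit-mean renewal process over the operational span (1 op unit = one
  # expected spike); rate 1000 sp/s at a ms clock gives mean interval 1
  op <- simulate_renewal_train(rate = 1000, shape = shape,
                               duration_ms = total)
  if (length(op) == 0) return(numeric(0))
  grid <- c(intensity$time, intensity$time[length(intensity$time)] + dt)
  times <- stats::approx(cum, grid, xout = op, ties = "ordered")$y
  enforce_dead_time(times, dead_time)
}

# Drop spikes closer than the dead time to the previously kept spike.
enforce_dead_time <- function(times, dead_time) {
  if (dead_time <= 0 || length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= dead_time) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate phase-locked spikes
#'
#' Multiplies an intensity profile by a von Mises factor
#' `exp(kappa cos(phase - preferred)) / I0(kappa)` of the instantaneous beta
#' phase, then simulates through [simulate_inhomogeneous_train()]. The
#' `1/I0(kappa)` normalisation keeps the cycle-averaged rate at its
#' unmodulated value, so rate and locking strength are separately
#' controllable; `kappa = 0` reduces exactly to the unlocked generator.
#' `kappa` may be a vector over the time grid, e.g. high during the waiting
#' period and zero during movement.
#'
#' @param intensity List with `time` and `rate`.
#' @param phase Instantaneous oscillation phase (radians) on the same grid.
#' @param kappa Von Mises concentration, scalar or vector on the grid.
#' @param preferred_phase Preferred firing phase in radians (0 = beta peak).
#' @param shape Gamma shape of the underlying renewal process.
#' @param dead_time Dead time in ms.
#' @return Numeric vector of spike times in ms.
#' @export
simulate_phase_locked_spikes <- function(intensity, phase, kappa,
                                         preferred_phase = 0, shape = 1,
                                         dead_time = 0) {
  stopifnot(length(phase) == length(intensity$rate))
  if (any(kappa > 0)) {
    mod <- exp(kappa * cos(phase - preferred_phase)) / besselI(kappa, 0)
    intensity$rate <- intensity$rate * mod
  }
  simulate_inhomogeneous_train(intensity, shape = shape,
                               dead_time = dead_time)
}

#' LFP generator specification
#'
#' @param beta_frequency Beta oscillation frequency, Hz (10-45).
#' @param amp_rest,amp_wait,amp_movement,amp_reward Beta envelope amplitudes
#'   (arbitrary units) at rest, during cue presentation and the preparatory
#'   delay, during movement execution, and around reward. Defaults emulate
#'   the canonical motor-cortical pattern: strong beta during the delay,
#'   suppression during movement, rebound at reward.
#' @param noise_sd SD of channel-private broadband noise.
#' @param shared_fraction Weight of the common beta component in each
#'   channel's signal.
#' @return List of class `lfp_gen_spec`.
#' @export
lfp_gen_spec <- function(beta_frequency = 20, amp_rest = 0.3, amp_wait = 1,
                         amp_movement = 0.1, amp_reward = 0.6,
                         noise_sd = 0.5, shared_fraction = 1) {
  stopifnot(beta_frequency >= 10, beta_frequency <= 45,
            all(c(amp_rest, amp_wait, amp_movement, amp_reward) >= 0))
  structure(list(beta_frequency = beta_frequency, amp_rest = amp_rest,
                 amp_wait = amp_wait, amp_movement = amp_movement,
                 amp_reward = amp_reward, noise_sd = noise_sd,
                 shared_fraction = shared_fraction),
            class = "lfp_gen_spec")
}

# Piecewise-linear beta amplitude envelope over one trial.
beta_envelope <- function(events, duration_ms, spec, dt_ms = 1) {
  tt <- seq(0, duration_ms - dt_ms, by = dt_ms)
  ev <- as.list(events)
  knots_t <- c(0, ev$CueOn - 100, ev$CueOn, ev$GO, ev$SR,
               ev$Rew - 100, ev$Rew, ev$Rew + 300,
               min(ev$Rew + 500, duration_ms), duration_ms)
  knots_a <- c(spec$amp_rest, spec$amp_rest, spec$amp_wait, spec$amp_wait,
               spec$amp_movement, spec$amp_movement, spec$amp_reward,
               spec$amp_reward, spec$amp_rest, spec$amp_rest)
  ok <- !duplicated(knots_t)
  stats::approx(knots_t[ok], knots_a[ok], xout = tt, rule = 2)$y
}

#' Simulate LFP channels for a set of trials
#'
#' Each trial has one common beta component `A(t) cos(2 pi f t + theta)`
#' with a task-locked amplitude envelope `A(t)` and a random phase offset
#' per trial; each electrode's signal is
#' `shared_fraction * common + noise_sd * private white noise`, so that
#' neighboring channels share the oscillation and neighbor averaging
#' suppresses the private noise.
#'
#' @param trials Trial table (needs event columns and `duration_ms`).
#' @param spec An [lfp_gen_spec()].
#' @param electrode_ids Electrodes to generate.
#' @param fs Sampling rate, Hz.
#' @return List with `lfp` (electrode -> trial -> samples) and
#'   `common_phase` (trial -> phase vector of the common beta, radians).
#' @export
simulate_lfp <- function(trials, spec, electrode_ids, fs = 1000) {
  lfp <- stats::setNames(vector("list", length(electrode_ids)),
                         as.character(electrode_ids))
  common_phase <- list()
  for (i in seq_len(nrow(trials))) {
    tid <- as.character(trials$trial_id[i])
    dur <- trials$duration_ms[i]
    n <- round(dur * fs / 1000)
    tt <- (seq_len(n) - 1) / fs  # seconds
    env <- beta_envelope(trials[i, ], dur, spec, dt_ms = 1000 / fs)
    theta <- stats::runif(1, -pi, pi)
    ph <- (2 * pi * spec$beta_frequency * tt + theta + pi) %% (2 * pi) - pi
    common <- env * cos(ph)
    common_phase[[tid]] <- ph
    for (el in as.character(electrode_ids)) {
      lfp[[el]][[tid]] <- spec$shared_fraction * common +
        spec$noise_sd * stats::rnorm(n)
    }
  }
  list(lfp = lfp, common_phase = common_phase)
}

#' Session generator specification
#'
#' Hyperparameters for [generate_session()]. Per-unit parameters are drawn
#' from the population settings: log-normal baseline rates, a mixture of
#' movement-gain profiles (a majority of rate-increasing and a minority of
#' rate-decreasing units), a common trial-gain SD confined to the waiting
#' period, and wait-only beta phase locking.
#'
#' @param n_trials_per_type Correct trials per trial type (default 30).
#' @param n_units Number of units (default 100).
#' @param monkey_profile `"fast"` or `"slow"` reaction-time profile. Mean
#'   reaction times are 215 ms (fast) and 413 ms (slow).
#' @param rate_meanlog,rate_sdlog Log-normal baseline-rate distribution
#'   (defaults give a median of 12 spikes/s).
#' @param shape Gamma shape of the renewal base process (default 1).
#' @param frac_rate_increase Fraction of units whose rate increases during
#'   movement (default 0.75).
#' @param gain_up_meanlog,gain_down_meanlog Log movement gains of the
#'   increasing / decreasing subpopulations (defaults `log(1.9)`,
#'   `log(0.55)`).
#' @param trial_gain_sd SD of the mean-1 log-normal per-trial gain applied
#'   to the waiting-period intensity (default 0.4).
#' @param kappa_wait,kappa_movement Von Mises concentration of beta phase
#'   locking during the cue/delay period and during movement (defaults 4.5
#'   and 0).
#' @param frac_locked Fraction of units that phase lock at all (default
#'   0.75); the rest get zero concentration in both epochs.
#' @param refractory_ms Per-unit relative refractory period in ms (default
#'   15): spikes closer than this to the previous one are discarded. The
#'   refractoriness is what lets beta entrainment pace the train (at most
#'   about one spike per cycle), so locking lowers the CV2.
#' @param decoy_frac Fraction of low-SNR decoy units (SNR <= 2.5) included
#'   to exercise the quality filter (default 0.1).
#' @param dead_time_ms Acquisition dead time recorded in the session
#'   metadata (default 1.3 ms).
#' @param lfp An [lfp_gen_spec()], or `NULL` to skip LFP generation.
#' @param lfp_scope `"used"` generates LFP only for electrodes carrying
#'   units and their neighbors; `"all"` generates all 96 channels.
#' @param seed Integer seed; the whole session is deterministic given it.
#' @return List of class `session_gen_spec`.
#' @export
session_gen_spec <- function(n_trials_per_type = 30, n_units = 100,
                             monkey_profile = c("fast", "slow"),
                             rate_meanlog = log(12), rate_sdlog = 0.4,
                             shape = 1, frac_rate_increase = 0.75,
                             gain_up_meanlog = log(1.9),
                             gain_down_meanlog = log(0.55),
                             trial_gain_sd = 0.4, kappa_wait = 4.5,
                             kappa_movement = 0, frac_locked = 0.75,
                             refractory_ms = 15, decoy_frac = 0.1,
                             dead_time_ms = 1.3, lfp = lfp_gen_spec(),
                             lfp_scope = c("used", "all"), seed = 1) {
  stopifnot(n_trials_per_type >= 2, n_units >= 1)
  structure(list(n_trials_per_type = n_trials_per_type, n_units = n_units,
                 monkey_profile = match.arg(monkey_profile),
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 shape = shape, frac_rate_increase = frac_rate_increase,
                 gain_up_meanlog = gain_up_meanlog,
                 gain_down_meanlog = gain_down_meanlog,
                 trial_gain_sd = trial_gain_sd, kappa_wait = kappa_wait,
                 kappa_movement = kappa_movement, frac_locked = frac_locked,
                 refractory_ms = refractory_ms, decoy_frac = decoy_frac,
                 dead_time_ms = dead_time_ms, lfp = lfp,
                 lfp_scope = match.arg(lfp_scope), seed = seed),
            class = "session_gen_spec")
}

# Reaction-time distributions of the two profiles (mean, SD, truncation).
rt_profile <- function(profile) {
  if (profile == "fast") c(mean = 215, sd = 50, lo = 100, hi = 650)
  else c(mean = 413, sd = 60, lo = 150, hi = 900)
}

#' Generate a full synthetic session
#'
#' Composes the trial table (four trial types interleaved at random with
#' equal probability), the electrode layout, unit metadata with SNR values
#' (plus low-SNR decoys), per-electrode LFP traces, and per-unit per-trial
#' spike trains from the doubly stochastic phase-locked renewal model.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [session_gen_spec()].
#' @return A validated [spike_session()]. Ground-truth per-unit parameters
#'   are attached as the `"ground_truth"` attribute.
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_gen_spec"))
  set.seed(spec$seed)
  types <- trial_types()
  n_tr <- spec$n_trials_per_type * length(types)
  type_seq <- sample(rep(types, spec$n_trials_per_type))
  rtp <- rt_profile(spec$monkey_profile)
  rt <- round(pmin(pmax(stats::rnorm(n_tr, rtp["mean"], rtp["sd"]),
                        rtp["lo"]), rtp["hi"]))
  gf <- do.call(rbind, strsplit(type_seq, "-"))
  trials <- data.frame(
    trial_id = seq_len(n_tr), grip = gf[, 1], force = gf[, 2],
    correct = TRUE, TS = 0, WS = 400, CueOn = 800, CueOff = 1100, GO = 2100,
    SR = 2100 + rt, Rew = 2100 + rt + 800,
    duration_ms = 2100 + rt + 800 + 600)

  layout <- grid_layout_96()
  n_decoy <- round(spec$decoy_frac * spec$n_units)
  n_good <- spec$n_units - n_decoy
  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(spec$n_units)),
    electrode_id = sample(layout$electrode_id, spec$n_units, replace = TRUE),
    snr = c(stats::runif(n_good, 2.6, 6), stats::runif(n_decoy, 1, 2.5)))

  increase <- stats::runif(spec$n_units) < spec$frac_rate_increase
  locks <- stats::runif(spec$n_units) < spec$frac_locked
  gt <- data.frame(
    unit_id = units$unit_id,
    base_rate = stats::rlnorm(spec$n_units, spec$rate_meanlog,
                              spec$rate_sdlog),
    shape = spec$shape,
    movement_gain = ifelse(increase,
                           stats::rlnorm(spec$n_units,
                                         spec$gain_up_meanlog, 0.25),
                           stats::rlnorm(spec$n_units,
                                         spec$gain_down_meanlog, 0.2)),
    trial_gain_sd = spec$trial_gain_sd,
    kappa_wait = ifelse(locks, spec$kappa_wait, 0),
    kappa_movement = ifelse(locks, spec$kappa_movement, 0),
    refractory_ms = spec$refractory_ms,
    preferred_phase = stats::runif(spec$n_units, -pi, pi))

  lfp <- NULL
  common_phase <- NULL
  if (!is.null(spec$lfp)) {
    els <- if (spec$lfp_scope == "all") {
      layout$electrode_id
    } else {
      sort(unique(unlist(lapply(unique(units$electrode_id), function(el) {
        grid_neighbors(el, layout, include_center = TRUE)
      }))))
    }
    sim <- simulate_lfp(trials, spec$lfp, els)
    lfp <- sim$lfp
    common_phase <- sim$common_phase
  }

  spikes <- stats::setNames(vector("list", spec$n_units), units$unit_id)
  for (u in seq_len(spec$n_units)) {
    per_trial <- stats::setNames(vector("list", n_tr),
                                 as.character(trials$trial_id))
    for (i in seq_len(n_tr)) {
      ev <- trials[i, ]
      prof <- simulate_rate_profile(ev, base_rate = gt$base_rate[u],
                                    movement_gain = gt$movement_gain[u],
                                    duration_ms = ev$duration_ms)
      prof <- apply_trial_gain(prof, spec$trial_gain_sd, events = ev,
                               scope = "wait")
      if (!is.null(common_phase) &&
          (gt$kappa_wait[u] > 0 || gt$kappa_movement[u] > 0)) {
        w <- locking_weight(prof$time, ev)
        kappa_t <- gt$kappa_movement[u] +
          (gt$kappa_wait[u] - gt$kappa_movement[u]) * w
        ph <- common_phase[[as.character(trials$trial_id[i])]]
        st <- simulate_phase_locked_spikes(prof, ph[seq_along(prof$time)],
                                           kappa = kappa_t,
                                           preferred_phase =
                                             gt$preferred_phase[u],
                                           shape = gt$shape[u],
                                           dead_time = gt$refractory_ms[u])
      } else {
        st <- simulate_inhomogeneous_train(prof, shape = gt$shape[u],
                                           dead_time = gt$refractory_ms[u])
      }
      st <- round(st)
      st <- st[st >= 0 & st < ev$duration_ms]
      st <- enforce_dead_time(unique(st), max(spec$dead_time_ms,
                                              gt$refractory_ms[u]))
      per_trial[[i]] <- st
    }
    spikes[[u]] <- per_trial
  }

  sess <- spike_session(
    trials = trials, units = units, spikes = spikes, lfp = lfp,
    layout = layout,
    meta = list(monkey_profile = spec$monkey_profile, sampling_rate = 1000,
                dead_time_ms = spec$dead_time_ms, seed = spec$seed))
  attr(sess, "ground_truth") <- gt
  sess
}
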