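test_that("stationary renewal trains have the right rate and regularity", {
  set.seed(101)
  # equilibrium start: windowed counts match the nominal rate
  cnt <- replicate(400, length(simulate_renewal_train(20, 4, 500)))
  expect_equal(mean(cnt), 10, tolerance = 0.05 * 10)
  st <- simulate_renewal_train(20, 4, 2e5)
  expect_equal(compute_cv(compute_isis(st)), 0.5, tolerance = 0.05)
  # dead time shifts the ISI floor but keeps the mean rate
  std <- simulate_renewal_train(40, 1, 1e5, dead_time = 10)
  expect_gte(min(compute_isis(std)), 10)
  expect_equal(length(std) / 100, 40, tolerance = 0.1 * 40)
  expect_identical(simulate_renewal_train(0.001, 1, 500), numeric(0))
})

test_that("rate profiles scale the movement epoch by the gain", {
  ev <- data.frame(SR = 2300, GO = 2100)
  flat <- simulate_rate_profile(ev, 10, 1, 3600)
  expect_true(all(flat$rate == 10))
  bump <- simulate_rate_profile(ev, 10, 2, 3600)
  expect_equal(max(bump$rate), 20, tolerance = 1e-6)
  expect_equal(bump$rate[bump$time == 2300], 20, tolerance = 1e-6)
  expect_equal(bump$rate[1], 10, tolerance = 0.01)
  set.seed(102)
  mov <- replicate(300, {
    st <- simulate_inhomogeneous_train(bump, shape = 1)
    sum(st >= 2150 & st < 2650)
  })
  wai <- replicate(300, {
    st <- simulate_inhomogeneous_train(bump, shape = 1)
    sum(st >= 1100 & st < 1600)
  })
  expect_equal(mean(mov) / mean(wai), 1.9, tolerance = 0.15)
})

test_that("trial gains are mean-one and respect their scope", {
  prof <- list(time = 0:3599, rate = rep(10, 3600))
  ev <- data.frame(GO = 2100, SR = 2300)
  same <- apply_trial_gain(prof, 0, ev)
  expect_equal(same$rate, prof$rate)
  expect_equal(same$gain, 1)
  set.seed(103)
  gains <- replicate(2000, apply_trial_gain(prof, 0.4, ev)$gain)
  expect_equal(mean(gains), 1, tolerance = 0.03)
  expect_equal(sd(gains), 0.4, tolerance = 0.05)
  g <- apply_trial_gain(prof, 0.4, ev, scope = "wait")
  expect_equal(g$rate[g$time > 2300], prof$rate[g$time > 2300])
  expect_equal(g$rate[g$time <= 2100], prof$rate[g$time <= 2100] * g$gain)
})

test_that("zero concentration reduces exactly to the unlocked generator", {
  prof <- list(time = 0:999, rate = rep(15, 1000))
  ph <- 2 * pi * 20 * (0:999) / 1000
  set.seed(104)
  a <- simulate_phase_locked_spikes(prof, ph, kappa = 0)
  set.seed(104)
  b <- simulate_inhomogeneous_train(prof)
  expect_identical(a, b)
})

test_that("von Mises locking concentrates spike phases at the target", {
  prof <- list(time = 0:4999, rate = rep(20, 5000))
  ph <- (2 * pi * 20 * (0:4999) / 1000 + pi) %% (2 * pi) - pi
  set.seed(105)
  hits <- replicate(60, {
    st <- simulate_phase_locked_spikes(prof, ph, kappa = 1,
                                       preferred_phase = 0.5)
    sp <- ph[pmin(round(st) + 1, length(ph))]
    rt <- rayleigh_test(sp)
    c(p = rt$p_value, mu = rt$mean_phase, n = rt$n)
  })
  expect_gt(mean(hits["p", ] < 0.05), 0.9)       # detection power
  expect_lt(abs(mean(hits["mu", ]) - 0.5), 0.2)  # recovered phase
  expect_gt(mean(hits["n", ]), 80)
})

test_that("generated LFP carries the task-locked beta oscillation", {
  trials <- data.frame(trial_id = 1:6, grip = "SG", force = "HF",
                       correct = TRUE, TS = 0, WS = 400, CueOn = 800,
                       CueOff = 1100, GO = 2100, SR = 2300, Rew = 3100,
                       duration_ms = 3600)
  set.seed(106)
  pure <- simulate_lfp(trials, lfp_gen_spec(noise_sd = 0), c(12, 13, 23))
  expect_equal(pure$lfp[["12"]][["1"]], pure$lfp[["13"]][["1"]])
  sim <- simulate_lfp(trials, lfp_gen_spec(noise_sd = 0.4), c(12))
  w <- default_windows("fast")$wait_extended
  segs <- lapply(sim$lfp[["12"]], function(x) x[601:1600])
  expect_lte(abs(detect_peak_beta(segs)$peak_frequency - 20), 1)
  # wait/movement band-power ratio of the noiseless common component
  bb <- structure(list(peak_frequency = 20, half_width = 5),
                  class = "beta_band")
  f1 <- bandpass_zero_phase(pure$lfp[["12"]][["1"]], bb)
  pw <- function(i) mean(f1[i]^2)
  expect_gt(pw(1101:1600) / pw(2301:2800), 2)
})

test_that("sessions are deterministic and balanced across trial types", {
  spec <- session_gen_spec(n_trials_per_type = 3, n_units = 6, seed = 77)
  s1 <- generate_session(spec)
  s2 <- generate_session(spec)
  expect_equal(s1$trials, s2$trials)
  expect_equal(s1$spikes, s2$spikes)
  expect_equal(s1$lfp, s2$lfp)
  tt <- table(paste(s1$trials$grip, s1$trials$force, sep = "-"))
  expect_true(all(tt == 3))
  expect_setequal(names(tt), trial_types())
  # decoy units fall below the SNR threshold and are filtered out
  expect_true(any(s1$units$snr <= 2.5))
  w <- default_windows("fast")$wait
  res <- unit_variability(s1, w, "SG-HF", min_rate = 0, min_m = 1)
  expect_false(any(res$unit_id %in% s1$units$unit_id[s1$units$snr <= 2.5]))
  expect_false(is.null(attr(s1, "ground_truth")))
  # spikes respect the trial span and the refractory period
  for (u in s1$spikes) for (st in u) {
    if (length(st) > 1) expect_gte(min(diff(st)), 2)
  }
})

test_that("the neutral generator reduces to a stationary renewal process", {
  spec <- session_gen_spec(n_trials_per_type = 20, n_units = 12,
                           rate_meanlog = log(25), rate_sdlog = 0,
                           frac_rate_increase = 1, gain_up_meanlog = 0,
                           trial_gain_sd = 0, kappa_wait = 0,
                           frac_locked = 0, refractory_ms = 10,
                           decoy_frac = 0, lfp = NULL, seed = 88)
  sess <- generate_session(spec)
  w <- default_windows("fast")
  res <- rbind(unit_variability(sess, w$wait, "SG-HF"),
               unit_variability(sess, w$movement, "SG-HF"))
  # pool trials across all four types for per-unit FF vs CV2^2
  allres <- do.call(rbind, lapply(trial_types(), function(tt) {
    rbind(unit_variability(sess, w$wait, tt),
          unit_variability(sess, w$movement, tt))
  }))
  ratio <- allres$ff / allres$cv2^2
  ratio <- ratio[!is.na(ratio)]
  expect_equal(median(ratio), 1, tolerance = 0.2)
  # rates are stationary: wait and movement medians agree
  expect_equal(median(res$rate[res$epoch == "wait"]),
               median(res$rate[res$epoch == "movement"]), tolerance = 3)
})
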