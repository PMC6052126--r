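test_that("grid neighborhoods have the expected sizes", {
  lay <- grid_layout_96()
  # interior site: 8 neighbors, 9 with the center
  mid <- lay$electrode_id[lay$row == 5 & lay$col == 5]
  expect_length(grid_neighbors(mid, lay), 8)
  expect_length(grid_neighbors(mid, lay, include_center = TRUE), 9)
  # site next to an unconnected corner loses that neighbor
  e12 <- lay$electrode_id[lay$row == 1 & lay$col == 2]
  expect_length(grid_neighbors(e12, lay), 4)
  # all neighborhood sizes (with center) lie in the 4..9 range
  sizes <- vapply(lay$electrode_id, function(e) {
    length(grid_neighbors(e, lay, include_center = TRUE))
  }, integer(1))
  expect_true(all(sizes >= 4 & sizes <= 9))
  expect_error(grid_neighbors(999, lay), "not in layout")
})

test_that("neighbor averaging is idempotent and suppresses private noise", {
  sess <- make_toy_session(with_lfp = TRUE)
  avg <- neighbor_average_lfp(sess, 12)
  expect_equal(avg[["1"]], sess$lfp[[1]][["1"]])  # identical channels
  # K independent unit-variance channels average to variance ~1/K
  set.seed(5)
  K <- 8
  for (el in names(sess$lfp)) {
    sess$lfp[[el]] <- lapply(sess$lfp[[el]], function(x) rnorm(length(x)))
  }
  lay <- sess$layout
  mid12 <- grid_neighbors(12, lay)
  avg <- neighbor_average_lfp(sess, 12)
  expect_equal(stats::var(avg[["1"]]), 1 / length(mid12), tolerance = 0.25)
})

test_that("the beta peak is found at the strongest in-band frequency", {
  tt <- (0:999) / 1000
  set.seed(6)
  segs <- lapply(1:10, function(i) {
    cos(2 * pi * 20 * tt + runif(1, -pi, pi)) + 0.2 * rnorm(1000)
  })
  bb <- detect_peak_beta(segs)
  expect_lte(abs(bb$peak_frequency - 20), 1)
  # larger amplitude wins
  two <- list(2 * cos(2 * pi * 15 * tt) + cos(2 * pi * 30 * tt))
  expect_equal(detect_peak_beta(two)$peak_frequency, 15)
  expect_error(detect_peak_beta(list(rep(0, 1000))), "flat spectrum")
})

test_that("the bandpass filter is zero-phase and selective", {
  tt <- (0:2999) / 1000
  tone18 <- cos(2 * pi * 18 * tt)
  bb <- structure(list(peak_frequency = 18, half_width = 5),
                  class = "beta_band")
  filt <- bandpass_zero_phase(tone18, bb)
  core <- 500:2500
  # passband amplitude preserved within 5%
  expect_equal(max(abs(filt[core])), 1, tolerance = 0.05)
  # cross-correlation peak at lag 0 (no phase shift)
  lags <- -30:30
  cc <- vapply(lags, function(l) {
    sum(tone18[core] * filt[core + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  # out-of-band 60 Hz attenuated by >= 20 dB
  tone60 <- cos(2 * pi * 60 * tt)
  f60 <- bandpass_zero_phase(tone60, bb)
  expect_lt(20 * log10(max(abs(f60[core]))), -20)
  expect_equal(bandpass_zero_phase(rep(0, 3000), bb), rep(0, 3000))
  expect_error(bandpass_zero_phase(tone18, c(400, 600)), "Nyquist")
})

test_that("instantaneous phase follows the analytic-signal convention", {
  tt <- (0:1999) / 1000
  f <- 20
  ph <- instantaneous_phase(cos(2 * pi * f * tt))
  expect_true(all(ph > -pi & ph <= pi))
  core <- 200:1800
  # phase 0 at signal maxima
  expect_equal(ph[201], 0, tolerance = 0.05)  # t = 0.2 s = 4 full periods
  # phase advances 2*pi*f/fs per sample
  dph <- diff(ph[core]) %% (2 * pi)
  expect_equal(median(dph), 2 * pi * f / 1000, tolerance = 0.01)
})

test_that("the Rayleigh statistic matches closed-form boundary cases", {
  rt <- rayleigh_test(rep(1.2, 40))
  expect_equal(rt$resultant_length, 1)
  expect_lt(rt$p_value, 1e-6)
  grid36 <- seq(-pi + pi / 36, pi, by = pi / 18)
  expect_equal(rayleigh_test(grid36)$resultant_length, 0, tolerance = 1e-12)
  expect_true(is.na(rayleigh_test(numeric(0))$p_value))
})

test_that("Rayleigh test keeps its type-I error near alpha", {
  set.seed(7)
  ph <- matrix(runif(2000 * 40, -pi, pi), nrow = 2000)
  r <- sqrt(rowMeans(cos(ph))^2 + rowMeans(sin(ph))^2)
  p <- vapply(seq_len(nrow(ph)), function(i) {
    rayleigh_test(ph[i, ])$p_value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("spike phases are read at the spike samples", {
  sess <- make_toy_session(with_lfp = TRUE)
  # place spikes of u1 exactly at cosine maxima (multiples of 50 ms)
  sess$spikes$u1 <- lapply(sess$spikes$u1, function(st) {
    seq(650, 1550, by = 50)
  })
  res <- phase_locking(sess, "SG-HF", min_spikes = 10)
  r1 <- res[res$unit_id == "u1" & res$window == "wait_extended", ]
  expect_equal(r1$beta_peak_hz, 20)
  expect_equal(r1$resultant_length, 1, tolerance = 1e-6)
  expect_lt(abs(r1$mean_phase), 0.05)
  expect_true(r1$locked)
})

test_that("locked fractions count tested units per window", {
  df <- data.frame(
    unit_id = letters[1:6],
    window = rep(c("wait_extended", "movement_extended"), each = 3),
    tested = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    locked = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(locked_fraction(df, "wait_extended"), 50)
  expect_equal(locked_fraction(df, "movement_extended"), 0)
  expect_true(is.na(locked_fraction(df[df$tested == FALSE, ],
                                    "wait_extended")))
})

test_that("spectrogram power is non-negative and zero for silence", {
  sp <- lfp_spectrogram(list(rep(0, 1000), rep(0, 1000)))
  expect_true(all(sp$power == 0))
  set.seed(8)
  sp2 <- lfp_spectrogram(list(rnorm(1000)))
  expect_true(all(sp2$power >= 0))
})
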