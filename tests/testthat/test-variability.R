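w500 <- epoch_window("wait", "CueOff", 0, 500)

test_that("ISIs are consecutive differences with the telescoping property", {
  expect_equal(compute_isis(c(0, 100, 250)), c(100, 150))
  expect_identical(compute_isis(5), numeric(0))
  expect_error(compute_isis(c(10, 5)), "strictly increasing")
  st <- cumsum(c(3, runif(30, 1, 80)))
  expect_equal(sum(compute_isis(st)), max(st) - min(st))
})

test_that("CV is zero for regular trains and ~1 for Poisson", {
  expect_equal(compute_cv(rep(100, 10)), 0)
  expect_true(is.na(compute_cv(100)))
  set.seed(11)
  st <- simulate_renewal_train(20, shape = 1, duration_ms = 3e5)
  expect_equal(compute_cv(compute_isis(st)), 1, tolerance = 0.05)
  st4 <- simulate_renewal_train(20, shape = 4, duration_ms = 3e5)
  expect_equal(compute_cv(compute_isis(st4)), 0.5, tolerance = 0.05)
})

test_that("m-values follow the normalized ISI difference formula", {
  # equal ISIs -> 0
  mv <- compute_m_values(as_aligned(list(c(0, 100, 200)), w500))
  expect_equal(mv$value, 0)
  expect_equal(mv$anchor_time, 100)
  # ISIs (50, 150) -> 2*100/200 = 1
  mv <- compute_m_values(as_aligned(list(c(0, 50, 200)), w500))
  expect_equal(mv$value, 1)
})

test_that("m-value inclusion is anchored at the middle spike", {
  # middle spike at the window start, flanking spikes outside
  mv <- compute_m_values(as_aligned(list(c(-60, 0, 80)), w500))
  expect_equal(nrow(mv), 1)
  # middle spike exactly at the window end -> excluded (half-open)
  mv <- compute_m_values(as_aligned(list(c(440, 500, 560)), w500))
  expect_equal(nrow(mv), 0)
  # m-values never span two trials
  mv <- compute_m_values(as_aligned(list(c(100, 200), c(250, 300, 350)),
                                    w500))
  expect_equal(nrow(mv), 1)
  expect_equal(mv$trial_id, "2")
})

test_that("m-values are bounded in [0,2], zero iff ISIs are equal", {
  isi <- seq(1, 400, by = 7)
  grid <- expand.grid(i1 = isi, i2 = isi)
  st <- lapply(seq_len(nrow(grid)), function(k) {
    c(0, grid$i1[k], grid$i1[k] + grid$i2[k])
  })
  mv <- compute_m_values(as_aligned(st, w500))
  expect_true(all(mv$value >= 0 & mv$value <= 2))
  expect_equal(mv$value == 0, grid$i1 == grid$i2)
})

test_that("CV2 needs a minimum number of m-values", {
  expect_true(is.na(compute_cv2(rep(0.5, 19))$cv2))
  expect_match(compute_cv2(rep(0.5, 19))$reason, "insufficient")
  expect_equal(compute_cv2(rep(0.5, 20))$cv2, 0.5)
})

test_that("LV matches hand-computed values and the Poisson limit", {
  expect_equal(compute_lv(rep(80, 12)), 0)
  expect_true(is.na(compute_lv(100)))
  # alternating 50,150: every pair contributes 3*(100/200)^2 = 0.75
  expect_equal(compute_lv(rep(c(50, 150), 4)), 0.75)
  set.seed(21)
  isis <- compute_isis(simulate_renewal_train(20, 1, 3e5))
  expect_equal(compute_lv(isis), 1, tolerance = 0.05)
})

test_that("FF is the count variance-to-mean ratio with selection rules", {
  tr <- list(c(10, 20, 30), c(40, 50, 60), c(70, 80, 90), c(100, 110, 120))
  expect_equal(compute_ff(as_aligned(tr, w500), min_rate = 0)$ff, 0)
  # counts 0,2,4: var 4, mean 2
  tr2 <- list(numeric(0), c(10, 20), c(30, 40, 50, 60))
  expect_equal(compute_ff(as_aligned(tr2, w500), min_rate = 0)$ff, 2)
  # mean rate 4 spikes/s < default 5 -> undefined
  ff <- compute_ff(as_aligned(tr2, w500))
  expect_true(is.na(ff$ff))
  expect_match(ff$reason, "rate below")
  ff0 <- compute_ff(as_aligned(list(numeric(0), numeric(0)), w500))
  expect_match(ff0$reason, "zero mean")
})

test_that("waveform SNR matches the trough-to-peak definition", {
  w <- rbind(c(-50, 50), c(-50, 50))
  # amplitudes 100; SD over all four samples = sqrt(10000/3)
  expect_equal(compute_snr(w), 100 / (2 * sqrt(10000 / 3)))
  expect_equal(compute_snr(w * 3.7), compute_snr(w))  # scale invariant
  expect_true(is.na(compute_snr(matrix(1, 2, 4))))
})

test_that("variability statistics are invariant under time rescaling", {
  set.seed(31)
  st <- sort(sample(0:499, 40))
  c_scale <- 8
  w_big <- list(name = "wait", align_event = "CueOff",
                start_offset = 0, end_offset = 500 * c_scale)
  class(w_big) <- "epoch_window"
  a1 <- as_aligned(list(st), w500)
  a2 <- as_aligned(list(st * c_scale), w_big)
  expect_equal(compute_cv(compute_isis(st)),
               compute_cv(compute_isis(st * c_scale)))
  expect_equal(compute_m_values(a1)$value, compute_m_values(a2)$value)
  expect_equal(window_counts(a1), window_counts(a2))
  expect_equal(compute_lv(compute_isis(st)),
               compute_lv(compute_isis(st * c_scale)))
})

test_that("m-values and FF agree with naive enumeration on random trains", {
  set.seed(41)
  for (rep in 1:50) {
    n_tr <- sample(1:3, 1)
    trains <- lapply(seq_len(n_tr), function(i) {
      sort(sample(-200:700, sample(2:10, 1)))
    })
    al <- as_aligned(trains, w500)
    expect_equal(sort(compute_m_values(al)$value),
                 sort(naive_m_values(trains, w500)), tolerance = 1e-12)
    ff <- compute_ff(al, min_rate = 0)$ff
    nf <- naive_ff(trains, w500)
    if (is.na(nf) || n_tr < 2) expect_true(is.na(ff))
    else expect_equal(ff, nf, tolerance = 1e-12)
  }
})

test_that("unit selection distinguishes either-epoch from both-epochs", {
  mk <- function(uid, epoch, rate, sel) {
    data.frame(unit_id = uid, epoch = epoch, trial_type = "SG-HF",
               rate = rate, cv2 = ifelse(sel, 0.8, NA), lv = 0.8,
               ff = ifelse(sel, 1, NA), n_m = 30, n_trials = 20,
               selected = sel, reason = "", bursty = FALSE)
  }
  res <- rbind(mk("a", "wait", 6, TRUE), mk("a", "movement", 3, FALSE),
               mk("b", "wait", 8, TRUE), mk("b", "movement", 9, TRUE))
  sel <- select_units(res, "either_epoch")
  expect_setequal(sel$wait, c("a", "b"))
  expect_equal(sel$movement, "b")
  expect_equal(select_units(res, "both_epochs"), "b")
})

test_that("per-unit variability flags bursty units but keeps them", {
  sess <- make_toy_session()
  sess$spikes$u1 <- lapply(sess$spikes$u1, function(st) {
    sort(c(st, st[2] + 2))  # add a 2 ms ISI in every trial
  })
  res <- unit_variability(sess, w500, "SG-HF", min_rate = 0, min_m = 1)
  expect_true(res$bursty[res$unit_id == "u1"])
  expect_false(res$bursty[res$unit_id == "u2"])
  expect_equal(nrow(res), 2)
})
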