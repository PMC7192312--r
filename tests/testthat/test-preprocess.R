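test_that("band-pass filter preserves the passband and rejects stopband", {
  srate <- 200
  tms <- epoch_times(srate)
  mid <- tms > -1500 & tms < 0     # avoid filter edge transients
  ts20 <- toy_trials_fn(function(t) sin(2 * pi * 20 * t / 1000))
  out <- bandpass_filter(ts20, 1, 50)
  ratio <- sd(out$data[1, 1, mid]) / sd(ts20$data[1, 1, mid])
  expect_gte(ratio, 0.89)

  ts02 <- toy_trials_fn(function(t) sin(2 * pi * 0.2 * t / 1000))
  out02 <- bandpass_filter(ts02, 1, 50)
  atten_db <- 20 * log10(max(abs(out02$data[1, 1, mid])))
  expect_lte(atten_db, -20)

  tsdc <- toy_trials_fn(function(t) rep(5, length(t)))
  outdc <- bandpass_filter(tsdc, 1, 50)
  expect_lt(abs(mean(outdc$data[1, 1, mid])), 0.05)

  expect_error(bandpass_filter(ts20, 1, 120), "Nyquist")
})

test_that("EMG onset detection finds sustained threshold crossings", {
  srate <- 200
  set.seed(11)
  tr <- emg_step_trace(1500, srate = srate)
  on <- detect_emg_onset(tr, srate)
  expect_lt(abs(on - 1500), 15)

  # silent trace: no onset
  set.seed(12)
  quiet <- abs(rnorm(541, 0, 0.01))
  expect_true(is.na(detect_emg_onset(quiet, srate)))

  # two bursts: first sustained crossing wins
  set.seed(13)
  tms <- seq(0, 2700, by = 1000 / srate)
  x <- rnorm(length(tms), 0, 0.05)
  x[tms >= 1200 & tms < 1300] <- x[tms >= 1200 & tms < 1300] + 5
  x[tms >= 1600 & tms < 1700] <- x[tms >= 1600 & tms < 1700] + 5
  on2 <- detect_emg_onset(abs(x), srate)
  expect_lt(abs(on2 - 1200), 15)

  # degenerate baseline
  expect_error(detect_emg_onset(c(rep(1, 200), rep(5, 341)), srate),
               "degenerate")
})

test_that("onset error on noiseless steps stays under the smoothing window", {
  srate <- 200
  for (true_on in c(800, 1500, 2100)) {
    tr <- emg_step_trace(true_on, srate = srate, noise_sd = 0)
    tr <- tr + 1e-6 * abs(sin(seq_along(tr)))    # avoid zero-variance baseline
    on <- detect_emg_onset(tr, srate)
    expect_lt(abs(on - true_on), 25)
  }
})

make_screened_trials <- function(diffs, srate = 200) {
  n <- length(diffs)
  n_samp <- length(epoch_times(srate))
  set.seed(21)
  emg <- array(0, dim = c(n, 2, n_samp))
  for (i in seq_len(n)) {
    emg[i, 1, ] <- emg_step_trace(2200, srate = srate)
    emg[i, 2, ] <- emg_step_trace(2200 - diffs[i], srate = srate)
  }
  data <- array(rnorm(n * 1 * n_samp, 0, 1), dim = c(n, 1, n_samp))
  ts <- trial_set(data, srate, emg = emg)
  detect_trial_onsets(ts)
}

test_that("trial screening applies the >= 500 ms simultaneity rule", {
  ts <- make_screened_trials(c(100, 480, 520, 600))
  ts <- screen_trials(ts, p2p_limit = Inf)
  expect_equal(sum(ts$valid$valid), 2L)
  expect_equal(ts$valid$reason[3:4], c("onset_diff", "onset_diff"))

  # a difference of exactly 500 ms is excluded
  ts500 <- screen_trials(make_screened_trials(c(500, 100)), p2p_limit = Inf)
  expect_false(ts500$valid$valid[1])
  expect_true(ts500$valid$valid[2])

  # all simultaneous, no artifacts: identity
  tsok <- screen_trials(make_screened_trials(c(10, 250, 499)),
                        p2p_limit = Inf)
  expect_true(all(tsok$valid$valid))

  # idempotent, never increases the valid count
  ts2 <- screen_trials(ts, p2p_limit = Inf)
  expect_identical(ts2$valid, ts$valid)
  expect_lte(sum(ts2$valid$valid), sum(ts$valid$valid))
})

test_that("amplitude artifacts are screened with a reason code", {
  ts <- make_screened_trials(c(100, 100))
  ts$data[2, 1, 50] <- 300      # large spike
  ts <- screen_trials(ts)
  expect_true(ts$valid$valid[1])
  expect_equal(ts$valid$reason[2], "artifact")
  expect_equal(as.integer(attr(ts$valid, "rejections")["artifact"]), 1L)
})

test_that("baseline correction subtracts the window mean per channel", {
  tsc <- toy_trials_fn(function(t) rep(7, length(t)))
  out <- baseline_correct_trials(tsc)
  expect_lt(max(abs(out$data)), 1e-12)

  # 5 + sin over integer periods inside the window: mean removes the offset
  srate <- 200
  f <- 1000 / 480   # one full period in the 480 ms baseline window
  tss <- toy_trials_fn(function(t) 5 + sin(2 * pi * f * (t + 2180) / 1000),
                       srate = srate)
  out2 <- baseline_correct_trials(tss, c(-2180, -1700))
  expected <- sin(2 * pi * f * (tss$times + 2180) / 1000)
  expect_lt(max(abs(out2$data[1, 1, ] - expected)), 0.02)

  # already centred in the window: unchanged
  out3 <- baseline_correct_trials(out2, c(-2180, -1700))
  expect_equal(out3$data, out2$data, tolerance = 1e-10)
})

test_that("filter + baseline keeps in-band oscillation amplitude within 12%", {
  srate <- 200
  ts <- toy_trials_fn(function(t) sin(2 * pi * 15 * t / 1000), srate = srate)
  out <- baseline_correct_trials(bandpass_filter(ts, 1, 50))
  mid <- ts$times > -1500 & ts$times < 0
  rel <- abs(sd(out$data[1, 1, mid]) / sd(ts$data[1, 1, mid]) - 1)
  expect_lt(rel, 0.12)
})

test_that("onset statistics summarize valid trials", {
  ts <- make_screened_trials(c(40, 60, 80))
  ts <- screen_trials(ts, p2p_limit = Inf)
  st <- onset_stats(ts)
  expect_equal(st$mean, 60, tolerance = 0.2)
  expect_equal(st$median, 60, tolerance = 0.2)

  ts1 <- screen_trials(make_screened_trials(36.5), p2p_limit = Inf)
  st1 <- onset_stats(ts1)
  expect_equal(st1$min, st1$max)
  expect_equal(st1$mean, 36.5, tolerance = 5)
})

test_that("generator onset-difference distribution is recovered at n = 720", {
  gt <- make_population("HO", n_subjects = 12, seed = 5)
  diffs <- unlist(lapply(1:12, function(s)
    simulate_subject_dataset(gt, s, emg = FALSE)$onset_diffs))
  expect_length(diffs, 720)
  expect_lt(abs(mean(diffs) - 75), 10)
})
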