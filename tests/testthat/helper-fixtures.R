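# small builders shared across test files

# trial_set with given per-trial channel signals (list of channels x samples)
toy_trials <- function(signals, srate = 200, window = c(-2200, 500),
                       emg = NULL) {
  n_samp <- round((window[2] - window[1]) / 1000 * srate) + 1
  arr <- array(0, dim = c(length(signals), nrow(signals[[1]]), n_samp))
  for (i in seq_along(signals)) arr[i, , ] <- signals[[i]]
  trial_set(arr, srate, emg = emg, window = window)
}

# single-channel trial set from a function of time (ms)
toy_trials_fn <- function(f, n_trials = 1, srate = 200,
                          window = c(-2200, 500)) {
  tms <- seq(window[1], window[2], by = 1000 / srate)
  sig <- matrix(f(tms), nrow = 1)
  toy_trials(replicate(n_trials, sig, simplify = FALSE), srate, window)
}

epoch_times <- function(srate = 200, window = c(-2200, 500)) {
  seq(window[1], window[2], by = 1000 / srate)
}

# rectified EMG trace with a step of given amplitude at onset_ms (from start)
emg_step_trace <- function(onset_ms, n_ms = 2700, srate = 200, amp = 10,
                           noise_sd = 0.1) {
  tms <- seq(0, n_ms, by = 1000 / srate)
  x <- rnorm(length(tms), 0, noise_sd)
  x[tms >= onset_ms] <- x[tms >= onset_ms] + amp
  abs(x)
}

# source_spectrogram with prescribed power array
toy_spec <- function(power, freqs = 4:48, times = seq(-1000, 0, by = 10)) {
  source_spectrogram(power, freqs, times)
}

# two-region, two-mode network/model for fast inversion tests
tiny_network <- function() {
  network_spec(data.frame(name = c("R1", "R2"),
                          x = c(-10, 10), y = 0, z = 50), "R1")
}

tiny_model <- function(intrinsic_nonlinear = FALSE, extrinsic = NULL) {
  dcm_model(tiny_network(), M = 2, extrinsic = extrinsic,
            intrinsic_nonlinear = intrinsic_nonlinear, name = "tiny")
}

# evidence table helper
ev_table <- function(mat, fam = NULL) evidence_table(mat, fam)
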