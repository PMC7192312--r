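#' Morlet wavelet spectrogram of source trials
#'
#' Computes the squared magnitude of complex Morlet wavelet coefficients for
#' every trial, source and frequency. The wavelet at frequency f has
#' `n_cycles` cycles (temporal SD `n_cycles / (2*pi*f)`) and unit energy;
#' samples whose wavelet support extends past the epoch edge are flagged in
#' the `edge` attribute.
#'
#' @param ts a [trial_set()] (typically in source space).
#' @param freqs frequency grid in Hz (default `4:48`, 1 Hz resolution).
#' @param n_cycles wavelet cycles, constant over frequency (default 7).
#' @return a `trial_tfr`: list with `power` (trials x sources x freqs x
#'   times), `freqs`, `times` (ms), `edge` (freqs x times logical), `valid`
#'   (per-trial flags inherited from `ts`), and `source_names`.
#' @export
morlet_spectrogram <- function(ts, freqs = 4:48, n_cycles = 7) {
  stopifnot(inherits(ts, "trial_set"), all(freqs > 0), n_cycles > 0)
  srate <- ts$srate
  n_samp <- length(ts$times)
  n_tr <- n_trials(ts)
  n_src <- dim(ts$data)[2]
  # lowest frequency must have full wavelet support inside the epoch
  if (2 * ceiling(3.5 * n_cycles / (2 * pi * min(freqs)) * srate) + 1 > n_samp)
    stop("epoch too short for the lowest-frequency wavelet", call. = FALSE)
  nf <- stats::nextn(2L * n_samp, 2)
  wl_f <- vector("list", length(freqs))
  half <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sig_t <- n_cycles / (2 * pi * f)
    h <- ceiling(3.5 * sig_t * srate)
    tt <- (-h:h) / srate
    w <- exp(-tt^2 / (2 * sig_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))
    wl_f[[k]] <- stats::fft(c(w, rep(0, nf - length(w))))
    half[k] <- h
  }
  power <- array(0, dim = c(n_tr, n_src, length(freqs), n_samp))
  for (tr in seq_len(n_tr)) for (s in seq_len(n_src)) {
    fx <- stats::fft(c(ts$data[tr, s, ], rep(0, nf - n_samp)))
    for (k in seq_along(freqs)) {
      y <- stats::fft(fx * wl_f[[k]], inverse = TRUE) / nf
      power[tr, s, k, ] <- Mod(y[half[k] + seq_len(n_samp)])^2
    }
  }
  edge <- matrix(FALSE, length(freqs), n_samp)
  for (k in seq_along(freqs)) {
    edge[k, seq_len(min(half[k], n_samp))] <- TRUE
    edge[k, seq.int(max(1L, n_samp - half[k] + 1L), n_samp)] <- TRUE
  }
  structure(list(power = power, freqs = freqs, times = ts$times,
                 edge = edge, valid = ts$valid$valid,
                 source_names = ts$channel_names),
            class = "trial_tfr")
}

#' Construct a source spectrogram
#'
#' Region x frequency x time power container used throughout the modelling
#' chain.
#'
#' @param power numeric array, sources x freqs x times.
#' @param freqs frequency grid (Hz).
#' @param times time grid (ms, 0 = EMG onset).
#' @param source_names character vector, one per source.
#' @param baseline_window baseline window in ms once power has been
#'   baseline-corrected, else `NULL`.
#' @param n_trials_averaged number of trials entering the average.
#' @return a `source_spectrogram`.
#' @export
source_spectrogram <- function(power, freqs, times, source_names = NULL,
                               baseline_window = NULL,
                               n_trials_averaged = NA_integer_) {
  stopifnot(is.array(power), length(dim(power)) == 3L,
            dim(power)[2] == length(freqs), dim(power)[3] == length(times),
            all(diff(freqs) > 0))
  if (is.null(source_names)) source_names <- paste0("src", seq_len(dim(power)[1]))
  structure(list(power = power, freqs = freqs, times = times,
                 source_names = source_names,
                 baseline_window = baseline_window,
                 n_trials_averaged = n_trials_averaged),
            class = "source_spectrogram")
}

#' @export
print.source_spectrogram <- function(x, ...) {
  cat(sprintf("<source_spectrogram> %d sources x %d freqs (%g..%g Hz) x %d times (%g..%g ms)\n",
              dim(x$power)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Average per-trial power over valid trials and crop in time
#'
#' Arithmetic mean of per-trial power over the valid trials, then restriction
#' of the time axis to `window` (default -1000 to 0 ms, the motor-preparation
#' segment analysed by the model).
#'
#' @param tfr a `trial_tfr` from [morlet_spectrogram()].
#' @param window length-2 numeric, ms (closed interval).
#' @return a [source_spectrogram()].
#' @export
average_and_crop <- function(tfr, window = c(-1000, 0)) {
  stopifnot(inherits(tfr, "trial_tfr"), length(window) == 2L)
  keep <- which(tfr$valid)
  if (length(keep) < 1L) stop("no valid trials to average", call. = FALSE)
  avg <- apply(tfr$power[keep, , , , drop = FALSE], c(2, 3, 4), mean)
  tol <- 1e-9
  sel <- tfr$times >= window[1] - tol & tfr$times <= window[2] + tol
  if (!any(sel)) stop("crop window outside epoch", call. = FALSE)
  source_spectrogram(avg[, , sel, drop = FALSE], tfr$freqs, tfr$times[sel],
                     source_names = tfr$source_names,
                     n_trials_averaged = length(keep))
}

#' Down-sample the time axis of a spectrogram by bin averaging
#'
#' Averages power within consecutive non-overlapping bins of width `dt` ms;
#' the reported bin time is the bin centre rounded onto the original grid.
#' Used to bring the spectrogram onto the coarser grid on which the dynamic
#' model is integrated.
#'
#' @param spec a [source_spectrogram()].
#' @param dt target time step in ms (default 10).
#' @return a [source_spectrogram()] on the coarser grid.
#' @export
downsample_time <- function(spec, dt = 10) {
  stopifnot(inherits(spec, "source_spectrogram"), dt > 0)
  t0 <- spec$times
  step <- if (length(t0) > 1) t0[2] - t0[1] else dt
  per <- max(1L, round(dt / step))
  if (per == 1L) return(spec)
  n_bins <- floor(length(t0) / per)
  idx <- split(seq_len(n_bins * per), rep(seq_len(n_bins), each = per))
  newp <- array(0, dim = c(dim(spec$power)[1:2], n_bins))
  newt <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    newp[, , b] <- apply(spec$power[, , idx[[b]], drop = FALSE], c(1, 2), mean)
    newt[b] <- mean(t0[idx[[b]]])
  }
  source_spectrogram(newp, spec$freqs, newt, spec$source_names,
                     spec$baseline_window, spec$n_trials_averaged)
}

#' Baseline-correct spectral power
#'
#' Subtracts, per source and frequency, the mean instantaneous power over the
#' baseline window (default -1000 to -833 ms). Negative corrected values are
#' event-related desynchronization, positive values synchronization.
#'
#' @param spec a [source_spectrogram()].
#' @param window length-2 numeric, ms; must lie inside the time grid. The
#'   window is closed at its start and open at its end (sample-aligned).
#' @return the corrected [source_spectrogram()] (`baseline_window` recorded).
#' @export
baseline_correct_power <- function(spec, window = c(-1000, -833)) {
  stopifnot(inherits(spec, "source_spectrogram"), length(window) == 2L)
  tol <- 1e-9
  sel <- spec$times >= window[1] - tol & spec$times < window[2] - tol
  if (!any(sel)) stop("baseline window outside time grid", call. = FALSE)
  mu <- apply(spec$power[, , sel, drop = FALSE], c(1, 2), mean)
  spec$power <- spec$power - array(mu, dim = dim(spec$power))
  spec$baseline_window <- window
  spec
}
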