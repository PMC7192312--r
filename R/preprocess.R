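#' Construct a set of EMG-locked EEG trials
#'
#' Container for per-trial multichannel EEG epochs locked to EMG onset
#' (0 ms = onset), together with rectified EMG traces for the two monitored
#' muscles (extensor digitorum communis, EDC, and deltoid, IDL). The default
#' epoch spans -2200 to +500 ms around onset.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param srate sampling rate in Hz.
#' @param channel_names character vector, length = number of channels.
#' @param emg optional numeric array, trials x 2 x samples of rectified EMG
#'   (muscle order EDC, IDL).
#' @param window epoch limits in ms relative to EMG onset
#'   (default `c(-2200, 500)`); the sample grid is
#'   `seq(window[1], window[2], by = 1000/srate)` and must match the data.
#' @return an object of class `trial_set` with elements `data`, `srate`,
#'   `times` (ms), `t0_index`, `channel_names`, `emg`, `onsets` (filled by
#'   [detect_trial_onsets()]), and `valid` (a data.frame with per-trial
#'   validity flag and rejection reason).
#' @export
trial_set <- function(data, srate, channel_names = NULL, emg = NULL,
                      window = c(-2200, 500)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, srate > 0,
            length(window) == 2L, window[1] < window[2])
  n_samp <- dim(data)[3]
  times <- window[1] + (seq_len(n_samp) - 1L) * 1000 / srate
  if (abs(times[n_samp] - window[2]) > 1000 / srate)
    stop("epoch length inconsistent with window and srate", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  stopifnot(length(channel_names) == dim(data)[2])
  if (!is.null(emg))
    stopifnot(length(dim(emg)) == 3L, dim(emg)[1] == dim(data)[1],
              dim(emg)[2] == 2L, dim(emg)[3] == n_samp)
  t0_index <- which.min(abs(times))
  structure(list(
    data = data, srate = srate, times = times, t0_index = t0_index,
    channel_names = channel_names, emg = emg,
    onsets = NULL,
    valid = data.frame(valid = rep(TRUE, dim(data)[1]),
                       reason = rep("ok", dim(data)[1]),
                       stringsAsFactors = FALSE)
  ), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  cat(sprintf("  epoch %g..%g ms (0 = EMG onset); valid: %d/%d\n",
              min(x$times), max(x$times), sum(x$valid$valid), d[1]))
  invisible(x)
}

n_trials <- function(ts) dim(ts$data)[1]

#' Zero-phase band-pass filter of all trials
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' trial and channel, so that passband signals are preserved and no group
#' delay is introduced that could shift EMG-locked timings.
#'
#' @param ts a [trial_set()].
#' @param lo,hi passband edges in Hz (defaults 1 and 50).
#' @param order Butterworth prototype order (default 4).
#' @return the filtered `trial_set`.
#' @export
bandpass_filter <- function(ts, lo = 1, hi = 50, order = 4) {
  stopifnot(inherits(ts, "trial_set"))
  nyq <- ts$srate / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq)
    stop("upper edge must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  d <- ts$data
  for (tr in seq_len(dim(d)[1]))
    for (ch in seq_len(dim(d)[2]))
      d[tr, ch, ] <- signal::filtfilt(bf, d[tr, ch, ])
  ts$data <- d
  ts
}

#' Detect EMG onset on a single rectified trace
#'
#' The rectified trace is smoothed with a centered moving-average envelope;
#' onset is the first time the envelope exceeds the baseline mean + `k_sd`
#' baseline standard deviations and stays above threshold for at least
#' `sustain_ms`. Returns `NA` ("none") if the threshold is never sustained.
#'
#' @param trace numeric vector, rectified EMG (one trial, one muscle).
#' @param srate sampling rate in Hz.
#' @param baseline_window length-2 numeric, ms from trace start delimiting the
#'   pre-movement baseline (default `c(0, 480)`).
#' @param smooth_ms moving-average envelope width in ms (default 25).
#' @param k_sd threshold in baseline SDs above the baseline mean (default 3).
#' @param sustain_ms minimum supra-threshold duration in ms (default 25).
#' @return onset time in ms from trace start, or `NA_real_` if none.
#' @export
detect_emg_onset <- function(trace, srate, baseline_window = c(0, 480),
                             smooth_ms = 25, k_sd = 3, sustain_ms = 25) {
  stopifnot(is.numeric(trace), srate > 0, length(baseline_window) == 2L)
  trace <- abs(trace)
  tms <- (seq_along(trace) - 1L) * 1000 / srate
  w <- ceiling(smooth_ms / 1000 * srate)
  if (w %% 2 == 0) w <- w + 1L
  env <- as.numeric(stats::filter(trace, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- trace[is.na(env)]      # edges: fall back to raw samples
  # threshold from the rectified baseline itself (not the smoothed envelope,
  # whose autocorrelation makes 3-SD excursions routine)
  bl <- trace[tms >= baseline_window[1] & tms <= baseline_window[2]]
  if (length(bl) < 2L) stop("baseline window too short", call. = FALSE)
  if (sd(bl) == 0)
    stop("degenerate baseline: zero variance, threshold undefined",
         call. = FALSE)
  thr <- mean(bl) + k_sd * sd(bl)
  sus <- max(1L, ceiling(sustain_ms / 1000 * srate))
  r <- rle(env > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sus)
  if (length(hit) == 0L) return(NA_real_)
  tms[starts[hit[1]]]
}

#' Detect EMG onsets for both muscles on every trial
#'
#' Runs [detect_emg_onset()] on the EDC and IDL traces of each trial and
#' stores onsets (ms relative to epoch start) plus the absolute onset
#' difference in the `trial_set`.
#'
#' @param ts a [trial_set()] with an `emg` array.
#' @param ... passed to [detect_emg_onset()].
#' @return `ts` with an `onsets` data.frame (`onset_edc`, `onset_idl`,
#'   `abs_diff`, all ms relative to epoch start).
#' @export
detect_trial_onsets <- function(ts, ...) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(ts$emg)) stop("trial_set has no EMG data", call. = FALSE)
  n <- n_trials(ts)
  on <- matrix(NA_real_, n, 2)
  for (tr in seq_len(n))
    for (m in 1:2)
      on[tr, m] <- detect_emg_onset(ts$emg[tr, m, ], ts$srate, ...)
  ts$onsets <- data.frame(onset_edc = on[, 1], onset_idl = on[, 2],
                          abs_diff = abs(on[, 1] - on[, 2]))
  ts
}

#' Screen trials for EMG-onset simultaneity and amplitude artifacts
#'
#' Marks a trial invalid when (a) an onset could not be detected for both
#' muscles, (b) the absolute EMG onset difference between the two muscles
#' meets the exclusion rule (default: >= 500 ms, i.e. non-simultaneous
#' activation), or (c) any EEG channel exceeds a peak-to-peak amplitude
#' threshold (programmatic stand-in for visual artifact rejection).
#' Screening is idempotent and never revalidates a trial.
#'
#' @param ts a [trial_set()]; run [detect_trial_onsets()] first (or supply
#'   `onsets` another way).
#' @param max_onset_diff exclusion threshold in ms (default 500).
#' @param comparator `">="` (default) or `">"`: how the onset difference is
#'   compared with `max_onset_diff`.
#' @param p2p_limit peak-to-peak amplitude artifact threshold in microvolts
#'   (default 150); `Inf` disables amplitude screening.
#' @return `ts` with updated `valid` flags/reasons; rejection counts are in
#'   `attr(ts$valid, "rejections")`.
#' @export
screen_trials <- function(ts, max_onset_diff = 500, comparator = c(">=", ">"),
                          p2p_limit = 150) {
  stopifnot(inherits(ts, "trial_set"))
  comparator <- match.arg(comparator)
  if (is.null(ts$onsets))
    stop("onsets not computed; run detect_trial_onsets() first", call. = FALSE)
  cmp <- if (comparator == ">=") `>=` else `>`
  n <- n_trials(ts)
  for (tr in seq_len(n)) {
    if (!ts$valid$valid[tr]) next
    o <- ts$onsets[tr, ]
    if (is.na(o$onset_edc) || is.na(o$onset_idl)) {
      ts$valid$valid[tr] <- FALSE; ts$valid$reason[tr] <- "no_onset"
    } else if (cmp(o$abs_diff, max_onset_diff)) {
      ts$valid$valid[tr] <- FALSE; ts$valid$reason[tr] <- "onset_diff"
    } else if (is.finite(p2p_limit)) {
      p2p <- apply(ts$data[tr, , , drop = FALSE], 2,
                   function(x) diff(range(x)))
      if (any(p2p > p2p_limit)) {
        ts$valid$valid[tr] <- FALSE; ts$valid$reason[tr] <- "artifact"
      }
    }
  }
  attr(ts$valid, "rejections") <-
    table(factor(ts$valid$reason[!ts$valid$valid],
                 levels = c("no_onset", "onset_diff", "artifact")))
  ts
}

#' Baseline-correct trials in the time domain
#'
#' Subtracts, per trial and channel, the mean signal over a baseline window
#' (default -2180 to -1700 ms relative to EMG onset).
#'
#' @param ts a [trial_set()].
#' @param window length-2 numeric, ms relative to EMG onset.
#' @return the corrected `trial_set`.
#' @export
baseline_correct_trials <- function(ts, window = c(-2180, -1700)) {
  stopifnot(inherits(ts, "trial_set"), length(window) == 2L)
  sel <- ts$times >= window[1] & ts$times < window[2]
  if (!any(sel)) stop("baseline window outside epoch", call. = FALSE)
  for (tr in seq_len(n_trials(ts)))
    for (ch in seq_len(dim(ts$data)[2]))
      ts$data[tr, ch, ] <- ts$data[tr, ch, ] - mean(ts$data[tr, ch, sel])
  ts
}

#' Summary statistics of the EMG onset difference over valid trials
#'
#' @param ts a screened [trial_set()] with onsets.
#' @return list with `n`, `mean`, `sd`, `median`, `min`, `max` of the absolute
#'   EDC-IDL onset difference (ms), valid trials only.
#' @export
onset_stats <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(ts$onsets)) stop("onsets not computed", call. = FALSE)
  d <- ts$onsets$abs_diff[ts$valid$valid]
  d <- d[!is.na(d)]
  if (length(d) < 1L) stop("no valid trials", call. = FALSE)
  list(n = length(d), mean = mean(d), sd = if (length(d) > 1) sd(d) else 0,
       median = median(d), min = min(d), max = max(d))
}
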