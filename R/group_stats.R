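#' Frequency band scheme
#'
#' Non-overlapping bands covering the analysed 4-48 Hz range: theta 4-7,
#' mu 8-12, beta 13-35, gamma 36-48 Hz.
#'
#' @return a data.frame with `band`, `symbol`, `lo`, `hi`.
#' @export
band_scheme <- function() {
  data.frame(band = c("theta", "mu", "beta", "gamma"),
             symbol = c("\u03b8", "\u03bc", "\u03b2", "\u03b3"),
             lo = c(4, 8, 13, 36), hi = c(7, 12, 35, 48),
             stringsAsFactors = FALSE)
}

band_of <- function(f, bands = band_scheme()) {
  idx <- vapply(f, function(x) {
    w <- which(x >= bands$lo & x <= bands$hi)
    if (length(w)) w[1] else NA_integer_
  }, 1L)
  bands$symbol[idx]
}

#' Project fitted coupling matrices back to frequency space, per connection
#'
#' For every subject and every ordered region pair, the fitted M x M coupling
#' block is back-projected through that subject's mode loadings
#' (`U A_ij t(U)`) and smoothed with a Gaussian kernel (default FWHM 8 Hz on
#' both the source- and target-frequency axes), yielding group-stackable
#' frequency-to-frequency coupling maps.
#'
#' @param fits list of `dcm_fit`, one per subject.
#' @param mds list of `mode_decomp`, one per subject (same order).
#' @param model the [dcm_model()] the fits used.
#' @param fwhm smoothing FWHM in Hz applied to both axes (default 8; 0
#'   disables).
#' @param include_intrinsic also return within-region maps (default FALSE).
#' @return named list (one element per connection `"src->tgt"`) of
#'   subjects x freqs x freqs arrays (rows of each map = target frequency);
#'   frequency grid in `attr(, "freqs")`.
#' @export
coupling_to_frequency <- function(fits, mds, model, fwhm = 8,
                                  include_intrinsic = FALSE) {
  stopifnot(length(fits) == length(mds), length(fits) >= 1)
  nm <- model$network$regions$name
  freqs <- mds[[1]]$freqs
  nf <- length(freqs)
  df <- if (nf > 1) freqs[2] - freqs[1] else 1
  pairs <- expand.grid(src = nm, tgt = nm, stringsAsFactors = FALSE)
  if (!include_intrinsic) pairs <- pairs[pairs$src != pairs$tgt, ]
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    arr <- array(0, dim = c(length(fits), nf, nf))
    for (s in seq_along(fits)) {
      blk <- coupling_block(fits[[s]], model, pairs$src[r], pairs$tgt[r])
      B <- backproject_coupling(mds[[s]], blk)
      if (fwhm > 0) B <- gaussian_smooth(B, c(fwhm, fwhm), c(df, df))
      arr[s, , ] <- B
    }
    out[[paste0(pairs$src[r], "->", pairs$tgt[r])]] <- arr
  }
  attr(out, "freqs") <- freqs
  out
}

# vectorized one-sample t over the first (subject) dimension of an array;
# zero-variance voxels get |t| capped and are flagged
array_tstat <- function(x, mu = 0, t_cap = 1e6) {
  nsub <- dim(x)[1]
  m <- apply(x, c(2, 3), mean) - mu
  sdv <- apply(x, c(2, 3), sd)
  zerovar <- sdv == 0
  tmap <- m / (sdv / sqrt(nsub))
  tmap[zerovar & m == 0] <- 0
  tmap[zerovar & m != 0] <- sign(m[zerovar & m != 0]) * t_cap
  list(t = tmap, df = nsub - 1, zerovar = zerovar)
}

make_stat_map <- function(ts, freqs, p_threshold, axes = c("freq", "freq")) {
  p <- 2 * pt(-abs(ts$t), df = ts$df)
  sig <- p < p_threshold
  clusters <- extract_clusters(ts$t, sig, freqs, axes)
  structure(list(t_map = ts$t, p_map = p, sign_map = sign(ts$t),
                 sig = sig, df = ts$df, zero_variance = ts$zerovar,
                 clusters = clusters, freqs = freqs,
                 p_threshold = p_threshold, axes = axes),
            class = "coupling_stat_map")
}

# split the suprathreshold mask by sign and label 4-connected components
extract_clusters <- function(tmap, sig, freqs, axes) {
  rows <- list()
  for (sgn in c(1, -1)) {
    lab <- label_components(sig & sign(tmap) == sgn)
    for (k in seq_len(max(lab))) {
      vox <- which(lab == k, arr.ind = TRUE)
      tv <- tmap[lab == k]
      peak <- vox[which.max(abs(tv)), ]
      rows[[length(rows) + 1]] <- data.frame(
        sign = sgn, n_voxels = nrow(vox),
        peak_t = tv[which.max(abs(tv))],
        # rows index the target axis, columns the source axis
        peak_target = freqs[peak[1]], peak_source = freqs[peak[2]])
    }
  }
  if (!length(rows))
    return(data.frame(sign = numeric(0), n_voxels = integer(0),
                      peak_t = numeric(0), peak_target = numeric(0),
                      peak_source = numeric(0)))
  df <- do.call(rbind, rows)
  df[order(-abs(df$peak_t)), , drop = FALSE]
}

#' @export
print.coupling_stat_map <- function(x, ...) {
  cat(sprintf("<coupling_stat_map> df = %d, p < %g: %d voxels in %d cluster(s)\n",
              x$df, x$p_threshold, sum(x$sig), nrow(x$clusters)))
  invisible(x)
}

#' One-sample t-map over subjects
#'
#' Voxel-wise two-tailed one-sample t-test (df = n-1) of subject maps against
#' zero, thresholded at `p_threshold` (default 0.005 uncorrected), with
#' clusters extracted per sign under 4-neighbourhood connectivity.
#' Zero-variance voxels are flagged and their t value capped rather than
#' infinite.
#'
#' @param maps subjects x d1 x d2 numeric array (rows of each map index the
#'   target axis).
#' @param freqs coordinate grid for both axes (Hz for coupling maps).
#' @param p_threshold two-tailed significance level (default 0.005).
#' @return a `coupling_stat_map` with `t_map`, `p_map`, `sign_map`, `sig`,
#'   `zero_variance`, and a `clusters` data.frame.
#' @export
one_sample_tmap <- function(maps, freqs = NULL, p_threshold = 0.005) {
  stopifnot(is.array(maps), length(dim(maps)) == 3L, dim(maps)[1] >= 2)
  if (is.null(freqs)) freqs <- seq_len(dim(maps)[2])
  make_stat_map(array_tstat(maps), freqs, p_threshold)
}

#' Paired t-map over subjects
#'
#' Voxel-wise paired t-test on per-subject condition differences (A - B),
#' otherwise as [one_sample_tmap()].
#'
#' @param maps_a,maps_b subjects x d1 x d2 arrays, same subjects and order.
#' @inheritParams one_sample_tmap
#' @return a `coupling_stat_map`.
#' @export
paired_tmap <- function(maps_a, maps_b, freqs = NULL, p_threshold = 0.005) {
  stopifnot(all(dim(maps_a) == dim(maps_b)))
  one_sample_tmap(maps_a - maps_b, freqs, p_threshold)
}

#' Paired contrast of spectrograms across subjects
#'
#' Smooths each subject's region spectrograms with a Gaussian kernel
#' (default FWHM 8 Hz x 96 ms), then runs a voxel-wise paired t-test between
#' conditions per region and returns masked t-maps (non-significant entries
#' set to 0), the spectrogram analogue of the coupling contrast.
#'
#' @param specs_a,specs_b lists of [source_spectrogram()] (one per subject).
#' @param fwhm length-2: FWHM in Hz and ms (default `c(8, 96)`).
#' @param p_threshold two-tailed threshold (default 0.005).
#' @return named list per region: `stat` (a `coupling_stat_map` whose axes
#'   are frequency x time) and `masked_t` (t-map zeroed where not
#'   significant).
#' @export
spectrogram_contrast <- function(specs_a, specs_b, fwhm = c(8, 96),
                                 p_threshold = 0.005) {
  stopifnot(length(specs_a) == length(specs_b), length(specs_a) >= 2)
  sp1 <- specs_a[[1]]
  nreg <- dim(sp1$power)[1]
  df <- if (length(sp1$freqs) > 1) sp1$freqs[2] - sp1$freqs[1] else 1
  dtm <- if (length(sp1$times) > 1) sp1$times[2] - sp1$times[1] else 1
  out <- list()
  for (j in seq_len(nreg)) {
    diffarr <- array(0, dim = c(length(specs_a), length(sp1$freqs),
                                length(sp1$times)))
    for (s in seq_along(specs_a)) {
      a <- gaussian_smooth(specs_a[[s]]$power[j, , ], fwhm, c(df, dtm))
      b <- gaussian_smooth(specs_b[[s]]$power[j, , ], fwhm, c(df, dtm))
      diffarr[s, , ] <- a - b
    }
    st <- make_stat_map(array_tstat(diffarr), sp1$freqs, p_threshold,
                        axes = c("freq", "time"))
    masked <- st$t_map
    masked[!st$sig] <- 0
    out[[sp1$source_names[j]]] <- list(stat = st, masked_t = masked)
  }
  out
}

#' Cluster report table across connections
#'
#' One row per suprathreshold cluster: connection, band-to-band label taken
#' at the cluster peak, peak source -> target frequency, voxel count, peak t
#' and coupling sign - the layout of a frequency-to-frequency coupling
#' results table.
#'
#' @param stat_maps named list of `coupling_stat_map` (names `"src->tgt"`),
#'   e.g. [one_sample_tmap()] applied to each element of
#'   [coupling_to_frequency()].
#' @param bands a band scheme (default [band_scheme()]).
#' @return data.frame with columns `connection`, `bands` (e.g.
#'   `"beta -> beta"`), `peak` (e.g. `"25 -> 24"`),
#'   `peak_source`, `peak_target`, `n_voxels`, `t`, `sign`.
#' @export
cluster_table <- function(stat_maps, bands = band_scheme()) {
  rows <- list()
  for (conn in names(stat_maps)) {
    cl <- stat_maps[[conn]]$clusters
    for (r in seq_len(nrow(cl))) {
      rows[[length(rows) + 1]] <- data.frame(
        connection = sub("->", " \u2192 ", conn, fixed = TRUE),
        bands = paste(band_of(cl$peak_source[r], bands), "\u2192",
                      band_of(cl$peak_target[r], bands)),
        peak = paste(cl$peak_source[r], "\u2192", cl$peak_target[r]),
        peak_source = cl$peak_source[r], peak_target = cl$peak_target[r],
        n_voxels = cl$n_voxels[r],
        t = round(cl$peak_t[r], 1),
        sign = if (cl$sign[r] > 0) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(connection = character(0), bands = character(0),
                      peak = character(0), peak_source = numeric(0),
                      peak_target = numeric(0), n_voxels = integer(0),
                      t = numeric(0), sign = character(0)))
  do.call(rbind, rows)
}
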