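#' Default five-source motor network
#'
#' The modelled network: bilateral primary motor cortices (cM1, iM1),
#' bilateral premotor cortices (cPM, iPM) and a single supplementary motor
#' area (SMA) node, with SMA as the extrinsic input region. Coordinates are
#' MNI (mm), adapted from the Human Motor Area Template; "c"/"i" denote the
#' hemisphere contra-/ipsilateral to the moving (right) arm.
#'
#' @return a `network_spec`: list with `regions` (data.frame `name`, `x`,
#'   `y`, `z`), `input_region`, and `J` (region count).
#' @export
default_network <- function() {
  regions <- data.frame(
    name = c("cM1", "iM1", "cPM", "iPM", "SMA"),
    x = c(-37, 37, -35, 35, -2),
    y = c(-26, -26, -4, -4, -7),
    z = c(60, 60, 60, 60, 60),
    stringsAsFactors = FALSE)
  network_spec(regions, input_region = "SMA")
}

#' Construct a network specification
#'
#' @param regions data.frame with columns `name`, `x`, `y`, `z` (MNI mm).
#' @param input_region name of the region receiving the extrinsic input.
#' @return a `network_spec`.
#' @export
network_spec <- function(regions, input_region) {
  stopifnot(is.data.frame(regions),
            all(c("name", "x", "y", "z") %in% names(regions)),
            !anyDuplicated(regions$name),
            input_region %in% regions$name)
  structure(list(regions = regions, input_region = input_region,
                 J = nrow(regions)), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d regions, input = %s\n", x$J, x$input_region))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Construct a lead field (gain matrix)
#'
#' Maps unit dipole moments at the network sources to scalp channels. The
#' gain matrix must have full column rank so that the generalized inverse
#' recovers source activity from gain-spanned data.
#'
#' @param gain channels x sources numeric matrix (microvolts per unit moment).
#' @param channel_names character vector aligned with the rows of `gain`.
#' @param source_names optional character vector for the columns.
#' @return a `lead_field`.
#' @export
lead_field <- function(gain, channel_names = NULL, source_names = NULL) {
  stopifnot(is.matrix(gain), nrow(gain) >= ncol(gain))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(gain)))
  stopifnot(length(channel_names) == nrow(gain))
  if (!is.null(source_names)) stopifnot(length(source_names) == ncol(gain))
  s <- svd(gain)
  if (any(s$d <= 1e-10 * s$d[1])) {
    null_idx <- which(s$d <= 1e-10 * s$d[1])
    offending <- unique(unlist(lapply(null_idx, function(k)
      which(abs(s$v[, k]) > 0.1))))
    stop("lead field is rank deficient; dependent source columns: ",
         paste(sort(offending), collapse = ", "), call. = FALSE)
  }
  structure(list(gain = gain, channel_names = channel_names,
                 source_names = source_names), class = "lead_field")
}

#' Project channel-space trials onto dipole sources
#'
#' Applies the Moore-Penrose generalized inverse of the lead field
#' (singular-value cutoff `1e-10` of the largest singular value, see
#' [pinv()]) to every sample of every trial, yielding per-trial source
#' waveforms. Channel noise orthogonal to the gain column space is removed.
#'
#' @param ts a [trial_set()] in channel space.
#' @param lf a [lead_field()] whose `channel_names` match `ts`.
#' @return a `trial_set` whose "channels" are the sources (region waveforms);
#'   EMG, onsets and validity flags are carried over.
#' @export
project_to_sources <- function(ts, lf) {
  stopifnot(inherits(ts, "trial_set"), inherits(lf, "lead_field"))
  if (!identical(ts$channel_names, lf$channel_names))
    stop("channel sets of trials and lead field do not match", call. = FALSE)
  Ginv <- pinv(lf$gain)
  n <- n_trials(ts)
  J <- ncol(lf$gain)
  src <- array(0, dim = c(n, J, dim(ts$data)[3]))
  for (tr in seq_len(n))
    src[tr, , ] <- Ginv %*% ts$data[tr, , ]
  out <- ts
  out$data <- src
  out$channel_names <- lf$source_names %||% paste0("src", seq_len(J))
  attr(out, "space") <- "source"
  out
}
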