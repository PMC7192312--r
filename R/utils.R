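`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moore-Penrose pseudoinverse with explicit singular-value cutoff
#'
#' Computes the generalized inverse by singular value decomposition,
#' discarding singular values below `rtol` times the largest one.
#'
#' @param x numeric matrix.
#' @param rtol relative singular-value cutoff (default `1e-10`).
#' @return the pseudoinverse of `x` (ncol(x) by nrow(x)).
#' @export
pinv <- function(x, rtol = 1e-10) {
  s <- svd(x)
  if (length(s$d) == 0L || s$d[1] == 0) return(t(x) * 0)
  keep <- s$d > rtol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# overflow-safe log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# FWHM (in axis units) -> Gaussian sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# n x n convolution matrix for a truncated, renormalized Gaussian kernel.
# sigma is expressed in bins; each row is renormalized to unit mass so that
# constants are preserved at the boundaries.
gauss_conv_matrix <- function(n, sigma_bins) {
  if (sigma_bins <= 0) return(diag(n))
  r <- ceiling(4 * sigma_bins)
  idx <- seq_len(n)
  W <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= r, exp(-d^2 / (2 * sigma_bins^2)), 0)
  })
  W / rowSums(W)
}

#' Separable Gaussian smoothing of a matrix
#'
#' Smooths rows and/or columns of a matrix with a Gaussian kernel specified by
#' its full width at half maximum, using kernel renormalization at the
#' boundaries (the truncated kernel is rescaled to unit mass, so constant maps
#' are left unchanged).
#'
#' @param x numeric matrix (e.g. frequency x time power, or target-frequency x
#'   source-frequency coupling).
#' @param fwhm length-2 numeric: FWHM along rows (first axis) and columns
#'   (second axis), in the units of `spacing`. Use 0 to skip an axis.
#' @param spacing length-2 numeric: grid step along each axis, same units as
#'   `fwhm` (default `c(1, 1)`).
#' @return smoothed matrix, same dimensions.
#' @export
gaussian_smooth <- function(x, fwhm, spacing = c(1, 1)) {
  stopifnot(is.matrix(x), length(fwhm) == 2L, all(fwhm >= 0),
            length(spacing) == 2L, all(spacing > 0))
  if (fwhm[1] > 0)
    x <- gauss_conv_matrix(nrow(x), fwhm_to_sigma(fwhm[1]) / spacing[1]) %*% x
  if (fwhm[2] > 0)
    x <- x %*% t(gauss_conv_matrix(ncol(x), fwhm_to_sigma(fwhm[2]) / spacing[2]))
  x
}

# Label connected components of a logical mask using 4-neighbourhood
# connectivity. Returns an integer matrix (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), ncol = 2)
    lab[i0, j0] <- cur
    while (nrow(queue) > 0) {
      i <- queue[1, 1]; j <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Truncated-normal sampler by rejection (bounds in the same units as mean/sd).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x < upper])
  }
  out[seq_len(n)]
}

# md5 of the canonical JSON serialization of an R object (config stamping)
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null")), f)
  unname(tools::md5sum(f))
}

# derive a reproducible 32-bit sub-seed from a base seed and an index
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919 * as.numeric(k)) %% 2147483647)
}
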