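#' Reduce the frequency dimension to spectral modes by SVD
#'
#' Computes a single orthonormal frequency-loading matrix U (freqs x M) from
#' the singular value decomposition of the frequency x (time * source *
#' condition) concatenation of one or more spectrograms, then projects each
#' region's power onto the modes. The reduced trajectories g stack regions in
#' region-major order: elements 1..M are region 1's modes, M+1..2M region 2's,
#' and so on - the state vector of the dynamic model.
#'
#' Each mode's sign is fixed so that its largest-magnitude frequency loading
#' is positive, making coupling estimates reproducible across runs.
#'
#' @param specs a [source_spectrogram()] or a list of them (e.g. one per
#'   condition); all must share frequency grid, time grid and sources.
#' @param M number of modes to keep (default 4). If the data rank is lower, a
#'   warning is issued and the effective number of modes is reduced.
#' @return a `mode_decomp`: list with `U` (freqs x M orthonormal loadings),
#'   `singular_values` (all), `g` (list, one (J*M) x times matrix per input
#'   spectrogram), `variance_preserved` (fraction of total squared singular
#'   value), `freqs`, `times`, `source_names`, `M`, `J`.
#' @export
reduce_to_modes <- function(specs, M = 4) {
  if (inherits(specs, "source_spectrogram")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "source_spectrogram")))
  f0 <- specs[[1]]$freqs
  J <- dim(specs[[1]]$power)[1]
  for (sp in specs)
    stopifnot(identical(sp$freqs, f0), dim(sp$power)[1] == J,
              identical(sp$times, specs[[1]]$times))
  if (M > length(f0)) stop("M exceeds number of frequencies", call. = FALSE)
  # freqs x (time*source*condition) concatenation
  X <- do.call(cbind, lapply(specs, function(sp) {
    do.call(cbind, lapply(seq_len(J), function(j) sp$power[j, , ]))
  }))
  s <- svd(X)
  d <- s$d
  rank_eff <- sum(d > max(dim(X)) * .Machine$double.eps * max(d, 0))
  M_eff <- min(M, rank_eff)
  if (M_eff < M)
    warning(sprintf("data rank %d < requested %d modes; keeping %d",
                    rank_eff, M, M_eff))
  U <- s$u[, seq_len(M_eff), drop = FALSE]
  flip <- apply(U, 2, function(u) sign(u[which.max(abs(u))]))
  U <- sweep(U, 2, flip, `*`)
  varp <- if (sum(d^2) > 0) sum(d[seq_len(M_eff)]^2) / sum(d^2) else 1
  g <- lapply(specs, function(sp) {
    out <- matrix(0, J * M_eff, length(sp$times))
    for (j in seq_len(J))
      out[(j - 1) * M_eff + seq_len(M_eff), ] <- t(U) %*% sp$power[j, , ]
    rownames(out) <- paste0(rep(sp$source_names, each = M_eff),
                            ".m", seq_len(M_eff))
    out
  })
  structure(list(U = U, singular_values = d, g = g,
                 variance_preserved = varp, freqs = f0,
                 times = specs[[1]]$times,
                 source_names = specs[[1]]$source_names,
                 M = M_eff, J = J),
            class = "mode_decomp")
}

#' @export
print.mode_decomp <- function(x, ...) {
  cat(sprintf("<mode_decomp> %d modes over %d freqs, %d regions; variance preserved %.1f%%\n",
              x$M, length(x$freqs), x$J, 100 * x$variance_preserved))
  invisible(x)
}

#' Back-project mode-space power trajectories to the frequency domain
#'
#' Inverts the mode reduction for a state trajectory: for each region, the
#' frequency x time power is `U %*% g_region`.
#'
#' @param md a `mode_decomp` from [reduce_to_modes()].
#' @param g a (J*M) x times matrix in region-major mode order.
#' @return a [source_spectrogram()] with freqs x times power per region.
#' @export
backproject_power <- function(md, g) {
  stopifnot(inherits(md, "mode_decomp"), is.matrix(g),
            nrow(g) == md$J * md$M)
  P <- array(0, dim = c(md$J, length(md$freqs), ncol(g)))
  for (j in seq_len(md$J))
    P[j, , ] <- md$U %*% g[(j - 1) * md$M + seq_len(md$M), , drop = FALSE]
  source_spectrogram(P, md$freqs,
                     if (ncol(g) == length(md$times)) md$times
                     else seq_len(ncol(g)),
                     source_names = md$source_names)
}

#' Back-project a mode-space coupling block to frequency-to-frequency coupling
#'
#' For a single connection's M x M coupling block A_ij (target modes in rows,
#' source modes in columns), the frequency-domain coupling map is
#' `U %*% A_ij %*% t(U)`: rows index target frequency, columns source
#' frequency.
#'
#' @param md a `mode_decomp`.
#' @param block M x M numeric matrix.
#' @return freqs x freqs coupling matrix.
#' @export
backproject_coupling <- function(md, block) {
  stopifnot(inherits(md, "mode_decomp"), is.matrix(block),
            all(dim(block) == md$M))
  md$U %*% block %*% t(md$U)
}
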