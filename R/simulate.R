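#' Forward-simulate mode-space power dynamics
#'
#' Integrates the linear power-dynamics equation
#' \deqn{\tau \dot g(t) = A g(t) + C u(t)}
#' where g stacks the spectral-mode power of all regions (region-major), A is
#' the (J*M) x (J*M) coupling matrix, C weights the extrinsic input u(t), and
#' tau is a fixed scaling time constant. Integration uses per-bin
#' matrix-exponential propagation with u held constant within each bin, which
#' is exact for piecewise-constant input.
#'
#' @param model a [dcm_model()] (provides the mask, input spec and tau).
#' @param A coupling matrix; entries outside `model$A_mask` must be zero.
#' @param C input weight vector (length J*M); nonzero only on input-region
#'   rows.
#' @param g0 initial state (length J*M).
#' @param times uniform time grid in ms (0 = EMG onset).
#' @param u optional input vector on `times`; default [gamma_input()] with
#'   the model's input spec.
#' @return (J*M) x length(times) matrix of state trajectories.
#' @export
simulate_power <- function(model, A, C = NULL, g0 = NULL, times, u = NULL) {
  stopifnot(inherits(model, "dcm_model"), is.matrix(A))
  n <- model$network$J * model$M
  stopifnot(all(dim(A) == n))
  if (any(A[!model$A_mask] != 0))
    stop("A has nonzero entries outside the model mask", call. = FALSE)
  if (is.null(C)) C <- rep(0, n)
  if (is.null(g0)) g0 <- rep(0, n)
  stopifnot(length(C) == n, length(g0) == n)
  nt <- length(times)
  stopifnot(nt >= 2)
  dts <- diff(times)
  if (max(abs(dts - dts[1])) > 1e-6 * abs(dts[1]))
    stop("time grid must be uniform", call. = FALSE)
  if (is.null(u))
    u <- gamma_input(times, model$input$peak_ms, model$input$dispersion_ms)
  stopifnot(length(u) == nt)
  dt_s <- dts[1] / 1000
  span_s <- (times[nt] - times[1]) / 1000
  ev_max <- max(Re(eigen(A, only.values = TRUE)$values))
  if (ev_max * span_s / model$tau > log(1e12))
    stop("unstable A: trajectories would overflow (max real eigenvalue ",
         signif(ev_max, 4), ")", call. = FALSE)
  EB <- propagator(A, C, dt_s / model$tau)
  g <- matrix(0, n, nt)
  g[, 1] <- g0
  for (k in seq_len(nt - 1))
    g[, k + 1] <- EB$E %*% g[, k] + EB$b * u[k]
  rownames(g) <- paste0(rep(model$network$regions$name, each = model$M),
                        ".m", seq_len(model$M))
  g
}

# one-step propagator for tau*g' = A g + C u with u constant over the bin:
# E = expm(A h), b = (int_0^h expm(A s) ds) C, via the augmented exponential
propagator <- function(A, C, h) {
  n <- nrow(A)
  Maug <- rbind(cbind(A, C), rep(0, n + 1)) * h
  P <- as.matrix(Matrix::expm(Maug))
  list(E = P[seq_len(n), seq_len(n), drop = FALSE], b = P[seq_len(n), n + 1])
}
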