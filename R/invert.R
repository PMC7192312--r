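#' Fraction of variance explained by a model prediction
#'
#' `1 - SS_residual / SS_total`, pooled over all states and times, with
#' SS_total taken about the grand mean of the observations. Defined as 0 for
#' zero-variance observations.
#'
#' @param observed,predicted equally shaped numeric matrices/vectors.
#' @return a scalar fraction (can be negative for predictions worse than the
#'   mean; never exceeds 1).
#' @export
variance_explained <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(0)
  1 - sum((observed - predicted)^2) / sst
}

#' Estimate coupling parameters by variational Laplace
#'
#' Fits the free entries of the A (coupling) and C (input weight) matrices of
#' a [dcm_model()], together with the initial state, to observed mode-space
#' power trajectories, minimizing the error between observed and simulated
#' spectrogram dynamics under Gaussian shrinkage priors. Estimation is
#' Gauss-Newton on the posterior mode with a finite-difference Jacobian, an
#' EM update of the observation noise precision (broad Gamma hyperprior),
#' and step-size control so that the recorded variational free energy is
#' non-decreasing over accepted iterations: a step that lowers the free
#' energy is reverted and retried at a smaller scale. The free energy is the
#' model evidence approximation consumed by [rfx_bms()]; a BIC value is also
#' reported for cross-checking.
#'
#' The initial state is a free parameter with its prior centered on the
#' first observed sample (fixing it to the noisy sample would force the
#' deterministic trajectory through an off-manifold point and push the
#' misfit into spurious couplings). Masked-out A entries remain exactly
#' zero.
#'
#' @param model a [dcm_model()].
#' @param observed_g (J*M) x times matrix (e.g. `mode_decomp$g[[cond]]`).
#' @param times uniform time grid in ms matching `observed_g`.
#' @param u optional input vector (default: the model's gamma input).
#' @param prior list: `a_var` (prior variance of free extrinsic A entries,
#'   default 1/16), `self_mean`, `self_var` (prior mean and variance of the
#'   intrinsic self-connections on the A diagonal, defaults -0.5 and 1:
#'   self-decay is known to be negative and of order one, so it gets a
#'   negative-mean, wider prior than the shrinkage prior on extrinsic
#'   couplings), `intr_var` (prior variance of within-region cross-mode
#'   entries when the intrinsic blocks are nonlinear; defaults to `a_var`),
#'   `c_var` (prior variance of C entries, default 1), `g0_var` (prior
#'   variance of the initial state about the first observed sample, default
#'   1), `a0`, `b0` (Gamma hyperprior on the noise precision, defaults 1e-3
#'   and 1e-6; the small rate keeps the precision essentially unbounded so
#'   that noise-free data can be fitted exactly).
#' @param init_diag initial value of intrinsic block-diagonal A entries
#'   (default -0.5, a stable decay).
#' @param max_iter maximum Gauss-Newton iterations (default 128).
#' @param tol free-energy convergence tolerance in nats (default 0.01).
#' @param fd_step finite-difference step (default 1e-4).
#' @return a `dcm_fit`: `A_hat`, `C_hat`, `g0_hat`, `posterior_cov`,
#'   `noise_precision`, `free_energy` (nats), `F_trace`, `bic`, `n_iter`,
#'   `converged`, `variance_explained`, `predicted_g`, `model_name`,
#'   `prior`.
#' @export
fit_dcm <- function(model, observed_g, times, u = NULL,
                    prior = list(), init_diag = -0.5, max_iter = 128,
                    tol = 0.01, fd_step = 1e-4) {
  stopifnot(inherits(model, "dcm_model"), is.matrix(observed_g))
  prior <- utils::modifyList(
    list(a_var = 1 / 16, self_mean = -0.5, self_var = 1,
         intr_var = NULL, c_var = 1, g0_var = 1, a0 = 1e-3, b0 = 1e-6),
    prior)
  if (is.null(prior$intr_var)) prior$intr_var <- prior$a_var
  n <- model$network$J * model$M
  if (nrow(observed_g) != n || ncol(observed_g) != length(times))
    stop("observed_g dimensions do not match model/times", call. = FALSE)
  nt <- length(times)
  dt_s <- (times[2] - times[1]) / 1000
  if (is.null(u))
    u <- gamma_input(times, model$input$peak_ms, model$input$dispersion_ms)
  idxA <- which(model$A_mask)
  idxC <- which(model$C_mask)
  pA <- length(idxA); pC <- length(idxC); p <- pA + pC + n
  y <- as.vector(observed_g)
  N <- length(y)

  forward <- function(theta) {
    A <- matrix(0, n, n); A[idxA] <- theta[seq_len(pA)]
    C <- rep(0, n); C[idxC] <- theta[pA + seq_len(pC)]
    EB <- propagator(A, C, dt_s / model$tau)
    g <- matrix(0, n, nt)
    g[, 1] <- theta[pA + pC + seq_len(n)]
    E <- EB$E; b <- EB$b
    for (k in seq_len(nt - 1))
      g[, k + 1] <- E %*% g[, k] + b * u[k]
    if (!all(is.finite(g)) || max(abs(g)) > 1e10) return(NULL)
    as.vector(g)
  }

  # forward differences while the residual is large; central differences
  # (half the truncation-order error) once the fit is within ~100*fd_step of
  # the data, where forward-difference error would drown the gradient
  jacobian <- function(theta, f0, rms_resid) {
    J <- matrix(0, N, p)
    central <- rms_resid < 100 * fd_step
    for (q in seq_len(p)) {
      th <- theta; th[q] <- th[q] + fd_step
      fq <- forward(th)
      if (central || is.null(fq)) {
        th <- theta; th[q] <- th[q] - fd_step
        fb <- forward(th)
        if (is.null(fq) && is.null(fb)) next
        if (is.null(fq)) J[, q] <- (f0 - fb) / fd_step
        else if (is.null(fb)) J[, q] <- (fq - f0) / fd_step
        else J[, q] <- (fq - fb) / (2 * fd_step)
      } else J[, q] <- (fq - f0) / fd_step
    }
    J
  }

  diag_idx <- which(idxA %in% ((0:(n - 1)) * n + 1:n))   # self-connections
  M <- model$M
  region_of <- function(state) (state - 1) %/% M + 1
  intr_idx <- which(region_of((idxA - 1) %% n + 1) ==
                    region_of((idxA - 1) %/% n + 1))  # within-region block
  avar <- rep(prior$a_var, pA)
  avar[intr_idx] <- prior$intr_var
  avar[diag_idx] <- prior$self_var
  amean <- rep(0, pA); amean[diag_idx] <- prior$self_mean
  pvar <- c(avar, rep(prior$c_var, pC), rep(prior$g0_var, n))
  Pi0 <- diag(1 / pvar, p)
  ld_Pi0 <- sum(log(1 / pvar))
  theta0 <- c(amean, rep(0, pC), observed_g[, 1])
  A_init <- matrix(0, n, n); diag(A_init) <- init_diag
  theta <- c(A_init[idxA], rep(0, pC), observed_g[, 1])

  f <- forward(theta)
  if (is.null(f))
    stop("divergent initial simulation (non-finite residuals)", call. = FALSE)
  lambda <- 1 / max(mean((y - f)^2), 1e-8)

  free_energy <- function(theta, lambda, ssr, cP) {
    dth <- theta - theta0
    -lambda / 2 * ssr + N / 2 * log(lambda) - N / 2 * log(2 * pi) -
      0.5 * sum(dth * (Pi0 %*% dth)) +
      0.5 * (ld_Pi0 - 2 * sum(log(diag(cP))))
  }

  F_trace <- numeric(0)
  best <- NULL
  converged <- FALSE
  step_scale <- 1
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    r <- y - f
    ssr <- sum(r^2)
    J <- jacobian(theta, f, sqrt(ssr / N))
    JtJ <- crossprod(J)
    for (k in 1:2) {
      cP <- chol(lambda * JtJ + Pi0)
      Spost <- chol2inv(cP)
      lambda <- (N + 2 * (prior$a0 - 1)) /
        (ssr + sum(JtJ * Spost) + 2 * prior$b0)
    }
    cP <- chol(lambda * JtJ + Pi0)
    Spost <- chol2inv(cP)
    Fcur <- free_energy(theta, lambda, ssr, cP)
    if (!is.null(best) && Fcur < best$F - 1e-8) {
      # revert to the best point and retry with a smaller step
      step_scale <- step_scale / 2
      if (step_scale < 1e-4) { converged <- TRUE; break }
      theta <- best$theta; f <- best$f; lambda <- best$lambda
      r <- y - f; ssr <- best$ssr
      J <- best$J; JtJ <- best$JtJ; Spost <- best$Spost
      Fcur <- best$F
    } else {
      if (!is.null(best) && abs(Fcur - best$F) < tol) {
        best <- list(theta = theta, f = f, ssr = ssr, lambda = lambda,
                     J = J, JtJ = JtJ, Spost = Spost, F = Fcur)
        F_trace <- c(F_trace, Fcur)
        converged <- TRUE
        break
      }
      best <- list(theta = theta, f = f, ssr = ssr, lambda = lambda,
                   J = J, JtJ = JtJ, Spost = Spost, F = Fcur)
      F_trace <- c(F_trace, Fcur)
      step_scale <- min(1, step_scale * 2)
    }
    dth <- theta - theta0
    delta <- Spost %*% (lambda * crossprod(J, r) - Pi0 %*% dth)
    Qcur <- -lambda / 2 * ssr - 0.5 * sum(dth * (Pi0 %*% dth))
    s <- step_scale
    accepted <- FALSE
    for (h in 1:8) {
      th_new <- theta + s * as.vector(delta)
      f_new <- forward(th_new)
      if (!is.null(f_new)) {
        dth_new <- th_new - theta0
        Qnew <- -lambda / 2 * sum((y - f_new)^2) -
          0.5 * sum(dth_new * (Pi0 %*% dth_new))
        if (Qnew > Qcur) {
          theta <- th_new; f <- f_new; accepted <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (!accepted) { converged <- TRUE; break }
  }
  theta <- best$theta
  A_hat <- matrix(0, n, n); A_hat[idxA] <- theta[seq_len(pA)]
  C_hat <- rep(0, n); C_hat[idxC] <- theta[pA + seq_len(pC)]
  pred <- matrix(best$f, n, nt)
  rownames(pred) <- rownames(observed_g)
  bic <- N * log(max(best$ssr, 1e-300) / N) + p * log(N)
  structure(list(
    A_hat = A_hat, C_hat = C_hat,
    g0_hat = theta[pA + pC + seq_len(n)],
    posterior_cov = best$Spost, noise_precision = best$lambda,
    free_energy = best$F, F_trace = F_trace, bic = bic,
    n_iter = it, converged = converged,
    variance_explained = variance_explained(y, best$f),
    predicted_g = pred, model_name = model$name, prior = prior,
    idxA = idxA, idxC = idxC
  ), class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %s: F = %.2f nats, var expl = %.1f%%, %d iter%s\n",
              x$model_name, x$free_energy, 100 * x$variance_explained,
              x$n_iter, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Extract one connection's coupling block from a fit
#'
#' @param fit a `dcm_fit`.
#' @param model the [dcm_model()] used for the fit.
#' @param from,to region names (source, target).
#' @return the M x M coupling block (target modes in rows).
#' @export
coupling_block <- function(fit, model, from, to) {
  nm <- model$network$regions$name
  i <- match(to, nm); j <- match(from, nm)
  if (is.na(i) || is.na(j)) stop("unknown region name", call. = FALSE)
  M <- model$M
  fit$A_hat[(i - 1) * M + seq_len(M), (j - 1) * M + seq_len(M), drop = FALSE]
}
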