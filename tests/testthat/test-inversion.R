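tiny_sim <- function(A, C, g0, tm, mod) {
  simulate_power(mod, A, C, g0, tm)
}

test_that("variance explained follows its definition", {
  set.seed(61)
  obs <- matrix(rnorm(40), 4, 10)
  expect_equal(variance_explained(obs, obs), 1)
  expect_equal(variance_explained(obs, matrix(mean(obs), 4, 10)), 0)
  expect_equal(variance_explained(matrix(0, 2, 5), matrix(0, 2, 5)), 0)

  # signal + noise at known SNR: expected fraction = SS_signal / SS_total
  sig <- matrix(rnorm(4000), 40, 100)
  noise <- matrix(rnorm(4000, 0, 0.5), 40, 100)
  obs2 <- sig + noise
  ve <- variance_explained(obs2, sig)
  expect_equal(ve, sum(sig^2) / sum((obs2 - mean(obs2))^2),
               tolerance = 0.05)
  expect_equal(ve, 1 / (1 + 0.25), tolerance = 0.05)
})

test_that("noise-free coupling is recovered within 0.05", {
  tm <- seq(-1000, 0, by = 10)
  mod <- tiny_model(intrinsic_nonlinear = TRUE)
  # distinct stable decay rates: states with identical time constants have
  # indistinguishable free-decay signatures and the entry is unidentifiable
  A <- matrix(0, 4, 4); diag(A) <- c(-0.8, -1.3, -1.0, -1.5)
  A[3, 1] <- 0.5                      # R1 mode 1 -> R2 mode 1
  C <- c(0.3, -1, 0, 0)
  set.seed(62)
  g0 <- rnorm(4, 0, 0.5)
  obs <- tiny_sim(A, C, g0, tm, mod)
  fit <- fit_dcm(mod, obs, tm)
  expect_lt(abs(fit$A_hat[3, 1] - 0.5), 0.05)
  expect_gt(fit$variance_explained, 0.999)
  expect_true(fit$converged)
})

test_that("zero data shrinks estimates to the prior and explains nothing", {
  tm <- seq(-1000, 0, by = 10)
  mod <- tiny_model()
  obs <- matrix(0, 4, length(tm))
  fit <- fit_dcm(mod, obs, tm)
  off <- fit$A_hat[row(fit$A_hat) != col(fit$A_hat)]
  expect_lt(max(abs(off)), 1e-3)
  expect_lt(max(abs(fit$C_hat)), 1e-3)
  expect_equal(fit$variance_explained, 0)
})

test_that("coupling signs are recovered under 10% noise in >= 11/12 fits", {
  tm <- seq(-1000, 0, by = 10)
  mod <- tiny_model(intrinsic_nonlinear = TRUE)
  hits <- 0
  set.seed(63)
  for (rep in 1:12) {
    A <- matrix(0, 4, 4); diag(A) <- runif(4, -1.4, -0.6)
    A[3, 1] <- 0.6; A[2, 4] <- -0.6
    C <- c(0.3, -1, 0, 0)
    g0 <- rnorm(4, 0, 0.5)
    g <- tiny_sim(A, C, g0, tm, mod)
    obs <- g + matrix(rnorm(length(g), 0, 0.1 * sd(g)), nrow(g))
    fit <- fit_dcm(mod, obs, tm)
    if (fit$A_hat[3, 1] > 0 && fit$A_hat[2, 4] < 0) hits <- hits + 1
  }
  expect_gte(hits, 11)
})

test_that("free energy is non-decreasing and masked entries stay zero", {
  tm <- seq(-1000, 0, by = 10)
  net <- tiny_network()
  ext <- matrix("nonlinear", 2, 2)
  ext[1, 2] <- "absent"               # no R2 -> R1 connection
  mod <- dcm_model(net, M = 2, extrinsic = ext)
  set.seed(64)
  A <- matrix(0, 4, 4); diag(A) <- -1; A[3, 1] <- 0.5
  g <- tiny_sim(A, c(0.3, -0.8, 0, 0), rnorm(4), tm, mod)
  obs <- g + matrix(rnorm(length(g), 0, 0.05 * sd(g)), nrow(g))
  fit <- fit_dcm(mod, obs, tm)
  expect_true(all(diff(fit$F_trace) >= -1e-8))
  expect_true(all(fit$A_hat[!mod$A_mask] == 0))
  expect_true(all(fit$C_hat[!mod$C_mask] == 0))
})

test_that("extra couplings in an over-specified model stay within 2 SD", {
  tm <- seq(-1000, 0, by = 10)
  full <- tiny_model(intrinsic_nonlinear = TRUE)
  n_ok <- 0; n_tot <- 0
  set.seed(65)
  for (rep in 1:5) {
    # data from a reduced model: only R1 -> R2 coupling active
    A <- matrix(0, 4, 4); diag(A) <- runif(4, -1.3, -0.7)
    A[3, 1] <- 0.5
    g <- tiny_sim(A, c(0.3, -1, 0, 0), rnorm(4, 0, 0.5), tm, full)
    obs <- g + matrix(rnorm(length(g), 0, 0.1 * sd(g)), nrow(g))
    fit <- fit_dcm(full, obs, tm)
    sds <- sqrt(diag(fit$posterior_cov))
    # free A entries absent in the generating model (R2 -> R1 block)
    idx_free <- which(fit$idxA %in% which(row(A) <= 2 & col(A) >= 3))
    est <- fit$A_hat[fit$idxA[idx_free]]
    n_ok <- n_ok + sum(abs(est) < 2 * sds[idx_free])
    n_tot <- n_tot + length(idx_free)
  }
  expect_gte(n_ok / n_tot, 0.9)
})

test_that("evidence ranks the generating structure above pruned models", {
  tm <- seq(-1000, 0, by = 10)
  net <- tiny_network()
  full <- tiny_model(intrinsic_nonlinear = TRUE)
  ext_red <- matrix("nonlinear", 2, 2); ext_red[2, 1] <- "absent"
  pruned <- dcm_model(net, M = 2, extrinsic = ext_red,
                      intrinsic_nonlinear = TRUE, name = "pruned")
  wins <- 0
  set.seed(66)
  for (rep in 1:5) {
    A <- matrix(0, 4, 4); diag(A) <- runif(4, -1.3, -0.7)
    A[3, 1] <- 0.8                    # truly active R1 -> R2 coupling
    g <- tiny_sim(A, c(0.3, -1, 0, 0), rnorm(4, 0, 0.5), tm, full)
    obs <- g + matrix(rnorm(length(g), 0, 0.1 * sd(g)), nrow(g))
    Ff <- fit_dcm(full, obs, tm)$free_energy
    Fp <- fit_dcm(pruned, obs, tm)$free_energy
    if (Ff > Fp) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
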