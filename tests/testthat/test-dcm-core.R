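test_that("the gamma input peaks 400 ms before onset with SD 400 ms", {
  tm <- seq(-1000, 0, by = 10)
  u <- gamma_input(tm)
  expect_equal(tm[which.max(u)], -400, tolerance = 5)
  expect_equal(max(u), 1)
  expect_true(all(u >= 0))

  # numerically computed SD of the un-truncated bump
  tl <- seq(-1000, 9000, by = 1)
  ul <- gamma_input(tl)
  m1 <- sum(tl * ul) / sum(ul)
  sdv <- sqrt(sum((tl - m1)^2 * ul) / sum(ul))
  expect_equal(sdv, 400, tolerance = 1)

  expect_error(gamma_input(seq(-300, 0, 10)), "window")
})

test_that("the model space has two families of six with model 12 full", {
  ms <- build_model_space()
  expect_length(ms$models, 12)
  expect_equal(as.vector(table(ms$families)), c(6, 6))
  expect_equal(unname(ms$families["m12"]), "nonlinear_intrinsic")
  m12 <- ms$models$m12
  off <- m12$extrinsic[row(m12$extrinsic) != col(m12$extrinsic)]
  expect_true(all(off == "nonlinear"))
  expect_true(m12$intrinsic_nonlinear)

  # families share extrinsic structure; only intrinsic linearity differs
  for (k in 1:6) {
    a <- ms$models[[k]]; b <- ms$models[[k + 6]]
    ea <- a$extrinsic; eb <- b$extrinsic
    expect_equal(ea[row(ea) != col(ea)], eb[row(eb) != col(eb)])
    expect_false(a$intrinsic_nonlinear)
    expect_true(b$intrinsic_nonlinear)
  }

  # each family: exactly one fully connected model
  n_absent <- vapply(ms$models, function(m) sum(m$extrinsic == "absent"), 0)
  expect_equal(unname(n_absent[c(6, 12)]), c(0, 0))
  expect_true(all(n_absent[c(1:5, 7:11)] >= 1))
})

test_that("masks encode linear, nonlinear and absent connections", {
  net <- default_network()
  ext <- matrix("nonlinear", 5, 5,
                dimnames = list(net$regions$name, net$regions$name))
  ext["cM1", "SMA"] <- "linear"
  ext["iM1", "SMA"] <- "absent"
  m <- dcm_model(net, extrinsic = ext)
  blk <- function(i, j) m$A_mask[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4]
  expect_equal(blk(1, 5), diag(4) > 0)          # linear: diagonal only
  expect_true(all(!blk(2, 5)))                  # absent: all zero
  expect_true(all(blk(3, 1)))                   # nonlinear: full
  expect_equal(blk(1, 1), diag(4) > 0)          # linear intrinsic
  m2 <- dcm_model(net, extrinsic = ext, intrinsic_nonlinear = TRUE)
  expect_true(all(m2$A_mask[1:4, 1:4]))
})

test_that("model spaces round-trip through the text config", {
  ms <- build_model_space()
  cfg <- model_space_to_config(ms)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  ms2 <- model_space_from_config(yaml::read_yaml(tmp))
  expect_equal(names(ms2$models), names(ms$models))
  for (k in seq_along(ms$models)) {
    expect_equal(ms2$models[[k]]$A_mask, ms$models[[k]]$A_mask)
    expect_equal(ms2$models[[k]]$extrinsic, ms$models[[k]]$extrinsic)
  }
  expect_equal(ms2$families, ms$families)
})

test_that("forward simulation matches closed-form solutions", {
  tm <- seq(-1000, 0, by = 10)
  mod <- tiny_model()
  n <- 4
  # A = 0, C = 0: constant state
  g0 <- c(1, -2, 3, 0.5)
  g <- simulate_power(mod, matrix(0, n, n), rep(0, n), g0, tm,
                      u = rep(0, length(tm)))
  expect_equal(g, matrix(g0, n, length(tm)), ignore_attr = TRUE,
               tolerance = 1e-12)

  # u = 0, stable A: matrix exponential solution
  set.seed(51)
  A <- matrix(rnorm(n * n, 0, 0.4), n, n); diag(A) <- diag(A) - 1.5
  A[!tiny_model(intrinsic_nonlinear = TRUE)$A_mask] <- 0
  modn <- tiny_model(intrinsic_nonlinear = TRUE)
  g2 <- simulate_power(modn, A, rep(0, n), g0, tm, u = rep(0, length(tm)))
  eg <- eigen(A)
  oracle <- sapply(tm, function(t)
    Re(eg$vectors %*% diag(exp(eg$values * (t - tm[1]) / 1000)) %*%
         solve(eg$vectors) %*% g0))
  expect_lt(max(abs(g2 - oracle)), 1e-8)

  # A = 0, unit C weight: cumulative input integral
  C <- c(1, 0, 0, 0)
  u <- gamma_input(tm)
  g3 <- simulate_power(mod, matrix(0, n, n), C, rep(0, n), tm, u = u)
  dt <- 10 / 1000
  quad <- c(0, cumsum(u[-length(u)] * dt))
  expect_lt(max(abs(g3[1, ] - quad)), 1e-10)
  expect_equal(max(abs(g3[2:4, ])), 0)
})

test_that("simulation is superposable and exact under step refinement", {
  tm <- seq(-1000, 0, by = 10)
  modn <- tiny_model(intrinsic_nonlinear = TRUE)
  set.seed(52)
  A <- matrix(rnorm(16, 0, 0.3), 4, 4); diag(A) <- diag(A) - 1
  g01 <- rnorm(4); g02 <- rnorm(4)
  z <- rep(0, length(tm))
  s <- function(g0) simulate_power(modn, A, rep(0, 4), g0, tm, u = z)
  expect_equal(s(g01 + g02), s(g01) + s(g02), tolerance = 1e-10)

  # same piecewise-constant input on a twice-finer grid: identical trajectory
  u <- gamma_input(tm)
  tm2 <- seq(-1000, 0, by = 5)
  u2 <- rep(u, each = 2)[seq_along(tm2)]
  C <- c(0.5, -1, 0, 0)
  g_c <- simulate_power(modn, A, C, g01, tm, u = u)
  g_f <- simulate_power(modn, A, C, g01, tm2, u = u2)
  expect_lt(max(abs(g_f[, seq(1, length(tm2), by = 2)] - g_c)), 1e-6)
})

test_that("instability and mask violations are caught", {
  tm <- seq(-1000, 0, by = 10)
  modn <- tiny_model(intrinsic_nonlinear = TRUE)
  A_bad <- diag(c(40, -1, -1, -1))
  expect_error(simulate_power(modn, A_bad, g0 = rep(1, 4), times = tm),
               "unstable")
  mod_lin <- tiny_model()
  A_off <- matrix(0, 4, 4); diag(A_off) <- -1; A_off[2, 1] <- 0.3
  expect_error(simulate_power(mod_lin, A_off, g0 = rep(0, 4), times = tm),
               "mask")
})
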