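test_that("band scheme partitions 4-48 Hz", {
  b <- band_scheme()
  expect_equal(b$lo[1], 4)
  expect_equal(b$hi[nrow(b)], 48)
  expect_true(all(b$lo[-1] == b$hi[-nrow(b)] + 1))
})

test_that("voxel t statistics match the textbook formula and t.test", {
  vals <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2, 3, 2)
  maps <- array(0, dim = c(12, 2, 2))
  maps[, 1, 1] <- vals
  set.seed(71)
  maps[, 1, 2] <- rnorm(12); maps[, 2, ] <- rnorm(24)
  st <- one_sample_tmap(maps)
  t_hand <- mean(vals) / (sd(vals) / sqrt(12))
  expect_equal(st$t_map[1, 1], t_hand, tolerance = 1e-12)
  expect_equal(st$t_map[1, 1], unname(t.test(vals)$statistic),
               tolerance = 1e-12)
  expect_equal(st$p_map[1, 2], t.test(maps[, 1, 2])$p.value,
               tolerance = 1e-12)
})

test_that("zero-variance voxels are capped and flagged, not infinite", {
  maps <- array(1, dim = c(5, 3, 3))
  st <- one_sample_tmap(maps)
  expect_true(all(is.finite(st$t_map)))
  expect_true(all(st$zero_variance))
  maps0 <- array(0, dim = c(5, 3, 3))
  st0 <- one_sample_tmap(maps0)
  expect_true(all(st0$t_map == 0))
})

test_that("the null false-positive rate matches the nominal level", {
  set.seed(72)
  n_vox <- 0; n_sig <- 0
  for (rep in 1:6) {
    maps <- array(rnorm(12 * 45 * 45), dim = c(12, 45, 45))
    st <- one_sample_tmap(maps, p_threshold = 0.005)
    n_sig <- n_sig + sum(st$sig)
    n_vox <- n_vox + length(st$sig)
  }
  se <- sqrt(0.005 * 0.995 / n_vox)
  expect_lt(abs(n_sig / n_vox - 0.005), 4 * se)
})

test_that("paired maps are null for identical inputs and antisymmetric", {
  set.seed(73)
  a <- array(rnorm(12 * 10 * 10), dim = c(12, 10, 10))
  st_eq <- paired_tmap(a, a)
  expect_equal(sum(st_eq$sig), 0)

  b <- array(rnorm(12 * 10 * 10), dim = c(12, 10, 10))
  st_ab <- paired_tmap(a, b)
  st_ba <- paired_tmap(b, a)
  expect_equal(st_ab$t_map, -st_ba$t_map, tolerance = 1e-12)
})

test_that("paired-test power matches the noncentral-t prediction", {
  set.seed(74)
  n <- 12; delta <- 1.2; sigma <- 1
  nrep <- 4000
  diffs <- matrix(rnorm(nrep * n, delta, sigma), n, nrep)
  tv <- colMeans(diffs) / (apply(diffs, 2, sd) / sqrt(n))
  tcrit <- qt(1 - 0.005 / 2, n - 1)
  emp <- mean(abs(tv) > tcrit)
  ncp <- delta / (sigma / sqrt(n))
  pred <- pt(tcrit, n - 1, ncp, lower.tail = FALSE) +
    pt(-tcrit, n - 1, ncp)
  expect_lt(abs(emp - pred), 0.05 * max(pred, 0.2))
})

test_that("coupling maps back-project blocks and smooth safely", {
  sp <- local({
    set.seed(75)
    U <- qr.Q(qr(matrix(rnorm(45 * 4), 45, 4)))
    pw <- array(0, dim = c(5, 45, 101))
    for (j in 1:5) pw[j, , ] <- U %*% matrix(rnorm(4 * 101), 4, 101)
    source_spectrogram(pw, 4:48, seq(-1000, 0, length.out = 101),
                       source_names = default_network()$regions$name)
  })
  md <- reduce_to_modes(sp, M = 4)
  # zero block -> zero map
  expect_equal(max(abs(backproject_coupling(md, matrix(0, 4, 4)))), 0)
  # rank-1 block u1 u1' -> outer product of loadings
  u1 <- c(1, 0.5, -0.2, 0)
  B <- backproject_coupling(md, u1 %o% u1)
  expect_equal(B, (md$U %*% u1) %*% t(md$U %*% u1), tolerance = 1e-10)
  # constant map is invariant under smoothing
  cmap <- matrix(3, 45, 45)
  expect_equal(gaussian_smooth(cmap, c(8, 8)), cmap, tolerance = 1e-12)
})

test_that("clusters are 4-connected, sign-split and fully accounted", {
  tmap <- matrix(0, 10, 10)
  tmap[2, 2] <- 6                      # isolated voxel
  tmap[5, 5] <- 7; tmap[6, 5] <- 6.5; tmap[6, 6] <- 6.2   # L-shaped blob
  tmap[7, 7] <- -6                     # opposite sign sharing a corner
  sig <- abs(tmap) > 3
  cl <- dcmir:::extract_clusters(tmap, sig, freqs = 1:10,
                                 axes = c("freq", "freq"))
  expect_equal(nrow(cl), 3)
  expect_equal(sum(cl$n_voxels), sum(sig))
  blob <- cl[cl$n_voxels == 3, ]
  expect_equal(blob$peak_t, 7)
  expect_equal(blob$sign, 1)
  expect_equal(sum(cl$sign == -1), 1)

  # diagonal neighbours of opposite sign stay separate clusters
  tmap2 <- matrix(0, 5, 5)
  tmap2[2, 2] <- 5; tmap2[3, 3] <- -5
  cl2 <- dcmir:::extract_clusters(tmap2, abs(tmap2) > 3, 1:5,
                                  c("freq", "freq"))
  expect_equal(nrow(cl2), 2)
})

test_that("the cluster table formats band labels like the coupling reports", {
  tmap <- matrix(0, 45, 45)
  tmap[21, 22] <- 6      # target 24 Hz (row), source 25 Hz (col)
  maps <- array(0, dim = c(12, 45, 45))
  set.seed(76)
  for (s in 1:12) maps[s, , ] <- tmap[21, 22] / 6 * tmap +
    matrix(rnorm(45 * 45, 0, 0.1), 45, 45)
  maps[, 21, 22] <- 6 + rnorm(12, 0, 0.1)
  st <- one_sample_tmap(maps, freqs = 4:48)
  tab <- cluster_table(list("SMA->cM1" = st))
  row <- tab[tab$peak_source == 25 & tab$peak_target == 24, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$connection, "SMA → cM1")
  expect_equal(row$bands, "β → β")
  expect_equal(row$peak, "25 → 24")
  expect_equal(row$sign, "+")
})

test_that("spectrogram contrasts smooth, test and mask per region", {
  set.seed(77)
  tm <- seq(-1000, 0, by = 10)
  mk <- function(shift) lapply(1:8, function(s) {
    pw <- array(rnorm(2 * 45 * length(tm), 0, 0.5),
                dim = c(2, 45, length(tm)))
    pw[1, 20:25, 40:60] <- pw[1, 20:25, 40:60] + shift
    source_spectrogram(pw, 4:48, tm, source_names = c("cM1", "iM1"))
  })
  res <- spectrogram_contrast(mk(2), mk(0), p_threshold = 0.005)
  expect_named(res, c("cM1", "iM1"))
  expect_gt(sum(res$cM1$stat$sig[20:25, 40:60]), 0)
  expect_equal(sum(res$iM1$masked_t != 0), sum(res$iM1$stat$sig))
})
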