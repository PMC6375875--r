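lf_small <- local({
  mon <- make_montage(32)
  build_leadfield(mon, grid_spacing = 0.02)
})

test_that("spherical lead field has the expected geometry", {
  lf <- lf_small
  expect_gt(nrow(lf$grid), 20)
  # average reference built in
  expect_lt(max(abs(colMeans(lf$gain))), 1e-12)
  # a radial dipole's largest-gain sensor is the nearest one
  v <- which.max(lf$grid[, 3])           # most superficial vertex voxel
  rhat <- lf$grid[v, ] / sqrt(sum(lf$grid[v, ]^2))
  g <- lf$gain[, (3 * (v - 1) + 1):(3 * v)] %*% rhat
  d <- sqrt(colSums((t(lf$ch_positions) - rhat * lf$head$radius)^2))
  expect_equal(unname(which.max(g)), unname(which.min(d)))
  # gains decay monotonically with distance along the cap (ties allowed
  # for symmetric sensor pairs)
  ord <- order(d)
  decayed <- g[ord]
  expect_true(all(diff(decayed[1:8]) <= 1e-9))
  # linearity in the dipole moment
  g2 <- lf$gain[, (3 * (v - 1) + 1):(3 * v)] %*% (2 * rhat)
  expect_equal(g2, 2 * g)
})

test_that("grid construction excludes the sphere center and respects the shell", {
  mon <- make_montage(16)
  lf <- build_leadfield(mon, grid_spacing = 0.015, shell = c(0.2, 0.8))
  rr <- sqrt(rowSums(lf$grid^2))
  expect_true(all(rr > 1e-4))
  expect_true(all(rr >= 0.2 * 0.09 - 1e-12 & rr <= 0.8 * 0.09 + 1e-12))
  expect_true(all(lf$grid[, 3] >= 0))
})

test_that("standardized inverse localizes noiseless point sources exactly", {
  inv <- slo_inverse(lf_small, reg = 1e-2)
  set.seed(14)
  nv <- nrow(lf_small$grid)
  vs <- sample(nv, 25)
  X <- sapply(vs, function(v) {
    m <- stats::rnorm(3); m <- m / sqrt(sum(m^2))
    lf_small$gain[, (3 * (v - 1) + 1):(3 * v)] %*% m
  })
  P <- source_power(inv, X, collapse_time = FALSE)
  hits <- sum(apply(P, 2, which.max) == vs)
  expect_gte(hits, 24)                  # >= 95% exact peaks
  # zero data give the zero image
  expect_equal(source_power(inv, numeric(nrow(lf_small$gain))),
               numeric(nv))
  expect_error(slo_inverse(lf_small, reg = 0), "reg > 0")
})

test_that("two well-separated sources appear as the two largest maxima", {
  inv <- slo_inverse(lf_small)
  nv <- nrow(lf_small$grid)
  d2 <- as.matrix(stats::dist(lf_small$grid))
  pair <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  x <- 0
  for (v in pair) {
    rhat <- lf_small$grid[v, ] / sqrt(sum(lf_small$grid[v, ]^2))
    x <- x + lf_small$gain[, (3 * (v - 1) + 1):(3 * v)] %*% rhat
  }
  p <- source_power(inv, x)
  top <- order(p, decreasing = TRUE)
  # the two top maxima lie at or adjacent to the true voxels
  for (v in pair) {
    dd <- sqrt(rowSums(sweep(lf_small$grid, 2, lf_small$grid[v, ])^2))
    expect_true(min(dd[top[1:2]]) <= 0.02 * sqrt(3) + 1e-9)
  }
})

test_that("variance smoothing halves toward the image mean, exactly", {
  set.seed(2)
  A <- matrix(stats::rnorm(12), 6, 2)
  B <- matrix(0, 6, 2)
  # engineer voxel variances 2 and 4
  A[, 1] <- A[, 1] / stats::sd(A[, 1]) * sqrt(2)
  A[, 2] <- A[, 2] / stats::sd(A[, 2]) * 2
  out <- paired_t_map(A, B)
  expect_equal(out$var, c(2, 4))
  expect_equal(out$var_smoothed, c(2.5, 3.5))
  # all-zero differences give t = 0 everywhere
  z <- paired_t_map(B, B)
  expect_true(all(z$t == 0))
  # uniform variance: smoothing is the identity, t equals the plain t
  set.seed(3)
  D <- matrix(stats::rnorm(8 * 5), 8, 5)
  D <- sweep(D, 2, apply(D, 2, stats::sd), "/")    # unit variance columns
  out2 <- paired_t_map(D, matrix(0, 8, 5))
  expect_equal(out2$var_smoothed, out2$var)
  expect_equal(out2$t, colMeans(D) / sqrt(out2$var / 8), tolerance = 1e-12)
  expect_error(paired_t_map(A, matrix(0, 5, 2)), "identical dimensions")
})

test_that("permutation correction is seeded, exact-capable, and coherent", {
  set.seed(8)
  A <- matrix(stats::rnorm(8 * 40), 8)
  B <- matrix(stats::rnorm(8 * 40), 8)
  s1 <- snpm_correct(A, B, n_perm = 150, seed = 7)
  s2 <- snpm_correct(A, B, n_perm = 150, seed = 7)
  expect_identical(s1$threshold, s2$threshold)
  expect_identical(s1$mask, s2$mask)
  # corrected p of the observed extreme follows the (1 + #)/(1 + N) rule
  expect_equal(s1$corrected_p,
               (1 + sum(s1$null >= max(-s1$t))) / (1 + s1$n_perm))
  # the largest null value is >= itself, so its corrected p is 2/(1+N)
  expect_equal(unname(s1$exceedance$corrected_p[nrow(s1$exceedance)]),
               2 / (1 + s1$n_perm))
  # exact enumeration announces itself when the flip space is small
  expect_message(se <- snpm_correct(A[1:5, ], B[1:5, ], n_perm = 40),
                 "exact enumeration")
  expect_true(se$exact)
  expect_equal(se$n_perm, 2^5 - 1)
  expect_error(snpm_correct(A[1:3, ], B[1:3, ], n_perm = 10),
               "at least 5")
})

test_that("growing a planted effect under fixed noise never raises corrected p", {
  set.seed(12)
  noiseA <- matrix(stats::rnorm(10 * 50), 10)
  B <- matrix(stats::rnorm(10 * 50), 10)
  p_prev <- Inf
  for (eff in c(0, 1, 2.5)) {
    A <- noiseA; A[, 1:4] <- A[, 1:4] - eff
    s <- snpm_correct(A, B, n_perm = 300, tail = "one", seed = 99)
    expect_lte(s$corrected_p, p_prev)
    p_prev <- s$corrected_p
  }
})

test_that("a planted focal effect is detected without remote false positives", {
  set.seed(5)
  A <- matrix(stats::rnorm(10 * 80), 10)
  B <- matrix(stats::rnorm(10 * 80), 10)
  A[, 3:6] <- A[, 3:6] - 3
  s <- snpm_correct(A, B, n_perm = 500, tail = "one", seed = 4)
  expect_true(all(s$mask[3:6]))
  expect_equal(sum(s$mask[-(3:6)]), 0)
})

test_that("condition images are trial-selective, normalized, scale-invariant", {
  mon <- make_montage(16)
  lf <- build_leadfield(mon, grid_spacing = 0.03)
  inv <- slo_inverse(lf)
  nv <- nrow(lf$grid)
  fs <- 250
  set.seed(9)
  nt <- 6
  late <- array(stats::rnorm(nt * 16 * 513, sd = 1), c(nt, 16, 513))
  early <- array(stats::rnorm(nt * 16 * 275, sd = 1), c(nt, 16, 275))
  ep <- manual_epoch_set(early, late, rep(c("neutral", "nonbio"), 3),
                         srate = fs, ch_names = mon$names)
  img <- condition_images(ep, inv, band = c(8, 13))
  expect_equal(dim(img), c(nv, 2))
  raw <- attr(img, "raw")
  expect_true(all(raw >= 0))
  # identical data for both conditions -> identical images
  ep_same <- ep; ep_same$design$condition <- rep("neutral", nt)
  img_a <- condition_images(ep_same, inv, conditions = "neutral")
  ep_same$design$condition <- rep("nonbio", nt)
  img_b <- condition_images(ep_same, inv, conditions = "nonbio")
  expect_equal(unname(img_a[, 1]), unname(img_b[, 1]))
  # scaling all sensor data by 10 leaves normalized images unchanged
  ep10 <- ep; ep10$late <- ep10$late * 10
  img10 <- condition_images(ep10, inv)
  expect_equal(img10, img, tolerance = 1e-10, ignore_attr = TRUE)
  # kept flags restrict the trials that enter an image
  img_k <- condition_images(ep, inv, kept = c(TRUE, TRUE, FALSE, TRUE,
                                              TRUE, TRUE))
  expect_false(isTRUE(all.equal(img_k[, "neutral"], img[, "neutral"])))
  expect_error(condition_images(ep, inv, kept = rep(FALSE, nt)),
               "no kept")
})

test_that("a planted focal suppression is most negative at its voxel in the contrast", {
  # focal 90% ERD at one vertex voxel over a sparse incoherent alpha
  # background; the image contrast must bottom out at the modulated voxel
  mon <- make_montage(64)
  lf <- build_leadfield(mon, grid_spacing = 0.025)
  inv <- slo_inverse(lf)
  nv <- nrow(lf$grid)
  fs <- 250
  set.seed(33)
  v_true <- which.max(lf$grid[, 3])
  bg <- sample(setdiff(seq_len(nv), v_true), 8)
  mk_img <- function(amp, ntr = 6) {
    late <- array(0, c(ntr, 64, 513))
    for (i in seq_len(ntr)) {
      tc <- matrix(0, nv, 513)
      for (v in c(bg, v_true))
        tc[v, ] <- musupp:::narrowband_osc(513, fs, c(8, 13), 1)
      tc[v_true, ] <- tc[v_true, ] * amp
      late[i, , ] <- simulate_from_sources(tc, lf, srate = fs)$data
    }
    ep <- manual_epoch_set(array(0.1, c(ntr, 64, 275)), late,
                           rep("x", ntr), srate = fs,
                           ch_names = mon$names)
    condition_images(ep, inv, conditions = "x")[, 1]
  }
  diffmap <- mk_img(sqrt(0.1)) - mk_img(1)
  expect_equal(which.min(diffmap), v_true)
})
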