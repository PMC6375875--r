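# Distributed-source contrast: analytic spherical-head lead field,
# standardized minimum-norm (sLORETA-style) inverse, per-condition band
# power images, smoothed-variance paired t map, max-statistic permutation
# correction.

#' Build an analytic spherical-head lead field
#'
#' Dipole-in-homogeneous-sphere potentials via the Legendre series
#' expansion: for a dipole at fractional radius f and a surface electrode
#' at angular distance gamma, the radial and tangential gains are
#' `sum_n (2n+1) f^(n-1) P_n(cos gamma)` and
#' `sum_n ((2n+1)/n) f^(n-1) P_n^1(cos gamma)` over `4 pi sigma R^2`.
#' Source space is a regular grid confined to a shell inside the sphere
#' (upper hemisphere by default, emulating cortex). Columns are average-
#' referenced, so per-column channel means are zero. Deterministic.
#'
#' @param montage an `eeg_montage`; sensors are projected onto the sphere
#'   surface.
#' @param grid_spacing grid step in meters (default 0.012).
#' @param head list with `radius` (m) and `sigma` (S/m) of the homogeneous
#'   sphere.
#' @param shell inner/outer source radii as fractions of the head radius;
#'   points at the sphere center are excluded (radial direction undefined).
#' @param upper_only keep only grid points with z >= 0.
#' @param n_terms series truncation order.
#' @return An object of class `leadfield`: `gain` (channels x 3*voxels,
#'   orientation-major: columns `3(v-1)+1..3` are voxel v's x/y/z dipole
#'   gains), `grid` (voxels x 3, meters), `ch_names`, `ch_positions`,
#'   `head`.
#' @export
build_leadfield <- function(montage, grid_spacing = 0.012,
                            head = list(radius = 0.09, sigma = 0.33),
                            shell = c(0.28, 0.80), upper_only = TRUE,
                            n_terms = 60) {
  R <- head$radius
  ax <- seq(-R, R, by = grid_spacing)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rr <- sqrt(rowSums(grid^2))
  keep <- rr >= shell[1] * R & rr <= shell[2] * R & rr > 1e-4
  if (upper_only) keep <- keep & grid[, 3] >= 0
  grid <- grid[keep, , drop = FALSE]
  rownames(grid) <- NULL
  nv <- nrow(grid)
  if (nv == 0) stop("empty source grid")

  # sensors projected to the sphere surface
  epos <- montage$positions
  epos <- epos / sqrt(rowSums(epos^2)) * R
  nch <- nrow(epos)
  ehat <- epos / R
  rhat <- grid / sqrt(rowSums(grid^2))
  f <- sqrt(rowSums(grid^2)) / R                      # fractional radius
  cosg <- pmin(1, pmax(-1, ehat %*% t(rhat)))         # channels x voxels

  # accumulate the Legendre series on channels x voxels matrices
  x <- cosg
  s <- sqrt(pmax(0, 1 - x^2))
  P_prev <- matrix(1, nch, nv); P_cur <- x             # P_0, P_1
  P1_prev <- matrix(0, nch, nv); P1_cur <- s           # P_0^1, P_1^1
  fr <- matrix(1, nch, nv)                             # f^(n-1), n = 1
  fv <- matrix(f, nch, nv, byrow = TRUE)
  rad <- 3 * fr * P_cur                                # n = 1 terms
  tan <- 3 * fr * P1_cur
  for (n in 2:n_terms) {
    fr <- fr * fv
    P_new <- ((2 * n - 1) * x * P_cur - (n - 1) * P_prev) / n
    P1_new <- ((2 * n - 1) * x * P1_cur - n * P1_prev) / (n - 1)
    rad <- rad + (2 * n + 1) * fr * P_new
    tan <- tan + ((2 * n + 1) / n) * fr * P1_new
    P_prev <- P_cur; P_cur <- P_new
    P1_prev <- P1_cur; P1_cur <- P1_new
  }
  const <- 1 / (4 * pi * head$sigma * R^2)
  rad <- const * rad
  tan <- const * tan

  # tangential unit vector of each (channel, voxel) pair: component of the
  # electrode direction orthogonal to the voxel's radial direction
  gain <- matrix(0, nch, 3 * nv)
  tx <- ty <- tz <- matrix(0, nch, nv)
  RX <- matrix(rhat[, 1], nch, nv, byrow = TRUE)
  RY <- matrix(rhat[, 2], nch, nv, byrow = TRUE)
  RZ <- matrix(rhat[, 3], nch, nv, byrow = TRUE)
  tx <- ehat[, 1] - cosg * RX
  ty <- ehat[, 2] - cosg * RY
  tz <- ehat[, 3] - cosg * RZ
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  tn[tn < 1e-12] <- Inf   # gamma = 0: tangential gain vanishes anyway
  tx <- tx / tn; ty <- ty / tn; tz <- tz / tn
  gain[, seq(1, 3 * nv, by = 3)] <- rad * RX + tan * tx
  gain[, seq(2, 3 * nv, by = 3)] <- rad * RY + tan * ty
  gain[, seq(3, 3 * nv, by = 3)] <- rad * RZ + tan * tz

  gain <- sweep(gain, 2, colMeans(gain))   # average reference
  structure(list(gain = gain, grid = grid, ch_names = montage$names,
                 ch_positions = epos, head = head,
                 grid_spacing = grid_spacing),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf(
    "<leadfield> %d channels x %d voxels (x3 orientations), sphere R = %.0f mm\n",
    nrow(x$gain), nrow(x$grid), x$head$radius * 1000))
  invisible(x)
}

# symmetric pseudoinverse via eigendecomposition
sym_pinv <- function(A, rtol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > rtol * max(abs(e$values))
  if (!any(pos)) return(A * 0)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Standardized minimum-norm (sLORETA-style) inverse operator
#'
#' Minimum-norm operator `M = L' (L L' + reg * H)^+` with `H` the average-
#' reference operator and `^+` the pseudoinverse (the system is rank-
#' deficient under the average reference). Each voxel's current estimate is
#' standardized by its 3 x 3 block of the resolution matrix `M L`, which is
#' the variance normalization that gives exact localization of noiseless
#' point sources. `reg` is expressed as a fraction of the mean eigenvalue
#' of `L L'`.
#'
#' @param L a `leadfield`.
#' @param reg regularization fraction, > 0.
#' @return An object of class `slo_inverse`: `M` (3*voxels x channels),
#'   `Sihalf` (3 x 3 x voxels array of inverse-square-root standardization
#'   blocks), `grid`, `reg`.
#' @export
slo_inverse <- function(L, reg = 1e-2) {
  if (!is.numeric(reg) || reg <= 0)
    stop("the regularized system needs reg > 0")
  G <- L$gain
  nch <- nrow(G)
  nv <- nrow(L$grid)
  Gram <- G %*% t(G)
  lam <- reg * mean(diag(Gram))
  H <- diag(nch) - matrix(1 / nch, nch, nch)
  Kinv <- sym_pinv(Gram + lam * H)
  M <- t(G) %*% Kinv
  Res <- M %*% G                       # resolution matrix, 3V x 3V
  Sihalf <- array(0, dim = c(3, 3, nv))
  for (v in seq_len(nv)) {
    ix <- (3 * (v - 1) + 1):(3 * v)
    S <- (Res[ix, ix] + t(Res[ix, ix])) / 2
    e <- eigen(S, symmetric = TRUE)
    pos <- e$values > 1e-12 * max(e$values)
    Sihalf[, , v] <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / sqrt(e$values[pos]))
  }
  structure(list(M = M, Sihalf = Sihalf, grid = L$grid, reg = reg,
                 ch_names = L$ch_names),
            class = "slo_inverse")
}

#' Standardized source power of sensor data
#'
#' Applies the inverse operator and returns, per voxel, the standardized
#' power `j' S^-1 j` summed over the 3 orientation components and averaged
#' over time samples. Zero data give a zero image.
#'
#' @param inv an `slo_inverse`.
#' @param x sensor data: channels vector or channels x samples matrix.
#' @param collapse_time if `TRUE` (default) average power over samples,
#'   returning one value per voxel; if `FALSE` return a voxels x samples
#'   matrix (each column treated independently, e.g. for localization
#'   sweeps over many single-sample fields).
#' @return numeric vector (or matrix) of non-negative standardized power.
#' @export
source_power <- function(inv, x, collapse_time = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  J <- inv$M %*% x                      # 3V x T
  nv <- nrow(inv$grid)
  out <- matrix(0, nv, ncol(x))
  for (v in seq_len(nv)) {
    W <- inv$Sihalf[, , v] %*% J[(3 * (v - 1) + 1):(3 * v), , drop = FALSE]
    out[v, ] <- colSums(W^2)
  }
  if (collapse_time) rowMeans(out) else out
}

# keep only FFT bins inside the band (per channel row)
bandpass_fft <- function(x, rate, band) {
  n <- ncol(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  mask <- f >= band[1] & f <= band[2]
  X <- t(stats::mvfft(t(x)))
  X[, !mask] <- 0
  Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
}

#' Per-condition standardized source band-power images
#'
#' For each requested condition: band-limits each kept late epoch to
#' `band`, computes the standardized source power image, averages over
#' trials, then band-wise normalizes (divides by the image mean) and
#' log10-transforms. Because of the normalization the images are invariant
#' to an overall scaling of the sensor data.
#'
#' @param epochs an `epoch_set` (uses the late epochs).
#' @param inv an `slo_inverse`.
#' @param band frequency band (Hz).
#' @param conditions conditions to image (default: all in the design).
#' @param kept optional logical per-trial keep flags (e.g. from the MAD
#'   rule), aligned with `epochs$design`.
#' @return matrix voxels x conditions of normalized log-power images, with
#'   the raw (non-negative) mean power images as attribute `"raw"`.
#' @export
condition_images <- function(epochs, inv, band = c(8, 13),
                             conditions = NULL, kept = NULL) {
  if (is.null(conditions)) conditions <- unique(epochs$design$condition)
  if (is.null(kept)) kept <- rep(TRUE, nrow(epochs$design))
  nv <- nrow(inv$grid)
  raw <- matrix(0, nv, length(conditions),
                dimnames = list(NULL, conditions))
  for (cd in conditions) {
    sel <- which(epochs$design$condition == cd & kept)
    if (length(sel) == 0) stop("no kept late epochs for condition ", cd)
    acc <- numeric(nv)
    for (i in sel) {
      xb <- bandpass_fft(epochs$late[i, , , drop = TRUE], epochs$srate,
                         band)
      acc <- acc + source_power(inv, xb)
    }
    raw[, cd] <- acc / length(sel)
  }
  out <- apply(raw, 2, function(img) log10(img / mean(img)))
  attr(out, "raw") <- raw
  out
}

#' Paired t map with image-wide variance smoothing
#'
#' Per voxel: paired differences `d = A - B` across participants; the
#' difference variance is smoothed by averaging it with the image-wide mean
#' variance, `v' = (v + vbar) / 2`, and `t = mean(d) / sqrt(v' / n)`. When
#' all voxel variances are equal the smoothing is the identity and the map
#' equals the ordinary paired t map.
#'
#' @param images_a,images_b participants x voxels matrices, matching rows.
#' @return list with `t`, `mean_diff`, `var`, `var_smoothed`, `n`.
#' @export
paired_t_map <- function(images_a, images_b) {
  if (!all(dim(images_a) == dim(images_b)))
    stop("image sets must have identical dimensions")
  if (!is.null(rownames(images_a)) && !is.null(rownames(images_b)) &&
      !identical(rownames(images_a), rownames(images_b)))
    stop("participant rows of the two image sets do not match")
  n <- nrow(images_a)
  if (n < 3) stop("need at least 3 participants")
  d <- images_a - images_b
  m <- colMeans(d)
  v <- colSums(sweep(d, 2, m)^2) / (n - 1)
  vs <- (v + mean(v)) / 2
  tmap <- ifelse(vs == 0, 0, m / sqrt(vs / n))  # 0/0 at zero differences
  list(t = tmap, mean_diff = m, var = v, var_smoothed = vs, n = n)
}

# sign patterns (codes 1..2^n-1; code 0 is the identity) as n x m matrices
decode_sign_flips <- function(codes, n) {
  sapply(codes, function(k)
    ifelse(bitwAnd(k, bitwShiftL(1, seq_len(n) - 1)) > 0, -1, 1))
}

#' Max-statistic permutation correction (statistical nonparametric mapping)
#'
#' Family-wise error control for the paired contrast `A - B`: the null
#' distribution of the image-wide maximum statistic is built by random
#' sign-flips of the participant difference images, recomputing the
#' smoothed-variance t map for every flip. The corrected threshold is the
#' `ceiling((1 - alpha) * n_perm)`-th order statistic of the null; a
#' voxel's corrected p is `(1 + #\{null >= stat\}) / (1 + n_perm)` (the
#' exact-valid Monte-Carlo permutation p), and the significance mask is
#' `corrected p <= alpha`. Sign patterns are drawn without replacement and
#' never include the identity (the `+1` in the p formula stands in for
#' it), which keeps the test exact rather than conservative when the
#' pattern space `2^n` is small. One-tailed (`A < B`) by default. If
#' `n_perm` is at least `2^n - 1`, exact enumeration of all non-identity
#' patterns is used instead (with a message).
#'
#' @param images_a,images_b participants x voxels matrices (n >= 5).
#' @param n_perm number of permutations.
#' @param alpha family-wise error level.
#' @param tail `"one"` (A < B, thresholds on max(-t)) or `"two"`
#'   (max |t|).
#' @param seed seed for the random sign flips.
#' @return An object of class `snpm_result`: observed `t` map, `threshold`,
#'   logical `mask` of significant voxels, the `null` max-statistic
#'   distribution, `corrected_p` of the observed extreme, and an
#'   `exceedance` table mapping thresholds to corrected p-values.
#' @export
snpm_correct <- function(images_a, images_b, n_perm = 5000, alpha = 0.05,
                         tail = c("one", "two"), seed = 1) {
  tail <- match.arg(tail)
  d <- images_a - images_b
  n <- nrow(d)
  if (n < 5) stop("need at least 5 participants for a useful sign-flip null")
  obs <- paired_t_map(images_a, images_b)
  stat_of <- function(tmap) if (tail == "one") max(-tmap) else max(abs(tmap))

  # identity is never drawn: the +1 in the Monte-Carlo p formula stands in
  # for it, and distinct (without-replacement) patterns keep the test exact
  # rather than conservative when 2^n is small
  n_distinct <- 2^n - 1
  exact <- n_perm >= n_distinct
  if (exact) {
    message("n_perm >= 2^n - 1: exact enumeration of all ", n_distinct,
            " non-identity sign patterns")
    signs <- decode_sign_flips(seq_len(n_distinct), n)
  } else {
    set.seed(seed)
    codes <- if (n <= 24) sample(n_distinct, n_perm)
             else sample(n_distinct, n_perm, replace = TRUE)
    signs <- decode_sign_flips(codes, n)
  }
  N <- ncol(signs)
  S2 <- colSums(d^2)                     # invariant under sign flips
  M <- crossprod(signs, d) / n           # N x V matrix of flipped means
  V <- sweep(-n * M^2, 2, S2, "+") / (n - 1)
  VS <- (V + rowMeans(V)) / 2
  Tmat <- M / sqrt(VS / n)
  null <- if (tail == "one") apply(-Tmat, 1, max) else
    apply(abs(Tmat), 1, max)

  thr <- sort(null)[ceiling((1 - alpha) * N)]
  # voxel-wise corrected p: exact-valid Monte-Carlo permutation p-value
  stat_v <- if (tail == "one") -obs$t else abs(obs$t)
  p_voxel <- vapply(stat_v, function(s) (1 + sum(null >= s)) / (1 + N),
                    numeric(1))
  mask <- p_voxel <= alpha
  obs_stat <- stat_of(obs$t)
  corrected_p <- (1 + sum(null >= obs_stat)) / (1 + N)
  ns <- sort(null)
  idx <- unique(pmax(1, ceiling(N * c(0.5, 0.75, 0.9, 0.95, 0.975, 0.99,
                                      0.995, 1))))
  exceedance <- data.frame(
    threshold = ns[idx],
    corrected_p = vapply(ns[idx],
                         function(v) (1 + sum(null >= v)) / (1 + N),
                         numeric(1)))
  structure(list(t = obs$t, var_smoothed = obs$var_smoothed,
                 threshold = thr, mask = mask, p_voxel = p_voxel,
                 null = null, alpha = alpha,
                 tail = tail, observed_stat = obs_stat,
                 corrected_p = corrected_p, exceedance = exceedance,
                 n_perm = N, exact = exact),
            class = "snpm_result")
}

#' @export
print.snpm_result <- function(x, ...) {
  cat(sprintf(
    "<snpm_result> %s-tailed, %d permutations%s; threshold %.3f (alpha %.3g)\n",
    x$tail, x$n_perm, if (x$exact) " (exact)" else "", x$threshold,
    x$alpha))
  cat(sprintf("  observed extreme %.3f, corrected p = %.4g; %d/%d voxels significant\n",
              x$observed_stat, x$corrected_p, sum(x$mask), length(x$mask)))
  invisible(x)
}
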