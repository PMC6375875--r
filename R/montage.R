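#' Build a spherical-cap sensor montage
#'
#' Places `n_channels` sensors on the upper part of a model head sphere.
#' Twelve canonical 10-20 sites (C3, C4, Cz, O1, Oz, O2, F3, Fz, F4, Fp1,
#' Fp2, Pz) are placed at fixed angular positions; remaining channels fill
#' the cap along a deterministic Fibonacci spiral and are named `E13`,
#' `E14`, ... The montage also carries default electrode groups: a central
#' cluster (the `central_k` sensors nearest C3 plus the `central_k` nearest
#' C4), an occipital cluster (O1, Oz, O2) and a frontal group (used by the
#' optional blink model).
#'
#' @param n_channels number of sensors (>= 6).
#' @param radius head sphere radius in meters.
#' @param central_k sensors per hemisphere in the central cluster (default 6,
#'   i.e. 12 central sensors in total).
#' @param cap_polar_deg maximal polar angle (degrees from vertex) of the
#'   spiral fill.
#' @return An object of class `eeg_montage`: list with `positions`
#'   (channels x 3, meters), `names`, `radius` and `groups`
#'   (`$central`, `$occipital`, `$frontal` channel-name vectors).
#' @export
make_montage <- function(n_channels = 128, radius = 0.09, central_k = 6,
                         cap_polar_deg = 100) {
  if (n_channels < 6) stop("need at least 6 channels")
  sph <- function(polar, azim) {
    p <- polar * pi / 180; a <- azim * pi / 180
    c(sin(p) * sin(a), sin(p) * cos(a), cos(p))
  }
  # priority order: cluster seeds first so tiny montages keep them
  fixed <- list(
    C3 = sph(46, 270), C4 = sph(46, 90), O1 = sph(80, 198),
    Oz = sph(80, 180), O2 = sph(80, 162), Cz = sph(0, 0),
    F3 = sph(62, 321), F4 = sph(62, 39), Fp1 = sph(80, 342),
    Fp2 = sph(80, 18), Fz = sph(46, 0), Pz = sph(46, 180)
  )
  n_fixed <- min(length(fixed), n_channels)
  pos <- do.call(rbind, fixed[seq_len(n_fixed)])
  nms <- names(fixed)[seq_len(n_fixed)]
  n_fill <- n_channels - n_fixed
  if (n_fill > 0) {
    # deterministic Fibonacci spiral on the cap
    golden <- pi * (3 - sqrt(5))
    k <- seq_len(n_fill)
    cmax <- cos(cap_polar_deg * pi / 180)
    z <- 1 - (k - 0.5) / n_fill * (1 - cmax)
    th <- k * golden
    r <- sqrt(pmax(0, 1 - z^2))
    pos <- rbind(pos, cbind(r * sin(th), r * cos(th), z))
    nms <- c(nms, paste0("E", n_fixed + k))
  }
  rownames(pos) <- nms
  pos <- pos * radius

  ang <- function(a, b) acos(pmin(1, pmax(-1, (pos %*% b)[, 1] / radius^2)))
  nearest <- function(site, k) {
    d <- ang(pos, pos[site, ])
    nms[order(d)][seq_len(min(k, n_channels))]
  }
  groups <- list(
    central = unique(c(nearest("C3", central_k),
                       if ("C4" %in% nms) nearest("C4", central_k))),
    occipital = intersect(c("O1", "Oz", "O2"), nms),
    frontal = intersect(c("Fp1", "Fp2", "F3", "F4", "Fz"), nms)
  )
  structure(list(positions = pos, names = nms, radius = radius,
                 groups = groups),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d sensors on a %.0f mm sphere\n",
              length(x$names), x$radius * 1000))
  cat(sprintf("  central cluster:   %s\n",
              paste(x$groups$central, collapse = ", ")))
  cat(sprintf("  occipital cluster: %s\n",
              paste(x$groups$occipital, collapse = ", ")))
  invisible(x)
}

#' Default electrode clusters from a montage
#'
#' @param montage an `eeg_montage`.
#' @return list with `central` and `occipital` channel-name vectors, and the
#'   analysis `band` in Hz.
#' @export
cluster_config <- function(montage) {
  cl <- list(central = montage$groups$central,
             occipital = montage$groups$occipital,
             band = c(8, 13))
  if (length(intersect(cl$central, cl$occipital)) > 0)
    stop("central and occipital clusters must be disjoint")
  cl
}
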