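# Enumerate ideal lattice nodes (um, image coordinates: x right, y down,
# origin at the centre of pixel (0,0)) that fit inside an ny x nx frame with
# the given pixel margin.
lattice_nodes_um <- function(spec, ny, nx, margin_px,
                             rotation_deg = 0, origin_um = NULL) {
  B <- lattice_basis(spec)
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% B
  ctr <- c((nx - 1) / 2, (ny - 1) / 2) * spec$pixel_size
  o <- origin_um %||% ctr
  lo <- margin_px * spec$pixel_size
  hix <- (nx - 1 - margin_px) * spec$pixel_size
  hiy <- (ny - 1 - margin_px) * spec$pixel_size
  # integer index range covering the frame corners generously
  corners <- rbind(c(lo, lo), c(hix, lo), c(lo, hiy), c(hix, hiy))
  f <- t(solve(A) %*% (t(corners) - o))
  n1 <- floor(min(f[, 1]) - 1):ceiling(max(f[, 1]) + 1)
  n2 <- floor(min(f[, 2]) - 1):ceiling(max(f[, 2]) + 1)
  g <- expand.grid(n1 = n1, n2 = n2)
  pos <- t(A %*% t(as.matrix(g)) + o)
  keep <- pos[, 1] >= lo & pos[, 1] <= hix & pos[, 2] >= lo & pos[, 2] <= hiy
  list(pos = pos[keep, , drop = FALSE], index = as.matrix(g)[keep, , drop = FALSE],
       A = A, origin = o)
}

# Render Gaussian spots (separable) onto a background image; centers in
# 0-based pixel coordinates.
render_spots <- function(ny, nx, centers_px, sigma_px, amplitude, background,
                         window_px) {
  img <- matrix(background, ny, nx)
  if (nrow(centers_px) == 0) return(img)
  W <- window_px
  for (i in seq_len(nrow(centers_px))) {
    cx <- centers_px[i, 1]; cy <- centers_px[i, 2]
    x0 <- max(0L, floor(cx) - W); x1 <- min(nx - 1L, floor(cx) + W + 1L)
    y0 <- max(0L, floor(cy) - W); y1 <- min(ny - 1L, floor(cy) + W + 1L)
    gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma_px^2))
    gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma_px^2))
    img[(y0:y1) + 1L, (x0:x1) + 1L] <-
      img[(y0:y1) + 1L, (x0:x1) + 1L] + amplitude * outer(gy, gx)
  }
  img
}

#' Generate a synthetic micropillar time-lapse with known deflections
#'
#' Renders pillar tops as Gaussian spots on an ideal lattice; pillars whose
#' node lies under `cell_mask` are deflected towards the mask centroid
#' (contractile geometry) with per-pillar magnitudes drawn so their mean is
#' `force_scale / k` um, modulated smoothly in time. The exact per-pillar
#' per-frame deflection field is stored in the returned ground truth.
#'
#' @param spec a [pillar_array_spec()].
#' @param cell_mask logical matrix (the frame dimensions are taken from it).
#' @param force_scale mean per-pillar force under the cell, nN (>= 0).
#' @param n_frames number of frames (1 fps convention; default one minute).
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param seed integer seed; identical seeds reproduce the stack bit-exactly.
#' @param target_max_force optional alternative parameterization: rescale the
#'   deflection field so the true per-cell mean-maximum traction (time-mean of
#'   the per-frame maximum pillar force) equals this value in nN exactly.
#' @param rotation_deg lattice rotation of the rendered array, degrees.
#' @param modulation_amp relative amplitude of the smooth temporal modulation
#'   of the deflection field (one sine period across the video; time-mean 1).
#' @param amplitude,background spot peak intensity and background level.
#' @return list with `stack` (ny x nx x n_frames array) and `truth`
#'   (a [ground_truth()] storing the exact deflections and the spec).
#' @export
generate_pillar_video <- function(spec, cell_mask, force_scale,
                                  n_frames = 60, noise_sd = 0, seed = 1,
                                  target_max_force = NULL,
                                  rotation_deg = 0, modulation_amp = 0.05,
                                  amplitude = 1000, background = 100) {
  stopifnot(inherits(spec, "pillar_array_spec"), is.matrix(cell_mask),
            force_scale >= 0, n_frames >= 1)
  ny <- nrow(cell_mask); nx <- ncol(cell_mask)
  W <- spot_window_px(spec)
  lat <- lattice_nodes_um(spec, ny, nx, margin_px = W + 2,
                          rotation_deg = rotation_deg)
  if (nrow(lat$pos) < 1) stop("lattice does not fit in the frame")
  npix <- lat$pos / spec$pixel_size
  under <- cell_mask[cbind(round(npix[, 2]) + 1L, round(npix[, 1]) + 1L)]
  n_p <- nrow(lat$pos)
  k <- spec$spring_constant_k

  withr::with_seed(seed, {
    defl <- array(0, dim = c(n_p, 2, n_frames))
    s_t <- 1 + modulation_amp * sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
    if (any(under) && (force_scale > 0 || !is.null(target_max_force))) {
      nu <- sum(under)
      w <- stats::rgamma(nu, shape = 4, rate = 4)
      w <- w / mean(w)                      # per-pillar weights, mean exactly 1
      mag <- (max(force_scale, 1e-12) / k) * w
      if (!is.null(target_max_force)) {
        stopifnot(target_max_force >= 0)
        mag <- mag * target_max_force / (k * max(mag))
      }
      ctr_um <- colMeans(matrix(npix[under, ], ncol = 2)) * spec$pixel_size
      dvec <- t(ctr_um - t(lat$pos[under, , drop = FALSE]))
      nrm <- sqrt(rowSums(dvec^2))
      # a pillar exactly at the centroid has no "inward": random direction
      deg <- nrm < 1e-9
      if (any(deg)) {
        ang <- stats::runif(sum(deg), 0, 2 * pi)
        dvec[deg, ] <- cbind(cos(ang), sin(ang))
        nrm[deg] <- 1
      }
      dvec <- dvec / nrm
      iu <- which(under)
      for (t in seq_len(n_frames)) {
        defl[iu, , t] <- dvec * (mag * s_t[t])
      }
    }
    stack <- array(0, dim = c(ny, nx, n_frames))
    sig <- spot_sigma_px(spec)
    for (t in seq_len(n_frames)) {
      centers <- (lat$pos + defl[, , t]) / spec$pixel_size
      fr <- render_spots(ny, nx, centers, sig, amplitude, background, W)
      if (noise_sd > 0) fr <- fr + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
      stack[, , t] <- fr
    }
  })

  per_frame_max <- apply(sqrt(defl[, 1, , drop = FALSE]^2 +
                              defl[, 2, , drop = FALSE]^2), 3, max) * k
  truth <- ground_truth("pillar", list(
    spring_constant_k = k,
    node_x_um = lat$pos[, 1], node_y_um = lat$pos[, 2],
    under_cell = under,
    deflections_um = defl,
    rotation_deg = rotation_deg,
    force_scale_nN = force_scale,
    true_mean_max_force_nN = mean(per_frame_max),
    pitch_um = spec$pitch, pixel_size_um = spec$pixel_size
  ), seed)
  list(stack = stack, truth = truth)
}
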