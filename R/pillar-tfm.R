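#' Detect pillar tops with subpixel precision
#'
#' Finds local intensity maxima above a robust threshold, enforces a minimum
#' separation of half the lattice pitch, and refines each spot centre with an
#' iterative Gaussian-windowed intensity-weighted centroid (weights recentred
#' at the current estimate; the fixed point of that iteration is the centre of
#' a Gaussian spot, so the estimator is unbiased for symmetric spots).
#'
#' @param frame 2-D numeric image matrix.
#' @param spec a [pillar_array_spec()].
#' @param threshold absolute detection threshold; default
#'   `median(frame) + 0.25 * (max(frame) - median(frame))`.
#' @param n_iter centroid refinement iterations.
#' @param min_separation_px minimum distance between accepted maxima; half the
#'   lattice pitch by default (undeflected arrays). Tracking relaxes this to
#'   the optical resolution limit, since pillars deflecting towards the cell
#'   centre legitimately approach each other.
#' @return data.frame with subpixel `x_px`, `y_px` (0-based pixels), `x_um`,
#'   `y_um` and peak `intensity` (strongest first); zero rows (with a
#'   warning) if no spots.
#' @export
detect_pillars <- function(frame, spec, threshold = NULL, n_iter = 8L,
                           min_separation_px = NULL) {
  stopifnot(is.matrix(frame), inherits(spec, "pillar_array_spec"))
  ny <- nrow(frame); nx <- ncol(frame)
  bg <- median(frame)
  # noise floor term (5 * mad) suppresses spurious maxima in noisy frames
  thr <- threshold %||% (bg + max(0.25 * (max(frame) - bg), 5 * mad(frame)))
  W <- spot_window_px(spec)
  # strict local maxima over the 8-neighbourhood, away from the border
  core <- frame[2:(ny - 1), 2:(nx - 1)]
  ismax <- core >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- frame[2:(ny - 1) + dy, 2:(nx - 1) + dx]
    ismax <- ismax & (core > nb | (core == nb & (dy < 0 | (dy == 0 & dx < 0))))
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no pillar spots found above background")
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  }
  py <- idx[, 1]           # 0-based y of the local max (core offset +1 - 1)
  px <- idx[, 2]
  inten <- frame[cbind(py + 1L, px + 1L)]
  # greedy minimum-separation pruning, strongest first
  min_sep <- min_separation_px %||% ((spec$pitch / spec$pixel_size) / 2)
  ord <- order(inten, decreasing = TRUE)
  keep <- logical(length(ord))
  for (i in ord) {
    if (any(keep & (px - px[i])^2 + (py - py[i])^2 < min_sep^2)) next
    keep[i] <- TRUE
  }
  px <- px[keep]; py <- py[keep]; inten <- inten[keep]
  # drop maxima whose refinement window would clip the frame border
  ok <- px - W >= 0 & px + W <= nx - 1 & py - W >= 0 & py + W <= ny - 1
  px <- px[ok]; py <- py[ok]; inten <- inten[ok]
  n <- length(px)
  if (n == 0) {
    warning("no pillar spots with a full refinement window")
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  }
  # vectorized refinement: stack all (2W+1)^2 windows as columns
  off <- -W:W
  m <- length(off)
  dys <- rep(off, times = m)              # window-local y offsets
  dxs <- rep(off, each = m)
  rows <- outer(dys, py, `+`) + 1L        # m^2 x n, 1-based rows
  cols <- outer(dxs, px, `+`) + 1L
  P <- matrix(frame[cbind(as.vector(rows), as.vector(cols))], m * m, n) - bg
  X <- outer(dxs, px, `+`)                # absolute 0-based coords
  Y <- outer(dys, py, `+`)
  sig <- spot_sigma_px(spec)
  mux <- as.numeric(px); muy <- as.numeric(py)
  for (it in seq_len(n_iter)) {
    Wt <- exp(-((X - rep(mux, each = m * m))^2 +
                (Y - rep(muy, each = m * m))^2) / (2 * sig^2))
    WP <- Wt * P
    denom <- colSums(WP)
    bad <- denom <= 0
    denom[bad] <- 1
    nmx <- colSums(WP * X) / denom
    nmy <- colSums(WP * Y) / denom
    mux <- ifelse(bad, mux, nmx)
    muy <- ifelse(bad, muy, nmy)
  }
  out <- data.frame(x_px = mux, y_px = muy,
                    x_um = mux * spec$pixel_size,
                    y_um = muy * spec$pixel_size,
                    intensity = inten)
  out[order(out$intensity, decreasing = TRUE), , drop = FALSE]
}

#' Fit the undeflected reference lattice from free pillars
#'
#' Estimates the lattice basis vectors, origin and rotation by least squares
#' using only centroids outside the cell mask (assumed undeflected), then
#' extrapolates ideal node positions for every pillar including those under
#' the cell. Rotation is first located by a 1-D search minimizing wrapped
#' fractional-coordinate residuals, then the basis and origin are refined by
#' linear least squares on the integer node assignment.
#'
#' @param centroids data.frame from [detect_pillars()].
#' @param spec a [pillar_array_spec()].
#' @param cell_mask logical matrix, or `NULL` if every pillar is free.
#' @param max_rotation_deg half-width of the rotation search interval.
#' @return list of class `pillar_reference`: `nodes` (data.frame with
#'   `pillar_id`, `ref_x_um`, `ref_y_um`, `under_cell`), basis matrix `A`
#'   (um, columns = lattice vectors), `origin_um`, `rotation_deg`,
#'   `rms_residual_px` of the free-pillar fit, and `assignment` mapping each
#'   input centroid to a `pillar_id` (NA when ambiguous: centroid-to-node
#'   distance beyond half a pitch).
#' @export
fit_reference_lattice <- function(centroids, spec, cell_mask = NULL,
                                  max_rotation_deg = 15) {
  stopifnot(nrow(centroids) >= 1)
  pos <- cbind(centroids$x_um, centroids$y_um)
  free <- rep(TRUE, nrow(pos))
  if (!is.null(cell_mask)) {
    r <- round(centroids$y_px) + 1L
    c <- round(centroids$x_px) + 1L
    inb <- r >= 1 & r <= nrow(cell_mask) & c >= 1 & c <= ncol(cell_mask)
    free[inb] <- !cell_mask[cbind(r[inb], c[inb])]
  }
  if (sum(free) < 6)
    stop("reference lattice unresolvable: only ", sum(free),
         " free pillars outside the cell mask (need >= 6)")
  B <- lattice_basis(spec)
  fpos <- pos[free, , drop = FALSE]
  ctr <- colMeans(fpos)

  wrap_score <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    f <- t(solve(R %*% B) %*% (t(fpos) - ctr))
    s <- 0
    for (j in 1:2) {
      ang <- 2 * pi * f[, j]
      offs <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)
      d <- f[, j] - offs
      s <- s + sum((d - round(d))^2)
    }
    s
  }
  lim <- max_rotation_deg * pi / 180
  # coarse grid then local refinement (the objective has lattice-symmetry
  # local minima; a plain golden-section search can land in the wrong one)
  grid <- seq(-lim, lim, length.out = 121)
  th0 <- grid[which.min(vapply(grid, wrap_score, numeric(1)))]
  opt <- optimize(wrap_score, c(th0 - 0.02, th0 + 0.02))
  theta <- opt$minimum
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  A <- R %*% B
  f <- t(solve(A) %*% (t(fpos) - ctr))
  offs <- vapply(1:2, function(j) {
    ang <- 2 * pi * f[, j]
    atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)
  }, numeric(1))
  o <- as.numeric(ctr + A %*% offs)

  # two rounds of integer assignment + linear LS refinement of (origin, A)
  for (round_i in 1:2) {
    nidx <- t(round(solve(A) %*% (t(fpos) - o)))
    X <- cbind(1, nidx)
    fit <- lm.fit(X, fpos)
    cf <- fit$coefficients
    o <- as.numeric(cf[1, ])
    A <- t(cf[2:3, , drop = FALSE])
  }
  resid_px <- sqrt(rowSums((fpos - t(A %*% t(nidx) + o))^2)) / spec$pixel_size
  rotation_deg <- atan2(A[2, 1], A[1, 1]) * 180 / pi

  # enumerate candidate nodes over the bounding box of all centroids
  half <- spec$pitch / 2
  fall <- t(solve(A) %*% (t(pos) - o))
  n1 <- (floor(min(fall[, 1])) - 1):(ceiling(max(fall[, 1])) + 1)
  n2 <- (floor(min(fall[, 2])) - 1):(ceiling(max(fall[, 2])) + 1)
  g <- as.matrix(expand.grid(n1 = n1, n2 = n2))
  nodes_um <- t(A %*% t(g) + o)

  # nearest-node assignment for every centroid (ambiguous -> NA)
  d2 <- outer(rowSums(pos^2), rowSums(nodes_um^2), `+`) -
    2 * pos %*% t(nodes_um)
  nearest <- max.col(-d2)
  ndist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(pos)), nearest)]))
  assignment <- ifelse(ndist <= half, nearest, NA_integer_)

  node_under <- rep(FALSE, nrow(nodes_um))
  if (!is.null(cell_mask)) {
    npx <- nodes_um / spec$pixel_size
    r <- round(npx[, 2]) + 1L; c <- round(npx[, 1]) + 1L
    inb <- r >= 1 & r <= nrow(cell_mask) & c >= 1 & c <= ncol(cell_mask)
    node_under[inb] <- cell_mask[cbind(r[inb], c[inb])]
  }
  # keep nodes that captured a centroid or sit under the cell (a deflected or
  # occluded pillar must keep its ideal reference even with no detection)
  occupied <- seq_len(nrow(nodes_um)) %in% assignment
  keep <- occupied | node_under
  old2new <- match(seq_len(nrow(nodes_um)), which(keep))
  assignment <- old2new[assignment]
  nodes_um <- nodes_um[keep, , drop = FALSE]
  node_under <- node_under[keep]

  structure(list(
    nodes = data.frame(pillar_id = seq_len(nrow(nodes_um)),
                       ref_x_um = nodes_um[, 1], ref_y_um = nodes_um[, 2],
                       under_cell = node_under),
    A = A, origin_um = o, rotation_deg = rotation_deg,
    rms_residual_px = sqrt(mean(resid_px^2)),
    assignment = assignment
  ), class = "pillar_reference")
}

#' Track pillar deflections through an image stack
#'
#' Detects spots in every frame, links them to the reference lattice by
#' nearest-reference assignment (ambiguous beyond half a pitch, or missed
#' detections, are recorded as missing, never interpolated) and returns
#' per-frame positions and deflection vectors for every pillar.
#'
#' @param stack 3-D array (ny x nx x n_frames).
#' @param spec a [pillar_array_spec()].
#' @param cell_mask logical matrix used to fit the reference lattice from
#'   free pillars and to label pillars under the cell.
#' @param reference optionally a precomputed [fit_reference_lattice()] result.
#' @return object of class `pillar_tracks`: the `reference`, arrays
#'   `positions_um` and `deflections_um` (n_pillars x 2 x n_frames, NA when
#'   missing), `forces_nN` (filled by [compute_forces()]), and the `spec`.
#' @export
track_pillars <- function(stack, spec, cell_mask, reference = NULL) {
  stopifnot(length(dim(stack)) == 3)
  n_frames <- dim(stack)[3]
  if (is.null(reference)) {
    cen1 <- detect_pillars(stack[, , 1], spec)
    reference <- fit_reference_lattice(cen1, spec, cell_mask)
  }
  nodes <- cbind(reference$nodes$ref_x_um, reference$nodes$ref_y_um)
  n_p <- nrow(nodes)
  half <- spec$pitch / 2
  # deflected pillars may approach each other below half a pitch; accept
  # spots down to the resolution limit and let the node assignment sort them
  sep <- max(3, 2.5 * spot_sigma_px(spec))
  positions <- array(NA_real_, dim = c(n_p, 2, n_frames))
  for (t in seq_len(n_frames)) {
    cen <- suppressWarnings(detect_pillars(stack[, , t], spec,
                                           min_separation_px = sep))
    if (nrow(cen) == 0) next
    pos <- cbind(cen$x_um, cen$y_um)
    d2 <- outer(rowSums(pos^2), rowSums(nodes^2), `+`) - 2 * pos %*% t(nodes)
    nearest <- max.col(-d2)
    dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(pos)), nearest)]))
    ok <- dist <= half
    # a node claimed by several centroids keeps only the nearest
    for (j in unique(nearest[ok])) {
      cand <- which(ok & nearest == j)
      best <- cand[which.min(dist[cand])]
      positions[j, , t] <- pos[best, ]
    }
  }
  defl <- positions - array(rep(nodes, times = n_frames),
                            dim = c(n_p, 2, n_frames))
  structure(list(reference = reference, positions_um = positions,
                 deflections_um = defl, forces_nN = NULL, spec = spec),
            class = "pillar_tracks")
}

#' Convert pillar deflections to traction forces
#'
#' Applies the linear pillar spring law F = k * |deflection| elementwise;
#' missing deflections propagate as missing forces.
#'
#' @param tracks a `pillar_tracks` object from [track_pillars()].
#' @param k spring constant in nN/um; defaults to the spec's calibration.
#' @return `tracks` with `forces_nN` (n_pillars x n_frames) and
#'   `deflection_mag_um` populated.
#' @export
compute_forces <- function(tracks, k = tracks$spec$spring_constant_k) {
  stopifnot(inherits(tracks, "pillar_tracks"), k > 0)
  mag <- sqrt(tracks$deflections_um[, 1, , drop = FALSE]^2 +
              tracks$deflections_um[, 2, , drop = FALSE]^2)
  mag <- array(mag, dim = dim(tracks$deflections_um)[c(1, 3)])
  tracks$deflection_mag_um <- mag
  tracks$forces_nN <- k * mag
  tracks
}

#' Per-cell traction summary (mean maximum traction)
#'
#' Restricts to pillars whose reference node lies under the cell mask, takes
#' the maximum pillar force in every frame, and averages that series over
#' frames with at least one valid pillar. This is the per-cell scalar
#' conventionally reported as "mean maximum traction force".
#'
#' @param tracks a `pillar_tracks` object with forces populated.
#' @return object of class `traction_summary`: `per_frame_max_force_nN`,
#'   `mean_max_traction_nN`, `n_frames` (valid frames) and
#'   `n_pillars_under_cell`.
#' @export
cell_traction_summary <- function(tracks) {
  stopifnot(inherits(tracks, "pillar_tracks"))
  if (is.null(tracks$forces_nN))
    stop("forces not computed; run compute_forces() first")
  under <- tracks$reference$nodes$under_cell
  if (!any(under))
    stop("no pillars under the cell mask: traction summary undefined")
  f <- tracks$forces_nN[under, , drop = FALSE]
  valid <- colSums(!is.na(f)) > 0
  if (!any(valid)) stop("no frame has a valid pillar under the cell mask")
  per_frame <- apply(f[, valid, drop = FALSE], 2, max, na.rm = TRUE)
  structure(list(per_frame_max_force_nN = per_frame,
                 mean_max_traction_nN = mean(per_frame),
                 n_frames = sum(valid),
                 n_pillars_under_cell = sum(under)),
            class = "traction_summary")
}

#' @export
print.traction_summary <- function(x, ...) {
  cat(sprintf(
    "<traction_summary> mean max traction %.3f nN over %d frames (%d pillars under cell)\n",
    x$mean_max_traction_nN, x$n_frames, x$n_pillars_under_cell))
  invisible(x)
}

#' Run the full micropillar traction pipeline on one video
#'
#' Convenience wrapper: detection on frame 1, reference-lattice fit, tracking,
#' force conversion, per-cell summary.
#'
#' @inheritParams track_pillars
#' @return a `traction_summary` with the `tracks` attached as an attribute.
#' @export
analyze_pillar_video <- function(stack, spec, cell_mask) {
  tracks <- track_pillars(stack, spec, cell_mask)
  tracks <- compute_forces(tracks)
  out <- cell_traction_summary(tracks)
  attr(out, "tracks") <- tracks
  out
}
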