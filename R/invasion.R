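#' Generate a synthetic two-channel transmigration z-stack
#'
#' The laminin channel is a bright plane (Gaussian axial profile) at
#' `bilayer_z`; the actin channel renders the cell as a spherical cortical
#' shell (f-actin concentrates at the cortex), positioned so that exactly
#' `below_fraction` of its axial extent lies below the bilayer. A sphere's
#' surface-band area per unit z is constant, so the lateral-mean actin
#' z-profile is a top-hat with soft (erf) edges whose half-maximum crossings
#' sit at the true cell top and bottom.
#'
#' @param bilayer_z axial position of the basement-membrane bilayer, um
#'   (z increases from the invaded side up towards the seeding side).
#' @param below_fraction fraction of the cell height below the bilayer,
#'   in `[0, 1]`.
#' @param cell_height cell axial extent (sphere diameter) in um.
#' @param z_step axial slice spacing in um.
#' @param z_depth total stack depth in um.
#' @param nx,ny lateral frame size in pixels.
#' @param pixel_size lateral um per pixel.
#' @param shell_sigma cortical shell thickness parameter, um.
#' @param bilayer_sigma axial thickness of the laminin plane, um.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param seed integer seed.
#' @return list with `laminin` and `actin` (ny x nx x nz arrays), `z_um`
#'   (slice positions), `z_step`, and `truth` (a [ground_truth()] storing the
#'   below-bilayer fraction and the cell geometry).
#' @export
generate_invasion_stack <- function(bilayer_z = 20, below_fraction = 0.5,
                                    cell_height = 15, z_step = 0.25,
                                    z_depth = 40, nx = 64, ny = 64,
                                    pixel_size = 0.3, shell_sigma = 0.3,
                                    bilayer_sigma = 0.4, noise_sd = 0,
                                    seed = 1) {
  stopifnot(below_fraction >= 0, below_fraction <= 1, cell_height > 0,
            z_step > 0)
  z <- seq(0, z_depth, by = z_step)
  nz <- length(z)
  cell_bottom <- bilayer_z - below_fraction * cell_height
  cell_top <- cell_bottom + cell_height
  Rcell <- cell_height / 2
  zc <- cell_bottom + Rcell
  if (cell_bottom < 2 * z_step || cell_top > z_depth - 2 * z_step)
    stop("cell extends outside the stack: increase z_depth or move bilayer_z")
  cx <- (nx - 1) / 2 * pixel_size
  cy <- (ny - 1) / 2 * pixel_size
  xs <- (0:(nx - 1)) * pixel_size
  ys <- (0:(ny - 1)) * pixel_size
  r2xy <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  laminin <- array(0, dim = c(ny, nx, nz))
  actin <- array(0, dim = c(ny, nx, nz))
  for (i in seq_len(nz)) {
    laminin[, , i] <- 1000 * exp(-(z[i] - bilayer_z)^2 / (2 * bilayer_sigma^2))
    d <- sqrt(r2xy + (z[i] - zc)^2)
    actin[, , i] <- 1000 * exp(-(d - Rcell)^2 / (2 * shell_sigma^2))
  }
  withr::with_seed(seed, {
    if (noise_sd > 0) {
      laminin <- laminin + array(rnorm(length(laminin), sd = noise_sd), dim(laminin))
      actin <- actin + array(rnorm(length(actin), sd = noise_sd), dim(actin))
    }
  })
  truth <- ground_truth("invasion", list(
    below_fraction = below_fraction, bilayer_z_um = bilayer_z,
    cell_bottom_um = cell_bottom, cell_top_um = cell_top,
    cell_height_um = cell_height, z_step_um = z_step
  ), seed)
  list(laminin = laminin, actin = actin, z_um = z, z_step = z_step,
       truth = truth)
}

#' Locate the basement-membrane bilayer from a laminin z-profile
#'
#' Intensity-weighted centroid of the background-subtracted profile restricted
#' to a window around its global maximum; rejects profiles without a dominant
#' peak.
#'
#' @param laminin_zprofile per-slice mean laminin intensity.
#' @param z_spacing axial slice spacing in um.
#' @param window_um half-width of the centroid window in um.
#' @param min_prominence minimum (max - median) / (max - min) for a peak to
#'   count as a bilayer.
#' @return bilayer axial position in um.
#' @export
locate_bilayer <- function(laminin_zprofile, z_spacing, window_um = 2,
                           min_prominence = 0.25) {
  p <- as.numeric(laminin_zprofile)
  stopifnot(length(p) >= 3, z_spacing > 0)
  rng <- max(p) - min(p)
  if (rng <= 0 || (max(p) - median(p)) / rng < min_prominence)
    stop("no dominant laminin peak: bilayer not found")
  z <- (seq_along(p) - 1) * z_spacing
  i0 <- which.max(p)
  w <- which(abs(z - z[i0]) <= window_um)
  q <- p[w] - min(p)
  sum(q * z[w]) / sum(q)
}

#' Axial extent of a cell from its actin z-profile
#'
#' Background-subtracts the profile (minimum as background), then finds the
#' outermost axial positions where intensity crosses
#' `threshold_fraction * max`, with linear interpolation between slices.
#' The default half-maximum threshold is the unbiased edge estimator for a
#' symmetric edge-spread profile.
#'
#' @param actin_zprofile per-slice mean actin intensity.
#' @param z_spacing axial slice spacing in um.
#' @param threshold_fraction crossing level as a fraction of the profile
#'   maximum, in (0, 1).
#' @return named numeric: `cell_top_z`, `cell_bottom_z` (um,
#'   top > bottom).
#' @export
cell_extent <- function(actin_zprofile, z_spacing, threshold_fraction = 0.5) {
  p <- as.numeric(actin_zprofile)
  stopifnot(length(p) >= 3, z_spacing > 0,
            threshold_fraction > 0, threshold_fraction < 1)
  p <- p - min(p)
  thr <- threshold_fraction * max(p)
  if (max(p) <= 0 || !any(p >= thr)) stop("no sample above threshold")
  z <- (seq_along(p) - 1) * z_spacing
  above <- which(p >= thr)
  i_lo <- above[1]; i_hi <- above[length(above)]
  interp <- function(i_in, i_out) {
    # crossing between the outermost above-threshold slice and its neighbour
    if (i_out < 1 || i_out > length(p)) return(z[i_in])
    z[i_in] + (z[i_out] - z[i_in]) * (p[i_in] - thr) / (p[i_in] - p[i_out])
  }
  bottom <- interp(i_lo, i_lo - 1L)
  top <- interp(i_hi, i_hi + 1L)
  c(cell_top_z = top, cell_bottom_z = bottom)
}

#' Percent invasion of one cell through the bilayer
#'
#' 100 x the fraction of the cell's axial extent lying below the bilayer,
#' clipped to `[0, 100]` for cells entirely above or below the plane.
#'
#' @param bilayer_z bilayer position in um.
#' @param extent named numeric from [cell_extent()].
#' @return percent invasion in `[0, 100]`.
#' @export
percent_invasion <- function(bilayer_z, extent) {
  top <- extent[["cell_top_z"]]; bottom <- extent[["cell_bottom_z"]]
  h <- top - bottom
  if (h <= 0) stop("zero or negative cell height")
  100 * min(1, max(0, (bilayer_z - bottom) / h))
}

#' Measure percent invasion from a two-channel z-stack
#'
#' Reduces each channel to a lateral-mean z-profile (over an optional ROI
#' mask), locates the bilayer in the laminin channel, the cell extent in the
#' actin channel, and combines them into percent invasion.
#'
#' @param stack list with `laminin`, `actin` (ny x nx x nz) and `z_step`,
#'   as produced by [generate_invasion_stack()] or [read_stack()].
#' @param roi optional logical ny x nx matrix restricting the lateral mean.
#' @param threshold_fraction passed to [cell_extent()].
#' @return object of class `invasion_measurement`: `bilayer_z`, `cell_top_z`,
#'   `cell_bottom_z`, `percent_invasion`.
#' @export
measure_invasion_stack <- function(stack, roi = NULL, threshold_fraction = 0.5) {
  prof <- function(a) {
    if (is.null(roi)) apply(a, 3, mean)
    else apply(a, 3, function(s) mean(s[roi]))
  }
  lam <- prof(stack$laminin)
  act <- prof(stack$actin)
  bz <- locate_bilayer(lam, stack$z_step)
  ext <- cell_extent(act, stack$z_step, threshold_fraction)
  structure(list(bilayer_z = bz,
                 cell_top_z = ext[["cell_top_z"]],
                 cell_bottom_z = ext[["cell_bottom_z"]],
                 percent_invasion = percent_invasion(bz, ext)),
            class = "invasion_measurement")
}

#' Generate per-ROI daily invasion counts
#'
#' New fully-transmigrated cells per ROI and day are drawn
#' Poisson(`rate_per_day`) and cumulated across days.
#'
#' @param rate_per_day expected newly invaded cells per ROI per day (>= 0).
#' @param days number of days (>= 1).
#' @param n_roi number of regions of interest.
#' @param seed integer seed.
#' @param deterministic if `TRUE`, counts are exactly `rate_per_day` per day
#'   (noise off; rate must then be an integer for exact counts).
#' @return list with `counts` (data.frame: roi_id, day, new_cells,
#'   cumulative_count) and `truth`.
#' @export
generate_cumulative_counts <- function(rate_per_day, days = 5, n_roi = 10,
                                       seed = 1, deterministic = FALSE) {
  stopifnot(rate_per_day >= 0, days >= 1, n_roi >= 1)
  withr::with_seed(seed, {
    new <- if (deterministic) rep(rate_per_day, n_roi * days)
           else rpois(n_roi * days, rate_per_day)
  })
  df <- data.frame(roi_id = rep(seq_len(n_roi), each = days),
                   day = rep(seq_len(days), times = n_roi),
                   new_cells = new)
  df$cumulative_count <- as.numeric(
    unlist(lapply(split(df$new_cells, df$roi_id), cumsum)))
  truth <- ground_truth("invasion",
                        list(rate_per_day = rate_per_day, days = days,
                             n_roi = n_roi), seed)
  list(counts = df, truth = truth)
}

#' Cumulate daily invasion counts per ROI
#'
#' @param daily_counts data.frame with columns `roi_id`, `day`, `new_cells`
#'   (and optionally `condition`). Days must be complete per ROI (1..max day,
#'   no gaps; counts are never imputed).
#' @return the input with a `cumulative_count` column (nondecreasing within
#'   each ROI), of class `cumulative_invasion`.
#' @export
cumulative_invasion <- function(daily_counts) {
  need <- c("roi_id", "day", "new_cells")
  stopifnot(all(need %in% names(daily_counts)))
  if (any(daily_counts$new_cells < 0)) stop("negative daily counts")
  key <- if ("condition" %in% names(daily_counts))
    interaction(daily_counts$condition, daily_counts$roi_id, drop = TRUE)
  else factor(daily_counts$roi_id)
  out <- daily_counts[order(key, daily_counts$day), , drop = FALSE]
  key <- key[order(key, daily_counts$day)]
  for (g in levels(key)) {
    d <- out$day[key == g]
    if (!identical(as.integer(d), seq_len(max(d))))
      stop("missing day for ROI group '", g, "': days must be 1..",
           max(d), " with no gaps")
  }
  out$cumulative_count <- as.numeric(
    unlist(lapply(split(out$new_cells, key), cumsum)))
  class(out) <- c("cumulative_invasion", "data.frame")
  out
}

#' Compare cumulative-invasion slopes between conditions
#'
#' Per-condition ordinary least squares of cumulative count on day, plus
#' pairwise slope-difference tests via the day-by-condition interaction term
#' of a pooled linear model.
#'
#' @param counts a `cumulative_invasion` data.frame with a `condition` column
#'   (>= 2 conditions, >= 3 days each).
#' @return list with `slopes` (data.frame: condition, slope, se) and
#'   `pairwise` (data.frame: condition_a, condition_b, slope_diff, p).
#' @export
compare_slopes <- function(counts) {
  stopifnot(all(c("condition", "day", "cumulative_count") %in% names(counts)))
  conds <- unique(as.character(counts$condition))
  if (length(conds) < 2) stop("need at least 2 conditions")
  for (cn in conds) {
    if (length(unique(counts$day[counts$condition == cn])) < 3)
      stop("condition '", cn, "' has fewer than 3 days")
  }
  slopes <- do.call(rbind, lapply(conds, function(cn) {
    d <- counts[counts$condition == cn, ]
    fit <- lm(cumulative_count ~ day, data = d)
    data.frame(condition = cn, slope = coef(fit)[["day"]],
               se = suppressWarnings(summary(fit))$coefficients["day", "Std. Error"])
  }))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    d <- counts[counts$condition %in% pr, ]
    d$condition <- factor(as.character(d$condition), levels = pr)
    fit <- lm(cumulative_count ~ day * condition, data = d)
    sm <- suppressWarnings(summary(fit))$coefficients
    term <- paste0("day:condition", pr[2])
    data.frame(condition_a = pr[1], condition_b = pr[2],
               slope_diff = -coef(fit)[[term]],
               p = if (all(abs(stats::residuals(fit)) < 1e-10)) {
                 # exact-fit degenerate case: p is 1 iff slopes are identical
                 if (abs(coef(fit)[[term]]) < 1e-10) 1 else 0
               } else sm[term, "Pr(>|t|)"])
  }))
  rownames(slopes) <- rownames(pairwise) <- NULL
  list(slopes = slopes, pairwise = pairwise)
}
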