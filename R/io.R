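#' Write / read a multi-page TIFF image stack
#'
#' Stacks are written as 32-bit float multi-page TIFF. TIFF stores values in
#' `[0, 1]`, so intensities are divided by a scale factor recorded (together
#' with spatial metadata) in a JSON sidecar named `<basename>.meta.json`.
#'
#' @param stack 3-D numeric array (ny x nx x n_planes).
#' @param path output `.tif` path.
#' @param pixel_size lateral um per pixel (metadata).
#' @param spacing axial (um) or temporal (s) plane spacing (metadata).
#' @param spacing_unit `"um"` or `"s"`.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   list with `stack`, `pixel_size`, `spacing`, `spacing_unit`.
#' @export
write_stack <- function(stack, path, pixel_size = NA, spacing = NA,
                        spacing_unit = "um") {
  stopifnot(length(dim(stack)) == 3)
  scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(i) pmax(stack[, , i], 0) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(scale = scale, pixel_size = pixel_size, spacing = spacing,
               spacing_unit = spacing_unit, n_planes = dim(stack)[3])
  jsonlite::write_json(meta, paste0(sub("\\.tiff?$", "", path), ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  metafile <- paste0(sub("\\.tiff?$", "", path), ".meta.json")
  meta <- if (file.exists(metafile))
    jsonlite::read_json(metafile, simplifyVector = TRUE)
  else list(scale = 1, pixel_size = NA, spacing = NA, spacing_unit = "um")
  stack <- array(unlist(pages),
                 dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  stack <- stack * meta$scale
  list(stack = stack, pixel_size = meta$pixel_size, spacing = meta$spacing,
       spacing_unit = meta$spacing_unit)
}

#' Write / read a bead trajectory CSV (time_s, x_um, y_um)
#'
#' @param traj a [bead_trajectory()].
#' @param path CSV path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `bead_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bead_trajectory"))
  write.csv(data.frame(time_s = traj$time, x_um = traj$position[, 1],
                       y_um = traj$position[, 2]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "x_um", "y_um") %in% names(d)))
  bead_trajectory(d$time_s, cbind(d$x_um, d$y_um))
}

#' Write / read a force-indentation curve CSV (z_um, force_nN)
#'
#' @param curve an [indentation_curve()].
#' @param path CSV path.
#' @param probe_radius_R,cantilever_k,poisson_nu probe metadata applied on
#'   read.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns an
#'   `indentation_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "indentation_curve"))
  write.csv(data.frame(z_um = curve$z, force_nN = curve$force),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, probe_radius_R = 7.5, cantilever_k = 0.03,
                       poisson_nu = 0.5) {
  d <- read.csv(path)
  stopifnot(all(c("z_um", "force_nN") %in% names(d)))
  indentation_curve(d$z_um, d$force_nN, probe_radius_R = probe_radius_R,
                    cantilever_k = cantilever_k, poisson_nu = poisson_nu)
}

#' Per-pillar force table from tracked pillars
#'
#' @param tracks a `pillar_tracks` object with forces populated.
#' @return data.frame: pillar_id, frame, x_um, y_um, defl_um, force_nN.
#' @export
pillar_force_table <- function(tracks) {
  stopifnot(inherits(tracks, "pillar_tracks"), !is.null(tracks$forces_nN))
  n_p <- dim(tracks$positions_um)[1]
  n_f <- dim(tracks$positions_um)[3]
  data.frame(
    pillar_id = rep(seq_len(n_p), times = n_f),
    frame = rep(seq_len(n_f), each = n_p),
    x_um = as.vector(tracks$positions_um[, 1, ]),
    y_um = as.vector(tracks$positions_um[, 2, ]),
    defl_um = as.vector(tracks$deflection_mag_um),
    force_nN = as.vector(tracks$forces_nN)
  )
}
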