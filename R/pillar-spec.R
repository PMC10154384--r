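#' Micropillar array geometry and calibration
#'
#' Describes the elastic (PDMS) micropillar array: lattice pitch, apparent
#' spot diameter of a pillar top in the image, the calibrated spring constant
#' converting tip deflection to force, lattice type and the image pixel size.
#' Defaults follow typical PDMS arrays used for single-cell traction
#' measurements; pitch and diameter are configurable assumptions, while the
#' spring constant default is the calibrated 1.36 nN/um of the arrays this
#' package models.
#'
#' @param pitch lattice spacing in um (> spot_diameter).
#' @param spot_diameter apparent pillar-top diameter in um.
#' @param spring_constant_k pillar spring constant in nN/um.
#' @param lattice `"square"` or `"hexagonal"`.
#' @param pixel_size image scale in um per pixel.
#' @return object of class `pillar_array_spec`.
#' @export
pillar_array_spec <- function(pitch = 6, spot_diameter = 2,
                              spring_constant_k = 1.36,
                              lattice = c("square", "hexagonal"),
                              pixel_size = 0.3) {
  lattice <- match.arg(lattice)
  stopifnot(pitch > 0, spot_diameter > 0, spring_constant_k > 0,
            pixel_size > 0)
  if (pitch <= spot_diameter)
    stop("lattice pitch (", pitch, " um) must exceed the spot diameter (",
         spot_diameter, " um): pillars would be unresolvable")
  structure(list(pitch = pitch, spot_diameter = spot_diameter,
                 spring_constant_k = spring_constant_k, lattice = lattice,
                 pixel_size = pixel_size),
            class = "pillar_array_spec")
}

# Gaussian spot sigma in pixels (sigma = diameter / 4).
spot_sigma_px <- function(spec) (spec$spot_diameter / 4) / spec$pixel_size

# Detection/refinement window half-width in pixels.
spot_window_px <- function(spec) {
  pitch_px <- spec$pitch / spec$pixel_size
  max(3L, min(floor(pitch_px / 2) - 2L, ceiling(3 * spot_sigma_px(spec))))
}

# Lattice basis matrix (columns = lattice vectors, um).
lattice_basis <- function(spec) {
  p <- spec$pitch
  if (spec$lattice == "square") p * diag(2)
  else p * matrix(c(1, 0, 0.5, sqrt(3) / 2), 2, 2)
}

#' Circular binary cell mask
#'
#' @param ny,nx image dimensions in pixels.
#' @param center_px centre `(x, y)` in 0-based pixels; default image centre.
#' @param radius_um mask radius in um.
#' @param pixel_size um per pixel.
#' @return logical matrix `ny` x `nx`.
#' @export
disk_mask <- function(ny, nx, radius_um, pixel_size,
                      center_px = c((nx - 1) / 2, (ny - 1) / 2)) {
  x <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  y <- matrix(0:(ny - 1), ny, nx)
  (x - center_px[1])^2 + (y - center_px[2])^2 <= (radius_um / pixel_size)^2
}
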