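#' Spherical-indenter Hertz force law
#'
#' Contact force for a rigid sphere of radius R indenting an elastic
#' half-space: F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2).
#' With E in Pa, R and delta in um, the force is returned in nN
#' (the unit conversion factor is 1e-3).
#'
#' @param delta indentation depth in um (negative values give zero force).
#' @param E Young's modulus in Pa.
#' @param R probe radius in um.
#' @param nu Poisson ratio (0.5 for an incompressible cell).
#' @return force in nN.
#' @export
hertz_force <- function(delta, E, R, nu = 0.5) {
  stopifnot(E > 0, R > 0, nu >= 0, nu < 0.5 + 1e-12)
  d <- pmax(delta, 0)
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * d^1.5 * 1e-3
}

#' Force-indentation curve container
#'
#' @param z piezo extension in um (strictly monotone; increasing z moves the
#'   probe into the cell).
#' @param force measured force in nN.
#' @param probe_radius_R probe (bead) radius in um.
#' @param cantilever_k cantilever spring constant in N/m (metadata only).
#' @param poisson_nu Poisson ratio assumed for the sample.
#' @return object of class `indentation_curve`.
#' @export
indentation_curve <- function(z, force, probe_radius_R = 7.5,
                              cantilever_k = 0.03, poisson_nu = 0.5) {
  stopifnot(length(z) == length(force), all(is.finite(force)),
            probe_radius_R > 0)
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0))) stop("z must be strictly monotone")
  structure(list(z = as.numeric(z), force = as.numeric(force),
                 probe_radius_R = probe_radius_R, cantilever_k = cantilever_k,
                 poisson_nu = poisson_nu),
            class = "indentation_curve")
}

#' Generate a synthetic force-indentation curve with known modulus
#'
#' Before contact the force is a linear baseline (slope `baseline_slope`);
#' after contact the spherical Hertz force is added on top. Gaussian force
#' noise is applied to every sample.
#'
#' @param E_true Young's modulus in Pa (> 0).
#' @param R probe radius in um.
#' @param nu Poisson ratio in (0, 0.5]; 0.5 default.
#' @param contact_z contact point in um (inside `z_range`).
#' @param z_range total piezo travel in um (curve spans 0..z_range).
#' @param z_step piezo step in um (> 0).
#' @param noise_sd force noise SD in nN.
#' @param baseline_slope pre-contact baseline slope in nN/um.
#' @param seed integer seed.
#' @return list with `curve` (an [indentation_curve()]) and `truth`
#'   (a [ground_truth()] storing `E_true` and `contact_z`).
#' @export
generate_indentation_curve <- function(E_true, R = 7.5, nu = 0.5,
                                       contact_z = 5, z_range = 10,
                                       z_step = 0.01, noise_sd = 0,
                                       baseline_slope = 0, seed = 1) {
  stopifnot(E_true > 0, nu > 0, nu <= 0.5)
  if (z_step <= 0) stop("z_step must be positive")
  if (contact_z <= 0 || contact_z >= z_range)
    stop("contact_z must lie inside the z range")
  z <- seq(0, z_range, by = z_step)
  f <- baseline_slope * z + hertz_force(z - contact_z, E_true, R, nu)
  withr::with_seed(seed, {
    if (noise_sd > 0) f <- f + rnorm(length(z), sd = noise_sd)
  })
  truth <- ground_truth("afm", list(E_true_Pa = E_true, contact_z_um = contact_z,
                                    R_um = R, nu = nu,
                                    baseline_slope_nN_per_um = baseline_slope,
                                    noise_sd_nN = noise_sd), seed)
  list(curve = indentation_curve(z, f, probe_radius_R = R, poisson_nu = nu),
       truth = truth)
}

#' Remove the linear pre-contact baseline from a curve
#'
#' Fits a straight line to the first `pre_contact_fraction` of samples
#' (assumed force-free) and subtracts it from the whole curve, so the
#' pre-contact force has mean ~0 and the fit sees only the contact response.
#'
#' @param curve an [indentation_curve()].
#' @param pre_contact_fraction fraction of leading samples used for the fit,
#'   in (0, 1); at least 10 samples must remain.
#' @return the baseline-corrected `indentation_curve`.
#' @export
baseline_correct <- function(curve, pre_contact_fraction = 0.2) {
  stopifnot(inherits(curve, "indentation_curve"),
            pre_contact_fraction > 0, pre_contact_fraction < 1)
  n <- length(curve$z)
  m <- floor(n * pre_contact_fraction)
  if (m < 10) stop("fewer than 10 pre-contact samples for baseline fit")
  fit <- lm(curve$force[1:m] ~ curve$z[1:m])
  curve$force <- curve$force - (coef(fit)[1] + coef(fit)[2] * curve$z)
  curve
}

# Closed-form least-squares modulus on a fixed post-contact window.
ls_modulus <- function(z, f, contact_z, R, nu, max_indentation) {
  d <- z - contact_z
  sel <- d > 0 & d <= max_indentation
  if (sum(sel) == 0) return(list(E = NA_real_, n = 0L, rss = NA_real_, sel = sel))
  phi <- (4 / 3) / (1 - nu^2) * sqrt(R) * d[sel]^1.5 * 1e-3
  E <- sum(f[sel] * phi) / sum(phi^2)
  list(E = E, n = sum(sel), rss = sum((f[sel] - E * phi)^2), sel = sel)
}

#' Detect the contact point of a baseline-corrected curve
#'
#' Scans candidate contact points on the sample grid and scores each with the
#' total residual of a piecewise model (zero force before contact, spherical
#' Hertz force after, modulus profiled out by least squares). Returns the
#' minimizer; if no candidate with a positive modulus improves on the flat
#' (no-contact) model, the curve is flagged as contact-free.
#'
#' @param curve a baseline-corrected [indentation_curve()].
#' @param max_indentation fit window after contact in um; default 10% of the
#'   probe radius (Hertz small-indentation validity).
#' @param coarse_by evaluate every `coarse_by`-th sample first, then refine.
#' @return list with `contact_z` (um), `found` flag, and the grid-search
#'   residual `rss` at the minimizer.
#' @export
find_contact_point <- function(curve, max_indentation = 0.1 * curve$probe_radius_R,
                               coarse_by = 5L) {
  stopifnot(inherits(curve, "indentation_curve"))
  z <- curve$z; f <- curve$force
  if (z[1] > z[length(z)]) { z <- rev(z); f <- rev(f) }
  n <- length(z)
  R <- curve$probe_radius_R; nu <- curve$poisson_nu
  lo <- max(2L, floor(0.02 * n))
  hi <- n - 5L
  if (hi <= lo) stop("curve too short for contact-point search")
  score <- function(i) {
    m <- ls_modulus(z, f, z[i], R, nu, max_indentation)
    if (is.na(m$E) || m$E <= 0) return(Inf)
    # modulus estimated on the small-indentation window, model extrapolated
    # over the full post-contact region so candidates score on equal domains
    pred <- hertz_force(z - z[i], m$E, R, nu)
    sum((f - pred)^2)
  }
  # residual of the flat model (no contact anywhere)
  rss_flat <- sum(f^2)
  cand <- unique(c(seq(lo, hi, by = coarse_by), hi))
  sc <- vapply(cand, score, numeric(1))
  if (all(!is.finite(sc)) || min(sc) >= rss_flat) {
    return(list(contact_z = NA_real_, found = FALSE, rss = rss_flat))
  }
  i0 <- cand[which.min(sc)]
  fine <- max(lo, i0 - coarse_by):min(hi, i0 + coarse_by)
  scf <- vapply(fine, score, numeric(1))
  i_best <- fine[which.min(scf)]
  list(contact_z = z[i_best], found = TRUE, rss = min(scf))
}

#' Fit the spherical Hertz model at a given contact point
#'
#' Least-squares estimate of the Young's modulus on the post-contact window
#' `0 < delta <= max_indentation`; the model is linear in E so the estimate is
#' closed-form.
#'
#' @param curve a baseline-corrected [indentation_curve()].
#' @param contact_z contact point in um.
#' @param max_indentation fit window in um (default 10% of probe radius).
#' @return object of class `hertz_fit`: `E` (Pa), `contact_z`, `rss` (nN^2),
#'   `fit_window` (um), `n_samples` and `converged`.
#' @export
hertz_fit <- function(curve, contact_z,
                      max_indentation = 0.1 * curve$probe_radius_R) {
  stopifnot(inherits(curve, "indentation_curve"), is.finite(contact_z))
  z <- curve$z; f <- curve$force
  if (z[1] > z[length(z)]) { z <- rev(z); f <- rev(f) }
  m <- ls_modulus(z, f, contact_z, curve$probe_radius_R, curve$poisson_nu,
                  max_indentation)
  converged <- m$n >= 20 && is.finite(m$E) && m$E > 0
  structure(list(E = if (converged) m$E else NA_real_,
                 contact_z = contact_z, rss = m$rss,
                 fit_window = max_indentation, n_samples = m$n,
                 converged = converged),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<hertz_fit> E = %.1f Pa (contact at %.3f um, %d samples)\n",
                x$E, x$contact_z, x$n_samples))
  else cat("<hertz_fit> not converged\n")
  invisible(x)
}

#' Full single-curve stiffness pipeline
#'
#' Baseline correction, contact-point detection and Hertz fit in one call.
#'
#' @inheritParams baseline_correct
#' @inheritParams find_contact_point
#' @return a `hertz_fit` (non-converged, with `contact_found = FALSE`
#'   attribute, if no contact region is detected).
#' @export
fit_indentation_curve <- function(curve, pre_contact_fraction = 0.2,
                                  max_indentation = 0.1 * curve$probe_radius_R) {
  bc <- baseline_correct(curve, pre_contact_fraction)
  cp <- find_contact_point(bc, max_indentation)
  if (!cp$found) {
    out <- structure(list(E = NA_real_, contact_z = NA_real_, rss = cp$rss,
                          fit_window = max_indentation, n_samples = 0L,
                          converged = FALSE),
                     class = "hertz_fit")
    attr(out, "contact_found") <- FALSE
    return(out)
  }
  out <- hertz_fit(bc, cp$contact_z, max_indentation)
  attr(out, "contact_found") <- TRUE
  out
}
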