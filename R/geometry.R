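#' Fiber-probe illumination and detection geometry
#'
#' Describes the contact fiber-bundle probe: oblique illumination through the
#' angle-polished bundle, the refractive indices on either side of the tissue
#' interface, and the numerical-aperture-limited acceptance cone of the
#' imaging fibers. Defaults correspond to a bundle polished at 20 degrees
#' with fused-silica-like upper index 1.60 in contact with tissue of index
#' 1.38, and an in-fiber acceptance half-angle of 13.2 degrees (NA 0.27 in
#' air, metadata only).
#'
#' @param incidence_angle_deg illumination angle in the upper medium, degrees
#'   from the surface normal.
#' @param acceptance_half_angle_deg detection cone half-angle in the upper
#'   medium, degrees.
#' @param n_upper refractive index above the tissue (fiber/polish side).
#' @param n_medium tissue refractive index.
#' @param fiber_field_diameter_um imaging field diameter, micrometres.
#' @param na_air fiber numerical aperture in air (recorded, not used by the
#'   transport model, which works with the acceptance half-angle directly).
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(incidence_angle_deg = 20,
                           acceptance_half_angle_deg = 13.2,
                           n_upper = 1.60, n_medium = 1.38,
                           fiber_field_diameter_um = 900,
                           na_air = 0.27) {
  if (incidence_angle_deg <= 0 || incidence_angle_deg >= 90 ||
      acceptance_half_angle_deg <= 0 || acceptance_half_angle_deg >= 90) {
    stop("angles must lie in (0, 90) degrees", call. = FALSE)
  }
  if (n_upper < 1 || n_medium < 1) {
    stop("refractive indices must be >= 1", call. = FALSE)
  }
  structure(list(incidence_angle_deg = incidence_angle_deg,
                 acceptance_half_angle_deg = acceptance_half_angle_deg,
                 n_upper = n_upper, n_medium = n_medium,
                 fiber_field_diameter_um = fiber_field_diameter_um,
                 na_air = na_air),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(paste0("<probe_geometry> incidence %.1f deg, acceptance ",
                     "%.1f deg, n %.2f -> %.2f, field %.0f um\n"),
              x$incidence_angle_deg, x$acceptance_half_angle_deg,
              x$n_upper, x$n_medium, x$fiber_field_diameter_um))
  invisible(x)
}

#' Homogeneous semi-infinite optical medium
#'
#' @param mus scattering coefficient, 1/mm (> 0).
#' @param mua absorption coefficient, 1/mm (>= 0). Default 0.01/mm, typical
#'   of weakly absorbing epithelium in the red.
#' @param phase_function a [phase_function()].
#' @return An object of class `optical_medium` with derived anisotropy `g`
#'   and reduced scattering `musp`.
#' @export
optical_medium <- function(mus, mua = 0.01, phase_function) {
  if (!is.numeric(mus) || mus <= 0) stop("`mus` must be > 0", call. = FALSE)
  if (!is.numeric(mua) || mua < 0) stop("`mua` must be >= 0", call. = FALSE)
  stopifnot(inherits(phase_function, "phase_function"))
  g <- anisotropy(phase_function)
  structure(list(mus = mus, mua = mua, phase_function = phase_function,
                 g = g, musp = mus * (1 - g)),
            class = "optical_medium")
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf("<optical_medium> mus = %.3g /mm, mua = %.3g /mm, g = %.4f, musp = %.3g /mm\n",
              x$mus, x$mua, x$g, x$musp))
  invisible(x)
}

#' Convenience constructor from reduced scattering
#'
#' Builds an [optical_medium()] with the scattering coefficient derived from
#' a reduced scattering coefficient and the phase function's anisotropy,
#' `mus = musp / (1 - g)`.
#'
#' @param musp reduced scattering coefficient, 1/mm.
#' @inheritParams optical_medium
#' @return An `optical_medium`.
#' @export
medium_from_musp <- function(musp, mua = 0.01, phase_function) {
  g <- anisotropy(phase_function)
  optical_medium(mus_from_musp(musp, g), mua, phase_function)
}

#' In-medium launch direction of the oblique beam
#'
#' Refracts the illumination axis from the upper medium into the tissue by
#' Snell's law. The beam lies in the x-z plane and points into the medium
#' (z grows with depth).
#'
#' @param geometry a [probe_geometry()].
#' @return unit vector `c(x, y, z)` of the launch direction in the medium.
#' @export
launch_direction <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  th_i <- geometry$incidence_angle_deg * pi / 180
  sin_t <- geometry$n_upper / geometry$n_medium * sin(th_i)
  if (sin_t >= 1) {
    stop("total internal reflection: illumination cannot enter the medium",
         call. = FALSE)
  }
  c(sin_t, 0, sqrt(1 - sin_t^2))
}

#' Detection axis in the upper medium
#'
#' The acceptance cone is centred on the fiber axis, i.e. the reverse of the
#' illumination axis in the upper medium: an exiting photon is detected only
#' if it travels back up the bundle.
#'
#' @param geometry a [probe_geometry()].
#' @return unit vector of the detection axis (pointing out of the tissue).
#' @export
detection_axis <- function(geometry) {
  th <- geometry$incidence_angle_deg * pi / 180
  c(-sin(th), 0, -cos(th))
}

#' Acceptance test for an exiting photon
#'
#' Refracts an upward exit direction from the tissue into the upper medium
#' and tests whether it falls inside the acceptance cone about the fiber
#' axis. Photons undergoing total internal reflection at the exit interface
#' are rejected.
#'
#' @param exit_direction unit vector with negative z component (photon
#'   leaving the tissue), in the tissue.
#' @param geometry a [probe_geometry()].
#' @return `TRUE` if the photon is detected.
#' @export
detect <- function(exit_direction, geometry) {
  stopifnot(inherits(geometry, "probe_geometry"), length(exit_direction) == 3)
  d <- exit_direction / sqrt(sum(exit_direction^2))
  if (d[3] >= 0) stop("`exit_direction` must point out of the tissue (z < 0)",
                      call. = FALSE)
  r <- geometry$n_medium / geometry$n_upper
  sin2_t <- r^2 * (d[1]^2 + d[2]^2)
  if (sin2_t >= 1) return(FALSE)       # total internal reflection at exit
  d_up <- c(r * d[1], r * d[2], -sqrt(1 - sin2_t))
  axis <- detection_axis(geometry)
  cos_acc <- cos(geometry$acceptance_half_angle_deg * pi / 180)
  sum(d_up * axis) >= cos_acc
}
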