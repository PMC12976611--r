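# Wall geometry and elastic-wall forcing -----------------------------------

#' Outer wall radius r2(z, t)
#'
#' The flexible outer wall carries a travelling sinusoidal wave,
#' `r2 = 1 + phi * sin(2 * pi * (z - t))` (lengths scaled on the mean outer
#' radius, z on the wavelength, t on the wave period).
#'
#' @param z Axial coordinate(s), in wavelengths.
#' @param t Time(s), in wave periods.
#' @param params A [carreau_params()] object.
#' @return Numeric vector of wall radii.
#' @export
outer_radius <- function(z, t, params) {
  1 + params$phi * sin(2 * pi * (z - t))
}

#' Elastic-wall forcing E(z, t)
#'
#' Applies the fifth-order compliant-wall operator
#' `e1 d^5/dz^5 - e2 d^3/dz^3 + e3 d^3/(dz dt^2) + e4 d^2/(dz dt) + e5 d/dz`
#' to the wall shape `r2(z, t)`. For a single-harmonic wall the operator
#' evaluates in closed form: with `theta = 2*pi*(z - t)` and `k = 2*pi`,
#'
#' `E = phi * ((k^5 e1 + k^3 e2 - k^3 e3 + k e5) * cos(theta)
#'             + k^2 e4 * sin(theta))`.
#'
#' This quantity replaces the axial pressure gradient in the reduced
#' momentum balance: the wall's flexural stiffness, tension and mass act
#' through the `cos` component, viscous wall damping through the `sin`
#' component. It is identically zero for a flat wall (`phi = 0`).
#'
#' @inheritParams outer_radius
#' @return Numeric vector of forcing values.
#' @export
wall_forcing <- function(z, t, params) {
  k <- 2 * pi
  th <- k * (z - t)
  ccoef <- k^5 * params$e1 + k^3 * params$e2 - k^3 * params$e3 + k * params$e5
  params$phi * (ccoef * cos(th) + k^2 * params$e4 * sin(th))
}

#' Fix an axial station of the wave
#'
#' The long-wavelength reduction makes the radial problems quasi-static:
#' each axial station `(z, t)` is an independent annular boundary-value
#' problem with outer radius `h = r2(z, t)` and wall forcing `E(z, t)`.
#' The default station `z - t = 0.5` is the package's reporting section:
#' there the wall sits at its mean radius and, for the reference
#' configuration, the elastic forcing is near its extreme, so the
#' characteristic single-peaked velocity profile is fully developed (at
#' the wave crest `z - t = 0.25` the `cos` component of the forcing
#' vanishes and the elastic terms `e1, e2, e3, e5` drop out entirely).
#'
#' @param params A [carreau_params()] object.
#' @param z Axial coordinate (wavelengths).
#' @param t Time (wave periods).
#' @return An object of class `axial_section` with fields `z`, `t`,
#'   `h` (outer radius) and `E` (wall forcing).
#' @export
axial_section <- function(params, z = 0.5, t = 0) {
  stopifnot(length(z) == 1L, length(t) == 1L, is.finite(z), is.finite(t))
  structure(
    list(z = z, t = t,
         h = outer_radius(z, t, params),
         E = wall_forcing(z, t, params)),
    class = "axial_section"
  )
}

#' @export
print.axial_section <- function(x, ...) {
  cat(sprintf("Axial section: z = %g, t = %g  (z - t = %g)\n", x$z, x$t, x$z - x$t))
  cat(sprintf("  outer radius h = %.6g, wall forcing E = %.6g\n", x$h, x$E))
  invisible(x)
}
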