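# Temperature and concentration fields -------------------------------------
#
# In the long-wavelength limit the energy balance decouples from the flow:
#   beta * (H'' + H'/r) - Omega * H = 0,   beta = 1/Pr + 4/(3*Rn),
# with H(eps) = 0, H(h) = 1.  This is a modified Helmholtz equation in the
# radius; its solution on the annulus is a combination of the real modified
# Bessel functions I0 and K0 with decay constant A = sqrt(Omega / beta).
# The concentration obeys a Soret-coupled balance whose combination
# xi + S1*S2*H is radially harmonic, so xi is a log profile minus the
# scaled temperature.

.beta_thermal <- function(params) 1 / params$Pr + 4 / (3 * params$Rn)

#' Temperature field across the annular gap
#'
#' Solves the radial heat balance with a uniform heat sink
#' (`beta (H'' + H'/r) = Omega H`, `beta = 1/Pr + 4/(3 Rn)`) subject to
#' `H = 0` on the catheter and `H = 1` on the outer wall. For
#' `Omega > 0` the solution is
#' `H(r) = (I0(Ar) K0(A eps) - I0(A eps) K0(Ar)) / (I0(Ah) K0(A eps) - I0(A eps) K0(Ah))`
#' with `A = sqrt(Omega / beta)`; for `Omega = 0` the exact limit is the
#' log profile `log(r/eps) / log(h/eps)`. Exponentially scaled Bessel
#' evaluations keep the form stable for large `A`.
#'
#' @param params A [carreau_params()] object.
#' @param section An [axial_section()]; defaults to the reporting section.
#' @param grid A [radial_grid()]; built on demand if `NULL`.
#' @return A `scalar_field` object: samples `value`, analytic radial
#'   derivatives `d1` and `d2`, the decay constant `A`, and the
#'   closed-form `coefficients`.
#' @export
solve_temperature <- function(params, section = NULL, grid = NULL) {
  if (is.null(section)) section <- axial_section(params)
  if (is.null(grid)) grid <- radial_grid(params, section)
  r <- grid$r
  eps <- params$eps
  h <- section$h
  beta <- .beta_thermal(params)
  A <- sqrt(params$Omega / beta)

  if (params$Omega == 0) {
    lg <- log(h / eps)
    value <- log(r / eps) / lg
    d1 <- 1 / (r * lg)
    d2 <- -1 / (r^2 * lg)
    coef <- list(form = "log", c_log = 1 / lg, c_const = -log(eps) / lg)
  } else {
    # scaled Bessel products; all exponents are <= 0 so nothing overflows
    I0s <- function(x) besselI(x, 0, expon.scaled = TRUE)
    K0s <- function(x) besselK(x, 0, expon.scaled = TRUE)
    I1s <- function(x) besselI(x, 1, expon.scaled = TRUE)
    K1s <- function(x) besselK(x, 1, expon.scaled = TRUE)
    den <- I0s(A * h) * K0s(A * eps) -
      I0s(A * eps) * K0s(A * h) * exp(2 * A * (eps - h))
    if (!is.finite(den) || abs(den) < 1e-300)
      stop("degenerate geometry: temperature denominator vanishes")
    num <- I0s(A * r) * K0s(A * eps) * exp(A * (r - h)) -
      I0s(A * eps) * K0s(A * r) * exp(A * (2 * eps - r - h))
    value <- num / den
    # d/dr: I0' = A I1, K0' = -A K1
    num1 <- I1s(A * r) * K0s(A * eps) * exp(A * (r - h)) +
      I0s(A * eps) * K1s(A * r) * exp(A * (2 * eps - r - h))
    d1 <- A * num1 / den
    d2 <- params$Omega * value / beta - d1 / r   # from the ODE itself
    coef <- list(form = "bessel", A = A, den = den)
  }

  structure(
    list(field = "temperature", grid = grid, value = value,
         d1 = d1, d2 = d2, A = A, beta = beta,
         coefficients = coef, section = section, params = params),
    class = "scalar_field"
  )
}

#' Soret-coupled concentration field
#'
#' Solves the mass balance `(1/S2)(xi'' + xi'/r) + S1 (H'' + H'/r) = 0`
#' with `xi = 1` on the catheter and `xi = 0` on the outer wall. Because
#' `xi + S1 S2 H` is radially harmonic,
#' `xi(r) = c_log log(r) + c_const - S1 S2 H(r)` with
#' `c_log = (S1 S2 - 1) / log(h/eps)` and
#' `c_const = 1 - c_log log(eps)`.
#'
#' @inheritParams solve_temperature
#' @param temperature The matching `scalar_field` from
#'   [solve_temperature()], solved on the same grid and section.
#' @return A `scalar_field` object (see [solve_temperature()]); its
#'   `coefficients` hold `c_log`, `c_const` and the coupling weight
#'   `-S1 * S2`.
#' @export
solve_concentration <- function(params, section = NULL, grid = NULL,
                                temperature = NULL) {
  if (is.null(section)) section <- axial_section(params)
  if (is.null(grid)) grid <- radial_grid(params, section)
  if (is.null(temperature)) temperature <- solve_temperature(params, section, grid)
  if (!identical(length(temperature$grid$r), length(grid$r)) ||
      max(abs(temperature$grid$r - grid$r)) > 1e-12)
    stop("temperature field was solved on a different grid")

  r <- grid$r
  eps <- params$eps
  h <- section$h
  ss <- params$S1 * params$S2
  c_log <- (ss - 1) / log(h / eps)
  c_const <- 1 - c_log * log(eps)

  value <- c_log * log(r) + c_const - ss * temperature$value
  d1 <- c_log / r - ss * temperature$d1
  d2 <- -c_log / r^2 - ss * temperature$d2

  structure(
    list(field = "concentration", grid = grid, value = value,
         d1 = d1, d2 = d2, A = temperature$A, beta = temperature$beta,
         coefficients = list(c_log = c_log, c_const = c_const,
                             coupling = -ss),
         section = section, params = params),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("%s field on [%.4g, %.4g] (%d nodes)\n",
              x$field, x$grid$r[1], x$grid$r[x$grid$n], x$grid$n))
  cat(sprintf("  wall values: %.6g (inner), %.6g (outer);  A = %.6g\n",
              x$value[1], x$value[x$grid$n], x$A))
  invisible(x)
}

#' @export
as.data.frame.scalar_field <- function(x, ...) {
  data.frame(r = x$grid$r, value = x$value, d1 = x$d1, d2 = x$d2)
}
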