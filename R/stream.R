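# Stream function and trapped-bolus extraction -----------------------------
#
# The wave-frame stream function follows from u3 = (1/r) dpsi/dr:
#   psi(r, z) = int_eps^r s * u3(s, z) ds,    gauge psi(eps, z) = 0.
# The field is assembled over one wavelength on a boundary-fitted mesh:
# a fixed grid in the normalised gap coordinate eta = (r - eps)/(h(z) - eps)
# maps to a radial grid per axial station, so the domain is rectangular in
# (eta, z) and closed streamlines (trapped boluses) can be extracted by
# marching squares without masking.

#' Wave-frame stream function over one wavelength
#'
#' Solves the velocity at `nz` axial stations covering one wavelength and
#' integrates `psi(r, z) = int s u3 ds` radially, with `psi = 0` on the
#' catheter surface.
#'
#' @param params A [carreau_params()] object.
#' @param t Time (wave periods) at which the snapshot is taken.
#' @param nz Number of axial stations over one wavelength (at least 32).
#' @param nr Number of radial nodes per station.
#' @return An object of class `stream_field`: `eta` (normalised radial
#'   coordinate), `z`, matrices `psi` and `r` (`nr` x `nz`), and inputs.
#' @export
stream_function <- function(params, t = 0, nz = 65, nr = 129) {
  stopifnot(nz >= 32)
  z <- seq(0, 1, length.out = nz)
  eta <- seq(0, 1, length.out = nr)
  psi <- matrix(NA_real_, nr, nz)
  rmat <- matrix(NA_real_, nr, nz)
  for (j in seq_len(nz)) {
    sec <- axial_section(params, z = z[j], t = t)
    grid <- radial_grid(params, sec, r = params$eps + eta * (sec$h - params$eps))
    sol <- solve_velocity(params, sec, grid)
    psi[, j] <- .cumint(grid, grid$r * sol$u3)
    rmat[, j] <- grid$r
  }
  structure(
    list(eta = eta, z = z, psi = psi, r = rmat, t = t, params = params),
    class = "stream_field"
  )
}

#' Extract closed streamlines (trapped boluses)
#'
#' Cuts the stream function at a ladder of evenly spaced levels strictly
#' between the field minimum and maximum, keeps the level curves that
#' close inside the mesh, and reports each with its enclosed area in the
#' physical `(z, r)` plane (shoelace formula). An empty contour set is a
#' valid result (no trapping).
#'
#' @param sf A `stream_field` from [stream_function()].
#' @param n_levels Number of contour levels (default 21).
#' @return An object of class `bolus_set`: a list of closed-contour data
#'   frames (`contour_id`, `level`, `z`, `r`), the level ladder, the
#'   closed-contour count `n_closed`, and `total_area`.
#' @export
extract_boluses <- function(sf, n_levels = 21) {
  rng <- range(sf$psi)
  if (diff(rng) <= 0) {
    return(structure(list(contours = list(), levels = numeric(0),
                          n_closed = 0L, total_area = 0),
                     class = "bolus_set"))
  }
  levels <- seq(rng[1], rng[2], length.out = n_levels + 2L)
  levels <- levels[-c(1L, n_levels + 2L)]
  cl <- grDevices::contourLines(x = sf$eta, y = sf$z, z = sf$psi,
                                levels = levels)
  eps <- sf$params$eps
  hz <- stats::approxfun(sf$z, sf$r[length(sf$eta), ])
  contours <- list()
  total <- 0
  for (cc in cl) {
    m <- length(cc$x)
    if (m < 4) next
    closed <- abs(cc$x[1] - cc$x[m]) < 1e-9 && abs(cc$y[1] - cc$y[m]) < 1e-9
    if (!closed) next
    r_phys <- eps + cc$x * (hz(cc$y) - eps)
    z_phys <- cc$y
    area <- abs(sum(z_phys * c(r_phys[-1], r_phys[1]) -
                    c(z_phys[-1], z_phys[1]) * r_phys)) / 2
    contours[[length(contours) + 1L]] <-
      data.frame(contour_id = length(contours) + 1L, level = cc$level,
                 z = z_phys, r = r_phys)
    total <- total + area
  }
  structure(
    list(contours = contours, levels = levels,
         n_closed = length(contours), total_area = total),
    class = "bolus_set"
  )
}

#' @export
print.stream_field <- function(x, ...) {
  cat(sprintf("Stream function: %d x %d mesh over one wavelength (t = %g)\n",
              length(x$eta), length(x$z), x$t))
  cat(sprintf("  psi range [%.6g, %.6g]\n", min(x$psi), max(x$psi)))
  invisible(x)
}

#' @export
print.bolus_set <- function(x, ...) {
  cat(sprintf("Trapped boluses: %d closed contour(s), total area %.6g\n",
              x$n_closed, x$total_area))
  invisible(x)
}

#' @export
as.data.frame.stream_field <- function(x, ...) {
  data.frame(r = as.vector(x$r),
             z = rep(x$z, each = length(x$eta)),
             eta = rep(x$eta, times = length(x$z)),
             psi = as.vector(x$psi))
}
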