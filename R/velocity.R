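# Double perturbation solution of the axial momentum balance ---------------
#
# The reduced momentum balance, with the pressure gradient replaced by the
# elastic-wall forcing E, is the flux balance
#
#   (1/r) d/dr [ r * M(H) * (u' + kappa We^2 u'^3) ] = F0(r),
#   F0 = E - G1 * H - G2 * xi,  M(H) = 1 - alpha H,  kappa = (n - 1)/2.
#
# Expanding u = (u300 + alpha u301) + We^2 (u310 + alpha u311) and writing
# v = u' per order, collecting powers of We^2 and alpha in the *flux* form
# gives one quadrature per order plus an affine constant:
#
#   O(1)      : r v0 = G + C0,                G(r) = int_eps^r s F0(s) ds
#   O(alpha)  : v1 = H v0 + C1 / r
#   O(We^2)   : v2 = -kappa v0^3 + C2 / r
#   O(We^2 a) : v3 = H v2 - 3 kappa v0^2 v1 + kappa H v0^3 + C3 / r
#
# Each constant is fixed by the outer-wall condition (u300 = -1 at both
# walls, corrections vanish at both walls), i.e. the total integral of
# each v over the gap must vanish, so Ck = -int(vk_particular)/log(h/eps).

.order_names <- c("u300", "u301", "u310", "u311")

#' Solve the four perturbation orders of the axial velocity
#'
#' Computes the wave-frame axial velocity as a double expansion in the
#' squared Weissenberg number and the viscosity-variation coefficient, on
#' one axial section, and assembles
#' `u3 = u300 + alpha u301 + We^2 (u310 + alpha u311)` together with the
#' lab-frame profile `w = u3 + 1`. The perturbation orders themselves
#' depend only on the geometry, the scalar fields and the power-law index;
#' `We` and `alpha` enter at assembly, so a solved object can be cheaply
#' re-assembled via [assemble_velocity()].
#'
#' @param params A [carreau_params()] object.
#' @param section An [axial_section()]; defaults to the reporting section.
#' @param grid A [radial_grid()]; built on demand if `NULL`.
#' @param temperature,concentration Optional pre-solved scalar fields on
#'   the same grid (solved on demand if `NULL`).
#' @return An object of class `velocity_solution` holding the order
#'   samples (`orders`), their radial derivatives (`derivs`), integration
#'   constants, forcing `F0`, assembled `u3` and `w`, and the inputs.
#' @export
solve_velocity <- function(params, section = NULL, grid = NULL,
                           temperature = NULL, concentration = NULL) {
  if (is.null(section)) section <- axial_section(params)
  if (is.null(grid)) grid <- radial_grid(params, section)
  if (is.null(temperature))
    temperature <- solve_temperature(params, section, grid)
  if (is.null(concentration))
    concentration <- solve_concentration(params, section, grid, temperature)

  r <- grid$r
  H <- temperature$value
  xi <- concentration$value
  kappa <- (params$n - 1) / 2
  # discrete counterpart of log(h/eps): using the quadrature of 1/r makes
  # the outer-wall condition hold to rounding, not just to O(h^4)
  lg <- .defint(grid, 1 / r)

  F0 <- section$E - params$G1 * H - params$G2 * xi
  G <- .cumint(grid, r * F0)

  fix <- function(vp) {
    C <- -.defint(grid, vp) / lg
    list(v = vp + C / r, C = C)
  }
  o0 <- fix(G / r)
  o1 <- fix(H * o0$v)
  o2 <- fix(-kappa * o0$v^3)
  o3 <- fix(H * o2$v - 3 * kappa * o0$v^2 * o1$v + kappa * H * o0$v^3)

  orders <- list(
    u300 = -1 + .cumint(grid, o0$v),
    u301 = .cumint(grid, o1$v),
    u310 = .cumint(grid, o2$v),
    u311 = .cumint(grid, o3$v)
  )

  sol <- structure(
    list(grid = grid, section = section, params = params,
         orders = orders,
         derivs = list(v0 = o0$v, v1 = o1$v, v2 = o2$v, v3 = o3$v),
         constants = c(C0 = o0$C, C1 = o1$C, C2 = o2$C, C3 = o3$C),
         F0 = F0, G = G, kappa = kappa,
         temperature = temperature, concentration = concentration,
         We = params$We, alpha = params$alpha),
    class = "velocity_solution"
  )
  assemble_velocity(sol)
}

#' Assemble the expansion at given We and alpha
#'
#' Combines the stored perturbation orders into the wave-frame velocity
#' `u3 = u300 + alpha u301 + We^2 (u310 + alpha u311)` and the lab-frame
#' profile `w = u3 + 1` (the frame shift of the travelling wave). The
#' orders are unchanged, so different `(We, alpha)` assemblies of one
#' solve are consistent with a single pair of scalar-field solves.
#'
#' @param sol A `velocity_solution` from [solve_velocity()].
#' @param We,alpha Assembly values (default: the ones in `sol`).
#' @return `sol` with updated `u3`, `w`, `We`, `alpha`.
#' @export
assemble_velocity <- function(sol, We = sol$We, alpha = sol$alpha) {
  o <- sol$orders
  sol$We <- We
  sol$alpha <- alpha
  sol$u3 <- o$u300 + alpha * o$u301 + We^2 * (o$u310 + alpha * o$u311)
  sol$w <- sol$u3 + 1
  sol$du3 <- with(sol$derivs, v0 + alpha * v1 + We^2 * (v2 + alpha * v3))
  sol
}

#' @export
print.velocity_solution <- function(x, ...) {
  n <- x$grid$n
  i <- which.max(x$w)
  cat(sprintf("Velocity solution at z - t = %g (%d nodes)\n",
              x$section$z - x$section$t, n))
  cat(sprintf("  We = %g, alpha = %g, n = %g\n", x$We, x$alpha, x$params$n))
  cat(sprintf("  wave frame u3(eps) = %.8g, u3(h) = %.8g\n",
              x$u3[1], x$u3[n]))
  cat(sprintf("  lab frame  max w = %.6g at r = %.4g\n", x$w[i], x$grid$r[i]))
  invisible(x)
}

#' @export
as.data.frame.velocity_solution <- function(x, ...) {
  data.frame(r = x$grid$r,
             u300 = x$orders$u300, u301 = x$orders$u301,
             u310 = x$orders$u310, u311 = x$orders$u311,
             u3 = x$u3, w = x$w)
}

#' @export
plot.velocity_solution <- function(x, frame = c("lab", "wave"), ...) {
  frame <- match.arg(frame)
  y <- if (frame == "lab") x$w else x$u3
  graphics::plot(x$grid$r, y, type = "l", xlab = "r",
                 ylab = if (frame == "lab") "w(r)" else "u3(r)", ...)
  invisible(x)
}
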