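# Radial grid and high-order cumulative quadrature -------------------------
#
# Every radial solve in the package reduces to repeated cumulative
# integration of smooth integrands sampled on a common grid, so the grid
# object pre-computes, once, fourth-order cumulative quadrature weights:
# over each cell the integrand is replaced by the cubic Lagrange
# interpolant through the four nearest nodes (one-sided at the ends).
# The rule is exact for cubics and O(h^4) globally on smooth data, on
# arbitrary strictly increasing nodes.

#' Radial sample grid on the annular gap
#'
#' Builds the shared radial grid on `[eps, h]` for one axial section, with
#' cumulative-integration weights attached. Endpoints are exactly the
#' catheter surface and the local outer wall.
#'
#' @param params A [carreau_params()] object.
#' @param section An [axial_section()]; defaults to the reporting section.
#' @param n Number of nodes (default 257; at least 8).
#' @param r Optional explicit strictly increasing node vector spanning
#'   `[eps, h]`; overrides `n`.
#' @return An object of class `radial_grid` with elements `r` and `n`.
#' @export
radial_grid <- function(params, section = NULL, n = 257, r = NULL) {
  if (is.null(section)) section <- axial_section(params)
  if (is.null(r)) {
    stopifnot(n >= 8)
    r <- seq(params$eps, section$h, length.out = n)
  } else {
    if (any(diff(r) <= 0)) stop("grid nodes must be strictly increasing")
    if (abs(r[1] - params$eps) > 1e-12 || abs(r[length(r)] - section$h) > 1e-12)
      stop("grid endpoints must be eps and h")
    if (length(r) < 8) stop("grid needs at least 8 nodes")
  }
  structure(
    list(r = r, n = length(r), quad = .cum_weights(r)),
    class = "radial_grid"
  )
}

# Pre-compute the per-cell 4-point weights.  Cell i spans [r[i], r[i+1]];
# its stencil starts at s[i] = clamp(i - 1, 1, n - 3).
.cum_weights <- function(x) {
  n <- length(x)
  s <- pmin(pmax(seq_len(n - 1L) - 1L, 1L), n - 3L)
  W <- matrix(0, n - 1L, 4L)
  for (i in seq_len(n - 1L)) {
    xs <- x[s[i] + 0:3] - x[i]            # local coordinates for conditioning
    d <- x[i + 1L] - x[i]
    V <- outer(xs, 0:3, `^`)              # V[m, j+1] = xs_m^j
    mom <- d^(1:4) / (1:4)                # integrals of u^j over [0, d]
    W[i, ] <- solve(t(V), mom)
  }
  list(W = W, s = s)
}

# Cumulative integral of samples y over the grid: F[1] = 0,
# F[i+1] = integral from r[1] to r[i+1].
.cumint <- function(grid, y) {
  q <- grid$quad
  idx <- q$s
  cell <- q$W[, 1L] * y[idx] + q$W[, 2L] * y[idx + 1L] +
    q$W[, 3L] * y[idx + 2L] + q$W[, 4L] * y[idx + 3L]
  c(0, cumsum(cell))
}

# Definite integral over the whole grid.
.defint <- function(grid, y) {
  f <- .cumint(grid, y)
  f[length(f)]
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("Radial grid: %d nodes on [%.6g, %.6g]\n",
              x$n, x$r[1], x$r[x$n]))
  invisible(x)
}
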