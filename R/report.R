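# Reporting front end: profiles, sweeps, streamline maps, verification -----

.param_header <- function(params, section = NULL) {
  s <- paste(sprintf("%s=%g", .param_fields, unlist(params[.param_fields])),
             collapse = " ")
  if (!is.null(section))
    s <- paste0(s, sprintf(" z=%g t=%g", section$z, section$t))
  paste0("# ", s)
}

.write_csv_commented <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(outdir, command, params, files, extra = list()) {
  manifest <- c(list(command = command,
                     parameters = params[.param_fields],
                     package_version = as.character(utils::packageVersion("pericarreau")),
                     outputs = basename(files)),
                extra)
  path <- file.path(outdir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Single-section profile report
#'
#' Solves the scalar fields and the velocity expansion at one axial
#' station and writes two CSV files (scalar fields; velocity orders and
#' assembled profiles in both frames), each headed by a comment line with
#' the full parameter set and the station. Prints the wall values and the
#' location of the lab-frame maximum.
#'
#' @param params A [carreau_params()] object.
#' @param z,t Axial station (defaults: the reporting section `z - t = 0.5`).
#' @param outdir Output directory (created if needed).
#' @param grid_n Radial grid size.
#' @param quiet Suppress the printed summary.
#' @return (Invisibly) a list with the solution objects and file paths.
#' @export
run_profile <- function(params, z = 0.5, t = 0, outdir = ".",
                        grid_n = 257, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sec <- axial_section(params, z, t)
  grid <- radial_grid(params, sec, n = grid_n)
  temp <- solve_temperature(params, sec, grid)
  conc <- solve_concentration(params, sec, grid, temp)
  vel <- solve_velocity(params, sec, grid, temp, conc)

  hdr <- .param_header(params, sec)
  f1 <- file.path(outdir, "scalar_fields.csv")
  .write_csv_commented(
    data.frame(r = grid$r, H = temp$value, dH_dr = temp$d1,
               xi = conc$value, dxi_dr = conc$d1),
    f1, hdr)
  f2 <- file.path(outdir, "velocity.csv")
  .write_csv_commented(as.data.frame(vel), f2, hdr)
  mf <- .write_manifest(outdir, "profile", params, c(f1, f2),
                        list(section = list(z = z, t = t), grid_n = grid_n))

  if (!quiet) {
    i <- which.max(vel$w)
    cat(sprintf("lab-frame w: wall values %.3e (r = eps), %.3e (r = h); max %.6g at r = %.4g\n",
                vel$w[1], vel$w[grid$n], vel$w[i], grid$r[i]))
    cat(sprintf("wave-frame u3 wall values: %.8g, %.8g\n",
                vel$u3[1], vel$u3[grid$n]))
  }
  invisible(list(section = sec, temperature = temp, concentration = conc,
                 velocity = vel, files = c(f1, f2, mf)))
}

#' Parameter sweep of a radial response
#'
#' Re-solves the model for each value of one parameter and returns the
#' family of profiles in long format (`param`, `value`, `r`, `response`),
#' plus a one-line monotone-trend summary of the mid-gap response.
#'
#' @param params Baseline [carreau_params()] object.
#' @param name Parameter field to sweep.
#' @param values At least two values.
#' @param response `"w"` (lab frame), `"u3"` (wave frame), `"H"` or `"xi"`.
#' @param z,t Axial station (default `z - t = 0.375`, where every wall
#'   coefficient acts on the forcing).
#' @param grid_n Radial grid size.
#' @param outdir Optional output directory; if given, writes `sweep_<name>.csv`.
#' @return A data frame (long format) with attributes `midgap` (response
#'   at mid-gap per value) and `trend` (`"increasing"`, `"decreasing"` or
#'   `"non-monotone"`).
#' @export
run_sweep <- function(params, name, values, response = c("w", "u3", "H", "xi"),
                      z = 0.375, t = 0, grid_n = 257, outdir = NULL) {
  response <- match.arg(response)
  if (!name %in% .param_fields)
    stop("not a model parameter: ", name)
  if (length(values) < 2)
    stop("a sweep needs at least two parameter values")

  rows <- vector("list", length(values))
  midgap <- numeric(length(values))
  for (i in seq_along(values)) {
    p <- params
    p[[name]] <- values[i]
    p <- validate_params(unclass(p))
    sec <- axial_section(p, z, t)
    grid <- radial_grid(p, sec, n = grid_n)
    y <- switch(response,
      w = solve_velocity(p, sec, grid)$w,
      u3 = solve_velocity(p, sec, grid)$u3,
      H = solve_temperature(p, sec, grid)$value,
      xi = solve_concentration(p, sec, grid)$value)
    rows[[i]] <- data.frame(param = name, value = values[i],
                            r = grid$r, response = y)
    midgap[i] <- stats::approx(grid$r, y, xout = (p$eps + sec$h) / 2)$y
  }
  out <- do.call(rbind, rows)
  d <- diff(midgap[order(values)])
  trend <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
           else "non-monotone"
  attr(out, "midgap") <- midgap
  attr(out, "trend") <- trend
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(outdir, paste0("sweep_", name, ".csv"))
    .write_csv_commented(out, f, .param_header(params))
    .write_manifest(outdir, paste0("sweep_", name), params, f,
                    list(values = values, response = response,
                         trend = trend))
  }
  out
}

#' Streamline map and bolus summary
#'
#' Computes the wave-frame stream function over one wavelength, extracts
#' closed streamlines, and (optionally) writes the field in long format,
#' the closed-contour polylines, and a bolus summary.
#'
#' @param params A [carreau_params()] object.
#' @param t Snapshot time.
#' @param nz,nr Mesh size (axial stations x radial nodes).
#' @param n_levels Contour levels.
#' @param outdir Optional output directory.
#' @return (Invisibly) list with the `stream_field`, the `bolus_set` and
#'   any file paths.
#' @export
run_streamlines <- function(params, t = 0, nz = 65, nr = 129,
                            n_levels = 21, outdir = NULL) {
  sf <- stream_function(params, t = t, nz = nz, nr = nr)
  bs <- extract_boluses(sf, n_levels = n_levels)
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .param_header(params)
    f1 <- file.path(outdir, "psi.csv")
    .write_csv_commented(as.data.frame(sf)[, c("r", "z", "psi")], f1, hdr)
    f2 <- file.path(outdir, "contours.csv")
    cdf <- if (bs$n_closed > 0) {
      do.call(rbind, bs$contours)[, c("contour_id", "r", "z")]
    } else {
      data.frame(contour_id = integer(0), r = numeric(0), z = numeric(0))
    }
    .write_csv_commented(cdf, f2, hdr)
    files <- c(f1, f2,
               .write_manifest(outdir, "streamlines", params, c(f1, f2),
                               list(t = t, nz = nz, nr = nr,
                                    n_closed = bs$n_closed,
                                    total_area = bs$total_area)))
  }
  invisible(list(stream = sf, boluses = bs, files = files))
}

#' Run the model's invariant suite
#'
#' Checks, with measured values: exact boundary conditions at the walls
#' for the scalar fields and every velocity order; the analytic limits
#' (log-profile temperature at `Omega = 0`, decoupled concentration at
#' `S1 = 0`, vanishing Weissenberg-order content at `n = 1`); the
#' periodicity and closed form of the wall forcing against a sixth-order
#' finite-difference application of the operator; the interior residuals
#' of both scalar-field equations; quadrature self-convergence; and the
#' gap to the nonlinear reference solver at small `We` and `alpha`.
#'
#' @param params A [carreau_params()] object.
#' @param grid_n Radial grid size (smaller grids degrade the quadrature
#'   properties gracefully; they are reported, not hidden).
#' @param quiet Suppress printing.
#' @return A data frame (`property`, `value`, `threshold`, `pass`);
#'   attribute `all_pass`.
#' @export
run_verify <- function(params = carreau_params(), grid_n = 257,
                       quiet = FALSE) {
  res <- list()
  add <- function(property, value, threshold) {
    res[[length(res) + 1L]] <<- data.frame(
      property = property, value = value, threshold = threshold,
      pass = is.finite(value) && value <= threshold)
  }

  sec <- axial_section(params)
  grid <- radial_grid(params, sec, n = grid_n)
  temp <- solve_temperature(params, sec, grid)
  conc <- solve_concentration(params, sec, grid, temp)
  vel <- solve_velocity(params, sec, grid, temp, conc)
  r <- grid$r
  nn <- grid$n

  add("temperature wall values", max(abs(temp$value[1]), abs(temp$value[nn] - 1)), 1e-12)
  add("concentration wall values", max(abs(conc$value[1] - 1), abs(conc$value[nn])), 1e-12)
  add("temperature interior residual",
      max(abs(temp$beta * (temp$d2 + temp$d1 / r) - params$Omega * temp$value)), 1e-8)
  add("concentration interior residual",
      max(abs((conc$d2 + conc$d1 / r) / params$S2 +
                params$S1 * (temp$d2 + temp$d1 / r))), 1e-8)
  add("wave-frame no-slip (u3 = -1 at both walls)",
      max(abs(vel$u3[1] + 1), abs(vel$u3[nn] + 1)), 1e-8)
  add("correction orders vanish at walls",
      max(abs(unlist(lapply(vel$orders[c("u301", "u310", "u311")],
                            function(u) u[c(1, nn)])))), 1e-8)

  # wall forcing: closed form vs finite differences, and periodicity
  fd <- .wall_forcing_fd(0.3, 0.1, params)
  cf <- wall_forcing(0.3, 0.1, params)
  add("wall forcing closed form vs finite differences",
      abs(cf - fd) / max(abs(fd), 1e-30), 1e-6)
  zs <- seq(0, 0.9, by = 0.1)
  add("wall forcing periodicity",
      max(abs(wall_forcing(zs + 1, 0, params) - wall_forcing(zs, 0, params))),
      1e-8)

  # analytic limits
  p0 <- params; p0$Omega <- 0; p0 <- validate_params(unclass(p0))
  t0 <- solve_temperature(p0, sec, grid)
  add("Omega = 0 temperature equals log profile",
      max(abs(t0$value - log(r / params$eps) / log(sec$h / params$eps))), 1e-12)
  p1 <- params; p1$n <- 1; p1 <- validate_params(unclass(p1))
  v1 <- solve_velocity(p1, sec, grid)
  add("n = 1 kills Weissenberg-order content",
      max(abs(v1$orders$u310), abs(v1$orders$u311)), 1e-12)

  # quadrature self-convergence (Richardson) at the crest, where the
  # forcing is moderate and the tolerance is meaningful in absolute terms
  crest0 <- axial_section(params, z = 0.25, t = 0)
  cg1 <- radial_grid(params, crest0, n = grid_n)
  cg2 <- radial_grid(params, crest0, n = 2 * grid_n - 1)
  velc <- solve_velocity(params, crest0, cg1)
  velc2 <- solve_velocity(params, crest0, cg2)
  add("quadrature self-convergence of u3 (crest)",
      max(abs(velc2$u3[seq(1, cg2$n, by = 2)] - velc$u3)), 1e-7)

  # oracle agreement at small We, alpha (crest section: moderate forcing)
  ps <- params; ps$We <- 0.05; ps$alpha <- 0.02
  ps <- validate_params(unclass(ps))
  crest <- axial_section(ps, z = 0.25, t = 0)
  cg <- radial_grid(ps, crest, n = grid_n)
  pert <- solve_velocity(ps, crest, cg)
  orac <- solve_nonlinear(ps, crest, cg, pert$temperature, pert$concentration)
  add("perturbation vs nonlinear reference (We = 0.05, alpha = 0.02)",
      max(abs(pert$u3 - orac$u)), 1e-3)

  out <- do.call(rbind, res)
  attr(out, "all_pass") <- all(out$pass)
  if (!quiet) {
    for (i in seq_len(nrow(out)))
      cat(sprintf("[%s] %-55s %.3e (<= %.0e)\n",
                  if (out$pass[i]) "PASS" else "FAIL",
                  out$property[i], out$value[i], out$threshold[i]))
  }
  invisible(out)
}

# Sixth-order central finite-difference application of the wall operator
# to r2(z, t); test oracle for the closed-form forcing.
.wall_forcing_fd <- function(z, t, params, h = 0.01) {
  r2 <- function(z, t) outer_radius(z, t, params)
  d1 <- function(f, x, ...) {   # 6th-order first derivative
    (-f(x - 3 * h, ...) + 9 * f(x - 2 * h, ...) - 45 * f(x - h, ...) +
       45 * f(x + h, ...) - 9 * f(x + 2 * h, ...) + f(x + 3 * h, ...)) / (60 * h)
  }
  dz <- function(f) function(z, t) d1(function(x, tt) f(x, tt), z, t)
  dt <- function(f) function(z, t) d1(function(x, zz) f(zz, x), t, z)
  f_z <- dz(r2)
  f_3z <- dz(dz(dz(r2)))
  f_5z <- dz(dz(dz(dz(dz(r2)))))
  f_z2t <- dt(dt(dz(r2)))
  f_zt <- dt(dz(r2))
  params$e1 * f_5z(z, t) - params$e2 * f_3z(z, t) +
    params$e3 * f_z2t(z, t) + params$e4 * f_zt(z, t) +
    params$e5 * f_z(z, t)
}
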