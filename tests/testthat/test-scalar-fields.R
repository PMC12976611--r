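# Finite-difference two-point BVP oracle for the temperature equation:
# second-order central differences on a fine uniform mesh, tridiagonal
# solve.  Independent of the package's closed Bessel form.
fd_temperature <- function(params, h_outer, n_cells) {
  eps <- params$eps
  beta <- 1 / params$Pr + 4 / (3 * params$Rn)
  r <- seq(eps, h_outer, length.out = n_cells + 1)
  dh <- r[2] - r[1]
  i <- 2:n_cells
  lower <- beta * (1 / dh^2 - 1 / (2 * dh * r[i]))
  diagm <- -2 * beta / dh^2 - params$Omega
  upper <- beta * (1 / dh^2 + 1 / (2 * dh * r[i]))
  A <- Matrix::bandSparse(n_cells - 1, n_cells - 1, k = -1:1,
                          diagonals = list(lower[-1], rep(diagm, n_cells - 1),
                                           upper[-(n_cells - 1)]))
  rhs <- rep(0, n_cells - 1)
  rhs[n_cells - 1] <- -upper[n_cells - 1] * 1   # H(h) = 1
  H <- as.numeric(Matrix::solve(A, rhs))
  c(0, H, 1)
}

test_that("temperature satisfies its boundary conditions and maximum principle", {
  set.seed(11)
  for (p in c(list(carreau_preset("default")), random_params(8))) {
    sec <- axial_section(p, 0.31, 0.07)
    H <- solve_temperature(p, sec)
    nn <- H$grid$n
    expect_equal(H$value[1], 0)
    expect_equal(H$value[nn], 1)
    expect_true(all(H$value >= -1e-12 & H$value <= 1 + 1e-12))
    expect_true(all(diff(H$value) > 0))  # strictly increasing for Omega >= 0
  }
})

test_that("temperature closed form matches a numerical two-point BVP solve", {
  skip_if_not_installed("Matrix")
  p <- carreau_preset("default")
  sec <- axial_section(p, 0.25, 0)        # crest
  grid <- radial_grid(p, sec, n = 257)
  H <- solve_temperature(p, sec, grid)
  # two FD resolutions whose nodes contain the grid nodes; Richardson
  # extrapolation lifts the second-order oracle to fourth order (the
  # resolutions are kept in the truncation-dominated regime: far finer
  # meshes only accumulate tridiagonal-solve roundoff)
  coarse <- fd_temperature(p, sec$h, 256 * 12)[seq(1, 256 * 12 + 1, by = 12)]
  fine <- fd_temperature(p, sec$h, 256 * 24)[seq(1, 256 * 24 + 1, by = 24)]
  oracle <- (4 * fine - coarse) / 3
  expect_lt(max(abs(H$value - oracle)), 1e-8)
})

test_that("temperature residual and log-profile limits hold", {
  p <- carreau_preset("default")
  sec <- axial_section(p)
  H <- solve_temperature(p, sec)
  r <- H$grid$r
  expect_lt(max(abs(H$beta * (H$d2 + H$d1 / r) - p$Omega * H$value)), 1e-8)

  # Omega = 0: exact log profile, including the midpoint identity
  p0 <- tweak(p, Omega = 0)
  H0 <- solve_temperature(p0, sec)
  expect_equal(H0$value, log(r / p$eps) / log(sec$h / p$eps), tolerance = 1e-13)
  sec1 <- axial_section(tweak(p0, phi = 0), 0, 0)   # h = 1
  g1 <- radial_grid(p0, sec1, r = c(0.2, seq(0.21, 0.4, by = 0.01),
                                    sqrt(0.2), seq(0.5, 0.9, by = 0.1), 1))
  H1 <- solve_temperature(tweak(p0, phi = 0), sec1, g1)
  expect_equal(H1$value[g1$r == sqrt(0.2)], 0.5, tolerance = 1e-12)

  # continuity: Omega -> 0+ converges to the log profile
  Hs <- solve_temperature(tweak(p, Omega = 1e-8), sec)
  expect_lt(max(abs(Hs$value - H0$value)), 1e-5)
})

test_that("concentration satisfies BCs, decouples at S1 = 0, and is Soret-shifted harmonic", {
  p <- carreau_preset("default")
  sec <- axial_section(p)
  grid <- radial_grid(p, sec)
  H <- solve_temperature(p, sec, grid)
  xi <- solve_concentration(p, sec, grid, H)
  r <- grid$r
  nn <- grid$n
  expect_equal(xi$value[1], 1)
  expect_equal(xi$value[nn], 0, tolerance = 1e-14)

  # interior residual of the coupled mass balance
  expect_lt(max(abs((xi$d2 + xi$d1 / r) / p$S2 + p$S1 * (H$d2 + H$d1 / r))), 1e-8)

  # xi + S1 S2 H is radially harmonic
  comb_d1 <- xi$d1 + p$S1 * p$S2 * H$d1
  comb_d2 <- xi$d2 + p$S1 * p$S2 * H$d2
  expect_lt(max(abs(comb_d2 + comb_d1 / r)), 1e-8)

  # S1 = 0: pure diffusion, complementary log profile
  p0 <- tweak(p, S1 = 0)
  xi0 <- solve_concentration(p0, sec, grid, solve_temperature(p0, sec, grid))
  expect_equal(xi0$value, 1 - log(r / p$eps) / log(sec$h / p$eps),
               tolerance = 1e-13)

  # grid mismatch is a contract error
  other <- radial_grid(p, sec, n = 129)
  expect_error(solve_concentration(p, sec, other, H), "different grid")
})

test_that("scalar-field trends have the documented signs", {
  p <- carreau_preset("default")
  at_mid <- function(p, what) {
    sec <- axial_section(p, 0.25, 0)
    g <- radial_grid(p, sec)
    s <- if (what == "H") solve_temperature(p, sec, g)
         else solve_concentration(p, sec, g)
    approx(g$r, s$value, xout = 0.6)$y
  }
  bump <- function(nm) {
    validate_params(modifyList(unclass(p),
                               setNames(list(unclass(p)[[nm]] * 1.3), nm)))
  }
  base_H <- at_mid(p, "H")
  for (nm in c("Pr", "eps", "Omega", "Rn"))
    expect_lt(at_mid(bump(nm), "H"), base_H,
              label = paste("H with", nm, "increased"))
  base_xi <- at_mid(p, "xi")
  for (nm in c("S1", "S2", "Rn", "Omega"))
    expect_gt(at_mid(bump(nm), "xi"), base_xi,
              label = paste("xi with", nm, "increased"))
})
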