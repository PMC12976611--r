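test_that("the reference preset is accepted and carries the documented values", {
  p <- carreau_preset("default")
  expect_s3_class(p, "carreau_params")
  expect_identical(
    unlist(p[c("e1", "e2", "e3", "e4", "e5")]),
    c(e1 = 0.3, e2 = 0.7, e3 = 0.5, e4 = 0.5, e5 = 0.2))
  expect_identical(
    unlist(p[c("Omega", "G1", "G2", "S1", "S2", "Rn", "Pr")]),
    c(Omega = 0.5, G1 = 2, G2 = 1, S1 = 0.7, S2 = 0.3, Rn = 0.5, Pr = 1.7))
  expect_identical(
    unlist(p[c("eps", "phi", "We", "alpha", "n")]),
    c(eps = 0.2, phi = 0.15, We = 0.2, alpha = 0.1, n = 0.3))
})

test_that("invariant violations are rejected with the offending field named", {
  base <- unclass(carreau_preset("default"))
  expect_error(validate_params(modifyList(base, list(eps = 0.9))), "eps")
  expect_error(validate_params(modifyList(base, list(Pr = 0))), "Pr")
  expect_error(validate_params(modifyList(base, list(Omega = -0.1))), "Omega")
  expect_error(validate_params(modifyList(base, list(alpha = 1.2))), "alpha")
  expect_error(validate_params(modifyList(base, list(S2 = 0))), "S2")
  expect_error(validate_params(c(base, list(bogus = 1))), "unknown")
  expect_error(validate_params(base[-1]), "missing")
})

test_that("config files round-trip, merge overrides, and reject unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("We: 0.05", "alpha: 0.0"), cfg)
  p <- read_params_config(cfg)
  expect_equal(p$We, 0.05)
  expect_equal(p$alpha, 0)
  expect_equal(p$Pr, 1.7)  # filled from the reference preset
  p2 <- read_params_config(cfg, overrides = list(We = 0.1))
  expect_equal(p2$We, 0.1)  # flags beat the file

  cfgj <- tempfile(fileext = ".json")
  writeLines('{"Pr": 2.0}', cfgj)
  expect_equal(read_params_config(cfgj)$Pr, 2)

  bad <- tempfile(fileext = ".yaml")
  writeLines("bogus: 3", bad)
  expect_error(read_params_config(bad), "unknown")
})

test_that("outer radius follows the travelling sine wave", {
  p <- carreau_preset("default")
  expect_equal(outer_radius(0.25, 0, p), 1.15)
  expect_equal(outer_radius(0, 0, p), 1)
  expect_equal(outer_radius(1.7, 1.7, p), 1)
  flat <- tweak(p, phi = 0)
  expect_equal(outer_radius(runif(5), runif(5), flat), rep(1, 5))
  # range and periodicity
  z <- seq(0, 1, by = 0.05)
  h <- outer_radius(z, 0.3, p)
  expect_true(all(h >= 1 - p$phi - 1e-12 & h <= 1 + p$phi + 1e-12))
  expect_equal(outer_radius(z + 1, 0.3, p), h)
})

test_that("wall forcing vanishes for a flat wall or a null operator", {
  p <- carreau_preset("default")
  flat <- tweak(p, phi = 0)
  expect_equal(wall_forcing(runif(5), runif(5), flat), rep(0, 5))
  null_op <- tweak(p, e1 = 0, e2 = 0, e3 = 0, e4 = 0, e5 = 0)
  expect_equal(wall_forcing(runif(5), runif(5), null_op), rep(0, 5))
})

test_that("closed-form wall forcing matches finite-difference operator application", {
  set.seed(41)
  draws <- c(list(carreau_preset("default")), random_params(10))
  for (p in draws) {
    amp <- p$phi * ((2 * pi)^5 * abs(p$e1) + (2 * pi)^3 * (abs(p$e2) + abs(p$e3)) +
                      (2 * pi)^2 * abs(p$e4) + 2 * pi * abs(p$e5))
    for (zt in list(c(0.13, 0), c(0.41, 0.2), c(0.77, 0.5))) {
      cf <- wall_forcing(zt[1], zt[2], p)
      fd <- pericarreau:::.wall_forcing_fd(zt[1], zt[2], p)
      expect_lt(abs(cf - fd), 1e-6 * max(amp, 1))
    }
  }
})

test_that("wall forcing is a travelling wave: periodic and a function of z - t only", {
  p <- carreau_preset("default")
  z <- seq(0, 0.95, by = 0.05)
  expect_equal(wall_forcing(z + 1, 0.2, p), wall_forcing(z, 0.2, p))
  expect_equal(wall_forcing(z, 1.2, p), wall_forcing(z, 0.2, p))
  expect_equal(wall_forcing(z, 0.37, p), wall_forcing(z - 0.37, 0, p))
})
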