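test_that("unforced annulus gives the rigid-body wave-frame solution at all orders", {
  p <- tweak(carreau_preset("default"), phi = 0, G1 = 0, G2 = 0)
  sol <- solve_velocity(p, axial_section(p, 0.3, 0.1))
  expect_lt(max(abs(sol$u3 + 1)), 1e-12)
  expect_lt(max(abs(sol$orders$u300 + 1)), 1e-12)
  for (o in c("u301", "u310", "u311"))
    expect_lt(max(abs(sol$orders[[o]])), 1e-12)
})

test_that("wall no-slip holds for random valid parameter draws", {
  set.seed(23)
  for (p in random_params(20, moderate_wall = FALSE)) {
    sec <- axial_section(p, runif(1), runif(1))
    sol <- solve_velocity(p, sec)
    nn <- sol$grid$n
    expect_lt(abs(sol$u3[1] + 1), 1e-8)
    expect_lt(abs(sol$u3[nn] + 1), 1e-8)
    expect_lt(abs(sol$w[1]), 1e-8)
    expect_lt(abs(sol$w[nn]), 1e-8)
    for (o in c("u301", "u310", "u311"))
      expect_lt(max(abs(sol$orders[[o]][c(1, nn)])),
                1e-8 * max(1, max(abs(sol$orders[[o]]))))
  }
})

test_that("Newtonian index or zero Weissenberg number kills the We^2 content", {
  p1 <- tweak(carreau_preset("default"), n = 1)
  s1 <- solve_velocity(p1)
  expect_lt(max(abs(s1$orders$u310)), 1e-12)
  expect_lt(max(abs(s1$orders$u311)), 1e-12)

  p2 <- tweak(carreau_preset("default"), We = 0)
  s2 <- solve_velocity(p2)
  expect_equal(s2$u3, s2$orders$u300 + p2$alpha * s2$orders$u301)

  # alpha = 0 removes the alpha-order contribution from the assembly
  s3 <- assemble_velocity(s2, We = 0, alpha = 0)
  expect_equal(s3$u3, s3$orders$u300)
})

test_that("re-assembly at different We and alpha is consistent and cheap", {
  p <- carreau_preset("default")
  sol <- solve_velocity(p)
  re <- assemble_velocity(sol, We = 0.1, alpha = 0.05)
  o <- sol$orders
  expect_equal(re$u3, o$u300 + 0.05 * o$u301 + 0.01 * (o$u310 + 0.05 * o$u311))
  direct <- solve_velocity(tweak(p, We = 0.1, alpha = 0.05))
  expect_equal(re$u3, direct$u3, tolerance = 1e-12)
})

test_that("assembled flux satisfies the momentum balance to the truncation order", {
  # flux residual: deviation of r*M*(v + kappa We^2 v^3) - G from a constant
  # must shrink like O(We^4 + alpha^2) under parameter halving
  p <- carreau_preset("default")
  sec <- axial_section(p, 0.25, 0)
  flux_dev <- function(We, alpha) {
    pp <- tweak(p, We = We, alpha = alpha)
    s <- solve_velocity(pp, sec)
    M <- 1 - alpha * s$temperature$value
    v <- s$du3
    flux <- s$grid$r * M * (v + s$kappa * We^2 * v^3) - s$G
    diff(range(flux))
  }
  d1 <- flux_dev(0.2, 0.1)
  d2 <- flux_dev(0.1, 0.05)
  expect_lt(d2, d1 / 3.5)  # dominated by the O(alpha^2) term: factor ~4
})

test_that("the reporting-section profile is single-peaked with near-wall zeros", {
  p <- carreau_preset("default")
  sol <- solve_velocity(p, axial_section(p, 0.5, 0))
  w <- sol$w
  i <- which.max(w)
  expect_gt(i, 1)
  expect_lt(i, sol$grid$n)
  expect_true(all(diff(w[1:i]) > 0))
  expect_true(all(diff(w[i:sol$grid$n]) < 0))
  # downward concavity in a neighbourhood of the peak
  around <- max(1, i - 20):min(sol$grid$n, i + 20)
  expect_true(all(diff(w[around], differences = 2) < 0))
})

test_that("velocity CSV export has the documented schema", {
  p <- carreau_preset("default")
  out <- run_profile(p, outdir = tempdir(), quiet = TRUE)
  vel <- read.csv(file.path(tempdir(), "velocity.csv"), comment.char = "#")
  expect_named(vel, c("r", "u300", "u301", "u310", "u311", "u3", "w"))
  sca <- read.csv(file.path(tempdir(), "scalar_fields.csv"), comment.char = "#")
  expect_named(sca, c("r", "H", "dH_dr", "xi", "dxi_dr"))
})
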