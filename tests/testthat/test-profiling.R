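# Bundle resampling, core trajectory, outlier cleaning, and weighted
# profile quantification.

test_that("resampling places nodes equidistantly along a straight fiber", {
  fiber <- rbind(c(0, 0, 0), c(99, 0, 0))
  r <- resample_fiber(fiber, 100)
  expect_equal(r$points[, 1], 0:99)
  expect_equal(r$points[, 2], rep(0, 100))
})

test_that("resampling an equidistant fiber is idempotent", {
  cl <- straight_centerline(50, 40)
  theta <- seq(0, pi, length.out = 100)
  curved <- cbind(cos(theta), sin(theta), theta / 5) * 10
  r1 <- resample_fiber(curved, 100)
  r2 <- resample_fiber(r1$points, 100)
  expect_lt(max(abs(r1$points - r2$points)), 1e-9)
  expect_error(resample_fiber(rbind(c(1, 1, 1), c(1, 1, 1)), 10),
               "zero-length")
})

test_that("a linear scalar field stays linear through spline resampling", {
  fiber <- straight_centerline(90, 31)
  vals <- 2 + 0.5 * fiber[, 1] # linear in arc length
  r <- resample_fiber(fiber, 100, values = vals)
  expect_equal(r$values, 2 + 0.5 * r$points[, 1], tolerance = 1e-8)
})

test_that("core trajectory is the pointwise mean with pointwise spread", {
  f <- straight_centerline(80, 30)
  # identical fibers: core equals the fiber, spread zero
  b <- streamline_bundle(list(f, f, f), rep(list(rep(1, 30)), 3))
  core <- core_trajectory(b, 50)
  expect_equal(core$node_positions, resample_fiber(f, 50)$points)
  expect_equal(max(abs(core$node_spread)), 0)
  # two parallel fibers offset by +/-1: core is the midline
  up <- f; up[, 2] <- 1
  dn <- f; dn[, 2] <- -1
  b2 <- streamline_bundle(list(up, dn), rep(list(rep(1, 30)), 2))
  core2 <- core_trajectory(b2, 50)
  expect_equal(core2$node_positions[, 2], rep(0, 50))
  expect_error(core_trajectory(streamline_bundle(list(f), list(rep(1, 30)))),
               ">= 2 fibers")
})

test_that("core of a dispersed bundle tracks the generating centerline", {
  cl <- straight_centerline(100, 60)
  b <- generate_bundle(200, cl, dispersion_sd = 2, seed = 42)
  core <- core_trajectory(b, 50)
  se <- 2 / sqrt(200)
  ref <- resample_fiber(cl, 50)$points
  # offsets average out: core within 3 SE of the centerline (y/z axes)
  expect_lt(max(abs(core$node_positions[, 2:3] - ref[, 2:3])), 3.5 * se)
})

test_that("cleaning removes nothing from a homogeneous bundle", {
  b <- generate_bundle(100, straight_centerline(100, 40), dispersion_sd = 1.5,
                       seed = 7)
  cleaned <- clean_bundle(b)
  expect_equal(n_fibers(cleaned), 100)
  expect_length(attr(cleaned, "removed"), 0)
})

test_that("cleaning removes exactly the injected over-length fibers", {
  b <- generate_bundle(100, straight_centerline(100, 40), dispersion_sd = 1.5,
                       outlier_spec = list(n_long = 3, n_far = 0), seed = 8)
  cleaned <- clean_bundle(b)
  expect_setequal(attr(cleaned, "removed"), attr(b, "injected")$long)
})

test_that("cleaning removes exactly the injected far-displaced fibers", {
  b <- generate_bundle(100, straight_centerline(100, 40), dispersion_sd = 1.5,
                       outlier_spec = list(n_long = 0, n_far = 2), seed = 9)
  cleaned <- clean_bundle(b)
  expect_setequal(attr(cleaned, "removed"), attr(b, "injected")$far)
})

test_that("cleaning is idempotent once converged", {
  b <- generate_bundle(80, straight_centerline(100, 40), dispersion_sd = 1.5,
                       outlier_spec = list(n_long = 2, n_far = 2), seed = 10)
  c1 <- clean_bundle(b)
  c2 <- clean_bundle(c1)
  expect_equal(n_fibers(c2), n_fibers(c1))
  expect_length(attr(c2, "removed"), 0)
})

test_that("a constant field profiles to a constant", {
  b <- generate_bundle(40, straight_centerline(100, 40), dispersion_sd = 2,
                       field = function(s) rep(0.37, length(s)), seed = 11)
  pr <- profile_bundle(b, "sub-001", "FA")
  expect_equal(pr$values, rep(0.37, 100), tolerance = 1e-12)
})

test_that("weights average equidistant fibers and favor the core", {
  f <- straight_centerline(80, 30)
  up <- f; up[, 2] <- 1
  dn <- f; dn[, 2] <- -1
  # two fibers equidistant from the core with values a and b -> (a+b)/2
  b2 <- streamline_bundle(list(up, dn),
                          list(rep(0.2, 30), rep(0.6, 30)), "left_ilf")
  pr <- profile_bundle(b2, "s", "FA")
  expect_equal(pr$values, rep(0.4, 100), tolerance = 1e-10)
  # fiber on the core with value a plus a far fiber with value b:
  # profile strictly between midpoint and a, closer to a
  far <- f; far[, 2] <- 6
  b3 <- streamline_bundle(list(f, up, dn, far),
                          list(rep(0.5, 30), rep(0.5, 30), rep(0.5, 30),
                               rep(0.9, 30)), "left_ilf")
  pr3 <- profile_bundle(b3, "s", "FA")
  expect_true(all(pr3$values > 0.5 & pr3$values < 0.7))
})

test_that("profile values are convex combinations of fiber values", {
  b <- generate_bundle(30, straight_centerline(100, 40), dispersion_sd = 2,
                       field = function(s) 0.3 + 0.4 * s, seed = 12)
  pr <- profile_bundle(b, "s", "FA")
  rs <- tractclass:::resampled_node_array(b, 100)
  expect_true(all(pr$values >= apply(rs$values, 2, min) - 1e-12))
  expect_true(all(pr$values <= apply(rs$values, 2, max) + 1e-12))
})

test_that("bundles round-trip through the JSON-lines format", {
  b <- generate_bundle(5, straight_centerline(50, 10), dispersion_sd = 1,
                       field = function(s) s, seed = 13, tract_id = "left_slf")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_bundle(b, path)
  b2 <- read_bundle(path)
  expect_equal(b2$tract_id, "left_slf")
  expect_equal(b2$fibers, b$fibers, tolerance = 1e-12)
  expect_equal(b2$values, b$values, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(generate_bundle(5, rbind(c(0, 0, 0), c(0, 0, 0)), 1),
               "zero arc length")
  f <- straight_centerline(10, 5)
  expect_error(clean_bundle(streamline_bundle(list(f, f), rep(list(rep(1, 5)), 2))),
               ">= 3 fibers")
})
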