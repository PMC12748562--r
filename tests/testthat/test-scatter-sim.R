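# Synthetic-data generator: screens, masks, measurements, fixtures.

test_that("phase screens have the requested statistics and are reproducible", {
  g <- small_grid()
  expect_equal(make_phase_screen(g, 2, 0, seed = 1)$phase,
               matrix(0, g$n_x, g$n_y))
  expect_error(make_phase_screen(g, 0.1, 5), "correlation_length")
  s1 <- make_phase_screen(g, 2, 5, seed = 3)
  s2 <- make_phase_screen(g, 2, 5, seed = 3)
  expect_identical(s1$phase, s2$phase)
  # RMS within 5% of the requested strength over 10 seeds
  rms <- vapply(1:10, function(s)
    sqrt(mean(make_phase_screen(g, 2, 5, seed = s)$phase^2)), numeric(1))
  expect_true(all(abs(rms - 5) / 5 < 0.05))
})

test_that("SLM masks are phase-only i.i.d. uniform per macropixel", {
  g <- small_grid()
  ms <- make_masks(g, 3, macropixel = 4, seed = 2)
  expect_equal(max(abs(Mod(ms$values) - 1)), 0, tolerance = 1e-12)
  # macropixel = full grid -> each mask is a global phase
  mg <- make_masks(g, 2, macropixel = g$n_x, seed = 2)
  for (m in 1:2) expect_lt(diff(range(Arg(mg$values[, , m]))), 1e-12)
  # masks from different seeds: circular correlation of phases near zero
  a <- make_masks(g, 1, macropixel = 1, seed = 10)$values[, , 1]
  b <- make_masks(g, 1, macropixel = 1, seed = 11)$values[, , 1]
  expect_lt(Mod(mean(a * Conj(b))), 3 / sqrt(g$n_x * g$n_y))
})

test_that("measurement model follows the incoherent modulated-intensity law", {
  g <- small_grid()
  src1 <- point_source_set(1.6, -0.8, 50)
  scr0 <- make_phase_screen(g, 2, 0, seed = 1) # transparent
  mask1 <- make_masks(g, 1, macropixel = g$n_x, seed = 1) # global phase
  m1 <- simulate_measurements(src1, scr0, mask1, g, na = 0.3)
  # transparent screen + phase-only flat mask, camera focused on the source:
  # the image is the focused diffraction-limited spot of that source
  ideal <- Mod(point_source_field(g, 1.6, -0.8, 0, na = 0.3)$values)^2
  expect_lt(max(abs(m1$images[, , 1] - ideal)) / max(ideal), 1e-8)

  # incoherent additivity over sources, exact without noise
  scr <- make_phase_screen(g, 2, 6, seed = 5)
  msk <- make_masks(g, 4, macropixel = 3, seed = 6)
  srcA <- point_source_set(-2, 1, 50)
  srcB <- point_source_set(3, -2, 50)
  srcAB <- point_source_set(c(-2, 3), c(1, -2), c(50, 50))
  iA <- simulate_measurements(srcA, scr, msk, g, focus_depth = 50, na = 0.3)
  iB <- simulate_measurements(srcB, scr, msk, g, focus_depth = 50, na = 0.3)
  iAB <- simulate_measurements(srcAB, scr, msk, g, focus_depth = 50, na = 0.3)
  expect_equal(iA$images + iB$images, iAB$images, tolerance = 1e-12)

  # total energy independent of the mask (unitary modulation)
  en <- apply(iAB$images, 3, sum)
  expect_lt(diff(range(en)) / mean(en), 1e-10)

  # ground truth at the layer satisfies E_n = exp(i S_o) h_n exactly
  h <- point_source_field(g, -2, 1, 50, na = 0.3)
  expect_lt(max(Mod(iA$truth[[1]] - exp(1i * scr$phase) * h$values)), 1e-12)
})

test_that("shot noise is unbiased at large photon budgets", {
  g <- small_grid()
  src <- point_source_set(0, 0, 50)
  scr <- make_phase_screen(g, 2, 6, seed = 5)
  msk <- make_masks(g, 2, macropixel = 3, seed = 6)
  clean <- simulate_measurements(src, scr, msk, g, na = 0.3)
  budget <- 1e7
  reps <- lapply(1:6, function(s)
    simulate_measurements(src, scr, msk, g, na = 0.3,
                          photon_budget = budget, seed = s)$images)
  avg <- Reduce(`+`, reps) / length(reps)
  # 3-sigma band on the total count of the averaged stack
  tot_clean <- sum(clean$images)
  se <- sqrt(2 * budget / length(reps)) * tot_clean / (2 * budget)
  expect_lt(abs(sum(avg) - tot_clean), 3 * se)
  expect_true(all(avg >= 0))
})

test_that("spiral fixture reproduces the printed parametric layout", {
  sp <- make_spiral_fixture()
  expect_equal(nrow(sp), 20)
  expect_equal(sqrt(sp$x_um[1]^2 + sp$y_um[1]^2), 10) # rho_1
  expect_equal(atan2(sp$y_um[1], sp$x_um[1]), 0)      # first azimuth
  # axial coverage n_sources * dz = 10 um
  expect_equal(diff(range(sp$z_um)) + 0.5, 10)
  radii <- sqrt(sp$x_um^2 + sp$y_um^2)
  expect_equal(radii, 10 - 6.7 * (0:19) / 20, tolerance = 1e-12)
  s1 <- make_spiral_fixture(n_sources = 1)
  expect_equal(unlist(s1[1, c("x_um", "y_um", "z_um")], use.names = FALSE),
               c(10, 0, 95.5))
  expect_error(make_spiral_fixture(rho1 = 1, rho2 = 40), "radius")
})

test_that("bead fixture honours depth assignment, separation and the seed", {
  b <- make_bead_fixture(2, plane_depths = c(80, 95), seed = 1)
  expect_setequal(b$z_um, c(80, 95))
  b2 <- make_bead_fixture(8, plane_depths = 100, min_separation = 3,
                          extent = 10, seed = 4)
  d <- as.matrix(stats::dist(cbind(b2$x_um, b2$y_um)))
  expect_true(all(d[upper.tri(d)] >= 3))
  expect_identical(b2, make_bead_fixture(8, 100, 3, 10, seed = 4))
  expect_error(make_bead_fixture(50, 100, min_separation = 8, extent = 5),
               "1000 attempts")
})

test_that("point-source tables round-trip through CSV", {
  src <- make_spiral_fixture(n_sources = 5)
  path <- tempfile(fileext = ".csv")
  write_point_sources(src, path)
  back <- read_point_sources(path)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(src)),
               tolerance = 1e-12)
})
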