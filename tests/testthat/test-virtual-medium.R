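# Relative-phase estimation, pair ranking, virtual-medium construction.

test_that("relative phase of identical and tilted fields is recovered exactly", {
  g <- small_grid()
  f <- random_bl_field(g, seed = 6)$values
  est <- estimate_relative_phase(f, f, model = "linear", grid = g)
  expect_lt(est$fit_residual, 1e-6)
  expect_lt(diff(range(est$phi)), 1e-6) # constant map
  # on-grid tilt: E_m = E_n e^{i k0 . r} -> linear model recovers k0
  dk <- 2 * pi / (g$n_x * g$pitch)
  X <- matrix(grid_x(g), g$n_x, g$n_y)
  Y <- matrix(grid_y(g), g$n_x, g$n_y, byrow = TRUE)
  fm <- f * exp(1i * (5 * dk * X - 3 * dk * Y))
  est2 <- estimate_relative_phase(f, fm, model = "linear", grid = g,
                                  refine_sigma = 0)
  expect_equal(est2$kx, 5 * dk, tolerance = 1e-9)
  expect_equal(est2$ky, -3 * dk, tolerance = 1e-9)
  expect_error(estimate_relative_phase(f, 0 * f, grid = g), "overlap")
})

test_that("the quadratic model recovers the defocus curvature of a depth pair", {
  # analytic oracle: paraxial curvature difference (k0/2)(1/z_m - 1/z_n)
  # for sources at the reference depths 80 and 95 um
  g <- optical_grid(128, 128, 0.65, 0.55, 0.42)
  h80 <- point_source_field(g, 0, 0, 80, na = 0.3)
  h95 <- point_source_field(g, 1.5, 0, 95, na = 0.3)
  est <- estimate_relative_phase(h80, h95, model = "quadratic",
                                 refine_sigma = 0)
  k0 <- 2 * pi / 0.55
  expected <- (k0 / 2) * (1 / 80 - 1 / 95)
  expect_equal(abs(est$curvature), expected, tolerance = 0.05)
})

test_that("pair ranking is phase-invariant and tops out for duplicates", {
  g <- small_grid()
  fl <- list(random_bl_field(g, 1)$values, random_bl_field(g, 2)$values)
  fl[[3]] <- fl[[1]] # duplicate
  rk <- rank_pairs(retrieved_fields(fl, g))
  expect_setequal(c(rk$n[1], rk$m[1]), c(1, 3))
  expect_equal(rk$score[1], 1, tolerance = 1e-9)
  # scores invariant to per-field global phases
  fl2 <- lapply(seq_along(fl), function(i) fl[[i]] * exp(1i * i))
  rk2 <- rank_pairs(retrieved_fields(fl2, g))
  expect_equal(rk2$score, rk$score, tolerance = 1e-10)
})

test_that("co-planar source fields outrank an independent speckle field", {
  sc <- small_scene()
  fl <- sc$measurements$truth
  alien <- random_bl_field(sc$grid, seed = 99)$values
  alien <- alien * sqrt(field_energy(fl[[1]]) / field_energy(alien))
  rk <- rank_pairs(retrieved_fields(c(fl, list(alien)), sc$grid))
  real_pairs <- rk$score[rk$n <= 3 & rk$m <= 3]
  alien_pairs <- rk$score[rk$n == 4 | rk$m == 4]
  expect_gt(min(real_pairs), max(alien_pairs))
})

test_that("virtual media have unit modulus and recover the screen phase", {
  g <- small_grid()
  scr <- make_phase_screen(g, 2, 5, seed = 15)
  X <- matrix(grid_x(g), g$n_x, g$n_y)
  Y <- matrix(grid_y(g), g$n_x, g$n_y, byrow = TRUE)
  dk <- 2 * pi / (g$n_x * g$pitch)
  tilts <- list(c(0, 0), c(4 * dk, 0), c(-2 * dk, 3 * dk), c(0, -5 * dk))
  fl <- lapply(tilts, function(k)
    exp(1i * (scr$phase + k[1] * X + k[2] * Y)))
  med <- build_virtual_medium(retrieved_fields(fl, g, plane_z = 50),
                              model = "linear")
  expect_equal(max(abs(Mod(exp(1i * med$phase)) - 1)), 0)
  # recovered phase equals the screen-times-reference phase up to a constant
  ref_phase <- Arg(fl[[med$reference]])
  expect_gt(circ_corr(med$phase, ref_phase), 0.95)
  # provenance scores never increase along the admission order
  expect_true(all(diff(med$provenance$score[-1]) <= 1e-9))
})

test_that("two identical fields give the reference phase exactly", {
  g <- small_grid()
  f <- random_bl_field(g, seed = 8)$values
  med <- build_virtual_medium(retrieved_fields(list(f, f), g),
                              model = "linear", passes = 1)
  expect_gt(circ_corr(med$phase, Arg(f)), 1 - 1e-6)
})

test_that("uncorrelated fields are rejected or excluded by the threshold", {
  g <- small_grid()
  fl <- list(random_bl_field(g, 1)$values, random_bl_field(g, 2)$values)
  expect_error(build_virtual_medium(retrieved_fields(fl, g),
                                    admission_threshold = 0.9),
               "uncorrelated|threshold")
  sc <- small_scene()
  alien <- random_bl_field(sc$grid, seed = 77)$values
  fl2 <- c(sc$measurements$truth, list(alien))
  med <- build_virtual_medium(retrieved_fields(fl2, sc$grid),
                              admission_threshold = 0.25)
  expect_true(4 %in% med$excluded)
})

test_that("stitching tiles of one global medium reproduces it", {
  g <- small_grid()
  scr <- make_phase_screen(g, 2, 5, seed = 20)
  lay <- tile_layout(g, 2, 2, overlap = 0.3)
  tiles <- lapply(lay$tiles, function(tl)
    holoscatter:::new_virtual_medium(scr$phase[tl$xs, tl$ys],
                                     optical_grid(length(tl$xs),
                                                  length(tl$ys),
                                                  g$pitch, g$wavelength,
                                                  g$na_max),
                                     50, 1L, data.frame(field = 1L,
                                                        score = 1),
                                     integer(0), "linear"))
  st <- stitch_virtual_medium(tiles, lay)
  expect_gt(circ_corr(st$phase, scr$phase), 0.999)
  expect_equal(max(abs(Mod(exp(1i * st$phase)) - 1)), 0)
  # 1 x 1 layout is the identity
  lay1 <- tile_layout(g, 1, 1)
  m1 <- holoscatter:::new_virtual_medium(scr$phase, g, 50, 1L,
                                         data.frame(field = 1L, score = 1),
                                         integer(0), "linear")
  st1 <- stitch_virtual_medium(list(m1), lay1)
  # phases agree on the circle (stitching re-wraps to (-pi, pi])
  expect_lt(max(Mod(exp(1i * (st1$phase - scr$phase)) - 1)), 1e-12)
  expect_error(stitch_virtual_medium(tiles[1:3], lay), "one medium per tile")
})

test_that("stitched tile seams are phase-continuous", {
  # per-tile media with distinct reference tilts and offsets: after
  # stitching, neighbouring phases must agree in the overlaps
  g <- small_grid()
  scr <- make_phase_screen(g, 2, 5, seed = 23)
  X <- matrix(grid_x(g), g$n_x, g$n_y)
  dk <- 2 * pi / (g$n_x * g$pitch)
  lay <- tile_layout(g, 2, 2, overlap = 0.3)
  offsets <- c(0.3, -1.2, 2.0, 0.7)
  tilts <- c(0, 2, -3, 1) * dk
  tiles <- lapply(seq_along(lay$tiles), function(t) {
    tl <- lay$tiles[[t]]
    ph <- scr$phase[tl$xs, tl$ys] + offsets[t] + tilts[t] * X[tl$xs, tl$ys]
    holoscatter:::new_virtual_medium(ph,
      optical_grid(length(tl$xs), length(tl$ys), g$pitch, g$wavelength,
                   g$na_max),
      50, 1L, data.frame(field = 1L, score = 1), integer(0), "linear")
  })
  st <- stitch_virtual_medium(tiles, lay)
  # against the anchor tile's frame: screen + offset1 (+ tilt1 = 0)
  resid <- Arg(exp(1i * (st$phase - scr$phase - offsets[1])))
  expect_lt(sqrt(mean(resid^2)), 0.1)
})
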