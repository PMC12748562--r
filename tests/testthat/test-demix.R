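# Unitary demixing: metric properties, ascent guarantees, oracle checks.

# fields that are exactly demixed: a common random screen times distinct
# plane-wave tilts (the ideal correlation-plane structure of a 2D object)
tilt_fields <- function(grid, tilts, seed = 1) {
  scr <- make_phase_screen(grid, 2, 5, seed = seed)
  X <- matrix(grid_x(grid), grid$n_x, grid$n_y)
  Y <- matrix(grid_y(grid), grid$n_x, grid$n_y, byrow = TRUE)
  amp <- exp(-(X^2 + Y^2) / (2 * (grid$n_x * grid$pitch / 4)^2))
  lapply(tilts, function(k)
    amp * exp(1i * (scr$phase + k[1] * X + k[2] * Y)))
}

metric_of <- function(fields, grid, U, excl = 3) {
  N <- length(fields)
  mixed <- holoscatter:::mix_fields(fields, U)
  arr <- array(0i, c(grid$n_x, grid$n_y, N))
  for (n in seq_len(N)) arr[, , n] <- mixed[[n]]
  holoscatter:::cpp_demix_metric(arr, c(grid$n_x, grid$n_y, N), excl)$M
}

test_that("total intensity and the metric respect the ambiguity group", {
  g <- small_grid()
  dk <- 2 * pi / (g$n_x * g$pitch)
  fl <- tilt_fields(g, list(c(0, 0), c(4 * dk, 0), c(0, -3 * dk)))
  set.seed(2)
  U <- holoscatter:::random_unitary(3)
  mixed <- holoscatter:::mix_fields(fl, U)
  # sum_n |E'_n|^2 is invariant under any unitary at every pixel
  I0 <- Reduce(`+`, lapply(fl, function(f) Mod(f)^2))
  I1 <- Reduce(`+`, lapply(mixed, function(f) Mod(f)^2))
  expect_equal(I1, I0, tolerance = 1e-12)
  # M is exactly invariant under diagonal phases and permutations
  m0 <- metric_of(fl, g, diag(3) + 0i)
  D <- diag(exp(1i * c(0.3, -1.2, 2.5)))
  P <- diag(3)[c(2, 3, 1), ] + 0i
  expect_equal(metric_of(fl, g, D), m0, tolerance = 1e-12)
  expect_equal(metric_of(fl, g, P), m0, tolerance = 1e-12)
  expect_equal(metric_of(fl, g, P %*% D), m0, tolerance = 1e-12)
})

test_that("already-demixed fields are left essentially unchanged", {
  g <- small_grid()
  dk <- 2 * pi / (g$n_x * g$pitch)
  fl <- tilt_fields(g, list(c(0, 0), c(4 * dk, 0), c(-3 * dk, 2 * dk)))
  fs <- retrieved_fields(fl, g)
  res <- demix_unitary(fs, seed = 1, max_iters = 60, restarts = 2)
  expect_gte(res$metric, res$metric_identity * 0.99)
  # U close to a phase-diagonal times permutation: row maxima ~ 1
  rowmax <- apply(Mod(res$U$matrix), 1, max)
  expect_true(all(rowmax^2 > 0.95))
  expect_lt(res$U$unitarity_error, 1e-8)
})

test_that("a known unitary mixture of two sources is inverted", {
  g <- small_grid()
  dk <- 2 * pi / (g$n_x * g$pitch)
  fl <- tilt_fields(g, list(c(0, 0), c(5 * dk, -2 * dk)), seed = 3)
  set.seed(7)
  V <- holoscatter:::random_unitary(2)
  mixed <- retrieved_fields(holoscatter:::mix_fields(fl, V), g)
  res <- demix_unitary(mixed, seed = 2, max_iters = 150, restarts = 3)
  W <- res$U$matrix %*% V # should be phase-diagonal x permutation
  off <- sum(Mod(W)^2) - sum(apply(Mod(W)^2, 1, max))
  expect_lt(off / sum(Mod(W)^2), 0.05)
  expect_lt(res$U$unitarity_error, 1e-8)
  expect_gte(res$metric, metric_of(mixed$fields, g, diag(2) + 0i))
})

test_that("the optimizer reaches the brute-force optimum for N = 2", {
  # exhaustive search over the quotient parameterization
  # U(theta, phi) = [[cos, sin e^{i phi}], [-sin e^{-i phi}, cos]]
  g16 <- optical_grid(16, 16, 0.5, 0.55, 0.5)
  scr <- make_phase_screen(g16, 1.5, 4, seed = 5)
  X <- matrix(grid_x(g16), 16, 16)
  dk <- 2 * pi / (16 * g16$pitch)
  fl <- list(exp(1i * scr$phase), exp(1i * (scr$phase + 4 * dk * X)))
  set.seed(9)
  V <- holoscatter:::random_unitary(2)
  mixed <- holoscatter:::mix_fields(fl, V)
  best <- 0
  for (th in seq(0, pi / 2, length.out = 46)) {
    for (ph in seq(0, 2 * pi, length.out = 61)[-61]) {
      U <- matrix(c(cos(th), -sin(th) * exp(-1i * ph),
                    sin(th) * exp(1i * ph), cos(th)), 2, 2)
      best <- max(best, metric_of(mixed, g16, U, excl = 2))
    }
  }
  res <- demix_unitary(retrieved_fields(mixed, g16), seed = 1,
                       max_iters = 200, restarts = 5, exclusion_radius = 2)
  expect_gt(res$metric, best * 0.99)
})

test_that("gradient ascent never ends below the identity metric", {
  sc <- small_scene()
  fcp <- holoscatter:::propagate_fields(sc$retrieved, 50)
  res <- demix_unitary(fcp, seed = 4, max_iters = 40, restarts = 2)
  expect_gte(res$metric, res$metric_identity)
  expect_lt(res$U$unitarity_error, 1e-8)
})

test_that("the analytic demixing gradient matches finite differences", {
  g16 <- optical_grid(16, 16, 0.5, 0.55, 0.5)
  set.seed(3)
  fl <- list(random_field(g16, 31)$values, random_field(g16, 32)$values)
  E <- array(0i, c(16, 16, 2))
  for (n in 1:2) E[, , n] <- fl[[n]]
  U0 <- holoscatter:::random_unitary(2)
  gr <- holoscatter:::cpp_demix_grad(E, c(16, 16, 2), U0, 2)
  set.seed(4)
  dU <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2) * 1e-7
  m1 <- metric_of(fl, g16, U0 + dU, excl = 2)
  m0 <- metric_of(fl, g16, U0 - dU, excl = 2)
  pred <- sum(Re(Conj(gr$G) * (2 * dU)))
  expect_equal(m1 - m0, pred, tolerance = 1e-3)
})

test_that("tile layouts cover the grid and 1x1 tiling equals global demixing", {
  g <- small_grid()
  lay <- tile_layout(g, 3, 3, overlap = 0.25)
  cover <- matrix(0, g$n_x, g$n_y)
  for (tl in lay$tiles) cover[tl$xs, tl$ys] <- cover[tl$xs, tl$ys] + 1
  expect_true(all(cover >= 1))
  # adjacent tiles overlap by the stated fraction of the window
  w <- length(lay$tiles[[1]]$xs)
  ov <- length(intersect(lay$tiles[[1]]$xs, lay$tiles[[2]]$xs))
  expect_equal(ov / w, 0.25, tolerance = 0.1)

  sc <- small_scene()
  fcp <- holoscatter:::propagate_fields(sc$retrieved, 50)
  lay1 <- tile_layout(sc$grid, 1, 1)
  td <- demix_tiled(fcp, lay1, seed = 4, max_iters = 40, restarts = 2)
  expect_length(td, 1)
  gd <- demix_unitary(fcp, seed = 4 + 1, max_iters = 40, restarts = 2)
  expect_equal(td[[1]]$metric, gd$metric, tolerance = 1e-10)
  expect_error(demix_tiled(fcp, tile_layout(sc$grid, 8, 8, 0), seed = 1),
               "16 x 16")
})

test_that("tiled demixing agrees with global demixing for a 2D object", {
  g <- small_grid()
  dk <- 2 * pi / (g$n_x * g$pitch)
  fl <- tilt_fields(g, list(c(0, 0), c(4 * dk, -2 * dk), c(-3 * dk, 3 * dk)),
                    seed = 11)
  set.seed(13)
  V <- holoscatter:::random_unitary(3)
  mixed <- retrieved_fields(holoscatter:::mix_fields(fl, V), g)
  gd <- demix_unitary(mixed, seed = 2, max_iters = 150, restarts = 3)
  lay <- tile_layout(g, 2, 2, overlap = 0.25)
  td <- demix_tiled(mixed, lay, seed = 2, max_iters = 150, restarts = 3)
  # on each tile the demixed fields must match the global ones up to
  # permutation and phase: compare via normalized correlation
  for (t in seq_along(td)) {
    tl <- td[[t]]$tile
    for (f_tile in td[[t]]$fields$fields) {
      best <- max(vapply(gd$fields$fields, function(fg) {
        sub <- fg[tl$xs, tl$ys] * tl$taper
        Mod(sum(Conj(f_tile) * sub)) /
          sqrt(sum(Mod(f_tile)^2) * sum(Mod(sub)^2))
      }, numeric(1)))
      expect_gt(best, 0.95)
    }
  }
})
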