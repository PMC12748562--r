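# Shared small-scale fixtures, built once per test run. The compact scene
# (64 px, 0.8 um pitch, sources 50 um behind the layer) keeps every field a
# fully developed speckle while unit tests stay fast; full-scale conditions
# are exercised in test-acceptance.R.

small_grid <- function() optical_grid(64, 64, pitch = 0.8, wavelength = 0.55,
                                      na_max = 0.34)

spec_grid <- function() optical_grid(128, 128, pitch = 0.4, wavelength = 0.55,
                                     na_max = 0.4)

random_field <- function(grid, seed = 1, plane_z = 0) {
  set.seed(seed)
  v <- matrix(complex(real = rnorm(grid$n_x * grid$n_y),
                      imaginary = rnorm(grid$n_x * grid$n_y)),
              grid$n_x, grid$n_y)
  complex_field(v, grid, plane_z = plane_z)
}

# band-limited random field (inside the grid's NA)
random_bl_field <- function(grid, seed = 1, na = grid$na_max * 0.9) {
  f <- random_field(grid, seed)
  k0 <- 2 * pi / grid$wavelength
  mask <- outer(grid_kx(grid)^2, grid_ky(grid)^2, "+") <= (k0 * na)^2
  complex_field(ift2(ft2(f$values) * mask), grid)
}

.scene_cache <- new.env(parent = emptyenv())

# compact simulated scene: 3 beads one depth, thin screen, 40 masks
small_scene <- function() {
  if (!is.null(.scene_cache$scene)) return(.scene_cache$scene)
  g <- small_grid()
  src <- make_bead_fixture(3, plane_depths = 50, min_separation = 3,
                           extent = 5, seed = 42)
  scr <- make_phase_screen(g, correlation_length = 2, strength = 6, seed = 7)
  msk <- make_masks(g, 40, macropixel = 3, seed = 9)
  meas <- simulate_measurements(src, scr, msk, g, na = 0.3)
  ret <- retrieve_fields(meas, n_states = 3, max_iters = 200, tol = 1e-10,
                         seed = 3)
  .scene_cache$scene <- list(grid = g, sources = src, screen = scr,
                             masks = msk, measurements = meas,
                             retrieved = ret$fields, trace = ret$trace)
  .scene_cache$scene
}

# truth fields of the scene moved to the camera-conjugate plane
scene_truth_camera <- function(scene) {
  H <- holoscatter:::as_transfer(scene$grid,
                                 -scene$measurements$geometry$focus_depth)
  lapply(scene$measurements$truth, function(v) ift2(ft2(v) * H))
}

circ_corr <- function(phase_a, phase_b) Mod(mean(exp(1i * (phase_a - phase_b))))

# largest principal angle (degrees) between the column spans of A and B
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(Conj(t(qa)) %*% qb)$d
  acos(min(1, min(s))) * 180 / pi
}
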