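# Grids, Fourier operators, angular-spectrum propagation, point sources.

test_that("grid construction enforces sampling invariants", {
  g <- optical_grid(128, 128, pitch = 0.4, wavelength = 0.55, na_max = 0.4)
  expect_s3_class(g, "optical_grid")
  expect_error(optical_grid(4, 4, 0.4, 0.55, 0.4), "n_x")
  expect_error(optical_grid(64, 64, -1, 0.55, 0.4))
  # Nyquist: pitch <= lambda / (2 na_max)
  expect_error(optical_grid(64, 64, 0.8, 0.55, 0.4), "Nyquist")
  expect_error(complex_field(matrix(NaN + 0i, 64, 64), small_grid()),
               "finite")
})

test_that("centred Fourier transform is unitary with zero frequency at centre", {
  f <- random_field(small_grid(), seed = 11)
  # forward then inverse is identity
  rt <- field_fft(field_fft(f, "forward"), "inverse")
  expect_lt(max(Mod(rt$values - f$values)) / max(Mod(f$values)), 1e-12)
  # Parseval on a 64x64 random field
  expect_equal(field_energy(field_fft(f, "forward")), field_energy(f),
               tolerance = 1e-12)
  # constant -> delta at the centre pixel
  g <- small_grid()
  const <- complex_field(matrix(1 + 0i, g$n_x, g$n_y), g)
  spec <- ft2(const$values)
  ctr <- c(g$n_x %/% 2 + 1, g$n_y %/% 2 + 1)
  expect_equal(Mod(spec[ctr[1], ctr[2]]), sqrt(g$n_x * g$n_y))
  expect_lt(max(Mod(spec[-ctr[1], ])), 1e-10)
})

test_that("propagation is unitary, composable and linear on band-limited fields", {
  g <- small_grid()
  f <- random_bl_field(g, seed = 4)
  expect_identical(propagate(f, 0)$values, f$values)
  # +z then -z
  rt <- propagate(propagate(f, 37), -37)
  expect_lt(max(Mod(rt$values - f$values)) / max(Mod(f$values)), 1e-10)
  # energy conservation of propagating components
  expect_equal(field_energy(propagate(f, 61.3)), field_energy(f),
               tolerance = 1e-10)
  # composition
  a <- propagate(propagate(f, 12), 23)
  b <- propagate(f, 35)
  expect_lt(max(Mod(a$values - b$values)) / max(Mod(f$values)), 1e-10)
  expect_equal(a$plane_z, 35)
  # linearity
  f2 <- random_bl_field(g, seed = 5)
  s <- propagate(complex_field(f$values + f2$values, g), 17)
  expect_lt(max(Mod(s$values - propagate(f, 17)$values -
                      propagate(f2, 17)$values)) / max(Mod(s$values)), 1e-10)
})

test_that("refocused point source has the diffraction-limited width", {
  # independent oracle: the Airy profile of a uniformly filled NA disk,
  # FWHM ~ 1.03 lambda / (2 NA); compared at 10% as a derived bound
  g <- spec_grid()
  na <- 0.35
  f <- point_source_field(g, 0, 0, z_to_plane = 100, na = na)
  back <- propagate(f, -100)
  I <- Mod(back$values)^2
  pk <- which(I == max(I), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(pk), c(65, 65)) # symmetric about the centre pixel
  prof <- I[, pk[2]]
  xs <- grid_x(g)
  half <- max(prof) / 2
  above <- which(prof >= half)
  fl <- stats::approx(prof[c(min(above) - 1, min(above))],
                      xs[c(min(above) - 1, min(above))], xout = half)$y
  fr <- stats::approx(prof[c(max(above), max(above) + 1)],
                      xs[c(max(above), max(above) + 1)], xout = half)$y
  airy_fwhm <- 1.0290 * g$wavelength / (2 * na)
  expect_lt(abs((fr - fl) - airy_fwhm) / airy_fwhm, 0.10)
})

test_that("point sources obey the Fourier shift theorem and energy scaling", {
  g <- small_grid()
  p0 <- point_source_field(g, 0, 0, 0, amplitude = 2)
  expect_equal(field_energy(p0), 4, tolerance = 1e-12)
  ps <- point_source_field(g, 0.4, 0, 0, amplitude = 2) # half-pixel shift
  ramp <- exp(-1i * outer(grid_kx(g) * 0.4, rep(0, g$n_y), "+"))
  expect_lt(max(Mod(ft2(ps$values) - ft2(p0$values) * ramp)), 1e-10)
  expect_error(point_source_field(g, 1e4, 0, 0), "outside")
})

test_that("two sources above the Rayleigh separation are resolved after refocus", {
  g <- spec_grid()
  na <- 0.35
  sep <- 2 # um, > 0.61 * 0.55 / 0.35 = 0.96 um
  f1 <- point_source_field(g, -sep / 2, 0, 100, na = na)
  f2 <- point_source_field(g, sep / 2, 0, 100, na = na)
  I <- Mod(propagate(f1, -100)$values)^2 + Mod(propagate(f2, -100)$values)^2
  prof <- I[, g$n_y %/% 2 + 1]
  xs <- grid_x(g)
  peaks <- which(diff(sign(diff(prof))) == -2) + 1
  peaks <- peaks[prof[peaks] > 0.5 * max(prof)]
  expect_length(peaks, 2)
  # incoherent overlap of the two Airy profiles pushes the maxima slightly
  # outward; resolvability plus coarse position agreement is the check
  expect_equal(abs(diff(xs[peaks])), sep, tolerance = 0.3)
})

test_that("Rayleigh limit at the experimental NA is 0.96 um", {
  expect_equal(round(rayleigh_resolution(0.55, 0.35), 2), 0.96)
})
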