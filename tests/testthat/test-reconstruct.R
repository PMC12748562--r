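# Holographic reconstruction, detection, calibration, metrics.

oracle_scene_medium <- function(sc) {
  # oracle virtual layer: the phase of the reference truth field S_o h_m
  ref <- 1L
  holoscatter:::new_virtual_medium(Arg(sc$measurements$truth[[ref]]),
                                   sc$grid, 50, ref,
                                   data.frame(field = ref, score = 1),
                                   integer(0), "oracle")
}

truth_fields_cp <- function(sc) {
  retrieved_fields(sc$measurements$truth, sc$grid, plane_z = 50,
                   label = "truth")
}

test_that("the oracle medium refocuses a source to a diffraction-limited spot", {
  sc <- small_scene()
  med <- oracle_scene_medium(sc)
  stk <- reconstruct_volume(truth_fields_cp(sc), med, seq(-6, 6, 2),
                            pad_factor = 2)
  expect_true(all(stk$intensity >= 0))
  det <- detect_sources(stk, 0.25, merge_radius = 1.5)
  expect_gte(nrow(det), 3)
  # brightest spot near best focus: lateral FWHM <= 1.2 x Rayleigh in
  # reconstruction units (|magnification| ~ 1.49 here)
  mag <- sc$grid$n_x * sc$grid$pitch^2 / (sc$grid$wavelength * 50)
  fw <- fwhm_measure(stk, unlist(det[1, c("x_um", "y_um", "z_um")]), "x")
  rayleigh <- rayleigh_resolution(sc$grid$wavelength, 0.3)
  expect_lte(fw / mag, 1.2 * rayleigh)
})

test_that("stack energy is conserved across refocus distances", {
  sc <- small_scene()
  med <- oracle_scene_medium(sc)
  stk <- reconstruct_volume(truth_fields_cp(sc), med, c(-4, 0, 4, 9),
                            pad_factor = 1)
  en <- apply(stk$intensity, 3, sum)
  expect_lt(diff(range(en)) / mean(en), 1e-8)
  expect_error(reconstruct_volume(truth_fields_cp(sc), med, numeric(0)),
               "non-empty")
})

test_that("reconstruction is invariant to field permutation, phases and mixing", {
  sc <- small_scene()
  med <- oracle_scene_medium(sc)
  fs <- truth_fields_cp(sc)
  stk <- reconstruct_volume(fs, med, c(0, 3), pad_factor = 1)
  perm <- retrieved_fields(fs$fields[c(3, 1, 2)], sc$grid, 50)
  ph <- retrieved_fields(lapply(seq_along(fs$fields), function(i)
    fs$fields[[i]] * exp(1i * i * 0.7)), sc$grid, 50)
  set.seed(31)
  U <- holoscatter:::random_unitary(3)
  mix <- retrieved_fields(holoscatter:::mix_fields(fs$fields, U),
                          sc$grid, 50)
  for (alt in list(perm, ph, mix)) {
    stk2 <- reconstruct_volume(alt, med, c(0, 3), pad_factor = 1)
    expect_equal(stk2$intensity, stk$intensity, tolerance = 1e-10)
  }
})

test_that("a scrambled medium collapses the focal contrast", {
  sc <- small_scene()
  med <- oracle_scene_medium(sc)
  stk <- reconstruct_volume(truth_fields_cp(sc), med, 0, pad_factor = 1)
  set.seed(17)
  scram <- med
  scram$phase <- matrix(sample(med$phase), nrow(med$phase), ncol(med$phase))
  stk_s <- reconstruct_volume(truth_fields_cp(sc), scram, 0, pad_factor = 1)
  contrast <- function(s) max(s$intensity) / mean(s$intensity)
  expect_gte(contrast(stk) / contrast(stk_s), 5)
})

test_that("detection finds isolated sources with sub-pixel accuracy", {
  sc <- small_scene()
  med <- oracle_scene_medium(sc)
  stk <- reconstruct_volume(truth_fields_cp(sc), med, seq(-6, 6, 2),
                            pad_factor = 2)
  det <- detect_sources(stk, 0.3, merge_radius = 1.5)
  expect_equal(nrow(det), 3)
  det1 <- detect_sources(stk, rel_threshold = 1)
  expect_lte(nrow(det1), 1)
  # matched pairwise geometry: distances agree with the truth after the
  # similarity calibration
  mt <- match_sources(det, sc$sources)
  expect_equal(length(mt$det_idx), 3)
  cal <- calibrate_coordinates(det[mt$det_idx, ], sc$sources[mt$truth_idx, ])
  expect_lt(cal$residual_rms, rayleigh_resolution(0.55, 0.3))
  mapped <- apply_calibration(cal, det[mt$det_idx, ])
  tr <- sc$sources[mt$truth_idx, ]
  d_err <- sqrt((mapped$x_um - tr$x_um)^2 + (mapped$y_um - tr$y_um)^2)
  expect_lt(max(d_err), 0.5)
})

test_that("two sources five microns apart are separated and measured", {
  g <- small_grid()
  src <- point_source_set(c(-2.5, 2.5), c(0, 0), c(50, 50))
  scr <- make_phase_screen(g, 2, 6, seed = 31)
  trans <- exp(1i * scr$phase)
  truth <- lapply(1:2, function(n) {
    h <- point_source_field(g, src$x_um[n], src$y_um[n], 50, na = 0.3)
    trans * h$values
  })
  med <- holoscatter:::new_virtual_medium(Arg(truth[[1]]), g, 50, 1L,
                                          data.frame(field = 1L, score = 1),
                                          integer(0), "oracle")
  stk <- reconstruct_volume(retrieved_fields(truth, g, 50), med,
                            seq(-4, 4, 2), pad_factor = 2)
  det <- detect_sources(stk, 0.3, merge_radius = 1.5)
  expect_equal(nrow(det), 2)
  mt <- match_sources(det, src)
  # pairwise distance in recon units, rescaled by the fitted magnification
  scale_fit <- sqrt(sum((det$x_um[1] - det$x_um[2])^2 +
                          (det$y_um[1] - det$y_um[2])^2))
  mag <- g$n_x * g$pitch^2 / (g$wavelength * 50)
  expect_equal(scale_fit / mag, 5, tolerance = 0.5)
})

test_that("coordinate calibration recovers similarity and axial transforms", {
  set.seed(3)
  truth <- point_source_set(runif(6, -5, 5), runif(6, -5, 5),
                            z_um = c(80, 95)[rep(1:2, 3)])
  expect_error(calibrate_coordinates(truth[1:2, ], truth[1:2, ]), ">= 3")
  cal <- calibrate_coordinates(truth, truth)
  expect_equal(cal$magnification, 1, tolerance = 1e-9)
  expect_equal(cal$rotation, 0, tolerance = 1e-9)
  expect_equal(cal$z_scale, 1, tolerance = 1e-9)
  expect_equal(cal$residual_rms, 0, tolerance = 1e-9)
  # z doubled in the detections -> z-scale 0.5
  det2 <- truth
  det2$z_um <- truth$z_um * 2
  cal2 <- calibrate_coordinates(det2, truth)
  expect_equal(cal2$z_scale, 0.5, tolerance = 1e-9)
  # rotation + parity + scale round trip
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  P <- cbind(truth$x_um, -truth$y_um) %*% R * 2.3
  det3 <- point_source_set(P[, 1], P[, 2], truth$z_um)
  cal3 <- calibrate_coordinates(det3, truth)
  expect_equal(cal3$parity, -1)
  expect_equal(abs(cal3$magnification), 1 / 2.3, tolerance = 1e-6)
  back <- apply_calibration(cal3, det3)
  expect_lt(max(abs(back$x_um - truth$x_um)), 1e-6)
})

test_that("image metrics behave like PSNR/SSIM on known cases", {
  g <- small_grid()
  img <- diffraction_limited_image(point_source_set(c(0, 3), c(1, -2),
                                                    c(1, 1)), g, na = 0.3)
  m <- image_metrics(img, img)
  expect_equal(m$psnr_db, 100)
  expect_equal(m$ssim, 1, tolerance = 1e-12)
  # reference + uniform noise of known variance: PSNR = -10 log10(v)
  set.seed(5)
  v <- 1e-4
  noisy <- img / max(img) + matrix(rnorm(length(img), sd = sqrt(v)),
                                   nrow(img))
  noisy <- pmax(noisy, 0)
  m2 <- image_metrics(noisy, img, register = FALSE)
  expect_equal(m2$psnr_db, -10 * log10(v), tolerance = 0.5)
  # SSIM symmetry
  a <- img / max(img)
  b <- pmax(img / max(img) + 0.05 * sin(outer(1:64, 1:64) / 40), 0)
  expect_equal(image_metrics(a, b, register = FALSE)$ssim,
               image_metrics(b, a, register = FALSE)$ssim,
               tolerance = 1e-12)
  expect_error(image_metrics(img[1:10, 1:10], img), "mismatch")
})

test_that("registration aligns translated reconstructions before scoring", {
  g <- small_grid()
  src <- point_source_set(c(0, 3, -4), c(1, -2, 2), rep(1, 3))
  img <- diffraction_limited_image(src, g, na = 0.3)
  shifted <- img[c(4:g$n_x, 1:3), c(60:g$n_y, 1:59)] # integer torus shift
  m <- image_metrics(shifted, img)
  expect_gt(m$psnr_db, 40)
  expect_gt(m$ssim, 0.99)
})

test_that("maximum intensity projections preserve peaks", {
  sc <- small_scene()
  med <- oracle_scene_medium(sc)
  stk <- reconstruct_volume(truth_fields_cp(sc), med, seq(-4, 4, 2),
                            pad_factor = 1)
  for (ax in c("x", "y", "z")) {
    mip <- max_intensity_projection(stk, ax)
    expect_equal(max(mip), max(stk$intensity))
  }
  # single-voxel impulse appears at its projected position
  st2 <- stk
  st2$intensity[] <- 0
  st2$intensity[10, 20, 2] <- 7
  expect_equal(max_intensity_projection(st2, "z")[10, 20], 7)
  expect_equal(max_intensity_projection(st2, "x")[20, 2], 7)
})

test_that("FWHM measurement matches the closed form for a Gaussian spot", {
  g <- small_grid()
  xs <- grid_x(g)
  I <- exp(-outer(xs^2, grid_y(g)^2, "+") / (2 * 1^2)) # sigma = 1 um
  stk <- structure(list(intensity = array(I, c(g$n_x, g$n_y, 1)),
                        z = 0, grid = g, provenance = list()),
                   class = "reconstruction_stack")
  fw <- fwhm_measure(stk, c(0, 0, 0), "x")
  expect_equal(fw, 2.3548, tolerance = 0.02 * 2.3548)
  stk$intensity <- stk$intensity * 123.4 # invariant under rescaling
  expect_equal(fwhm_measure(stk, c(0, 0, 0), "x"), fw, tolerance = 1e-12)
  flat <- stk
  flat$intensity[] <- 1
  expect_error(fwhm_measure(flat, c(0, 0, 0), "x"), "half maximum")
})
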