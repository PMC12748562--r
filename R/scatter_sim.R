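#' Incoherent point-source object
#'
#' A set of mutually incoherent point emitters. `z_um` is the distance from
#' the scattering layer, positive on the hidden (object) side; `intensity`
#' is the relative emitted power of each source.
#'
#' @param x_um,y_um lateral positions (um).
#' @param z_um depth behind the scattering layer (um, > 0).
#' @param intensity relative source intensities (> 0).
#' @return A `point_source_set`, a data.frame with columns
#'   `x_um, y_um, z_um, intensity`.
#' @export
point_source_set <- function(x_um, y_um, z_um, intensity = 1) {
  n <- length(x_um)
  stopifnot(n >= 1, length(y_um) == n, length(z_um) == n)
  intensity <- rep_len(intensity, n)
  stopifnot(all(intensity > 0), all(is.finite(c(x_um, y_um, z_um))))
  structure(data.frame(x_um = x_um, y_um = y_um, z_um = z_um,
                       intensity = intensity),
            class = c("point_source_set", "data.frame"))
}

#' @export
print.point_source_set <- function(x, ...) {
  cat(sprintf("<point_source_set> %d source(s), depth range [%.4g, %.4g] um\n",
              nrow(x), min(x$z_um), max(x$z_um)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read/write point-source tables as CSV
#'
#' Plain CSV with columns `x_um, y_um, z_um, intensity`.
#' @param sources a [point_source_set()].
#' @param path file path.
#' @export
write_point_sources <- function(sources, path) {
  utils::write.csv(as.data.frame(unclass(sources))[, c("x_um", "y_um", "z_um",
                                                       "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_sources
#' @export
read_point_sources <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_um", "y_um", "z_um", "intensity")
  if (!all(need %in% names(d)))
    stop("point-source CSV must have columns: ", paste(need, collapse = ", "))
  point_source_set(d$x_um, d$y_um, d$z_um, d$intensity)
}

#' Thin random scattering layer
#'
#' A Gaussian random phase screen: white noise low-pass filtered with a
#' Gaussian kernel of 1/e half-width `correlation_length`, rescaled so the
#' phase has the requested RMS. `exp(1i * phase)` is the unit-modulus
#' transmission of the layer. Deterministic given `seed`.
#'
#' @param grid an [optical_grid()].
#' @param correlation_length lateral correlation length (um, >= pitch).
#' @param strength RMS phase depth (radians); 0 gives a transparent screen.
#' @param seed integer RNG seed.
#' @return An object of class `phase_screen` with elements `phase` (matrix,
#'   radians), `grid`, `correlation_length`, `strength`, `seed`.
#' @export
make_phase_screen <- function(grid, correlation_length, strength, seed = 1) {
  stopifnot(inherits(grid, "optical_grid"), strength >= 0)
  if (correlation_length < grid$pitch)
    stop("correlation_length must be >= grid pitch (", grid$pitch, " um)")
  if (strength == 0) {
    ph <- matrix(0, grid$n_x, grid$n_y)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    w <- matrix(stats::rnorm(grid$n_x * grid$n_y), grid$n_x, grid$n_y)
    # Gaussian low-pass in the frequency domain
    kx <- grid_kx(grid)
    ky <- grid_ky(grid)
    filt <- exp(-outer(kx^2, ky^2, "+") * correlation_length^2 / 4)
    ph <- Re(ift2(ft2(w) * filt))
    ph <- ph - mean(ph)
    ph <- ph * (strength / sqrt(mean(ph^2)))
  }
  structure(list(phase = ph, grid = grid,
                 correlation_length = correlation_length,
                 strength = strength, seed = as.integer(seed)),
            class = "phase_screen")
}

#' @export
print.phase_screen <- function(x, ...) {
  cat(sprintf(
    "<phase_screen> %d x %d, correlation length %.3g um, RMS %.3g rad (seed %d)\n",
    nrow(x$phase), ncol(x$phase), x$correlation_length,
    sqrt(mean((x$phase - mean(x$phase))^2)), x$seed))
  invisible(x)
}

# transmission exp(i phase) of a screen
screen_transmission <- function(screen) exp(1i * screen$phase)

#' Random SLM phase-mask set
#'
#' `count` phase-only masks displayed on the modulation (Fourier) plane.
#' Phases are i.i.d. uniform on [0, 2pi) per square macropixel, so
#' `|K_m| = 1` everywhere. Deterministic given `seed`.
#'
#' @param grid an [optical_grid()] (the masks share the field sampling).
#' @param count number of masks (>= 1).
#' @param macropixel macropixel edge length in grid pixels.
#' @param seed integer RNG seed.
#' @return An object of class `mask_set`: complex array `values` of dim
#'   `c(n_x, n_y, count)` plus parameters.
#' @export
make_masks <- function(grid, count, macropixel = 4, seed = 1) {
  stopifnot(inherits(grid, "optical_grid"), count >= 1, macropixel >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nbx <- ceiling(grid$n_x / macropixel)
  nby <- ceiling(grid$n_y / macropixel)
  ix <- rep(seq_len(nbx), each = macropixel)[seq_len(grid$n_x)]
  iy <- rep(seq_len(nby), each = macropixel)[seq_len(grid$n_y)]
  vals <- array(0i, c(grid$n_x, grid$n_y, count))
  for (m in seq_len(count)) {
    blocks <- matrix(stats::runif(nbx * nby, 0, 2 * pi), nbx, nby)
    vals[, , m] <- exp(1i * blocks[ix, iy])
  }
  structure(list(values = vals, grid = grid, count = as.integer(count),
                 macropixel = as.integer(macropixel), seed = as.integer(seed)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d mask(s), %d x %d px, macropixel %d (seed %d)\n",
              x$count, dim(x$values)[1], dim(x$values)[2], x$macropixel,
              x$seed))
  invisible(x)
}

#' Simulate random-mask modulated speckle measurements
#'
#' The measurement model: the field of source n propagates `z_um[n]` to the
#' thin scattering layer, acquires its phase distortion
#' (`E_n = exp(i S_o) h_n`), and is imaged; the camera is conjugate to the
#' nominal object plane at `focus_depth` behind the layer, so the retrieved
#' field plane sits `focus_depth` um upstream of the layer. An SLM at the
#' Fourier plane multiplies the field spectrum by each random mask `K_m`, and
#' the camera records the incoherent sum over sources,
#' `I_m = sum_n |IFT[E~_n K_m]|^2`. Optional shot noise draws each image from
#' a Poisson law scaled to `photon_budget` expected photons per image.
#'
#' @param sources a [point_source_set()].
#' @param screen a [make_phase_screen()] layer.
#' @param masks a [make_masks()] set.
#' @param grid an [optical_grid()] (must match screen and masks).
#' @param focus_depth plane the camera is conjugate to, as a distance behind
#'   the layer (um); default the mean source depth.
#' @param na emission/collection numerical aperture of the source fields.
#' @param photon_budget expected photons per image, or `NULL` (noiseless).
#' @param seed RNG seed for the shot noise.
#' @return An object of class `speckle_measurements`: `images` array
#'   `c(n_x, n_y, M)`, the `masks`, `grid`, `geometry` list, optional `noise`
#'   record, and `truth` — the per-source ground-truth fields at the layer
#'   (list of complex matrices, for testing only).
#' @export
simulate_measurements <- function(sources, screen, masks, grid,
                                  focus_depth = NULL, na = 0.35,
                                  photon_budget = NULL, seed = 1) {
  stopifnot(inherits(sources, "point_source_set"),
            inherits(screen, "phase_screen"), inherits(masks, "mask_set"),
            inherits(grid, "optical_grid"))
  if (!grids_compatible(grid, screen$grid) ||
      !grids_compatible(grid, masks$grid))
    stop("sources/screen/masks must share one grid")
  if (masks$count < 1) stop("empty mask set")
  if (any(sources$z_um <= 0)) stop("sources must lie behind the layer (z > 0)")
  if (is.null(focus_depth)) focus_depth <- mean(sources$z_um)
  N <- nrow(sources)
  M <- masks$count
  trans <- screen_transmission(screen)
  truth <- vector("list", N)
  Etil <- vector("list", N)
  for (n in seq_len(N)) {
    h <- point_source_field(grid, sources$x_um[n], sources$y_um[n],
                            z_to_plane = sources$z_um[n],
                            amplitude = sqrt(sources$intensity[n]), na = na)
    scr <- complex_field(trans * h$values, grid, plane_z = 0,
                         label = "layer-exit")
    truth[[n]] <- scr$values
    cam <- propagate(scr, -focus_depth) # virtual field at the conjugate plane
    Etil[[n]] <- ft2(cam$values)        # SLM (Fourier) plane
  }
  images <- array(0, c(grid$n_x, grid$n_y, M))
  for (m in seq_len(M)) {
    K <- masks$values[, , m]
    acc <- matrix(0, grid$n_x, grid$n_y)
    for (n in seq_len(N)) acc <- acc + Mod(ift2(Etil[[n]] * K))^2
    images[, , m] <- acc
  }
  noise <- NULL
  if (!is.null(photon_budget)) {
    stopifnot(photon_budget > 0)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    for (m in seq_len(M)) {
      lam <- images[, , m]
      sc <- photon_budget / sum(lam)
      images[, , m] <- stats::rpois(length(lam), lam * sc) / sc
    }
    noise <- list(photon_budget = photon_budget, seed = as.integer(seed))
  }
  structure(list(images = images, masks = masks, grid = grid,
                 geometry = list(focus_depth = focus_depth, na = na),
                 noise = noise, sources = sources, truth = truth),
            class = "speckle_measurements")
}

#' @export
print.speckle_measurements <- function(x, ...) {
  cat(sprintf(
    "<speckle_measurements> %d image(s) %d x %d, focus depth %.4g um, NA %.3g%s\n",
    dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
    x$geometry$focus_depth, x$geometry$na,
    if (is.null(x$noise)) ", noiseless"
    else sprintf(", ~%.3g photons/image", x$noise$photon_budget)))
  invisible(x)
}

#' Spiral test object
#'
#' `n_sources` point sources on a spiral in cylindrical coordinates: source n
#' at radius `rho1 - rho2 * (n-1) / n_sources`, azimuth
#' `turns_total_angle * (n-1) / n_sources`, depth `z_base + n * dz`. The
#' defaults trace two full turns of 20 equal-intensity foci from 10 um radius
#' inward with a 0.5 um axial increment (total axial coverage
#' `n_sources * dz = 10` um).
#'
#' @param rho1 outer radius (um).
#' @param rho2 total radial decrease (um).
#' @param n_sources number of sources.
#' @param turns_total_angle total azimuthal sweep (radians).
#' @param dz axial increment per source (um).
#' @param z_base depth of the (virtual) 0th source behind the layer (um).
#' @return a [point_source_set()].
#' @export
make_spiral_fixture <- function(rho1 = 10, rho2 = 6.7, n_sources = 20,
                                turns_total_angle = 4 * pi, dz = 0.5,
                                z_base = 95) {
  stopifnot(n_sources >= 1)
  n <- seq_len(n_sources)
  rho <- rho1 - rho2 * (n - 1) / n_sources
  if (any(rho < 0)) stop("negative spiral radius: rho2 too large")
  phi <- turns_total_angle * (n - 1) / n_sources
  point_source_set(x_um = rho * cos(phi), y_um = rho * sin(phi),
                   z_um = z_base + n * dz, intensity = 1)
}

#' Random bead test object
#'
#' `n_beads` equal-intensity beads at random lateral positions with a minimum
#' pairwise lateral separation, assigned round-robin to the given depth
#' planes. Deterministic given `seed`.
#'
#' @param n_beads number of beads.
#' @param plane_depths depths behind the layer (um), e.g. `c(80, 95)`.
#' @param min_separation minimum pairwise lateral distance (um).
#' @param extent half-width of the lateral placement region (um).
#' @param seed integer RNG seed.
#' @return a [point_source_set()].
#' @export
make_bead_fixture <- function(n_beads, plane_depths, min_separation = 3,
                              extent = 10, seed = 1) {
  stopifnot(n_beads >= 1, length(plane_depths) >= 1, min_separation >= 0,
            extent > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_beads) {
    x <- stats::runif(1, -extent, extent)
    y <- stats::runif(1, -extent, extent)
    if (!length(xs) || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_separation)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1
    if (tries > 1000)
      stop("could not place ", n_beads, " beads with separation ",
           min_separation, " um in 1000 attempts; enlarge extent")
  }
  z <- rep_len(plane_depths, n_beads)
  point_source_set(xs, ys, z, intensity = 1)
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
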