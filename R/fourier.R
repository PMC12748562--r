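#' Centred unitary 2D Fourier transform
#'
#' The package-wide discrete Fourier convention: zero frequency at the array
#' centre, norm-preserving scaling (`1/sqrt(n_x n_y)` in both directions), so
#' forward followed by inverse is the identity and Parseval's theorem holds
#' exactly. `ft2`/`ift2` operate on bare complex matrices; `field_fft` wraps
#' them for [complex_field()] objects and maps between a spatial plane and its
#' Fourier (pupil) plane.
#'
#' @param x complex matrix.
#' @return complex matrix of the same dimension.
#' @export
ft2 <- function(x) {
  if (is.numeric(x)) x <- x + 0i
  cpp_ft2(x, FALSE)
}

#' @rdname ft2
#' @export
ift2 <- function(x) {
  if (is.numeric(x)) x <- x + 0i
  cpp_ft2(x, TRUE)
}

#' @rdname ft2
#' @param field a [complex_field()]; values must be finite.
#' @param direction `"forward"` or `"inverse"`.
#' @export
field_fft <- function(field, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(field, "complex_field"))
  v <- if (direction == "forward") ft2(field$values) else ift2(field$values)
  complex_field(v, field$grid, plane_z = field$plane_z,
                label = paste0(field$label,
                               if (direction == "forward") ":ft" else ":ift"))
}

# band-limited angular-spectrum transfer function H(kx, ky) = exp(i z kz);
# evanescent components (k > k0) and spatial frequencies beyond the grid's
# na_max are removed.
as_transfer <- function(grid, distance, clamp_na = TRUE) {
  k0 <- 2 * pi / grid$wavelength
  kx <- grid_kx(grid)
  ky <- grid_ky(grid)
  k2 <- outer(kx^2, ky^2, "+")
  kcut2 <- if (clamp_na) (k0 * min(1, grid$na_max))^2 else k0^2
  kz <- sqrt(pmax(k0^2 - k2, 0))
  H <- exp(1i * distance * kz)
  H[k2 > kcut2] <- 0
  H
}

#' Free-space propagation (band-limited angular spectrum)
#'
#' Propagates a field by `distance` um along +z (object toward detector;
#' negative distances back-propagate). The transfer function
#' `exp(i z sqrt(k0^2 - kx^2 - ky^2))` is exact for scalar free-space
#' propagation; evanescent components and spatial frequencies beyond the
#' grid's `na_max` are zeroed, so the operator is unitary on the band-limited
#' subspace (energy of propagating components is conserved).
#'
#' @param field a [complex_field()].
#' @param distance propagation distance (um); 0 returns the field unchanged.
#' @return a [complex_field()] at `plane_z + distance`.
#' @export
propagate <- function(field, distance) {
  stopifnot(inherits(field, "complex_field"), is.finite(distance))
  if (distance == 0) return(field)
  H <- as_transfer(field$grid, distance)
  v <- ift2(ft2(field$values) * H)
  complex_field(v, field$grid, plane_z = field$plane_z + distance,
                label = field$label)
}

#' Band-limited point-source field
#'
#' The field emitted by a point source under free-space propagation: a
#' sub-pixel-accurate source at `(x, y)` realized as a frequency-domain linear
#' phase ramp band-limited to `na` (default the grid's `na_max`), then
#' propagated by `z_to_plane` toward the detector. `amplitude` scales the
#' total energy (`field_energy` equals `amplitude^2`).
#'
#' @param grid an [optical_grid()].
#' @param x,y lateral source position (um), inside the grid extent.
#' @param z_to_plane propagation distance from the source to the returned
#'   plane (um, >= 0).
#' @param amplitude square root of the total field energy.
#' @param na band limit of the emission cone (numerical aperture).
#' @return a [complex_field()] at `plane_z = z_to_plane`.
#' @export
point_source_field <- function(grid, x = 0, y = 0, z_to_plane = 0,
                               amplitude = 1, na = grid$na_max) {
  stopifnot(inherits(grid, "optical_grid"), z_to_plane >= 0, na <= grid$na_max)
  hx <- grid$n_x * grid$pitch / 2
  hy <- grid$n_y * grid$pitch / 2
  if (abs(x) > hx || abs(y) > hy)
    stop("source position (", x, ", ", y, ") outside grid extent")
  k0 <- 2 * pi / grid$wavelength
  kx <- grid_kx(grid)
  ky <- grid_ky(grid)
  spec <- exp(-1i * outer(kx * x, ky * y, "+"))
  spec[outer(kx^2, ky^2, "+") > (k0 * na)^2] <- 0
  v <- ift2(spec)
  e <- sqrt(sum(Mod(v)^2))
  if (e == 0) stop("empty band: na too small for this grid")
  v <- v * (amplitude / e)
  f <- complex_field(v, grid, plane_z = 0, label = "point-source")
  propagate(f, z_to_plane)
}

#' Rayleigh resolution limit
#'
#' Classical lateral resolution `0.61 * lambda / NA` of an imaging system.
#' @param wavelength vacuum wavelength (um).
#' @param na numerical aperture.
#' @return resolution (um).
#' @examples
#' rayleigh_resolution(0.55, 0.35) # 0.96 um
#' @export
rayleigh_resolution <- function(wavelength, na) 0.61 * wavelength / na
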