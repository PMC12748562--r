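#' Optical sampling grid
#'
#' Defines the discrete sampling of the transverse coordinate r = (x, y) shared
#' by every field in a computation. Coordinates are in micrometres with the
#' origin at the grid centre (pixel `floor(n/2) + 1`); z increases from the
#' object toward the detector. The Nyquist condition
#' `pitch <= wavelength / (2 * na_max)` guarantees that a field band-limited to
#' the numerical aperture `na_max` is sampled without aliasing.
#'
#' @param n_x,n_y pixel counts (>= 8).
#' @param pitch sampling interval (um).
#' @param wavelength vacuum wavelength (um).
#' @param na_max largest numerical aperture the grid must support.
#' @return An object of class `optical_grid`.
#' @examples
#' g <- optical_grid(128, 128, pitch = 0.4, wavelength = 0.55, na_max = 0.4)
#' @export
optical_grid <- function(n_x, n_y = n_x, pitch, wavelength, na_max = 1) {
  stopifnot(n_x >= 8, n_y >= 8, pitch > 0, wavelength > 0,
            na_max > 0, na_max <= 1)
  if (pitch > wavelength / (2 * na_max) + 1e-12) {
    stop("Nyquist violation: pitch must be <= wavelength / (2 * na_max) (",
         format(wavelength / (2 * na_max), digits = 4), " um)")
  }
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 pitch = pitch, wavelength = wavelength, na_max = na_max),
            class = "optical_grid")
}

#' @export
print.optical_grid <- function(x, ...) {
  cat(sprintf("<optical_grid> %d x %d px, pitch %.4g um (%.3g x %.3g um), ",
              x$n_x, x$n_y, x$pitch, x$n_x * x$pitch, x$n_y * x$pitch))
  cat(sprintf("lambda %.4g um, na_max %.3g\n", x$wavelength, x$na_max))
  invisible(x)
}

# centred integer offsets for a dimension of length n (zero at floor(n/2)+1)
centered_index <- function(n) seq_len(n) - (n %/% 2 + 1L)

#' Grid coordinate vectors
#'
#' `grid_x`/`grid_y` return the centred spatial coordinates (um);
#' `grid_kx`/`grid_ky` the angular spatial frequencies (rad/um) of the
#' zero-centred Fourier convention used throughout the package.
#' @param grid an [optical_grid()].
#' @return numeric vector.
#' @export
grid_x <- function(grid) centered_index(grid$n_x) * grid$pitch

#' @rdname grid_x
#' @export
grid_y <- function(grid) centered_index(grid$n_y) * grid$pitch

#' @rdname grid_x
#' @export
grid_kx <- function(grid) 2 * pi * centered_index(grid$n_x) / (grid$n_x * grid$pitch)

#' @rdname grid_x
#' @export
grid_ky <- function(grid) 2 * pi * centered_index(grid$n_y) / (grid$n_y * grid$pitch)

grids_compatible <- function(a, b) {
  isTRUE(all.equal(a[c("n_x", "n_y", "pitch", "wavelength")],
                   b[c("n_x", "n_y", "pitch", "wavelength")]))
}

#' Complex wave field on an optical grid
#'
#' A 2D complex scalar field sampled on an [optical_grid()] at a named axial
#' plane. `values[i, j]` holds the sample at `x = grid_x(grid)[i]`,
#' `y = grid_y(grid)[j]`.
#'
#' @param values complex (or numeric) matrix of dim `c(n_x, n_y)`; must be
#'   finite everywhere.
#' @param grid an [optical_grid()].
#' @param plane_z axial coordinate of the sampling plane (um).
#' @param label free-text plane label (e.g. "camera", "correlation-plane").
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, grid, plane_z = 0, label = "") {
  stopifnot(inherits(grid, "optical_grid"))
  if (is.numeric(values)) values <- values + 0i
  stopifnot(is.complex(values), is.matrix(values))
  if (nrow(values) != grid$n_x || ncol(values) != grid$n_y)
    stop("values must be a ", grid$n_x, " x ", grid$n_y, " matrix")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  structure(list(values = values, grid = grid, plane_z = plane_z,
                 label = label),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d at z = %.4g um%s, energy %.4g\n",
              nrow(x$values), ncol(x$values), x$plane_z,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              field_energy(x)))
  invisible(x)
}

#' Total field energy
#'
#' Sum of squared moduli over the grid (the discrete version of the integral
#' of the intensity, up to the constant pixel area).
#' @param field a [complex_field()] or complex matrix.
#' @return non-negative scalar.
#' @export
field_energy <- function(field) {
  v <- if (inherits(field, "complex_field")) field$values else field
  sum(Mod(v)^2)
}

field_values <- function(field) {
  if (inherits(field, "complex_field")) field$values else field
}
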