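#' File formats
#'
#' All artifacts are written as self-describing bundle directories: 32-bit
#' float TIFF images plus a JSON sidecar and CSV tables. TIFF pages are
#' stored normalized to [0, 1] with per-page `scale`/`offset` recorded in the
#' sidecar (the float TIFF writer preserves only that range), giving ~1e-7
#' relative round-trip precision. Complex fields are stored as paired
#' real/imag pages.
#'
#' @name holoscatter-io
#' @keywords internal
NULL

# --- low-level helpers ------------------------------------------------------

write_pages_tiff <- function(pages, path) {
  norm <- lapply(pages, function(p) {
    lo <- min(p); hi <- max(p)
    sc <- if (hi > lo) hi - lo else 1
    list(page = (p - lo) / sc, offset = lo, scale = sc)
  })
  tiff::writeTIFF(lapply(norm, `[[`, "page"), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  list(offset = vapply(norm, `[[`, numeric(1), "offset"),
       scale = vapply(norm, `[[`, numeric(1), "scale"))
}

read_pages_tiff <- function(path, offset, scale) {
  if (!file.exists(path)) stop("missing file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(offset))
    stop("page count mismatch in ", path)
  lapply(seq_along(pages), function(i) pages[[i]] * scale[i] + offset[i])
}

grid_to_list <- function(g) {
  list(n_x = g$n_x, n_y = g$n_y, pitch = g$pitch,
       wavelength = g$wavelength, na_max = g$na_max)
}

grid_from_list <- function(l) {
  optical_grid(l$n_x, l$n_y, l$pitch, l$wavelength, l$na_max)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_json_file <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# complex matrices <-> interleaved real/imag page list
complex_to_pages <- function(mats) {
  out <- list()
  for (m in mats) { out <- c(out, list(Re(m), Im(m))) }
  out
}

pages_to_complex <- function(pages) {
  n <- length(pages) / 2
  lapply(seq_len(n), function(i) {
    pages[[2 * i - 1]] + 1i * pages[[2 * i]]
  })
}

# --- measurement bundle -----------------------------------------------------

#' Read and write measurement bundles
#'
#' A bundle directory holds `images.tif` (M intensity pages), `masks.tif`
#' (M phase pages, radians), `meta.json` (grid, geometry, noise record,
#' per-page scales) and, when available, `sources.csv` with the ground-truth
#' source table. Round trips are loss-free to ~1e-7 relative for
#' floating-point data. Reading validates the schema (mask unit modulus is
#' implied by storing phases; image non-negativity and page counts are
#' checked) and reports offending files by name.
#'
#' @param measurements a [simulate_measurements()] result.
#' @param dir bundle directory (created if needed).
#' @return `write_measurement_bundle` returns `dir`;
#'   `read_measurement_bundle` a `speckle_measurements` object (without the
#'   ground-truth fields).
#' @export
write_measurement_bundle <- function(measurements, dir) {
  stopifnot(inherits(measurements, "speckle_measurements"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- dim(measurements$images)[3]
  ipages <- lapply(seq_len(M), function(m) measurements$images[, , m])
  isc <- write_pages_tiff(ipages, file.path(dir, "images.tif"))
  mpages <- lapply(seq_len(M), function(m) Arg(measurements$masks$values[, , m]))
  msc <- write_pages_tiff(mpages, file.path(dir, "masks.tif"))
  meta <- list(kind = "speckle_measurements",
               grid = grid_to_list(measurements$grid),
               geometry = measurements$geometry,
               noise = measurements$noise,
               mask_macropixel = measurements$masks$macropixel,
               mask_seed = measurements$masks$seed,
               n_images = M,
               images_tiff = isc, masks_tiff = msc)
  write_json_file(meta, file.path(dir, "meta.json"))
  if (!is.null(measurements$sources))
    write_point_sources(measurements$sources, file.path(dir, "sources.csv"))
  invisible(dir)
}

#' @rdname write_measurement_bundle
#' @export
read_measurement_bundle <- function(dir) {
  meta <- read_json_file(file.path(dir, "meta.json"))
  if (is.null(meta$kind) || meta$kind != "speckle_measurements")
    stop("meta.json: not a measurement bundle (field 'kind')")
  grid <- grid_from_list(meta$grid)
  ipages <- read_pages_tiff(file.path(dir, "images.tif"),
                            meta$images_tiff$offset, meta$images_tiff$scale)
  mpages <- read_pages_tiff(file.path(dir, "masks.tif"),
                            meta$masks_tiff$offset, meta$masks_tiff$scale)
  M <- meta$n_images
  if (length(ipages) != M) stop("images.tif: expected ", M, " pages")
  if (length(mpages) != M) stop("masks.tif: expected ", M, " pages")
  images <- array(0, c(grid$n_x, grid$n_y, M))
  mvals <- array(0i, c(grid$n_x, grid$n_y, M))
  for (m in seq_len(M)) {
    img <- ipages[[m]]
    if (!all(dim(img) == c(grid$n_x, grid$n_y)))
      stop("images.tif page ", m, ": wrong dimensions")
    if (min(img) < -1e-9 * max(abs(img)))
      stop("images.tif page ", m, ": negative intensities")
    images[, , m] <- pmax(img, 0)
    K <- exp(1i * mpages[[m]])
    if (max(abs(Mod(K) - 1)) > 1e-6)
      stop("masks.tif page ", m, ": |K| != 1")
    mvals[, , m] <- K
  }
  masks <- structure(list(values = mvals, grid = grid, count = M,
                          macropixel = meta$mask_macropixel %||% NA_integer_,
                          seed = meta$mask_seed %||% NA_integer_),
                     class = "mask_set")
  sources <- NULL
  if (file.exists(file.path(dir, "sources.csv")))
    sources <- read_point_sources(file.path(dir, "sources.csv"))
  structure(list(images = images, masks = masks, grid = grid,
                 geometry = meta$geometry, noise = meta$noise,
                 sources = sources, truth = NULL),
            class = "speckle_measurements")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- field sets -------------------------------------------------------------

#' Read and write retrieved field sets
#'
#' `fields.tif` holds interleaved real/imag 32-bit pages; `meta.json` the
#' grid, plane and per-page scales; `residuals.csv` an optional convergence
#' trace.
#' @param fields a [retrieved_fields()].
#' @param dir bundle directory.
#' @param trace optional `convergence_trace` to store alongside.
#' @export
write_field_set <- function(fields, dir, trace = NULL) {
  stopifnot(inherits(fields, "retrieved_fields"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- write_pages_tiff(complex_to_pages(fields$fields),
                         file.path(dir, "fields.tif"))
  meta <- list(kind = "retrieved_fields", grid = grid_to_list(fields$grid),
               plane_z = fields$plane_z, label = fields$label,
               n_fields = length(fields$fields), fields_tiff = sc)
  write_json_file(meta, file.path(dir, "meta.json"))
  if (!is.null(trace))
    utils::write.csv(data.frame(epoch = seq_along(trace$residuals),
                                residual = trace$residuals),
                     file.path(dir, "residuals.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_field_set
#' @export
read_field_set <- function(dir) {
  meta <- read_json_file(file.path(dir, "meta.json"))
  if (is.null(meta$kind) || meta$kind != "retrieved_fields")
    stop("meta.json: not a field-set bundle (field 'kind')")
  pages <- read_pages_tiff(file.path(dir, "fields.tif"),
                           meta$fields_tiff$offset, meta$fields_tiff$scale)
  mats <- pages_to_complex(pages)
  if (length(mats) != meta$n_fields)
    stop("fields.tif: expected ", meta$n_fields, " complex fields")
  retrieved_fields(mats, grid_from_list(meta$grid), plane_z = meta$plane_z,
                   label = meta$label %||% "")
}

# --- virtual medium ---------------------------------------------------------

#' Read and write virtual media
#'
#' `phase.tif` (radians), `meta.json` (grid, plane, reference),
#' `provenance.csv` (admission table).
#' @param medium a [build_virtual_medium()] result.
#' @param dir bundle directory.
#' @export
write_virtual_medium <- function(medium, dir) {
  stopifnot(inherits(medium, "virtual_medium"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- write_pages_tiff(list(medium$phase), file.path(dir, "phase.tif"))
  meta <- list(kind = "virtual_medium", grid = grid_to_list(medium$grid),
               plane_z = medium$plane_z, reference = medium$reference,
               model = medium$model, excluded = medium$excluded,
               phase_tiff = sc)
  write_json_file(meta, file.path(dir, "meta.json"))
  utils::write.csv(medium$provenance, file.path(dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_virtual_medium
#' @export
read_virtual_medium <- function(dir) {
  meta <- read_json_file(file.path(dir, "meta.json"))
  if (is.null(meta$kind) || meta$kind != "virtual_medium")
    stop("meta.json: not a virtual-medium bundle (field 'kind')")
  ph <- read_pages_tiff(file.path(dir, "phase.tif"),
                        meta$phase_tiff$offset, meta$phase_tiff$scale)[[1]]
  prov <- utils::read.csv(file.path(dir, "provenance.csv"))
  new_virtual_medium(ph, grid_from_list(meta$grid), meta$plane_z,
                     meta$reference, prov,
                     as.integer(meta$excluded %||% integer(0)),
                     meta$model %||% "linear")
}

# --- reconstruction stack ---------------------------------------------------

#' Read and write reconstruction stacks
#'
#' Multi-page intensity TIFF (one page per z) plus JSON z axis and grid.
#' @param stack a [reconstruct_volume()] result.
#' @param dir bundle directory.
#' @export
write_reconstruction <- function(stack, dir) {
  stopifnot(inherits(stack, "reconstruction_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- length(stack$z)
  sc <- write_pages_tiff(lapply(seq_len(nz),
                                function(i) stack$intensity[, , i]),
                         file.path(dir, "intensity.tif"))
  meta <- list(kind = "reconstruction_stack",
               grid = grid_to_list(stack$grid), z = stack$z,
               provenance = stack$provenance, intensity_tiff = sc)
  write_json_file(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_reconstruction
#' @export
read_reconstruction <- function(dir) {
  meta <- read_json_file(file.path(dir, "meta.json"))
  if (is.null(meta$kind) || meta$kind != "reconstruction_stack")
    stop("meta.json: not a reconstruction bundle (field 'kind')")
  grid <- grid_from_list(meta$grid)
  pages <- read_pages_tiff(file.path(dir, "intensity.tif"),
                           meta$intensity_tiff$offset,
                           meta$intensity_tiff$scale)
  v <- array(0, c(grid$n_x, grid$n_y, length(pages)))
  for (i in seq_along(pages)) v[, , i] <- pmax(pages[[i]], 0)
  structure(list(intensity = v, z = as.numeric(meta$z), grid = grid,
                 provenance = meta$provenance),
            class = "reconstruction_stack")
}

# --- complex field (single) -------------------------------------------------

#' Read and write a single complex field
#'
#' Paired real/imag 32-bit TIFF pages plus JSON metadata (grid, plane,
#' label).
#' @param field a [complex_field()].
#' @param path base path; `.tif` and `.json` files are written.
#' @export
write_complex_field <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  sc <- write_pages_tiff(list(Re(field$values), Im(field$values)),
                         paste0(path, ".tif"))
  write_json_file(list(kind = "complex_field",
                       grid = grid_to_list(field$grid),
                       plane_z = field$plane_z, label = field$label,
                       tiff = sc),
                  paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_complex_field
#' @export
read_complex_field <- function(path) {
  meta <- read_json_file(paste0(path, ".json"))
  if (is.null(meta$kind) || meta$kind != "complex_field")
    stop(path, ".json: not a complex-field file")
  pages <- read_pages_tiff(paste0(path, ".tif"), meta$tiff$offset,
                           meta$tiff$scale)
  complex_field(pages[[1]] + 1i * pages[[2]], grid_from_list(meta$grid),
                plane_z = meta$plane_z, label = meta$label %||% "")
}
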