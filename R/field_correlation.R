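#' Shift/tilt correlation between two scattered fields
#'
#' The discrete correlation
#' `C(dr, dk) = sum_r E_n(r - dr) conj(E_m(r)) exp(i dk . r)`, the quantity
#' whose maximum over shift and tilt expresses the optical memory effect of
#' forward-scattering layers. Sub-pixel shifts are realized by Fourier
#' interpolation.
#'
#' @param E_n,E_m [complex_field()]s on one grid.
#' @param shift lateral shift `dr = c(dx, dy)` (um).
#' @param tilt wavefront tilt `dk = c(dkx, dky)` (rad/um).
#' @return complex scalar. For `n = m`, zero shift and tilt it equals the
#'   total field energy.
#' @export
shift_tilt_correlation <- function(E_n, E_m, shift = c(0, 0), tilt = c(0, 0)) {
  stopifnot(inherits(E_n, "complex_field"), inherits(E_m, "complex_field"))
  g <- E_n$grid
  if (!grids_compatible(g, E_m$grid)) stop("fields must share one grid")
  if (abs(shift[1]) > g$n_x * g$pitch || abs(shift[2]) > g$n_y * g$pitch)
    stop("shift beyond grid extent")
  v <- E_n$values
  if (any(shift != 0)) {
    ramp <- exp(-1i * outer(grid_kx(g) * shift[1], grid_ky(g) * shift[2], "+"))
    v <- ift2(ft2(v) * ramp)
  }
  phase <- exp(1i * outer(grid_x(g) * tilt[1], grid_y(g) * tilt[2], "+"))
  sum(v * Conj(E_m$values) * phase)
}

#' All-tilt correlation maps for a field set
#'
#' For each ordered pair (n, m), the tilt correlation for every tilt at
#' once: the centred Fourier transform of the product `E_n conj(E_m)`,
#' scaled so the map value at bin dk equals
#' `sum_r E_n conj(E_m) exp(-i dk . r)`. The peak location is the optimal
#' aligning tilt `dk_opt` (the ramp with `E_n ~ E_m exp(i dk_opt . r)`) and
#' the peak magnitude is `max |C|`.
#'
#' @param fields a [retrieved_fields()] at a common plane.
#' @param pairs optional 2-column matrix of (n, m) index pairs; default all
#'   ordered pairs including n = m.
#' @return list with `maps` (complex array `c(n_x, n_y, npairs)`), `pairs`,
#'   and `kx`, `ky` tilt axes (rad/um).
#' @export
tilt_correlation_map <- function(fields, pairs = NULL) {
  stopifnot(inherits(fields, "retrieved_fields"))
  N <- length(fields$fields)
  if (is.null(pairs))
    pairs <- as.matrix(expand.grid(n = seq_len(N), m = seq_len(N)))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  g <- fields$grid
  P <- g$n_x * g$n_y
  maps <- array(0i, c(g$n_x, g$n_y, nrow(pairs)))
  for (k in seq_len(nrow(pairs))) {
    prod_nm <- fields$fields[[pairs[k, 1]]] * Conj(fields$fields[[pairs[k, 2]]])
    maps[, , k] <- ft2(prod_nm) * sqrt(P)
  }
  list(maps = maps, pairs = pairs, kx = grid_kx(g), ky = grid_ky(g))
}

#' Pairwise tilt-correlation volume over candidate planes
#'
#' For each candidate propagation distance z, all fields are propagated and
#' the squared magnitudes of every pairwise tilt-correlation map are
#' accumulated:
#' `Gamma(r, z) = sum_{n,m} |FT[conj(P_z E_n) P_z E_m](r)|^2`.
#' The double sum includes the n = m terms; their autocorrelation peak at
#' r = 0 is removed downstream by the exclusion disk of
#' [locate_correlation_plane()].
#'
#' @param fields a [retrieved_fields()] (>= 2 fields).
#' @param z_candidates candidate distances (um, toward the detector).
#' @param exclusion_radius radius (pixels) of the r = 0 disk recorded for
#'   downstream masking.
#' @return An object of class `correlation_volume`: `gamma` array
#'   `c(n_x, n_y, nz)`, `z` axis, `exclusion_radius`, `grid`.
#' @export
correlation_volume <- function(fields, z_candidates, exclusion_radius = 3) {
  stopifnot(inherits(fields, "retrieved_fields"))
  N <- length(fields$fields)
  if (N < 2) stop("plane localization needs at least 2 fields")
  stopifnot(length(z_candidates) >= 1)
  g <- fields$grid
  gam <- array(0, c(g$n_x, g$n_y, length(z_candidates)))
  spectra <- lapply(fields$fields, ft2)
  for (iz in seq_along(z_candidates)) {
    H <- as_transfer(g, z_candidates[iz])
    prop <- lapply(spectra, function(s) ift2(s * H))
    acc <- matrix(0, g$n_x, g$n_y)
    for (n in seq_len(N)) for (m in seq_len(N)) {
      acc <- acc + Mod(ft2(Conj(prop[[n]]) * prop[[m]]))^2
    }
    gam[, , iz] <- acc
  }
  structure(list(gamma = gam, z = z_candidates,
                 exclusion_radius = exclusion_radius, grid = g),
            class = "correlation_volume")
}

#' @export
print.correlation_volume <- function(x, ...) {
  cat(sprintf("<correlation_volume> %d plane(s) in [%.4g, %.4g] um\n",
              length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

# logical mask, TRUE outside the centred exclusion disk (radius <= 0: none)
exclusion_ok <- function(n1, n2, radius) {
  if (radius <= 0) return(matrix(TRUE, n1, n2))
  c1 <- n1 %/% 2 + 1L
  c2 <- n2 %/% 2 + 1L
  outer((seq_len(n1) - c1)^2, (seq_len(n2) - c2)^2, "+") > radius^2
}

#' Locate the internal correlation plane
#'
#' The plane where fields from different sources differ only by a wavefront
#' tilt: `z_hat = argmax_z [ max_{r != 0} Gamma(r, z) ]`, with a disk of
#' `exclusion_radius` pixels around r = 0 masked to eliminate the
#' autocorrelation contribution. The confidence ratio is the winning peak
#' value divided by the median over z; profiles flatter than 1.05 are flagged
#' as unlocalized.
#'
#' @param volume a [correlation_volume()].
#' @return list with `z_hat` (um), `confidence`, `localized` (logical), and
#'   the per-z peak `profile`.
#' @export
locate_correlation_plane <- function(volume) {
  stopifnot(inherits(volume, "correlation_volume"))
  if (length(volume$z) < 2) stop("need at least 2 z candidates")
  ok <- exclusion_ok(dim(volume$gamma)[1], dim(volume$gamma)[2],
                     volume$exclusion_radius)
  profile <- apply(volume$gamma, 3, function(sl) max(sl[ok]))
  iz <- which.max(profile)
  confidence <- profile[iz] / stats::median(profile)
  localized <- is.finite(confidence) && confidence >= 1.05
  if (!localized)
    warning("flat correlation profile (confidence ",
            format(confidence, digits = 4), "): plane not localized")
  list(z_hat = volume$z[iz], confidence = confidence, localized = localized,
       profile = profile)
}

#' Tile layout for local demixing
#'
#' Divides the field of view into `rows x cols` partially overlapping
#' rectangular tiles. Window sizes are chosen so the tiles cover every pixel
#' and adjacent tiles overlap by `overlap` of the window size; cosine-taper
#' apodization weights are attached for stitching.
#'
#' @param grid an [optical_grid()].
#' @param rows,cols tile grid counts.
#' @param overlap overlap fraction in [0, 0.5).
#' @return An object of class `tile_layout`: list of tiles with pixel windows
#'   `xs`, `ys` and taper weight matrices.
#' @export
tile_layout <- function(grid, rows = 3, cols = 3, overlap = 0.25) {
  stopifnot(inherits(grid, "optical_grid"), rows >= 1, cols >= 1,
            overlap >= 0, overlap < 0.5)
  win <- function(n, k) {
    if (k == 1) return(list(list(lo = 1L, hi = n)))
    w <- ceiling(n / (k - (k - 1) * overlap))
    step <- (n - w) / (k - 1)
    lapply(seq_len(k), function(i) {
      lo <- round(1 + (i - 1) * step)
      list(lo = as.integer(lo), hi = as.integer(min(lo + w - 1, n)))
    })
  }
  wx <- win(grid$n_x, cols)
  wy <- win(grid$n_y, rows)
  taper1 <- function(lo, hi, n) {
    m <- hi - lo + 1
    ov <- max(1, round(m * overlap))
    w <- rep(1, m)
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(ov) - 0.5) / ov)
    if (lo > 1) w[seq_len(ov)] <- ramp
    if (hi < n) w[m + 1 - seq_len(ov)] <- ramp
    w
  }
  tiles <- list()
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    tx <- wx[[cc]]; ty <- wy[[r]]
    tiles[[length(tiles) + 1]] <- list(
      row = r, col = cc,
      xs = tx$lo:tx$hi, ys = ty$lo:ty$hi,
      taper = outer(taper1(tx$lo, tx$hi, grid$n_x),
                    taper1(ty$lo, ty$hi, grid$n_y)))
  }
  structure(list(tiles = tiles, rows = rows, cols = cols, overlap = overlap,
                 grid = grid),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf("<tile_layout> %d x %d tiles, overlap %.0f%%\n",
              x$rows, x$cols, 100 * x$overlap))
  invisible(x)
}

# random unitary matrix (QR of a Ginibre matrix with phase fix)
random_unitary <- function(N) {
  Z <- matrix(complex(real = stats::rnorm(N * N),
                      imaginary = stats::rnorm(N * N)), N, N)
  qrz <- qr(Z)
  Q <- qr.Q(qrz)
  d <- diag(qr.R(qrz))
  Q %*% diag(d / Mod(d), N)
}

# polar retraction onto the unitary group
polar_unitary <- function(A) {
  s <- svd(A)
  s$u %*% Conj(t(s$v))
}

unitarity_error <- function(U) {
  N <- nrow(U)
  max(Mod(U %*% Conj(t(U)) - diag(N)))
}

# apply U (rows index output fields) to a field list
mix_fields <- function(fields, U) {
  N <- length(fields)
  out <- vector("list", nrow(U))
  for (n in seq_len(nrow(U))) {
    acc <- matrix(0i, nrow(fields[[1]]), ncol(fields[[1]]))
    for (m in seq_len(N)) acc <- acc + U[n, m] * fields[[m]]
    out[[n]] <- acc
  }
  out
}

#' Demix the unitary ambiguity of retrieved fields
#'
#' Phase retrieval determines incoherent fields only up to a unitary mixture.
#' At the correlation plane, fields of individual sources differ pairwise by
#' a single (locally linear) phase ramp, so their pairwise products have
#' sharply peaked Fourier transforms, while mixtures spread that energy. The
#' demixing metric
#' `M(U) = sum_{n != m} max_{r != 0} |FT[conj(E'_n) E'_m](r)|`,
#' with `E'_n = sum_m U[n, m] E_m`, is ascended over the unitary group by
#' Riemannian gradient ascent: the Euclidean gradient (argmax pixel held
#' fixed within each step) is projected onto the tangent space, a backtracked
#' step is taken, and the iterate is retracted by polar factorization.
#' Ascent starts from the identity plus `restarts - 1` seeded random
#' unitaries; the best run is returned.
#'
#' @param fields a [retrieved_fields()] propagated to the correlation plane.
#' @param seed RNG seed for the random restarts.
#' @param max_iters gradient iterations per restart.
#' @param tol relative metric-improvement stopping threshold.
#' @param restarts number of ascent starts (>= 1; the first is identity).
#' @param exclusion_radius radius (pixels) of the r = 0 disk excluded from
#'   the metric's max.
#' @return list with `U` (the mixing matrix, class `mixing_matrix`), `fields`
#'   (the demixed [retrieved_fields()]), `metric` (final M), `metric_identity`
#'   (M at U = I), `iterations`, `converged`.
#' @export
demix_unitary <- function(fields, seed = 1, max_iters = 200, tol = 1e-7,
                          restarts = 5, exclusion_radius = 3) {
  stopifnot(inherits(fields, "retrieved_fields"))
  N <- length(fields$fields)
  g <- fields$grid
  E <- fields_array(fields)
  dims <- c(g$n_x, g$n_y, N)
  metric_of <- function(U) {
    mixed <- array(0i, dims)
    fl <- mix_fields(fields$fields, U)
    for (n in seq_len(N)) mixed[, , n] <- fl[[n]]
    cpp_demix_metric(mixed, dims, exclusion_radius)$M
  }
  if (N == 1) {
    U <- matrix(1 + 0i, 1, 1)
    return(list(U = structure(list(matrix = U, metric = 0, iterations = 0L),
                              class = "mixing_matrix"),
                fields = fields, metric = 0, metric_identity = 0,
                iterations = 0L, converged = TRUE))
  }
  m_id <- metric_of(diag(N) + 0i)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  best <- list(U = diag(N) + 0i, M = m_id, iters = 0L, converged = TRUE)
  for (r in seq_len(max(1, restarts))) {
    U <- if (r == 1) diag(N) + 0i else {
      set.seed(seed + r)
      random_unitary(N)
    }
    Mcur <- metric_of(U)
    step <- NULL
    stall <- 0L
    it <- 0L
    converged <- FALSE
    while (it < max_iters) {
      it <- it + 1L
      gr <- cpp_demix_grad(E, dims, U, exclusion_radius)
      G <- gr$G
      W <- Conj(t(U)) %*% G
      xi <- U %*% ((W - Conj(t(W))) / 2) # tangent direction
      gn <- sqrt(sum(Mod(xi)^2))
      if (gn < 1e-12) { converged <- TRUE; break }
      if (is.null(step)) step <- 0.1 / gn
      improved <- FALSE
      for (bt in 1:30) {
        Utry <- polar_unitary(U + step * xi)
        Mtry <- metric_of(Utry)
        if (Mtry > Mcur) {
          rel <- (Mtry - Mcur) / max(Mcur, 1e-300)
          U <- Utry
          Mcur <- Mtry
          step <- step * 1.5
          improved <- TRUE
          stall <- if (rel < tol) stall + 1L else 0L
          break
        }
        step <- step / 2
      }
      if (!improved || stall >= 3L) { converged <- TRUE; break }
    }
    if (Mcur > best$M)
      best <- list(U = U, M = Mcur, iters = it, converged = converged)
  }
  if (!best$converged)
    warning("demixing did not converge within max_iters; best iterate returned")
  demixed <- retrieved_fields(mix_fields(fields$fields, best$U), g,
                              plane_z = fields$plane_z, label = "demixed")
  list(U = structure(list(matrix = best$U, metric = best$M,
                          iterations = best$iters,
                          unitarity_error = unitarity_error(best$U)),
                     class = "mixing_matrix"),
       fields = demixed, metric = best$M, metric_identity = m_id,
       iterations = best$iters, converged = best$converged)
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat(sprintf(
    "<mixing_matrix> %d x %d, metric %.6g, %d iteration(s), unitarity error %.2g\n",
    nrow(x$matrix), ncol(x$matrix), x$metric, x$iterations,
    x$unitarity_error))
  invisible(x)
}

#' Tile-wise local demixing
#'
#' For 3D objects the pairwise relative phase is quadratic over the full
#' field of view but locally linear, so demixing is run independently on
#' apodized tiles ([tile_layout()]): each tile's windowed fields are tapered
#' and passed to [demix_unitary()]. The per-tile results feed the stitched
#' virtual-medium construction.
#'
#' @param fields a [retrieved_fields()] at the correlation plane.
#' @param layout a [tile_layout()]; tile windows must be at least 16 x 16 px.
#' @param seed,max_iters,tol,restarts,exclusion_radius passed to
#'   [demix_unitary()].
#' @return list of per-tile results (each as [demix_unitary()] plus the tile
#'   window), with the layout attached as attribute `layout`.
#' @export
demix_tiled <- function(fields, layout, seed = 1, max_iters = 200,
                        tol = 1e-7, restarts = 5, exclusion_radius = 3) {
  stopifnot(inherits(fields, "retrieved_fields"),
            inherits(layout, "tile_layout"))
  out <- vector("list", length(layout$tiles))
  for (t in seq_along(layout$tiles)) {
    tl <- layout$tiles[[t]]
    if (length(tl$xs) < 16 || length(tl$ys) < 16)
      stop("tile ", t, " smaller than 16 x 16 px")
    sub <- optical_grid(length(tl$xs), length(tl$ys), fields$grid$pitch,
                        fields$grid$wavelength, fields$grid$na_max)
    cut <- lapply(fields$fields,
                  function(f) f[tl$xs, tl$ys] * tl$taper)
    subfields <- retrieved_fields(cut, sub, plane_z = fields$plane_z,
                                  label = paste0(fields$label, ":tile", t))
    res <- demix_unitary(subfields, seed = seed + t, max_iters = max_iters,
                         tol = tol, restarts = restarts,
                         exclusion_radius = exclusion_radius)
    res$tile <- tl
    out[[t]] <- res
  }
  attr(out, "layout") <- layout
  out
}
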