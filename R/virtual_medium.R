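#' Estimate the pairwise relative phase between two demixed fields
#'
#' At the correlation plane the fields of two sources share the layer's
#' distortion, so `conj(E_n) E_m` is (approximately) a pure phase
#' `exp(i Phi_nm)`: a tilt for laterally separated co-planar sources, plus a
#' defocus-like quadratic term when the sources sit at different depths.
#'
#' The `linear` model locates the sub-pixel peak of `FT[conj(E_n) E_m]`
#' (3-point quadratic interpolation around the argmax bin) and returns
#' `Phi = dk . r + phi0`. The `quadratic` model removes the best tilt, finds
#' the isotropic curvature maximizing phasor concentration by a 1-D search,
#' then refines all degree-2 polynomial coefficients by a magnitude-weighted
#' least-squares fit to the (mild) residual phase of the Gaussian-smoothed
#' product. Fit quality is the magnitude-weighted circular residual
#' `1 - |sum w exp(i(arg(prod) - Phi))| / sum w` (0 = perfect).
#'
#' At high NA and wide fields of view the exact two-source phase difference
#' `k0 (sqrt(z^2 + |r - r_n|^2) - sqrt(z^2 + |r - r_m|^2))` carries
#' non-paraxial terms beyond any degree-2 polynomial (several radians at
#' NA 0.35 over an ~80 um field). When `refine_sigma > 0` the polynomial
#' estimate is therefore corrected by the phase of the Gaussian-smoothed
#' residual phasor `prod * exp(-i Phi_poly)` — a smooth, non-parametric
#' refinement that tracks the true aberration landscape while averaging
#' speckle-scale retrieval noise. Set `refine_sigma = 0` for the pure
#' polynomial models.
#'
#' @param E_n,E_m [complex_field()]s (or bare matrices with `grid` supplied)
#'   at the correlation plane.
#' @param model `"linear"` or `"quadratic"`.
#' @param grid grid to use when bare matrices are given.
#' @param smooth_sigma Gaussian smoothing (pixels) of the product before the
#'   quadratic fit.
#' @param refine_sigma Gaussian width (pixels) of the non-parametric
#'   residual-phase refinement; 0 disables it.
#' @param overlap_threshold minimum `||conj(E_n) E_m||_1` relative to
#'   `||E_n|| ||E_m||` below which the pair is rejected for insufficient
#'   spatial overlap.
#' @return list with `phi` (phase map, radians), `kx`, `ky` (tilt, rad/um),
#'   `curvature` (mean quadratic coefficient, rad/um^2; 0 for linear),
#'   `coefficients`, and `fit_residual`.
#' @export
estimate_relative_phase <- function(E_n, E_m, model = c("linear", "quadratic"),
                                    grid = NULL, smooth_sigma = 2,
                                    refine_sigma = 1.5,
                                    overlap_threshold = 0.02) {
  model <- match.arg(model)
  if (inherits(E_n, "complex_field")) { grid <- E_n$grid; E_n <- E_n$values }
  if (inherits(E_m, "complex_field")) { grid <- E_m$grid; E_m <- E_m$values }
  stopifnot(inherits(grid, "optical_grid"), is.matrix(E_n), is.matrix(E_m),
            all(dim(E_n) == dim(E_m)))
  prod_nm <- Conj(E_n) * E_m
  nrg <- sqrt(field_energy(E_n) * field_energy(E_m))
  if (nrg == 0 || sum(Mod(prod_nm)) < overlap_threshold * nrg)
    stop("insufficient overlap between the fields")
  X <- matrix(grid_x(grid), grid$n_x, grid$n_y)
  Y <- matrix(grid_y(grid), grid$n_x, grid$n_y, byrow = TRUE)

  dkx <- 2 * pi / (grid$n_x * grid$pitch)
  dky <- 2 * pi / (grid$n_y * grid$pitch)
  tilt_at <- function(map) {
    # forward kernel exp(-i k.r): a product exp(i q.r) peaks at bin k = +q
    pk <- subpixel_peak(Mod(map))
    c((pk[1] - (grid$n_x %/% 2 + 1)) * dkx,
      (pk[2] - (grid$n_y %/% 2 + 1)) * dky)
  }
  coefs <- c(phi0 = 0, kx = 0, ky = 0, cxx = 0, cyy = 0, cxy = 0)

  if (model == "quadratic") {
    ps <- gaussian_blur(prod_nm, smooth_sigma)
    r2 <- X^2 + Y^2
    # joint curvature/tilt search: under strong defocus the correlation
    # peak is a broad chirp blob and a tilt-first estimate fails, so scan
    # the isotropic curvature and score each candidate by the peak of the
    # de-chirped tilt map, then refine by golden-section
    amax <- pi / (2 * max(abs(X)) * grid$pitch)
    conc <- function(a) max(Mod(ft2(ps * exp(-1i * a * r2))))
    a_grid <- seq(-amax, amax, length.out = 81)
    a0 <- a_grid[which.max(vapply(a_grid, conc, numeric(1)))]
    opt <- stats::optimize(conc, c(a0 - 2 * amax / 80, a0 + 2 * amax / 80),
                           maximum = TRUE)
    a0 <- opt$maximum
    k_est <- tilt_at(ft2(ps * exp(-1i * a0 * r2)))
    kx <- k_est[1]; ky <- k_est[2]
    phi <- kx * X + ky * Y
    # weighted LS on the residual phase (now mild, no wrapping)
    rem <- ps * exp(-1i * (phi + a0 * r2))
    w <- Mod(rem)
    th <- Arg(rem)
    A <- cbind(1, c(X), c(Y), c(X^2), c(Y^2), c(X * Y))
    wl <- c(w)
    fit <- stats::lm.wfit(A, c(th), wl)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coefs <- c(phi0 = cf[1], kx = kx + cf[2], ky = ky + cf[3],
               cxx = a0 + cf[4], cyy = a0 + cf[5], cxy = cf[6])
    names(coefs) <- c("phi0", "kx", "ky", "cxx", "cyy", "cxy")
    phi <- coefs["phi0"] + coefs["kx"] * X + coefs["ky"] * Y +
      coefs["cxx"] * X^2 + coefs["cyy"] * Y^2 + coefs["cxy"] * X * Y
  } else {
    k_est <- tilt_at(ft2(prod_nm))
    kx <- k_est[1]; ky <- k_est[2]
    phi <- kx * X + ky * Y
    coefs["kx"] <- kx; coefs["ky"] <- ky
    # residual global phase
    coefs["phi0"] <- Arg(sum(prod_nm * exp(-1i * phi)))
    phi <- phi + coefs["phi0"]
  }
  if (refine_sigma > 0) {
    q <- gaussian_blur(prod_nm * exp(-1i * phi), refine_sigma)
    corr <- Arg(q)
    corr[Mod(q) < 1e-12 * max(Mod(q))] <- 0
    phi <- phi + corr
  }
  w <- Mod(prod_nm)
  fit_residual <- 1 - Mod(sum(w * exp(1i * (Arg(prod_nm) - phi)))) / sum(w)
  list(phi = phi, kx = unname(coefs["kx"]), ky = unname(coefs["ky"]),
       curvature = unname((coefs["cxx"] + coefs["cyy"]) / 2),
       coefficients = coefs, fit_residual = fit_residual)
}

# 3-point quadratic sub-pixel refinement of the argmax of a non-negative map
subpixel_peak <- function(m) {
  ij <- which(m == max(m), arr.ind = TRUE)[1, ]
  out <- as.numeric(ij)
  for (d in 1:2) {
    i <- ij[d]
    if (i > 1 && i < dim(m)[d]) {
      idx <- function(k) if (d == 1) m[k, ij[2]] else m[ij[1], k]
      f0 <- idx(i); fm <- idx(i - 1); fp <- idx(i + 1)
      den <- fm - 2 * f0 + fp
      if (den < 0) out[d] <- i + 0.5 * (fm - fp) / den
    }
  }
  out
}

# separable Gaussian blur (FFT-based, circular boundary)
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  g1 <- exp(-centered_index(n1)^2 / (2 * sigma^2))
  g2 <- exp(-centered_index(n2)^2 / (2 * sigma^2))
  ker <- outer(g1, g2)
  ker <- ker / sum(ker)
  ift2(ft2(x) * ft2(ker)) * sqrt(n1 * n2)
}

#' Rank field pairs by tilt correlation
#'
#' All ordered pairs (n, m), n != m, ranked by the peak of
#' `|FT[conj(E_n) E_m]|` normalized by the field norms (1 for a duplicated
#' field), descending. Used to seed and order the incremental virtual-medium
#' construction.
#'
#' @param fields a [retrieved_fields()] (>= 2 fields).
#' @param exclusion_radius radius (pixels) of a central disk to exclude from
#'   the peak search (0 = none; ranking only scores distinct pairs, so the
#'   autocorrelation peak is not a concern by default).
#' @return data.frame with columns `n`, `m`, `score`, sorted by decreasing
#'   score.
#' @export
rank_pairs <- function(fields, exclusion_radius = 0) {
  stopifnot(inherits(fields, "retrieved_fields"))
  N <- length(fields$fields)
  if (N < 2) stop("need at least 2 fields")
  g <- fields$grid
  ok <- exclusion_ok(g$n_x, g$n_y, exclusion_radius)
  P <- g$n_x * g$n_y
  nn <- mm <- ss <- numeric(0)
  norms <- vapply(fields$fields, function(f) sqrt(field_energy(f)), numeric(1))
  for (n in seq_len(N)) for (m in seq_len(N)) {
    if (n == m) next
    map <- Mod(ft2(Conj(fields$fields[[n]]) * fields$fields[[m]])) * sqrt(P)
    nn <- c(nn, n); mm <- c(mm, m)
    ss <- c(ss, max(map[ok]) / (norms[n] * norms[m]))
  }
  d <- data.frame(n = nn, m = mm, score = ss)
  d[order(-d$score), , drop = FALSE]
}

#' Virtual scattering medium
#'
#' Builds the unit-modulus virtual layer `S(r) = exp(i arg[sum_n E_n
#' exp(i Phi_n)])` by coherent fusion of the demixed fields at the
#' correlation plane: the reference is the field with the highest total
#' correlation to all others (for extended objects this is the most central
#' source, which minimizes the worst-case off-axis aberration of the
#' holographic reconstruction); its best-correlated peer seeds the running
#' sum, then the remaining fields are admitted in ranking order, each
#' phase-aligned to the running sum with [estimate_relative_phase()]. Fields whose correlation against the running
#' sum falls below `admission_threshold` are excluded and listed. The
#' recovered phase represents the distortion of the physical layer times the
#' reference source's free-space field (`S_o h_m`), which suffices for the
#' holographic compensation.
#'
#' @param fields a [retrieved_fields()] at the correlation plane (>= 2, or a
#'   single field which is returned as its own phase).
#' @param plane_z plane of the medium (um); default the fields' plane.
#' @param model relative-phase model, `"linear"` or `"quadratic"`.
#' @param admission_threshold minimum normalized correlation score.
#' @param reference optional forced reference field index.
#' @param refine_sigma non-parametric residual-phase refinement width
#'   (pixels) passed to [estimate_relative_phase()].
#' @param passes alignment passes. The first pass is the incremental
#'   construction; each further pass re-estimates every admitted field's
#'   phase against the completed unit-modulus medium and re-sums, which
#'   equalizes the alignment quality across fields (early admissions are
#'   otherwise aligned against noisier partial sums).
#' @return An object of class `virtual_medium`: `phase` matrix (radians),
#'   `grid`, `plane_z`, `reference`, `provenance` (admission table),
#'   `excluded`.
#' @export
build_virtual_medium <- function(fields, plane_z = NULL,
                                 model = c("linear", "quadratic"),
                                 admission_threshold = 0.1,
                                 reference = NULL, refine_sigma = 1.5,
                                 passes = 2) {
  model <- match.arg(model)
  stopifnot(inherits(fields, "retrieved_fields"))
  if (is.null(plane_z)) plane_z <- fields$plane_z
  g <- fields$grid
  N <- length(fields$fields)
  if (N == 1) {
    return(new_virtual_medium(Arg(fields$fields[[1]]), g, plane_z, 1L,
                              data.frame(field = 1L, score = 1),
                              integer(0), model))
  }
  rk <- rank_pairs(fields)
  if (rk$score[1] < admission_threshold)
    stop("no field pair above the admission threshold: ",
         "object fields mutually uncorrelated")
  if (is.null(reference)) {
    # reference = field with the highest total correlation to all others
    # (the most central source): minimizes the worst-case tilt relative to
    # the reference and hence the off-axis aberration of the reconstruction
    rowsum <- vapply(seq_len(N),
                     function(n) sum(rk$score[rk$n == n]), numeric(1))
    ref <- which.max(rowsum)
  } else {
    ref <- as.integer(reference)
  }
  peers <- rk[rk$n == ref, , drop = FALSE]
  other <- peers$m[which.max(peers$score)]
  top <- c(ref, other)
  rk_seed <- max(peers$score)
  if (rk_seed < admission_threshold)
    stop("no partner for the reference above the admission threshold")
  est <- estimate_relative_phase(fields$fields[[other]], fields$fields[[ref]],
                                 model = model, grid = g,
                                 refine_sigma = refine_sigma)
  acc <- fields$fields[[ref]] + fields$fields[[other]] * exp(1i * est$phi)
  prov <- data.frame(field = c(ref, other), score = c(1, rk_seed))
  # admit remaining fields in the order of their best score against the seed
  remaining <- setdiff(seq_len(N), top)
  if (length(remaining)) {
    seed_score <- vapply(remaining, function(n) {
      max(rk$score[rk$n == n & rk$m %in% top])
    }, numeric(1))
    remaining <- remaining[order(-seed_score)]
  }
  excluded <- integer(0)
  for (n in remaining) {
    sc <- pair_score(fields$fields[[n]], acc)
    if (!is.finite(sc) || sc < admission_threshold) {
      excluded <- c(excluded, n)
      next
    }
    est <- estimate_relative_phase(fields$fields[[n]], acc, model = model,
                                   grid = g, refine_sigma = refine_sigma)
    acc <- acc + fields$fields[[n]] * exp(1i * est$phi)
    prov <- rbind(prov, data.frame(field = n, score = sc))
  }
  for (p in seq_len(max(0, passes - 1))) {
    sref <- exp(1i * Arg(acc))
    acc2 <- matrix(0i, g$n_x, g$n_y)
    for (n in prov$field) {
      est <- estimate_relative_phase(fields$fields[[n]], sref, model = model,
                                     grid = g, refine_sigma = refine_sigma)
      acc2 <- acc2 + fields$fields[[n]] * exp(1i * est$phi)
    }
    acc <- acc2
  }
  new_virtual_medium(Arg(acc), g, plane_z, ref, prov, excluded, model)
}

# normalized tilt-correlation score between a candidate field and a reference
pair_score <- function(f, ref) {
  P <- length(f)
  nf <- sqrt(field_energy(f) * field_energy(ref))
  if (nf == 0) return(NA_real_)
  max(Mod(ft2(Conj(f) * ref))) * sqrt(P) / nf
}

new_virtual_medium <- function(phase, grid, plane_z, reference, provenance,
                               excluded, model) {
  structure(list(phase = phase, grid = grid, plane_z = plane_z,
                 reference = as.integer(reference), provenance = provenance,
                 excluded = as.integer(excluded), model = model),
            class = "virtual_medium")
}

#' @export
print.virtual_medium <- function(x, ...) {
  cat(sprintf(
    "<virtual_medium> %d x %d at z = %.4g um, reference field %d, %d admitted, %d excluded (%s model)\n",
    nrow(x$phase), ncol(x$phase), x$plane_z, x$reference,
    nrow(x$provenance), length(x$excluded), x$model))
  invisible(x)
}

# unit-modulus transmission of the virtual medium
medium_transmission <- function(medium) exp(1i * medium$phase)

#' Stitch per-tile virtual media into one layer
#'
#' Per-tile media are defined up to their own reference phase; neighbouring
#' tiles are aligned by fitting a wavefront tilt plus constant to the phasor
#' product of the two media over their overlap (two references that are
#' distinct sources differ by a tilt at the correlation plane; when the
#' references agree the fitted tilt is ~0 and this reduces to constant
#' alignment). Tiles are blended with their cosine-taper weights; the result
#' has unit modulus everywhere.
#'
#' @param per_tile_media list of [build_virtual_medium()] results, one per
#'   tile of `layout` (in tile order).
#' @param layout the [tile_layout()] used.
#' @return a [build_virtual_medium()]-style `virtual_medium` on the full
#'   grid.
#' @export
stitch_virtual_medium <- function(per_tile_media, layout) {
  stopifnot(inherits(layout, "tile_layout"))
  tiles <- layout$tiles
  if (length(per_tile_media) != length(tiles))
    stop("need one medium per tile (", length(tiles), ")")
  g <- layout$grid
  accum <- matrix(0i, g$n_x, g$n_y)
  wsum <- matrix(0, g$n_x, g$n_y)
  for (t in seq_along(tiles)) {
    tl <- tiles[[t]]
    med <- per_tile_media[[t]]
    if (is.null(med)) stop("missing medium for tile ", t)
    ph <- med$phase
    if (!all(dim(ph) == c(length(tl$xs), length(tl$ys))))
      stop("tile ", t, " medium does not conform to the layout window")
    z <- exp(1i * ph)
    w <- tl$taper
    ov <- wsum[tl$xs, tl$ys] > 0
    if (any(ov)) {
      # align to the mosaic built so far: tilt + constant on the phasor ratio
      mosaic <- accum[tl$xs, tl$ys]
      q <- matrix(0i, length(tl$xs), length(tl$ys))
      q[ov] <- (mosaic[ov] / pmax(Mod(mosaic[ov]), 1e-300)) * Conj(z[ov])
      # tilt from the circular mean of the per-pixel phase gradient: exact
      # for a constant tilt regardless of the overlap strip's shape (the
      # FT-peak route is too coarse on narrow strips)
      n1 <- length(tl$xs); n2 <- length(tl$ys)
      kx <- Arg(sum(q[-1, ] * Conj(q[-n1, ])))
      ky <- Arg(sum(q[, -1] * Conj(q[, -n2])))
      ramp <- exp(1i * (outer(centered_index(n1) * kx,
                              centered_index(n2) * ky, "+")))
      phi0 <- Arg(sum(q * Conj(ramp)))
      z <- z * ramp * exp(1i * phi0)
    }
    accum[tl$xs, tl$ys] <- accum[tl$xs, tl$ys] + w * z
    wsum[tl$xs, tl$ys] <- wsum[tl$xs, tl$ys] + w
  }
  if (any(wsum == 0)) stop("tile layout does not cover the grid")
  refs <- vapply(per_tile_media, function(m) m$reference, integer(1))
  new_virtual_medium(Arg(accum), g, per_tile_media[[1]]$plane_z,
                     per_tile_media[[1]]$reference,
                     data.frame(field = refs,
                                score = rep(NA_real_, length(refs))),
                     integer(0), per_tile_media[[1]]$model)
}
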