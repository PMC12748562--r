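#' Set of mutually incoherent retrieved fields
#'
#' Container for N complex fields sharing one grid and plane. Phase retrieval
#' from intensity-only data determines such a set only up to a per-field
#' global phase and an N x N unitary mixture; [demix_unitary()] resolves the
#' mixture.
#'
#' @param fields list of complex matrices (all the same dimension).
#' @param grid an [optical_grid()].
#' @param plane_z axial coordinate of the common plane (um).
#' @param label free-text plane label.
#' @return An object of class `retrieved_fields`.
#' @export
retrieved_fields <- function(fields, grid, plane_z = 0, label = "camera") {
  stopifnot(is.list(fields), length(fields) >= 1,
            inherits(grid, "optical_grid"))
  for (f in fields) {
    stopifnot(is.complex(f) || is.numeric(f), is.matrix(f),
              nrow(f) == grid$n_x, ncol(f) == grid$n_y)
    if (!all(is.finite(Re(f))) || !all(is.finite(Im(f))))
      stop("all fields must be finite")
  }
  fields <- lapply(fields, function(f) if (is.numeric(f)) f + 0i else f)
  structure(list(fields = fields, grid = grid, plane_z = plane_z,
                 label = label),
            class = "retrieved_fields")
}

#' @export
print.retrieved_fields <- function(x, ...) {
  cat(sprintf("<retrieved_fields> %d field(s) %d x %d at z = %.4g um [%s]\n",
              length(x$fields), x$grid$n_x, x$grid$n_y, x$plane_z, x$label))
  invisible(x)
}

#' @export
length.retrieved_fields <- function(x) length(x$fields)

# stack the fields into a (n_x, n_y, N) complex array
fields_array <- function(fs) {
  N <- length(fs$fields)
  a <- array(0i, c(fs$grid$n_x, fs$grid$n_y, N))
  for (n in seq_len(N)) a[, , n] <- fs$fields[[n]]
  a
}

# propagate every field by `distance` (um, +z toward the detector)
propagate_fields <- function(fs, distance, label = fs$label) {
  if (distance == 0) return(fs)
  H <- as_transfer(fs$grid, distance)
  out <- lapply(fs$fields, function(f) ift2(ft2(f) * H))
  retrieved_fields(out, fs$grid, plane_z = fs$plane_z + distance,
                   label = label)
}

#' Mixed-state phase retrieval
#'
#' Recovers `n_states` mutually incoherent fields from random-mask modulated
#' intensity images by alternating projections: starting from i.i.d. circular
#' complex Gaussian SLM-plane fields, each mask's modelled camera intensities
#' have their amplitudes replaced by the measured ones,
#' `psi -> sqrt(I_m / sum_n |psi_n|^2) psi_n` (pixels with vanishing model
#' intensity are left unchanged), and the SLM-plane fields are updated as
#' `E~_n = FT[psi_n] conj(K_m)`. One epoch is a cyclic pass over all masks;
#' iteration stops when the relative change of the measurement residual over
#' an epoch falls below `tol` or after `max_iters` epochs.
#'
#' The returned fields live at the camera-conjugate plane. They span the true
#' field subspace but are determined only up to a unitary mixture.
#'
#' @param measurements a [simulate_measurements()] bundle (or a compatible
#'   list read by [read_measurement_bundle()]).
#' @param n_states number of incoherent states to retrieve (>= 1). More
#'   states than sources is tolerated: surplus states decay to low energy and
#'   a warning flags states holding < 1% of the total.
#' @param max_iters maximum epochs.
#' @param tol relative residual-change stopping threshold.
#' @param seed RNG seed for the Gaussian initialization.
#' @param order `"cyclic"` (as printed) or `"random"` mask order per epoch.
#' @return list with `fields` (a [retrieved_fields()]) and `trace` (class
#'   `convergence_trace`: per-epoch residuals, epoch count, stop reason).
#' @export
retrieve_fields <- function(measurements, n_states, max_iters = 500,
                            tol = 1e-6, seed = 1,
                            order = c("cyclic", "random")) {
  order <- match.arg(order)
  stopifnot(n_states >= 1)
  imgs <- measurements$images
  masks <- measurements$masks$values
  stopifnot(length(dim(imgs)) == 3, length(dim(masks)) == 3)
  M <- dim(imgs)[3]
  if (dim(masks)[3] != M) stop("image count must equal mask count")
  if (all(imgs == 0)) stop("measurement stack is identically zero")
  if (any(imgs < 0)) stop("intensity images must be non-negative")
  if (n_states > M)
    warning("n_states exceeds the mask count; retrieval is ill-posed")
  grid <- measurements$grid
  n1 <- grid$n_x; n2 <- grid$n_y
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scale0 <- sqrt(mean(imgs) / n_states)
  Et <- array(complex(real = stats::rnorm(n1 * n2 * n_states),
                      imaginary = stats::rnorm(n1 * n2 * n_states)),
              c(n1, n2, n_states)) * (scale0 / sqrt(2))
  ord <- if (order == "cyclic") seq_len(M) - 1L else sample.int(M) - 1L
  res <- cpp_retrieve(Et, masks, imgs, c(n1, n2, n_states, M),
                      as.integer(max_iters), tol, as.integer(ord))
  Etil <- res$Etilde
  cam <- lapply(seq_len(n_states), function(n) ift2(Etil[, , n]))
  en <- vapply(cam, field_energy, numeric(1))
  weak <- which(en < 0.01 * sum(en))
  if (length(weak))
    warning("state(s) ", paste(weak, collapse = ", "),
            " hold < 1% of the total energy (surplus states?)")
  fields <- retrieved_fields(cam, grid, plane_z = 0, label = "camera")
  trace <- structure(list(residuals = res$residuals, epochs = res$epochs,
                          reason = res$reason),
                     class = "convergence_trace")
  list(fields = fields, trace = trace)
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("<convergence_trace> %d epoch(s), final residual %.4g (%s)\n",
              x$epochs, x$residuals[length(x$residuals)], x$reason))
  invisible(x)
}

#' Measurement-model residual
#'
#' Relative L1 misfit between the intensities modelled from a field set and
#' the measured images:
#' `sum_m || sum_n |IFT[E~_n K_m]|^2 - I_m ||_1 / sum_m ||I_m||_1`.
#' Exactly invariant under any unitary mixing of the fields.
#'
#' @param fields a [retrieved_fields()] at the camera plane.
#' @param measurements the measurement bundle.
#' @return dimensionless scalar (0 for a perfect noiseless fit, 1 for
#'   all-zero fields).
#' @export
measurement_residual <- function(fields, measurements) {
  stopifnot(inherits(fields, "retrieved_fields"))
  if (!grids_compatible(fields$grid, measurements$grid))
    stop("fields and measurements must share one grid")
  Etil <- lapply(fields$fields, ft2)
  imgs <- measurements$images
  M <- dim(imgs)[3]
  num <- 0
  for (m in seq_len(M)) {
    K <- measurements$masks$values[, , m]
    acc <- matrix(0, nrow(K), ncol(K))
    for (Ei in Etil) acc <- acc + Mod(ift2(Ei * K))^2
    num <- num + sum(abs(acc - imgs[, , m]))
  }
  num / sum(abs(imgs))
}
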