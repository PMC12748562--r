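#' Pipeline configuration
#'
#' Assembles and validates the configuration for an end-to-end run:
#' simulate -> retrieve -> locate plane -> demix -> build medium ->
#' reconstruct -> evaluate. Every stochastic stage has an explicit integer
#' seed derived from `seed` unless overridden, so a config fixes every
#' artifact. The configuration round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param object object fixture: `list(type = "beads", n_beads, plane_depths,
#'   min_separation, extent, seed)`, `list(type = "spiral", ...)` (arguments
#'   of [make_spiral_fixture()]), or `list(type = "csv", path)`.
#' @param grid grid parameters `list(n, pitch, wavelength, na_max)`. The
#'   default 128 x 128 at 0.65 um pitch puts the holographic magnification
#'   near 1 at ~100 um working depth.
#' @param na imaging/emission numerical aperture.
#' @param focus_depth camera-conjugate plane depth behind the layer (um);
#'   `NULL` = mean source depth.
#' @param screen scattering layer: `list(correlation_length, strength, seed)`.
#' @param masks SLM masks: `list(count, macropixel, seed)`; `count = NULL`
#'   defaults to 10x the source count.
#' @param noise `list(photon_budget, seed)`; `photon_budget = NULL` is
#'   noiseless.
#' @param retrieval `list(n_states, max_iters, tol, seed)`; `n_states = NULL`
#'   defaults to the source count.
#' @param locate correlation-plane search: `list(z_min, z_max, z_step,
#'   exclusion_radius, max_fields)`; `NULL` bounds default to 0.5x and 1.5x
#'   the focus depth.
#' @param demix `list(mode, rows, cols, overlap, restarts, max_iters, seed)`
#'   with `mode` `"global"` (2D objects) or `"tiled"` (3D objects).
#' @param medium `list(model, admission_threshold, refine_sigma)`.
#' @param reconstruct `list(z_min, z_max, z_step, pad_factor)` in
#'   reconstruction coordinates around the correlation plane.
#' @param detect `list(rel_threshold, merge_radius)`.
#' @param seed master seed for defaulted stage seeds.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(object = list(type = "beads", n_beads = 5,
                                          plane_depths = 100),
                            grid = list(n = 128, pitch = 0.65,
                                        wavelength = 0.55, na_max = 0.42),
                            na = 0.35,
                            focus_depth = NULL,
                            screen = list(), masks = list(), noise = list(),
                            retrieval = list(), locate = list(),
                            demix = list(), medium = list(),
                            reconstruct = list(), detect = list(),
                            seed = 1) {
  seed <- as.integer(seed)
  fill <- function(x, defaults) {
    stopifnot(is.list(x))
    for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
    x
  }
  object <- fill(object, list(type = "beads", n_beads = 5,
                              plane_depths = 100, min_separation = 4,
                              extent = 9, seed = seed + 11L))
  grid <- fill(grid, list(n = 128, pitch = 0.65, wavelength = 0.55,
                          na_max = 0.42))
  screen <- fill(screen, list(correlation_length = 1.5, strength = 8,
                              seed = seed + 101L))
  masks <- fill(masks, list(count = NULL, macropixel = 4, seed = seed + 202L))
  noise <- fill(noise, list(photon_budget = NULL, seed = seed + 303L))
  retrieval <- fill(retrieval, list(n_states = NULL, max_iters = 300,
                                    tol = 1e-9, seed = seed + 404L))
  locate <- fill(locate, list(z_min = NULL, z_max = NULL, z_step = 2,
                              exclusion_radius = 3, max_fields = 6))
  demix <- fill(demix, list(mode = "global", rows = 3, cols = 3,
                            overlap = 0.25, restarts = 3, max_iters = 150,
                            tol = 1e-7, seed = seed + 505L,
                            exclusion_radius = 3))
  medium <- fill(medium, list(model = "linear", admission_threshold = 0.1,
                              refine_sigma = 1.5))
  reconstruct <- fill(reconstruct, list(z_min = -25, z_max = 25, z_step = 1.5,
                                        pad_factor = 2))
  detect <- fill(detect, list(rel_threshold = 0.5, merge_radius = 1.2))
  stopifnot(object$type %in% c("beads", "spiral", "csv"),
            demix$mode %in% c("global", "tiled"),
            medium$model %in% c("linear", "quadratic"))
  structure(list(object = object, grid = grid, na = na,
                 focus_depth = focus_depth, screen = screen, masks = masks,
                 noise = noise, retrieval = retrieval, locate = locate,
                 demix = demix, medium = medium, reconstruct = reconstruct,
                 detect = detect, seed = seed),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %s object, %d x %d grid, NA %.2f, seed %d, %s demixing\n",
              x$object$type, x$grid$n, x$grid$n, x$na, x$seed, x$demix$mode))
  invisible(x)
}

#' Write/read a pipeline configuration (JSON)
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  write_json_file(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- read_json_file(path)
  do.call(pipeline_config, l)
}

config_grid <- function(config) {
  optical_grid(config$grid$n, config$grid$n, config$grid$pitch,
               config$grid$wavelength, config$grid$na_max)
}

config_sources <- function(config) {
  ob <- config$object
  switch(ob$type,
         beads = make_bead_fixture(ob$n_beads, unlist(ob$plane_depths),
                                   ob$min_separation, ob$extent, ob$seed),
         spiral = make_spiral_fixture(
           rho1 = ob$rho1 %||% 10, rho2 = ob$rho2 %||% 6.7,
           n_sources = ob$n_sources %||% 20,
           turns_total_angle = ob$turns_total_angle %||% (4 * pi),
           dz = ob$dz %||% 0.5, z_base = ob$z_base %||% 95),
         csv = read_point_sources(ob$path))
}

plog <- function(verbose, log, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  if (verbose) message(line)
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  invisible(NULL)
}

#' Run the full reconstruction pipeline
#'
#' Executes simulate -> retrieve -> locate plane -> demix -> build medium ->
#' reconstruct -> detect -> calibrate -> evaluate on a seeded synthetic
#' scene, returning every intermediate plus a JSON-able summary. With
#' `out_dir` set, all artifacts are persisted in the module bundle formats
#' plus `summary.json` and a structured `run.log`; a stage failure stops the
#' run with the stage name after persisting completed artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional run directory.
#' @param verbose print per-stage progress.
#' @return An object of class `pipeline_result` (list): `sources`,
#'   `measurements`, `retrieved`, `trace`, `z_hat`, `demix`, `medium`,
#'   `stack`, `detections`, `calibration`, `evaluation`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.json"))
    log <- file.path(out_dir, "run.log")
    cat("", file = log)
  }
  stage <- "simulate"
  result <- new.env(parent = emptyenv())
  tryCatch({
    t0 <- Sys.time()
    g <- config_grid(config)
    sources <- config_sources(config)
    N <- nrow(sources)
    mask_count <- config$masks$count %||% (10L * N)
    focus <- config$focus_depth %||% mean(sources$z_um)
    screen <- make_phase_screen(g, config$screen$correlation_length,
                                config$screen$strength, config$screen$seed)
    masks <- make_masks(g, mask_count, config$masks$macropixel,
                        config$masks$seed)
    meas <- simulate_measurements(sources, screen, masks, g,
                                  focus_depth = focus, na = config$na,
                                  photon_budget = config$noise$photon_budget,
                                  seed = config$noise$seed)
    result$sources <- sources
    result$measurements <- meas
    plog(verbose, log, "simulate: %d sources, %d masks, focus %.5g um (%.1fs)",
         N, mask_count, focus, as.numeric(Sys.time() - t0, units = "secs"))
    if (!is.null(out_dir))
      write_measurement_bundle(meas, file.path(out_dir, "measurements"))

    stage <- "retrieve"
    t0 <- Sys.time()
    n_states <- config$retrieval$n_states %||% N
    ret <- retrieve_fields(meas, n_states, config$retrieval$max_iters,
                           config$retrieval$tol, config$retrieval$seed)
    result$retrieved <- ret$fields
    result$trace <- ret$trace
    plog(verbose, log, "retrieve: %d states, %d epochs, residual %.3g (%.1fs)",
         n_states, ret$trace$epochs, utils::tail(ret$trace$residuals, 1),
         as.numeric(Sys.time() - t0, units = "secs"))
    if (!is.null(out_dir))
      write_field_set(ret$fields, file.path(out_dir, "retrieved"),
                      trace = ret$trace)

    stage <- "locate-plane"
    t0 <- Sys.time()
    zmin <- config$locate$z_min %||% (0.5 * focus)
    zmax <- config$locate$z_max %||% (1.5 * focus)
    loc_fields <- ret$fields
    nf <- min(length(loc_fields$fields), config$locate$max_fields)
    en <- vapply(loc_fields$fields, field_energy, numeric(1))
    keep <- order(-en)[seq_len(nf)]
    loc_fields <- retrieved_fields(loc_fields$fields[keep], loc_fields$grid,
                                   loc_fields$plane_z, loc_fields$label)
    vol <- correlation_volume(loc_fields,
                              seq(zmin, zmax, by = config$locate$z_step),
                              config$locate$exclusion_radius)
    loc <- locate_correlation_plane(vol)
    result$z_hat <- loc$z_hat
    result$locate <- loc
    plog(verbose, log, "locate-plane: z_hat %.5g um, confidence %.3g (%.1fs)",
         loc$z_hat, loc$confidence, as.numeric(Sys.time() - t0, units = "secs"))

    stage <- "demix"
    t0 <- Sys.time()
    fcp <- propagate_fields(ret$fields, loc$z_hat, label = "correlation-plane")
    if (config$demix$mode == "global") {
      dm <- demix_unitary(fcp, seed = config$demix$seed,
                          max_iters = config$demix$max_iters,
                          tol = config$demix$tol,
                          restarts = config$demix$restarts,
                          exclusion_radius = config$demix$exclusion_radius)
      result$demix <- dm
      plog(verbose, log, "demix (global): metric %.5g (identity %.5g), %d iters (%.1fs)",
           dm$metric, dm$metric_identity, dm$iterations,
           as.numeric(Sys.time() - t0, units = "secs"))
    } else {
      layout <- tile_layout(fcp$grid, config$demix$rows, config$demix$cols,
                            config$demix$overlap)
      dm <- demix_tiled(fcp, layout, seed = config$demix$seed,
                        max_iters = config$demix$max_iters,
                        tol = config$demix$tol,
                        restarts = config$demix$restarts,
                        exclusion_radius = config$demix$exclusion_radius)
      result$demix <- dm
      plog(verbose, log, "demix (tiled %dx%d): mean metric gain %.3g (%.1fs)",
           config$demix$rows, config$demix$cols,
           mean(vapply(dm, function(r)
             r$metric / max(r$metric_identity, 1e-300), numeric(1))),
           as.numeric(Sys.time() - t0, units = "secs"))
    }

    stage <- "build-medium"
    t0 <- Sys.time()
    if (config$demix$mode == "global") {
      med <- build_virtual_medium(result$demix$fields,
                                  model = config$medium$model,
                                  admission_threshold =
                                    config$medium$admission_threshold,
                                  refine_sigma = config$medium$refine_sigma)
    } else {
      layout <- attr(result$demix, "layout")
      media <- lapply(result$demix, function(r)
        build_virtual_medium(r$fields, model = config$medium$model,
                             admission_threshold =
                               config$medium$admission_threshold,
                             refine_sigma = config$medium$refine_sigma))
      med <- stitch_virtual_medium(media, layout)
    }
    result$medium <- med
    plog(verbose, log, "build-medium: reference %d, %d admitted (%.1fs)",
         med$reference, nrow(med$provenance),
         as.numeric(Sys.time() - t0, units = "secs"))
    if (!is.null(out_dir))
      write_virtual_medium(med, file.path(out_dir, "medium"))

    stage <- "reconstruct"
    t0 <- Sys.time()
    zs <- seq(config$reconstruct$z_min, config$reconstruct$z_max,
              by = config$reconstruct$z_step)
    stk <- reconstruct_volume(fcp, med, zs, config$reconstruct$pad_factor)
    result$stack <- stk
    plog(verbose, log, "reconstruct: %d planes, peak %.4g (%.1fs)",
         length(zs), max(stk$intensity),
         as.numeric(Sys.time() - t0, units = "secs"))
    if (!is.null(out_dir))
      write_reconstruction(stk, file.path(out_dir, "reconstruction"))

    stage <- "evaluate"
    t0 <- Sys.time()
    det <- detect_sources(stk, config$detect$rel_threshold,
                          config$detect$merge_radius)
    result$detections <- det
    ev <- evaluate_reconstruction(stk, det, sources, config)
    result$calibration <- ev$calibration
    result$evaluation <- ev
    plog(verbose, log, "evaluate: %d detections, PSNR %.4g dB, SSIM %.4g (%.1fs)",
         nrow(det), ev$psnr_db %||% NA, ev$ssim %||% NA,
         as.numeric(Sys.time() - t0, units = "secs"))

    summary <- list(
      n_sources = N, n_masks = mask_count, n_states = n_states,
      focus_depth = focus,
      retrieval_residual = utils::tail(ret$trace$residuals, 1),
      retrieval_epochs = ret$trace$epochs,
      z_hat = loc$z_hat, z_confidence = loc$confidence,
      medium_reference = med$reference,
      n_detections = nrow(det),
      detections = as.data.frame(unclass(det)),
      calibration = if (!is.null(ev$calibration))
        list(magnification = ev$calibration$magnification,
             rotation = ev$calibration$rotation,
             parity = ev$calibration$parity,
             z_scale = ev$calibration$z_scale,
             z_offset = ev$calibration$z_offset,
             residual_rms = ev$calibration$residual_rms),
      psnr_db = ev$psnr_db, ssim = ev$ssim,
      planes = ev$planes, fwhm_um = ev$fwhm_um,
      detection_table = ev$detection_table)
    result$summary <- summary
    if (!is.null(out_dir)) {
      write_json_file(summary, file.path(out_dir, "summary.json"))
      utils::write.csv(as.data.frame(unclass(det)),
                       file.path(out_dir, "detections.csv"),
                       row.names = FALSE)
    }
    out <- as.list(result)
    class(out) <- "pipeline_result"
    out
  }, error = function(e) {
    plog(verbose, log, "FAILED at stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d detection(s), z_hat %.5g um",
              nrow(x$detections), x$z_hat))
  if (!is.null(x$evaluation$psnr_db))
    cat(sprintf(", PSNR %.4g dB, min SSIM %.4g",
                x$evaluation$psnr_db, x$evaluation$ssim))
  cat("\n")
  invisible(x)
}

# per-plane evaluation: calibration, registered PSNR/SSIM against the
# diffraction-limited ground truth rendered in reconstruction coordinates,
# best-focus depths, FWHM of the brightest detection
evaluate_reconstruction <- function(stack, detections, sources, config) {
  out <- list(calibration = NULL, psnr_db = NULL, ssim = NULL,
              planes = NULL, fwhm_um = NULL, detection_table = NULL)
  if (nrow(detections) < 3) return(out)
  mt <- match_sources(detections, sources)
  if (length(mt$det_idx) < 3) return(out)
  cal <- calibrate_coordinates(detections[mt$det_idx, ],
                               sources[mt$truth_idx, ])
  out$calibration <- cal
  det_obj <- apply_calibration(cal, detections)
  out$detection_table <- data.frame(
    det = mt$det_idx, truth = mt$truth_idx,
    x_um = det_obj$x_um[mt$det_idx], y_um = det_obj$y_um[mt$det_idx],
    z_um = det_obj$z_um[mt$det_idx],
    x_true = sources$x_um[mt$truth_idx], y_true = sources$y_um[mt$truth_idx],
    z_true = sources$z_um[mt$truth_idx])
  truth_rec <- apply_calibration(cal, sources, inverse = TRUE)
  na_rec <- min(config$na * abs(cal$magnification),
                0.95 * stack$grid$na_max)
  depths <- sort(unique(round(sources$z_um, 6)))
  planes <- list()
  psnrs <- ssims <- numeric(0)
  for (zp in depths) {
    z_rec <- (zp - cal$z_offset) / cal$z_scale
    iz <- which.min(abs(stack$z - z_rec))
    gt <- diffraction_limited_image(truth_rec, stack$grid, na = na_rec,
                                    focus_z = if (length(depths) > 1)
                                      stack$z[iz] else NULL)
    m <- image_metrics(stack$intensity[, , iz], gt)
    # best-focus depth of this plane group: the axial maximum of the group's
    # summed intensity profile, sampled at the detected spot centres
    grp <- which(abs(sources$z_um[mt$truth_idx] - zp) < 1e-6)
    det_grp <- detections[mt$det_idx[grp], , drop = FALSE]
    prof <- rowSums(vapply(seq_len(nrow(det_grp)), function(k) {
      i <- which.min(abs(grid_x(stack$grid) - det_grp$x_um[k]))
      j <- which.min(abs(grid_y(stack$grid) - det_grp$y_um[k]))
      stack$intensity[i, j, ]
    }, numeric(length(stack$z))))
    zpk <- subpixel_peak_1d(prof)
    z_best_rec <- stats::approx(seq_along(stack$z), stack$z, xout = zpk)$y
    planes[[length(planes) + 1]] <- list(
      depth_um = zp, z_rec = z_rec, z_slice = stack$z[iz],
      z_best_focus_rec = z_best_rec,
      depth_recovered_um = cal$z_scale * z_best_rec + cal$z_offset,
      psnr_db = m$psnr_db, ssim = m$ssim)
    psnrs <- c(psnrs, m$psnr_db)
    ssims <- c(ssims, m$ssim)
  }
  out$planes <- planes
  out$psnr_db <- min(psnrs)
  out$ssim <- min(ssims)
  # lateral FWHM of the brightest detection, in calibrated object units
  bd <- detections[1, ]
  fw <- tryCatch({
    fx <- fwhm_measure(stack, c(bd$x_um, bd$y_um, bd$z_um), "x")
    fy <- fwhm_measure(stack, c(bd$x_um, bd$y_um, bd$z_um), "y")
    abs(cal$magnification) * c(x = fx, y = fy)
  }, error = function(e) NULL)
  out$fwhm_um <- fw
  out
}

subpixel_peak_1d <- function(prof) {
  i <- which.max(prof)
  if (i > 1 && i < length(prof)) {
    den <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
    if (den < 0) return(i + max(-0.5, min(0.5,
      0.5 * (prof[i - 1] - prof[i + 1]) / den)))
  }
  i
}

#' Run a single pipeline stage against a run directory
#'
#' The CLI entry point: each stage reads its inputs from `run_dir` (bundles
#' written by earlier stages) and writes its outputs there. `"run"` executes
#' all stages in memory.
#'
#' @param stage one of `"simulate"`, `"retrieve"`, `"locate-plane"`,
#'   `"demix"`, `"build-medium"`, `"reconstruct"`, `"evaluate"`, `"run"`.
#' @param config a [pipeline_config()].
#' @param run_dir run directory.
#' @param verbose print progress.
#' @return invisibly, the stage's main artifact.
#' @export
run_stage <- function(stage, config, run_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "run") return(invisible(run_pipeline(config, run_dir, verbose)))
  g <- config_grid(config)
  meas_dir <- file.path(run_dir, "measurements")
  ret_dir <- file.path(run_dir, "retrieved")
  state_path <- file.path(run_dir, "state.json")
  state <- if (file.exists(state_path)) read_json_file(state_path) else list()
  save_state <- function(...) {
    state[names(list(...))] <- list(...)
    write_json_file(state, state_path)
    state <<- state
  }
  switch(stage,
    "simulate" = {
      sources <- config_sources(config)
      screen <- make_phase_screen(g, config$screen$correlation_length,
                                  config$screen$strength, config$screen$seed)
      masks <- make_masks(g, config$masks$count %||% (10L * nrow(sources)),
                          config$masks$macropixel, config$masks$seed)
      meas <- simulate_measurements(sources, screen, masks, g,
                                    focus_depth = config$focus_depth,
                                    na = config$na,
                                    photon_budget = config$noise$photon_budget,
                                    seed = config$noise$seed)
      write_measurement_bundle(meas, meas_dir)
      save_state(focus_depth = meas$geometry$focus_depth)
      invisible(meas)
    },
    "retrieve" = {
      meas <- read_measurement_bundle(meas_dir)
      n_states <- config$retrieval$n_states %||%
        (if (!is.null(meas$sources)) nrow(meas$sources) else
           stop("retrieval$n_states must be set when sources are unknown"))
      ret <- retrieve_fields(meas, n_states, config$retrieval$max_iters,
                             config$retrieval$tol, config$retrieval$seed)
      write_field_set(ret$fields, ret_dir, trace = ret$trace)
      invisible(ret$fields)
    },
    "locate-plane" = {
      fields <- read_field_set(ret_dir)
      focus <- state$focus_depth %||% 100
      vol <- correlation_volume(fields,
                                seq(config$locate$z_min %||% (0.5 * focus),
                                    config$locate$z_max %||% (1.5 * focus),
                                    by = config$locate$z_step),
                                config$locate$exclusion_radius)
      loc <- locate_correlation_plane(vol)
      save_state(z_hat = loc$z_hat, z_confidence = loc$confidence)
      invisible(loc)
    },
    "demix" = {
      fields <- read_field_set(ret_dir)
      z_hat <- state$z_hat %||% stop("run locate-plane first")
      fcp <- propagate_fields(fields, z_hat, label = "correlation-plane")
      if (config$demix$mode == "global") {
        dm <- demix_unitary(fcp, seed = config$demix$seed,
                            max_iters = config$demix$max_iters,
                            tol = config$demix$tol,
                            restarts = config$demix$restarts,
                            exclusion_radius = config$demix$exclusion_radius)
        write_field_set(dm$fields, file.path(run_dir, "demixed"))
        write_json_file(list(mode = "global", metric = dm$metric,
                             metric_identity = dm$metric_identity,
                             iterations = dm$iterations,
                             unitarity_error = dm$U$unitarity_error),
                        file.path(run_dir, "demix.json"))
      } else {
        layout <- tile_layout(fcp$grid, config$demix$rows, config$demix$cols,
                              config$demix$overlap)
        dm <- demix_tiled(fcp, layout, seed = config$demix$seed,
                          max_iters = config$demix$max_iters,
                          tol = config$demix$tol,
                          restarts = config$demix$restarts,
                          exclusion_radius = config$demix$exclusion_radius)
        for (t in seq_along(dm))
          write_field_set(dm[[t]]$fields,
                          file.path(run_dir, sprintf("demixed-tile%02d", t)))
        write_json_file(list(mode = "tiled", rows = config$demix$rows,
                             cols = config$demix$cols,
                             overlap = config$demix$overlap,
                             metric = vapply(dm, `[[`, numeric(1), "metric")),
                        file.path(run_dir, "demix.json"))
      }
      invisible(dm)
    },
    "build-medium" = {
      z_hat <- state$z_hat %||% stop("run locate-plane first")
      info <- read_json_file(file.path(run_dir, "demix.json"))
      if (info$mode == "global") {
        dmf <- read_field_set(file.path(run_dir, "demixed"))
        med <- build_virtual_medium(dmf, plane_z = z_hat,
                                    model = config$medium$model,
                                    admission_threshold =
                                      config$medium$admission_threshold,
                                    refine_sigma = config$medium$refine_sigma)
      } else {
        layout <- tile_layout(g, info$rows, info$cols, info$overlap)
        media <- lapply(seq_along(layout$tiles), function(t)
          build_virtual_medium(
            read_field_set(file.path(run_dir, sprintf("demixed-tile%02d", t))),
            plane_z = z_hat, model = config$medium$model,
            admission_threshold = config$medium$admission_threshold,
            refine_sigma = config$medium$refine_sigma))
        med <- stitch_virtual_medium(media, layout)
      }
      write_virtual_medium(med, file.path(run_dir, "medium"))
      invisible(med)
    },
    "reconstruct" = {
      fields <- read_field_set(ret_dir)
      z_hat <- state$z_hat %||% stop("run locate-plane first")
      fcp <- propagate_fields(fields, z_hat, label = "correlation-plane")
      med <- read_virtual_medium(file.path(run_dir, "medium"))
      zs <- seq(config$reconstruct$z_min, config$reconstruct$z_max,
                by = config$reconstruct$z_step)
      stk <- reconstruct_volume(fcp, med, zs, config$reconstruct$pad_factor)
      write_reconstruction(stk, file.path(run_dir, "reconstruction"))
      invisible(stk)
    },
    "evaluate" = {
      stk <- read_reconstruction(file.path(run_dir, "reconstruction"))
      meas <- read_measurement_bundle(meas_dir)
      det <- detect_sources(stk, config$detect$rel_threshold,
                            config$detect$merge_radius)
      utils::write.csv(as.data.frame(unclass(det)),
                       file.path(run_dir, "detections.csv"),
                       row.names = FALSE)
      ev <- if (!is.null(meas$sources))
        evaluate_reconstruction(stk, det, meas$sources, config) else list()
      summary <- list(n_detections = nrow(det),
                      z_hat = state$z_hat, z_confidence = state$z_confidence,
                      psnr_db = ev$psnr_db, ssim = ev$ssim,
                      planes = ev$planes, fwhm_um = ev$fwhm_um,
                      detection_table = ev$detection_table)
      write_json_file(summary, file.path(run_dir, "summary.json"))
      invisible(summary)
    },
    stop("unknown stage: ", stage))
}
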