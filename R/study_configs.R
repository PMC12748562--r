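#' Study-condition pipeline configurations
#'
#' The three benchmark scenes of the package, codified once
#' so tests, scripts and examples share identical conditions:
#'
#' * `"beads2d"` — five 1-um-bead-like point sources at one depth ~100 um
#'   behind a strongly scattering thin layer; 128 x 128 camera, lambda
#'   0.55 um, NA 0.35, 120 random SLM masks, noiseless; global demixing.
#' * `"beads3d"` — six beads split over two depth planes at 80 and 95 um;
#'   3 x 3 tiled demixing and stitched virtual layer.
#' * `"spiral"` — the 20-focus spiral (radii 10 to 3.65 um over a 4*pi
#'   sweep, 0.5 um axial increments, 10 um total span) behind the layer;
#'   200 masks, 3 x 3 tiled demixing.
#'
#' The master `seed` fixes every stochastic stage (object placement, screen,
#' masks, retrieval initialization, demixing restarts).
#'
#' @param which scenario name.
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
study_config <- function(which = c("beads2d", "beads3d", "spiral"),
                         seed = 1) {
  which <- match.arg(which)
  switch(which,
    beads2d = pipeline_config(
      object = list(type = "beads", n_beads = 5, plane_depths = 100,
                    min_separation = 4, extent = 9),
      masks = list(count = 120),
      retrieval = list(max_iters = 300, tol = 1e-9),
      demix = list(mode = "global", restarts = 3, max_iters = 150),
      locate = list(z_min = 50, z_max = 150, z_step = 2),
      reconstruct = list(z_min = -10, z_max = 10, z_step = 2),
      detect = list(rel_threshold = 0.5, merge_radius = 1.2),
      seed = seed),
    beads3d = pipeline_config(
      object = list(type = "beads", n_beads = 6, plane_depths = c(80, 95),
                    min_separation = 4, extent = 8),
      masks = list(count = 100),
      retrieval = list(max_iters = 300, tol = 1e-9),
      demix = list(mode = "tiled", rows = 3, cols = 3, restarts = 2,
                   max_iters = 100),
      locate = list(z_min = 45, z_max = 135, z_step = 2),
      reconstruct = list(z_min = -25, z_max = 25, z_step = 1.25),
      detect = list(rel_threshold = 0.3, merge_radius = 1.2),
      seed = seed),
    spiral = pipeline_config(
      object = list(type = "spiral"),
      masks = list(count = 200),
      retrieval = list(max_iters = 120, tol = 1e-9),
      demix = list(mode = "tiled", rows = 3, cols = 3, restarts = 2,
                   max_iters = 100),
      locate = list(z_min = 50, z_max = 150, z_step = 2),
      reconstruct = list(z_min = -18, z_max = 18, z_step = 1.2),
      detect = list(rel_threshold = 0.5, merge_radius = 0.96),
      seed = seed))
}
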