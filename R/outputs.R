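#' Write all case outputs
#'
#' Writes `ratios.csv` (overall plus the six regions), `deviation_grid.csv`
#' (one row per grid point: phi, theta, planar x/y, region, hit flags,
#' distance), the TrABL color graph `trabl_map.png`, the per-region radar
#' plot `radar.png`, and a machine-readable `run_log.json` with the fitted
#' parameters, grid size and warnings.
#'
#' @param fit a [trabl()] result.
#' @param outdir output directory (created if needed).
#' @param px color-graph size in pixels.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(fit, outdir, px = 600L) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  res <- fit$result
  ratios <- rbind(
    data.frame(region = "overall", A_rec = res$A_rec, A_def = res$A_def,
               ratio = res$ratio, assessable = TRUE),
    res$per_region)
  f_ratios <- file.path(outdir, "ratios.csv")
  utils::write.csv(ratios, f_ratios, row.names = FALSE)
  f_grid <- file.path(outdir, "deviation_grid.csv")
  utils::write.csv(as.data.frame(fit), f_grid, row.names = FALSE)
  f_map <- file.path(outdir, "trabl_map.png")
  img <- render_color_graph(fit$planar, fit$deviation, fit$labels,
                            d_max = fit$color_max, px = px)
  png::writePNG(img, f_map)
  f_radar <- file.path(outdir, "radar.png")
  grDevices::png(f_radar, width = 640, height = 480, type = "cairo")
  plot_radar(radar_data(res), main = "TrABL ratio per subregion")
  grDevices::dev.off()
  f_log <- file.path(outdir, "run_log.json")
  jsonlite::write_json(list(
    grid = list(n_phi = fit$grid$n_phi, n_theta = fit$grid$n_theta),
    sphere = list(center = fit$sphere$center,
                  radius = fit$sphere$radius,
                  rms_residual = fit$sphere$rms_residual),
    axes = list(n = fit$frame$n, ap_axis = fit$frame$ap_axis,
                sup_axis = fit$frame$sup_axis, side = fit$frame$side),
    areas = list(A_rec = res$A_rec, A_def = res$A_def),
    ratio = res$ratio,
    per_region = res$per_region,
    color_range = res$metadata$color_range,
    warnings = res$metadata$warnings),
    f_log, auto_unbox = TRUE, digits = NA)
  invisible(c(f_ratios, f_grid, f_map, f_radar, f_log))
}

#' Run a complete case end to end
#'
#' Reads the meshes and the case configuration, runs [trabl()], and
#' writes all outputs to `outdir`.
#'
#' @param deficient_path,reconstructed_path STL/OBJ mesh paths.
#' @param config_path case-configuration JSON path.
#' @param outdir output directory.
#' @param ... passed on to [trabl()] (e.g. `grid_size`, `color_max`).
#' @return The [trabl()] fit, invisibly.
#' @export
run_case <- function(deficient_path, reconstructed_path, config_path,
                     outdir, ...) {
  fit <- trabl(deficient_path, reconstructed_path, config_path, ...)
  write_outputs(fit, outdir)
  invisible(fit)
}
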