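#' Total radial acetabular bone loss analysis
#'
#' Runs the full analysis for one case: fits the joint-center sphere to
#' the acetabular-region points and the least-squares plane to the rim
#' outline, builds the acetabular frame (axis `n`, projected
#' anteroposterior and superior axes), casts the spherical ray grid
#' against both meshes, unfolds the hits onto the planar
#' azimuthal-equidistant grid, labels the six anatomical subregions, and
#' evaluates the TrABL ratio globally and per region.
#'
#' @param deficient deficient bone mesh: a [triangle_mesh()] or a file
#'   path accepted by [read_mesh()].
#' @param reconstructed anatomically reconstructed bone mesh (same
#'   millimeter coordinate frame), mesh or path.
#' @param config a [case_config()] or path to its JSON file.
#' @param grid_size integer 2-vector `c(n_phi, n_theta)`; the fixed
#'   default 100 x 100 makes maps comparable across cases.
#' @param color_max upper end of the deviation color range (mm).
#' @param sector_offset rotation of the five sector boundaries (degrees).
#' @param cell_rule,metric area accounting options, see [masked_area()].
#' @param method ray caster, see [cast_first_hit()].
#' @return An object of class `trabl`: the fitted `sphere`, `plane`,
#'   `frame`, the `grid`, `deviation` map, `planar` map, region `labels`,
#'   and `result` (a `trabl_result`).
#' @examples
#' ph <- make_phantom(phantom_preset("wedge25", tessellation_level = 2))
#' fit <- trabl(ph$deficient, ph$reconstructed, ph$config,
#'              grid_size = c(50, 50))
#' coef(fit)
#' @export
trabl <- function(deficient, reconstructed, config,
                  grid_size = c(100L, 100L), color_max = 10,
                  sector_offset = 0,
                  cell_rule = c("fractional", "all"),
                  metric = c("planar", "spherical"),
                  method = c("bvh", "brute")) {
  cell_rule <- match.arg(cell_rule)
  metric <- match.arg(metric)
  method <- match.arg(method)
  cl <- match.call()
  if (is.character(reconstructed)) reconstructed <- read_mesh(reconstructed)
  if (is.character(deficient)) deficient <- read_mesh(deficient)
  if (is.character(config))
    config <- read_case_config(config, mesh = reconstructed)
  stopifnot(inherits(deficient, "triangle_mesh"),
            inherits(reconstructed, "triangle_mesh"),
            inherits(config, "case_config"))
  sphere <- fit_sphere(config$acetabular_region)
  plane <- fit_rim_plane(config$rim_outline)
  frame <- build_frame(sphere, plane, config$landmarks, config$side)
  grid <- build_grid(frame, grid_size[1], grid_size[2])
  deviation <- compute_deviation_map(grid, deficient, reconstructed,
                                     method = method)
  planar <- project_to_plane(grid)
  labels <- assign_regions(grid, frame, offset_deg = sector_offset)
  result <- evaluate(deviation, planar, labels, cell_rule = cell_rule,
                     metric = metric)
  result$metadata$color_range <- c(0, color_max)
  structure(list(sphere = sphere, plane = plane, frame = frame,
                 grid = grid, deviation = deviation, planar = planar,
                 labels = labels, result = result,
                 color_max = color_max, call = cl),
            class = "trabl")
}

#' @export
print.trabl <- function(x, ...) {
  cat("Total radial acetabular bone loss (TrABL)\n")
  cat(sprintf("  joint center : (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
              x$sphere$center[1], x$sphere$center[2], x$sphere$center[3],
              x$sphere$radius))
  cat(sprintf("  grid         : %d x %d (phi x theta)\n",
              x$grid$n_phi, x$grid$n_theta))
  cat(sprintf("  TrABL ratio  : %.1f %%\n", x$result$ratio))
  pr <- x$result$per_region
  cat("  per region   :",
      paste(sprintf("%s %.0f", pr$region, pr$ratio), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.trabl <- function(object, ...) {
  pr <- object$result$per_region
  c(overall = object$result$ratio,
    stats::setNames(pr$ratio, pr$region))
}

#' @export
summary.trabl <- function(object, ...) {
  structure(list(fit = object), class = "summary.trabl")
}

#' @export
print.summary.trabl <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  A_rec %.2f mm^2, A_def %.2f mm^2\n",
              f$result$A_rec, f$result$A_def))
  cat(sprintf("  acetabular axis n: (%.3f, %.3f, %.3f), side %s\n",
              f$frame$n[1], f$frame$n[2], f$frame$n[3], f$frame$side))
  cat(sprintf("  sphere fit RMS residual: %.4f mm\n",
              f$sphere$rms_residual))
  hits <- sum(f$deviation$hit_rec & f$deviation$hit_def)
  none <- sum(f$deviation$hit_rec & !f$deviation$hit_def)
  cat(sprintf("  rays: %d with bony support, %d uncontained\n",
              hits, none))
  for (w in f$result$metadata$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
as.data.frame.trabl <- function(x, ...) {
  np <- x$grid$n_phi
  nt <- x$grid$n_theta
  data.frame(
    phi = rep(x$grid$phi, times = nt),
    theta = rep(x$grid$theta, each = np),
    x = as.vector(x$planar$x),
    y = as.vector(x$planar$y),
    region = as.vector(x$labels$labels),
    hit_rec = as.vector(x$deviation$hit_rec),
    hit_def = as.vector(x$deviation$hit_def),
    distance = as.vector(x$deviation$distance))
}

#' @export
plot.trabl <- function(x, type = c("map", "radar"), px = 600, ...) {
  type <- match.arg(type)
  if (type == "map") {
    img <- render_color_graph(x$planar, x$deviation, x$labels,
                              d_max = x$color_max, px = px)
    op <- graphics::par(mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot.new()
    graphics::plot.window(c(-pi, pi), c(-pi, pi), asp = 1)
    graphics::rasterImage(img, -pi, -pi, pi, pi)
    graphics::title("TrABL color graph")
  } else {
    plot_radar(radar_data(x$result),
               main = "TrABL ratio per subregion")
  }
  invisible(x)
}
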