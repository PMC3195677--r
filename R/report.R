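#' Deviation color scale
#'
#' Maps distance deviations to colors: a perceptual green -> yellow ->
#' red -> dark red ramp, linear in distance from `d_min` (green, no
#' deficiency) to `d_max` (dark red); distances at or above `d_max` clamp
#' to the terminal color. Non-finite distances (no bony support) map to
#' grey.
#'
#' @param distance numeric vector of deviations (mm).
#' @param d_max upper color range end (mm), default 10.
#' @param d_min lower end (mm), default 0.
#' @return Matrix (n x 3) of RGB values in `[0, 1]`.
#' @export
trabl_color <- function(distance, d_max = 10, d_min = 0) {
  stopifnot(d_min < d_max)
  ramp <- grDevices::colorRamp(
    c("#00A000", "#FFFF00", "#FF4000", "#8B0000"), space = "rgb")
  fin <- is.finite(distance)
  d <- pmin(pmax((distance[fin] - d_min) / (d_max - d_min), 0), 1)
  out <- matrix(0.6, length(distance), 3L)  # grey for no-intersection
  if (any(fin)) out[fin, ] <- ramp(d) / 255
  out
}

#' Render the TrABL color graph as a pixel array
#'
#' Rasterizes the planar deviation map: grey where only the reconstructed
#' mesh is hit (total bone loss in that direction), the deviation color
#' ramp where the deficient bone is present, white outside the grid.
#' Overlays the circles \eqn{r = \pi/2} (black) and \eqn{r = \pi} (green), the
#' medial-region circle \eqn{r = \pi/6} (yellow), and the radial sector
#' boundary lines (black). Rendering is deterministic: a pure function of
#' the inputs.
#'
#' @param planar a [project_to_plane()] result.
#' @param deviation a [compute_deviation_map()] result.
#' @param labels an [assign_regions()] result (for the sector line
#'   offset); may be `NULL` to skip sector lines.
#' @param d_max color range end (mm).
#' @param px image side length in pixels.
#' @return An `px x px x 3` RGB array (rows top to bottom, anterior to
#'   the right, superior up), suitable for [png::writePNG()].
#' @export
render_color_graph <- function(planar, deviation, labels = NULL,
                               d_max = 10, px = 600L) {
  px <- as.integer(px)
  lim <- pi * 1.02
  xs <- seq(-lim, lim, length.out = px)
  ys <- seq(lim, -lim, length.out = px)  # row 1 = top = +y (superior)
  X <- matrix(xs, px, px, byrow = TRUE)
  Y <- matrix(ys, px, px)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X)
  np <- planar$n_phi
  nt <- planar$n_theta
  # nearest grid point
  gi <- pmin(pmax(round(R / (pi * planar$r_u) * (np - 1)) + 1, 1), np)
  gj <- (round((TH + pi) / (2 * pi) * nt) %% nt) + 1
  lin <- cbind(as.vector(gi), as.vector(gj))
  hr <- deviation$hit_rec[lin]
  hd <- deviation$hit_def[lin]
  dist <- deviation$distance[lin]
  img <- matrix(1, px * px, 3L)  # white background
  inside <- as.vector(R) <= pi * planar$r_u
  grey_zone <- inside & hr & !hd            # uncontained: grey
  col_zone <- inside & hd                   # deficient bone present
  img[grey_zone, ] <- 0.6
  if (any(col_zone)) {
    dcol <- dist[col_zone]
    base_blue <- !is.finite(dcol) # deficient-only surface: uniform blue
    cols <- trabl_color(dcol, d_max = d_max)
    if (any(base_blue))
      cols[base_blue, ] <- matrix(c(0.25, 0.41, 0.88), sum(base_blue),
                                  3L, byrow = TRUE)
    img[col_zone, ] <- cols
  }
  lw <- 2.5 * (2 * lim / px)
  ring <- function(rad) abs(as.vector(R) - rad) < lw
  img[ring(pi / 2), ] <- 0
  img[ring(pi / 6), ] <- matrix(c(1, 1, 0), sum(ring(pi / 6)), 3L,
                                byrow = TRUE)
  gr <- ring(pi)
  img[gr, ] <- matrix(c(0, 0.7, 0), sum(gr), 3L, byrow = TRUE)
  if (!is.null(labels)) {
    off <- (labels$offset_deg %||% 0) * pi / 180
    bounds <- off + seq(0, 2 * pi * 4 / 5, by = 2 * pi / 5)
    thv <- as.vector(TH)
    rv <- as.vector(R)
    for (b in bounds) {
      d_ang <- abs(((thv - b + pi) %% (2 * pi)) - pi)
      sel <- d_ang * rv < lw & rv >= pi / 6 & rv <= pi
      img[sel, ] <- 0
    }
  }
  array(img, dim = c(px, px, 3L))
}

#' Radar data: sector ratios plus the medial value
#'
#' The five sector ratios in fixed radar order (PostInf, Inf, AntInf,
#' AntSup, PostSup) plus the medial ratio as a separate scalar (shown as
#' a bar, not a spoke).
#'
#' @param result a `trabl_result` (from [evaluate()] or `fit$result`), or
#'   a named vector/one-row data frame with the six region columns.
#' @return A list with `sectors` (named numeric, length 5) and `med`.
#' @export
radar_data <- function(result) {
  sector_names <- c("PostInf", "Inf", "AntInf", "AntSup", "PostSup")
  if (inherits(result, "trabl_result")) {
    v <- stats::setNames(result$per_region$ratio,
                         result$per_region$region)
  } else if (is.data.frame(result)) {
    v <- unlist(result[1, region_names()])
  } else {
    v <- result[region_names()]
  }
  list(sectors = stats::setNames(as.numeric(v[sector_names]),
                                 sector_names),
       med = as.numeric(v["Med"]))
}

#' Radar plot of per-region ratios
#'
#' @param rd a [radar_data()] result.
#' @param main plot title.
#' @param max_ratio axis maximum (percent).
#' @return `rd`, invisibly.
#' @export
plot_radar <- function(rd, main = "", max_ratio = 100) {
  n <- length(rd$sectors)
  ang <- pi / 2 + (seq_len(n) - 1L) * 2 * pi / n
  op <- graphics::par(mar = c(2, 2, 3, 6))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(-1.2, 1.2), c(-1.2, 1.2), asp = 1)
  for (frac in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(frac * cos(ang), frac * sin(ang), border = "grey70")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey70")
  v <- pmin(pmax(rd$sectors, 0), max_ratio) / max_ratio
  graphics::polygon(v * cos(ang), v * sin(ang), border = "firebrick",
                    col = grDevices::adjustcolor("firebrick", 0.35),
                    lwd = 2)
  graphics::text(1.12 * cos(ang), 1.12 * sin(ang), names(rd$sectors),
                 cex = 0.8)
  mb <- pmin(pmax(rd$med, 0), max_ratio) / max_ratio
  graphics::rect(1.35, -0.5, 1.45, -0.5 + mb, col = "steelblue",
                 xpd = NA)
  graphics::text(1.4, -0.62, sprintf("Med\n%.0f%%", rd$med), cex = 0.7,
                 xpd = NA)
  graphics::title(main)
  invisible(rd)
}
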