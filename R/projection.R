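#' Azimuthal equidistant projection of the grid
#'
#' Unfolds the spherical grid onto the plane: planar radius equals arc
#' length from the pole, \eqn{r = r_u \varphi}, with \eqn{x = r \cos\theta},
#' \eqn{y = r \sin\theta}. Areas measured on this planar grid carry the
#' projection's distortion by construction (the ratio compares like with
#' like, both surfaces living on the same grid).
#'
#' @param grid a [build_grid()] result.
#' @return A list of class `planar_map` with `n_phi x n_theta` matrices
#'   `x`, `y`, `r` (mm) and the grid dimensions.
#' @export
project_to_plane <- function(grid) {
  r <- grid$r_u * matrix(grid$phi, grid$n_phi, grid$n_theta)
  TH <- matrix(grid$theta, grid$n_phi, grid$n_theta, byrow = TRUE)
  structure(list(x = r * cos(TH), y = r * sin(TH), r = r,
                 n_phi = grid$n_phi, n_theta = grid$n_theta,
                 r_u = grid$r_u),
            class = "planar_map")
}

# linear indices of the 4 corners of every grid cell; the azimuth wraps so
# cells close the disk across the theta seam. Cells touching the phi = 0
# pole degenerate to triangles (two corners coincide at the origin).
cell_corners <- function(n_phi, n_theta) {
  i <- rep(seq_len(n_phi - 1L), times = n_theta)
  j <- rep(seq_len(n_theta), each = n_phi - 1L)
  jp <- j %% n_theta + 1L
  cbind(c1 = i + (j - 1L) * n_phi,
        c2 = i + 1L + (j - 1L) * n_phi,
        c3 = i + 1L + (jp - 1L) * n_phi,
        c4 = i + (jp - 1L) * n_phi)
}

# shoelace area of each projected grid cell
cell_areas_planar <- function(planar) {
  cc <- cell_corners(planar$n_phi, planar$n_theta)
  x <- planar$x
  y <- planar$y
  0.5 * abs(x[cc[, 1]] * (y[cc[, 2]] - y[cc[, 4]]) +
            x[cc[, 2]] * (y[cc[, 3]] - y[cc[, 1]]) +
            x[cc[, 3]] * (y[cc[, 4]] - y[cc[, 2]]) +
            x[cc[, 4]] * (y[cc[, 1]] - y[cc[, 3]]))
}

# true spherical cell areas (lat-long bands are exact on the unit sphere)
cell_areas_spherical <- function(planar) {
  n_phi <- planar$n_phi
  n_theta <- planar$n_theta
  phi <- planar$r[, 1] / planar$r_u
  dth <- 2 * pi / n_theta
  band <- (cos(phi[-n_phi]) - cos(phi[-1])) * dth * planar$r_u^2
  rep(band, times = n_theta)
}

#' Masked planar area on the projected grid
#'
#' Area enclosed by a boolean mask on the planar grid, summed over grid
#' cells (quadrilaterals of four index-adjacent points, wrapping in
#' azimuth). With `cell_rule = "fractional"` (default) each cell
#' contributes its shoelace area weighted by k/4 where k corners pass the
#' mask (and the region filter, when given) -- this converges to the
#' continuous area and makes region areas partition the global area
#' exactly. `cell_rule = "all"` counts a cell only when all four corners
#' pass (strict membership, used by the independent oracle path).
#'
#' @param planar a [project_to_plane()] result.
#' @param mask logical `n_phi x n_theta` matrix (or vector of that length).
#' @param region_filter optional logical matrix of the same shape
#'   (per-point; combined with the mask corner-wise).
#' @param region_cells optional logical vector, one element per grid cell
#'   in [cell_corners()] order, restricting the summation to cells whose
#'   midpoint lies in a region (see `cell_labels` in [assign_regions()]).
#' @param cell_rule `"fractional"` or `"all"`.
#' @param metric `"planar"` (default; areas in the distorted azimuthal
#'   metric, as the ratio is defined) or `"spherical"` (true unit-sphere
#'   areas, for sensitivity checks only).
#' @return Area in mm^2.
#' @export
masked_area <- function(planar, mask, region_filter = NULL,
                        region_cells = NULL,
                        cell_rule = c("fractional", "all"),
                        metric = c("planar", "spherical")) {
  cell_rule <- match.arg(cell_rule)
  metric <- match.arg(metric)
  ok <- as.vector(mask)
  if (!is.null(region_filter)) ok <- ok & as.vector(region_filter)
  cc <- cell_corners(planar$n_phi, planar$n_theta)
  k <- ok[cc[, 1]] + ok[cc[, 2]] + ok[cc[, 3]] + ok[cc[, 4]]
  w <- if (cell_rule == "fractional") k / 4 else as.numeric(k == 4L)
  if (!is.null(region_cells)) w <- w * as.vector(region_cells)
  areas <- if (metric == "planar") cell_areas_planar(planar)
           else cell_areas_spherical(planar)
  sum(areas * w)
}

#' TrABL ratio
#'
#' `ratio = (1 - A_def / A_rec) * 100` (percent): the fraction of the
#' reconstructed acetabulum's radial hit surface for which the deficient
#' bone offers no intersection. Not clamped: deficient bone pushed beyond
#' the reconstruction can make `A_def > A_rec` and the ratio negative.
#'
#' @param A_def,A_rec planar areas (mm^2).
#' @return Percentage.
#' @export
trabl_ratio <- function(A_def, A_rec) {
  if (!is.finite(A_rec) || A_rec <= 0)
    stop("undefined ratio: A_rec must be positive", call. = FALSE)
  (1 - A_def / A_rec) * 100
}

#' Evaluate areas and TrABL ratios on the planar grid
#'
#' Computes `A_rec` (area of the reconstructed-mesh hit surface) and
#' `A_def` (deficient-mesh hit surface) globally and per anatomical
#' region, and the corresponding ratios. A region whose `A_rec` is zero is
#' flagged not-assessable (`NA` ratio); other regions are unaffected.
#'
#' @param deviation a [compute_deviation_map()] result.
#' @param planar a [project_to_plane()] result.
#' @param labels an [assign_regions()] result.
#' @inheritParams masked_area
#' @return A list of class `trabl_result`: `A_rec`, `A_def`, `ratio`,
#'   `per_region` (data frame with columns region, A_rec, A_def, ratio,
#'   assessable), `metadata`.
#' @export
evaluate <- function(deviation, planar, labels,
                     cell_rule = c("fractional", "all"),
                     metric = c("planar", "spherical")) {
  cell_rule <- match.arg(cell_rule)
  metric <- match.arg(metric)
  A_rec <- masked_area(planar, deviation$hit_rec, cell_rule = cell_rule,
                       metric = metric)
  A_def <- masked_area(planar, deviation$hit_def, cell_rule = cell_rule,
                       metric = metric)
  warnings <- deviation$warnings
  ar_reg <- region_masked_areas(planar, labels, deviation$hit_rec,
                                cell_rule = cell_rule, metric = metric)
  ad_reg <- region_masked_areas(planar, labels, deviation$hit_def,
                                cell_rule = cell_rule, metric = metric)
  per <- do.call(rbind, lapply(region_names(), function(rg) {
    ok <- ar_reg[[rg]] > 0
    data.frame(region = rg, A_rec = ar_reg[[rg]], A_def = ad_reg[[rg]],
               ratio = if (ok) trabl_ratio(ad_reg[[rg]], ar_reg[[rg]])
                       else NA_real_,
               assessable = ok)
  }))
  ratio <- trabl_ratio(A_def, A_rec)
  if (is.finite(ratio) && ratio < 0)
    warnings <- c(warnings,
                  "A_def exceeds A_rec (bone beyond the reconstruction); negative ratio reported as computed")
  structure(list(A_rec = A_rec, A_def = A_def, ratio = ratio,
                 per_region = per,
                 metadata = list(warnings = warnings,
                                 grid = c(planar$n_phi, planar$n_theta),
                                 cell_rule = cell_rule, metric = metric)),
            class = "trabl_result")
}
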