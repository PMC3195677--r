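#' Anatomical region names
#'
#' Fixed serialization order of the six subregions: the five sectors in
#' radar order followed by the medial cap.
#' @return Character vector.
#' @export
region_names <- function() {
  c("PostInf", "Inf", "AntInf", "AntSup", "PostSup", "Med")
}

#' Assign anatomical subregion labels to the grid
#'
#' Partitions the grid into six regions. The medial region collects the
#' unit-sphere grid points within half a unit radius of the acetabular
#' axis on the medial side: perpendicular distance `sin(phi) <= 0.5`
#' (boundary inclusive) and `phi <= pi/2`, i.e. the cap `phi <= pi/6`. The
#' remaining points fall into five equal 72-degree sectors of the in-plane
#' angle `psi`, measured from the projected anteroposterior axis toward
#' the superior axis: AntSup `[0, 72)`, PostSup `[72, 144)`, PostInf
#' `[144, 216)`, Inf `[216, 288)`, AntInf `[288, 360)` degrees. The
#' lateral pole (`phi = pi`), where the in-plane projection vanishes,
#' falls in the `psi = 0` sector by convention.
#'
#' @param grid a [build_grid()] result.
#' @param frame an [build_frame()] result (defaults to the frame stored in
#'   the grid).
#' @param offset_deg rotate the five sector boundaries by this angle
#'   (degrees); the default places the anterior direction on the
#'   AntSup/AntInf boundary.
#' @return A list of class `region_labels` with `labels`, an
#'   `n_phi x n_theta` character matrix.
#' @export
assign_regions <- function(grid, frame = grid$frame, offset_deg = 0) {
  d <- grid$directions
  dn <- pmin(pmax(d %*% frame$n, -1), 1)
  phi <- acos(-dn)               # polar angle from -n
  axdist <- sqrt(pmax(1 - dn^2, 0))  # sin(phi): distance to the axis
  med <- axdist <= 0.5 + 1e-9 & phi <= pi / 2 + 1e-9
  psi <- atan2(d %*% frame$sup_axis, d %*% frame$ap_axis) * 180 / pi
  psi <- (psi - offset_deg) %% 360
  # half-open [lo, hi) sectors; the 1e-7 tie tolerance keeps grid columns
  # that fall exactly on a boundary on its inclusive side, and the mod-5
  # wraps psi values that round up to 360 back to the first sector
  sector <- c("AntSup", "PostSup", "PostInf", "Inf", "AntInf")[
    floor(psi / 72 + 1e-7) %% 5 + 1L]
  lab <- ifelse(med, "Med", sector)
  # cell-level labels by the midpoint rule: each grid cell (the area
  # element) belongs to the region of its (phi, theta) center. Unlike any
  # per-corner rule this is unbiased when a sector boundary coincides
  # with a grid column, and cells partition the regions exactly.
  np <- grid$n_phi
  nt <- grid$n_theta
  phim <- (grid$phi[-np] + grid$phi[-1]) / 2
  them <- grid$theta + pi / nt  # uniform step, wrap cell included
  PM <- rep(phim, times = nt)
  TM <- rep(them, each = np - 1L)
  dm <- outer(-cos(PM), frame$n) +
    (sin(PM) * cos(TM)) %o% frame$ap_axis +
    (sin(PM) * sin(TM)) %o% frame$sup_axis
  dnm <- pmin(pmax(dm %*% frame$n, -1), 1)
  phic <- acos(-dnm)
  # cell midpoints exactly on the Med circle are ambiguous (the cell is
  # half medial, half sector); ties go to the sector side
  medc <- sqrt(pmax(1 - dnm^2, 0)) < 0.5 - 1e-9 & phic <= pi / 2 + 1e-9
  psic <- atan2(dm %*% frame$sup_axis, dm %*% frame$ap_axis) * 180 / pi
  psic <- (psic - offset_deg) %% 360
  secc <- c("AntSup", "PostSup", "PostInf", "Inf", "AntInf")[
    floor(psic / 72 + 1e-7) %% 5 + 1L]
  # exact sub-cell region geometry, used by the area accounting: in the
  # (phi, theta) parameter rectangle of each cell the Med boundary is the
  # horizontal line phi = pi/6 and the sector boundaries are vertical
  # lines of the in-plane angle (psi == theta for a grid built on this
  # frame, which build_grid guarantees). u0 is the phi-fraction of the
  # cell below the Med circle; a cell crosses at most one sector
  # boundary, at theta-fraction v0, between sectors sec_lo and sec_hi.
  dphi <- grid$phi[-1] - grid$phi[-np]
  u0 <- pmin(pmax((pi / 6 - grid$phi[-np]) / dphi, 0), 1)
  u0 <- rep(u0, times = nt)
  secs <- c("AntSup", "PostSup", "PostInf", "Inf", "AntInf")
  sector_of <- function(theta_deg) {
    psi <- (theta_deg - offset_deg) %% 360
    secs[floor(psi / 72 + 1e-7) %% 5 + 1L]
  }
  th_lo <- rep(grid$theta * 180 / pi, each = np - 1L)
  dth <- 360 / nt
  th_hi <- th_lo + dth
  # first sector boundary at or above th_lo (in the offset frame)
  b <- (floor((th_lo - offset_deg) / 72 + 1e-7) + 1L) * 72 + offset_deg
  split <- b < th_hi - 1e-7
  v0 <- ifelse(split, (b - th_lo) / dth, 1)
  sec_lo <- sector_of(th_lo + pmin(v0, 1) * dth / 2)
  sec_hi <- ifelse(split, sector_of(b + (th_hi - b) / 2), sec_lo)
  structure(list(labels = matrix(lab, np, nt),
                 cell_labels = ifelse(medc, "Med", secc),
                 cell_split = list(u0 = u0, v0 = v0, sec_lo = sec_lo,
                                   sec_hi = sec_hi),
                 offset_deg = offset_deg),
            class = "region_labels")
}

# Per-region masked areas with exact sub-cell apportionment: the mask is
# interpolated bilinearly from its 4 corner samples and integrated over
# each region's exact share of the cell rectangle. Inside a region this
# reduces to the fractional corner rule (k/4); across all regions the
# integrals sum to k/4 exactly, so region areas partition the global
# masked area. cell_rule = "all" instead counts whole cells (all four
# corners masked, cell midpoint in the region).
region_masked_areas <- function(planar, labels, mask,
                                cell_rule = "fractional",
                                metric = "planar") {
  cc <- cell_corners(planar$n_phi, planar$n_theta)
  areas <- if (metric == "planar") cell_areas_planar(planar)
           else cell_areas_spherical(planar)
  m <- as.numeric(as.vector(mask))
  m00 <- m[cc[, 1]]; m10 <- m[cc[, 2]]
  m11 <- m[cc[, 3]]; m01 <- m[cc[, 4]]
  regs <- region_names()
  if (cell_rule == "all") {
    full <- (m00 + m10 + m11 + m01) == 4
    out <- vapply(regs, function(rg)
      sum(areas[full & labels$cell_labels == rg]), numeric(1))
    return(out)
  }
  sp <- labels$cell_split
  u0 <- sp$u0; v0 <- sp$v0
  # separable integrals of (1-u) and u over the u-ranges, (1-v), v over v
  A1l <- u0 - u0^2 / 2;        A2l <- u0^2 / 2          # u in [0, u0]
  A1u <- (1 - u0)^2 / 2;       A2u <- (1 - u0^2) / 2    # u in [u0, 1]
  B1a <- v0 - v0^2 / 2;        B2a <- v0^2 / 2          # v in [0, v0]
  B1b <- (1 - v0)^2 / 2;       B2b <- (1 - v0^2) / 2    # v in [v0, 1]
  I_med <- (A1l * (m00 + m01) + A2l * (m10 + m11)) / 2
  I_a <- m00 * A1u * B1a + m10 * A2u * B1a +
         m01 * A1u * B2a + m11 * A2u * B2a
  I_b <- m00 * A1u * B1b + m10 * A2u * B1b +
         m01 * A1u * B2b + m11 * A2u * B2b
  out <- stats::setNames(numeric(length(regs)), regs)
  out["Med"] <- sum(areas * I_med)
  for (rg in setdiff(regs, "Med")) {
    out[rg] <- sum(areas * (I_a * (sp$sec_lo == rg) +
                            I_b * (sp$sec_hi == rg)))
  }
  out
}

#' Planar-area fraction of each region
#'
#' @param labels an [assign_regions()] result.
#' @param planar a [project_to_plane()] result.
#' @param within optional logical matrix restricting the reference area
#'   (e.g. the disk \eqn{r \le \pi/2}).
#' @inheritParams masked_area
#' @return Named numeric vector of area fractions (summing to 1 over the
#'   reference area).
#' @export
region_fractions <- function(labels, planar, within = NULL,
                             cell_rule = c("fractional", "all")) {
  cell_rule <- match.arg(cell_rule)
  base <- if (is.null(within))
    matrix(TRUE, planar$n_phi, planar$n_theta) else within
  tot <- masked_area(planar, base, cell_rule = cell_rule)
  region_masked_areas(planar, labels, base, cell_rule = cell_rule) / tot
}

#' Connected components of a planar grid mask
#'
#' Labels 4-connected components of a boolean mask on the grid, wrapping
#' in azimuth. Used to detect detached strips in the hit surface (the
#' "needle head" made by rays slipping through the obturator foramen and
#' re-detecting bone on the lower pubic ramus).
#'
#' @param mask logical `n_phi x n_theta` matrix.
#' @return Integer matrix of component ids (0 outside the mask); the
#'   number of components is `max(result)`.
#' @export
planar_components <- function(mask) {
  np <- nrow(mask)
  nt <- ncol(mask)
  comp <- matrix(0L, np, nt)
  cur <- 0L
  for (start in which(mask & comp == 0L)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      idx <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (idx - 1L) %% np + 1L
      j <- (idx - 1L) %/% np + 1L
      nb_i <- c(i - 1L, i + 1L, i, i)
      nb_j <- c(j, j, (j - 2L) %% nt + 1L, j %% nt + 1L)
      ok <- nb_i >= 1L & nb_i <= np
      nb <- nb_i[ok] + (nb_j[ok] - 1L) * np
      nb <- nb[mask[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
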