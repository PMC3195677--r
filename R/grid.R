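#' Build the spherical ray grid
#'
#' Uniform spherical grid of ray directions anchored in the acetabular
#' frame. The polar angle `phi` is measured from `-n` (so `phi = 0` points
#' along the acetabular axis into the middle of the reconstructed
#' acetabulum) and is sampled uniformly on the closed interval `[0, pi]`;
#' the azimuth `theta` is sampled uniformly on the half-open interval
#' `[-pi, pi)` to avoid duplicating the seam column. The direction of grid
#' point `(phi, theta)` is
#' `-cos(phi) n + sin(phi) (cos(theta) ap_axis + sin(theta) sup_axis)`
#' on a unit sphere of radius `r_u = 1` mm.
#'
#' @param frame an [build_frame()] result.
#' @param n_phi number of polar samples (>= 2).
#' @param n_theta number of azimuthal samples (>= 2).
#' @return A list of class `spherical_grid`: `n_phi`, `n_theta`, `phi`,
#'   `theta`, `r_u`, `origin`, `frame`, and `directions` (an
#'   `(n_phi * n_theta) x 3` matrix, phi index varying fastest).
#' @export
build_grid <- function(frame, n_phi = 100L, n_theta = 100L) {
  n_phi <- as.integer(n_phi)
  n_theta <- as.integer(n_theta)
  if (n_phi < 2L || n_theta < 2L)
    stop("grid needs n_phi >= 2 and n_theta >= 2", call. = FALSE)
  phi <- seq(0, pi, length.out = n_phi)
  theta <- -pi + 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  P <- matrix(phi, n_phi, n_theta)
  TH <- matrix(theta, n_phi, n_theta, byrow = TRUE)
  sp <- sin(P)
  dirs <- outer(-cos(as.vector(P)), frame$n) +
    as.vector(sp * cos(TH)) %o% frame$ap_axis +
    as.vector(sp * sin(TH)) %o% frame$sup_axis
  structure(list(n_phi = n_phi, n_theta = n_theta, phi = phi,
                 theta = theta, r_u = 1, origin = frame$center,
                 frame = frame, directions = dirs),
            class = "spherical_grid")
}

#' First-hit ray casting against a mesh
#'
#' Smallest ray parameter `t > eps` at which `origin + t * direction` lies
#' on a mesh triangle, irrespective of surface orientation. Intersections
#' duplicated on shared edges or vertices collapse to a single hit (the
#' minimum t). `method = "bvh"` uses the accelerated caster; `"brute"` uses
#' the independent exhaustive-loop implementation; both must agree exactly.
#'
#' @param origin length-3 ray origin (mm).
#' @param directions unit direction 3-vector or n x 3 matrix.
#' @param mesh a [triangle_mesh()].
#' @param eps minimum accepted ray parameter (mm); guards self-origin hits.
#' @param method `"bvh"` or `"brute"`.
#' @return Numeric vector of hit parameters t (mm), `NA` where the ray does
#'   not intersect the mesh.
#' @export
cast_first_hit <- function(origin, directions, mesh, eps = 1e-6,
                           method = c("bvh", "brute")) {
  method <- match.arg(method)
  D <- if (is.matrix(directions)) directions else matrix(directions, 1L, 3L)
  storage.mode(D) <- "double"
  fun <- if (method == "bvh") cpp_cast_bvh else cpp_cast_brute
  fun(mesh$vertices, mesh$faces, as.numeric(origin), D, eps)
}

#' Compute the deviation map
#'
#' Casts every grid ray against the reconstructed and the deficient mesh
#' and records the per-ray Euclidean distance deviation between the two
#' entry points: `|t_def - t_rec|` where both meshes are hit, `Inf` (no
#' radial bony support -- the defect is uncontained in that direction)
#' otherwise. Rays where the deficient bone lies beyond the reconstruction
#' (overgrowth) are kept with their absolute deviation.
#'
#' @param grid a [build_grid()] result.
#' @param deficient,reconstructed [triangle_mesh()] objects in the same
#'   coordinate frame as the grid.
#' @param method ray caster selection, see [cast_first_hit()].
#' @return A list of class `deviation_map` with `n_phi x n_theta` matrices
#'   `hit_rec`, `hit_def`, `t_rec`, `t_def`, `distance` (mm; `Inf` marks no
#'   intersection), plus `warnings` (character).
#' @export
compute_deviation_map <- function(grid, deficient, reconstructed,
                                  method = c("bvh", "brute")) {
  method <- match.arg(method)
  shape <- c(grid$n_phi, grid$n_theta)
  warnings <- character(0)
  cast_one <- function(mesh, label) {
    t_use <- cast_first_hit(grid$origin, grid$directions, mesh,
                            eps = 1e-6, method = method)
    # detection pass accepting t >= 0: flags an origin on the surface
    t_det <- cast_first_hit(grid$origin, grid$directions, mesh,
                            eps = -1e-9, method = method)
    near <- !is.na(t_det) & t_det <= 1e-6
    if (mean(near) > 0.01) {
      warnings <<- c(warnings, paste0(
        "grid origin lies on the ", label, " mesh surface (",
        sum(near), " near-origin hits)"))
    }
    matrix(t_use, shape[1], shape[2])
  }
  t_rec <- cast_one(reconstructed, "reconstructed")
  t_def <- cast_one(deficient, "deficient")
  hit_rec <- !is.na(t_rec)
  hit_def <- !is.na(t_def)
  distance <- matrix(Inf, shape[1], shape[2])
  both <- hit_rec & hit_def
  distance[both] <- abs(t_def[both] - t_rec[both])
  structure(list(hit_rec = hit_rec, hit_def = hit_def,
                 t_rec = t_rec, t_def = t_def, distance = distance,
                 warnings = warnings),
            class = "deviation_map")
}
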