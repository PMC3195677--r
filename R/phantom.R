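#' Phantom specification
#'
#' Describes a synthetic acetabular test case: a closed hemispherical cup
#' shell (inner radius `cavity_radius`, outer radius plus
#' `shell_thickness`, capped by a flat rim annulus) with known joint
#' center, rim plane and anatomical axes, plus a list of defect operations
#' applied to the deficient copy. Defaults emulate an adult acetabulum
#' (25 mm cavity radius, 4 mm shell).
#'
#' @param cavity_radius inner (cavity) radius in mm.
#' @param shell_thickness shell thickness in mm.
#' @param tessellation_level mesh refinement (>= 2): the cup uses
#'   `12 * 2^level` azimuthal segments and `3 * 2^level` polar rings.
#' @param defects list of defect operations, see [defect_wedge()],
#'   [defect_cap_hole()], [defect_erosion()].
#' @param pubic_strip `NULL`, or a list `list(phi_range, theta_range)`
#'   adding a detached bone strip beyond the rim (emulates the lower pubic
#'   ramus seen through the obturator foramen -- the "needle head").
#' @param rotation,translation optional rigid motion applied to the whole
#'   case (meshes, landmarks, truth), placing the phantom in a non-trivial
#'   world frame.
#' @param seed integer recorded in the spec; phantom construction is fully
#'   deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(cavity_radius = 25, shell_thickness = 4,
                         tessellation_level = 3, defects = list(),
                         pubic_strip = NULL, rotation = diag(3),
                         translation = c(0, 0, 0), seed = 1L) {
  stopifnot(cavity_radius > 0, shell_thickness > 0, tessellation_level >= 2)
  structure(list(cavity_radius = cavity_radius,
                 shell_thickness = shell_thickness,
                 tessellation_level = as.integer(tessellation_level),
                 defects = defects, pubic_strip = pubic_strip,
                 rotation = rotation, translation = as.numeric(translation),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Defect operations for the phantom
#'
#' `defect_wedge` deletes all faces (full thickness) whose centroid
#' azimuth lies in `[theta_min, theta_max]`; `defect_cap_hole` deletes
#' faces with centroid polar angle below `phi_max` (a medial
#' perforation); `defect_erosion` displaces inner-surface vertices in the
#' angular window radially outward by `depth` mm (cavity deepening
#' without perforation).
#'
#' @param theta_min,theta_max azimuth range (rad, in `[-pi, pi]`;
#'   `theta_min > theta_max` wraps across the seam).
#' @param phi_max polar angle bound (rad).
#' @param depth erosion depth (mm), > 0.
#' @param theta_range,phi_range length-2 angular windows (rad).
#' @return A defect description list.
#' @name defects
NULL

#' @rdname defects
#' @export
defect_wedge <- function(theta_min, theta_max) {
  list(kind = "theta_wedge", theta_min = theta_min, theta_max = theta_max)
}

#' @rdname defects
#' @export
defect_cap_hole <- function(phi_max) {
  stopifnot(phi_max > 0)
  list(kind = "cap_hole", phi_max = phi_max)
}

#' @rdname defects
#' @export
defect_erosion <- function(depth, theta_range, phi_range) {
  stopifnot(depth > 0)
  list(kind = "erosion", depth = depth, theta_range = theta_range,
       phi_range = phi_range)
}

# structured polar tessellation of the cup shell; pole at local -z,
# rim an exact circle in the local z = 0 plane
build_cup <- function(R, th, level) {
  n_b <- 12L * 2L^level
  n_a <- 3L * 2L^level
  alpha <- (seq_len(n_a) / n_a) * (pi / 2)
  # azimuths offset half a facet so the mesh seam and vertex meridians
  # never coincide with ray-grid columns (which sample multiples of
  # 2*pi/n); rays through mesh vertices are numerically fragile
  beta <- -pi + 2 * pi * (seq_len(n_b) - 0.5) / n_b
  ring_dirs <- lapply(alpha, function(a)
    cbind(sin(a) * cos(beta), sin(a) * sin(beta), rep(-cos(a), n_b)))
  surface <- function(rad) {
    verts <- rbind(c(0, 0, -rad),
                   do.call(rbind, lapply(ring_dirs, function(d) rad * d)))
    ring_idx <- function(a) 1L + (a - 1L) * n_b + seq_len(n_b)
    faces <- list()
    r1 <- ring_idx(1L)
    faces[[1]] <- cbind(1L, r1, c(r1[-1L], r1[1L]))  # pole fan
    for (a in seq_len(n_a - 1L)) {
      lo <- ring_idx(a)
      hi <- ring_idx(a + 1L)
      lon <- c(lo[-1L], lo[1L])
      hin <- c(hi[-1L], hi[1L])
      # alternate the quad diagonal so tessellation artifacts (ragged
      # defect edges after face deletion) carry no directional bias
      alt <- (a + seq_len(n_b)) %% 2L == 0L
      faces[[length(faces) + 1L]] <- rbind(
        cbind(lo, hi, hin)[alt, , drop = FALSE],
        cbind(lo, hin, lon)[alt, , drop = FALSE],
        cbind(lo, hi, lon)[!alt, , drop = FALSE],
        cbind(hi, hin, lon)[!alt, , drop = FALSE])
    }
    list(vertices = verts, faces = do.call(rbind, faces),
         rim = ring_idx(n_a))
  }
  inner <- surface(R)
  outer <- surface(R + th)
  nvi <- nrow(inner$vertices)
  verts <- rbind(inner$vertices, outer$vertices)
  faces <- rbind(inner$faces, outer$faces + nvi)
  ri <- inner$rim
  ro <- outer$rim + nvi
  rin <- c(ri[-1L], ri[1L])
  ron <- c(ro[-1L], ro[1L])
  alt <- seq_along(ri) %% 2L == 0L
  faces <- rbind(faces,
                 cbind(ri, ro, ron)[alt, , drop = FALSE],
                 cbind(ri, ron, rin)[alt, , drop = FALSE],
                 cbind(ri, ro, rin)[!alt, , drop = FALSE],
                 cbind(ro, ron, rin)[!alt, , drop = FALSE])
  list(vertices = verts, faces = faces,
       inner_idx = seq_len(nvi), n_b = n_b, n_a = n_a)
}

# local spherical coordinates of points/centroids: polar from -z
local_phi <- function(p) acos(pmin(pmax(-p[, 3] / sqrt(rowSums(p^2)), -1), 1))
local_theta <- function(p) atan2(p[, 2], p[, 1])

theta_in <- function(th, lo, hi) {
  if (lo <= hi) th >= lo & th <= hi
  else th >= lo | th <= hi  # wraps across the seam
}

# spherical rectangle patch at radius R (detached strip)
build_patch <- function(R, phi_range, theta_range, n_p = 5L, n_t = 12L) {
  ph <- seq(phi_range[1], phi_range[2], length.out = n_p)
  tt <- seq(theta_range[1], theta_range[2], length.out = n_t)
  g <- expand.grid(phi = ph, theta = tt)
  verts <- R * cbind(sin(g$phi) * cos(g$theta),
                     sin(g$phi) * sin(g$theta),
                     -cos(g$phi))
  id <- function(i, j) i + (j - 1L) * n_p
  i <- rep(seq_len(n_p - 1L), n_t - 1L)
  j <- rep(seq_len(n_t - 1L), each = n_p - 1L)
  faces <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                 cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  list(vertices = verts, faces = faces)
}

#' Generate a synthetic phantom case
#'
#' Builds the reconstructed (defect-free) cup shell, applies the defect
#' operations to obtain the deficient mesh, and assembles the matching
#' case configuration (exact rim circle points, inner-surface vertex
#' indices for the sphere fit, landmarks placed so that the anterior axis
#' is the local +x direction and the acetabular axis the local +z) plus a
#' ground-truth record.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `deficient`, `reconstructed`
#'   ([triangle_mesh()]), `config` ([case_config()]), and `truth` (list
#'   with `center`, `radius`, `n`, `ap_axis`, `sup_axis`, per-defect
#'   expectations).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$cavity_radius
  cup <- build_cup(R, spec$shell_thickness, spec$tessellation_level)
  verts_rec <- cup$vertices
  faces_rec <- cup$faces
  if (!is.null(spec$pubic_strip)) {
    patch <- build_patch(R, spec$pubic_strip$phi_range,
                         spec$pubic_strip$theta_range)
    faces_rec <- rbind(faces_rec, patch$faces + nrow(verts_rec))
    verts_rec <- rbind(verts_rec, patch$vertices)
  }
  verts_def <- verts_rec
  faces_def <- faces_rec
  for (df in spec$defects) {
    cen <- (verts_def[faces_def[, 1], , drop = FALSE] +
            verts_def[faces_def[, 2], , drop = FALSE] +
            verts_def[faces_def[, 3], , drop = FALSE]) / 3
    if (df$kind == "theta_wedge") {
      drop <- theta_in(local_theta(cen), df$theta_min, df$theta_max)
      faces_def <- faces_def[!drop, , drop = FALSE]
    } else if (df$kind == "cap_hole") {
      faces_def <- faces_def[local_phi(cen) >= df$phi_max, , drop = FALSE]
    } else if (df$kind == "erosion") {
      vin <- rep(FALSE, nrow(verts_def))
      vin[cup$inner_idx] <- TRUE
      ph <- local_phi(verts_def)
      th <- local_theta(verts_def)
      win <- vin & ph >= df$phi_range[1] & ph <= df$phi_range[2] &
        theta_in(th, df$theta_range[1], df$theta_range[2])
      len <- sqrt(rowSums(verts_def[win, , drop = FALSE]^2))
      verts_def[win, ] <- verts_def[win, , drop = FALSE] *
        (1 + df$depth / len)
    } else stop("unknown defect kind: ", df$kind, call. = FALSE)
  }
  if (nrow(faces_def) == 0L)
    stop("phantom degenerate: defects removed the entire mesh",
         call. = FALSE)
  # the rim must survive: keep at least one rim-annulus face
  cen_def <- (verts_def[faces_def[, 1], , drop = FALSE] +
              verts_def[faces_def[, 2], , drop = FALSE] +
              verts_def[faces_def[, 3], , drop = FALSE]) / 3
  if (!any(abs(cen_def[, 3]) < 1e-9 &
           sqrt(rowSums(cen_def^2)) > R * 0.9))
    stop("phantom degenerate: defects removed the entire rim",
         call. = FALSE)
  rot <- spec$rotation
  tra <- spec$translation
  place <- function(p) sweep(as.matrix(p) %*% t(rot), 2L, tra, "+")
  rec <- triangle_mesh(place(verts_rec), faces_rec, clean = FALSE)
  def <- triangle_mesh(place(verts_def), faces_def, clean = FALSE)
  # landmarks: anterior = local +x, superior = local +y, lateral = +z
  lms <- list(asis_left = drop(place(rbind(c(10, 60, -140)))),
              asis_right = drop(place(rbind(c(10, 60, 60)))),
              pubis = drop(place(rbind(c(70, 60, -40)))))
  rim_beta <- -pi + 2 * pi * (seq_len(48L) - 1L) / 48L
  rim_pts <- place(cbind(R * cos(rim_beta), R * sin(rim_beta), 0))
  config <- case_config(rim_pts, list(indices = cup$inner_idx), lms,
                        side = "right", mesh = rec)
  truth <- list(center = drop(place(rbind(c(0, 0, 0)))),
                radius = R,
                n = as.numeric(rot %*% c(0, 0, 1)),
                ap_axis = as.numeric(rot %*% c(1, 0, 0)),
                sup_axis = as.numeric(rot %*% c(0, 1, 0)),
                defects = spec$defects,
                expected = phantom_expectations(spec))
  list(deficient = def, reconstructed = rec, config = config,
       truth = truth, spec = spec)
}

# analytic expectations where a closed form exists
phantom_expectations <- function(spec) {
  out <- list()
  for (df in spec$defects) {
    if (df$kind == "theta_wedge") {
      width <- (df$theta_max - df$theta_min) %% (2 * pi)
      out$global_ratio <- (out$global_ratio %||% 0) +
        width / (2 * pi) * 100
    }
    if (df$kind == "cap_hole" && isTRUE(all.equal(df$phi_max, pi / 6)))
      out$med_ratio <- 100
  }
  if (length(spec$defects) == 0L) out$global_ratio <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged phantom presets
#'
#' Named fixture set used throughout validation: `identity` (no defect),
#' `wedge25` (full-thickness quarter-turn wedge, 25 percent expected
#' global ratio), `perforation` (medial cap hole coinciding with the Med
#' region), `erosion3` (3 mm cavity erosion, no total loss),
#' `needlehead` (healthy cup plus a detached pubic-ramus strip), and
#' `combined` (wedge + medial hole + erosion).
#'
#' @param name preset name.
#' @param ... passed on to [phantom_spec()] (e.g. `tessellation_level`).
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("identity", "wedge25", "perforation",
                                    "erosion3", "needlehead", "combined"),
                           ...) {
  name <- match.arg(name)
  args <- switch(name,
    identity = list(),
    wedge25 = list(defects = list(defect_wedge(-pi / 4, pi / 4))),
    perforation = list(defects = list(defect_cap_hole(pi / 6))),
    erosion3 = list(defects = list(
      defect_erosion(3, c(-pi / 3, pi / 3), c(0.5, 1.2)))),
    needlehead = list(pubic_strip = list(
      phi_range = c(pi / 2 + 0.15, pi / 2 + 0.35),
      theta_range = c(-0.5, 0.5))),
    combined = list(
      defects = list(defect_wedge(1.8, 2.8),
                     defect_cap_hole(pi / 8),
                     defect_erosion(2, c(-2.5, -1.5), c(0.6, 1.2)))))
  do.call(phantom_spec, c(args, list(...)))
}

#' Write a phantom case to disk
#'
#' Writes `deficient.stl`, `reconstructed.stl`, `case.json`, `truth.json`
#' into `outdir`.
#'
#' @param phantom a [make_phantom()] result.
#' @param outdir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(phantom$deficient, file.path(outdir, "deficient.stl"))
  write_mesh(phantom$reconstructed, file.path(outdir, "reconstructed.stl"))
  write_case_config(phantom$config, file.path(outdir, "case.json"))
  tr <- phantom$truth
  tr$defects <- NULL
  jsonlite::write_json(tr, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
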