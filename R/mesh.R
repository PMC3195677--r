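#' Triangle surface mesh
#'
#' Lightweight container for a triangle surface mesh in millimeters: an
#' `n x 3` numeric vertex matrix and an `m x 3` integer face matrix of
#' 1-based vertex indices. On construction the mesh is cleaned: duplicate
#' vertices are merged within `merge_tol` and degenerate faces (repeated
#' vertices, or area at or below `area_tol`) are dropped.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices. May have
#'   zero rows (a point set with no surface; casts never hit it).
#' @param clean logical; merge duplicate vertices and drop degenerate faces.
#' @param merge_tol vertex merge tolerance in mm.
#' @param area_tol zero-area face threshold in mm^2.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' tet <- triangle_mesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' )
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE,
                          merge_tol = 1e-6, area_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("mesh vertices must be an n x 3 matrix", call. = FALSE)
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(faces) != 3L)
    stop("mesh faces must be an m x 3 matrix", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("mesh vertices contain non-finite coordinates", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("mesh face index out of range", call. = FALSE)
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (clean) m <- clean_mesh(m, merge_tol = merge_tol, area_tol = area_tol)
  if (nrow(m$vertices) < 4L)
    stop("degenerate mesh: fewer than 4 vertices after cleaning",
         call. = FALSE)
  m
}

#' Merge duplicate vertices and drop degenerate faces
#'
#' @param mesh a [triangle_mesh()].
#' @inheritParams triangle_mesh
#' @return The cleaned `triangle_mesh`. Non-degenerate faces are never
#'   altered beyond index remapping.
#' @export
clean_mesh <- function(mesh, merge_tol = 1e-6, area_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  # quantize to the merge grid; identical keys collapse to one vertex
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  if (nrow(f) > 0L) {
    f2 <- matrix(map[f], ncol = 3L)
    rep_ok <- f2[, 1] != f2[, 2] & f2[, 1] != f2[, 3] & f2[, 2] != f2[, 3]
    f2 <- f2[rep_ok, , drop = FALSE]
    if (nrow(f2) > 0L) {
      a <- v2[f2[, 1], , drop = FALSE]
      e1 <- v2[f2[, 2], , drop = FALSE] - a
      e2 <- v2[f2[, 3], , drop = FALSE] - a
      cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
      cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
      cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
      area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
      f2 <- f2[area > area_tol, , drop = FALSE]
    }
  } else {
    f2 <- f
  }
  structure(list(vertices = v2, faces = f2), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  invisible(x)
}

#' Apply a rigid motion to a mesh or point matrix
#'
#' @param x a `triangle_mesh` or an n x 3 point matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return The transformed object.
#' @export
transform_rigid <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(p) sweep(p %*% t(rotation), 2L, translation, "+")
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- tr(x$vertices)
    x
  } else {
    tr(as.matrix(x))
  }
}

# face centroids, n x 3
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
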