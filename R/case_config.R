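#' Case configuration
#'
#' Bundles the per-case inputs that accompany the two meshes: the ordered
#' rim outline of the reconstructed acetabulum, the acetabular-region point
#' set used for sphere fitting, the three pelvic landmarks, and the side.
#'
#' @param rim_outline ordered matrix (>= 3 x 3) of points on the
#'   reconstructed acetabular rim (mm), or a list `list(indices = ...)` of
#'   1-based vertex indices into the reconstructed mesh.
#' @param acetabular_region matrix (>= 4 x 3) of points on the reconstructed
#'   cup surface, or `list(indices = ...)`.
#' @param landmarks named list with 3-vectors `asis_left`, `asis_right`,
#'   `pubis` (mm).
#' @param side `"left"` or `"right"`.
#' @param mesh optional reconstructed [triangle_mesh()] used to resolve
#'   index-form inputs to coordinates.
#' @return An object of class `case_config` with matrix-valued
#'   `rim_outline` and `acetabular_region` (indices, when given, are kept in
#'   attributes for serialization).
#' @export
case_config <- function(rim_outline, acetabular_region, landmarks, side,
                        mesh = NULL) {
  side <- match.arg(side, c("left", "right"))
  resolve <- function(x, what) {
    idx <- NULL
    if (is.list(x) && !is.null(x$indices)) {
      if (is.null(mesh))
        stop("config error: ", what,
             " given as indices but no reconstructed mesh supplied",
             call. = FALSE)
      idx <- as.integer(x$indices)
      if (any(idx < 1L) || any(idx > nrow(mesh$vertices)))
        stop("config error: ", what, " index out of range", call. = FALSE)
      x <- mesh$vertices[idx, , drop = FALSE]
    }
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (ncol(x) != 3L || !all(is.finite(x)))
      stop("config error: ", what, " must be finite n x 3 points",
           call. = FALSE)
    attr(x, "indices") <- idx
    x
  }
  rim <- resolve(rim_outline, "rim_outline")
  if (nrow(rim) < 3L)
    stop("config error: rim_outline needs >= 3 points", call. = FALSE)
  if (points_rank(rim) < 2L)
    stop("config error: rim_outline points are collinear", call. = FALSE)
  reg <- resolve(acetabular_region, "acetabular_region")
  if (nrow(reg) < 4L || points_rank(reg) < 3L)
    stop("config error: acetabular_region needs >= 4 non-coplanar points",
         call. = FALSE)
  need <- c("asis_left", "asis_right", "pubis")
  if (!is.list(landmarks) || !all(need %in% names(landmarks)))
    stop("config error: landmarks must include asis_left, asis_right, pubis",
         call. = FALSE)
  lm <- lapply(landmarks[need], function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("config error: landmark must be a finite 3-vector", call. = FALSE)
    p
  })
  d <- utils::combn(3L, 2L)
  if (any(apply(d, 2L, function(ij) {
    vnorm(lm[[ij[1]]] - lm[[ij[2]]]) < 1e-9
  })))
    stop("config error: landmarks must be distinct", call. = FALSE)
  structure(list(rim_outline = rim, acetabular_region = reg,
                 landmarks = lm, side = side),
            class = "case_config")
}

# affine rank of a point set (1 = collinear, 2 = coplanar, 3 = general)
points_rank <- function(p, tol = 1e-9) {
  cen <- sweep(p, 2L, colMeans(p))
  d <- svd(cen, nu = 0L, nv = 0L)$d
  sum(d > tol * max(d[1], 1))
}

#' Read a case configuration from JSON
#'
#' JSON schema:
#' `{"rim_outline": [[x,y,z],...] | {"indices":[...]},`
#' `"acetabular_region": {"indices":[...]} | [[x,y,z],...],`
#' `"landmarks": {"asis_left":[x,y,z], "asis_right":[x,y,z],`
#' `"pubis":[x,y,z]}, "side": "left"|"right"}`.
#' Indices are 1-based into the reconstructed mesh vertex list; explicit
#' points take precedence over indices when both are present.
#'
#' @param path JSON file path.
#' @param mesh optional reconstructed [triangle_mesh()] to resolve
#'   index-form entries.
#' @return A [case_config()].
#' @export
read_case_config <- function(path, mesh = NULL) {
  if (!file.exists(path))
    stop("config error: file not found: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  pick <- function(x) {
    # points take precedence over indices
    if (is.list(x) && !is.null(x$points)) return(as.matrix(x$points))
    if (is.list(x) && !is.null(x$indices)) return(list(indices = x$indices))
    x
  }
  case_config(pick(js$rim_outline), pick(js$acetabular_region),
              js$landmarks, js$side, mesh = mesh)
}

#' Write a case configuration to JSON
#'
#' @param config a [case_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_config <- function(config, path) {
  ser <- function(x) {
    idx <- attr(x, "indices")
    if (!is.null(idx)) list(indices = idx) else unname(as.matrix(x))
  }
  jsonlite::write_json(
    list(rim_outline = ser(config$rim_outline),
         acetabular_region = ser(config$acetabular_region),
         landmarks = lapply(config$landmarks, as.numeric),
         side = config$side),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
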