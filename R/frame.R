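#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud (the user-outlined reconstructed
#' acetabular cup); its center is the origin of all radial rays. An
#' algebraic linear fit initializes a geometric Gauss-Newton refinement of
#' `sum((|p - c| - r)^2)`, iterated to a step tolerance of 1e-9 mm.
#'
#' @param points numeric matrix (>= 4 x 3) of non-coplanar points (mm).
#' @return A list of class `sphere_fit`: `center` (mm), `radius` (mm),
#'   `rms_residual` (mm, RMS of `|dist(p, center) - radius|`).
#' @export
fit_sphere <- function(points) {
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (nrow(p) < 4L || points_rank(p) < 3L)
    stop("degenerate geometry: sphere fit needs >= 4 non-coplanar points",
         call. = FALSE)
  # algebraic init: |p|^2 = 2 c.p + (r^2 - |c|^2), linear in (c, k)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  beta <- qr.coef(qr(A), b)
  cen <- beta[1:3]
  r <- sqrt(max(beta[4] + sum(cen^2), .Machine$double.eps))
  # geometric Gauss-Newton on (c, r)
  for (it in 1:100) {
    d <- sweep(p, 2L, cen)
    len <- sqrt(rowSums(d^2))
    len[len < 1e-12] <- 1e-12
    res <- len - r
    J <- cbind(-d / len, -1)
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 4))
    step[is.na(step)] <- 0
    cen <- cen + step[1:3]
    r <- r + step[4]
    if (max(abs(step)) < 1e-9) break
  }
  len <- sqrt(rowSums(sweep(p, 2L, cen)^2))
  structure(list(center = as.numeric(cen), radius = as.numeric(r),
                 rms_residual = sqrt(mean((len - r)^2))),
            class = "sphere_fit")
}

#' Total-least-squares rim plane fit
#'
#' Fits a plane to the ordered rim outline points: the plane through their
#' centroid whose normal is the smallest principal component of the
#' centered points.
#'
#' @param rim_points numeric matrix (>= 3 x 3) of non-collinear points (mm).
#' @return A list of class `rim_plane`: `point` (centroid, mm) and unit
#'   `normal`.
#' @export
fit_rim_plane <- function(rim_points) {
  p <- as.matrix(rim_points)
  storage.mode(p) <- "double"
  if (nrow(p) < 3L || points_rank(p) < 2L)
    stop("degenerate geometry: plane fit needs >= 3 non-collinear points",
         call. = FALSE)
  cen <- colMeans(p)
  sv <- svd(sweep(p, 2L, cen), nu = 0L)
  structure(list(point = as.numeric(cen),
                 normal = as.numeric(sv$v[, 3])),
            class = "rim_plane")
}

#' Build the acetabular coordinate frame
#'
#' Combines the fitted sphere, the rim plane, and the pelvic landmarks into
#' the frame used by the ray grid and the region labels:
#' \itemize{
#' \item `n` — the acetabular axis: the rim-plane normal, signed to point
#'   laterally (positive dot product with the direction from the ASIS
#'   midpoint to the sphere center).
#' \item `ap_axis` — the ISB anterior pelvic axis projected into the rim
#'   plane. The ISB pelvic frame is built as: Z from left ASIS to right
#'   ASIS; X (anterior) orthogonal to Z within the plane through both ASIS
#'   and the pubis point, pointing toward the pubis; Y (superior) = Z x X.
#' \item `sup_axis` — `n x ap_axis`, sign-flipped if needed so that it has
#'   a positive dot product with the ISB superior axis; this absorbs the
#'   left/right handedness so the same sector table serves both sides.
#' }
#'
#' @param sphere a [fit_sphere()] result.
#' @param plane a [fit_rim_plane()] result.
#' @param landmarks named list with `asis_left`, `asis_right`, `pubis`.
#' @param side `"left"` or `"right"`.
#' @return A list of class `acetabular_frame`: `center`, `n`, `rim_plane`,
#'   `ap_axis`, `sup_axis`, `side`.
#' @export
build_frame <- function(sphere, plane, landmarks, side = c("right", "left")) {
  side <- match.arg(side)
  lml <- as.numeric(landmarks$asis_left)
  lmr <- as.numeric(landmarks$asis_right)
  pub <- as.numeric(landmarks$pubis)
  mid <- (lml + lmr) / 2
  # ISB pelvic axes from the ASIS line and the pubis point
  z_isb <- unit(lmr - lml)
  w <- pub - mid
  x_raw <- w - sum(w * z_isb) * z_isb
  if (vnorm(x_raw) < 1e-9)
    stop("frame error: landmarks are collinear", call. = FALSE)
  x_isb <- unit(x_raw)
  y_isb <- cross3(z_isb, x_isb)
  # lateral sign of n: from the ASIS midpoint toward the sphere center
  n <- unit(plane$normal)
  lat <- sphere$center - mid
  if (sum(lat * n) < 0) n <- -n
  # anterior axis projected into the rim plane
  ap_raw <- x_isb - sum(x_isb * n) * n
  if (vnorm(ap_raw) < sin(pi / 180))
    stop("frame error: anterior axis is parallel to the acetabular axis",
         call. = FALSE)
  ap <- unit(ap_raw)
  sup <- cross3(n, ap)
  if (sum(sup * y_isb) < 0) sup <- -sup
  structure(list(center = as.numeric(sphere$center), n = n,
                 rim_plane = plane, ap_axis = ap, sup_axis = sup,
                 side = side, isb = list(x = x_isb, y = y_isb, z = z_isb)),
            class = "acetabular_frame")
}

#' @export
print.acetabular_frame <- function(x, ...) {
  cat("acetabular_frame (side:", x$side, ")\n")
  cat("  center  :", paste(sprintf("%.3f", x$center), collapse = ", "), "mm\n")
  cat("  n       :", paste(sprintf("%.4f", x$n), collapse = ", "), "\n")
  cat("  ap_axis :", paste(sprintf("%.4f", x$ap_axis), collapse = ", "), "\n")
  cat("  sup_axis:", paste(sprintf("%.4f", x$sup_axis), collapse = ", "), "\n")
  invisible(x)
}
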