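# Test helpers. r_cast_first_hit is a third, pure-R Moller-Trumbore
# reference caster (vectorized over triangles, one ray at a time) used as
# the independent oracle on small meshes; it shares no code with either
# compiled caster.

r_cast_first_hit <- function(origin, dir, mesh, eps = 1e-6) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(NA_real_)
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  s <- matrix(origin, nrow(a), 3, byrow = TRUE) - a
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / det
  t <- rowSums(e2 * q) / det
  ok <- abs(det) > 1e-12 & u >= 0 & u <= 1 & vv >= 0 & u + vv <= 1 &
    t > eps
  if (!any(ok, na.rm = TRUE)) return(NA_real_)
  min(t[ok], na.rm = TRUE)
}

# unit tetrahedron mesh
tetra_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# small, fast phantom for unit tests
fast_preset <- function(name, ...) {
  phantom_preset(name, tessellation_level = 2, ...)
}

rotation_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
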