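#' Icosphere mesh
#'
#' Unit icosahedron subdivided `level` times with vertices projected onto
#' the sphere of radius `radius`. Mainly used as a closed analytic test
#' body for the ray caster (the maximum chord error of the tessellation
#' is returned as an attribute).
#'
#' @param radius sphere radius (mm).
#' @param level subdivision level (0 = icosahedron, 20 faces; each level
#'   quadruples the face count).
#' @param center sphere center.
#' @return A [triangle_mesh()] with attribute `chord_error` (mm), the
#'   maximal radial shortfall of a face relative to the sphere.
#' @export
icosphere <- function(radius = 1, level = 2L, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      mids[[k]] <- nv + length(newv)
      mids[[k]]
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  # chord error: face centroid falls short of the sphere by this much
  cenr <- sqrt(rowSums(((v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3)^2))
  err <- radius * (1 - min(cenr))
  m <- triangle_mesh(sweep(v * radius, 2L, center, "+"), f, clean = FALSE)
  attr(m, "chord_error") <- err
  m
}
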