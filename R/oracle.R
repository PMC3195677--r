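#' Dense brute-force oracle ratios for a phantom
#'
#' Recomputes the global and per-region TrABL ratios of a phantom case
#' along a standalone path that shares no code with the main pipeline:
#' a `dense_n x dense_n` direction set built inline from the phantom's
#' ground-truth frame, the exhaustive triangle-loop ray caster (no
#' spatial acceleration), strict all-corner cell membership, and its own
#' shoelace area summation. Used to validate the pipeline within a stated
#' tolerance, never as the implementation.
#'
#' @param spec a [phantom_spec()].
#' @param dense_n grid resolution per axis.
#' @return A list: `global` ratio (percent), `per_region` named vector
#'   (NA where a region has no reconstructed hit area), `A_rec`, `A_def`.
#' @export
oracle_ratio <- function(spec, dense_n = 400L) {
  ph <- make_phantom(spec)
  tru <- ph$truth
  n <- as.integer(dense_n)
  phiv <- seq(0, pi, length.out = n)
  thev <- -pi + 2 * pi * (seq_len(n) - 1L) / n
  P <- matrix(phiv, n, n)
  TH <- matrix(thev, n, n, byrow = TRUE)
  dir <- cbind(-cos(as.vector(P)) * tru$n[1] +
                 sin(as.vector(P)) * (cos(as.vector(TH)) * tru$ap_axis[1] +
                                      sin(as.vector(TH)) * tru$sup_axis[1]),
               -cos(as.vector(P)) * tru$n[2] +
                 sin(as.vector(P)) * (cos(as.vector(TH)) * tru$ap_axis[2] +
                                      sin(as.vector(TH)) * tru$sup_axis[2]),
               -cos(as.vector(P)) * tru$n[3] +
                 sin(as.vector(P)) * (cos(as.vector(TH)) * tru$ap_axis[3] +
                                      sin(as.vector(TH)) * tru$sup_axis[3]))
  t_rec <- cpp_cast_brute(ph$reconstructed$vertices,
                          ph$reconstructed$faces,
                          as.numeric(tru$center), dir, 1e-6)
  t_def <- cpp_cast_brute(ph$deficient$vertices, ph$deficient$faces,
                          as.numeric(tru$center), dir, 1e-6)
  hit_rec <- matrix(!is.na(t_rec), n, n)
  hit_def <- matrix(!is.na(t_def), n, n)
  # planar coordinates, r = phi (unit sphere)
  X <- P * cos(TH)
  Y <- P * sin(TH)
  # region labels: medial cap, then 72-degree sectors of theta from the
  # anterior axis toward the superior axis (psi == theta here since the
  # direction set is built on the truth axes)
  med <- sin(P) <= 0.5 + 1e-9 & P <= pi / 2 + 1e-9
  psi <- (TH * 180 / pi) %% 360
  sec <- c("AntSup", "PostSup", "PostInf", "Inf", "AntInf")[
    floor(psi / 72 + 1e-7) %% 5 + 1L]
  lab <- matrix(ifelse(med, "Med", sec), n, n)
  # all-corner cell area: cell (i, j) spans rows i:i+1, cols j, j+1 (mod n)
  area_all_corner <- function(keep) {
    i <- rep(seq_len(n - 1L), times = n)
    j <- rep(seq_len(n), each = n - 1L)
    jp <- j %% n + 1L
    a1 <- i + (j - 1L) * n
    a2 <- i + 1L + (j - 1L) * n
    a3 <- i + 1L + (jp - 1L) * n
    a4 <- i + (jp - 1L) * n
    inside <- keep[a1] & keep[a2] & keep[a3] & keep[a4]
    sh <- 0.5 * abs(X[a1] * (Y[a2] - Y[a4]) + X[a2] * (Y[a3] - Y[a1]) +
                    X[a3] * (Y[a4] - Y[a2]) + X[a4] * (Y[a1] - Y[a3]))
    sum(sh[inside])
  }
  A_rec <- area_all_corner(hit_rec)
  A_def <- area_all_corner(hit_def)
  regs <- c("PostInf", "Inf", "AntInf", "AntSup", "PostSup", "Med")
  per <- vapply(regs, function(rg) {
    ar <- area_all_corner(hit_rec & lab == rg)
    if (ar <= 0) return(NA_real_)
    ad <- area_all_corner(hit_def & lab == rg)
    (1 - ad / ar) * 100
  }, numeric(1))
  list(global = (1 - A_def / A_rec) * 100, per_region = per,
       A_rec = A_rec, A_def = A_def)
}
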