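test_that("sphere fit recovers exact spherical data", {
  set.seed(11)
  n <- 200
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p <- sweep(24 * u, 2, c(10, -5, 3), "+")
  fit <- fit_sphere(p)
  expect_equal(fit$center, c(10, -5, 3), tolerance = 1e-6)
  expect_equal(fit$radius, 24, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-6)
})

test_that("noisy sphere fit matches direct numerical least squares", {
  set.seed(42)
  n <- 500
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p <- 24 * u + matrix(rnorm(3 * n, sd = 0.2), ncol = 3)
  fit <- fit_sphere(p)
  # independent oracle: direct minimization of sum((|p - c| - r)^2)
  obj <- function(th) {
    d <- sqrt(rowSums(sweep(p, 2, th[1:3])^2))
    sum((d - th[4])^2)
  }
  opt <- stats::optim(c(0, 0, 0, 20), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_lt(abs(fit$radius - opt$par[4]), 0.05)
  expect_lt(sum((fit$center - opt$par[1:3])^2), 0.05^2)
  # and the fit objective is no worse than the oracle's
  expect_lte(obj(c(fit$center, fit$radius)), opt$value * (1 + 1e-6))
})

test_that("degenerate sphere inputs error", {
  flat <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_error(fit_sphere(flat), "non-coplanar")
  expect_error(fit_sphere(flat[1:3, ]), "non-coplanar")
})

test_that("sphere fit is invariant under rigid motion", {
  set.seed(7)
  u <- matrix(rnorm(600), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  p <- 18 * u + matrix(rnorm(600, sd = 0.1), ncol = 3)
  f0 <- fit_sphere(p)
  R <- rotation_xyz(0.3, -0.7, 1.2)
  tr <- c(5, -40, 12)
  f1 <- fit_sphere(transform_rigid(p, R, tr))
  expect_equal(f1$center, as.numeric(R %*% f0$center + tr),
               tolerance = 1e-6)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-6)
})

test_that("rim plane fit recovers exact planes", {
  set.seed(3)
  p <- cbind(runif(30, -10, 10), runif(30, -10, 10), 5)
  pl <- fit_rim_plane(p)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl$point[3], 5, tolerance = 1e-9)
  expect_error(fit_rim_plane(p[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rim_plane(line), "collinear")
})

test_that("phantom rim plane is recovered exactly", {
  ph <- make_phantom(fast_preset("identity"))
  pl <- fit_rim_plane(ph$config$rim_outline)
  expect_equal(abs(sum(pl$normal * ph$truth$n)), 1, tolerance = 1e-9)
  expect_lt(abs(sum((pl$point - ph$truth$center) * ph$truth$n)), 1e-9)
})

test_that("frame axes are axis-aligned on the phantom and orthonormal", {
  ph <- make_phantom(fast_preset("identity"))
  sp <- fit_sphere(ph$config$acetabular_region)
  pl <- fit_rim_plane(ph$config$rim_outline)
  fr <- build_frame(sp, pl, ph$config$landmarks, ph$config$side)
  expect_equal(fr$n, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$ap_axis, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$sup_axis, c(0, 1, 0), tolerance = 1e-9)
  # orthonormal triad
  M <- rbind(fr$n, fr$ap_axis, fr$sup_axis)
  expect_equal(M %*% t(M), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("n is plane-determined: sphere displacement leaves it unchanged", {
  ph <- make_phantom(fast_preset("identity"))
  sp <- fit_sphere(ph$config$acetabular_region)
  pl <- fit_rim_plane(ph$config$rim_outline)
  sp2 <- sp
  sp2$center <- sp$center + c(2, 0, 0)  # 2 mm in-plane displacement
  fr <- build_frame(sp, pl, ph$config$landmarks, ph$config$side)
  fr2 <- build_frame(sp2, pl, ph$config$landmarks, ph$config$side)
  expect_equal(fr2$n, fr$n, tolerance = 1e-12)
})

test_that("frame errors when the anterior axis parallels the axis", {
  ph <- make_phantom(fast_preset("identity"))
  sp <- fit_sphere(ph$config$acetabular_region)
  pl <- fit_rim_plane(ph$config$rim_outline)
  # pubis on the ASIS line -> no anterior direction
  lm_col <- list(asis_left = c(0, 10, -100), asis_right = c(0, 10, 100),
                 pubis = c(0, 10, 0))
  expect_error(build_frame(sp, pl, lm_col, "right"), "collinear")
  # anterior axis along +z, parallel to the acetabular axis n
  lm_par <- list(asis_left = c(0, -100, 0), asis_right = c(0, 100, 0),
                 pubis = c(0, 0, 60))
  expect_error(build_frame(sp, pl, lm_par, "right"), "parallel")
})

test_that("superior axis flips with handedness to stay superior", {
  ph <- make_phantom(fast_preset("identity"))
  sp <- fit_sphere(ph$config$acetabular_region)
  pl <- fit_rim_plane(ph$config$rim_outline)
  fr <- build_frame(sp, pl, ph$config$landmarks, "right")
  # mirrored landmarks (left/right ASIS swapped across the midline)
  lm <- ph$config$landmarks
  lm_mirror <- list(asis_left = lm$asis_right, asis_right = lm$asis_left,
                    pubis = lm$pubis)
  fr_l <- build_frame(sp, pl, lm_mirror, "left")
  expect_equal(fr_l$ap_axis, fr$ap_axis, tolerance = 1e-9)
  # ISB superior axis flipped with Z; sup_axis follows it
  expect_equal(fr_l$sup_axis, -fr$sup_axis, tolerance = 1e-9)
})
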