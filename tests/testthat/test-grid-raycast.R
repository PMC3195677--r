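phantom_frame <- function(ph) {
  build_frame(fit_sphere(ph$config$acetabular_region),
              fit_rim_plane(ph$config$rim_outline),
              ph$config$landmarks, ph$config$side)
}

test_that("grid sampling and pole directions follow the parameterization", {
  ph <- make_phantom(fast_preset("identity"))
  fr <- phantom_frame(ph)
  g <- build_grid(fr, 100, 100)
  expect_equal(length(g$phi) * length(g$theta), 10000L)
  expect_equal(range(g$phi), c(0, pi))
  expect_equal(g$theta[1], -pi)
  expect_lt(max(g$theta), pi)  # half-open azimuth
  expect_equal(diff(g$phi), rep(pi / 99, 99))
  # phi = 0 points along -n for every theta
  d0 <- g$directions[seq(1, by = 100, length.out = 100), ]
  expect_equal(d0, matrix(-fr$n, 100, 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # phi = pi points along +n
  dpi <- g$directions[100, ]
  expect_equal(dpi, fr$n, tolerance = 1e-12)
  # phi = pi/2, theta = 0 points along the anterior axis
  g2 <- build_grid(fr, 3, 4)  # phi = 0, pi/2, pi; theta = -pi..pi/2
  d <- g2$directions[2 + 2 * 3, ]  # phi index 2, theta index 3 (theta=0)
  expect_equal(d, fr$ap_axis, tolerance = 1e-12)
  expect_error(build_grid(fr, 1, 10), "n_phi")
  # unit directions
  expect_equal(rowSums(g$directions^2), rep(1, 10000), tolerance = 1e-12)
})

test_that("first hit on an icosphere equals its radius within chord error", {
  ico <- icosphere(radius = 20, level = 3)
  chord <- attr(ico, "chord_error")
  set.seed(5)
  d <- matrix(rnorm(90), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  t <- cast_first_hit(c(0, 0, 0), d, ico)
  expect_true(all(is.finite(t)))
  expect_true(all(t <= 20 + 1e-9 & t >= 20 - chord - 1e-9))
})

test_that("rays through an open hemisphere's missing half miss", {
  ico <- icosphere(radius = 10, level = 2)
  cen <- (ico$vertices[ico$faces[, 1], ] +
          ico$vertices[ico$faces[, 2], ] +
          ico$vertices[ico$faces[, 3], ]) / 3
  hemi <- triangle_mesh(ico$vertices, ico$faces[cen[, 3] < 0, ],
                        clean = FALSE)
  expect_true(is.na(cast_first_hit(c(0, 0, 0), c(0, 0, 1), hemi)))
  expect_equal(cast_first_hit(c(0, 0, 0), c(0, 0, -1), hemi), 10,
               tolerance = 0.2)
})

test_that("a ray through a shared edge yields a single deduplicated hit", {
  v <- rbind(c(-1, -1, 5), c(1, -1, 5), c(1, 1, 5), c(-1, 1, 5))
  quad <- triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  # the diagonal edge passes through (0, 0, 5)
  t <- cast_first_hit(c(0, 0, 0), c(0, 0, 1), quad)
  expect_equal(t, 5)
  expect_length(t, 1L)
})

test_that("bvh and brute casters agree exactly; both match the R oracle", {
  ico <- icosphere(radius = 15, level = 1, center = c(3, -2, 1))
  expect_lte(nrow(ico$faces), 500L)
  set.seed(99)
  n <- 1000
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  origin <- c(2, 0, 0)
  t_bvh <- cast_first_hit(origin, d, ico, method = "bvh")
  t_brute <- cast_first_hit(origin, d, ico, method = "brute")
  expect_identical(t_bvh, t_brute)
  t_r <- vapply(seq_len(n), function(i)
    r_cast_first_hit(origin, d[i, ], ico), numeric(1))
  expect_equal(t_bvh, t_r, tolerance = 1e-9)
})

test_that("coinciding meshes give zero deviation wherever both are hit", {
  ph <- make_phantom(fast_preset("identity"))
  fr <- phantom_frame(ph)
  g <- build_grid(fr, 60, 60)
  dm <- compute_deviation_map(g, ph$deficient, ph$reconstructed)
  expect_identical(dm$hit_rec, dm$hit_def)
  expect_true(all(dm$distance[dm$hit_rec] == 0))
  expect_true(all(is.infinite(dm$distance[!dm$hit_rec])))
  expect_true(all(dm$t_rec[dm$hit_rec] > 0))
})

test_that("3 mm erosion reads 3 mm in the deviation map", {
  ph <- make_phantom(fast_preset("erosion3"))
  fr <- phantom_frame(ph)
  g <- build_grid(fr, 100, 100)
  dm <- compute_deviation_map(g, ph$deficient, ph$reconstructed)
  # interior of the erosion window: phi in [0.5, 1.2], theta in [-pi/3, pi/3]
  P <- matrix(g$phi, 100, 100)
  TH <- matrix(g$theta, 100, 100, byrow = TRUE)
  inwin <- P > 0.65 & P < 1.05 & abs(TH) < pi / 4
  expect_true(all(abs(dm$distance[inwin] - 3) < 0.1))
  outwin <- P < 0.35 & dm$hit_rec
  expect_true(all(dm$distance[outwin] < 0.1))
})

test_that("medial perforation gives no-intersection through the cap", {
  ph <- make_phantom(fast_preset("perforation"))
  fr <- phantom_frame(ph)
  g <- build_grid(fr, 100, 100)
  dm <- compute_deviation_map(g, ph$deficient, ph$reconstructed)
  P <- matrix(g$phi, 100, 100)
  cap <- P < pi / 6 - 0.1
  expect_true(all(!dm$hit_def[cap]))
  expect_true(all(is.infinite(dm$distance[cap])))
  expect_true(all(dm$hit_rec[cap]))
})

test_that("deviation map is invariant under a common rigid motion", {
  ph <- make_phantom(fast_preset("erosion3"))
  fr <- phantom_frame(ph)
  g <- build_grid(fr, 40, 40)
  dm <- compute_deviation_map(g, ph$deficient, ph$reconstructed)
  R <- rotation_xyz(0.4, -0.2, 0.9)
  tr <- c(30, -12, 44)
  ph2 <- make_phantom(fast_preset("erosion3", rotation = R,
                                  translation = tr))
  fr2 <- phantom_frame(ph2)
  g2 <- build_grid(fr2, 40, 40)
  dm2 <- compute_deviation_map(g2, ph2$deficient, ph2$reconstructed)
  expect_identical(dm2$hit_rec, dm$hit_rec)
  expect_identical(dm2$hit_def, dm$hit_def)
  fin <- is.finite(dm$distance)
  expect_equal(dm2$distance[fin], dm$distance[fin], tolerance = 1e-6)
})

test_that("an origin on the mesh surface is flagged", {
  ph <- make_phantom(fast_preset("identity"))
  fr <- phantom_frame(ph)
  # move the grid origin onto the inner cup surface
  fr$center <- c(0, 0, -25)
  g <- build_grid(fr, 30, 30)
  dm <- compute_deviation_map(g, ph$deficient, ph$reconstructed)
  expect_true(length(dm$warnings) > 0)
})
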