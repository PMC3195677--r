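test_that("the color scale is linear, clamped, and grey for no support", {
  expect_equal(trabl_color(0)[1, ], c(0, 160, 0) / 255, tolerance = 1e-9)
  expect_equal(trabl_color(25), trabl_color(10))  # "10 mm or higher"
  expect_equal(trabl_color(Inf)[1, ], rep(0.6, 3))
  d <- trabl_color(c(2, 4, 6))
  expect_false(any(duplicated(d)))
})

test_that("the color graph is green for identity and ramped for erosion", {
  id <- make_phantom(fast_preset("identity"))
  fit <- trabl(id$deficient, id$reconstructed, id$config,
               grid_size = c(100, 100))
  img <- render_color_graph(fit$planar, fit$deviation, fit$labels,
                            px = 201)
  # sample a pixel inside the cup surface away from overlays:
  # r ~ 0.9 along the 45-degree diagonal
  px_at <- function(img, x, y) {
    lim <- pi * 1.02
    col <- round((x + lim) / (2 * lim) * (dim(img)[2] - 1)) + 1
    row <- round((lim - y) / (2 * lim) * (dim(img)[1] - 1)) + 1
    img[row, col, ]
  }
  expect_equal(px_at(img, 0.64, 0.64), c(0, 160, 0) / 255,
               tolerance = 0.02)

  er <- make_phantom(fast_preset("erosion3"))
  fit3 <- trabl(er$deficient, er$reconstructed, er$config,
                grid_size = c(100, 100))
  img3 <- render_color_graph(fit3$planar, fit3$deviation, fit3$labels,
                             px = 201)
  # inside the erosion window (phi ~ 0.87, psi ~ 13 deg), clear of the
  # sector boundary overlay at psi = 0
  expect_equal(px_at(img3, 0.85, 0.2), trabl_color(3)[1, ],
               tolerance = 0.02)
  # outside the disk is white; beyond the hit surface inside r <= pi is white
  expect_equal(px_at(img3, 3.1, 1.0), c(1, 1, 1))
})

test_that("rendering is deterministic", {
  ph <- make_phantom(fast_preset("wedge25"))
  fit <- trabl(ph$deficient, ph$reconstructed, ph$config,
               grid_size = c(60, 60))
  a <- render_color_graph(fit$planar, fit$deviation, fit$labels, px = 90)
  b <- render_color_graph(fit$planar, fit$deviation, fit$labels, px = 90)
  expect_identical(a, b)
})

test_that("radar data orders the five sectors and separates Med", {
  tab <- trabl_cohort()
  rd <- radar_data(tab[tab$specimen == "A", ])
  expect_equal(unname(rd$sectors), c(0, 8, 58, 22, 28))
  expect_equal(names(rd$sectors),
               c("PostInf", "Inf", "AntInf", "AntSup", "PostSup"))
  expect_equal(rd$med, 0)

  id <- make_phantom(fast_preset("identity"))
  fit <- trabl(id$deficient, id$reconstructed, id$config,
               grid_size = c(60, 60))
  rd0 <- radar_data(fit$result)
  expect_equal(unname(rd0$sectors), rep(0, 5))
  expect_equal(rd0$med, 0)

  wd <- make_phantom(fast_preset("wedge25"))
  fitw <- trabl(wd$deficient, wd$reconstructed, wd$config,
                grid_size = c(100, 100))
  rdw <- radar_data(fitw$result)
  expect_true(all(rdw$sectors[c("PostInf", "Inf", "PostSup")] == 0))
  expect_true(all(rdw$sectors[c("AntInf", "AntSup")] > 40))
})

test_that("cohort summary reproduces the reference table's margins", {
  tab <- trabl_cohort()
  expect_equal(nrow(tab), 12L)
  sm <- summarize_cohort(tab, thresholds = c(15, 25, 50))
  # per-region extremes across specimens
  expect_equal(sm$per_region$max, c(42, 55, 83, 53, 92, 86))
  expect_equal(sm$per_region$min, c(0, 0, 0, 3, 23, 0))
  # per-specimen extremes
  ps <- sm$per_specimen
  expect_equal(ps$min[ps$specimen == "D"], 3)
  expect_equal(ps$max[ps$specimen == "D"], 92)
  expect_equal(ps$max[ps$specimen == "L"], 25)
  # five specimens show >25% total loss in three or more regions
  expect_equal(sm$specimens_with_k_regions["over_25", "k3"], 5)
  # every specimen lost >= a quarter in at least one region (>= 23 here)
  expect_true(all(ps$max >= 23))
})

test_that("cohort summary handles a single all-zero row and bad input", {
  one <- data.frame(specimen = "X", PostInf = 0, Inf. = 0, AntInf = 0,
                    AntSup = 0, PostSup = 0, Med = 0,
                    check.names = FALSE)
  names(one)[3] <- "Inf"
  sm <- summarize_cohort(one)
  expect_equal(sm$per_specimen$min, 0)
  expect_equal(sm$per_specimen$max, 0)
  expect_true(all(sm$specimens_with_k_regions == 0))
  bad <- one
  bad$Med <- "n/a"
  expect_error(summarize_cohort(bad), "numeric")
})

test_that("run_case produces a complete output set end to end", {
  ph <- make_phantom(fast_preset("identity"))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  out <- file.path(dir, "results")
  fit <- run_case(file.path(dir, "deficient.stl"),
                  file.path(dir, "reconstructed.stl"),
                  file.path(dir, "case.json"),
                  out, grid_size = c(60, 60))
  expect_equal(fit$result$ratio, 0)
  ratios <- read.csv(file.path(out, "ratios.csv"))
  expect_equal(ratios$ratio, rep(0, 7))
  expect_error(run_case(file.path(dir, "deficient.stl"),
                        file.path(dir, "reconstructed.stl"),
                        file.path(dir, "nope.json"), out),
               "not found")
})

test_that("plot methods run on a null device", {
  ph <- make_phantom(fast_preset("wedge25"))
  fit <- trabl(ph$deficient, ph$reconstructed, ph$config,
               grid_size = c(50, 50))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_no_error(plot(fit, type = "map", px = 80))
  expect_no_error(plot(fit, type = "radar"))
  expect_output(print(fit), "TrABL ratio")
  expect_output(print(summary(fit)), "sphere fit RMS")
})
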