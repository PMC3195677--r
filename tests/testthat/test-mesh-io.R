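test_that("binary STL round-trips a tetrahedron", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tet, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(nrow(back$faces), 4L)
  # vertex sets match to float32 precision
  ord <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
  expect_equal(ord(back$vertices), ord(tet$vertices), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("ASCII STL round-trips and drops zero-area faces", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(tet, path, ascii = TRUE)
  back <- read_mesh(path)
  expect_equal(nrow(back$faces), 4L)

  # append a degenerate (zero-area) facet to the ASCII file
  lines <- readLines(path)
  deg <- c("  facet normal 0 0 1", "    outer loop",
           "      vertex 5 5 5", "      vertex 5 5 5",
           "      vertex 6 6 6", "    endloop", "  endfacet")
  writeLines(c(lines[-length(lines)], deg, lines[length(lines)]), path)
  back2 <- read_mesh(path)
  expect_equal(nrow(back2$faces), 4L)
})

test_that("phantom STL round-trip preserves vertices to float precision", {
  ph <- make_phantom(fast_preset("identity"))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(ph$reconstructed, path)
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), nrow(ph$reconstructed$vertices))
  expect_equal(nrow(back$faces), nrow(ph$reconstructed$faces))
  # per-face corner coordinates agree within STL float32 precision
  orig <- ph$reconstructed$vertices[t(ph$reconstructed$faces), ]
  got <- back$vertices[t(back$faces), ]
  expect_lt(max(abs(orig - got)), 1e-5)
})

test_that("OBJ reader parses vertices and faces", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), path)
  m <- read_mesh(path)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
})

test_that("degenerate and unreadable meshes error", {
  expect_error(read_mesh(tempfile()), "not found")
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines("solid junk but no facets", path)
  expect_error(read_mesh(path), "unreadable")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 1, 1)),
                             matrix(integer(0), 0, 3)),
               "fewer than 4")
})

test_that("cleaning merges duplicate vertices, keeps sound faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1e-9, 0, 0))  # duplicate of vertex 1 within tolerance
  f <- rbind(c(5, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  m <- triangle_mesh(v, f)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
})

test_that("case config validates and resolves indices", {
  ph <- make_phantom(fast_preset("identity"))
  path <- withr::local_tempfile(fileext = ".json")
  write_case_config(ph$config, path)
  back <- read_case_config(path, mesh = ph$reconstructed)
  expect_s3_class(back, "case_config")
  expect_equal(back$side, "right")
  expect_equal(back$landmarks, ph$config$landmarks)
  expect_equal(back$rim_outline, ph$config$rim_outline,
               ignore_attr = TRUE)
  expect_equal(back$acetabular_region, ph$config$acetabular_region,
               ignore_attr = TRUE)

  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  js$landmarks$pubis <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(js, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_case_config(path2, mesh = ph$reconstructed), "pubis")

  expect_error(
    case_config(ph$config$rim_outline[1:2, ], ph$config$acetabular_region,
                ph$config$landmarks, "right"),
    ">= 3")
})

test_that("write_outputs emits ratios, a full deviation grid, and images", {
  ph <- make_phantom(fast_preset("identity"))
  fit <- trabl(ph$deficient, ph$reconstructed, ph$config,
               grid_size = c(100, 100))
  out <- withr::local_tempdir()
  files <- write_outputs(fit, out, px = 120)
  expect_true(all(file.exists(files)))

  ratios <- read.csv(file.path(out, "ratios.csv"))
  expect_equal(nrow(ratios), 7L)
  expect_equal(ratios$ratio, rep(0, 7))
  grid <- read.csv(file.path(out, "deviation_grid.csv"))
  expect_equal(nrow(grid), 100L * 100L)
  expect_true(all(c("phi", "theta", "x", "y", "hit_rec", "hit_def",
                    "distance") %in% names(grid)))
  # round trip: ratios CSV values equal result fields
  expect_equal(ratios$A_rec[1], fit$result$A_rec)
  expect_equal(ratios$ratio[-1], fit$result$per_region$ratio)
  log <- jsonlite::fromJSON(file.path(out, "run_log.json"))
  expect_equal(log$sphere$radius, fit$sphere$radius)
})
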