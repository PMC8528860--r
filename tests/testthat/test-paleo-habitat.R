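test_that("slice and stack validation rejects malformed inputs", {
  ok <- habitat_slice(matrix(0, 2, 3), c(0, 1, 2), c(0, 1, 2, 3), 5)
  expect_s3_class(ok, "habitat_slice")
  expect_error(habitat_slice(matrix(0.5, 2, 3), c(0, 1, 2), c(0, 1, 2, 3), 5),
               "0 or 1")
  expect_error(habitat_slice(matrix(0, 2, 2), c(0, 1, 2), c(0, 1, 2, 3), 5),
               "shape")
  expect_error(habitat_slice(matrix(0, 2, 3), c(0, 2, 1), c(0, 1, 2, 3), 5),
               "increasing")
  expect_error(habitat_slice(matrix(0, 2, 3), c(0, 1, 2), c(0, 1, 2, 3), -1),
               "non-negative")
  other <- habitat_slice(matrix(0, 3, 3), c(0, 1, 2, 3), c(0, 1, 2, 3), 1)
  expect_error(habitat_stack(list(ok, other)), "lattice")
  expect_error(habitat_stack(list(ok, ok)), "unique")
})

test_that("cell areas are exact spherical band areas", {
  R <- 6371
  # one cell covering the whole sphere
  full <- cell_areas(c(-90, 90), c(-180, 180), R)
  expect_equal(as.numeric(full), 4 * pi * R^2, tolerance = 1e-12)
  # 1x1 degree cell at the equator: closed form R^2 (pi/180) sin(1 deg)
  a <- cell_areas(c(0, 1), c(10, 11), R)
  expect_equal(as.numeric(a), R^2 * (pi / 180) * sin(pi / 180),
               tolerance = 1e-12)
  # mirror-latitude bands have equal areas; longitude plays no role
  grid <- cell_areas(seq(-30, 30, by = 10), seq(-180, 180, by = 60), R)
  expect_equal(grid[1, ], grid[6, ])
  expect_true(all(abs(grid - grid[, 1]) < 1e-9))
  expect_error(cell_areas(c(0, 0, 1), c(0, 1)), "increasing")
})

test_that("patch counting handles the textbook adjacency cases", {
  mk <- function(g) habitat_slice(g, seq(-10, 10, length.out = nrow(g) + 1),
                                  seq(-180, 180, length.out = ncol(g) + 1),
                                  0)
  expect_identical(count_patches(mk(matrix(0, 4, 6))), 0L)
  g1 <- matrix(0, 4, 6); g1[2, 3] <- 1
  expect_identical(count_patches(mk(g1)), 1L)
  gd <- matrix(0, 4, 6); gd[2, 3] <- 1; gd[3, 4] <- 1
  expect_identical(count_patches(mk(gd), connectivity = 8), 1L)
  expect_identical(count_patches(mk(gd), connectivity = 4), 2L)
  # date-line joining: habitat in first and last columns
  gw <- matrix(0, 4, 6); gw[2, 1] <- 1; gw[2, 6] <- 1
  expect_identical(count_patches(mk(gw), wrap_longitude = TRUE), 1L)
  expect_identical(count_patches(mk(gw), wrap_longitude = FALSE), 2L)
})

test_that("patch counts match the flood-fill oracle and obey invariants", {
  for (s in 1:30) {
    sl <- random_slice(12, 24, p = 0.35, seed = s)
    n_hab <- sum(sl$grid)
    for (conn in c(4, 8)) for (wrap in c(TRUE, FALSE)) {
      got <- count_patches(sl, connectivity = conn, wrap_longitude = wrap)
      expect_identical(got,
                       flood_fill_count(sl$grid, conn, wrap),
                       info = sprintf("seed %d conn %d wrap %s", s, conn, wrap))
      expect_true(got >= (n_hab > 0) && got <= n_hab)
    }
    # 8-connectivity merges, never splits, 4-connected patches
    expect_lte(count_patches(sl, 8), count_patches(sl, 4))
    # cyclic longitude shift leaves wrapped counts unchanged
    shift <- 7
    g2 <- sl$grid[, c((shift + 1):ncol(sl$grid), 1:shift)]
    sl2 <- habitat_slice(g2, sl$lat_edges, sl$lon_edges, 0)
    expect_identical(count_patches(sl2), count_patches(sl))
  }
})

test_that("total area sums habitat cells and is additive", {
  sl <- random_slice(10, 20, p = 0.4, seed = 99)
  ar <- cell_areas(sl$lat_edges, sl$lon_edges)
  expect_equal(total_area(sl, ar), sum(ar[sl$grid == 1]))
  # complement + habitat = full band
  comp <- habitat_slice(1 - sl$grid, sl$lat_edges, sl$lon_edges, 0)
  expect_equal(total_area(sl, ar) + total_area(comp, ar), sum(ar))
  # all-ones grid equals the analytic band area
  ones <- habitat_slice(matrix(1, 10, 20), sl$lat_edges, sl$lon_edges, 0)
  R <- 6371
  band <- 2 * pi * R^2 * (sin(20 * pi / 180) - sin(-20 * pi / 180))
  expect_equal(total_area(ones, ar), band, tolerance = 1e-12)
  expect_error(total_area(sl, ar[, 1:5]), "shape")
})

test_that("environment series knots, interpolation and extrapolation", {
  sim <- simulate_habitat_stack(3, k = c(3, 5, 8), seed = 11)
  es <- build_env_series(sim$stack, "patch_count")
  expect_equal(as.data.frame(es)$value, c(3, 5, 8))
  # linear interpolation midway is the knot mean; extrapolation is constant
  expect_equal(env_eval(es, 0.5), 4)
  expect_equal(env_eval(es, c(-3, 99)), c(3, 8))
  ea <- build_env_series(sim$stack, "total_area_km2")
  expect_equal(as.data.frame(ea)$value, sim$truth$total_area_km2)
  # a constant stack gives a flat series
  cst <- habitat_stack(lapply(0:2, function(a)
    habitat_slice(sim$stack$slices[[1]]$grid, sim$stack$lat_edges,
                  sim$stack$lon_edges, a)))
  ec <- build_env_series(cst, "patch_count")
  expect_true(all(ec$value == ec$value[1]))
  expect_error(habitat_stack(list()), "empty")
  expect_error(env_series(c(0, 1), c(1, -2)), "non-negative")
})

test_that("ASCII grid round trip, coercion, and stack loading", {
  sim <- simulate_habitat_stack(3, k = c(2, 4, 6), seed = 21)
  d <- withr::local_tempdir()
  paths <- file.path(d, sprintf("habitat_%dMa.asc", 0:2))
  for (i in 1:3) write_ascii_grid(sim$stack$slices[[i]], paths[i])
  st <- load_habitat_stack(paths)   # ages parsed from filenames
  expect_equal(st$ages, c(0, 1, 2))
  expect_identical(st$slices[[2]]$grid, sim$stack$slices[[2]]$grid)
  # non-binary and NODATA cells are coerced to 0 with a warning
  lines <- readLines(paths[1])
  vals <- strsplit(lines[7], " ")[[1]]
  vals[1] <- "0.5"; vals[2] <- "-9999"
  lines[7] <- paste(vals, collapse = " ")
  writeLines(lines, paths[1])
  expect_warning(sl <- read_ascii_grid(paths[1], 0), "coerced")
  expect_equal(attr(sl, "n_coerced"), 2)
  expect_true(all(sl$grid %in% c(0, 1)))
  # mismatched lattice across files is a hard error
  small <- habitat_slice(matrix(0, 4, 36), seq(-20, 20, length.out = 5),
                         seq(-180, 180, length.out = 37), 1)
  write_ascii_grid(small, paths[2])
  # (the doctored first file still warns about its coerced cells)
  suppressWarnings(expect_error(load_habitat_stack(paths), "lattice"))
  expect_error(read_ascii_grid(file.path(d, "nope.asc"), 0), "cannot read")
})
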