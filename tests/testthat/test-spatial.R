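two_sites <- data.frame(x = c(0, 1), y = c(0, 0), value = c(0, 10))

test_that("queries at a site return that site's value exactly", {
  sites <- data.frame(x = c(0, 3, 7), y = c(0, 2, 5), value = c(1, 4, 9))
  for (i in seq_len(nrow(sites))) {
    expect_equal(
      idw_interpolate(sites, sites$x[i], sites$y[i]),
      sites$value[i]
    )
  }
})

test_that("weights follow the inverse-power law", {
  # midpoint of two sites: symmetric weights
  expect_equal(idw_interpolate(two_sites, 0.5, 0), 5.0)
  # at (0.25, 0): d = 0.25, 0.75 -> weights 16 and 16/9;
  # (16*0 + 16/9*10) / (16 + 16/9) = 1.0
  expect_equal(idw_interpolate(two_sites, 0.25, 0), 1.0)
})

test_that("the interpolant is a convex combination of site values", {
  set.seed(33)
  for (rep in 1:5) {
    sites <- data.frame(
      x = runif(8, 0, 10), y = runif(8, 0, 10), value = runif(8, 0, 100)
    )
    qx <- runif(20, -2, 12)
    qy <- runif(20, -2, 12)
    v <- idw_interpolate(sites, qx, qy, power = runif(1, 0.5, 4))
    expect_true(all(v >= min(sites$value) - 1e-12))
    expect_true(all(v <= max(sites$value) + 1e-12))
  }
})

test_that("interpolation is translation invariant", {
  sites <- data.frame(x = c(0, 2, 5), y = c(1, 4, 2), value = c(3, 8, 6))
  v0 <- idw_interpolate(sites, 1.3, 2.1)
  shift <- c(17.5, -4.2)
  moved <- transform(sites, x = x + shift[1], y = y + shift[2])
  expect_equal(
    idw_interpolate(moved, 1.3 + shift[1], 2.1 + shift[2]),
    v0
  )
})

test_that("large powers approach nearest-neighbor assignment", {
  v <- idw_interpolate(two_sites, 0.4, 0, power = 50)
  expect_equal(v, 0, tolerance = 1e-4) # nearer site holds value 0
  v2 <- idw_interpolate(two_sites, 0.6, 0, power = 50)
  expect_equal(v2, 10, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(
    idw_interpolate(two_sites[0, ], 0, 0),
    class = "metalrisk_domain_error"
  )
  expect_error(
    idw_interpolate(two_sites, 0.5, 0, power = 0),
    class = "metalrisk_domain_error"
  )
  dup <- data.frame(x = c(1, 1), y = c(2, 2), value = c(5, 9))
  expect_error(
    idw_interpolate(dup, 0, 0),
    class = "metalrisk_validation_error"
  )
  expect_error(idw_interpolate(dup, 0, 0), "\\(1, 2\\)")
  # duplicated coordinates with equal values are fine
  dup$value <- c(5, 5)
  expect_equal(idw_interpolate(dup, 1, 2), 5)
})

test_that("rasterization produces in-range fields on the site bounding box", {
  samples <- as_water_samples(tibble::tibble(
    site_id = sprintf("S%d", 1:5),
    x = c(0, 10, 0, 10, 5),
    y = c(0, 0, 10, 10, 5),
    metal = "Ni",
    concentration_ug_L = c(60, 65, 70, 75, 90)
  ))
  field <- idw_raster(samples, "Ni", nx = 10, ny = 10)
  expect_equal(dim(field$values), c(10, 10))
  expect_true(all(field$values >= 60 & field$values <= 90))
  # the peak cell sits at the central high-value site
  expect_equal(unname(grid_argmax(field)), c(5, 5), tolerance = 0.51)

  expect_error(
    idw_raster(samples, "Pb"),
    class = "metalrisk_validation_error"
  )

  one <- samples[samples$site_id == "S5", ]
  const <- idw_raster(one, "Ni", nx = 4, ny = 4)
  expect_equal(const$values, matrix(90, 4, 4))
})

test_that("repeat measurements at one site are averaged before interpolation", {
  samples <- as_water_samples(tibble::tibble(
    site_id = c("A", "A", "B"),
    x = c(0, 0, 1),
    y = c(0, 0, 0),
    metal = "Pb",
    concentration_ug_L = c(4, 6, 10)
  ))
  field <- idw_raster(samples, "Pb", nx = 2, ny = 1, bbox = c(0, 1, -0.5, 0.5))
  expect_true(all(field$values >= 5 & field$values <= 10))
})

test_that("grids serialize to the ESRI ASCII convention and back", {
  samples <- as_water_samples(tibble::tibble(
    site_id = c("A", "B"),
    x = c(0, 8), y = c(0, 8),
    metal = "Cd", concentration_ug_L = c(2, 4)
  ))
  field <- idw_raster(samples, "Cd", nx = 8, ny = 8)
  path <- tempfile(fileext = ".asc")
  write_esri_ascii(field, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ncols 8")
  expect_equal(lines[2], "nrows 8")
  expect_length(lines, 6 + 8)
  body <- do.call(rbind, lapply(lines[7:14], function(l) {
    as.numeric(strsplit(l, " ")[[1]])
  }))
  # rows are written north to south
  expect_equal(body, field$values[rev(seq_len(8)), ], ignore_attr = TRUE)

  uneven <- idw_raster(samples, "Cd", nx = 8, ny = 4, bbox = c(0, 8, 0, 2))
  expect_error(
    write_esri_ascii(uneven, tempfile()),
    class = "metalrisk_validation_error"
  )
})
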