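test_that("a constant field returns its value whatever the pixel count", {
  r <- flat_raster(0.4)
  out <- extract_buffer(r, lat = 19.5, lon = -101.5)
  expect_equal(out$mean_evi, 0.4)
  expect_gt(out$n_pixels, 0)
  small <- extract_buffer(r, lat = 19.5, lon = -101.5, radius_km = 5)
  expect_equal(small$mean_evi, 0.4)
  expect_lt(small$n_pixels, out$n_pixels)
})

test_that("no-data pixels are dropped; an all-water site returns 0 pixels", {
  vals <- matrix(NA_real_, 40, 40)
  vals[20, 20] <- 0.3
  vals[20, 21] <- 0.5
  r <- evi_raster(vals, xmin = -101, ymin = 19, resolution = 0.05)
  out <- extract_buffer(r, lat = 19 + 19.5 * 0.05, lon = -101 + 19.5 * 0.05)
  expect_equal(out$n_pixels, 2L)
  expect_equal(out$mean_evi, 0.4)
  empty <- extract_buffer(r, lat = 19.1, lon = -100.2)
  expect_equal(empty$n_pixels, 0L)
  expect_true(is.na(empty$mean_evi))
})

test_that("buffer pixel counts match the closed-form geometric oracle", {
  r <- flat_raster(0.5, nr = 460, nc = 200, xmin = -102, ymin = 14)
  withr::with_seed(41, {
    lat <- runif(120, 15, 30)
    lon <- runif(120, -101.5, -93)
  })
  out <- extract_buffer(r, lat, lon)
  # oracle: buffer area / per-pixel area at that latitude
  predicted <- pi * 100 / (110.574 * 0.05 * 111.320 * 0.05 * cos(lat * pi / 180))
  expect_true(all(abs(out$n_pixels - predicted) <= 3))
  expect_gt(mean(out$n_pixels), 9)
  expect_lt(mean(out$n_pixels), 14)
  expect_true(all(out$n_pixels >= 3 & out$n_pixels <= 16))
})

test_that("pixel counts rise weakly with latitude as pixels shrink", {
  r <- flat_raster(0.5, nr = 500, nc = 100, xmin = -100, ymin = 10)
  lats <- c(12, 18, 24, 30, 33)
  out <- extract_buffer(r, lats, rep(-97.5, 5))
  expect_true(all(diff(out$n_pixels) >= 0))
})

test_that("buffers are invariant to translating raster and point together", {
  base <- generate_rasters(resolution = 0.05, lat_range = c(18, 22),
                           lon_range = c(-104, -100), seed = 9)[[4]]
  shifted <- evi_raster(base$values, xmin = base$xmin + 2.5,
                        ymin = base$ymin + 1.25, resolution = base$res,
                        month = base$month)
  a <- extract_buffer(base, 20.3, -102.2)
  b <- extract_buffer(shifted, 20.3 + 1.25, -102.2 + 2.5)
  expect_equal(b$n_pixels, a$n_pixels)
  expect_equal(b$mean_evi, a$mean_evi, tolerance = 1e-4)
})

test_that("random locations land in the polygon, reproduce under a seed, and spread uniformly", {
  square <- tibble::tibble(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  pts <- sample_random_locations(square, n = 1000, seed = 2)
  expect_equal(nrow(pts), 1000)
  expect_true(all(pts$lat >= 0 & pts$lat <= 1 & pts$lon >= 0 & pts$lon <= 1))
  quad <- table(pts$lat > 0.5, pts$lon > 0.5) / 1000
  expect_true(all(abs(quad - 0.25) < 0.05))
  again <- sample_random_locations(square, n = 1000, seed = 2)
  expect_identical(pts, again)
  boundary_pts <- sample_random_locations(test_boundary(), n = 200, seed = 3)
  inside <- abindex:::point_in_polygon(boundary_pts$lon, boundary_pts$lat,
                                       test_boundary())
  expect_true(all(inside))
  degenerate <- tibble::tibble(lon = c(0, 0, 0), lat = c(0, 1, 2))
  expect_error(sample_random_locations(degenerate, 5), "degenerate")
})

test_that("reference subsampling rounds, merges, filters and weights as specified", {
  r <- flat_raster(0.4, nr = 80, nc = 80, xmin = -102, ymin = 18)
  recs <- dplyr::bind_rows(
    make_recs(5, latitude = 19.501, longitude = -100.501, month = 3,
              scientific_name = "Vireo gilvus"),
    make_recs(1, latitude = 19.498, longitude = -100.499, month = 3,
              scientific_name = "Vireo gilvus"),   # merges with above at 0.01
    make_recs(2, latitude = 20.2, longitude = -99.4, month = 3,
              scientific_name = "Empidonax affinis"),
    make_recs(1, latitude = 21.1, longitude = -98.6, month = 3,
              scientific_name = "Catharus occidentalis"),
    make_recs(9, latitude = 21.1, longitude = -98.6, month = 4,
              scientific_name = "Catharus occidentalis")  # other month
  )
  expect_warning(
    out <- subsample_reference_locations(recs, r, month = 3,
                                         n_locations = 250, seed = 1),
    "using all"
  )
  expect_equal(nrow(out), 3)
  expect_equal(sort(out$weight), c(1, 2, 6))
  expect_equal(sum(rep(out$mean_evi, out$weight) == 0.4), 9)
})

test_that("locations under the pixel minimum are removed before weighting", {
  vals <- matrix(NA_real_, 60, 60)
  vals[30, 30] <- 0.3
  vals[30, 31] <- 0.5                      # a 2-pixel site: filtered at 3
  vals[10, 10:14] <- 0.6                   # a 5-pixel site: kept
  r <- evi_raster(vals, xmin = -101, ymin = 19, resolution = 0.05)
  two_pix <- make_recs(4, latitude = 19 + 29.5 * 0.05,
                       longitude = -101 + 29.5 * 0.05, month = 5,
                       scientific_name = "Vireo gilvus")
  five_pix <- make_recs(2, latitude = 19 + 9.5 * 0.05,
                        longitude = -101 + 11.5 * 0.05, month = 5,
                        scientific_name = "Vireo gilvus")
  out <- suppressWarnings(subsample_reference_locations(
    dplyr::bind_rows(two_pix, five_pix), r, month = 5, n_locations = 10))
  expect_equal(nrow(out), 1)
  expect_equal(out$weight, 2)
  expect_equal(out$mean_evi, 0.6)
})

test_that("identical samples give t = 0 and p = 1; tiny samples are not computable", {
  s <- tibble::tibble(mean_evi = c(0.3, 0.4, 0.5), weight = c(1L, 1L, 1L))
  out <- monthly_null_comparison(s, s, month = 6)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)
  flat <- tibble::tibble(mean_evi = rep(0.4, 5), weight = rep(1L, 5))
  out2 <- monthly_null_comparison(flat, flat)
  expect_equal(out2$t_statistic, 0)
  expect_equal(out2$p_value, 1)
  tiny <- monthly_null_comparison(s[1, ], s)
  expect_false(tiny$computable)
})

test_that("weights duplicate specimen values in the comparison", {
  heavy <- tibble::tibble(mean_evi = c(0.8, 0.2), weight = c(9L, 1L))
  light <- tibble::tibble(mean_evi = c(0.8, 0.2), weight = c(1L, 1L))
  null_s <- tibble::tibble(mean_evi = seq(0.3, 0.5, length.out = 20),
                           weight = rep(1L, 20))
  a <- monthly_null_comparison(heavy, null_s)
  b <- monthly_null_comparison(light, null_s)
  expect_equal(a$n_specimen, 10)
  expect_equal(b$n_specimen, 2)
  expect_equal(a$specimen_mean, (9 * 0.8 + 0.2) / 10)
  expect_gt(a$specimen_mean, b$specimen_mean)
  expect_true(a$specimen_lo <= a$specimen_mean &
                a$specimen_mean <= a$specimen_hi)
})

test_that("the battery covers both nulls per month and degrades gracefully", {
  boundary <- test_boundary()
  rasters <- coarse_rasters()
  scen <- movement_scenario(n_focal = 250, n_reference = 3000, seed = 17)
  recs <- generate_records(scen, boundary = boundary)
  other <- recs$reference[recs$reference$scientific_name != "Passerina ciris", ]
  w <- capture_warnings(
    out <- run_evi_battery(recs$focal, rasters[1:5], boundary, other,
                           n_random = 60, n_reference_locations = 40, seed = 5)
  )
  expect_true(any(grepl("no raster for month 6", w)))
  expect_true(all(out$comparison %in% c("random", "reference")))
  expect_equal(sort(unique(out$month)), 1:5)
  # all-constant rasters: every computable comparison has t = 0
  const <- lapply(1:3, function(m) flat_raster(0.35, nr = 120, nc = 180,
                                               xmin = -112, ymin = 15,
                                               month = m))
  out2 <- suppressWarnings(run_evi_battery(
    recs$focal, const, boundary, other, n_random = 40,
    n_reference_locations = 30, seed = 6
  ))
  comp <- out2[out2$computable, ]
  expect_true(all(abs(comp$t_statistic) < 1e-12))
})

test_that("battery results are reproducible bit for bit under a fixed seed", {
  boundary <- test_boundary()
  rasters <- coarse_rasters()[1:2]
  scen <- movement_scenario(n_focal = 120, n_reference = 1500, seed = 19)
  recs <- generate_records(scen, boundary = boundary)
  other <- recs$reference[recs$reference$scientific_name != "Passerina ciris", ]
  run1 <- suppressWarnings(run_evi_battery(recs$focal, rasters, boundary, other,
                                           n_random = 50,
                                           n_reference_locations = 30, seed = 44))
  run2 <- suppressWarnings(run_evi_battery(recs$focal, rasters, boundary, other,
                                           n_random = 50,
                                           n_reference_locations = 30, seed = 44))
  expect_identical(tibble::as_tibble(run1), tibble::as_tibble(run2))
})
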