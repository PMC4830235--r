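test_that("raster generation is deterministic and degenerates to the base surface", {
  m0 <- greenness_model(amplitude = c(NW = 0, NE = 0, S = 0), noise_sd = 0,
                        mesoscale_amplitude = 0)
  rs <- generate_rasters(m0, lat_range = c(18, 22), lon_range = c(-104, -100),
                         resolution = 0.1, seed = 1)
  expect_length(rs, 12)
  for (m in 2:12) expect_identical(rs[[m]]$values, rs[[1]]$values)
  # pure latitude gradient
  expect_equal(rs[[1]]$values[1, 1],
               0.35 - 0.012 * ((18.05) - 20), tolerance = 1e-12)
  rs2 <- generate_rasters(lat_range = c(18, 22), lon_range = c(-104, -100),
                          resolution = 0.1, seed = 5)
  rs3 <- generate_rasters(lat_range = c(18, 22), lon_range = c(-104, -100),
                          resolution = 0.1, seed = 5)
  expect_identical(rs2, rs3)
  expect_false(identical(rs2[[1]]$values,
                         generate_rasters(lat_range = c(18, 22),
                                          lon_range = c(-104, -100),
                                          resolution = 0.1,
                                          seed = 6)[[1]]$values))
})

test_that("regional seasonal peaks land on the configured month", {
  rs <- coarse_rasters()
  part <- region_partition()
  nw_mean <- vapply(rs, function(r) {
    lats <- abindex:::raster_row_lats(r)
    lons <- abindex:::raster_col_lons(r)
    reg <- matrix(assign_region(rep(lats, times = length(lons)),
                                rep(lons, each = length(lats)), part),
                  length(lats), length(lons))
    mean(r$values[reg == "NW"], na.rm = TRUE)
  }, numeric(1))
  expect_equal(which.max(nw_mean), 9)  # monsoon peak in September
  # clip range respected
  for (r in rs) expect_true(all(r$values >= -0.2 & r$values <= 1, na.rm = TRUE))
})

test_that("generated records stay in the boundary and carry plausible fields", {
  recs <- generate_records(movement_scenario(n_focal = 200, n_reference = 2000,
                                             seed = 3),
                           boundary = test_boundary())
  inside <- abindex:::point_in_polygon(recs$reference$longitude,
                                       recs$reference$latitude,
                                       test_boundary())
  expect_true(all(inside))
  expect_true(all(recs$reference$month %in% 1:12))
  expect_true(all(recs$focal$scientific_name == "Passerina ciris"))
  expect_true(all(recs$focal$record_id %in% recs$reference$record_id))
  expect_false(any(duplicated(recs$reference$record_id)))
})

test_that("realized totals track their Poisson expectations across seeds", {
  totals <- vapply(1:12, function(s) {
    r <- generate_records(movement_scenario(n_focal = 300, n_reference = 1200,
                                            seed = 100 + s),
                          boundary = test_boundary())
    c(nrow(r$focal), nrow(r$reference) - nrow(r$focal))
  }, numeric(2))
  expect_true(all(abs(totals[1, ] - 300) <= 3 * sqrt(300)))
  expect_true(all(abs(totals[2, ] - 1200) <= 3 * sqrt(1200)))
})

test_that("corruption damages the stated fraction and cleaning removes exactly those rows", {
  scen <- movement_scenario(n_focal = 500, n_reference = 5000,
                            corruption_fraction = 0.08, seed = 9)
  recs <- generate_records(scen, boundary = test_boundary())
  bad <- attr(recs$reference, "corrupted_rows")
  n <- nrow(recs$reference)
  expect_gt(length(bad), 0)
  expect_lt(abs(length(bad) / n - 0.08), 3 * sqrt(0.08 * 0.92 / n))
  cleaned <- clean_records(recs$reference)
  expect_equal(nrow(cleaned), n - length(bad))
  expect_equal(cleaning_report(cleaned)$drop_fraction, length(bad) / n)
  expect_true(all(setdiff(recs$reference$record_id,
                          cleaned$record_id) %in%
                    recs$reference$record_id[bad]))
})

test_that("habitat preference raises focal greenness above the areal mean", {
  rasters <- coarse_rasters()
  scen <- movement_scenario(n_focal = 600, n_reference = 3000,
                            evi_preference_beta = 4, seed = 21)
  recs <- generate_records(scen, rasters = rasters, boundary = test_boundary())
  m <- 8
  foc_m <- recs$focal[recs$focal$month == m, ]
  e_foc <- evi_at(rasters[[m]], foc_m$latitude, foc_m$longitude)
  areal <- mean(rasters[[m]]$values, na.rm = TRUE)
  expect_gt(mean(e_foc, na.rm = TRUE), areal)
  # and beta = 0 does not (within noise): compare the two scenarios
  scen0 <- movement_scenario(n_focal = 600, n_reference = 3000, seed = 21)
  recs0 <- generate_records(scen0, boundary = test_boundary())
  f0 <- recs0$focal[recs0$focal$month == m, ]
  e0 <- evi_at(rasters[[m]], f0$latitude, f0$longitude)
  expect_gt(mean(e_foc, na.rm = TRUE), mean(e0, na.rm = TRUE))
})

test_that("an all-zero occupancy month simply yields no focal records there", {
  occ <- matrix(1, 12, 3)
  occ[5, ] <- 0
  occ[6, ] <- 0
  recs <- generate_records(movement_scenario(occupancy = occ, n_focal = 400,
                                             n_reference = 1000, seed = 33),
                           boundary = test_boundary())
  expect_equal(sum(recs$focal$month %in% c(5, 6)), 0)
  expect_gt(sum(recs$reference$month %in% c(5, 6)), 0)
})

test_that("the default circular scenario encodes the annual loop", {
  scen <- default_circular_scenario()
  occ <- scen$occupancy
  argmax <- apply(occ, 1, function(x) colnames(occ)[which.max(x)])
  expect_equal(unname(argmax[7:9]), rep("NW", 3))
  expect_equal(unname(occ[7, "S"]), 0)
  expect_true(all(rowSums(occ) > 0))
  expect_true(all(argmax[c(10, 11, 12, 2)] == "S"))
  expect_gt(scen$evi_preference_beta, 0)
})

test_that("the circular scenario's regional index peaks move NW to S to NE", {
  recs <- generate_records(default_circular_scenario(n_focal = 1200,
                                                     n_reference = 20000,
                                                     seed = 55),
                           rasters = coarse_rasters(),
                           boundary = test_boundary())
  ai <- ai_by_region(recs$focal, recs$reference) |> tibble::as_tibble()
  top_region <- ai |>
    dplyr::group_by(month) |>
    dplyr::slice_max(ai, n = 1, with_ties = FALSE) |>
    dplyr::pull(region) |>
    as.character()
  expect_equal(top_region[8:9], c("NW", "NW"))
  expect_equal(top_region[11], "S")
  expect_true(top_region[3] %in% c("NE", "S"))
})
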