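test_that("CSV reading populates fields, tolerates bad numerics, preserves order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "catalogNumber,scientificName,order,family,decimalLatitude,decimalLongitude,year,month,day,elevation",
    "a1,Passerina ciris,Passeriformes,Cardinalidae,23.5,-105.2,1975,8,3,120",
    "a2,Vireo gilvus,Passeriformes,Vireonidae,abc,-99.1,1980,11,,",
    "a3,Coccyzus minor,Cuculiformes,Cuculidae,18.2,-95.0,,2,7,850"
  ), path)
  recs <- read_occurrences(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$record_id, c("a1", "a2", "a3"))
  expect_equal(recs$latitude, c(23.5, NA, 18.2))
  expect_equal(recs$month, c(8L, 11L, 2L))
  expect_true(is.na(recs$year[3]))
  expect_true(is.na(recs$elevation_m[2]))
})

test_that("header-only files give empty tibbles; bad paths and columns are fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("catalogNumber,scientificName,order,family,decimalLatitude,decimalLongitude,year,month,day,elevation",
             path)
  expect_equal(nrow(read_occurrences(path)), 0)
  expect_error(read_occurrences(file.path(tempdir(), "nope.csv")), "not found")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,lat", "x,1"), path2)
  expect_error(read_occurrences(path2), "scientificName")
})

test_that("column remapping reads non-default headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,o,f,lat,lon,yy,mm,dd,el,id",
               "Passerina ciris,Passeriformes,Cardinalidae,20,-100,1990,3,2,50,z9"),
             path)
  recs <- read_occurrences(path, column_map = c(
    scientific_name = "sp", order_name = "o", family_name = "f",
    latitude = "lat", longitude = "lon", year = "yy", month = "mm",
    day = "dd", elevation_m = "el", record_id = "id"
  ))
  expect_equal(recs$record_id, "z9")
  expect_equal(recs$longitude, -100)
})

test_that("cleaning applies the drop rules in order, first failure wins", {
  recs <- dplyr::bind_rows(
    make_recs(6),                                   # valid
    make_recs(1, month = NA),                       # date rule
    make_recs(1, month = NA, latitude = 95),        # date rule shadows coords
    make_recs(1, longitude = NA),                   # missing coords
    make_recs(1, latitude = 95),                    # out of range
    make_recs(1, latitude = 0, longitude = 0)       # null island
  )
  cleaned <- clean_records(recs)
  rep <- cleaning_report(cleaned)
  expect_equal(nrow(cleaned), 6)
  expect_equal(rep$n_input, 11)
  expect_equal(rep$n_dropped_missing_date, 2)
  expect_equal(rep$n_dropped_missing_coords, 1)
  expect_equal(rep$n_dropped_erroneous_coords, 2)
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_dropped_missing_date +
                 rep$n_dropped_missing_coords + rep$n_dropped_erroneous_coords)
  expect_equal(rep$drop_fraction, 1 - 6 / 11)
})

test_that("cleaning keeps day/year-less records, is idempotent, and can be an identity", {
  recs <- make_recs(5, year = NA, day = NA)
  cleaned <- clean_records(recs)
  expect_equal(nrow(cleaned), 5)
  expect_equal(cleaning_report(cleaned)$drop_fraction, 0)
  twice <- clean_records(cleaned)
  expect_equal(as.data.frame(twice), as.data.frame(cleaned))
  expect_equal(cleaning_report(twice)$n_dropped_erroneous_coords, 0)
})

test_that("the optional boundary rule drops in-range points outside the polygon", {
  recs <- dplyr::bind_rows(
    make_recs(2, latitude = 22, longitude = -100),   # inside synthetic area
    make_recs(1, latitude = 45, longitude = -100)    # valid range, outside
  )
  cleaned <- clean_records(recs, boundary = test_boundary(),
                           drop_outside_boundary = TRUE)
  expect_equal(nrow(cleaned), 2)
  expect_equal(cleaning_report(cleaned)$n_dropped_erroneous_coords, 1)
  # default off: all three retained
  expect_equal(nrow(clean_records(recs, boundary = test_boundary())), 3)
})

test_that("round trip through CSV preserves retained records field for field", {
  recs <- clean_records(dplyr::bind_rows(
    make_recs(3, latitude = c(21.125, 19.5, 24.75),
              longitude = c(-101.3, -96.25, -107.125), month = c(1, 7, 12)),
    make_recs(1, month = NA)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(recs, path)
  back <- read_occurrences(path)
  expect_equal(as.data.frame(back), as.data.frame(recs), ignore_attr = TRUE)
})

test_that("focal/reference split keeps focal inside the reference set", {
  recs <- dplyr::bind_rows(
    make_recs(5),
    make_recs(90, scientific_name = "Vireo gilvus", family_name = "Vireonidae"),
    make_recs(5, scientific_name = "Melanerpes aurifrons",
              order_name = "Piciformes", family_name = "Picidae"),
    make_recs(3, scientific_name = "Falco sparverius",
              order_name = "Falconiformes", family_name = "Falconidae")
  )
  sets <- split_focal_reference(recs, "Passerina ciris")
  expect_equal(nrow(sets$focal), 5)
  expect_equal(nrow(sets$reference), 100)
  expect_false(any(sets$reference$order_name == "Falconiformes"))
  expect_true(all(sets$focal$record_id %in% sets$reference$record_id))
  expect_lte(nrow(sets$focal), nrow(sets$reference))
})

test_that("a filter restricted to woodpeckers passes exactly the woodpeckers", {
  wood <- make_recs(7, scientific_name = "Melanerpes aurifrons",
                    order_name = "Piciformes", family_name = "Picidae")
  flt <- reference_taxon_filter(orders = character(0),
                                families = list(Piciformes = "Picidae"))
  sets <- suppressWarnings(split_focal_reference(wood, "Passerina ciris", flt))
  expect_equal(nrow(sets$reference), 7)
  expect_equal(nrow(sets$focal), 0)
  expect_warning(split_focal_reference(wood, "Passerina ciris", flt),
                 "no records match")
})
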