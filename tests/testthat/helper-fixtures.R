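# Shared builders for the test suite. Everything is generated in code; the
# heavier shared objects are built once per run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# A record tibble with sensible defaults, overridable per field.
make_recs <- function(n = 1, latitude = 22, longitude = -100, month = 1,
                      scientific_name = "Passerina ciris",
                      order_name = "Passeriformes",
                      family_name = "Cardinalidae",
                      year = 1980L, day = 15L, elevation_m = 100,
                      record_id = NULL) {
  tibble::tibble(
    record_id = record_id %||% sprintf("t-%04d", seq_len(n)),
    scientific_name = rep_len(scientific_name, n),
    order_name = rep_len(order_name, n),
    family_name = rep_len(family_name, n),
    latitude = rep_len(latitude, n),
    longitude = rep_len(longitude, n),
    year = as.integer(rep_len(year, n)),
    month = as.integer(rep_len(month, n)),
    day = as.integer(rep_len(day, n)),
    elevation_m = rep_len(elevation_m, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A constant-valued raster.
flat_raster <- function(value = 0.4, nr = 60, nc = 60, xmin = -102,
                        ymin = 18, res = 0.05, month = 1L) {
  evi_raster(matrix(value, nr, nc), xmin = xmin, ymin = ymin,
             resolution = res, month = month)
}

test_boundary <- function() cache_get("boundary", synthetic_boundary)

# Coarse monthly rasters over the synthetic boundary, cheap to build.
coarse_rasters <- function() {
  cache_get("coarse_rasters", function() {
    generate_rasters(resolution = 0.2, boundary = synthetic_boundary(),
                     seed = 424242)
  })
}

# Full-resolution rasters for buffer-geometry and greenness tests.
fine_rasters <- function() {
  cache_get("fine_rasters", function() {
    generate_rasters(resolution = 0.05, boundary = synthetic_boundary(),
                     seed = 424242)
  })
}

# Independent Pearson / Yates oracle from first principles (margins ->
# expected counts -> sum over cells), kept free of stats::chisq.test.
oracle_chisq <- function(tab, yates = FALSE) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  sum(dev^2 / expected)
}
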