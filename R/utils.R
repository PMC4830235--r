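# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Great-circle distance in km between one reference point and many points.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Vectorized even-odd (ray casting) point-in-polygon test. `poly` is a data
# frame with `lon`, `lat` vertex columns (ring closure optional). Points on
# an edge follow the crossing rule; fine for the sampling uses here.
point_in_polygon <- function(lon, lat, poly) {
  px <- poly$lon
  py <- poly$lat
  nv <- length(px)
  if (nv >= 2 && px[1] == px[nv] && py[1] == py[nv]) {
    px <- px[-nv]
    py <- py[-nv]
    nv <- nv - 1
  }
  if (nv < 3) abort("boundary polygon must have at least 3 distinct vertices")
  inside <- rep(FALSE, length(lon))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((py[i] > lat) != (py[j] > lat)) &
      (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i])
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read a boundary polygon from GeoJSON
#'
#' Accepts a `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first feature is a polygon. Only the outer ring
#' is used.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with `lon` and `lat` vertex columns.
#' @export
read_boundary <- function(path) {
  if (!file.exists(path)) abort(paste0("boundary file not found: ", path))
  gj <- jsonlite::read_json(path)
  geom <- switch(gj$type %||% "",
    "Polygon" = gj,
    "Feature" = gj$geometry,
    "FeatureCollection" = gj$features[[1]]$geometry,
    abort("unsupported GeoJSON type for a boundary polygon")
  )
  if (!identical(geom$type, "Polygon")) abort("boundary geometry must be a Polygon")
  ring <- geom$coordinates[[1]]
  tibble(
    lon = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
    lat = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
  )
}

#' Write a boundary polygon to GeoJSON
#'
#' @param boundary Tibble with `lon`, `lat` vertex columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(boundary, path) {
  lon <- boundary$lon
  lat <- boundary$lat
  n <- length(lon)
  if (lon[1] != lon[n] || lat[1] != lat[n]) {
    lon <- c(lon, lon[1])
    lat <- c(lat, lat[1])
  }
  ring <- lapply(seq_along(lon), function(i) c(lon[i], lat[i]))
  gj <- list(type = "Polygon", coordinates = list(ring))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
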