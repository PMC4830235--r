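# Grid, region, seasonal-period and elevation assignment.

#' Define a latitude/longitude analysis grid
#'
#' A regular grid of `cell_size_min` arc-minute cells whose edges are
#' anchored at `lat_origin`/`lon_origin` (so with the defaults, cell edges
#' fall on multiples of 5 arc-minutes from (0 deg, -120 deg)). Cells are
#' half-open `[edge, edge + size)` in both axes.
#'
#' @param cell_size_min Cell size in arc-minutes (default 5).
#' @param lat_origin,lon_origin Degrees anchoring cell edges.
#' @param lat_range,lon_range Numeric length-2 extents (degrees) the grid
#'   covers; points outside map to the out-of-grid sentinel.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(cell_size_min = 5, lat_origin = 0, lon_origin = -120,
                      lat_range = c(10, 40), lon_range = c(-120, -70)) {
  if (cell_size_min <= 0) abort("cell_size_min must be positive")
  structure(
    list(cell_size_min = cell_size_min,
         cell_size_deg = cell_size_min / 60,
         lat_origin = lat_origin, lon_origin = lon_origin,
         lat_range = sort(lat_range), lon_range = sort(lon_range)),
    class = "grid_spec"
  )
}

#' Assign points to grid cells
#'
#' Rows index from the south, columns from the west (both relative to the
#' grid origin). Points outside the grid extent get `NA` row/column (the
#' out-of-grid sentinel), never an error.
#'
#' @param lat,lon Numeric vectors of coordinates (degrees).
#' @param spec A [grid_spec()].
#' @return A tibble with `cell_row`, `cell_col` (integer) and `cell_id`
#'   (string, `NA` outside the extent).
#' @export
assign_cell <- function(lat, lon, spec = grid_spec()) {
  sz <- spec$cell_size_deg
  row <- as.integer(floor((lat - spec$lat_origin) / sz + 1e-9))
  col <- as.integer(floor((lon - spec$lon_origin) / sz + 1e-9))
  inside <- lat >= spec$lat_range[1] & lat < spec$lat_range[2] &
    lon >= spec$lon_range[1] & lon < spec$lon_range[2]
  inside[is.na(inside)] <- FALSE
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  tibble(
    cell_row = row, cell_col = col,
    cell_id = ifelse(is.na(row), NA_character_, paste0("r", row, "c", col))
  )
}

#' Grid-cell centers
#'
#' @param cell_row,cell_col Integer indices as returned by [assign_cell()].
#' @param spec A [grid_spec()].
#' @return Tibble with `lat`, `lon` cell-center coordinates.
#' @export
cell_center <- function(cell_row, cell_col, spec = grid_spec()) {
  sz <- spec$cell_size_deg
  tibble(
    lat = spec$lat_origin + (cell_row + 0.5) * sz,
    lon = spec$lon_origin + (cell_col + 0.5) * sz
  )
}

#' Regional partition of the study area
#'
#' Splits the study area into NW, NE and S bands: S is everything south of
#' `lat_split`; the northern band divides at `lon_split` into NW (west) and
#' NE (east). Points exactly on a split line go to the north/east side.
#' `tehuantepec_lon` marks the isthmus meridian used by the optional
#' east-of-isthmus exclusion, and `elevation_split_m` the lowland/upland
#' threshold.
#'
#' @param lat_split Latitude of the N/S divide (default 20).
#' @param lon_split Longitude of the NW/NE divide (default -103).
#' @param tehuantepec_lon Isthmus exclusion meridian (default -94).
#' @param elevation_split_m Lowland threshold in meters (default 200).
#' @return A `region_partition` object.
#' @export
region_partition <- function(lat_split = 20, lon_split = -103,
                             tehuantepec_lon = -94, elevation_split_m = 200) {
  structure(
    list(lat_split = lat_split, lon_split = lon_split,
         tehuantepec_lon = tehuantepec_lon,
         elevation_split_m = elevation_split_m),
    class = "region_partition"
  )
}

#' Assign coordinates to regions
#'
#' @param lat,lon Numeric coordinate vectors (degrees).
#' @param part A [region_partition()].
#' @return Character vector of `"NW"`, `"NE"` or `"S"` (`NA` for missing
#'   coordinates).
#' @export
assign_region <- function(lat, lon, part = region_partition()) {
  dplyr::case_when(
    is.na(lat) | is.na(lon) ~ NA_character_,
    lat < part$lat_split ~ "S",
    lon < part$lon_split ~ "NW",
    TRUE ~ "NE"
  )
}

#' Seasonal periods of the non-breeding cycle
#'
#' Defaults follow the focal species' annual cycle in the study area:
#' molt-stopover July--October, winter November--February, spring migration
#' March--April. May and June fall in no period.
#'
#' @param molt,winter,spring Integer month sets (1--12), pairwise disjoint.
#' @return A `seasonal_periods` object.
#' @export
seasonal_periods <- function(molt = 7:10, winter = c(11, 12, 1, 2), spring = 3:4) {
  all <- c(molt, winter, spring)
  if (anyDuplicated(all)) abort("seasonal periods must be pairwise disjoint")
  structure(list(molt = as.integer(molt), winter = as.integer(winter),
                 spring = as.integer(spring)),
            class = "seasonal_periods")
}

#' Assign months to seasonal periods
#'
#' @param month Integer vector of months (1--12; anything else is an error).
#' @param periods A [seasonal_periods()].
#' @return Character vector of `"molt"`, `"winter"`, `"spring"` or
#'   `"unassigned"`.
#' @export
assign_period <- function(month, periods = seasonal_periods()) {
  bad <- !is.na(month) & (month < 1 | month > 12 | month != round(month))
  if (any(bad)) abort("month values must be integers in 1..12")
  dplyr::case_when(
    is.na(month) ~ NA_character_,
    month %in% periods$molt ~ "molt",
    month %in% periods$winter ~ "winter",
    month %in% periods$spring ~ "spring",
    TRUE ~ "unassigned"
  )
}

#' Classify record elevations
#'
#' @param elevation_m Numeric elevations in meters (may be `NA`).
#' @param part A [region_partition()] supplying the threshold.
#' @return `"lowland"` (below the threshold), `"upland"` (at or above), or
#'   `"unknown"` when missing.
#' @export
classify_elevation <- function(elevation_m, part = region_partition()) {
  dplyr::case_when(
    is.na(elevation_m) ~ "unknown",
    elevation_m < part$elevation_split_m ~ "lowland",
    TRUE ~ "upland"
  )
}

#' Annotate records with grid, region, period and elevation class
#'
#' Convenience wrapper adding `cell_row`/`cell_col`/`cell_id`, `region`,
#' `period` and `elevation_class` columns to a cleaned record tibble.
#'
#' @param records Cleaned occurrence record tibble.
#' @param spec A [grid_spec()].
#' @param part A [region_partition()].
#' @param periods A [seasonal_periods()].
#' @return The records with assignment columns appended.
#' @export
annotate_records <- function(records, spec = grid_spec(),
                             part = region_partition(),
                             periods = seasonal_periods()) {
  cells <- assign_cell(records$latitude, records$longitude, spec)
  dplyr::bind_cols(records, cells) |>
    mutate(
      region = assign_region(.data$latitude, .data$longitude, part),
      period = assign_period(.data$month, periods),
      elevation_class = classify_elevation(.data$elevation_m, part)
    )
}
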