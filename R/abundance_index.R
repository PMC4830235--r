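# The abundance-index statistic and its per-cell / per-region tables.

#' Compute the abundance index
#'
#' The abundance index for species k in spatial-temporal unit r is
#' `AI = 100 * x_kr / sum_j x_jr`: the percentage of the focal species'
#' specimens among specimens of all comparably collected species in that
#' unit. It is a crude effort-corrected relative density. A unit with zero
#' total specimens has an undefined (not zero) index, returned as `NA`.
#'
#' @param focal_count,total_count Non-negative counts (vectorized);
#'   `focal_count` must not exceed `total_count` since the denominator sums
#'   over all species including the focal one.
#' @return Numeric AI values in `[0, 100]`, `NA` where `total_count` is 0.
#' @export
compute_ai <- function(focal_count, total_count) {
  if (any(focal_count < 0 | total_count < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  if (any(focal_count > total_count, na.rm = TRUE)) {
    abort("focal_count exceeds total_count; the denominator must include focal specimens")
  }
  ifelse(total_count > 0, 100 * focal_count / total_count, NA_real_)
}

# Monthly counts per arbitrary grouping key columns.
count_by <- function(records, keys) {
  records |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n") |>
    ungroup()
}

#' Abundance indices per grid cell and month
#'
#' Emits an index only for (cell, month) pairs where at least one focal
#' specimen was collected, mirroring how indices are mapped; the denominator
#' counts all reference specimens (focal included unless
#' `include_focal = FALSE`) in that cell-month. Records that fall outside
#' the grid extent are ignored.
#'
#' @param focal,reference Cleaned record tibbles (reference includes the
#'   focal species' records, as produced by [split_focal_reference()]).
#' @param spec A [grid_spec()].
#' @param include_focal Count focal specimens in the denominator (default
#'   `TRUE`; `FALSE` gives the sensitivity variant).
#' @return Tibble of `cell_row`, `cell_col`, `cell_id`, `month`,
#'   `focal_count`, `total_count`, `ai`.
#' @export
ai_by_cell <- function(focal, reference, spec = grid_spec(), include_focal = TRUE) {
  fc <- dplyr::bind_cols(focal, assign_cell(focal$latitude, focal$longitude, spec)) |>
    filter(!is.na(.data$cell_id)) |>
    count_by(c("cell_row", "cell_col", "cell_id", "month")) |>
    rename(focal_count = "n")
  rc <- dplyr::bind_cols(reference, assign_cell(reference$latitude, reference$longitude, spec)) |>
    filter(!is.na(.data$cell_id)) |>
    count_by(c("cell_id", "month")) |>
    rename(total_count = "n")
  out <- fc |>
    left_join(rc, by = c("cell_id", "month")) |>
    mutate(total_count = dplyr::coalesce(.data$total_count, 0L))
  if (!include_focal) out <- mutate(out, total_count = .data$total_count - .data$focal_count)
  out |>
    mutate(ai = compute_ai(.data$focal_count, .data$total_count)) |>
    arrange(.data$cell_row, .data$cell_col, .data$month)
}

#' Abundance indices per region and month
#'
#' Pools raw counts within each (month, region) and applies the index
#' formula to the pooled counts (a pooled ratio, not a mean of cell
#' indices). The table is dense: all 12 months by all three regions, with
#' explicit zeros where the focal species is absent but reference specimens
#' exist, and `NA` where a region-month has no reference specimens at all.
#'
#' @inheritParams ai_by_cell
#' @param part A [region_partition()].
#' @return Long tibble of `month`, `region`, `focal_count`, `total_count`,
#'   `ai`, with class `ai_region` (see [ai_region_wide()], [autoplot.ai_region()]).
#' @export
ai_by_region <- function(focal, reference, part = region_partition(),
                         include_focal = TRUE) {
  frame <- tidyr::expand_grid(month = 1:12, region = c("NW", "NE", "S"))
  fc <- focal |>
    mutate(region = assign_region(.data$latitude, .data$longitude, part)) |>
    count_by(c("month", "region")) |>
    rename(focal_count = "n")
  rc <- reference |>
    mutate(region = assign_region(.data$latitude, .data$longitude, part)) |>
    count_by(c("month", "region")) |>
    rename(total_count = "n")
  out <- frame |>
    left_join(fc, by = c("month", "region")) |>
    left_join(rc, by = c("month", "region")) |>
    mutate(
      focal_count = dplyr::coalesce(.data$focal_count, 0L),
      total_count = dplyr::coalesce(.data$total_count, 0L)
    )
  if (!include_focal) out <- mutate(out, total_count = .data$total_count - .data$focal_count)
  out <- out |>
    mutate(ai = compute_ai(.data$focal_count, .data$total_count)) |>
    mutate(region = factor(.data$region, levels = c("NW", "NE", "S"))) |>
    arrange(.data$month, .data$region)
  class(out) <- c("ai_region", class(out))
  out
}

#' Reshape a regional index table to months x regions
#'
#' One row per month (January--December), one column per region -- the
#' conventional presentation of a monthly regional abundance-index table.
#'
#' @param ai_tbl Output of [ai_by_region()].
#' @return A 12-row tibble with `month` plus `NW`, `NE`, `S` columns.
#' @export
ai_region_wide <- function(ai_tbl) {
  ai_tbl |>
    as_tibble() |>
    select("month", "region", "ai") |>
    tidyr::pivot_wider(names_from = "region", values_from = "ai") |>
    mutate(month = month.name[.data$month]) |>
    select("month", "NW", "NE", "S")
}

#' Raw monthly specimen counts
#'
#' Plain per-month record totals with no effort correction -- useful where
#' reference collections are too sparse for an index (e.g. country-level
#' summaries outside the gridded study area).
#'
#' @param records Cleaned occurrence record tibble.
#' @return Tibble with `month` (1--12) and `count`, zero-filled.
#' @export
raw_monthly_counts <- function(records) {
  tibble(month = 1:12) |>
    left_join(count_by(records, "month"), by = "month") |>
    mutate(count = dplyr::coalesce(.data$n, 0L)) |>
    select("month", "count")
}

#' Export cell-level indices as a GeoJSON point layer
#'
#' Writes one point feature per (cell, month) at the cell center with the
#' index as a size field, for inspection in any GIS.
#'
#' @param ai_cells Output of [ai_by_cell()].
#' @param spec The [grid_spec()] the cells were assigned with.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ai_geojson <- function(ai_cells, spec, path) {
  centers <- cell_center(ai_cells$cell_row, ai_cells$cell_col, spec)
  features <- purrr::pmap(
    list(centers$lon, centers$lat, ai_cells$month, ai_cells$focal_count,
         ai_cells$total_count, ai_cells$ai),
    function(lon, lat, month, fc, tc, ai) {
      list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(lon, lat)),
        properties = list(month = month, focal_count = fc,
                          total_count = tc, ai = ai)
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
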