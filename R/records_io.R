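# Reading, validating and cleaning occurrence-record tables.

# Canonical internal column names and their default Darwin-Core-style CSV
# headers.
occurrence_column_map <- function() {
  c(
    record_id = "catalogNumber",
    scientific_name = "scientificName",
    order_name = "order",
    family_name = "family",
    latitude = "decimalLatitude",
    longitude = "decimalLongitude",
    year = "year",
    month = "month",
    day = "day",
    elevation_m = "elevation"
  )
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  ifelse(is.finite(v), as.integer(round(v)), NA_integer_)
}

#' Read occurrence records from CSV
#'
#' Reads a Darwin-Core-style occurrence table into the canonical record
#' tibble used throughout the package. Numeric fields that fail to parse
#' become missing values rather than errors; row order is preserved.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (`record_id`, `scientific_name`, `order_name`, `family_name`,
#'   `latitude`, `longitude`, `year`, `month`, `day`, `elevation_m`) to
#'   column headers in the file. Defaults to Darwin-Core-style headers;
#'   supply a partial map to override individual columns. Map a field to
#'   `NA` to omit it.
#' @return A tibble of occurrence records, one row per input row.
#' @export
read_occurrences <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("occurrence file not found: ", path))
  cmap <- occurrence_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- cmap[!is.na(cmap)]
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mapped column(s) absent from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  pull_chr <- function(field) {
    if (is.na(cmap[[field]])) rep(NA_character_, nrow(raw)) else raw[[cmap[[field]]]]
  }
  tibble(
    record_id = pull_chr("record_id"),
    scientific_name = pull_chr("scientific_name"),
    order_name = pull_chr("order_name"),
    family_name = pull_chr("family_name"),
    latitude = as_num(pull_chr("latitude")),
    longitude = as_num(pull_chr("longitude")),
    year = as_int(pull_chr("year")),
    month = as_int(pull_chr("month")),
    day = as_int(pull_chr("day")),
    elevation_m = as_num(pull_chr("elevation_m"))
  )
}

#' Write occurrence records to CSV
#'
#' Inverse of [read_occurrences()]: writes the canonical record tibble with
#' Darwin-Core-style headers so a written file re-reads field-identically.
#'
#' @param records Occurrence record tibble.
#' @param path Output path.
#' @param column_map As in [read_occurrences()].
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path, column_map = NULL) {
  cmap <- occurrence_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  out <- records[, names(cmap)]
  names(out) <- unname(cmap)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Clean occurrence records
#'
#' Applies the exclusion rules for missing or obviously erroneous date and
#' coordinate values. Each record is judged by the first failing rule, in
#' order: (1) missing month; (2) missing latitude or longitude; (3)
#' erroneous coordinates -- outside valid ranges, exactly (0, 0) (the
#' null-island sentinel), or (optionally) outside a supplied boundary
#' polygon. Day and year are not required: the analysis is monthly and all
#' years are pooled.
#'
#' @param records Occurrence record tibble.
#' @param boundary Optional boundary polygon (tibble with `lon`, `lat`).
#' @param drop_outside_boundary If `TRUE` (and `boundary` given), in-range
#'   coordinates falling outside the polygon also count as erroneous.
#'   Default `FALSE`.
#' @return The retained records, with the cleaning tally attached as the
#'   `"cleaning_report"` attribute (see [cleaning_report()]).
#' @export
clean_records <- function(records, boundary = NULL, drop_outside_boundary = FALSE) {
  n_input <- nrow(records)
  bad_date <- is.na(records$month) | records$month < 1 | records$month > 12
  miss_coord <- !bad_date & (is.na(records$latitude) | is.na(records$longitude))
  lat <- records$latitude
  lon <- records$longitude
  erro <- !bad_date & !miss_coord &
    (lat < -90 | lat > 90 | lon < -180 | lon > 180 | (lat == 0 & lon == 0))
  erro[is.na(erro)] <- FALSE
  if (drop_outside_boundary && !is.null(boundary)) {
    candidate <- !bad_date & !miss_coord & !erro
    if (any(candidate)) {
      outside <- !point_in_polygon(lon[candidate], lat[candidate], boundary)
      erro[candidate] <- outside
    }
  }
  keep <- !(bad_date | miss_coord | erro)
  report <- tibble(
    n_input = n_input,
    n_retained = sum(keep),
    n_dropped_missing_date = sum(bad_date),
    n_dropped_missing_coords = sum(miss_coord),
    n_dropped_erroneous_coords = sum(erro),
    drop_fraction = if (n_input == 0) 0 else 1 - sum(keep) / n_input
  )
  out <- records[keep, , drop = FALSE]
  attr(out, "cleaning_report") <- report
  out
}

#' Retrieve the cleaning report
#'
#' @param records A tibble returned by [clean_records()].
#' @return One-row tibble with input/retained/dropped counts and the drop
#'   fraction.
#' @export
cleaning_report <- function(records) {
  rep <- attr(records, "cleaning_report")
  if (is.null(rep)) abort("no cleaning report attached; was this cleaned with clean_records()?")
  rep
}

#' Reference-taxon filter
#'
#' Declares which taxa count as reference specimens (collected with similar
#' methods to the focal species). The default is the classic songbird
#' collecting suite: all Passeriformes, all Cuculiformes, and family Picidae
#' within Piciformes.
#'
#' @param orders Character vector of order names included wholesale.
#' @param families Named list mapping an order name to the families included
#'   from that order.
#' @return A `reference_taxon_filter` object.
#' @export
reference_taxon_filter <- function(orders = c("Passeriformes", "Cuculiformes"),
                                   families = list(Piciformes = "Picidae")) {
  structure(list(orders = orders, families = families),
            class = "reference_taxon_filter")
}

matches_filter <- function(records, filter) {
  ok <- records$order_name %in% filter$orders
  for (ord in names(filter$families)) {
    ok <- ok | (records$order_name %in% ord &
                  records$family_name %in% filter$families[[ord]])
  }
  ok
}

#' Split records into focal and reference sets
#'
#' The focal set holds the records whose scientific name equals
#' `focal_name`. The reference set holds every record passing the taxon
#' filter -- including the focal species' own records, since the abundance
#' index denominator sums specimens of all species. Records outside the
#' filter are discarded.
#'
#' @param records Cleaned occurrence record tibble.
#' @param focal_name Scientific name of the focal species.
#' @param filter A [reference_taxon_filter()].
#' @return A list with `focal` and `reference` tibbles.
#' @export
split_focal_reference <- function(records, focal_name,
                                  filter = reference_taxon_filter()) {
  focal <- records[records$scientific_name %in% focal_name, , drop = FALSE]
  if (nrow(focal) == 0) {
    warn(paste0("no records match focal species '", focal_name, "'"))
  }
  reference <- records[matches_filter(records, filter), , drop = FALSE]
  list(focal = focal, reference = reference)
}
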