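# Buffered greenness extraction and the two randomization nulls.

#' Extract buffered pixel means around locations
#'
#' For each location, collects every raster pixel whose center lies within
#' `radius_km` great-circle kilometers, drops no-data pixels, and averages
#' the rest. A location with zero valid pixels gets `n_pixels = 0` and an
#' `NA` mean (filterable downstream), never an error.
#'
#' @param raster An [evi_raster()].
#' @param lat,lon Coordinate vectors (degrees).
#' @param radius_km Buffer radius in km (default 10).
#' @return Tibble with `lat`, `lon`, `month`, `n_pixels`, `mean_evi`.
#' @export
extract_buffer <- function(raster, lat, lon, radius_km = 10) {
  row_lats <- raster_row_lats(raster)
  col_lons <- raster_col_lons(raster)
  nr <- length(row_lats)
  nc <- length(col_lons)
  dlat <- radius_km / 110.574 + raster$res
  n_pix <- integer(length(lat))
  mean_v <- rep(NA_real_, length(lat))
  for (i in seq_along(lat)) {
    la <- lat[i]
    lo <- lon[i]
    if (is.na(la) || is.na(lo)) next
    dlon <- radius_km / (111.320 * max(cos(la * pi / 180), 0.05)) + raster$res
    r0 <- max(1L, ceiling((la - dlat - raster$ymin) / raster$res))
    r1 <- min(nr, ceiling((la + dlat - raster$ymin) / raster$res))
    c0 <- max(1L, ceiling((lo - dlon - raster$xmin) / raster$res))
    c1 <- min(nc, ceiling((lo + dlon - raster$xmin) / raster$res))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1
    cols <- c0:c1
    cand_lat <- rep(row_lats[rows], times = length(cols))
    cand_lon <- rep(col_lons[cols], each = length(rows))
    d <- haversine_km(la, lo, cand_lat, cand_lon)
    sel <- d <= radius_km
    if (!any(sel)) next
    vals <- raster$values[cbind(rep(rows, times = length(cols))[sel],
                                rep(cols, each = length(rows))[sel])]
    vals <- vals[!is.na(vals)]
    n_pix[i] <- length(vals)
    if (length(vals) > 0) mean_v[i] <- mean(vals)
  }
  tibble(lat = lat, lon = lon, month = raster$month,
         n_pixels = n_pix, mean_evi = mean_v)
}

#' Sample uniformly random locations within a polygon
#'
#' Rejection sampling from the bounding box; uniform over the polygon's
#' area (in lat/lon degrees, matching how random control points are drawn
#' for occurrence-record null models).
#'
#' @param boundary Tibble with `lon`, `lat` vertex columns.
#' @param n Number of points (default 500).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return Tibble with `lat`, `lon`.
#' @export
sample_random_locations <- function(boundary, n = 500, seed = NULL) {
  if (nrow(boundary) < 3) abort("degenerate boundary polygon")
  with_seed(seed, {
    xr <- range(boundary$lon)
    yr <- range(boundary$lat)
    if (diff(xr) == 0 || diff(yr) == 0) abort("degenerate boundary polygon")
    got_lat <- numeric(0)
    got_lon <- numeric(0)
    while (length(got_lat) < n) {
      m <- max(2L * (n - length(got_lat)), 100L)
      lo <- runif(m, xr[1], xr[2])
      la <- runif(m, yr[1], yr[2])
      keep <- point_in_polygon(lo, la, boundary)
      got_lat <- c(got_lat, la[keep])
      got_lon <- c(got_lon, lo[keep])
    }
    tibble(lat = got_lat[seq_len(n)], lon = got_lon[seq_len(n)])
  })
}

# Round coordinates to the nearest 0.01 degree (~1 km) and tally specimen
# multiplicity per unique rounded location.
round_locations <- function(records, digits = 2) {
  records |>
    mutate(lat = round(.data$latitude, digits),
           lon = round(.data$longitude, digits)) |>
    dplyr::count(.data$lat, .data$lon, name = "weight")
}

#' Weighted reference-location subsample for one month
#'
#' Implements the reference null in order: round coordinates to the nearest
#' 0.01 degree (about 1 km); sample `n_locations` unique rounded locations
#' present in that month (all of them, with a warning, if fewer exist);
#' extract buffered pixel means; drop locations with fewer than
#' `min_pixels` valid pixels (sites surrounded by water yield few pixels);
#' and carry each surviving location's specimen multiplicity as its weight,
#' so downstream comparisons duplicate its mean accordingly.
#'
#' @param reference Cleaned reference record tibble.
#' @param raster The month's [evi_raster()].
#' @param month Month to subsample (defaults to the raster's stamp).
#' @param n_locations Unique locations to draw (default 250).
#' @param min_pixels Minimum valid pixels to keep a location (default 3).
#' @param radius_km Buffer radius (default 10).
#' @param seed Optional integer seed.
#' @return Tibble with `lat`, `lon`, `month`, `n_pixels`, `mean_evi`,
#'   `weight`.
#' @export
subsample_reference_locations <- function(reference, raster,
                                          month = raster$month,
                                          n_locations = 250, min_pixels = 3,
                                          radius_km = 10, seed = NULL) {
  locs <- round_locations(reference[reference$month %in% month, , drop = FALSE])
  if (nrow(locs) < n_locations) {
    warn(sprintf("month %s has only %d unique locations (< %d); using all",
                 paste(month, collapse = ","), nrow(locs), n_locations))
    chosen <- locs
  } else {
    chosen <- with_seed(seed, dplyr::slice_sample(locs, n = n_locations))
  }
  extract_buffer(raster, chosen$lat, chosen$lon, radius_km) |>
    mutate(weight = chosen$weight, month = month) |>
    filter(.data$n_pixels >= min_pixels)
}

#' Specimen-side buffered samples for one month
#'
#' Per-location buffered mean computed once, entered once per specimen:
#' coordinates are rounded to the nearest 0.01 degree, multiple specimens
#' at a rounded location become that location's weight.
#'
#' @inheritParams subsample_reference_locations
#' @param records Cleaned focal record tibble.
#' @return Tibble as in [subsample_reference_locations()].
#' @export
specimen_evi_samples <- function(records, raster, month = raster$month,
                                 min_pixels = 3, radius_km = 10) {
  locs <- round_locations(records[records$month %in% month, , drop = FALSE])
  if (nrow(locs) == 0) {
    return(tibble(lat = numeric(0), lon = numeric(0), month = integer(0),
                  n_pixels = integer(0), mean_evi = numeric(0),
                  weight = integer(0)))
  }
  extract_buffer(raster, locs$lat, locs$lon, radius_km) |>
    mutate(weight = locs$weight, month = month) |>
    filter(.data$n_pixels >= min_pixels)
}

# Expand weighted location means into one value per specimen.
expand_weights <- function(samples) {
  w <- if ("weight" %in% names(samples)) samples$weight else rep(1L, nrow(samples))
  rep(samples$mean_evi, times = w)
}

mean_ci95 <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2 || sd(x) == 0) return(c(mean = m, lo = m, hi = m))
  half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Compare specimen greenness against a null sample for one month
#'
#' Two-sample t-test (two-sided; Welch by default) on per-location buffered
#' means, with specimen values entered once per specimen (multiplicity
#' weights) and 95% confidence intervals on each overall mean. Degenerate
#' inputs (either side with fewer than 2 values) are marked not computable;
#' two identical constant sides give t = 0, p = 1.
#'
#' @param specimen_samples,null_samples Tibbles with `mean_evi` (and
#'   optionally `weight`) columns, e.g. from [specimen_evi_samples()],
#'   [extract_buffer()] or [subsample_reference_locations()]. `NA` means
#'   are dropped.
#' @param month Month label for the output row.
#' @param var_equal Pooled-variance t-test instead of Welch (default
#'   `FALSE`).
#' @return One-row tibble: month, means, CI bounds, t statistic, p-value,
#'   sample sizes, `computable` flag.
#' @export
monthly_null_comparison <- function(specimen_samples, null_samples,
                                    month = NA_integer_, var_equal = FALSE) {
  xs <- expand_weights(specimen_samples)
  xn <- expand_weights(null_samples)
  xs <- xs[!is.na(xs)]
  xn <- xn[!is.na(xn)]
  base <- tibble(
    month = month,
    specimen_mean = if (length(xs)) mean(xs) else NA_real_,
    null_mean = if (length(xn)) mean(xn) else NA_real_,
    specimen_lo = NA_real_, specimen_hi = NA_real_,
    null_lo = NA_real_, null_hi = NA_real_,
    t_statistic = NA_real_, p_value = NA_real_,
    n_specimen = length(xs), n_null = length(xn),
    computable = FALSE
  )
  if (length(xs) < 2 || length(xn) < 2) return(base)
  cs <- mean_ci95(xs)
  cn <- mean_ci95(xn)
  base$specimen_lo <- cs[["lo"]]
  base$specimen_hi <- cs[["hi"]]
  base$null_lo <- cn[["lo"]]
  base$null_hi <- cn[["hi"]]
  if (sd(xs) == 0 && sd(xn) == 0) {
    base$t_statistic <- 0
    base$p_value <- if (mean(xs) == mean(xn)) 1 else 0
    base$computable <- TRUE
    return(base)
  }
  tt <- t.test(xs, xn, var.equal = var_equal)
  base$t_statistic <- unname(tt$statistic)
  base$p_value <- tt$p.value
  base$computable <- TRUE
  base
}

#' Run the monthly greenness comparison battery
#'
#' For every month with a raster, compares specimen-site greenness against
#' (A) a fixed set of `n_random` uniformly random locations within the
#' boundary (the same points reused across months, extracted from each
#' monthly raster) and (B) a fresh weighted reference-location subsample.
#' Months with no focal specimens are reported as not computable; months
#' with a missing raster are skipped with a warning.
#'
#' @param focal Cleaned focal record tibble.
#' @param rasters List of 12 [evi_raster()]s (or fewer; index or `month`
#'   stamp identifies the month; `NULL` entries are skipped).
#' @param boundary Boundary polygon tibble (`lon`, `lat`).
#' @param reference Cleaned reference record tibble.
#' @param n_random Random control locations (default 500).
#' @param n_reference_locations Reference subsample size per month
#'   (default 250).
#' @param min_pixels Minimum valid pixels for specimen and reference
#'   locations (default 3); random locations are kept regardless unless
#'   `filter_random = TRUE`.
#' @param filter_random Apply the pixel filter to random locations too
#'   (default `FALSE`).
#' @param radius_km Buffer radius (default 10).
#' @param var_equal Pooled-variance t-tests (default `FALSE`, Welch).
#' @param seed Integer seed driving the random locations and the monthly
#'   subsamples (split deterministically).
#' @return An `evi_battery`: tibble with one row per (month, comparison),
#'   `comparison` in `"random"`/`"reference"`, plus the
#'   [monthly_null_comparison()] columns.
#' @export
run_evi_battery <- function(focal, rasters, boundary, reference,
                            n_random = 500, n_reference_locations = 250,
                            min_pixels = 3, filter_random = FALSE,
                            radius_km = 10, var_equal = FALSE, seed = NULL) {
  rand_pts <- sample_random_locations(boundary, n = n_random, seed = seed)
  rows <- list()
  for (m in 1:12) {
    raster <- NULL
    for (r in rasters) {
      if (!is.null(r) && isTRUE(r$month == m)) raster <- r
    }
    if (is.null(raster) && m <= length(rasters) && !is.null(rasters[[m]]) &&
        is.na(rasters[[m]]$month)) {
      raster <- rasters[[m]]
    }
    if (is.null(raster)) {
      warn(sprintf("no raster for month %d; skipping", m))
      next
    }
    spec_s <- specimen_evi_samples(focal, raster, month = m,
                                   min_pixels = min_pixels,
                                   radius_km = radius_km)
    rand_s <- extract_buffer(raster, rand_pts$lat, rand_pts$lon, radius_km)
    if (filter_random) rand_s <- filter(rand_s, .data$n_pixels >= min_pixels)
    ref_s <- subsample_reference_locations(
      reference, raster, month = m, n_locations = n_reference_locations,
      min_pixels = min_pixels, radius_km = radius_km,
      seed = if (is.null(seed)) NULL else seed + m
    )
    rows[[length(rows) + 1]] <- monthly_null_comparison(
      spec_s, rand_s, month = m, var_equal = var_equal) |>
      mutate(comparison = "random", .after = "month")
    rows[[length(rows) + 1]] <- monthly_null_comparison(
      spec_s, ref_s, month = m, var_equal = var_equal) |>
      mutate(comparison = "reference", .after = "month")
  }
  out <- bind_rows(rows)
  class(out) <- c("evi_battery", class(out))
  out
}

#' @describeIn run_evi_battery Battery rows as a plain tibble.
#' @param x An `evi_battery`.
#' @param ... Unused.
#' @export
tidy.evi_battery <- function(x, ...) as_tibble(x)

#' @describeIn run_evi_battery One-row summary of the battery.
#' @export
glance.evi_battery <- function(x, ...) {
  tibble(
    n_months = length(unique(x$month)),
    n_computable = sum(x$computable),
    n_specimen_greener_random = sum(
      x$comparison == "random" & x$computable &
        x$specimen_mean > x$null_mean & x$p_value < 0.05),
    n_specimen_greener_reference = sum(
      x$comparison == "reference" & x$computable &
        x$specimen_mean > x$null_mean & x$p_value < 0.05)
  )
}
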