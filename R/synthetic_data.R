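# Synthetic occurrence records, greenness rasters and boundaries with the
# statistical structure the analysis assumes, so every stage can be tested
# against known truth.

#' Synthetic study-area boundary
#'
#' A simple multi-vertex polygon roughly shaped like the study area (not
#' actual country borders), spanning all three analysis regions and
#' extending east of the isthmus exclusion meridian.
#'
#' @return Tibble with `lon`, `lat` vertex columns.
#' @export
synthetic_boundary <- function() {
  tibble(
    lon = c(-117, -108, -103, -100, -97, -96, -90, -87, -87, -91,
            -92, -95, -98, -103, -106, -110, -114, -117),
    lat = c(32.7, 31.5, 29.5, 29, 27, 22, 21.5, 21, 18, 17,
            15.5, 15.5, 16, 18, 21, 23, 27, 32.7)
  )
}

#' Parametric greenness (EVI) surface model
#'
#' Generated monthly EVI is `base + lat_slope * (lat - 20) + mosaic(lat,
#' lon) + amplitude[region] * cos(2 * pi * (month - peak_month[region]) /
#' 12) + noise`, clipped to `clip`. The mosaic term is a fixed (month- and
#' seed-independent) sinusoidal field,
#' `mesoscale_amplitude * sin(2 * pi * lon / wavelength) * sin(2 * pi *
#' lat / wavelength)`, giving the landscape the strong few-degree-scale
#' heterogeneity (coastal forest versus interior dryland) that real
#' greenness maps show and that habitat selection acts on. Defaults
#' emulate the study area's phenology: a greener south, a monsoon-driven
#' NW peak in September, a spring NE peak, and an autumn S peak.
#'
#' @param base Base EVI at 20 degrees latitude (default 0.35).
#' @param lat_slope EVI change per degree latitude (default -0.012).
#' @param amplitude Named seasonal amplitudes per region.
#' @param peak_month Named peak months per region.
#' @param mesoscale_amplitude Amplitude of the fixed vegetation-mosaic
#'   field (default 0.25).
#' @param mesoscale_wavelength_deg Mosaic wavelength in degrees (default 3).
#' @param noise_sd Pixel noise standard deviation (default 0.03).
#' @param clip Length-2 value range (default `c(-0.2, 1)`).
#' @return A `greenness_model` object.
#' @export
greenness_model <- function(base = 0.35, lat_slope = -0.012,
                            amplitude = c(NW = 0.15, NE = 0.08, S = 0.10),
                            peak_month = c(NW = 9, NE = 4, S = 10),
                            mesoscale_amplitude = 0.25,
                            mesoscale_wavelength_deg = 3,
                            noise_sd = 0.03, clip = c(-0.2, 1)) {
  structure(list(base = base, lat_slope = lat_slope, amplitude = amplitude,
                 peak_month = peak_month,
                 mesoscale_amplitude = mesoscale_amplitude,
                 mesoscale_wavelength_deg = mesoscale_wavelength_deg,
                 noise_sd = noise_sd, clip = clip),
            class = "greenness_model")
}

#' Generate 12 monthly greenness rasters
#'
#' Deterministic given `seed`. When a boundary is supplied, pixels outside
#' it become no-data (emulating water and out-of-country masking).
#'
#' @param model A [greenness_model()].
#' @param lat_range,lon_range Extent (degrees); defaults cover the
#'   synthetic boundary.
#' @param resolution Degrees per pixel (default 0.05).
#' @param boundary Optional polygon tibble for the no-data mask.
#' @param part A [region_partition()] defining the seasonal regions.
#' @param seed Optional integer seed.
#' @return List of 12 [evi_raster()]s, month-stamped.
#' @export
generate_rasters <- function(model = greenness_model(),
                             lat_range = c(14, 34), lon_range = c(-118, -86),
                             resolution = 0.05, boundary = NULL,
                             part = region_partition(), seed = NULL) {
  if (resolution <= 0) abort("resolution must be positive")
  nr <- round(diff(lat_range) / resolution)
  nc <- round(diff(lon_range) / resolution)
  lats <- lat_range[1] + (seq_len(nr) - 0.5) * resolution
  lons <- lon_range[1] + (seq_len(nc) - 0.5) * resolution
  lat_m <- matrix(lats, nr, nc)
  lon_m <- matrix(lons, nr, nc, byrow = TRUE)
  region <- matrix(assign_region(as.vector(lat_m), as.vector(lon_m), part), nr, nc)
  base_surface <- model$base + model$lat_slope * (lat_m - 20) +
    model$mesoscale_amplitude *
      sin(2 * pi * lon_m / model$mesoscale_wavelength_deg) *
      sin(2 * pi * lat_m / model$mesoscale_wavelength_deg)
  amp <- matrix(model$amplitude[region], nr, nc)
  peak <- matrix(model$peak_month[region], nr, nc)
  mask <- NULL
  if (!is.null(boundary)) {
    mask <- !point_in_polygon(as.vector(lon_m), as.vector(lat_m), boundary)
  }
  with_seed(seed, {
    lapply(1:12, function(m) {
      v <- base_surface + amp * cos(2 * pi * (m - peak) / 12)
      if (model$noise_sd > 0) v <- v + rnorm(length(v), 0, model$noise_sd)
      v <- pmin(pmax(v, model$clip[1]), model$clip[2])
      if (!is.null(mask)) v[mask] <- NA_real_
      evi_raster(matrix(v, nr, nc), xmin = lon_range[1], ymin = lat_range[1],
                 resolution = resolution, month = m)
    })
  })
}

#' Default collector-effort hotspots
#'
#' Gaussian effort clusters shared by focal and reference generation, with
#' deliberately unequal weights across regions so that raw counts are
#' effort-confounded while the abundance index is not.
#'
#' @return Tibble with `lat`, `lon`, `sd_deg`, `weight`.
#' @export
default_effort_hotspots <- function() {
  tibble(
    lat = c(24.5, 29.0, 22.5, 25.5, 19.3, 17.0, 19.5),
    lon = c(-107.3, -110.5, -100.5, -99.5, -99.0, -96.5, -88.5),
    sd_deg = c(1.0, 0.9, 1.1, 0.9, 0.8, 1.0, 0.8),
    weight = c(1.5, 1.0, 1.2, 1.0, 2.0, 1.0, 0.8)
  )
}

#' Define a movement scenario for the synthetic generator
#'
#' `occupancy` is a 12 x 3 non-negative matrix (months x NW/NE/S) of focal
#' intensity *multipliers* on the shared collector-effort process: within a
#' month, the focal species' regional distribution is proportional to
#' `occupancy[month, region]` times the reference effort mass in that
#' region, and monthly totals are proportional to the occupancy row sums.
#' A matrix of ones therefore makes the focal records statistically
#' indistinguishable from the reference process (the null), while
#' region-varying rows move the population. `evi_preference_beta` tilts
#' focal locations by `exp(beta * EVI)` (habitat selection);
#' `reference_evi_beta` does the same for reference collecting (collection
#' bias toward productive sites).
#'
#' @param occupancy 12 x 3 matrix, columns NW/NE/S.
#' @param n_focal,n_reference Expected specimen counts.
#' @param effort_hotspots Tibble as [default_effort_hotspots()].
#' @param evi_preference_beta Focal habitat-selection strength per EVI unit.
#' @param reference_evi_beta Reference collection-bias strength per EVI
#'   unit (default 0).
#' @param lowland_focal,lowland_reference Probability a focal / reference
#'   record lies below the elevation threshold.
#' @param corruption_fraction Fraction of rows corrupted (missing month,
#'   out-of-range or null-island coordinates) to exercise cleaning.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `movement_scenario` object.
#' @export
movement_scenario <- function(occupancy = matrix(1, 12, 3,
                                                 dimnames = list(NULL, c("NW", "NE", "S"))),
                              n_focal = 2000, n_reference = 50000,
                              effort_hotspots = default_effort_hotspots(),
                              evi_preference_beta = 0,
                              reference_evi_beta = 0,
                              lowland_focal = 0.5, lowland_reference = 0.5,
                              corruption_fraction = 0, seed = 1) {
  stopifnot(nrow(occupancy) == 12, ncol(occupancy) == 3)
  if (any(occupancy < 0)) abort("occupancy must be non-negative")
  if (n_focal <= 0 || n_reference <= 0) abort("n_focal and n_reference must be positive")
  colnames(occupancy) <- c("NW", "NE", "S")
  structure(
    list(occupancy = occupancy, n_focal = n_focal, n_reference = n_reference,
         effort_hotspots = effort_hotspots,
         evi_preference_beta = evi_preference_beta,
         reference_evi_beta = reference_evi_beta,
         lowland_focal = lowland_focal, lowland_reference = lowland_reference,
         corruption_fraction = corruption_fraction, seed = seed),
    class = "movement_scenario"
  )
}

#' The default quasi-circular movement scenario
#'
#' Encodes the qualitative annual loop the analysis is designed to detect:
#' the focal population concentrated in the NW during the July--October
#' molt-stopover (absent from the S in July), shifting to the S for
#' October--April, with the NE Gulf corridor loaded in late winter and
#' spring. Monthly intensities dip in May--June when most of the
#' population is on its breeding grounds. Habitat preference for green
#' sites is on (`beta = 4`), reference collecting is unbiased, and focal
#' records lean lowland.
#'
#' @param n_focal,n_reference Expected counts (defaults 2000 / 50000).
#' @param seed Integer seed (default 1).
#' @return A [movement_scenario()].
#' @export
default_circular_scenario <- function(n_focal = 2000, n_reference = 50000,
                                      seed = 1) {
  mult <- rbind(
    c(0.15, 0.45, 0.40),  # Jan
    c(0.15, 0.30, 0.55),  # Feb
    c(0.10, 0.38, 0.52),  # Mar
    c(0.10, 0.40, 0.50),  # Apr
    c(0.05, 0.75, 0.20),  # May
    c(0.10, 0.55, 0.35),  # Jun
    c(0.80, 0.20, 0.00),  # Jul
    c(0.85, 0.12, 0.03),  # Aug
    c(0.90, 0.07, 0.03),  # Sep
    c(0.30, 0.12, 0.58),  # Oct
    c(0.10, 0.38, 0.52),  # Nov
    c(0.15, 0.33, 0.52)   # Dec
  )
  intensity <- c(0.8, 0.7, 0.9, 0.7, 0.25, 0.15, 1.2, 1.4, 1.5, 1.2, 1.0, 0.9)
  occ <- mult * intensity
  colnames(occ) <- c("NW", "NE", "S")
  movement_scenario(
    occupancy = occ, n_focal = n_focal, n_reference = n_reference,
    evi_preference_beta = 4, reference_evi_beta = 0,
    lowland_focal = 0.8, lowland_reference = 0.5,
    corruption_fraction = 0, seed = seed
  )
}

# Draw n collecting-site locations from the effort-hotspot mixture,
# truncated to the boundary.
sample_effort_locations <- function(n, hotspots, boundary) {
  if (n == 0) return(tibble(lat = numeric(0), lon = numeric(0)))
  draw <- function(m) {
    comp <- sample.int(nrow(hotspots), m, replace = TRUE, prob = hotspots$weight)
    tibble(lat = rnorm(m, hotspots$lat[comp], hotspots$sd_deg[comp]),
           lon = rnorm(m, hotspots$lon[comp], hotspots$sd_deg[comp]))
  }
  got <- tibble(lat = numeric(0), lon = numeric(0))
  while (nrow(got) < n) {
    cand <- draw(max(2L * (n - nrow(got)), 200L))
    keep <- point_in_polygon(cand$lon, cand$lat, boundary)
    got <- bind_rows(got, cand[keep, ])
  }
  got[seq_len(n), ]
}

reference_taxon_pool <- function() {
  tibble(
    scientific_name = c(
      sprintf("Refpasser species%02d", 1:18),
      sprintf("Refcuculus species%02d", 1:3),
      sprintf("Refpicus species%02d", 1:3),
      "Reffalco offfilter"
    ),
    order_name = c(rep("Passeriformes", 18), rep("Cuculiformes", 3),
                   rep("Piciformes", 3), "Falconiformes"),
    family_name = c(rep("Parulidae", 9), rep("Tyrannidae", 9),
                    rep("Cuculidae", 3), rep("Picidae", 3), "Falconidae"),
    abundance = c(exp(seq(0, 2.5, length.out = 18)), 1.5, 1, 0.8,
                  2, 1.2, 0.6, 1)
  )
}

draw_elevations <- function(n, lowland_prob, split = 200) {
  low <- runif(n) < lowland_prob
  ifelse(low, runif(n, 0, split - 0.1), runif(n, split, 2800))
}

corrupt_records <- function(records, fraction) {
  if (fraction <= 0 || nrow(records) == 0) {
    attr(records, "corrupted_rows") <- integer(0)
    return(records)
  }
  idx <- which(runif(nrow(records)) < fraction)
  kinds <- rep_len(c("missing_month", "lat_out_of_range", "null_island",
                     "missing_lon"), length(idx))
  for (i in seq_along(idx)) {
    j <- idx[i]
    switch(kinds[i],
      missing_month = {records$month[j] <- NA_integer_},
      lat_out_of_range = {records$latitude[j] <- 95},
      null_island = {records$latitude[j] <- 0; records$longitude[j] <- 0},
      missing_lon = {records$longitude[j] <- NA_real_}
    )
  }
  attr(records, "corrupted_rows") <- idx
  records
}

#' Generate synthetic focal and reference occurrence records
#'
#' Reference records: monthly counts Poisson around `n_reference / 12`,
#' locations from the effort-hotspot mixture restricted to the boundary
#' (tilted by `reference_evi_beta` if nonzero), taxa drawn from a skewed
#' pool of reference species (plus a small off-filter fraction). Focal
#' records: monthly counts proportional to occupancy row sums, locations
#' from the same effort mixture thinned by the month's regional occupancy
#' multipliers and tilted by `exp(evi_preference_beta * EVI)`. Elevations
#' follow the scenario's lowland fractions. A `corruption_fraction` of
#' rows is then damaged (missing month, out-of-range or null-island
#' coordinates, missing longitude) to exercise cleaning; the damaged row
#' indices are attached as the `"corrupted_rows"` attribute.
#'
#' The returned `reference` tibble includes the focal records (the focal
#' species is itself a reference taxon), matching the sets
#' [split_focal_reference()] produces; `focal` holds just the focal rows.
#'
#' @param scenario A [movement_scenario()].
#' @param rasters Monthly rasters (required when either beta is nonzero).
#' @param boundary Boundary polygon tibble.
#' @param focal_name Scientific name given to focal records.
#' @param seed Seed override (defaults to `scenario$seed`).
#' @return List with `focal` and `reference` record tibbles.
#' @export
generate_records <- function(scenario, rasters = NULL,
                             boundary = synthetic_boundary(),
                             focal_name = "Passerina ciris",
                             seed = scenario$seed) {
  needs_raster <- scenario$evi_preference_beta != 0 ||
    scenario$reference_evi_beta != 0
  if (needs_raster && is.null(rasters)) {
    abort("rasters are required when an EVI preference beta is nonzero")
  }
  part <- region_partition()
  with_seed(seed, {
    n_m_ref <- rpois(12, scenario$n_reference / 12)
    row_w <- rowSums(scenario$occupancy)
    n_m_foc <- rpois(12, scenario$n_focal * row_w / sum(row_w))
    if (any(n_m_foc > 0 & row_w == 0)) {
      abort("focal records demanded for a month with all-zero occupancy")
    }

    ref_list <- vector("list", 12)
    foc_list <- vector("list", 12)
    for (m in 1:12) {
      n_ref <- n_m_ref[m]
      n_foc <- n_m_foc[m]
      if (n_ref + n_foc == 0) next
      # Collectors revisit discrete localities: both datasets draw records
      # from a shared per-month site pool, which yields the locality
      # multiplicity museum data show and keeps the focal and other rows
      # exchangeable under a null scenario.
      n_sites <- max(200L, ceiling(0.25 * (n_ref + n_foc)))
      sites <- sample_effort_locations(n_sites, scenario$effort_hotspots,
                                       boundary)
      site_evi <- NULL
      if (scenario$evi_preference_beta != 0 || scenario$reference_evi_beta != 0) {
        site_evi <- evi_at(rasters[[m]], sites$lat, sites$lon)
        site_evi[is.na(site_evi)] <- stats::median(site_evi, na.rm = TRUE)
      }
      tilt <- function(beta) {
        if (beta == 0) rep(1, n_sites) else exp(beta * (site_evi - max(site_evi)))
      }

      if (n_ref > 0) {
        locs <- sites[sample.int(n_sites, n_ref, replace = TRUE,
                                 prob = tilt(scenario$reference_evi_beta)), ]
        pool <- reference_taxon_pool()
        sp <- pool[sample.int(nrow(pool), n_ref, replace = TRUE,
                              prob = pool$abundance), ]
        ref_list[[m]] <- tibble(
          record_id = NA_character_,
          scientific_name = sp$scientific_name,
          order_name = sp$order_name,
          family_name = sp$family_name,
          latitude = locs$lat, longitude = locs$lon,
          year = sample(1950:2010, n_ref, replace = TRUE),
          month = rep(m, n_ref),
          day = sample(1:28, n_ref, replace = TRUE),
          elevation_m = draw_elevations(n_ref, scenario$lowland_reference,
                                        part$elevation_split_m)
        )
      }

      if (n_foc > 0) {
        w <- scenario$occupancy[m, assign_region(sites$lat, sites$lon, part)] *
          tilt(scenario$evi_preference_beta)
        if (sum(w) == 0) {
          abort(sprintf("month %d: occupancy is zero everywhere effort reaches", m))
        }
        locs <- sites[sample.int(n_sites, n_foc, replace = TRUE, prob = w), ]
        foc_list[[m]] <- tibble(
          record_id = NA_character_,
          scientific_name = focal_name,
          order_name = "Passeriformes",
          family_name = "Cardinalidae",
          latitude = locs$lat, longitude = locs$lon,
          year = sample(1950:2010, n_foc, replace = TRUE),
          month = rep(m, n_foc),
          day = sample(1:28, n_foc, replace = TRUE),
          elevation_m = draw_elevations(n_foc, scenario$lowland_focal,
                                        part$elevation_split_m)
        )
      }
    }
    ref <- bind_rows(ref_list)
    ref$record_id <- sprintf("ref-%06d", seq_len(nrow(ref)))
    foc <- bind_rows(foc_list)
    foc$record_id <- sprintf("foc-%06d", seq_len(nrow(foc)))

    foc <- corrupt_records(foc, scenario$corruption_fraction)
    ref <- corrupt_records(ref, scenario$corruption_fraction)
    combined <- bind_rows(ref, foc)
    attr(combined, "corrupted_rows") <- c(
      attr(ref, "corrupted_rows"),
      nrow(ref) + attr(foc, "corrupted_rows")
    )
    list(focal = foc, reference = combined)
  })
}
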