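# Management-area assignment and per-whale residency summaries.

#' Load management areas from GeoJSON
#'
#' Reads polygon features with `name` and `category` properties. The
#' packaged default is a simplified box representation of the relevant
#' CCAMLR Statistical Areas, IWC Management Areas and the proposed Drygalski
#' MPA; the true boundaries are external shapefiles, so these are documented
#' approximations, swappable for any GeoJSON with the same properties.
#'
#' @param file Path to a GeoJSON file; default: the packaged area file.
#' @return A list of class `management_areas`; each element has `name`,
#'   `category` (one of `CCAMLR`, `IWC`, `MPA`) and `polygon` (a closed
#'   two-column lon/lat matrix).
#' @export
management_areas <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "management_areas.geojson",
                        package = "argosmove")
  if (!nzchar(file) || !file.exists(file))
    stop("management area file not found: ", file, call. = FALSE)
  gj <- jsonlite::read_json(file)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  areas <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p)
      c(wrap_lon(p[[1]]), p[[2]])))
    .validate_polygon(poly, f$properties$name)
    list(name = f$properties$name, category = f$properties$category,
         polygon = poly)
  })
  structure(areas, class = "management_areas")
}

.validate_polygon <- function(poly, name = "polygon") {
  if (nrow(poly) < 4 || any(poly[1, ] != poly[nrow(poly), ]))
    stop(name, ": polygon ring must be closed", call. = FALSE)
  if (any(!is.finite(poly)))
    stop(name, ": non-finite polygon coordinates", call. = FALSE)
  # reject self-intersection (O(n^2) segment test; polygons here are small)
  n <- nrow(poly) - 1
  seg <- function(i) rbind(poly[i, ], poly[i + 1, ])
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # first and last share the closing vertex
      if (.segments_cross(seg(i), seg(j)))
        stop(name, ": self-intersecting polygon", call. = FALSE)
    }
  }
  invisible(poly)
}

.segments_cross <- function(a, b) {
  d <- function(p, q, r)
    (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(a[1, ], a[2, ], b[1, ]); d2 <- d(a[1, ], a[2, ], b[2, ])
  d3 <- d(b[1, ], b[2, ], a[1, ]); d4 <- d(b[1, ], b[2, ], a[2, ])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Point-in-polygon test with half-open boundary convention
#'
#' Even-odd ray casting with a horizontal ray to the east. For axis-aligned
#' boxes this yields the documented convention exactly: south and west edges
#' inclusive, north and east edges exclusive, so abutting areas partition
#' the plane with no double counting.
#'
#' @param lon,lat Point coordinates (vectors), decimal degrees.
#' @param polygon Closed two-column lon/lat matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  n <- nrow(polygon) - 1
  inside <- rep(FALSE, length(lon))
  for (i in seq_len(n)) {
    x1 <- polygon[i, 1]; y1 <- polygon[i, 2]
    x2 <- polygon[i + 1, 1]; y2 <- polygon[i + 1, 2]
    crosses <- (y1 > lat) != (y2 > lat)
    if (any(crosses)) {
      xint <- x1 + (lat - y1) * (x2 - x1) / (y2 - y1)
      flip <- crosses & (lon < xint)
      inside <- xor(inside, flip)
    }
  }
  inside
}

#' Assign locations to management areas
#'
#' Labels each location with the containing area of the requested category;
#' locations in no CCAMLR area are labelled `"Northern"`. Within a category
#' areas must not overlap (the MPA layer may overlap CCAMLR areas and is
#' queried separately).
#'
#' @param lon,lat Location coordinates, decimal degrees.
#' @param areas A [management_areas()] object.
#' @param category Area category to query (default `"CCAMLR"`).
#' @param outside_label Label for unmatched locations (default `"Northern"`
#'   for CCAMLR, `NA` otherwise).
#' @return Character vector of area names.
#' @export
assign_area <- function(lon, lat, areas, category = "CCAMLR",
                        outside_label = if (category == "CCAMLR")
                          "Northern" else NA_character_) {
  stopifnot(inherits(areas, "management_areas"))
  lon <- wrap_lon(lon)
  sel <- Filter(function(a) a$category == category, areas)
  if (length(sel) == 0) stop("no areas of category ", category, call. = FALSE)
  lab <- rep(outside_label, length(lon))
  hit <- rep(FALSE, length(lon))
  for (a in sel) {
    inside <- point_in_polygon(lon, lat, a$polygon)
    if (any(inside & hit))
      stop("overlapping areas within category ", category, call. = FALSE)
    lab[inside] <- a$name
    hit <- hit | inside
  }
  lab
}

#' Per-whale spatial usage summary
#'
#' The Table-1-style row for one track: maximum displacement from the
#' deployment location, total along-track distance (plus any declared net
#' displacement across non-reporting gaps), location count, percent of
#' locations decoded as resident (suppressed where the count is below
#' `min_locations`), and the same count/percentage per management area.
#'
#' @param track Regularized track data frame (single id, realization 0)
#'   with columns `id`, `date`, `lon`, `lat` and optionally `segment`.
#' @param states Character vector of decoded states, one per location (the
#'   state of the step starting at the location; the final location of each
#'   segment inherits the last step's state). `NA` allowed.
#' @param deploy_location `c(lon, lat)` of tag deployment.
#' @param areas A [management_areas()] object (CCAMLR layer + optional MPA).
#' @param sex Sex label for the row.
#' @param min_locations Residency percentages are reported only where the
#'   location count is at least this (default 10).
#' @param gap_displacement_km Net displacement (km) accrued during declared
#'   non-reporting gaps, added to the total distance.
#' @return A list of class `track_summary_row`: scalars `id`, `sex`,
#'   `max_displacement_km`, `total_distance_km`, `n_locations`,
#'   `pct_resident`, and data frame `per_area`.
#' @export
track_summary <- function(track, states, deploy_location, areas,
                          sex = "unknown", min_locations = 10,
                          gap_displacement_km = 0) {
  if (nrow(track) == 0) stop("empty track", call. = FALSE)
  if (length(states) != nrow(track))
    stop("states must align one-to-one with locations", call. = FALSE)
  track <- track[order(track$date), , drop = FALSE]
  if (is.null(track$segment)) track$segment <- 1L

  disp <- great_circle_km(deploy_location[1], deploy_location[2],
                          track$lon, track$lat)
  dist <- gap_displacement_km
  for (s in unique(track$segment)) {
    g <- track[track$segment == s, , drop = FALSE]
    n <- nrow(g)
    if (n > 1)
      dist <- dist + sum(great_circle_km(g$lon[-n], g$lat[-n],
                                         g$lon[-1], g$lat[-1]))
  }

  pct <- function(st, n) {
    if (n < min_locations) return(NA_real_)
    100 * mean(st == "resident", na.rm = TRUE)
  }
  n_loc <- nrow(track)
  lab <- assign_area(track$lon, track$lat, areas, "CCAMLR")
  area_names <- c(vapply(Filter(function(a) a$category == "CCAMLR", areas),
                         `[[`, character(1), "name"), "Northern")
  per_area <- do.call(rbind, lapply(area_names, function(a) {
    i <- lab == a
    data.frame(area = a, category = "CCAMLR", n_locations = sum(i),
               pct_resident = pct(states[i], sum(i)),
               stringsAsFactors = FALSE)
  }))
  mpa <- Filter(function(a) a$category == "MPA", areas)
  for (a in mpa) {
    i <- point_in_polygon(wrap_lon(track$lon), track$lat, a$polygon)
    per_area <- rbind(per_area, data.frame(
      area = a$name, category = "MPA", n_locations = sum(i),
      pct_resident = pct(states[i], sum(i)), stringsAsFactors = FALSE))
  }

  structure(list(
    id = track$id[1], sex = sex,
    max_displacement_km = max(disp),
    total_distance_km = dist,
    n_locations = n_loc,
    pct_resident = pct(states, n_loc),
    per_area = per_area
  ), class = "track_summary_row")
}

#' @export
print.track_summary_row <- function(x, ...) {
  cat(sprintf("%s (%s): max displacement %.0f km, distance %.0f km, %d locations (%s%% resident)\n",
              x$id, x$sex, x$max_displacement_km, x$total_distance_km,
              x$n_locations,
              if (is.na(x$pct_resident)) "-" else sprintf("%.0f", x$pct_resident)))
  print(x$per_area, row.names = FALSE)
  invisible(x)
}

#' Overall summary across whales
#'
#' Arithmetic mean and sample SD (n-1 denominator) of the displacement and
#' distance columns, the grand location total, and the location-weighted
#' overall resident percentage.
#'
#' @param rows Data frame with columns `max_displacement_km`,
#'   `total_distance_km`, `n_locations` and optionally `pct_resident` (one
#'   row per whale), e.g. [reported_track_summaries()] or rows built from
#'   [track_summary()].
#' @return A list with `mean_displacement_km`, `sd_displacement_km`,
#'   `mean_distance_km`, `sd_distance_km`, `total_locations`,
#'   `pct_resident`.
#' @export
overall_summary <- function(rows) {
  if (nrow(rows) < 2) stop("need at least 2 rows", call. = FALSE)
  pr <- NA_real_
  if (!is.null(rows$pct_resident)) {
    ok <- !is.na(rows$pct_resident)
    pr <- sum(rows$pct_resident[ok] * rows$n_locations[ok]) /
      sum(rows$n_locations[ok])
  }
  list(mean_displacement_km = mean(rows$max_displacement_km),
       sd_displacement_km = sd(rows$max_displacement_km),
       mean_distance_km = mean(rows$total_distance_km),
       sd_distance_km = sd(rows$total_distance_km),
       total_locations = sum(rows$n_locations),
       pct_resident = pr)
}

#' Published per-whale summary table
#'
#' The packaged per-whale summary statistics (12 Southern Ocean humpback
#' tracks): maximum displacement and total distance from the tagging
#' location, filtered 6-h location counts and overall resident percentages.
#' Rows whose total distance includes a net displacement across a
#' non-reporting period are flagged.
#'
#' @return Data frame with columns `id`, `sex`, `max_displacement_km`,
#'   `total_distance_km`, `n_locations`, `pct_resident`, `gap_in_distance`.
#' @export
reported_track_summaries <- function() {
  f <- system.file("extdata", "table1_summary.csv", package = "argosmove")
  read.csv(f, colClasses = c(id = "character"))
}

#' Published pooled HMM estimates
#'
#' The packaged pooled parameter estimates (and 95% CIs) for the
#' best-supported movement HMM: per-sex transit and resident step-speed
#' means, per-sex transit turn concentrations, the two state transition
#' probabilities, and the overall resident-time percentage.
#'
#' @return Data frame with columns `parameter`, `state`, `sex`, `estimate`,
#'   `lo95`, `hi95`.
#' @export
reported_hmm_estimates <- function() {
  f <- system.file("extdata", "reported_hmm_estimates.csv",
                   package = "argosmove")
  read.csv(f)
}

#' Arrival time into a region
#'
#' Fractional days from a reference (departure) event to the first location
#' inside the region; `NA` if the track never enters. The default reference
#' operationalizes "leaving coastal waters" as the last location north of
#' `departure_lat` before the first crossing south of it; an explicit
#' POSIXct reference overrides this.
#'
#' @param track Track data frame with `date`, `lon`, `lat`.
#' @param region A single area (element of [management_areas()]) or a list
#'   with a `polygon` matrix.
#' @param reference Optional POSIXct departure event.
#' @param departure_lat Latitude defining the default departure event
#'   (default -36).
#' @return Days (numeric scalar) or `NA` if the region is never entered.
#' @export
arrival_time <- function(track, region, reference = NULL,
                         departure_lat = -36) {
  track <- track[order(track$date), , drop = FALSE]
  if (is.null(reference)) {
    south <- which(track$lat < departure_lat)
    if (length(south) == 0) return(NA_real_)
    first_south <- south[1]
    reference <- if (first_south == 1) track$date[1] else
      track$date[first_south - 1]
  }
  inside <- point_in_polygon(wrap_lon(track$lon), track$lat, region$polygon)
  if (!any(inside)) return(NA_real_)
  as.numeric(difftime(track$date[which(inside)[1]], reference,
                      units = "days"))
}
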