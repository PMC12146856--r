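#' Albers equal-area conic projection (spherical)
#'
#' Projects WGS84 longitude/latitude to planar km. Area-true, which the
#' buffer-fraction and density statistics require. Defaults match the
#' standard parallels conventionally used for maps of China.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lon0 Central meridian (degrees).
#' @param lat0 Latitude of origin (degrees).
#' @param lat1,lat2 Standard parallels (degrees).
#' @return A tibble with columns `x`, `y` in km.
#' @export
project_albers <- function(lon, lat, lon0 = 105, lat0 = 0,
                           lat1 = 25, lat2 = 47) {
  R <- 6371.0088
  rad <- pi / 180
  n <- (sin(lat1 * rad) + sin(lat2 * rad)) / 2
  C <- cos(lat1 * rad)^2 + 2 * n * sin(lat1 * rad)
  rho <- R / n * sqrt(C - 2 * n * sin(lat * rad))
  rho0 <- R / n * sqrt(C - 2 * n * sin(lat0 * rad))
  theta <- n * (lon - lon0) * rad
  tibble::tibble(x = rho * sin(theta), y = rho0 - rho * cos(theta))
}

#' Read an occurrence-record table
#'
#' Expects columns `record_id`, `species`, `lon`, `lat`, `year` (WGS84
#' degrees); extra columns pass through untouched. Coordinates are
#' reprojected to Albers km once, at load. Unparsable rows are counted in
#' the attached `parse_failures` attribute, never silently skipped.
#'
#' @param path CSV file path.
#' @param project Reproject lon/lat to Albers km (adds `x`, `y`)?
#' @param ... Passed to [project_albers()].
#' @return A tibble of records.
#' @export
read_occurrences <- function(path, project = TRUE, ...) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  tb <- readr::read_csv(path, show_col_types = FALSE)
  fails <- nrow(readr::problems(tb))
  if (project && all(c("lon", "lat") %in% names(tb))) {
    xy <- project_albers(tb$lon, tb$lat, ...)
    tb$x <- xy$x
    tb$y <- xy$y
  }
  attr(tb, "parse_failures") <- fails
  tb
}

#' Quality control of raw occurrence records
#'
#' Applies the standard record filters: duplicate `record_id`s are collapsed
#' to their first occurrence, rows missing coordinates or collection year
#' are dropped, and records flagged imprecise (optional logical `precise`
#' column, honoured when present) are removed. Idempotent. Counts per rule
#' are reported, never silently discarded.
#'
#' @param records Data frame with at least `record_id`, coordinate columns
#'   (`x`/`y` or `lon`/`lat`) and `year`.
#' @return A list with `records` (clean tibble) and `report`
#'   (tibble of `rule`, `n`).
#' @export
qc_filter <- function(records) {
  tb <- tibble::as_tibble(records)
  report <- list()
  if (nrow(tb) == 0) {
    return(list(records = tb,
                report = tibble::tibble(rule = character(), n = integer())))
  }
  dup <- duplicated(tb$record_id)
  report$duplicate <- sum(dup)
  tb <- tb[!dup, ]
  cx <- if ("x" %in% names(tb)) tb$x else tb$lon
  cy <- if ("y" %in% names(tb)) tb$y else tb$lat
  bad_coord <- is.na(cx) | is.na(cy) | !is.finite(cx) | !is.finite(cy)
  report$missing_coordinates <- sum(bad_coord)
  tb <- tb[!bad_coord, ]
  bad_year <- is.na(tb$year)
  report$missing_year <- sum(bad_year)
  tb <- tb[!bad_year, ]
  if ("precise" %in% names(tb)) {
    imprecise <- !tb$precise | is.na(tb$precise)
    report$imprecise <- sum(imprecise)
    tb <- tb[!imprecise, ]
  }
  list(
    records = tb,
    report = tibble::tibble(rule = names(report),
                            n = as.integer(unlist(report)))
  )
}

#' Default decade-to-road-map lookup
#'
#' Six decades, each associated with the road map of its period; the last
#' decade spans eleven years (2010--2020).
#'
#' @return A tibble: `period`, `map_year`, `start`, `end`.
#' @export
default_period_map <- function() {
  tibble::tibble(
    period = c("1960s", "1970s", "1980s", "1990s", "2000s", "2010s"),
    map_year = c(1962L, 1974L, 1986L, 1995L, 2000L, 2012L),
    start = c(1960L, 1970L, 1980L, 1990L, 2000L, 2010L),
    end = c(1969L, 1979L, 1989L, 1999L, 2009L, 2020L)
  )
}

#' Assign each collection year to its decade (road-map period)
#'
#' Years outside the covered range map to `NA` (such records are excluded
#' from period analyses, mirroring the exclusion of records predating the
#' earliest road map).
#'
#' @param year Integer vector of collection years.
#' @param map A period map, see [default_period_map()].
#' @return Character vector of period labels (`NA` = out of range).
#' @examples
#' assign_period(c(1984, 2020, 1959))
#' @export
assign_period <- function(year, map = default_period_map()) {
  idx <- purrr::map_int(as.integer(year), function(y) {
    if (is.na(y)) return(NA_integer_)
    i <- which(map$start <= y & y <= map$end)
    if (length(i) == 1) i else NA_integer_
  })
  map$period[idx]
}

#' Split records into period buckets
#'
#' @param records Data frame with a `year` column.
#' @param map A period map, see [default_period_map()].
#' @return A list: `records` (with `period` column, out-of-range rows
#'   dropped) and `rejected` (tibble of dropped rows with `reason`).
#' @export
split_by_period <- function(records, map = default_period_map()) {
  tb <- tibble::as_tibble(records)
  tb$period <- assign_period(tb$year, map)
  rejected <- tb[is.na(tb$period), ]
  if (nrow(rejected) > 0) rejected$reason <- "year outside period range"
  list(records = tb[!is.na(tb$period), ], rejected = rejected)
}

# ---- GeoJSON ---------------------------------------------------------------

close_ring <- function(x, y) {
  list(c(x, x[1]), c(y, y[1]))
}

ring_coords <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  tibble::tibble(x = m[, 1], y = m[, 2])
}

#' Write a road network to GeoJSON
#'
#' Each segment becomes a two-point LineString feature; period label and map
#' year are stored as feature properties, and a top-level `crs_units` field
#' records that coordinates are projected km.
#'
#' @param roads A [road_network()].
#' @param path Output file.
#' @export
write_roads_geojson <- function(roads, path) {
  s <- roads$segments
  feats <- purrr::pmap(s, function(x0, y0, x1, y1) {
    list(
      type = "Feature",
      properties = list(period_label = roads$period_label,
                        map_year = roads$map_year),
      geometry = list(type = "LineString",
                      coordinates = list(c(x0, y0), c(x1, y1)))
    )
  })
  obj <- list(type = "FeatureCollection", crs_units = "km", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from GeoJSON
#'
#' Accepts LineString and MultiLineString features; polylines are split into
#' their constituent segments. Coordinates in lon/lat (no `crs_units: km`
#' marker) are reprojected to Albers km.
#'
#' @param path GeoJSON file.
#' @param ... Albers parameters passed to [project_albers()] when
#'   reprojection applies.
#' @return A [road_network()].
#' @export
read_roads_geojson <- function(path, ...) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  in_km <- identical(obj$crs_units, "km")
  period <- "all"; map_year <- NA_integer_
  segs <- list()
  line_to_segs <- function(coords) {
    pts <- ring_coords(coords)
    if (!in_km) pts <- project_albers(pts$x, pts$y, ...)
    if (nrow(pts) < 2) return(NULL)
    tibble::tibble(x0 = pts$x[-nrow(pts)], y0 = pts$y[-nrow(pts)],
                   x1 = pts$x[-1], y1 = pts$y[-1])
  }
  for (f in obj$features) {
    g <- f$geometry
    if (!is.null(f$properties$period_label)) period <- f$properties$period_label
    if (!is.null(f$properties$map_year)) map_year <- f$properties$map_year
    if (g$type == "LineString") {
      segs <- c(segs, list(line_to_segs(g$coordinates)))
    } else if (g$type == "MultiLineString") {
      segs <- c(segs, purrr::map(g$coordinates, line_to_segs))
    }
  }
  road_network(purrr::list_rbind(purrr::compact(segs)), period, map_year)
}

# reopen a closed GeoJSON ring as an unclosed coordinate tibble, projecting
# if the file is in lon/lat
read_poly_ring <- function(geom, in_km, ...) {
  ring <- ring_coords(geom$coordinates[[1]])
  if (!in_km) ring <- project_albers(ring$x, ring$y, ...)
  ring
}

#' Write a region (boundary + counties) to GeoJSON
#'
#' @param region A [region()].
#' @param path Output file.
#' @export
write_region_geojson <- function(region, path) {
  poly_feature <- function(ring, props) {
    cl <- close_ring(ring$x, ring$y)
    list(
      type = "Feature", properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(purrr::map(seq_along(cl[[1]]),
                                      function(i) c(cl[[1]][i], cl[[2]][i])))
      )
    )
  }
  feats <- list(poly_feature(region$boundary, list(role = "boundary")))
  if (!is.null(region$counties)) {
    for (lab in unique(region$counties$county)) {
      feats <- c(feats, list(poly_feature(county_ring(region, lab),
                                          list(county = lab))))
    }
  }
  obj <- list(type = "FeatureCollection", crs_units = "km", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region from GeoJSON
#'
#' The feature with property `role: boundary` (or the first Polygon) is the
#' region boundary; features carrying a `county` property become the county
#' partition.
#'
#' @param path GeoJSON file.
#' @param ... Albers parameters for lon/lat inputs.
#' @return A [region()].
#' @export
read_region_geojson <- function(path, ...) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path)
  in_km <- identical(obj$crs_units, "km")
  boundary <- NULL
  counties <- list()
  for (f in obj$features) {
    if (f$geometry$type != "Polygon") next
    ring <- read_poly_ring(f$geometry, in_km, ...)
    if (!is.null(f$properties$county)) {
      counties <- c(counties, list(dplyr::mutate(ring,
                                                 county = f$properties$county,
                                                 .before = 1)))
    } else if (is.null(boundary)) {
      boundary <- ring
    }
  }
  if (is.null(boundary)) stop("no boundary polygon found in ", path)
  region(boundary,
         if (length(counties) > 0) purrr::list_rbind(counties) else NULL)
}
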