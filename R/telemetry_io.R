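# Reading, validating and writing the three input tables and the land mask.
# Detections, tag deployments and station deployments arrive as delimited
# text (ETN-style exports differ in column naming, so every reader takes a
# schema map from canonical names to file column names). Coordinates must
# already be projected planar metres; timestamps are ISO-8601 and fixed to
# UTC on ingest.

detection_cols <- c("tag_id", "station_id", "timestamp")

deployment_cols <- c(
  "fish_id", "tag_id", "species", "release_time", "release_x_m",
  "release_y_m", "min_delay_s", "max_delay_s", "length_cm"
)

station_cols <- c(
  "station_id", "array_name", "region", "x_m", "y_m",
  "active_start", "active_end", "damaged"
)

#' Default column-name mappings for the three input tables
#'
#' A schema map is a named character vector `c(canonical = "file_column")`.
#' Pass a modified copy to the readers when a file uses different headers.
#'
#' @param table One of `"detections"`, `"deployments"`, `"stations"`.
#' @return Named character vector mapping canonical to file column names.
#' @export
default_schema <- function(table = c("detections", "deployments", "stations")) {
  table <- match.arg(table)
  cols <- switch(table,
    detections = detection_cols,
    deployments = deployment_cols,
    stations = station_cols
  )
  stats::setNames(cols, cols)
}

read_table_raw <- function(path, delim = ",") {
  if (!file.exists(path)) stop_mt("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, quote = "\"")
}

map_columns <- function(raw, schema_map, required, what) {
  missing_map <- setdiff(required, names(schema_map))
  if (length(missing_map) > 0)
    stop_mt("schema map for ", what, " lacks entries for: ",
            paste(missing_map, collapse = ", "))
  missing_col <- setdiff(unname(schema_map[required]), names(raw))
  if (length(missing_col) > 0)
    stop_mt("missing column(s) in ", what, " file: ",
            paste(missing_col, collapse = ", "))
  out <- raw[, unname(schema_map[required]), drop = FALSE]
  names(out) <- required
  tibble::as_tibble(out)
}

#' Read acoustic detection records
#'
#' Parses a delimited file of transmitter detections into the canonical
#' detection table: `tag_id`, `station_id`, `timestamp` (POSIXct, UTC).
#' Rows whose timestamp cannot be parsed are rejected and reported; the read
#' aborts when the rejected fraction exceeds `max_bad_fraction`.
#'
#' @param path Path to a delimited text file.
#' @param schema_map Named character vector mapping canonical column names
#'   (`tag_id`, `station_id`, `timestamp`) to the file's column names.
#' @param delim Field delimiter (default comma).
#' @param max_bad_fraction Abort when more than this fraction of rows has an
#'   unparseable timestamp (default 0.01).
#' @return A tibble sorted by (`tag_id`, `timestamp`, `station_id`) with
#'   attribute `parse_report`: a list with `parsed`, `rejected` and the
#'   offending row numbers.
#' @export
read_detections <- function(path, schema_map = default_schema("detections"),
                            delim = ",", max_bad_fraction = 0.01) {
  raw <- read_table_raw(path, delim)
  det <- map_columns(raw, schema_map, detection_cols, "detections")
  ts <- parse_timestamp(det$timestamp)
  bad <- which(is.na(ts))
  if (length(bad) > nrow(det) * max_bad_fraction)
    stop_mt(length(bad), " of ", nrow(det),
            " rows have unparseable timestamps (limit ",
            max_bad_fraction * 100, "%)")
  det$timestamp <- ts
  if (length(bad) > 0) det <- det[-bad, ]
  det <- det[order(det$tag_id, det$timestamp, det$station_id), ]
  rownames(det) <- NULL
  attr(det, "parse_report") <- list(
    parsed = nrow(det), rejected = length(bad), rejected_rows = bad
  )
  det
}

#' Read tag-deployment metadata
#'
#' One row per tagged fish: identifiers, species, release time and position
#' (projected metres), the transmitter's minimum and maximum transmission
#' delay in seconds, and total length. The minimum transmission delay anchors
#' the min-delay false-detection filter, so `min_delay_s <= max_delay_s` and
#' a unique active `tag_id` are enforced here.
#'
#' @inheritParams read_detections
#' @param length_band Plausibility band for total length in cm
#'   (default 10–100); rows outside it are an error.
#' @return A tibble of tag deployments.
#' @export
read_deployments <- function(path, schema_map = default_schema("deployments"),
                             delim = ",", length_band = c(10, 100)) {
  raw <- read_table_raw(path, delim)
  dep <- map_columns(raw, schema_map, deployment_cols, "deployments")
  dep$release_time <- parse_timestamp(dep$release_time)
  for (col in c("release_x_m", "release_y_m", "min_delay_s", "max_delay_s",
                "length_cm")) {
    dep[[col]] <- as.numeric(dep[[col]])
  }
  validate_deployments(dep, length_band)
}

validate_deployments <- function(dep, length_band = c(10, 100)) {
  if (anyNA(dep$release_time)) stop_mt("unparseable release_time in deployments")
  dup <- unique(dep$tag_id[duplicated(dep$tag_id)])
  if (length(dup) > 0)
    stop_mt("duplicate active tag_id in deployments: ",
            paste(dup, collapse = ", "))
  bad_delay <- dep$min_delay_s <= 0 | dep$min_delay_s > dep$max_delay_s
  if (any(bad_delay))
    stop_mt("invalid transmission delays (need 0 < min_delay_s <= max_delay_s) for tag(s): ",
            paste(dep$tag_id[bad_delay], collapse = ", "))
  bad_len <- dep$length_cm < length_band[1] | dep$length_cm > length_band[2]
  if (any(bad_len))
    stop_mt("length_cm outside plausibility band [", length_band[1], ", ",
            length_band[2], "] for fish: ",
            paste(dep$fish_id[bad_len], collapse = ", "))
  bad_sp <- !dep$species %in% c("thicklip", "thinlip", "other")
  if (any(bad_sp))
    stop_mt("unknown species label(s): ",
            paste(unique(dep$species[bad_sp]), collapse = ", "))
  dep
}

#' Read receiver-station deployment metadata
#'
#' One row per station deployment interval: a station redeployed after
#' maintenance appears as several rows with disjoint active windows, all
#' kept. Regions are restricted to the closed three-region set of
#' [regions()]; an unknown label is an error naming the offending row.
#'
#' @inheritParams read_detections
#' @return A tibble of station deployments with attribute `array_counts`
#'   (stations per array).
#' @export
read_stations <- function(path, schema_map = default_schema("stations"),
                          delim = ",") {
  raw <- read_table_raw(path, delim)
  st <- map_columns(raw, schema_map, station_cols, "stations")
  st$x_m <- as.numeric(st$x_m)
  st$y_m <- as.numeric(st$y_m)
  st$active_start <- parse_timestamp(st$active_start)
  st$active_end <- parse_timestamp(st$active_end)
  st$damaged <- tolower(st$damaged) %in% c("true", "t", "1", "yes")
  validate_stations(st)
}

validate_stations <- function(st) {
  bad_region <- which(!st$region %in% regions())
  if (length(bad_region) > 0)
    stop_mt("unknown region label '", st$region[bad_region[1]],
            "' in stations row ", bad_region[1],
            " (station ", st$station_id[bad_region[1]], "); must be one of: ",
            paste(regions(), collapse = ", "))
  if (any(!is.finite(st$x_m)) || any(!is.finite(st$y_m)))
    stop_mt("non-finite station coordinates")
  bad_win <- !(st$active_start < st$active_end)
  if (any(bad_win))
    stop_mt("active_start must precede active_end for station(s): ",
            paste(st$station_id[bad_win], collapse = ", "))
  # one station id must map to one region across deployment intervals
  reg <- unique(st[, c("station_id", "region")])
  conflicted <- reg$station_id[duplicated(reg$station_id)]
  if (length(conflicted) > 0)
    stop_mt("station(s) assigned to more than one region: ",
            paste(unique(conflicted), collapse = ", "))
  attr(st, "array_counts") <-
    table(unique(st[, c("station_id", "array_name")])$array_name)
  st
}

#' Write a canonical table back to delimited text
#'
#' Deterministic column order and formatting (ISO-8601 UTC timestamps,
#' unquoted fields) so that diffs between runs are stable and a written
#' dataset re-reads identically.
#'
#' @param records A detections, deployments or stations tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(records, path) {
  canonical <- list(detection_cols, deployment_cols, station_cols)
  for (cols in canonical) {
    if (setequal(names(records), cols)) {
      records <- records[, cols, drop = FALSE]
      break
    }
  }
  write_csv_strict(as.data.frame(records), path)
}

# ---- land mask -------------------------------------------------------------

#' Construct a land mask from polygon vertex lists
#'
#' @param polygons A list of two-column matrices (x, y in metres), one per
#'   simple polygon (exterior rings only, no holes). Polygons are assumed
#'   pairwise disjoint, as is standard for land masks; self-intersecting
#'   polygons are rejected.
#' @return An object of class `landmask`.
#' @export
landmask <- function(polygons) {
  if (!is.list(polygons)) polygons <- list(polygons)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) stop_mt("each polygon needs >= 3 (x, y) vertices")
    storage.mode(p) <- "double"
    if (!all(is.finite(p))) stop_mt("non-finite land-mask vertex")
    # drop an explicitly closed last vertex
    if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (!is_simple_polygon(p)) stop_mt("self-intersecting land-mask polygon")
    p
  })
  structure(list(polygons = polygons), class = "landmask")
}

#' Read a land mask from a well-known-text file
#'
#' Supports `POLYGON` and `MULTIPOLYGON` geometries (exterior rings only),
#' one or more per file, in projected planar metres.
#'
#' @param path Path to a WKT text file.
#' @return A [landmask()] object.
#' @export
read_landmask <- function(path) {
  if (!file.exists(path)) stop_mt("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  rings <- character(0)
  # pull every innermost "(x y, x y, ...)" ring group
  for (geom in regmatches(txt, gregexpr("(POLYGON|MULTIPOLYGON)\\s*\\(.*?\\)\\)+", txt, ignore.case = TRUE))[[1]]) {
    inner <- regmatches(geom, gregexpr("\\(([^()]+)\\)", geom))[[1]]
    rings <- c(rings, inner)
  }
  if (length(rings) == 0) stop_mt("no POLYGON geometry found in ", path)
  polys <- lapply(rings, function(r) {
    r <- gsub("[()]", "", r)
    parts <- strsplit(trimws(strsplit(r, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
    if (anyNA(m)) stop_mt("unparseable WKT coordinates in ", path)
    m
  })
  landmask(polys)
}

#' Write a land mask as well-known text
#'
#' @param mask A [landmask()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_landmask <- function(mask, path) {
  stopifnot(inherits(mask, "landmask"))
  wkt <- vapply(mask$polygons, function(p) {
    p <- rbind(p, p[1, ])
    coords <- paste(apply(p, 1, function(v) paste(v, collapse = " ")),
                    collapse = ", ")
    paste0("POLYGON ((", coords, "))")
  }, character(1))
  writeLines(wkt, path)
  invisible(path)
}
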