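# Minimum convex polygon space use, land-clipped areas, and the planar
# geometry primitives they need. The environment supplies no simple-features
# stack, so the hull (via grDevices::chull), shoelace area, polygon
# simplicity check and Sutherland-Hodgman clipping are implemented here.
# All coordinates are projected planar metres; areas are reported in km^2.

# signed shoelace area (positive for counter-clockwise vertex order), m^2
poly_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(p) abs(poly_signed_area(p))

ensure_ccw <- function(p) if (poly_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p

# proper / improper intersection test for segments p1-p2 and p3-p4
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# a polygon is simple when no two non-adjacent edges intersect
is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (shared vertex), including the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(p[idx[i, 1], ], p[idx[i, 2], ],
                         p[idx[j, 1], ], p[idx[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman: clip an arbitrary simple polygon against a convex
# polygon given in counter-clockwise order; returns the intersection
# polygon (possibly with zero area) as a matrix, or NULL when empty.
clip_polygon_convex <- function(subject, clip_ccw) {
  out <- subject
  nc <- nrow(clip_ccw)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip_ccw[i, ]
    b <- clip_ccw[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >= 0 is inside
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    new_pts <- list()
    for (k in seq_len(n)) {
      p <- out[k, ]; q <- out[nxt[k], ]
      sp <- side[k]; sq <- side[nxt[k]]
      if (sp >= 0) new_pts[[length(new_pts) + 1L]] <- p
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        new_pts[[length(new_pts) + 1L]] <- p + t * (q - p)
      }
    }
    out <- if (length(new_pts) == 0) NULL else do.call(rbind, new_pts)
  }
  if (!is.null(out) && nrow(out) < 3) out <- NULL
  out
}

#' Minimum convex polygon over a point set
#'
#' The 100% MCP: the smallest convex polygon enclosing the supplied points
#' (receiver stations with at least one retained detection, in this
#' workflow). Area is the planar shoelace area converted to km^2. Collinear
#' point sets are legal input but yield a degenerate hull with zero area.
#'
#' @param points Two-column matrix or data frame of projected coordinates in
#'   metres. At least 3 distinct points are required.
#' @return A list with `vertices` (counter-clockwise hull matrix),
#'   `raw_area_km2`, `n_points` (distinct input points) and `degenerate`
#'   (TRUE for zero-area hulls).
#' @export
mcp <- function(points) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  if (!all(is.finite(p))) stop_mt("non-finite coordinates in mcp()")
  p <- unique(p)
  if (nrow(p) < 3) stop_mt("mcp() needs at least 3 distinct points")
  hull <- p[grDevices::chull(p), , drop = FALSE]
  hull <- ensure_ccw(hull)
  area <- poly_area(hull) / 1e6
  list(vertices = hull, raw_area_km2 = area, n_points = nrow(p),
       degenerate = area == 0)
}

#' Clip a convex hull to water using a land mask
#'
#' Subtracts the area of overlap between the hull and each land polygon:
#' `clipped = raw - sum(area(hull intersect land_i))`. Mask polygons are
#' assumed pairwise disjoint (the usual situation for a land mask); the
#' remaining water area may consist of several disjoint pieces, whose total
#' area is what is reported. An empty mask returns the raw area unchanged.
#'
#' @param hull Result of [mcp()] or a convex vertex matrix (metres).
#' @param mask A [landmask()] object, or NULL for no clipping.
#' @return A list with `clipped_area_km2`, `raw_area_km2`, and
#'   `land_pieces` (the intersection polygons that were removed).
#' @export
clip_to_water <- function(hull, mask) {
  verts <- if (is.list(hull) && !is.null(hull$vertices)) hull$vertices else as.matrix(hull)
  verts <- ensure_ccw(verts)
  raw <- poly_area(verts) / 1e6
  if (is.null(mask) || length(mask$polygons) == 0) {
    return(list(clipped_area_km2 = raw, raw_area_km2 = raw, land_pieces = list()))
  }
  stopifnot(inherits(mask, "landmask"))
  pieces <- list()
  removed <- 0
  for (poly in mask$polygons) {
    if (!is_simple_polygon(poly)) stop_mt("self-intersecting land-mask polygon")
    inter <- clip_polygon_convex(poly, verts)
    if (!is.null(inter)) {
      a <- poly_area(inter)
      if (a > 0) {
        pieces[[length(pieces) + 1L]] <- inter
        removed <- removed + a
      }
    }
  }
  list(clipped_area_km2 = max(0, raw - removed / 1e6),
       raw_area_km2 = raw, land_pieces = pieces)
}

#' Fish-years eligible for space-use estimation
#'
#' A fish-year enters the MCP analysis when the fish was resident for more
#' than the minimum duration (default > 5 days) and was detected at no fewer
#' than `min_stations` distinct stations that year.
#'
#' @param residence Output of [residence_records()].
#' @param min_stations Minimum distinct stations (default 3).
#' @return Tibble of `fish_id`, `year` pairs.
#' @export
eligible_fish_years <- function(residence, min_stations = 3) {
  ok <- residence$included & residence$n_stations >= min_stations
  tibble::as_tibble(residence[ok, c("fish_id", "year"), drop = FALSE])
}

#' Per fish-year minimum convex polygon table
#'
#' Computes the MCP over the coordinates of the stations at which each
#' eligible fish was detected in each year, optionally clipped to water.
#'
#' @param detections Filtered detections.
#' @param deployments Tag deployments (maps tags to fish and species).
#' @param stations Station deployments (coordinates and regions).
#' @param residence Output of [residence_records()] for the focal region.
#' @param mask Optional [landmask()].
#' @param min_stations Minimum distinct stations per fish-year (default 3).
#' @param region Region whose stations define the polygon
#'   (default `"wadden_sea"`).
#' @return Tibble: fish_id, species, year, n_stations, raw_area_km2,
#'   clipped_area_km2, degenerate.
#' @export
mcp_table <- function(detections, deployments, stations, residence,
                      mask = NULL, min_stations = 3, region = "wadden_sea") {
  elig <- eligible_fish_years(residence, min_stations)
  if (nrow(elig) == 0) {
    return(tibble::tibble(fish_id = character(), species = character(),
                          year = integer(), n_stations = integer(),
                          raw_area_km2 = numeric(), clipped_area_km2 = numeric(),
                          degenerate = logical()))
  }
  coords <- unique(stations[stations$region == region,
                            c("station_id", "x_m", "y_m")])
  det <- dplyr::inner_join(detections,
                           deployments[, c("tag_id", "fish_id", "species")],
                           by = "tag_id")
  det$year <- utc_year(det$timestamp)
  det <- dplyr::inner_join(det, coords, by = "station_id")
  det <- dplyr::semi_join(det, elig, by = c("fish_id", "year"))
  used <- dplyr::distinct(det, .data$fish_id, .data$species, .data$year,
                          .data$station_id, .data$x_m, .data$y_m)
  grp <- dplyr::group_by(used, .data$fish_id, .data$species, .data$year)
  out <- dplyr::group_modify(grp, function(d, key) {
    h <- mcp(cbind(d$x_m, d$y_m))
    cl <- clip_to_water(h, mask)
    tibble::tibble(n_stations = nrow(d),
                   raw_area_km2 = h$raw_area_km2,
                   clipped_area_km2 = cl$clipped_area_km2,
                   degenerate = h$degenerate)
  })
  dplyr::ungroup(out)
}
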