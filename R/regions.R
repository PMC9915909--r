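#' A set of study regions with optional polygon geometry
#'
#' Geometry is stored in planar coordinates as GeoJSON-style Polygon or
#' MultiPolygon ring lists; it is only ever used for contiguity, centroids
#' and point-in-polygon tests, so no projection handling is attempted.
#'
#' @param ids character vector of unique region ids.
#' @param names display names (defaults to ids).
#' @param geometry list (one element per region) of geometries as returned
#'   by [read_regions_geojson()], or `NULL` entries for regions without
#'   geometry.
#' @return An object of class `region_set`.
#' @export
region_set <- function(ids, names = ids, geometry = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate region id: ", ids[duplicated(ids)][1L])
  if (is.null(geometry)) geometry <- vector("list", length(ids))
  stopifnot(length(names) == length(ids), length(geometry) == length(ids))
  structure(list(ids = ids, names = as.character(names), geometry = geometry),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", length(x$ids), "regions;",
      sum(!vapply(x$geometry, is.null, logical(1))), "with geometry\n")
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$ids)

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
  # drop an explicit closing vertex; rings are treated as implicitly closed
  if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

geom_rings <- function(geometry) {
  if (is.null(geometry)) return(list())
  switch(geometry$type,
         Polygon = geometry$rings,
         MultiPolygon = do.call(c, geometry$rings),
         stop("unsupported geometry type: ", geometry$type))
}

#' Read regions from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon or MultiPolygon and carry an `id` (or,
#' failing that, a `name`) property; feature order is preserved.
#'
#' @param path GeoJSON (RFC 7946) file path.
#' @return A [region_set()].
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  if (length(feats) == 0L) stop("FeatureCollection has no features: ", path)
  ids <- character(length(feats))
  nms <- character(length(feats))
  geo <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    props <- f$properties
    id <- props$id
    if (is.null(id)) id <- props$name
    if (is.null(id))
      stop("feature ", k, " has neither an 'id' nor a 'name' property")
    ids[k] <- as.character(id)
    nms[k] <- as.character(if (!is.null(props$name)) props$name else id)
    g <- f$geometry
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon"))
      stop("feature '", ids[k], "' has non-polygon geometry: ",
           if (is.null(g$type)) "none" else g$type)
    if (g$type == "Polygon") {
      geo[[k]] <- list(type = "Polygon",
                       rings = lapply(g$coordinates, ring_to_matrix))
    } else {
      geo[[k]] <- list(type = "MultiPolygon",
                       rings = lapply(g$coordinates, function(poly)
                         lapply(poly, ring_to_matrix)))
    }
  }
  region_set(ids, nms, geo)
}

#' Write regions to a GeoJSON FeatureCollection
#'
#' @param regions a [region_set()]; every region must have geometry.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  close_ring <- function(m) {
    m <- rbind(m, m[1L, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
  }
  feats <- lapply(seq_along(regions$ids), function(k) {
    g <- regions$geometry[[k]]
    if (is.null(g)) stop("region '", regions$ids[k], "' has no geometry")
    coords <- if (g$type == "Polygon") {
      lapply(g$rings, close_ring)
    } else {
      lapply(g$rings, function(poly) lapply(poly, close_ring))
    }
    list(type = "Feature",
         properties = list(id = regions$ids[k], name = regions$names[k]),
         geometry = list(type = g$type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Signed shoelace area and centroid of one ring (implicitly closed).
ring_area_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps)
    return(list(area = 0, cx = mean(x), cy = mean(y)))
  list(area = a,
       cx = sum((x + xn) * cross) / (6 * a),
       cy = sum((y + yn) * cross) / (6 * a))
}

#' Region centroids
#'
#' Area-weighted centroid over the outer ring(s) of each region's
#' geometry (holes are ignored, which is adequate for contiguity-grade
#' geometry).
#'
#' @param regions a [region_set()] with geometry.
#' @return A two-column matrix of (x, y) centroids, rownames = region ids.
#' @export
region_centroids <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  out <- matrix(NA_real_, length(regions$ids), 2L,
                dimnames = list(regions$ids, c("x", "y")))
  for (k in seq_along(regions$ids)) {
    g <- regions$geometry[[k]]
    if (is.null(g)) stop("region '", regions$ids[k], "' has no geometry")
    outer_rings <- if (g$type == "Polygon") list(g$rings[[1L]]) else
      lapply(g$rings, function(poly) poly[[1L]])
    acc <- vapply(outer_rings, function(r) {
      rc <- ring_area_centroid(r)
      c(abs(rc$area), rc$cx * abs(rc$area), rc$cy * abs(rc$area))
    }, numeric(3))
    A <- sum(acc[1L, ])
    out[k, ] <- if (A > 0) c(sum(acc[2L, ]) / A, sum(acc[3L, ]) / A) else
      colMeans(do.call(rbind, outer_rings))
  }
  out
}

# Even-odd ray-casting test of many points against one ring.
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Point-in-region membership
#'
#' Even-odd rule over all rings, so interior holes are excluded.
#'
#' @param px,py coordinates of the query points.
#' @param geometry one region geometry (Polygon or MultiPolygon entry).
#' @return Logical vector, one entry per point.
#' @export
points_in_geometry <- function(px, py, geometry) {
  inside <- rep(FALSE, length(px))
  for (r in geom_rings(geometry)) inside <- xor(inside, points_in_ring(px, py, r))
  inside
}
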