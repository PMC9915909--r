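#' Spatial weights over a set of regions
#'
#' Sparse adjacency-list weights: `neighbors[[i]]` holds the integer
#' indices of unit i's neighbours and `weights[[i]]` the aligned weights.
#' Self-neighbours are not stored (the Gi* statistic adds self-inclusion
#' internally).
#'
#' @param ids ordered character unit ids.
#' @param neighbors list of integer vectors of neighbour indices.
#' @param weights list of numeric vectors aligned with `neighbors`;
#'   defaults to binary 1s.
#' @param standardized `"binary"` or `"row"`.
#' @return An object of class `spatial_weights`.
#' @export
spatial_weights <- function(ids, neighbors, weights = NULL,
                            standardized = c("binary", "row")) {
  standardized <- match.arg(standardized)
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate unit id")
  if (length(neighbors) != n) stop("neighbors list length != number of ids")
  neighbors <- lapply(neighbors, as.integer)
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb) && (any(nb < 1L | nb > n))) stop("neighbour index out of range")
    if (i %in% nb) stop("self-neighbour at unit ", ids[i])
  }
  if (is.null(weights))
    weights <- lapply(neighbors, function(nb) rep(1, length(nb)))
  for (i in seq_len(n))
    if (length(weights[[i]]) != length(neighbors[[i]]))
      stop("weights/neighbors length mismatch at unit ", ids[i])
  structure(list(ids = ids, neighbors = neighbors, weights = weights,
                 standardized = standardized),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat("spatial_weights:", length(x$ids), "units,", sum(k) / 2,
      "symmetric links (mean degree", round(mean(k), 2), "),",
      x$standardized, "\n")
  if (any(k == 0)) cat("  isolates:", sum(k == 0), "\n")
  invisible(x)
}

#' Dense weight matrix form
#'
#' @param w a [spatial_weights()].
#' @return n x n numeric matrix with zero diagonal.
#' @export
weights_matrix <- function(w) {
  n <- length(w$ids)
  m <- matrix(0, n, n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(n))
    m[i, w$neighbors[[i]]] <- w$weights[[i]]
  m
}

region_vertex_keys <- function(regions, digits = 7) {
  lapply(seq_along(regions$ids), function(k) {
    g <- regions$geometry[[k]]
    if (is.null(g))
      stop("region '", regions$ids[k], "' has no geometry")
    pts <- do.call(rbind, geom_rings(g))
    unique(paste(round(pts[, 1L], digits), round(pts[, 2L], digits)))
  })
}

contiguity_from_shared_vertices <- function(regions, min_shared, digits = 7) {
  keys <- region_vertex_keys(regions, digits)
  n <- length(keys)
  df <- data.frame(key = unlist(keys),
                   region = rep.int(seq_len(n), lengths(keys)))
  counts <- matrix(0L, n, n)
  for (grp in split(df$region, df$key)) {
    if (length(grp) < 2L) next
    for (a in seq_len(length(grp) - 1L)) for (b in (a + 1L):length(grp)) {
      i <- grp[a]; j <- grp[b]
      counts[i, j] <- counts[i, j] + 1L
      counts[j, i] <- counts[j, i] + 1L
    }
  }
  nb <- lapply(seq_len(n), function(i) which(counts[i, ] >= min_shared))
  if (any(lengths(nb) == 0L))
    warning("isolated unit(s): ",
            paste(regions$ids[lengths(nb) == 0L], collapse = ", "))
  spatial_weights(regions$ids, nb)
}

#' Queen contiguity weights from polygons
#'
#' Two regions are neighbours iff their boundaries share at least one
#' vertex (vertices snapped to `digits` decimals).  This matches queen
#' contiguity on topologically clean tilings, where adjacent polygons
#' share their boundary vertices.
#'
#' @param regions a [region_set()] with geometry.
#' @param digits vertex snapping precision (decimal places).
#' @return Binary symmetric [spatial_weights()].
#' @export
queen_contiguity <- function(regions, digits = 7) {
  contiguity_from_shared_vertices(regions, min_shared = 1L, digits = digits)
}

#' Rook contiguity weights from polygons
#'
#' Two regions are neighbours iff they share at least two snapped
#' vertices (an edge on clean tilings); corner-touching neighbours are
#' excluded.
#'
#' @inheritParams queen_contiguity
#' @return Binary symmetric [spatial_weights()].
#' @export
rook_contiguity <- function(regions, digits = 7) {
  contiguity_from_shared_vertices(regions, min_shared = 2L, digits = digits)
}

#' k-nearest-neighbour weights from region centroids
#'
#' @param regions a [region_set()] with geometry.
#' @param k number of neighbours (1 <= k <= n - 1).
#' @return Binary (directed) [spatial_weights()].
#' @export
knn_weights <- function(regions, k) {
  ctr <- region_centroids(regions)
  n <- nrow(ctr)
  if (k < 1L || k > n - 1L) stop("k must be in 1..n-1")
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) sort(order(d[i, ])[seq_len(k)]))
  spatial_weights(regions$ids, nb)
}

#' Distance-band weights from region centroids
#'
#' @param regions a [region_set()] with geometry.
#' @param d_max centroid-distance threshold (inclusive).
#' @return Binary symmetric [spatial_weights()].
#' @export
distance_band_weights <- function(regions, d_max) {
  ctr <- region_centroids(regions)
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  nb <- lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= d_max))
  if (any(lengths(nb) == 0L))
    warning("isolated unit(s) at distance band ", d_max)
  spatial_weights(regions$ids, nb)
}

#' Row-standardize spatial weights
#'
#' Each non-isolated row is divided by its sum (so rows sum to 1);
#' isolates keep empty rows, with a warning, and are excluded from
#' permutation inference downstream rather than dropped.
#'
#' @param w a [spatial_weights()].
#' @return Row-standardized [spatial_weights()].
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  wt <- lapply(w$weights, function(v) if (length(v)) v / sum(v) else v)
  if (any(lengths(w$neighbors) == 0L))
    warning("isolated unit(s) left with empty rows")
  spatial_weights(w$ids, w$neighbors, wt, standardized = "row")
}

#' Write spatial weights as a GAL adjacency file
#'
#' Dialect: a header line with the unit count, then for each unit a line
#' `id k` followed by a line of k neighbour ids (empty for isolates).
#' Weights are implied binary.
#'
#' @param w a [spatial_weights()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(w$ids)), con)
  for (i in seq_along(w$ids)) {
    nb <- w$neighbors[[i]]
    writeLines(paste(w$ids[i], length(nb)), con)
    writeLines(paste(w$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read a GAL adjacency file
#'
#' @param path GAL file path (dialect of [write_gal()]).
#' @return Binary [spatial_weights()].
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty GAL file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  # plain "n" header, or the GeoDa "0 n shp var" variant
  n <- as.integer(if (length(hdr) >= 2L) hdr[2L] else hdr[1L])
  if (is.na(n)) stop("cannot parse GAL header: ", lines[1L])
  ids <- character(n)
  raw_nb <- vector("list", n)
  ln <- 2L
  for (i in seq_len(n)) {
    if (ln > length(lines)) stop("GAL header count exceeds file contents")
    head <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(head) != 2L) stop("malformed GAL unit line: ", lines[ln])
    ids[i] <- head[1L]
    k <- as.integer(head[2L])
    nbl <- if (ln + 1L <= length(lines)) trimws(lines[ln + 1L]) else ""
    nbs <- if (nzchar(nbl)) strsplit(nbl, "\\s+")[[1L]] else character(0)
    if (length(nbs) != k)
      stop("unit '", ids[i], "' declares ", k, " neighbours but lists ",
           length(nbs))
    raw_nb[[i]] <- nbs
    ln <- ln + 2L
  }
  if (ln <= length(lines) && any(nzchar(trimws(lines[ln:length(lines)]))))
    stop("GAL header count smaller than file contents")
  nb <- lapply(raw_nb, function(nbs) {
    idx <- match(nbs, ids)
    if (anyNA(idx))
      stop("dangling neighbour id: ", nbs[is.na(idx)][1L])
    idx
  })
  spatial_weights(ids, nb)
}
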