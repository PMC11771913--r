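# Density-based clustering of crash locations (DBSCAN), with the
# radius/density sensitivity-sweep protocol and hotspot polygon export.
#
# Conventions (deliberate, and worth stating prominently):
#   * the eps-neighbourhood uses the STRICT inequality d(p, q) < eps — many
#     implementations use <=; points exactly eps apart are NOT neighbours;
#   * a point is always a member of its own neighbourhood, and minPts counts
#     the point itself;
#   * distances are Euclidean on the given planar (projected) coordinates —
#     no geodesy.

as_coords <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    m <- points
  } else {
    stopifnot(all(c("x", "y") %in% names(points)))
    m <- cbind(points$x, points$y)
  }
  if (nrow(m) > 0 && !all(is.finite(m))) stop("non-finite coordinates")
  storage.mode(m) <- "double"
  m
}

# All eps-neighbourhoods at once. Brute force below 1,000 points; a uniform
# grid of cell size eps above (3x3 neighbouring cells cover the disc).
neighborhood_lists <- function(coords, eps) {
  n <- nrow(coords)
  if (n == 0) return(list())
  if (n < 1000) {
    d <- as.matrix(stats::dist(coords))
    return(lapply(seq_len(n), function(i) which(d[i, ] < eps)))
  }
  cx <- floor(coords[, 1] / eps)
  cy <- floor(coords[, 2] / eps)
  key <- paste(cx, cy)
  cell <- split(seq_len(n), key)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      c_ids <- cell[[k]]
      if (!is.null(c_ids)) cand <- c(cand, c_ids)
    }
    dd <- sqrt((coords[cand, 1] - coords[i, 1])^2 +
               (coords[cand, 2] - coords[i, 2])^2)
    out[[i]] <- sort(cand[dd < eps])
  }
  out
}

#' Epsilon-neighbourhood of a point
#'
#' All point indices strictly within radius `eps` of point `index`,
#' including the query point itself (its self-distance is 0).
#'
#' @param points Data frame with `x`, `y` columns, or a two-column matrix of
#'   planar coordinates.
#' @param index Index of the query point.
#' @param eps Neighbourhood radius (> 0), in coordinate units.
#' @return Sorted integer vector of neighbour indices.
#' @export
eps_neighborhood <- function(points, index, eps) {
  stopifnot(eps > 0)
  coords <- as_coords(points)
  stopifnot(index >= 1, index <= nrow(coords))
  d <- sqrt((coords[, 1] - coords[index, 1])^2 +
            (coords[, 2] - coords[index, 2])^2)
  which(d < eps)
}

#' Classify points as core, border or noise
#'
#' A point is *core* when its eps-neighbourhood (self included) holds at
#' least `min_pts` points; *border* when not core but inside some core
#' point's neighbourhood; *noise* otherwise.
#'
#' @inheritParams eps_neighborhood
#' @param eps Neighbourhood radius (> 0).
#' @param min_pts Density threshold (>= 1).
#' @return Character vector in `{"core", "border", "noise"}`, one per point.
#' @export
classify_points <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  coords <- as_coords(points)
  nb <- neighborhood_lists(coords, eps)
  sizes <- lengths(nb)
  core <- sizes >= min_pts
  cls <- rep("noise", nrow(coords))
  cls[core] <- "core"
  if (any(core)) {
    reached <- unique(unlist(nb[core], use.names = FALSE))
    cls[setdiff(reached[!core[reached]], which(core))] <- "border"
  }
  cls
}

#' Density-based clustering (DBSCAN)
#'
#' Clusters are the maximal density-connected sets: starting from each
#' not-yet-assigned core point (in index order) the cluster is grown by
#' breadth-first expansion through the eps-neighbourhoods of its core
#' members; border points join the first cluster that reaches them; points
#' never reached are noise (cluster id 0).
#'
#' @inheritParams classify_points
#' @return An object of class `dbscan_result`: list with `cluster`
#'   (integer per point, 0 = noise), `point_class` (core/border/noise),
#'   `clusters` (list of member index vectors), `eps`, `min_pts`,
#'   `n_border_ties` (count of border points reachable from more than one
#'   cluster, reported via a message when positive).
#' @export
dbscan <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 1)
  coords <- as_coords(points)
  n <- nrow(coords)
  if (n == 0) {
    return(structure(list(cluster = integer(0), point_class = character(0),
                          clusters = list(), eps = eps, min_pts = min_pts,
                          n_border_ties = 0L),
                     class = "dbscan_result"))
  }
  nb <- neighborhood_lists(coords, eps)
  core <- lengths(nb) >= min_pts
  cluster <- integer(n)           # 0 = unassigned / noise
  tie_pts <- integer(0)
  cid <- 0L
  for (p in seq_len(n)) {
    if (!core[p] || cluster[p] != 0L) next
    cid <- cid + 1L
    cluster[p] <- cid
    queue <- nb[[p]]
    head <- 1L
    while (head <= length(queue)) {
      q <- queue[head]
      head <- head + 1L
      if (cluster[q] == 0L) {
        cluster[q] <- cid
        if (core[q]) queue <- c(queue, nb[[q]])
      } else if (cluster[q] != cid && !core[q]) {
        tie_pts <- c(tie_pts, q)  # border point also reachable from this cluster
      }
    }
  }
  ties <- length(unique(tie_pts))
  if (ties > 0) message(ties, " border-point tie(s): kept first-discovered cluster")
  cls <- rep("noise", n)
  cls[core] <- "core"
  cls[!core & cluster != 0L] <- "border"
  structure(list(cluster = cluster, point_class = cls,
                 clusters = if (cid > 0) split(seq_len(n)[cluster != 0L],
                                               cluster[cluster != 0L])
                            else list(),
                 eps = eps, min_pts = min_pts, n_border_ties = ties),
            class = "dbscan_result")
}

#' @export
print.dbscan_result <- function(x, ...) {
  cat("DBSCAN (eps =", x$eps, ", minPts =", x$min_pts, "):",
      length(x$clusters), "cluster(s),",
      sum(x$point_class == "core"), "core /",
      sum(x$point_class == "border"), "border /",
      sum(x$point_class == "noise"), "noise\n")
  invisible(x)
}

#' Radius/density sensitivity sweep
#'
#' Runs one full clustering per cell of the `eps` x `min_pts` grid — the
#' protocol used to pick a working (radius, density) pair by inspecting how
#' the number of high-density locations responds (e.g. radii of 100/150/200
#' ft crossed with density thresholds 5/10/15).
#'
#' @inheritParams classify_points
#' @param eps_values,min_pts_values Non-empty parameter grids.
#' @return Data frame ordered by (`eps`, `min_pts`) with columns
#'   `eps`, `min_pts`, `n_clusters`, `n_core`, `n_border`, `n_noise`.
#' @export
sensitivity_sweep <- function(points, eps_values = c(100, 150, 200),
                              min_pts_values = c(5, 10, 15)) {
  stopifnot(length(eps_values) >= 1, length(min_pts_values) >= 1)
  grid <- expand.grid(min_pts = sort(min_pts_values),
                      eps = sort(eps_values))[, c("eps", "min_pts")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- dbscan(points, grid$eps[i], grid$min_pts[i])
    data.frame(eps = grid$eps[i], min_pts = grid$min_pts[i],
               n_clusters = length(r$clusters),
               n_core = sum(r$point_class == "core"),
               n_border = sum(r$point_class == "border"),
               n_noise = sum(r$point_class == "noise"))
  })
  do.call(rbind, rows)
}

#' Convex hull polygon of each cluster
#'
#' The hotspot geometry reported per cluster is the convex hull of its
#' member coordinates. Clusters with fewer than three non-collinear members
#' yield degenerate geometry (a segment or a point), flagged as such.
#'
#' @inheritParams eps_neighborhood
#' @param result A [dbscan()] result on the same points.
#' @return List of hulls, one per cluster: `cluster_id`, `members`,
#'   `n_core`, `vertices` (matrix, counter-clockwise, not closed),
#'   `geometry` in `{"polygon", "segment", "point"}`, `degenerate`, `area`.
#' @export
cluster_hulls <- function(points, result) {
  coords <- as_coords(points)
  lapply(seq_along(result$clusters), function(ci) {
    idx <- result$clusters[[ci]]
    m <- coords[idx, , drop = FALSE]
    u <- unique(m)
    h <- grDevices::chull(m)           # indices into m, clockwise
    verts <- m[rev(h), , drop = FALSE] # counter-clockwise
    area <- polygon_area(verts)
    geometry <- if (nrow(u) == 1) "point" else if (area == 0) "segment"
                else "polygon"
    if (geometry == "segment") {
      # endpoints of the degenerate (collinear) hull: most distant pair
      dd <- as.matrix(stats::dist(u))
      ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      verts <- u[ij, , drop = FALSE]
    }
    if (geometry == "point") verts <- u
    list(cluster_id = ci, members = idx,
         n_core = sum(result$point_class[idx] == "core"),
         vertices = verts, geometry = geometry,
         degenerate = geometry != "polygon", area = area)
  })
}

# signed shoelace area, absolute value
polygon_area <- function(v) {
  k <- nrow(v)
  if (k < 3) return(0)
  xs <- v[, 1]; ys <- v[, 2]
  abs(sum(xs * ys[c(2:k, 1)] - xs[c(2:k, 1)] * ys)) / 2
}

#' Write per-point cluster labels as a delimited text file
#'
#' @inheritParams cluster_hulls
#' @param path Output path (tab-separated: `id`, `x`, `y`, `cluster`,
#'   `point_class`).
#' @export
write_cluster_labels <- function(points, result, path) {
  coords <- as_coords(points)
  ids <- if (is.data.frame(points) && "id" %in% names(points)) points$id
         else seq_len(nrow(coords))
  df <- data.frame(id = ids, x = coords[, 1], y = coords[, 2],
                   cluster = result$cluster, point_class = result$point_class)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export cluster hulls as a GeoJSON FeatureCollection
#'
#' One feature per cluster: a `Polygon` (closed ring), or a `LineString` /
#' `Point` for degenerate hulls. Properties: `cluster_id`, `member_count`,
#' `core_count`, `degenerate`. Coordinates are the planar units of the
#' input; no coordinate reference system is asserted.
#'
#' @param hulls Output of [cluster_hulls()].
#' @param path Output `.geojson` path.
#' @export
write_hulls_geojson <- function(hulls, path) {
  feat <- lapply(hulls, function(h) {
    v <- h$vertices
    geom <- switch(h$geometry,
      polygon = list(type = "Polygon",
                     coordinates = list(lapply(c(seq_len(nrow(v)), 1L),
                                               function(i) c(v[i, 1], v[i, 2])))),
      segment = list(type = "LineString",
                     coordinates = lapply(seq_len(nrow(v)),
                                          function(i) c(v[i, 1], v[i, 2]))),
      point = list(type = "Point", coordinates = c(v[1, 1], v[1, 2])))
    list(type = "Feature", geometry = geom,
         properties = list(cluster_id = h$cluster_id,
                           member_count = length(h$members),
                           core_count = h$n_core,
                           degenerate = h$degenerate))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
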