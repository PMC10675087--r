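#' Instantaneous lake level from station records
#'
#' The lake is gauged by one or more level stations reporting metres above the
#' datum. The instantaneous level at time `at` is the arithmetic mean over
#' stations of each station's most recent reading within a staleness window,
#' so a station that has gone quiet cannot drag the level with old data.
#'
#' @param records data frame with columns `station_id`, `timestamp`
#'   (POSIXct or ISO-8601 text, UTC) and `level` (metres above datum; a
#'   `level_m` column is also accepted).
#' @param at time of interest (POSIXct or ISO-8601 text, UTC).
#' @param window_hours staleness window: only records with
#'   `at - window <= t <= at` count. Default 6 h.
#' @return the water level in metres (scalar).
#' @export
mean_water_level <- function(records, at, window_hours = 6) {
  if (!is.data.frame(records) || !nrow(records))
    stop("`records` must be a non-empty data frame")
  if (!"level" %in% names(records) && "level_m" %in% names(records))
    records$level <- records$level_m
  stopifnot(all(c("station_id", "timestamp", "level") %in% names(records)))
  t <- as_utc(records$timestamp)
  at <- as_utc(at)
  ok <- !is.na(t) & t <= at & t >= at - window_hours * 3600 &
    is.finite(records$level)
  if (!any(ok))
    stop(sprintf("stale level: no water-level records within %g h of %s",
                 window_hours, format(at, "%Y-%m-%dT%H:%M:%SZ")))
  r <- records[ok, ]
  t <- t[ok]
  latest <- vapply(split(seq_len(nrow(r)), r$station_id), function(i) {
    i[which.max(as.numeric(t[i]))]
  }, 0L)
  mean(r$level[latest])
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamp(s)")
  out
}

#' Lake surface at a given water level
#'
#' Intersects the planar water surface with the watershed terrain: the wetted
#' mask is the connected component of cells with elevation at or below the
#' level (ties count as water) that contains a user-supplied seed point, so
#' disconnected low-lying terrain elsewhere in the watershed is excluded. The
#' shoreline is the iso-contour of the mask; island holes remain non-water.
#'
#' @param dem an [elevation_grid()] of terrain elevation.
#' @param level water level, metres above the DEM datum.
#' @param seed_xy length-2 map point known to be on the lake (e.g. mid-lake).
#' @param connectivity 8 (default, diagonal neighbours connect) or 4.
#' @return an object of class `lake_surface`: the boolean mask, the boundary
#'   polylines in map coordinates, the surface area in km^2, and the grid
#'   geometry.
#' @export
determine_lake_surface <- function(dem, level, seed_xy, connectivity = 8) {
  stopifnot(inherits(dem, "elevation_grid"), is.finite(level))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  rc <- xy_to_rowcol(dem, seed_xy[1], seed_xy[2])
  if (anyNA(rc)) stop("seed point lies outside the grid")
  wet <- !is.na(dem$values) & dem$values <= level
  if (!wet[rc[1], rc[2]])
    stop(sprintf("seed cell elevation exceeds water level (%g m): dry seed",
                 level))
  mask <- flood_fill(wet, rc[1], rc[2], connectivity)
  boundary <- mask_boundary(mask, dem)
  structure(
    list(level = level, mask = mask, boundary = boundary,
         area_km2 = sum(mask) * dem$cell_size^2 / 1e6,
         origin = dem$origin, cell_size = dem$cell_size),
    class = "lake_surface"
  )
}

#' @export
print.lake_surface <- function(x, ...) {
  cat(sprintf("<lake_surface> level %g m | %d wet cells | %.4f km^2 | %d boundary ring(s)\n",
              x$level, sum(x$mask), x$area_km2, length(x$boundary)))
  invisible(x)
}

# connected component containing (r0, c0), by frontier dilation within `wet`
flood_fill <- function(wet, r0, c0, connectivity = 8) {
  nr <- nrow(wet); nc <- ncol(wet)
  mask <- matrix(FALSE, nr, nc)
  mask[r0, c0] <- TRUE
  repeat {
    grown <- dilate_once(mask, connectivity) & wet
    if (sum(grown) == sum(mask)) return(mask)
    mask <- grown
  }
}

dilate_once <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  if (connectivity == 8) {
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
  }
  out
}

# 0.5 iso-contour of the binary mask, as closed polylines in map coordinates
mask_boundary <- function(mask, geom) {
  xs <- geom$origin[1] + (seq_len(ncol(mask)) - 0.5) * geom$cell_size
  ys <- geom$origin[2] - (seq_len(nrow(mask)) - 0.5) * geom$cell_size
  # contourLines wants increasing axes; z[i, j] at x[i], y[j]
  z <- t(mask * 1)[, rev(seq_len(nrow(mask))), drop = FALSE]
  cl <- grDevices::contourLines(x = xs, y = rev(ys), z = z, levels = 0.5)
  lapply(cl, function(s) list(x = s$x, y = s$y))
}

#' Underwater terrain mesh from bathymetry soundings
#'
#' Assigns each sounding its bed elevation and fits the piecewise-linear
#' surface through all of them: a Delaunay triangulation of the planform
#' coordinates with z carried on the vertices. The mesh reproduces every
#' input sounding exactly.
#'
#' @param points data frame or matrix with columns `x`, `y`, `z` (metres;
#'   z = bed elevation above the datum, not depth).
#' @return a [terrain_mesh()].
#' @export
build_underwater_mesh <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points))) {
    if (ncol(points) >= 3L) names(points)[1:3] <- c("x", "y", "z")
    else stop("`points` needs columns x, y, z")
  }
  if (nrow(points) < 3L) stop("need at least 3 bathymetry points")
  if (!all(is.finite(as.matrix(points[, c("x", "y", "z")]))))
    stop("bathymetry points must be finite")
  tri <- delaunay_triangles(points$x, points$y)
  terrain_mesh(cbind(points$x, points$y, points$z), tri)
}

#' Merge lake surface and underwater terrain into the lake twin
#'
#' Reconciles the instantaneous wetted surface with the bathymetry mesh using
#' two rules: where the mesh footprint falls short of the wetted area (an
#' empty annulus between the surveyed bed and the shoreline), the gap is
#' *mended* with terrain vertices sampled from the DEM at cell centres; where
#' mesh vertices sit above the water level, the mesh is *clipped*, keeping
#' only vertices with z at or below the level, and re-triangulated. The
#' branch(es) that fired are recorded in the result's provenance; if neither
#' fires the input mesh is returned unchanged.
#'
#' @param surface a [determine_lake_surface()] result.
#' @param mesh a [terrain_mesh()] of the surveyed bed.
#' @param dem the [elevation_grid()] the surface was derived from.
#' @param timestamp time attached to the twin (POSIXct or ISO-8601 text).
#' @return an object of class `twin_lake` with fields `timestamp`, `level`,
#'   `surface`, `underwater`, `provenance`.
#' @export
merge_twin <- function(surface, mesh, dem, timestamp = Sys.time()) {
  stopifnot(inherits(surface, "lake_surface"), inherits(mesh, "terrain_mesh"),
            inherits(dem, "elevation_grid"))
  level <- surface$level
  prov <- character(0)
  v <- mesh$vertices
  if (all(v[, 3] > level))
    stop("mesh entirely above water level: no submerged terrain to merge")
  out <- mesh

  if (any(v[, 3] > level)) {            # clip
    keep <- v[, 3] <= level
    v <- v[keep, , drop = FALSE]
    if (nrow(v) < 3L) stop("fewer than 3 submerged vertices after clipping")
    out <- terrain_mesh(v, delaunay_triangles(v[, 1], v[, 2]))
    prov <- c(prov, "clip")
  }

  wet <- which(surface$mask, arr.ind = TRUE)
  cx <- surface$origin[1] + (wet[, 2] - 0.5) * surface$cell_size
  cy <- surface$origin[2] - (wet[, 1] - 0.5) * surface$cell_size
  covered <- mesh_covers(out, cx, cy)
  if (any(!covered)) {                  # mend
    zi <- dem$values[wet[!covered, , drop = FALSE]]
    add <- cbind(cx[!covered], cy[!covered], zi)
    allv <- rbind(out$vertices, add)
    dup <- duplicated(allv[, 1:2])
    allv <- allv[!dup, , drop = FALSE]
    out <- terrain_mesh(allv, delaunay_triangles(allv[, 1], allv[, 2]))
    prov <- c(prov, "mend")
  }

  structure(
    list(timestamp = as_utc(timestamp), level = level, surface = surface,
         underwater = out, provenance = prov, dem = dem),
    class = "twin_lake"
  )
}

#' @export
print.twin_lake <- function(x, ...) {
  cat(sprintf("<twin_lake> %s | level %g m | area %.4f km^2 | mesh %d vert / %d faces | branches: %s\n",
              format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ"), x$level,
              x$surface$area_km2, nrow(x$underwater$vertices),
              nrow(x$underwater$faces),
              if (length(x$provenance)) paste(x$provenance, collapse = "+")
              else "none"))
  invisible(x)
}

#' @export
summary.twin_lake <- function(object, ...) {
  v <- object$underwater$vertices
  s <- list(
    timestamp = object$timestamp, level_m = object$level,
    area_km2 = object$surface$area_km2,
    mean_depth_m = mean(object$level - v[, 3]),
    max_depth_m = max(object$level - v[, 3]),
    provenance = object$provenance
  )
  class(s) <- "summary.twin_lake"
  s
}

#' @export
print.summary.twin_lake <- function(x, ...) {
  cat(sprintf(
    "Lake twin at %s\n  level: %g m  area: %.4f km^2\n  depth: mean %.2f m, max %.2f m\n  merge branches: %s\n",
    format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ"), x$level_m, x$area_km2,
    x$mean_depth_m, x$max_depth_m,
    if (length(x$provenance)) paste(x$provenance, collapse = "+") else "none"))
  invisible(x)
}

#' @export
plot.twin_lake <- function(x, ...) {
  s <- x$surface
  xs <- s$origin[1] + (seq_len(ncol(s$mask)) - 0.5) * s$cell_size
  ys <- s$origin[2] - (seq_len(nrow(s$mask)) - 0.5) * s$cell_size
  graphics::image(xs, rev(ys), t(s$mask * 1)[, rev(seq_len(nrow(s$mask)))],
                  col = c("wheat", "steelblue2"), xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("lake surface, level %g m", s$level), ...)
  for (b in s$boundary) graphics::lines(b$x, b$y, col = "navy")
  invisible(x)
}

#' Rebuild the lake twin at a point in time
#'
#' One-shot composition for the time-varying twin: average the level stations,
#' re-derive the wetted surface, triangulate the bathymetry, and merge. With
#' fixed inputs the result is bit-identical between calls, so the twin can be
#' refreshed on every new water-level reading.
#'
#' @inheritParams mean_water_level
#' @inheritParams determine_lake_surface
#' @param bathymetry data frame with columns x, y, z (bed elevation).
#' @param at time of the refresh.
#' @return a `twin_lake` (see [merge_twin()]).
#' @export
refresh_twin <- function(dem, bathymetry, records, at, seed_xy,
                         window_hours = 6, connectivity = 8) {
  level <- mean_water_level(records, at, window_hours)
  surface <- determine_lake_surface(dem, level, seed_xy, connectivity)
  mesh <- build_underwater_mesh(bathymetry)
  merge_twin(surface, mesh, dem, timestamp = at)
}

#' Export the shoreline as GeoJSON
#'
#' Writes the boundary rings of a lake surface as a Polygon or MultiPolygon
#' FeatureCollection in map coordinates.
#' @param surface a `lake_surface`.
#' @param path output path.
#' @export
write_boundary_geojson <- function(surface, path) {
  stopifnot(inherits(surface, "lake_surface"))
  rings <- lapply(surface$boundary, function(b) {
    xy <- cbind(b$x, b$y)
    if (!all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
    list(xy)
  })
  geom <- if (length(rings) == 1L) {
    list(type = "Polygon", coordinates = rings[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = rings)
  }
  fc <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(level_m = surface$level, area_km2 = surface$area_km2),
      geometry = geom
    ))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
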