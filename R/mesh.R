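#' Triangulated terrain mesh
#'
#' Piecewise-linear surface used for the underwater topography of the lake
#' twin: vertices carry bed elevation (metres above the same datum as the DEM
#' and the water level), faces are triangles indexing vertices.
#'
#' @param vertices numeric n x 3 matrix of (x, y, z).
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @return an object of class `terrain_mesh`.
#' @export
terrain_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3 (x, y, z)")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  a <- tri_area2(vertices[, 1], vertices[, 2], faces)
  if (any(abs(a) <= 0))
    stop("mesh contains degenerate (zero-area) faces")
  structure(list(vertices = vertices, faces = faces), class = "terrain_mesh")
}

#' @export
print.terrain_mesh <- function(x, ...) {
  cat(sprintf("<terrain_mesh> %d vertices, %d faces, z in [%g, %g]\n",
              nrow(x$vertices), nrow(x$faces),
              min(x$vertices[, 3]), max(x$vertices[, 3])))
  invisible(x)
}

# twice the signed area of each face
tri_area2 <- function(x, y, faces) {
  i <- faces[, 1]; j <- faces[, 2]; k <- faces[, 3]
  (x[j] - x[i]) * (y[k] - y[i]) - (x[k] - x[i]) * (y[j] - y[i])
}

#' Delaunay triangulation of planar points (Bowyer-Watson)
#'
#' Incremental insertion with cached circumcircles. Cocircular point sets
#' (ubiquitous on grid-sampled bathymetry) are disambiguated by a deterministic
#' symbolic perturbation of the insertion coordinates only; output vertex
#' coordinates are the exact inputs.
#'
#' @param x,y point coordinates.
#' @return integer m x 3 matrix of counter-clockwise triangles.
#' @keywords internal
delaunay_triangles <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for triangulation")
  if (anyDuplicated(cbind(x, y)))
    stop("duplicate (x, y) points in triangulation input")
  span <- max(max(x) - min(x), max(y) - min(y))
  if (span <= 0) stop("points are coincident")
  # collinearity check against the first non-degenerate edge
  cr <- (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  if (max(abs(cr)) <= 1e-12 * span^2)
    stop("points are collinear; cannot build a surface mesh")

  # deterministic symbolic perturbation (insertion copy only)
  h <- ((seq_len(n) * 2654435761) %% 65536L) / 65536 - 0.5
  px <- x + span * 1e-9 * h
  py <- y + span * 1e-9 * rev(h)

  cx0 <- (min(x) + max(x)) / 2; cy0 <- (min(y) + max(y)) / 2
  big <- 20 * span + 1
  sx <- c(cx0 - big, cx0 + big, cx0)
  sy <- c(cy0 - big, cy0 - big, cy0 + big)
  vx <- c(px, sx); vy <- c(py, sy)

  tri <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3L)
  cc <- circumcircle(vx, vy, tri)
  ord <- order(px, py)

  for (p in ord) {
    d2 <- (vx[p] - cc$cx)^2 + (vy[p] - cc$cy)^2
    bad <- which(d2 <= cc$r2 * (1 + 1e-12))
    if (!length(bad)) { # numerical fallback: nearest circumcircle
      bad <- which.min(d2 - cc$r2)
    }
    bt <- tri[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    key <- pmin(edges[, 1], edges[, 2]) * (n + 4) + pmax(edges[, 1], edges[, 2])
    keep <- !(key %in% key[duplicated(key)])
    poly <- edges[keep, , drop = FALSE]
    newtri <- cbind(poly, p)
    tri <- rbind(tri[-bad, , drop = FALSE], newtri)
    ncc <- circumcircle(vx, vy, newtri)
    cc <- list(cx = c(cc$cx[-bad], ncc$cx),
               cy = c(cc$cy[-bad], ncc$cy),
               r2 = c(cc$r2[-bad], ncc$r2))
  }

  tri <- tri[rowSums(tri > n) == 0L, , drop = FALSE]
  if (!nrow(tri)) stop("triangulation failed (no interior triangles)")
  # orient counter-clockwise on the true coordinates, drop degenerates
  a2 <- tri_area2(x, y, tri)
  flip <- a2 < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  tri[abs(tri_area2(x, y, tri)) > 1e-14 * span^2, , drop = FALSE]
}

circumcircle <- function(x, y, tri) {
  ax <- x[tri[, 1]]; ay <- y[tri[, 1]]
  bx <- x[tri[, 2]]; by <- y[tri[, 2]]
  cx <- x[tri[, 3]]; cy <- y[tri[, 3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[d == 0] <- NA_real_
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  r2[is.na(r2)] <- Inf
  ux[!is.finite(ux)] <- 0; uy[!is.finite(uy)] <- 0
  list(cx = ux, cy = uy, r2 = r2)
}

#' Linear interpolation on a terrain mesh
#'
#' Barycentric interpolation of vertex heights within the containing face;
#' exact at vertices and exact for any affine surface. Points outside the mesh
#' footprint return `NA`.
#'
#' @param mesh a [terrain_mesh()].
#' @param x,y query coordinates.
#' @return numeric vector of interpolated z.
#' @export
mesh_interpolate <- function(mesh, x, y) {
  v <- mesh$vertices; f <- mesh$faces
  ax <- v[f[, 1], 1]; ay <- v[f[, 1], 2]
  bx <- v[f[, 2], 1]; by <- v[f[, 2], 2]
  cx <- v[f[, 3], 1]; cy <- v[f[, 3], 2]
  den <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  tol <- 1e-9
  out <- rep(NA_real_, length(x))
  for (q in seq_along(x)) {
    l1 <- ((by - cy) * (x[q] - cx) + (cx - bx) * (y[q] - cy)) / den
    l2 <- ((cy - ay) * (x[q] - cx) + (ax - cx) * (y[q] - cy)) / den
    l3 <- 1 - l1 - l2
    hit <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)[1]
    if (!is.na(hit)) {
      out[q] <- l1[hit] * v[f[hit, 1], 3] + l2[hit] * v[f[hit, 2], 3] +
        l3[hit] * v[f[hit, 3], 3]
    }
  }
  out
}

#' Planform footprint test (convex hull of the mesh vertices)
#'
#' A Delaunay mesh tiles the convex hull of its vertices, so planform coverage
#' reduces to a point-in-convex-polygon test.
#' @keywords internal
mesh_covers <- function(mesh, x, y, tol = 1e-9) {
  v <- mesh$vertices
  h <- grDevices::chull(v[, 1], v[, 2])
  hx <- v[h, 1]; hy <- v[h, 2]
  m <- length(h)
  span <- max(max(hx) - min(hx), max(hy) - min(hy))
  inside <- rep(TRUE, length(x))
  # chull returns clockwise order; test each edge half-plane
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (y - hy[i]) - (hy[j] - hy[i]) * (x - hx[i])
    inside <- inside & (cr <= tol * span)
  }
  inside
}

#' Export a mesh as Wavefront OBJ
#'
#' Writes plain-text `v x y z` and `f i j k` records.
#' @param mesh a [terrain_mesh()].
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "terrain_mesh"))
  v <- sprintf("v %.6f %.6f %.6f",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c("# terrain_mesh", v, f), path)
  invisible(path)
}
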