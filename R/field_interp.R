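#' Variogram specification
#'
#' Parametric semivariogram used by the ordinary-kriging interpolator:
#' `gamma(h)` rises from the nugget at h -> 0+ to the sill at (or beyond) the
#' range. Supported models: spherical, exponential, gaussian.
#'
#' @param model one of "spherical", "exponential", "gaussian".
#' @param nugget micro-scale variance at h -> 0+, >= 0.
#' @param sill total variance plateau, >= nugget.
#' @param range correlation length in metres, > 0.
#' @return an object of class `variogram_spec`.
#' @export
variogram_spec <- function(model = c("spherical", "exponential", "gaussian"),
                           nugget = 0, sill = 1, range = 1000) {
  model <- match.arg(model)
  if (nugget < 0) stop("nugget must be >= 0")
  if (sill < nugget) stop("sill must be >= nugget")
  if (range <= 0) stop("range must be > 0")
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_spec")
}

#' @export
print.variogram_spec <- function(x, ...) {
  cat(sprintf("<variogram_spec> %s | nugget %.4g sill %.4g range %.4g m\n",
              x$model, x$nugget, x$sill, x$range))
  invisible(x)
}

#' Evaluate a semivariogram
#'
#' `gamma(0) = 0` by convention; the nugget applies for any h > 0.
#' @param spec a [variogram_spec()].
#' @param h lag distances (metres), >= 0.
#' @return semivariance values.
#' @export
variogram_gamma <- function(spec, h) {
  a <- spec$range; c0 <- spec$nugget; c1 <- spec$sill - spec$nugget
  g <- switch(spec$model,
    spherical = ifelse(h >= a, c1, c1 * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = c1 * (1 - exp(-3 * h / a)),
    gaussian = c1 * (1 - exp(-3 * (h / a)^2))
  )
  out <- c0 + g
  out[h == 0] <- 0
  out
}

#' Empirical variogram and weighted least-squares fit
#'
#' Bins the squared half-differences of all sample pairs by lag distance and
#' fits the chosen model by WLS with the standard `N_j / gamma(h_j)^2`
#' weights.
#'
#' @param x,y,value sample coordinates and values.
#' @param model variogram model name.
#' @param n_bins number of lag bins (default 12).
#' @param cutoff maximum lag considered; default one third of the bounding-box
#'   diagonal.
#' @return a fitted [variogram_spec()] with the empirical cloud attached as
#'   attribute `"empirical"`.
#' @export
fit_variogram <- function(x, y, value, model = "spherical", n_bins = 12,
                          cutoff = NULL) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n, length(value) == n)
  d <- as.matrix(stats::dist(cbind(x, y)))
  sq <- 0.5 * outer(value, value, `-`)^2
  iu <- upper.tri(d)
  h <- d[iu]; g <- sq[iu]
  if (is.null(cutoff)) {
    cutoff <- sqrt(diff(range(x))^2 + diff(range(y))^2) / 3
  }
  keep <- h > 0 & h <= cutoff
  if (sum(keep) < max(30, 3 * n_bins)) {   # sparse geometries: widen the lag span
    cutoff <- max(h)
    keep <- h > 0
  }
  h <- h[keep]; g <- g[keep]
  if (length(h) < 3)
    stop("too few sample pairs to estimate a variogram")
  br <- seq(0, cutoff, length.out = n_bins + 1L)
  bin <- findInterval(h, br, rightmost.closed = TRUE)
  emp <- data.frame(
    h = tapply(h, bin, mean),
    gamma = tapply(g, bin, mean),
    n = as.integer(table(bin))
  )
  svar <- stats::var(value)
  if (svar == 0) {
    out <- variogram_spec(model, 0, 0 + 1e-12, max(emp$h))
    attr(out, "empirical") <- emp
    return(out)
  }
  obj <- function(p) {
    n0 <- max(exp(p[1]) - 1e-9, 0)
    sp <- variogram_spec(model, nugget = n0, sill = n0 + exp(p[2]),
                         range = exp(p[3]))
    mod <- variogram_gamma(sp, emp$h)
    w <- emp$n / pmax(mod, 1e-12)^2
    sum(w * (emp$gamma - mod)^2)
  }
  p0 <- c(log(max(svar * 0.05, 1e-9)), log(max(svar, 1e-9)),
          log(max(emp$h) * 0.6))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500))
  out <- variogram_spec(model, nugget = max(exp(fit$par[1]) - 1e-9, 0),
                        sill = max(exp(fit$par[1]) - 1e-9, 0) + exp(fit$par[2]),
                        range = exp(fit$par[3]))
  attr(out, "empirical") <- emp
  out
}

#' Ordinary-kriging weights for one prediction point
#'
#' Solves the ordinary-kriging system (semivariance matrix bordered by the
#' unbiasedness constraint); the returned weights sum to 1 by construction.
#' Exposed mainly for diagnostics and tests.
#'
#' @param samples data frame with x, y, value.
#' @param variogram a [variogram_spec()].
#' @param x0,y0 prediction location.
#' @return list(weights, lagrange, prediction, variance).
#' @export
kriging_weights <- function(samples, variogram, x0, y0) {
  n <- nrow(samples)
  d <- as.matrix(stats::dist(cbind(samples$x, samples$y)))
  A <- rbind(cbind(variogram_gamma(variogram, d), 1), c(rep(1, n), 0))
  g0 <- variogram_gamma(variogram,
                        sqrt((samples$x - x0)^2 + (samples$y - y0)^2))
  w <- solve(A, c(g0, 1))
  list(weights = w[1:n], lagrange = w[n + 1],
       prediction = sum(w[1:n] * samples$value),
       variance = sum(w[1:n] * g0) + w[n + 1])
}

#' 2-D ordinary kriging onto a raster grid
#'
#' Predicts a field on the geometry of `geometry` (any grid-like object with
#' `origin`, `cell_size` and a `values` matrix, e.g. an [elevation_grid()])
#' from scattered samples. Ordinary kriging is exact at the samples when the
#' nugget is zero and its weights sum to one, so a constant sample set yields
#' a constant field. Duplicate sample locations are averaged with a warning;
#' with fewer than 3 distinct samples the interpolator falls back to
#' inverse-distance weighting (constant for a single sample), with a warning.
#'
#' @param samples data frame with columns x, y, value.
#' @param geometry grid template defining origin, cell size and shape.
#' @param variogram a [variogram_spec()]; `NULL` fits a spherical model to the
#'   samples via [fit_variogram()].
#' @param parameter label stored on the output field.
#' @return an object of class `field_2d`: `values` and kriging `variance`
#'   matrices plus grid geometry. Attribute `"variogram"` carries the model
#'   used.
#' @export
ordinary_kriging_2d <- function(samples, geometry, variogram = NULL,
                                parameter = "value") {
  stopifnot(all(c("x", "y", "value") %in% names(samples)))
  samples <- samples[is.finite(samples$value), , drop = FALSE]
  if (!nrow(samples)) stop("no finite samples")
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    warning("duplicate sample locations averaged before kriging")
    samples <- do.call(rbind, lapply(split(samples, key), function(s) {
      data.frame(x = s$x[1], y = s$y[1], value = mean(s$value))
    }))
    rownames(samples) <- NULL
  }
  nr <- nrow(geometry$values); nc <- ncol(geometry$values)
  px <- geometry$origin[1] + (seq_len(nc) - 0.5) * geometry$cell_size
  py <- geometry$origin[2] - (seq_len(nr) - 0.5) * geometry$cell_size
  gx <- rep(px, each = nr); gy <- rep(py, times = nc)

  n <- nrow(samples)
  if (n < 3) {
    warning("fewer than 3 distinct samples; falling back to inverse-distance weighting")
    vals <- idw_predict(samples$x, samples$y, samples$value, gx, gy, power = 2)
    return(structure(
      list(values = matrix(vals, nr, nc), variance = NULL,
           origin = geometry$origin, cell_size = geometry$cell_size,
           parameter = parameter, method = "idw"),
      class = "field_2d"))
  }
  if (is.null(variogram))
    variogram <- fit_variogram(samples$x, samples$y, samples$value)

  d <- as.matrix(stats::dist(cbind(samples$x, samples$y)))
  A <- rbind(cbind(variogram_gamma(variogram, d), 1), c(rep(1, n), 0))
  D0 <- sqrt(outer(samples$x, gx, `-`)^2 + outer(samples$y, gy, `-`)^2)
  B <- rbind(variogram_gamma(variogram, D0), 1)
  W <- solve(A, B)
  pred <- drop(crossprod(W[1:n, , drop = FALSE], samples$value))
  vari <- colSums(W[1:n, , drop = FALSE] * variogram_gamma(variogram, D0)) +
    W[n + 1, ]
  out <- structure(
    list(values = matrix(pred, nr, nc),
         variance = matrix(pmax(vari, 0), nr, nc),
         origin = geometry$origin, cell_size = geometry$cell_size,
         parameter = parameter, method = "ordinary_kriging"),
    class = "field_2d")
  attr(out, "variogram") <- variogram
  out
}

#' @export
print.field_2d <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<field_2d> %s (%s) | %d x %d cells | range [%.4g, %.4g]\n",
              x$parameter, x$method %||% "?", nrow(x$values), ncol(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
plot.field_2d <- function(x, ...) {
  xs <- x$origin[1] + (seq_len(ncol(x$values)) - 0.5) * x$cell_size
  ys <- x$origin[2] - (seq_len(nrow(x$values)) - 0.5) * x$cell_size
  graphics::image(xs, rev(ys), t(x$values)[, rev(seq_len(nrow(x$values)))],
                  xlab = "x (m)", ylab = "y (m)", main = x$parameter, ...)
  invisible(x)
}

# inverse-distance weighting with zero-distance short-circuit
idw_predict <- function(sx, sy, sv, px, py, power = 2, sz = NULL, pz = NULL) {
  d2 <- outer(sx, px, `-`)^2 + outer(sy, py, `-`)^2
  if (!is.null(sz)) d2 <- d2 + outer(sz, pz, `-`)^2
  hit <- apply(d2, 2, which.min)
  mind <- d2[cbind(hit, seq_along(px))]
  w <- 1 / pmax(d2, 1e-300)^(power / 2)
  pred <- drop(crossprod(w, sv)) / colSums(w)
  exact <- mind < 1e-12
  pred[exact] <- sv[hit[exact]]
  pred
}

#' Chamfer distance to the nearest background cell
#'
#' Two-pass 3-4-style chamfer transform with 1 / sqrt(2) local steps, scaled
#' by the cell size: for each TRUE cell, the approximate Euclidean distance in
#' metres to the nearest FALSE cell. Used to delimit the nearshore band.
#' @keywords internal
chamfer_distance <- function(mask, cell_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[!mask] <- 0
  s2 <- sqrt(2)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i > 1) {
      v <- min(v, d[i - 1, j] + 1)
      if (j > 1) v <- min(v, d[i - 1, j - 1] + s2)
      if (j < nc) v <- min(v, d[i - 1, j + 1] + s2)
    }
    if (j > 1) v <- min(v, d[i, j - 1] + 1)
    d[i, j] <- v
  }
  for (i in rev(seq_len(nr))) for (j in rev(seq_len(nc))) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i < nr) {
      v <- min(v, d[i + 1, j] + 1)
      if (j > 1) v <- min(v, d[i + 1, j - 1] + s2)
      if (j < nc) v <- min(v, d[i + 1, j + 1] + s2)
    }
    if (j < nc) v <- min(v, d[i, j + 1] + 1)
    d[i, j] <- v
  }
  d * cell_size
}

#' Nearshore HAB condition field from camera coverage ratios
#'
#' Kriges the latest coverage ratio of each camera device over the lake grid
#' and clips the result to the nearshore band: water cells within
#' `band_width_m` of the shoreline. Interpolated ratios are clamped to
#' \[0, 1\]; the number of clamped cells is recorded in attribute
#' `"overshoots"`.
#'
#' @param records coverage records (data frame with `device_id` and `ratio`);
#'   only the latest record per device is used.
#' @param sites data frame `device_id`, `x`, `y` of the camera positions.
#' @param twin a `twin_lake` from [merge_twin()] / [refresh_twin()].
#' @param band_width_m nearshore band width in metres (default 500; `Inf`
#'   covers all water cells).
#' @param variogram optional [variogram_spec()].
#' @return a `field_2d` of coverage ratio, `NA` outside the band.
#' @export
nearshore_condition <- function(records, sites, twin, band_width_m = 500,
                                variogram = NULL) {
  stopifnot(inherits(twin, "twin_lake"))
  if (!nrow(records)) stop("no coverage records")
  latest <- do.call(rbind, lapply(split(records, records$device_id), function(r) {
    r[order(r$timestamp), ][nrow(r), ]
  }))
  m <- merge(latest, sites, by = "device_id")
  if (!nrow(m)) stop("no coverage records match the device sites")
  samples <- data.frame(x = m$x, y = m$y, value = m$ratio)
  dem <- twin$dem
  field <- ordinary_kriging_2d(samples, dem, variogram, parameter = "coverage_ratio")
  band <- twin$surface$mask
  if (is.finite(band_width_m)) {
    band <- band & chamfer_distance(twin$surface$mask, dem$cell_size) <= band_width_m
  }
  v <- field$values
  over <- sum(band & (v > 1 | v < 0), na.rm = TRUE)
  v <- pmin(pmax(v, 0), 1)
  v[!band] <- NA_real_
  field$values <- v
  if (!is.null(field$variance)) field$variance[!band] <- NA_real_
  attr(field, "overshoots") <- over
  field
}

#' 3-D interpolation of depth-resolved water quality
#'
#' Builds a gridded 3-D field (depth levels x rows x cols) from station
#' profile samples. Two interpolators are available:
#' \describe{
#'   \item{"separable" (default)}{each station's vertical profile is first
#'     interpolated linearly to the requested depth (constant beyond its
#'     shallowest/deepest sample), then the per-station values are spread
#'     horizontally by inverse-distance weighting. Profiling stations sample
#'     the water column densely in depth but sparsely in planform, and this
#'     scheme preserves the measured vertical structure exactly at every
#'     horizontal distance.}
#'   \item{"idw3d"}{plain inverse-distance weighting in anisotropy-scaled
#'     coordinates (horizontal metres; depth multiplied by `anisotropy`).
#'     Simpler, but far-field predictions blend across depths once horizontal
#'     distances exceed the scaled depth spacing.}
#' }
#' Both are exact at sample points. Cells below the local lake bed (from the
#' twin) are masked `NA`.
#'
#' @param samples data frame with columns `x`, `y`, `depth` (metres below the
#'   instantaneous surface, positive down) and `value`.
#' @param geometry grid template (e.g. the DEM or a coarsened copy).
#' @param depth_levels strictly increasing depths of the output levels.
#' @param method "separable" or "idw3d".
#' @param power IDW exponent (default 2).
#' @param anisotropy vertical scaling factor for `"idw3d"` (default 100).
#' @param twin optional `twin_lake` used to mask below-bed cells.
#' @param parameter label for the field.
#' @return an object of class `field_3d`.
#' @export
interpolate_3d <- function(samples, geometry, depth_levels,
                           method = c("separable", "idw3d"), power = 2,
                           anisotropy = 100, twin = NULL, parameter = "value") {
  method <- match.arg(method)
  stopifnot(all(c("x", "y", "depth", "value") %in% names(samples)))
  samples <- samples[is.finite(samples$value), , drop = FALSE]
  if (!nrow(samples)) stop("no finite samples to interpolate")
  if (any(samples$depth < 0)) stop("depths must be >= 0 (positive down)")
  if (is.unsorted(depth_levels, strictly = TRUE))
    stop("depth_levels must be strictly increasing")
  nr <- nrow(geometry$values); nc <- ncol(geometry$values)
  px <- geometry$origin[1] + (seq_len(nc) - 0.5) * geometry$cell_size
  py <- geometry$origin[2] - (seq_len(nr) - 0.5) * geometry$cell_size
  gx <- rep(px, each = nr); gy <- rep(py, times = nc)

  bed_depth <- NULL
  water <- NULL
  if (!is.null(twin)) {
    bed_depth <- matrix(twin$level - twin$dem$values, nr, nc)
    water <- twin$surface$mask
    if (!identical(dim(water), c(nr, nc)))
      stop("twin grid does not match the interpolation geometry")
  }

  if (method == "separable") {
    key <- paste(samples$x, samples$y)
    stations <- !duplicated(key)
    sx <- samples$x[stations]; sy <- samples$y[stations]
    profiles <- split(samples[, c("depth", "value")], match(key, key[stations]))
  }

  vals <- array(NA_real_, c(length(depth_levels), nr, nc))
  for (k in seq_along(depth_levels)) {
    d <- depth_levels[k]
    if (method == "separable") {
      sv <- vapply(profiles, function(p) {
        p <- p[order(p$depth), ]
        if (nrow(p) == 1L) return(p$value)
        stats::approx(p$depth, p$value, xout = d, rule = 2, ties = mean)$y
      }, 0)
      pred <- idw_predict(sx, sy, sv, gx, gy, power = power)
    } else {
      pred <- idw_predict(samples$x, samples$y, samples$value, gx, gy,
                          power = power,
                          sz = samples$depth * anisotropy,
                          pz = rep(d * anisotropy, length(gx)))
    }
    slice <- matrix(pred, nr, nc)
    if (!is.null(bed_depth)) slice[!water | bed_depth < d] <- NA_real_
    vals[k, , ] <- slice
  }
  structure(
    list(values = vals, depth_levels = depth_levels,
         origin = geometry$origin, cell_size = geometry$cell_size,
         parameter = parameter, bed_depth = bed_depth, water = water),
    class = "field_3d")
}

#' @export
print.field_3d <- function(x, ...) {
  cat(sprintf("<field_3d> %s | %d levels (%g..%g m) x %d x %d cells\n",
              x$parameter, length(x$depth_levels), min(x$depth_levels),
              max(x$depth_levels), dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Horizontal layer of a 3-D field
#'
#' Slice at a fixed depth: the stored level when `depth` matches one, linear
#' interpolation between the two bracketing levels otherwise. `NA` (below-bed)
#' cells propagate.
#'
#' @param field a `field_3d`.
#' @param depth metres below the surface, inside the stored level span.
#' @return a `field_2d`.
#' @export
extract_layer <- function(field, depth) {
  stopifnot(inherits(field, "field_3d"))
  lv <- field$depth_levels
  if (depth < lv[1] || depth > lv[length(lv)])
    stop(sprintf("depth %g m outside the stored levels [%g, %g]",
                 depth, lv[1], lv[length(lv)]))
  i <- findInterval(depth, lv)
  slice <- if (lv[i] == depth) {
    field$values[i, , ]
  } else {
    t1 <- (depth - lv[i]) / (lv[i + 1] - lv[i])
    (1 - t1) * field$values[i, , ] + t1 * field$values[i + 1, , ]
  }
  structure(
    list(values = slice, variance = NULL, origin = field$origin,
         cell_size = field$cell_size,
         parameter = sprintf("%s @ %g m", field$parameter, depth),
         method = "layer"),
    class = "field_2d")
}

# bilinear sampling of a matrix field at map points; NA outside
bilinear_sample <- function(values, origin, cell_size, x, y) {
  nr <- nrow(values); nc <- ncol(values)
  cj <- (x - origin[1]) / cell_size + 0.5   # fractional column index
  ri <- (origin[2] - y) / cell_size + 0.5   # fractional row index
  out <- rep(NA_real_, length(x))
  ok <- cj >= 1 & cj <= nc & ri >= 1 & ri <= nr
  if (!any(ok)) return(out)
  j0 <- pmin(floor(cj[ok]), nc - 1); i0 <- pmin(floor(ri[ok]), nr - 1)
  fx <- cj[ok] - j0; fy <- ri[ok] - i0
  v00 <- values[cbind(i0, j0)]; v01 <- values[cbind(i0, j0 + 1)]
  v10 <- values[cbind(i0 + 1, j0)]; v11 <- values[cbind(i0 + 1, j0 + 1)]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  out
}

#' Vertical section of a 3-D field along a polyline
#'
#' Samples every stored depth level at a fixed along-line step, producing a
#' (depth x distance) array. Columns are masked below the local bed depth
#' when the field carries one.
#'
#' @param field a `field_3d`.
#' @param polyline matrix or data frame of (x, y) vertices, >= 2, at least
#'   partly inside the grid.
#' @param step along-line sampling step in metres (default: the cell size).
#' @return an object of class `section_slice`: `values` (levels x stations),
#'   `distance` along the line, `depth_levels`, and the sample coordinates.
#' @export
extract_section <- function(field, polyline, step = NULL) {
  stopifnot(inherits(field, "field_3d"))
  pl <- as.matrix(polyline)
  if (nrow(pl) < 2L) stop("polyline needs at least 2 vertices")
  seg <- sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2)
  if (sum(seg) == 0) stop("zero-length polyline")
  if (is.null(step)) step <- field$cell_size
  cum <- c(0, cumsum(seg))
  dist <- seq(0, cum[length(cum)], by = step)
  sx <- stats::approx(cum, pl[, 1], xout = dist)$y
  sy <- stats::approx(cum, pl[, 2], xout = dist)$y

  nl <- length(field$depth_levels)
  vals <- matrix(NA_real_, nl, length(dist))
  for (k in seq_len(nl)) {
    vals[k, ] <- bilinear_sample(field$values[k, , ], field$origin,
                                 field$cell_size, sx, sy)
  }
  if (all(is.na(vals))) stop("polyline lies entirely outside the grid")
  if (!is.null(field$bed_depth)) {
    bed <- bilinear_sample(field$bed_depth, field$origin, field$cell_size,
                           sx, sy)
    for (k in seq_len(nl)) {
      vals[k, !is.na(bed) & field$depth_levels[k] > bed] <- NA_real_
    }
  }
  structure(
    list(values = vals, distance = dist, depth_levels = field$depth_levels,
         x = sx, y = sy, parameter = field$parameter),
    class = "section_slice")
}

#' @export
print.section_slice <- function(x, ...) {
  cat(sprintf("<section_slice> %s | %d levels x %d stations over %.0f m\n",
              x$parameter, nrow(x$values), ncol(x$values),
              max(x$distance)))
  invisible(x)
}

#' Export a field as CSV / Esri ASCII
#'
#' `write_field_asc` writes the value matrix of a `field_2d` as an Esri ASCII
#' grid; `write_section_csv` writes a section as a depth x distance matrix
#' with headers.
#' @export
write_field_asc <- function(field, path) {
  g <- elevation_grid(field$values, field$origin, field$cell_size)
  write_asc(g, path)
}

#' @rdname write_field_asc
#' @export
write_section_csv <- function(section, path) {
  m <- as.data.frame(section$values)
  names(m) <- sprintf("d%.1fm", section$distance)
  m <- cbind(depth_m = section$depth_levels, m)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
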