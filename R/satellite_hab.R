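#' Multiband reflectance scene
#'
#' Container for Rayleigh-corrected reflectance (R_rc, dimensionless) from an
#' ocean-colour sensor, one 2-D array per band wavelength, on the same raster
#' geometry as [elevation_grid()]. Typical band sets: MODIS 645/859/1240 nm,
#' Sentinel-2 MSI 665/865/1610 nm.
#'
#' @param bands named list of numeric matrices; names are band wavelengths in
#'   nm (e.g. `"645"`). All bands must share dimensions.
#' @param origin,cell_size raster geometry as in [elevation_grid()].
#' @param timestamp acquisition time.
#' @param sensor_label free-text sensor tag.
#' @return an object of class `multiband_scene`.
#' @export
multiband_scene <- function(bands, origin, cell_size, timestamp = Sys.time(),
                            sensor_label = "") {
  if (!length(bands) || is.null(names(bands)))
    stop("`bands` must be a named list (names = wavelength in nm)")
  wl <- as.numeric(names(bands))
  if (anyNA(wl) || any(wl <= 0)) stop("band names must be positive wavelengths in nm")
  d <- dim(bands[[1]])
  for (b in bands) {
    if (!identical(dim(b), d)) stop("all bands must share the same shape")
    if (any(is.infinite(b))) stop("reflectance must be finite or NA")
  }
  structure(
    list(bands = bands, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), timestamp = as_utc(timestamp),
         sensor_label = sensor_label),
    class = "multiband_scene"
  )
}

#' @export
print.multiband_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<multiband_scene> %s | %d x %d px @ %g m | bands: %s nm\n",
              x$sensor_label, d[1], d[2], x$cell_size,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

scene_band <- function(scene, nm) {
  i <- match(as.character(nm), names(scene$bands))
  if (is.na(i)) {
    # tolerate numeric formatting differences
    i <- which(abs(as.numeric(names(scene$bands)) - nm) < 0.5)[1]
  }
  if (is.na(i)) stop(sprintf("scene has no band at %g nm", nm))
  scene$bands[[i]]
}

#' Floating Algae Index (FAI)
#'
#' Linear-baseline subtraction across red/NIR/SWIR: the NIR reflectance is
#' compared against the chord drawn from the red to the SWIR band,
#' \deqn{FAI = R_{NIR} - R_{red} - (R_{SWIR} - R_{red})
#'   \frac{\lambda_{NIR} - \lambda_{red}}{\lambda_{SWIR} - \lambda_{red}},}
#' which is insensitive to a constant offset across the three bands and zero
#' whenever the NIR reflectance lies on the red--SWIR chord. Floating
#' cyanobacterial scums raise NIR reflectance well above the chord, giving
#' strongly positive FAI over blooms. Default wavelengths are the MODIS set.
#'
#' @param scene a [multiband_scene()].
#' @param red_nm,nir_nm,swir_nm band wavelengths to use; must satisfy
#'   red < NIR < SWIR and be present in the scene.
#' @return an object of class `fai_grid` (values, geometry, wavelengths).
#' @export
compute_fai <- function(scene, red_nm = 645, nir_nm = 859, swir_nm = 1240) {
  stopifnot(inherits(scene, "multiband_scene"))
  if (!(red_nm < nir_nm && nir_nm < swir_nm))
    stop("wavelengths must satisfy red < NIR < SWIR")
  r <- scene_band(scene, red_nm)
  n <- scene_band(scene, nir_nm)
  s <- scene_band(scene, swir_nm)
  fai <- n - r - (s - r) * (nir_nm - red_nm) / (swir_nm - red_nm)
  structure(
    list(values = fai, origin = scene$origin, cell_size = scene$cell_size,
         wavelengths = c(red = red_nm, nir = nir_nm, swir = swir_nm),
         index = "fai", timestamp = scene$timestamp,
         sensor_label = scene$sensor_label),
    class = "fai_grid"
  )
}

#' NDVI-style two-band bloom index
#'
#' Fallback for sensors without a SWIR band (e.g. GOCI), computed as the
#' normalised difference (NIR - red) / (NIR + red) and exposed behind the same
#' grid contract as [compute_fai()]; results are labelled `"ndvi"` so summaries
#' never silently mix the two indices.
#'
#' @inheritParams compute_fai
#' @return a `fai_grid` with `index = "ndvi"`.
#' @export
compute_ndvi <- function(scene, red_nm = 645, nir_nm = 859) {
  stopifnot(inherits(scene, "multiband_scene"), red_nm < nir_nm)
  r <- scene_band(scene, red_nm)
  n <- scene_band(scene, nir_nm)
  structure(
    list(values = (n - r) / (n + r), origin = scene$origin,
         cell_size = scene$cell_size,
         wavelengths = c(red = red_nm, nir = nir_nm, swir = NA_real_),
         index = "ndvi", timestamp = scene$timestamp,
         sensor_label = scene$sensor_label),
    class = "fai_grid"
  )
}

#' @export
print.fai_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<fai_grid> index %s | %d x %d px | range [%.4g, %.4g]\n",
              x$index, nrow(x$values), ncol(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Threshold an index grid into a bloom mask
#'
#' Pixels with index value strictly above the threshold (and inside the water
#' mask, if given) are classified as HAB. `threshold = "otsu"` picks the
#' threshold per scene by Otsu's between-class variance maximisation over the
#' finite index values.
#'
#' @param fai a `fai_grid` from [compute_fai()] / [compute_ndvi()].
#' @param threshold finite scalar, or `"otsu"`.
#' @param water_mask optional logical matrix of the same shape restricting
#'   classification to water.
#' @return an object of class `hab_mask` (mask, threshold used, pixel size,
#'   area in km^2).
#' @export
classify_hab <- function(fai, threshold = 0, water_mask = NULL) {
  stopifnot(inherits(fai, "fai_grid"))
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(fai$values[is.finite(fai$values)])
  }
  if (!is.numeric(threshold) || !is.finite(threshold))
    stop("`threshold` must be a finite number or \"otsu\"")
  m <- !is.na(fai$values) & fai$values > threshold
  if (!is.null(water_mask)) {
    if (!identical(dim(water_mask), dim(fai$values)))
      stop("water_mask shape does not match the index grid")
    m <- m & water_mask
  }
  structure(
    list(mask = m, threshold = threshold, pixel_size = fai$cell_size,
         origin = fai$origin, area_km2 = sum(m) * fai$cell_size^2 / 1e6,
         index = fai$index, timestamp = fai$timestamp),
    class = "hab_mask"
  )
}

#' @export
print.hab_mask <- function(x, ...) {
  cat(sprintf("<hab_mask> %d bloom px @ %g m | %.4f km^2 | threshold %.4g (%s)\n",
              sum(x$mask), x$pixel_size, x$area_km2, x$threshold, x$index))
  invisible(x)
}

# Otsu's method on a 256-bin histogram of the supplied values
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values for Otsu thresholding")
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  w <- cumsum(h); mu <- cumsum(h * seq_len(nbins))
  tot <- w[nbins]; mt <- mu[nbins]
  w1 <- w[-nbins]; w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (mt * w1[valid] - tot * mu[-nbins][valid])^2 /
    (w1[valid] * w2[valid])
  br[which.max(bc) + 1L]
}

#' Automatic scene-level HAB monitoring
#'
#' The unattended satellite chain: compute the index (FAI when a SWIR band is
#' configured, NDVI fallback otherwise), threshold it, and append a one-row
#' summary (timestamp, sensor, index, bloom pixel count, area, threshold,
#' validity flag) suitable for a long-running results log. A scene of all
#' nodata still yields a row, flagged invalid.
#'
#' @param scene a [multiband_scene()].
#' @param config list with optional entries `red_nm`, `nir_nm`, `swir_nm`
#'   (set `swir_nm = NA` for the NDVI fallback), `threshold`, `water_mask`.
#' @param log optional existing summary data frame to append to.
#' @return list with `fai`, `mask`, `summary` (data frame, the log with one
#'   new row).
#' @export
run_scene_monitoring <- function(scene, config = list(), log = NULL) {
  red <- config$red_nm %||% 645
  nir <- config$nir_nm %||% 859
  swir <- if ("swir_nm" %in% names(config)) config$swir_nm else 1240
  fai <- if (is.null(swir) || is.na(swir)) compute_ndvi(scene, red, nir)
         else compute_fai(scene, red, nir, swir)
  mask <- classify_hab(fai, config$threshold %||% 0, config$water_mask)
  row <- data.frame(
    timestamp = format(scene$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
    sensor = scene$sensor_label, index = fai$index,
    pixels = sum(mask$mask), area_km2 = mask$area_km2,
    threshold = mask$threshold,
    valid = any(is.finite(fai$values)),
    stringsAsFactors = FALSE
  )
  list(fai = fai, mask = mask,
       summary = if (is.null(log)) row else rbind(log, row))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write multiband scenes as a band directory
#'
#' On disk a scene is a directory of one Esri ASCII grid per band
#' (`band_<nm>.asc`) plus `scene.json` carrying wavelengths, timestamp and
#' sensor label.
#' @param scene a [multiband_scene()].
#' @param dir directory path.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "multiband_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene$bands)) {
    g <- elevation_grid(scene$bands[[nm]], scene$origin, scene$cell_size)
    write_asc(g, file.path(dir, sprintf("band_%s.asc", nm)))
  }
  jsonlite::write_json(
    list(wavelengths_nm = as.numeric(names(scene$bands)),
         timestamp = format(scene$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
         sensor_label = scene$sensor_label),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  wl <- meta$wavelengths_nm
  bands <- stats::setNames(lapply(wl, function(nm) {
    read_asc(file.path(dir, sprintf("band_%s.asc", format(nm))))$values
  }), as.character(wl))
  g <- read_asc(file.path(dir, sprintf("band_%s.asc", format(wl[1]))))
  multiband_scene(bands, g$origin, g$cell_size,
                  timestamp = meta$timestamp, sensor_label = meta$sensor_label)
}
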