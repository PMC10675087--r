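#' Analytic basin DEM
#'
#' Synthetic watershed terrain with a known level-set shoreline: a cone
#' `z = slope * r` or a paraboloid `z = a * r^2` about the grid centre,
#' optionally capped at a rim elevation. Because the basin is analytic, the
#' shoreline radius at any water level L is known in closed form
#' (`r = L / slope`, resp. `r = sqrt(L / a)`), giving exact ground truth for
#' surface-extraction tests.
#'
#' @param shape c(rows, cols), each >= 101.
#' @param cell_size metres per cell (default 5).
#' @param basin "cone" or "paraboloid".
#' @param slope cone slope (rise per metre, default 0.01).
#' @param a paraboloid coefficient (default 1e-4).
#' @param rim_elevation cap applied outside the basin walls (default `Inf`,
#'   no cap).
#' @param origin map coordinates of the upper-left corner (default c(0, 0)
#'   places the basin centre at the grid midpoint).
#' @return list with `dem` (an [elevation_grid()]) and `truth`
#'   (basin parameters, centre, and `radius_at(level)` closure).
#' @export
make_basin_dem <- function(shape = c(201L, 201L), cell_size = 5,
                           basin = c("cone", "paraboloid"), slope = 0.01,
                           a = 1e-4, rim_elevation = Inf, origin = c(0, 0)) {
  basin <- match.arg(basin)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nr < 101L || nc < 101L) stop("basin grid must be at least 101 x 101")
  if (basin == "cone" && (!is.finite(slope) || slope <= 0))
    stop("cone slope must be > 0")
  if (basin == "paraboloid" && (!is.finite(a) || a <= 0))
    stop("paraboloid coefficient must be > 0")
  xs <- origin[1] + (seq_len(nc) - 0.5) * cell_size
  ys <- origin[2] - (seq_len(nr) - 0.5) * cell_size
  cx <- mean(range(xs)); cy <- mean(range(ys))
  r <- sqrt(outer(rep(1, nr), (xs - cx)^2) + outer((ys - cy)^2, rep(1, nc)))
  z <- if (basin == "cone") slope * r else a * r^2
  z <- pmin(z, rim_elevation)
  truth <- list(
    basin = basin, slope = slope, a = a, center = c(cx, cy),
    rim_elevation = rim_elevation,
    radius_at = if (basin == "cone") function(level) level / slope
                else function(level) sqrt(level / a)
  )
  list(dem = elevation_grid(z, origin, cell_size, crs_label = "synthetic metres"),
       truth = truth)
}

#' Synthetic multiband bloom scene
#'
#' Reflectance scene with exact FAI ground truth: the background is spectrally
#' flat (all bands equal), so FAI is identically zero outside blooms; inside
#' each elliptical patch the NIR band is raised by `uplift`, so FAI equals the
#' uplift there. The generating mask is returned as truth.
#'
#' @param geometry grid template (origin, cell_size, values shape).
#' @param wavelengths numeric, named or not, the band wavelengths in nm
#'   (default MODIS c(645, 859, 1240)); the NIR band is the middle one.
#' @param background flat background reflectance (default 0.05).
#' @param patches list of `list(center = c(x, y), radii = c(rx, ry),
#'   uplift = )` ellipses in map coordinates.
#' @param noise_sd per-pixel, per-band Gaussian noise (default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param timestamp,sensor_label scene metadata.
#' @return list with `scene` (a [multiband_scene()]) and `truth_mask`
#'   (logical matrix of bloom pixels).
#' @export
make_bloom_scene <- function(geometry, wavelengths = c(645, 859, 1240),
                             background = 0.05, patches = list(),
                             noise_sd = 0, seed = 1,
                             timestamp = "2021-09-17T05:00:00Z",
                             sensor_label = "synthetic-modis") {
  nr <- nrow(geometry$values); nc <- ncol(geometry$values)
  xs <- geometry$origin[1] + (seq_len(nc) - 0.5) * geometry$cell_size
  ys <- geometry$origin[2] - (seq_len(nr) - 0.5) * geometry$cell_size
  X <- outer(rep(1, nr), xs); Y <- outer(ys, rep(1, nc))
  mask <- matrix(FALSE, nr, nc)
  uplift_field <- matrix(0, nr, nc)
  for (p in patches) {
    if (!is.finite(p$uplift) || p$uplift <= 0) stop("patch uplift must be > 0")
    if (p$center[1] < min(xs) || p$center[1] > max(xs) ||
        p$center[2] < min(ys) || p$center[2] > max(ys))
      stop("bloom patch centre outside the scene")
    inside <- ((X - p$center[1]) / p$radii[1])^2 +
      ((Y - p$center[2]) / p$radii[2])^2 <= 1
    mask <- mask | inside
    uplift_field[inside] <- pmax(uplift_field[inside], p$uplift)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  bands <- lapply(seq_along(wavelengths), function(i) {
    b <- matrix(background, nr, nc)
    if (i == 2L) b <- b + uplift_field
    if (noise_sd > 0) b <- b + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    b
  })
  names(bands) <- as.character(wavelengths)
  list(scene = multiband_scene(bands, geometry$origin, geometry$cell_size,
                               timestamp = timestamp,
                               sensor_label = sensor_label),
       truth_mask = mask)
}

#' Synthetic camera frames with exact coverage truth
#'
#' Renders bloom as green-dominant connected blobs on blue-grey water. Blob
#' shapes come from a seeded sum of Gaussian bumps; the HAB mask is the top
#' `round(f * H * W)` pixels of that smooth field, so the true coverage
#' matches the scheduled fraction to within one pixel. Water pixels are
#' (70, 90, 110) RGB and bloom pixels (70, 170, 80), separable by green
#' excess by construction; optional Gaussian pixel noise is added on top.
#'
#' @param n number of frames.
#' @param size c(height, width), default c(64, 64).
#' @param fractions scheduled bloom fraction per frame in \[0, 1\] (recycled).
#' @param n_blobs Gaussian bumps per frame (default 4).
#' @param noise_sd 8-bit channel noise (default 0).
#' @param seed integer seed.
#' @param device_id,start_time,period_s frame metadata; timestamps advance by
#'   `period_s` per frame.
#' @return list of `list(frame = camera_frame, truth = logical matrix,
#'   fraction = scheduled fraction)`.
#' @export
make_camera_frames <- function(n, size = c(64L, 64L), fractions = 0.3,
                               n_blobs = 4L, noise_sd = 0, seed = 1,
                               device_id = "cam01",
                               start_time = "2021-07-01T10:00:00Z",
                               period_s = 1) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  fractions <- rep_len(fractions, n)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  t0 <- as_utc(start_time)
  water <- c(70, 90, 110); bloom <- c(70, 170, 80)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- stats::runif(n_blobs, 1, w); cy <- stats::runif(n_blobs, 1, h)
    sg <- stats::runif(n_blobs, min(h, w) / 8, min(h, w) / 4)
    X <- outer(rep(1, h), seq_len(w)); Y <- outer(seq_len(h), rep(1, w))
    fld <- matrix(0, h, w)
    for (b in seq_len(n_blobs))
      fld <- fld + exp(-(((X - cx[b])^2 + (Y - cy[b])^2) / (2 * sg[b]^2)))
    k <- round(fractions[i] * h * w)
    mask <- matrix(FALSE, h, w)
    if (k > 0) mask[order(fld, decreasing = TRUE)[seq_len(k)]] <- TRUE
    px <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      m <- matrix(water[ch], h, w)
      m[mask] <- bloom[ch]
      if (noise_sd > 0) m <- m + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      px[, , ch] <- pmin(pmax(m, 0), 255)
    }
    out[[i]] <- list(
      frame = camera_frame(px, device_id, t0 + (i - 1) * period_s),
      truth = mask, fraction = fractions[i])
  }
  out
}

#' Synthetic depth-profile station records
#'
#' Samples an analytic water-quality field `field_fun(x, y, depth)` at each
#' station, depth and time step (default: every 4 hours), emulating automatic
#' profiling stations. Optional Gaussian noise; the analytic field is the
#' ground truth for 3-D interpolation tests.
#'
#' @param sites data frame `station_id`, `x`, `y`.
#' @param depths sampling depths in metres (positive down).
#' @param field_fun function(x, y, depth) -> value.
#' @param parameter parameter label (default "chl_a").
#' @param start_time first sampling time.
#' @param span_h monitored span in hours (default 24; times are
#'   `start + 0, interval, ...` strictly inside the span).
#' @param interval_h sampling interval in hours (default 4).
#' @param noise_sd record noise (default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return data frame `station_id`, `timestamp`, `depth_m`, `parameter`,
#'   `value`.
#' @export
make_station_profiles <- function(sites, depths = c(0.5, 1, 1.5, 2),
                                  field_fun = function(x, y, d) 2 + 3 * d,
                                  parameter = "chl_a",
                                  start_time = "2021-07-01T00:00:00Z",
                                  span_h = 24, interval_h = 4,
                                  noise_sd = 0, seed = 1) {
  stopifnot(all(c("station_id", "x", "y") %in% names(sites)))
  t0 <- as_utc(start_time)
  times <- t0 + 3600 * seq(0, span_h - interval_h, by = interval_h)
  grid <- expand.grid(si = seq_len(nrow(sites)), depth = depths,
                      ti = seq_along(times))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  val <- mapply(function(si, d) field_fun(sites$x[si], sites$y[si], d),
                grid$si, grid$depth)
  if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, noise_sd)
  data.frame(
    station_id = sites$station_id[grid$si],
    timestamp = format(times[grid$ti], "%Y-%m-%dT%H:%M:%SZ"),
    depth_m = grid$depth, parameter = parameter, value = val,
    stringsAsFactors = FALSE)
}

#' Synthetic hourly water-level records
#'
#' Hourly readings for several gauging stations: a shared deterministic tide
#' (sinusoidal) plus per-station offsets that sum to zero, so the cross-
#' station mean at any hour equals the known true level exactly.
#'
#' @param n_stations number of stations (default 3).
#' @param base_level mean level in metres (default 2).
#' @param amplitude tide amplitude in metres (default 0.1).
#' @param start_time,hours series start and length.
#' @param station_spread max absolute per-station offset (default 0.05 m).
#' @return list with `records` data frame (`station_id`, `timestamp`,
#'   `level`) and `truth` (`level_at(time)` closure).
#' @export
make_water_levels <- function(n_stations = 3, base_level = 2, amplitude = 0.1,
                              start_time = "2021-07-01T00:00:00Z", hours = 24,
                              station_spread = 0.05) {
  t0 <- as_utc(start_time)
  times <- t0 + 3600 * (seq_len(hours) - 1)
  off <- if (n_stations > 1) {
    o <- seq(-station_spread, station_spread, length.out = n_stations)
    o - mean(o)
  } else 0
  level_at <- function(at) {
    h <- as.numeric(difftime(as_utc(at), t0, units = "hours"))
    base_level + amplitude * sin(2 * pi * h / 12.42)
  }
  recs <- expand.grid(s = seq_len(n_stations), ti = seq_along(times))
  list(
    records = data.frame(
      station_id = sprintf("WL%02d", recs$s),
      timestamp = format(times[recs$ti], "%Y-%m-%dT%H:%M:%SZ"),
      level = level_at(times[recs$ti]) + off[recs$s],
      stringsAsFactors = FALSE),
    truth = list(base_level = base_level, amplitude = amplitude,
                 level_at = level_at))
}

#' Shoreline camera sites on an analytic basin
#'
#' Places `n` device sites evenly around the analytic shoreline circle of a
#' basin fixture, `margin_m` inside the waterline (cameras observe the water
#' just off their shore segment).
#'
#' @param basin a [make_basin_dem()] result.
#' @param level water level defining the shoreline.
#' @param n number of sites (default 42, one every few hundred metres on the
#'   synthetic lake; real guidance is one device per ~5 km of shoreline).
#' @param margin_m inward offset from the analytic shoreline (default 2 cell
#'   sizes).
#' @return data frame `device_id`, `x`, `y`.
#' @export
make_shoreline_sites <- function(basin, level, n = 42,
                                 margin_m = 2 * basin$dem$cell_size) {
  r <- basin$truth$radius_at(level) - margin_m
  if (r <= 0) stop("margin exceeds the shoreline radius")
  th <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(device_id = sprintf("cam%02d", seq_len(n)),
             x = basin$truth$center[1] + r * cos(th),
             y = basin$truth$center[2] + r * sin(th),
             stringsAsFactors = FALSE)
}

#' Gaussian-bump scalar field
#'
#' Closure `f(x, y) = base + amplitude * exp(-((x-cx)^2+(y-cy)^2)/(2 sigma^2))`
#' used as analytic truth for kriging-recovery tests.
#' @param center c(x, y); @param sigma metres; @param amplitude,base levels.
#' @return function(x, y).
#' @export
bump_field <- function(center, sigma, amplitude = 1, base = 0) {
  force(center); force(sigma); force(amplitude); force(base)
  function(x, y) {
    base + amplitude * exp(-((x - center[1])^2 + (y - center[2])^2) /
                             (2 * sigma^2))
  }
}

#' Generate and write a complete input bundle
#'
#' One call that materialises every input the pipeline reads, at the default
#' deployment scale (42 shoreline cameras, 8 water-quality stations, 3 level
#' stations), plus a `truth.json` describing the generating parameters. The
#' same seed reproduces the bundle bit-identically.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @param shape,cell_size,slope DEM parameters (cone basin).
#' @param level nominal water level (default 2 m).
#' @param n_cameras,n_stations,n_level_stations deployment counts.
#' @param frames_per_camera frames generated per camera (default 3).
#' @param frame_noise_sd,scene_noise_sd,station_noise_sd noise levels
#'   (default 0: noiseless ground truth).
#' @return invisible list of written paths plus the in-memory objects.
#' @export
make_fixture_bundle <- function(dir, seed = 1, shape = c(151L, 151L),
                                cell_size = 5, slope = 0.01, level = 2,
                                n_cameras = 42, n_stations = 8,
                                n_level_stations = 3, frames_per_camera = 3,
                                frame_noise_sd = 0, scene_noise_sd = 0,
                                station_noise_sd = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed) %% .Machine$integer.max

  basin <- make_basin_dem(shape, cell_size, "cone", slope = slope)
  write_asc(basin$dem, file.path(dir, "dem.asc"))

  wl <- make_water_levels(n_level_stations, base_level = level)
  utils::write.csv(wl$records, file.path(dir, "water_levels.csv"),
                   row.names = FALSE)

  # bathymetry: subsampled wet cell centres of the analytic basin
  wet <- which(basin$dem$values <= level * 1.2, arr.ind = TRUE)
  stride <- max(1L, floor(nrow(wet) / 600))
  pick <- wet[seq(1, nrow(wet), by = stride), , drop = FALSE]
  bathy <- data.frame(
    x = basin$dem$origin[1] + (pick[, 2] - 0.5) * cell_size,
    y = basin$dem$origin[2] - (pick[, 1] - 0.5) * cell_size,
    z = basin$dem$values[pick])
  utils::write.csv(bathy, file.path(dir, "bathymetry.csv"), row.names = FALSE)

  ctr <- basin$truth$center
  r_shore <- basin$truth$radius_at(level)
  bloom <- make_bloom_scene(
    basin$dem,
    patches = list(list(center = ctr + c(r_shore / 3, 0),
                        radii = c(r_shore / 3, r_shore / 4), uplift = 0.05)),
    noise_sd = scene_noise_sd, seed = seed + 101L)
  write_scene(bloom$scene, file.path(dir, "scene"))

  sites <- make_shoreline_sites(basin, level, n_cameras)
  utils::write.csv(sites, file.path(dir, "camera_sites.csv"), row.names = FALSE)
  frames_dir <- file.path(dir, "frames")
  dir.create(frames_dir, showWarnings = FALSE)
  truths_dir <- file.path(dir, "frame_truth")
  dir.create(truths_dir, showWarnings = FALSE)
  set.seed(seed + 202L)
  cam_fracs <- stats::runif(n_cameras, 0.05, 0.6)
  for (i in seq_len(n_cameras)) {
    fr <- make_camera_frames(
      frames_per_camera, fractions = cam_fracs[i],
      noise_sd = frame_noise_sd, seed = seed + 300L + i,
      device_id = sites$device_id[i],
      start_time = "2021-07-01T10:00:00Z")
    for (f in fr) {
      stamp <- format(f$frame$timestamp, "%Y-%m-%dT%H-%M-%SZ")
      write_frame_png(f$frame, file.path(
        frames_dir, sprintf("%s_%s.png", f$frame$device_id, stamp)))
      png::writePNG(f$truth * 1, file.path(
        truths_dir, sprintf("%s_%s.png", f$frame$device_id, stamp)))
    }
  }

  set.seed(seed + 404L)
  th <- stats::runif(n_stations, 0, 2 * pi)
  rr <- sqrt(stats::runif(n_stations, 0.05, 0.8)) * r_shore
  st_sites <- data.frame(station_id = sprintf("WQ%02d", seq_len(n_stations)),
                         x = ctr[1] + rr * cos(th), y = ctr[2] + rr * sin(th),
                         stringsAsFactors = FALSE)
  utils::write.csv(st_sites, file.path(dir, "station_sites.csv"),
                   row.names = FALSE)
  profiles <- make_station_profiles(
    st_sites, depths = c(0.5, 1, 1.5, 2),
    noise_sd = station_noise_sd, seed = seed + 505L)
  utils::write.csv(profiles, file.path(dir, "station_records.csv"),
                   row.names = FALSE)

  truth <- list(
    seed = seed, basin = "cone", slope = slope, cell_size = cell_size,
    shape = shape, level = level, center = ctr,
    shoreline_radius_m = r_shore,
    depth_field = "chl_a = 2 + 3 * depth_m",
    camera_fractions = stats::setNames(as.list(cam_fracs), sites$device_id),
    n_cameras = n_cameras, n_stations = n_stations,
    n_level_stations = n_level_stations)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, basin = basin, water_levels = wl,
                 bathymetry = bathy, scene = bloom, sites = sites,
                 station_sites = st_sites, profiles = profiles, truth = truth))
}
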