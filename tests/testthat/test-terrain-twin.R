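test_that("mean water level averages the latest record per station in the window", {
  at <- "2021-07-01T12:00:00Z"
  r3 <- rbind(wl_rec("a", at, 8.0), wl_rec("b", at, 8.2), wl_rec("c", at, 8.4))
  expect_equal(mean_water_level(r3, at), 8.2)
  expect_equal(mean_water_level(wl_rec("a", at, 7.5), at), 7.5)

  # station b last reported 3 h ago; with a 1 h window only station a counts
  r2 <- rbind(wl_rec("a", "2021-07-01T12:00:00Z", 8.0),
              wl_rec("b", "2021-07-01T09:00:00Z", 8.6))
  expect_equal(mean_water_level(r2, at, window_hours = 1), 8.0)
  # with a wide window both stations count, each at its latest reading
  expect_equal(mean_water_level(r2, at, window_hours = 6), 8.3)
  # per-station latest: stale readings of a reporting station are ignored
  r4 <- rbind(wl_rec("a", "2021-07-01T11:00:00Z", 9.9),
              wl_rec("a", "2021-07-01T12:00:00Z", 8.0))
  expect_equal(mean_water_level(r4, at), 8.0)

  expect_error(mean_water_level(r2, "2021-07-02T12:00:00Z", window_hours = 1),
               "stale")
})

test_that("lake surface on the cone basin matches the analytic level set", {
  b <- small_cone()
  s <- determine_lake_surface(b$dem, 2, b$truth$center)
  expect_s3_class(s, "lake_surface")
  # area identity holds exactly
  expect_identical(s$area_km2, sum(s$mask) * 25 / 1e6)
  # analytic disc: pi * 200^2 / 1e6 km^2
  expect_lt(abs(s$area_km2 - pi * 0.04) / (pi * 0.04), 0.02)
  # boundary ~ circle of radius 200 m
  r <- sqrt((s$boundary[[1]]$x - b$truth$center[1])^2 +
              (s$boundary[[1]]$y - b$truth$center[2])^2)
  expect_lt(abs(mean(r) - 200) / 200, 0.015)
  # every wet cell is at or below the level
  expect_true(all(b$dem$values[s$mask] <= 2))
})

test_that("surface extraction rejects dry or out-of-grid seeds", {
  flat <- elevation_grid(matrix(10, 20, 20), c(0, 200), 10)
  expect_error(determine_lake_surface(flat, 9, c(100, 100)), "dry seed")
  b <- small_cone()
  expect_error(determine_lake_surface(b$dem, 2, c(1e6, 1e6)), "outside")
})

test_that("flood fill keeps only the seeded basin", {
  dem <- two_basin_dem()
  # seed in basin A (cell centre of row 3, col 3: x=25, y=75)
  s <- determine_lake_surface(dem, 2, c(25, 75))
  expect_equal(sum(s$mask), 9L)
  expect_true(all(which(s$mask, arr.ind = TRUE)[, "row"] <= 4))
  # seed in basin B picks up the other component only
  s2 <- determine_lake_surface(dem, 2, c(75, 25))
  expect_equal(sum(s2$mask), 9L)
  expect_true(all(which(s2$mask, arr.ind = TRUE)[, "row"] >= 7))
})

test_that("level-set masks are monotone in the water level", {
  b <- small_cone()
  levels <- c(0.5, 1, 1.5, 2)
  masks <- lapply(levels, function(L)
    determine_lake_surface(b$dem, L, b$truth$center)$mask)
  for (i in seq_len(length(levels) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]))   # L1 <= L2 => mask1 in mask2
  }
  areas <- vapply(levels, function(L)
    determine_lake_surface(b$dem, L, b$truth$center)$area_km2, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("underwater mesh triangulates and interpolates exactly", {
  # unit square, flat bed: 2 triangles, all z = 0
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  m <- build_underwater_mesh(sq)
  expect_equal(nrow(m$faces), 2L)
  expect_true(all(m$vertices[, 3] == 0))

  # linear interpolation is exact on a plane z = x + 2y
  set.seed(11)
  pts <- data.frame(x = runif(80, 0, 100), y = runif(80, 0, 100))
  pts$z <- pts$x + 2 * pts$y
  m2 <- build_underwater_mesh(pts)
  qx <- runif(25, 20, 80); qy <- runif(25, 20, 80)
  expect_lt(max(abs(mesh_interpolate(m2, qx, qy) - (qx + 2 * qy))), 1e-9)
  # mesh reproduces every input height at input locations
  expect_lt(max(abs(mesh_interpolate(m2, pts$x, pts$y) - pts$z)), 1e-9)

  expect_error(build_underwater_mesh(
    data.frame(x = 1:3, y = 2 * (1:3), z = 0)), "collinear")
  expect_error(build_underwater_mesh(sq[1:2, ]), "at least 3")
})

test_that("merge rules: mend fills the annulus, clip drops emergent land", {
  b <- small_cone()
  level <- 2
  s <- determine_lake_surface(b$dem, level, b$truth$center)

  # bathymetry only out to r = 150 m inside a 200 m lake -> mend
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  ring <- expand.grid(r = c(30, 80, 150), th = th)
  pts <- data.frame(x = b$truth$center[1] + ring$r * cos(ring$th),
                    y = b$truth$center[2] + ring$r * sin(ring$th))
  pts$z <- 0.01 * ring$r
  pts <- rbind(pts, data.frame(x = b$truth$center[1], y = b$truth$center[2], z = 0))
  mesh <- build_underwater_mesh(pts)
  tw <- merge_twin(s, mesh, b$dem, "2021-07-01T00:00:00Z")
  expect_true("mend" %in% tw$provenance)
  # merged footprint covers (essentially all of) the wetted area
  wet <- which(s$mask, arr.ind = TRUE)
  cx <- s$origin[1] + (wet[, 2] - 0.5) * s$cell_size
  cy <- s$origin[2] - (wet[, 1] - 0.5) * s$cell_size
  expect_gte(mean(twinlake:::mesh_covers(tw$underwater, cx, cy)), 0.99)

  # vertices above the level get clipped; none survive
  pts2 <- pts
  pts2$z[which.max(pts2$x)] <- level + 1
  tw2 <- merge_twin(s, build_underwater_mesh(pts2), b$dem)
  expect_true("clip" %in% tw2$provenance)
  expect_lte(max(tw2$underwater$vertices[, 3]), level + 1e-9)

  # no-op: mesh of all wet cell centres, everything submerged
  full <- data.frame(x = cx, y = cy, z = b$dem$values[wet])
  mesh3 <- build_underwater_mesh(full)
  tw3 <- merge_twin(s, mesh3, b$dem)
  expect_identical(tw3$provenance, character(0))
  expect_identical(tw3$underwater, mesh3)

  # mesh entirely above the level is an error
  dry <- data.frame(x = c(0, 50, 25), y = c(0, 0, 40), z = level + 5)
  expect_error(merge_twin(s, terrain_mesh(as.matrix(dry), rbind(1:3)),
                          b$dem), "above water level")
})

test_that("refresh_twin is deterministic and respects rising levels", {
  b <- small_cone()
  wl <- make_water_levels(3, base_level = 1.5, amplitude = 0)
  wet <- which(b$dem$values <= 2, arr.ind = TRUE)
  pick <- wet[seq(1, nrow(wet), by = 7), ]
  bathy <- data.frame(
    x = b$dem$origin[1] + (pick[, 2] - 0.5) * 5,
    y = b$dem$origin[2] - (pick[, 1] - 0.5) * 5,
    z = b$dem$values[pick])
  at <- "2021-07-01T12:00:00Z"
  t1 <- refresh_twin(b$dem, bathy, wl$records, at, b$truth$center)
  t2 <- refresh_twin(b$dem, bathy, wl$records, at, b$truth$center)
  expect_identical(t1$underwater, t2$underwater)
  expect_identical(t1$surface$mask, t2$surface$mask)
  expect_equal(t1$level, 1.5)

  # a higher stage enlarges the surface and contains the lower one
  wl2 <- make_water_levels(3, base_level = 1.9, amplitude = 0)
  t3 <- refresh_twin(b$dem, bathy, wl2$records, at, b$truth$center)
  expect_gt(t3$surface$area_km2, t1$surface$area_km2)
  expect_true(all(t3$surface$mask[t1$surface$mask]))
})

test_that("shoreline radius converges to L/slope as the grid refines", {
  for (cs in c(10, 5)) {
    n <- as.integer(2 * ceiling(600 / cs) + 1)
    b <- make_basin_dem(c(n, n), cs, "cone", slope = 0.01)
    s <- determine_lake_surface(b$dem, 2, b$truth$center)
    r <- sqrt((s$boundary[[1]]$x - b$truth$center[1])^2 +
                (s$boundary[[1]]$y - b$truth$center[2])^2)
    expect_lt(abs(mean(r) - 200) / 200, cs / 200 + 0.01)
  }
})
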