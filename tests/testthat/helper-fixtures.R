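# Shared small fixtures, built in code at test time.

# 101x101 cone basin at 5 m cells: shoreline radius = level / 0.01
small_cone <- function() make_basin_dem(c(101L, 101L), 5, "cone", slope = 0.01)

# hand-built 10x10 DEM with two depressions separated by a ridge
two_basin_dem <- function() {
  z <- matrix(10, 10, 10)
  z[2:4, 2:4] <- 1       # basin A (rows 2-4, cols 2-4)
  z[7:9, 7:9] <- 1       # basin B
  elevation_grid(z, origin = c(0, 100), cell_size = 10)
}

# water-level record helper
wl_rec <- function(station, iso, level) {
  data.frame(station_id = station, timestamp = iso, level = level,
             stringsAsFactors = FALSE)
}

# flat multiband scene with constant reflectance per band
flat_scene <- function(r, n, s, dim = c(8L, 8L), wl = c(645, 859, 1240)) {
  bands <- list(matrix(r, dim[1], dim[2]), matrix(n, dim[1], dim[2]),
                matrix(s, dim[1], dim[2]))
  names(bands) <- as.character(wl)
  multiband_scene(bands, c(0, 0), 250, timestamp = "2021-09-17T05:00:00Z",
                  sensor_label = "test")
}
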