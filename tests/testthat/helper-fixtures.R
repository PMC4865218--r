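# Shared small fixtures. Geometry objects cache their system matrix, so the
# helpers memoize them in this environment to keep the suite fast.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_geometry <- function() {
  fixture("geom32", function() {
    fanbeam_geometry(detector_count = 64, view_count = 40, grid_n = 32, fov = 32)
  })
}

mid_geometry <- function() {
  fixture("geom64", function() {
    fanbeam_geometry(detector_count = 128, view_count = 60, grid_n = 64, fov = 32)
  })
}

test_spectrum <- function(total = 1e7) {
  make_spectrum(seq(30, 120, length.out = 9), model = "parametric",
                total_photons = total)
}

single_bin_spectrum <- function(total = 1e6) {
  make_spectrum(c(55, 65), model = "uniform", total_photons = total)
}

# Deterministic pseudo-random stream identical across languages: a small
# multiplicative LCG that stays exact in double precision.
lcg_uniform <- function(seed, n) {
  x <- numeric(n)
  s <- seed
  for (i in seq_len(n)) {
    s <- (69069 * s + 1) %% 2147483648
    x[i] <- s / 2147483648
  }
  x
}

# Water-only disk phantom as a spectral image on a geometry grid.
disk_phantom <- function(geometry, radius = 10, value = 0.02) {
  n <- geometry$grid_n
  px <- geometry$pixel_size
  h <- geometry$fov / 2
  xs <- (col(matrix(0, n, n)) - 0.5) * px - h
  ys <- h - (row(matrix(0, n, n)) - 0.5) * px
  img <- matrix(0, n, n)
  img[xs^2 + ys^2 <= radius^2] <- value
  img
}

# Physical pixel-center radii from the iso-center.
pixel_radii <- function(geometry) {
  n <- geometry$grid_n
  px <- geometry$pixel_size
  h <- geometry$fov / 2
  xs <- (col(matrix(0, n, n)) - 0.5) * px - h
  ys <- h - (row(matrix(0, n, n)) - 0.5) * px
  sqrt(xs^2 + ys^2)
}
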