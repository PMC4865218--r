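# Run code with a private RNG stream, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normalized pixel-center coordinates: x right, y up, both in [-1, 1].
pixel_grid <- function(n) {
  x <- ((seq_len(n) - 0.5) / n) * 2 - 1
  list(x = matrix(x, n, n, byrow = TRUE),
       y = matrix(rev(x), n, n, byrow = FALSE))
}

in_ellipse <- function(gx, gy, cx, cy, a, b, angle = 0) {
  dx <- gx - cx
  dy <- gy - cy
  if (angle != 0) {
    co <- cos(angle); si <- sin(angle)
    tmp <- dx * co + dy * si
    dy <- -dx * si + dy * co
    dx <- tmp
  }
  (dx / a)^2 + (dy / b)^2 <= 1
}

#' Synthetic abdomen phantom (material fraction maps)
#'
#' Builds a parametric stand-in for an abdominal cross-section as two
#' material fraction maps: an elliptical water body with smooth soft-tissue
#' texture, and a spine plus rib-like set of bone ellipses. Outside the body
#' the maps are zero (air). The construction is fully deterministic given
#' `seed`; the texture bump positions, amplitudes and the number of rib
#' ellipses (body + 2 to 4 bone ellipses in total) are drawn from the seeded
#' generator.
#'
#' @param grid_size Image side in pixels, `>= 32`.
#' @param seed Integer seed controlling the random texture and rib layout.
#' @return Object of class `material_maps`: list with `water`, `bone`,
#'   `gadolinium` fraction matrices (values in `[0, 1]`) and `grid_n`.
#' @export
make_abdomen_phantom <- function(grid_size = 256, seed = 1) {
  if (grid_size < 32) stop("make_abdomen_phantom: grid_size must be >= 32", call. = FALSE)
  n <- as.integer(grid_size)
  g <- pixel_grid(n)
  body <- in_ellipse(g$x, g$y, 0, -0.05, 0.80, 0.60)
  with_local_seed(seed, {
    water <- matrix(1, n, n)
    n_bumps <- 6L
    for (b in seq_len(n_bumps)) {
      cx <- stats::runif(1, -0.5, 0.5)
      cy <- stats::runif(1, -0.45, 0.35)
      amp <- stats::runif(1, -0.06, 0.06)
      sig <- stats::runif(1, 0.08, 0.20)
      water <- water + amp * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sig^2))
    }
    water[!body] <- 0
    water <- pmin(pmax(water, 0), 1)

    bone <- matrix(0, n, n)
    spine <- in_ellipse(g$x, g$y, 0, -0.38, 0.13, 0.11)
    marrow <- in_ellipse(g$x, g$y, 0, -0.38, 0.06, 0.05)
    bone[spine] <- 0.95
    bone[marrow] <- 0.40
    n_ribs <- sample(1:3, 1)
    for (r in seq_len(n_ribs)) {
      side <- if (r %% 2 == 0) 1 else -1
      cy <- stats::runif(1, -0.05, 0.25)
      rib <- in_ellipse(g$x, g$y, side * stats::runif(1, 0.52, 0.62), cy,
                        0.05, 0.16, angle = side * stats::runif(1, 0.2, 0.5))
      bone[rib & body] <- pmax(bone[rib & body], 0.85)
    }
    bone[!body] <- 0
    water <- water * (1 - bone)
    structure(
      list(water = water, bone = bone,
           gadolinium = matrix(0, n, n), grid_n = n),
      class = "material_maps"
    )
  })
}

#' @export
print.material_maps <- function(x, ...) {
  cat(sprintf("<material_maps> %dx%d: water %d px, bone %d px, gadolinium %d px\n",
              x$grid_n, x$grid_n, sum(x$water > 0), sum(x$bone > 0),
              sum(x$gadolinium > 0)))
  invisible(x)
}

#' Default gadolinium contrast layout (four spots and one strip)
#'
#' Feature coordinates in pixels for [add_gadolinium_features()]: four
#' disjoint circular spots spread over the body and one horizontal strip
#' crossing the image center (and hence the central spectral FOV).
#'
#' @param grid_n Image side in pixels.
#' @return List with elements `spots` (list of `list(center = c(row, col),
#'   radius)`) and `strip` (`list(row, col_start, col_end, width)`).
#' @export
default_gd_layout <- function(grid_n) {
  n <- grid_n
  r <- max(2, round(n / 32))
  list(
    spots = list(
      list(center = c(round(n * 0.32), round(n * 0.38)), radius = r),
      list(center = c(round(n * 0.38), round(n * 0.68)), radius = r),
      list(center = c(round(n * 0.62), round(n * 0.25)), radius = r),
      list(center = c(round(n * 0.68), round(n * 0.62)), radius = r)
    ),
    strip = list(row = round(n * 0.52), col_start = round(n * 0.22),
                 col_end = round(n * 0.80), width = max(2, round(n / 40)))
  )
}

#' Add gadolinium contrast features to a phantom
#'
#' Sets the gadolinium fraction map on circular spots and/or a horizontal
#' strip, leaving the water and bone maps unchanged. Coordinates are in
#' pixels (row 1 at the top). Passing `NULL` for both arguments uses the
#' default four-spots-plus-strip layout of [default_gd_layout()]; pass empty
#' lists to add nothing.
#'
#' @param maps A `material_maps` object.
#' @param spots List of `list(center = c(row, col), radius)` in pixels.
#' @param strip `list(row, col_start, col_end, width)` in pixels, or `NULL`.
#' @param fraction Gadolinium fraction assigned to feature pixels.
#' @return The updated `material_maps`.
#' @export
add_gadolinium_features <- function(maps, spots = NULL, strip = NULL,
                                    fraction = 1) {
  stopifnot(inherits(maps, "material_maps"))
  n <- maps$grid_n
  if (is.null(spots) && is.null(strip)) {
    layout <- default_gd_layout(n)
    spots <- layout$spots
    strip <- layout$strip
  }
  gd <- maps$gadolinium
  rows <- row(gd)
  cols <- col(gd)
  for (s in (spots %||% list())) {
    ctr <- s$center
    if (any(ctr < 1) || any(ctr > n)) {
      stop("add_gadolinium_features: spot center outside image", call. = FALSE)
    }
    sel <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= s$radius^2
    gd[sel] <- fraction
  }
  if (!is.null(strip)) {
    if (strip$row < 1 || strip$row > n || strip$col_start < 1 ||
        strip$col_end > n || strip$col_start > strip$col_end) {
      stop("add_gadolinium_features: strip outside image", call. = FALSE)
    }
    half <- strip$width / 2
    sel <- abs(rows - strip$row) <= half &
      cols >= strip$col_start & cols <= strip$col_end
    gd[sel] <- fraction
  }
  maps$gadolinium <- gd
  maps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose per-bin mono-energy attenuation images
#'
#' Produces the multi-energy ground-truth image `X` (pixels x bins): each
#' column `k` is the mono-energy attenuation map at the bin center energy,
#' `X[, k] = sum_m fraction_m * mu_m(E_k)`, treating each narrow bin as
#' monochromatic at its center.
#'
#' @param maps A `material_maps` object.
#' @param spectrum An `xray_spectrum` (bin centers define the energies).
#' @param materials Named list of [material_spec()] objects for `water`,
#'   `bone` and (if used) `gadolinium`; defaults to [default_material()].
#' @return A `spectral_image`: numeric matrix of dimension
#'   `grid_n^2 x n_bins` (column-major pixel order) with attribute `grid_n`.
#' @export
compose_spectral_images <- function(maps, spectrum, materials = NULL) {
  stopifnot(inherits(maps, "material_maps"), inherits(spectrum, "xray_spectrum"))
  if (is.null(materials)) {
    materials <- list(water = default_material("water"),
                      bone = default_material("bone"),
                      gadolinium = default_material("gadolinium"))
  }
  n <- maps$grid_n
  M <- spectrum$n_bins
  X <- matrix(0, n * n, M)
  for (m in c("water", "bone", "gadolinium")) {
    frac <- maps[[m]]
    if (is.null(frac) || !any(frac > 0)) next
    mu <- material_mu(materials[[m]], spectrum$bin_centers)
    X <- X + outer(as.numeric(frac), mu)
  }
  structure(X, grid_n = n, bin_centers = spectrum$bin_centers,
            class = c("spectral_image", "matrix"))
}

#' Reshape one energy channel of a spectral image to the grid
#'
#' @param X A `spectral_image` (pixels x bins matrix).
#' @param bin Energy-bin index.
#' @return `grid_n` x `grid_n` matrix.
#' @export
channel_image <- function(X, bin) {
  n <- attr(X, "grid_n")
  if (is.null(n)) n <- as.integer(sqrt(nrow(X)))
  matrix(X[, bin], n, n)
}
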