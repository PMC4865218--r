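#' Fan-beam scan geometry
#'
#' Describes a 2D equiangular-in-space fan-beam system with a flat,
#' equi-spaced detector array: source and detector rotate together around the
#' iso-center, with `view_count` uniform view angles over `[0, 2*pi)`
#' (measured counter-clockwise from +x). The reconstruction grid is an
#' `grid_n` x `grid_n` pixel square of physical side `fov` cm centered at the
#' iso-center, pixel (1,1) at the top-left.
#'
#' @param source_to_iso Source-to-iso-center distance in cm.
#' @param iso_to_detector Iso-center-to-detector distance in cm.
#' @param detector_count Number of detector elements.
#' @param detector_length Total detector length in cm.
#' @param view_count Number of projection angles, uniform over 360 degrees.
#' @param grid_n Image grid size (pixels per side).
#' @param fov Physical image side length in cm. The inscribed circle of the
#'   image must fit inside the scan field of view defined by the fan.
#' @return Object of class `fanbeam_geometry`.
#' @export
fanbeam_geometry <- function(source_to_iso = 50, iso_to_detector = 50,
                             detector_count = 512, detector_length = 70,
                             view_count = 180, grid_n = 256, fov = 32) {
  if (source_to_iso <= 0 || iso_to_detector <= 0 || detector_count < 1 ||
      detector_length <= 0 || view_count < 1 || grid_n < 2 || fov <= 0) {
    stop("fanbeam_geometry: all lengths and counts must be positive", call. = FALSE)
  }
  sdd <- source_to_iso + iso_to_detector
  half_fan <- atan((detector_length / 2) / sdd)
  scan_radius <- source_to_iso * sin(half_fan)
  if (fov / 2 > scan_radius + 1e-9) {
    stop(sprintf(
      "fanbeam_geometry: image FOV (%.3g cm) exceeds the scan FOV (radius %.3g cm)",
      fov, scan_radius), call. = FALSE)
  }
  g <- list(
    source_to_iso = source_to_iso,
    iso_to_detector = iso_to_detector,
    detector_count = detector_count,
    detector_length = detector_length,
    view_count = view_count,
    view_angles = seq(0, 2 * pi, length.out = view_count + 1)[seq_len(view_count)],
    grid_n = grid_n,
    fov = fov,
    pixel_size = fov / grid_n,
    half_fan_angle = half_fan,
    scan_radius = scan_radius,
    n_rays = view_count * detector_count,
    cache = new.env(parent = emptyenv())
  )
  class(g) <- "fanbeam_geometry"
  g
}

#' Build a geometry from a configuration list
#'
#' Accepts a list (e.g. from [read_config()]) with any of the
#' [fanbeam_geometry()] argument names; missing entries take the defaults.
#'
#' @param config Named list of geometry parameters.
#' @return A `fanbeam_geometry`.
#' @export
build_geometry <- function(config = list()) {
  keep <- intersect(names(config), names(formals(fanbeam_geometry)))
  do.call(fanbeam_geometry, lapply(config[keep], as.numeric))
}

#' @export
print.fanbeam_geometry <- function(x, ...) {
  cat(sprintf(
    "<fanbeam_geometry> %d views x %d detectors (%.4g cm array), SID %.4g cm, SDD %.4g cm\n  grid %dx%d, FOV %.4g cm (pixel %.4g cm), scan radius %.4g cm\n",
    x$view_count, x$detector_count, x$detector_length, x$source_to_iso,
    x$source_to_iso + x$iso_to_detector, x$grid_n, x$grid_n, x$fov,
    x$pixel_size, x$scan_radius))
  invisible(x)
}

# Source and detector-element positions for one view angle.
ray_endpoints <- function(geometry, beta) {
  nd <- geometry$detector_count
  pitch <- geometry$detector_length / nd
  src <- geometry$source_to_iso * c(cos(beta), sin(beta))
  dc <- -geometry$iso_to_detector * c(cos(beta), sin(beta))
  u <- c(-sin(beta), cos(beta))
  t <- (seq_len(nd) - (nd + 1) / 2) * pitch
  list(src = src,
       det_x = dc[1] + t * u[1],
       det_y = dc[2] + t * u[2])
}

# Siddon ray tracing for one ray from (sx, sy) to (dx, dy) through the
# square grid; returns pixel indices (column-major) and intersection lengths.
siddon_ray <- function(sx, sy, dx, dy, n, h, px) {
  rx <- dx - sx
  ry <- dy - sy
  planes <- -h + (0:n) * px
  a0 <- 0
  a1 <- 1
  if (abs(rx) > 1e-12) {
    ax <- (planes - sx) / rx
    a0 <- max(a0, min(ax[1], ax[n + 1]))
    a1 <- min(a1, max(ax[1], ax[n + 1]))
  } else if (sx <= -h || sx >= h) {
    return(NULL)
  } else {
    ax <- numeric(0)
  }
  if (abs(ry) > 1e-12) {
    ay <- (planes - sy) / ry
    a0 <- max(a0, min(ay[1], ay[n + 1]))
    a1 <- min(a1, max(ay[1], ay[n + 1]))
  } else if (sy <= -h || sy >= h) {
    return(NULL)
  } else {
    ay <- numeric(0)
  }
  if (a0 >= a1) return(NULL)
  a <- c(a0, a1,
         if (length(ax)) ax[ax > a0 & ax < a1],
         if (length(ay)) ay[ay > a0 & ay < a1])
  a <- sort.int(unique(a))
  if (length(a) < 2) return(NULL)
  da <- diff(a)
  keep <- da > 1e-14
  if (!any(keep)) return(NULL)
  da <- da[keep]
  mid <- (a[-length(a)] + a[-1])[keep] / 2
  mx <- sx + mid * rx
  my <- sy + mid * ry
  col <- pmin(pmax(floor((mx + h) / px), 0), n - 1) + 1
  row <- pmin(pmax(floor((h - my) / px), 0), n - 1) + 1
  len <- da * sqrt(rx * rx + ry * ry)
  list(j = (col - 1L) * n + row, w = len)
}

#' Sparse fan-beam system matrix
#'
#' Materializes the full system matrix `A` (rays x pixels) whose entries
#' `a_ij` are the intersection lengths (cm) of ray `i` with pixel `j`,
#' computed by Siddon ray tracing. Rays are ordered view-major:
#' `ray = (view - 1) * detector_count + detector`. The matrix is cached on
#' the geometry object, so repeated calls are free.
#'
#' @param geometry A [fanbeam_geometry()].
#' @return A `dgCMatrix` of dimension `n_rays` x `grid_n^2`.
#' @export
system_matrix <- function(geometry) {
  stopifnot(inherits(geometry, "fanbeam_geometry"))
  if (!is.null(geometry$cache$A)) return(geometry$cache$A)
  n <- geometry$grid_n
  h <- geometry$fov / 2
  px <- geometry$pixel_size
  nd <- geometry$detector_count
  ii <- vector("list", geometry$n_rays)
  jj <- vector("list", geometry$n_rays)
  ww <- vector("list", geometry$n_rays)
  for (v in seq_len(geometry$view_count)) {
    ep <- ray_endpoints(geometry, geometry$view_angles[v])
    base <- (v - 1L) * nd
    for (d in seq_len(nd)) {
      tr <- siddon_ray(ep$src[1], ep$src[2], ep$det_x[d], ep$det_y[d], n, h, px)
      if (is.null(tr)) next
      k <- base + d
      ii[[k]] <- rep.int(k, length(tr$j))
      jj[[k]] <- tr$j
      ww[[k]] <- tr$w
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(ww),
    dims = c(geometry$n_rays, n * n)
  )
  geometry$cache$A <- A
  geometry$cache$At <- Matrix::t(A)
  A
}

# Cached transpose of the system matrix (for fast adjoints).
system_matrix_t <- function(geometry) {
  system_matrix(geometry)
  geometry$cache$At
}

#' Hybrid detector layout from the PCD-to-EID extent ratio
#'
#' The detector array hosts a single centered, contiguous photon-counting
#' module. `peer` is the ratio of PCD array length to EID array length, so
#' the PCD occupies a fraction `peer / (1 + peer)` of the array (rounded to
#' whole elements, kept symmetric about the center). The sentinel
#' `peer = "full"` flags every element as photon-counting.
#'
#' @param geometry A [fanbeam_geometry()].
#' @param peer Positive ratio, or `"full"`.
#' @return Object of class `hybrid_layout` with fields `peer`,
#'   `pcd_elements` (logical per detector element) and `pcd_count`.
#' @export
hybrid_layout <- function(geometry, peer = 1) {
  stopifnot(inherits(geometry, "fanbeam_geometry"))
  nd <- geometry$detector_count
  if (identical(peer, "full")) {
    mask <- rep(TRUE, nd)
    peer_val <- Inf
  } else {
    peer_val <- as.numeric(peer)
    if (!is.finite(peer_val) || peer_val <= 0) {
      stop("hybrid_layout: peer must be > 0 (or \"full\")", call. = FALSE)
    }
    m <- round(nd * peer_val / (1 + peer_val))
    m <- max(1L, min(nd, as.integer(m)))
    if ((nd - m) %% 2L == 1L && m < nd) m <- m + 1L
    start <- (nd - m) %/% 2L + 1L
    mask <- rep(FALSE, nd)
    mask[start:(start + m - 1L)] <- TRUE
  }
  structure(
    list(peer = peer_val, pcd_elements = mask, pcd_count = sum(mask)),
    class = "hybrid_layout"
  )
}

#' @export
print.hybrid_layout <- function(x, ...) {
  cat(sprintf("<hybrid_layout> PEER = %s: %d photon-counting elements (centered)\n",
              format(x$peer), x$pcd_count))
  invisible(x)
}

#' Ray mask of the photon-counting sub-array
#'
#' Logical vector over all rays (view-major order) that is `TRUE` exactly for
#' rays hitting the central PCD module in every view.
#'
#' @param geometry A [fanbeam_geometry()].
#' @param layout A [hybrid_layout()] (or a `peer` value passed through).
#' @return Logical vector of length `n_rays`.
#' @export
pcd_ray_mask <- function(geometry, layout) {
  if (!inherits(layout, "hybrid_layout")) layout <- hybrid_layout(geometry, layout)
  rep(layout$pcd_elements, times = geometry$view_count)
}

#' Radius of the spectral field of view
#'
#' The spectral FOV is the disc around the iso-center covered by the
#' photon-counting rays of every view; its radius follows from the half-width
#' of the PCD module seen from the source.
#'
#' @param geometry A [fanbeam_geometry()].
#' @param layout A [hybrid_layout()].
#' @return Radius in cm.
#' @export
spectral_fov_radius <- function(geometry, layout) {
  stopifnot(inherits(layout, "hybrid_layout"))
  pitch <- geometry$detector_length / geometry$detector_count
  half_width <- layout$pcd_count * pitch / 2
  sdd <- geometry$source_to_iso + geometry$iso_to_detector
  geometry$source_to_iso * sin(atan(half_width / sdd))
}

#' Forward projection (line integrals)
#'
#' Applies the system matrix to an attenuation image: for each (optionally
#' masked) ray `i`, returns `sum_j a_ij * mu_j` (dimensionless when `mu` is
#' in cm^-1 and `a_ij` in cm).
#'
#' @param image `grid_n` x `grid_n` matrix (or a vector of length
#'   `grid_n^2`, column-major).
#' @param geometry A [fanbeam_geometry()].
#' @param mask Optional logical ray mask (e.g. from [pcd_ray_mask()]).
#' @return Numeric vector of line integrals (all rays, or masked rays).
#' @export
forward_project <- function(image, geometry, mask = NULL) {
  x <- as.numeric(image)
  if (length(x) != geometry$grid_n^2) {
    stop("forward_project: image does not match the geometry grid", call. = FALSE)
  }
  A <- system_matrix(geometry)
  p <- as.numeric(A %*% x)
  if (is.null(mask)) return(p)
  if (length(mask) != geometry$n_rays) {
    stop("forward_project: mask length does not match ray count", call. = FALSE)
  }
  p[mask]
}

#' Back projection (adjoint of the forward projector)
#'
#' Exact adjoint of [forward_project()] through the shared sparse system
#' matrix: returns `A^T y` reshaped to the image grid. When a mask is given,
#' `ray_values` correspond to the masked rays and all other rays contribute
#' zero.
#'
#' @param ray_values Numeric vector of per-ray values.
#' @param geometry A [fanbeam_geometry()].
#' @param mask Optional logical ray mask.
#' @return `grid_n` x `grid_n` matrix.
#' @export
back_project <- function(ray_values, geometry, mask = NULL) {
  At <- system_matrix_t(geometry)
  if (is.null(mask)) {
    y <- ray_values
    if (length(y) != geometry$n_rays) {
      stop("back_project: ray_values length does not match ray count", call. = FALSE)
    }
  } else {
    if (length(ray_values) != sum(mask)) {
      stop("back_project: ray_values length does not match mask", call. = FALSE)
    }
    y <- numeric(geometry$n_rays)
    y[mask] <- ray_values
  }
  matrix(as.numeric(At %*% y), geometry$grid_n, geometry$grid_n)
}
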