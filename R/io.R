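#' Read a plain key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical; everything else stays character.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) {
      stop(sprintf("read_config: cannot parse line '%s'", ln), call. = FALSE)
    }
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  out
}

#' Export an image stack as a multi-page TIFF
#'
#' One 32-bit page per energy bin. Values already inside `[0, 1]` (such as
#' attenuation maps in cm^-1 at diagnostic energies) are written unscaled;
#' otherwise the stack is min-max scaled into `[0, 1]` and the affine
#' transform is recorded in a `<path>.scale.txt` sidecar so physical values
#' can be restored. Requires the `tiff` package.
#'
#' @param X A `spectral_image` (pixels x bins) or a list of matrices.
#' @param path Output TIFF path.
#' @export
write_image_stack <- function(X, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_image_stack requires the 'tiff' package", call. = FALSE)
  }
  pages <- if (is.list(X)) {
    X
  } else {
    n <- attr(X, "grid_n") %||% as.integer(sqrt(nrow(X)))
    lapply(seq_len(ncol(X)), function(k) matrix(X[, k], n, n))
  }
  rng <- range(unlist(lapply(pages, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    pages <- lapply(pages, function(p) (p - rng[1]) / span)
    writeLines(sprintf("offset = %.17g\nscale = %.17g", rng[1], span),
               paste0(path, ".scale.txt"))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Export sinograms as a multi-page TIFF plus a ray index table
#'
#' Writes one page per energy bin of the per-bin PCD sinogram (rows = views,
#' columns = detector elements; non-PCD elements are zero), one page for the
#' EID sinogram, and a CSV mapping ray index to view and detector element.
#'
#' @param projections A `projection_data` object.
#' @param geometry A [fanbeam_geometry()].
#' @param tiff_path Output TIFF path.
#' @param index_path Output CSV path for the ray index table.
#' @export
write_sinograms <- function(projections, geometry, tiff_path, index_path) {
  nv <- geometry$view_count
  nd <- geometry$detector_count
  M <- ncol(projections$pcd_counts)
  pages <- vector("list", M + 1)
  for (k in seq_len(M)) {
    full <- numeric(geometry$n_rays)
    full[projections$pcd_mask] <- projections$pcd_counts[, k]
    pages[[k]] <- matrix(full, nv, nd, byrow = TRUE)
  }
  pages[[M + 1]] <- matrix(projections$eid_intensity, nv, nd, byrow = TRUE)
  mx <- max(vapply(pages, max, numeric(1)))
  write_image_stack(lapply(pages, function(p) p / mx), tiff_path)
  idx <- data.frame(
    ray = seq_len(geometry$n_rays),
    view = rep(seq_len(nv), each = nd),
    detector = rep(seq_len(nd), times = nv),
    is_pcd = projections$pcd_mask
  )
  utils::write.csv(idx, index_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Write a scan metadata manifest as JSON
#'
#' Records the geometry, spectrum bins and weights, detector layout and
#' noise settings of a simulated scan. Requires the `jsonlite` package.
#'
#' @param projections A `projection_data` object.
#' @param geometry A [fanbeam_geometry()].
#' @param layout A [hybrid_layout()].
#' @param path Output JSON path.
#' @export
write_scan_metadata <- function(projections, geometry, layout, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_scan_metadata requires the 'jsonlite' package", call. = FALSE)
  }
  meta <- list(
    geometry = list(
      source_to_iso = geometry$source_to_iso,
      iso_to_detector = geometry$iso_to_detector,
      detector_count = geometry$detector_count,
      detector_length = geometry$detector_length,
      view_count = geometry$view_count,
      grid_n = geometry$grid_n, fov = geometry$fov
    ),
    layout = list(peer = layout$peer, pcd_count = layout$pcd_count),
    spectrum = list(
      bin_edges = projections$spectrum$bin_edges,
      weights = projections$spectrum$weights,
      blank_total = projections$blank_total
    ),
    noise = projections$noise,
    seed = projections$seed
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
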