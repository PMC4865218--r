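#' Simulate a polychromatic hybrid (EID + PCD) scan
#'
#' Forward-simulates the hybrid acquisition from a multi-energy ground-truth
#' image. For every ray `i` and bin `k` the per-bin transmitted intensity is
#' `S_k * exp(-(A x_k)_i)` (Beer-Lambert per narrow bin). The
#' energy-integrating detector records the sum over bins on every ray of the
#' full array; the photon-counting module records the per-bin intensities on
#' the central rays selected by the layout. With `noise = TRUE`, every
#' per-bin intensity is replaced by a Poisson draw (the EID reading is the
#' sum of its per-bin draws) and counts become integers.
#'
#' The spectrum is rescaled so that the blank-scan total per ray equals
#' `incident_total`.
#'
#' @param X_true `spectral_image` (pixels x bins) ground truth in cm^-1.
#' @param spectrum An `xray_spectrum`.
#' @param geometry A [fanbeam_geometry()].
#' @param layout A [hybrid_layout()].
#' @param noise Add Poisson counting noise?
#' @param incident_total Blank-scan photon total per ray (default: the
#'   spectrum's own total).
#' @param seed Seed for the Poisson draws (required when `noise = TRUE` for
#'   reproducibility; ignored otherwise).
#' @return Object of class `projection_data`: `eid_intensity` (length
#'   `n_rays`), `pcd_counts` (PCD rays x bins), `pcd_mask` (logical over all
#'   rays), `spectrum` (rescaled), `blank_total`, `noise`, `seed`.
#' @export
simulate_hybrid_scan <- function(X_true, spectrum, geometry, layout,
                                 noise = FALSE, incident_total = NULL,
                                 seed = 1) {
  stopifnot(inherits(spectrum, "xray_spectrum"),
            inherits(geometry, "fanbeam_geometry"),
            inherits(layout, "hybrid_layout"))
  X <- unclass(X_true)
  if (nrow(X) != geometry$grid_n^2 || ncol(X) != spectrum$n_bins) {
    stop("simulate_hybrid_scan: X_true shape does not match geometry/spectrum",
         call. = FALSE)
  }
  if (any(X < 0)) {
    warning("simulate_hybrid_scan: X_true has negative attenuation values")
  }
  if (!is.null(incident_total)) {
    spectrum$weights <- spectrum$weights / spectrum$blank_total * incident_total
    spectrum$blank_total <- incident_total
  }
  A <- system_matrix(geometry)
  P <- as.matrix(A %*% X)                                  # rays x bins
  I_bin <- sweep(exp(-P), 2, spectrum$weights, `*`)        # S_k exp(-p)
  mask <- pcd_ray_mask(geometry, layout)
  if (noise) {
    with_local_seed(seed, {
      eid_draws <- matrix(
        stats::rpois(length(I_bin), lambda = as.numeric(I_bin)),
        nrow(I_bin), ncol(I_bin))
      eid <- rowSums(eid_draws)
      pcd <- matrix(
        stats::rpois(sum(mask) * ncol(I_bin),
                     lambda = as.numeric(I_bin[mask, , drop = FALSE])),
        sum(mask), ncol(I_bin))
    })
  } else {
    eid <- rowSums(I_bin)
    pcd <- I_bin[mask, , drop = FALSE]
  }
  structure(
    list(eid_intensity = eid, pcd_counts = pcd, pcd_mask = mask,
         spectrum = spectrum, blank_total = spectrum$blank_total,
         noise = noise, seed = if (noise) seed else NULL),
    class = "projection_data"
  )
}

#' @export
print.projection_data <- function(x, ...) {
  cat(sprintf(
    "<projection_data> %d EID rays, %d PCD rays x %d bins, blank total %.4g photons%s\n",
    length(x$eid_intensity), nrow(x$pcd_counts), ncol(x$pcd_counts),
    x$blank_total, if (x$noise) sprintf(", Poisson noise (seed %d)", x$seed) else ""))
  invisible(x)
}
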