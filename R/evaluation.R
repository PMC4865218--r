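#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` with the peak taken as the maximum of the
#' reference image (the convention is recorded here because absolute PSNR
#' values depend on it). Identical images return `Inf`.
#'
#' @param image Test image (matrix or vector).
#' @param reference Reference image of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(image, reference) {
  x <- as.numeric(image)
  r <- as.numeric(reference)
  if (length(x) != length(r)) stop("psnr: shape mismatch", call. = FALSE)
  if (max(r) == min(r)) stop("psnr: reference is constant", call. = FALSE)
  mse <- mean((x - r)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(r)^2 / mse)
}

# Separable Gaussian filtering with replicate (nearest) edge padding.
gaussian_filter2d <- function(img, kernel) {
  r <- (length(kernel) - 1) / 2
  n1 <- nrow(img)
  n2 <- ncol(img)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1), n)
  p <- img[pad_idx(n1), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * p[seq_len(n1) + (k - 1), , drop = FALSE]
  }
  p <- out[, pad_idx(n2), drop = FALSE]
  out2 <- matrix(0, n1, n2)
  for (k in seq_along(kernel)) {
    out2 <- out2 + kernel[k] * p[, seq_len(n2) + (k - 1), drop = FALSE]
  }
  out2
}

#' Structural similarity index (mean SSIM)
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, and dynamic range equal to the reference
#' max - min. Local moments are weighted by the (normalized) Gaussian
#' window; the SSIM map is cropped by the window radius before averaging so
#' the result does not depend on edge padding.
#'
#' @param image Test image (matrix).
#' @param reference Reference image (matrix of the same dimension).
#' @param sigma Gaussian window standard deviation.
#' @param win_size Window size (odd).
#' @param K1,K2 Stabilization constants.
#' @param data_range Dynamic range; default `max(reference) - min(reference)`.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(image, reference, sigma = 1.5, win_size = 11,
                 K1 = 0.01, K2 = 0.03, data_range = NULL) {
  x <- as.matrix(image)
  r <- as.matrix(reference)
  if (!all(dim(x) == dim(r))) stop("ssim: shape mismatch", call. = FALSE)
  if (win_size %% 2 != 1) stop("ssim: win_size must be odd", call. = FALSE)
  if (is.null(data_range)) data_range <- max(r) - min(r)
  if (data_range <= 0) stop("ssim: data_range must be > 0", call. = FALSE)
  rad <- (win_size - 1) / 2
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  mu_x <- gaussian_filter2d(x, k)
  mu_r <- gaussian_filter2d(r, k)
  xx <- gaussian_filter2d(x * x, k)
  rr <- gaussian_filter2d(r * r, k)
  xr <- gaussian_filter2d(x * r, k)
  var_x <- xx - mu_x^2
  var_r <- rr - mu_r^2
  cov_xr <- xr - mu_x * mu_r
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  S <- ((2 * mu_x * mu_r + C1) * (2 * cov_xr + C2)) /
    ((mu_x^2 + mu_r^2 + C1) * (var_x + var_r + C2))
  core <- S[(rad + 1):(nrow(S) - rad), (rad + 1):(ncol(S) - rad)]
  mean(core)
}

#' Per-bin maximum quadratic Taylor error
#'
#' For each energy bin, the maximum over rays of the squared difference of
#' line integrals between the Taylor center and an image:
#' `max_i ((A_g (X~ - X))[, k]_i)^2`. This is the quantity whose decay
#' certifies the validity of the first-order linearization.
#'
#' @param X Image (pixels x bins).
#' @param X_tilde Taylor center (pixels x bins).
#' @param geometry A [fanbeam_geometry()].
#' @return Numeric vector, one value per bin.
#' @export
quadratic_taylor_error <- function(X, X_tilde, geometry) {
  A <- system_matrix(geometry)
  P <- as.matrix(A %*% (unclass(X_tilde) - unclass(X)))
  apply(P^2, 2, max)
}

#' Per-bin quality report (PSNR and SSIM)
#'
#' @param X Reconstructed `spectral_image`.
#' @param X_true Reference `spectral_image`.
#' @return Data frame with columns `bin`, `psnr_db`, `ssim`.
#' @export
quality_report <- function(X, X_true) {
  n <- attr(X_true, "grid_n") %||% as.integer(sqrt(nrow(X_true)))
  M <- ncol(X_true)
  data.frame(
    bin = seq_len(M),
    psnr_db = vapply(seq_len(M), function(k) {
      psnr(X[, k], X_true[, k])
    }, numeric(1)),
    ssim = vapply(seq_len(M), function(k) {
      ssim(matrix(X[, k], n, n), matrix(X_true[, k], n, n))
    }, numeric(1))
  )
}

#' Default study configuration for the experiment drivers
#'
#' Desk-scale settings used by [run_experiment()]: grid, geometry, spectrum,
#' phantom seed and solver iterations. Override any entry through the
#' `config` argument of [run_experiment()].
#'
#' @return Named list of settings.
#' @export
experiment_config <- function() {
  list(
    grid_n = 64, view_count = 60, detector_count = 128,
    detector_length = 70, source_to_iso = 50, iso_to_detector = 50,
    fov = 32, n_bins = 8, e_min = 30, e_max = 120,
    incident_total = 1e7, phantom_seed = 7, noise = FALSE, noise_seed = 11,
    outer_iterations = 200, inner_iterations = 5, cg_iterations = 10,
    lambda = 1, lambda1 = 0.01, lambda2 = 0.01,
    cgls_iterations = 50, z_eff = 7.42
  )
}

# Shared setup for the experiment drivers.
experiment_setup <- function(cfg) {
  geometry <- fanbeam_geometry(
    source_to_iso = cfg$source_to_iso, iso_to_detector = cfg$iso_to_detector,
    detector_count = cfg$detector_count, detector_length = cfg$detector_length,
    view_count = cfg$view_count, grid_n = cfg$grid_n, fov = cfg$fov
  )
  spectrum <- make_spectrum(
    seq(cfg$e_min, cfg$e_max, length.out = cfg$n_bins + 1),
    model = "parametric", total_photons = cfg$incident_total
  )
  list(geometry = geometry, spectrum = spectrum)
}

# Simulate + initial estimate + PRISM for one setting; returns fit pieces.
run_single_recon <- function(maps, peer, cfg, setup) {
  X_true <- compose_spectral_images(maps, setup$spectrum)
  layout <- hybrid_layout(setup$geometry, peer)
  proj <- simulate_hybrid_scan(X_true, setup$spectrum, setup$geometry, layout,
                               noise = cfg$noise,
                               incident_total = cfg$incident_total,
                               seed = cfg$noise_seed)
  init <- initial_estimate(proj, setup$geometry, z_eff = cfg$z_eff,
                           cgls_iterations = cfg$cgls_iterations)
  params <- prism_params(
    lambda = cfg$lambda, lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
    outer_iterations = cfg$outer_iterations,
    inner_iterations = cfg$inner_iterations,
    cg_iterations = cfg$cg_iterations
  )
  fit <- run_algorithm1(proj, setup$geometry, layout, init$X, params)
  list(X_true = X_true, init = init, fit = fit, layout = layout, proj = proj)
}

#' Experiment drivers mirroring the hybrid-CT study protocols
#'
#' Orchestrates simulate -> initial estimate -> PRISM reconstruction ->
#' metrics for a family of settings:
#' * `"peer_sweep"` — PCD-to-EID extent ratios 1, 1/2, 1/3; per-bin PSNR and
#'   SSIM against the ground truth.
#' * `"noise_study"` — the same sweep with Poisson counting noise.
#' * `"gd_spot_sweep"` — a single gadolinium spot moved outward from the
#'   center along the horizontal mid-line (PEER 1/2); reports the MSE over
#'   the spot's support versus its offset.
#' * `"gd_strip_sweep"` — a horizontal gadolinium strip crossing the
#'   spectral FOV, shifted outward; MSE over the strip support versus
#'   offset.
#'
#' @param profile One of the profiles above.
#' @param config Named list overriding entries of [experiment_config()].
#' @return Data frame of metrics (`experiment`, `peer`, setting columns,
#'   `bin`, `psnr_db`, `ssim` or `mse`).
#' @export
run_experiment <- function(profile = c("peer_sweep", "noise_study",
                                       "gd_spot_sweep", "gd_strip_sweep"),
                           config = list()) {
  profile <- match.arg(profile)
  cfg <- utils::modifyList(experiment_config(), config)
  if (profile == "noise_study") cfg$noise <- TRUE
  setup <- experiment_setup(cfg)
  n <- cfg$grid_n
  if (profile %in% c("peer_sweep", "noise_study")) {
    maps <- make_abdomen_phantom(n, seed = cfg$phantom_seed)
    out <- lapply(c(1, 1 / 2, 1 / 3), function(peer) {
      res <- run_single_recon(maps, peer, cfg, setup)
      qr <- quality_report(res$fit$X, res$X_true)
      cbind(experiment = profile, peer = peer, qr)
    })
    return(do.call(rbind, out))
  }
  # gadolinium position sweeps: feature moved left from the center along
  # the horizontal mid-line, PEER = 1/2
  offsets <- cfg$gd_offsets %||% round(seq(0, 0.35 * n, length.out = 4))
  base <- make_abdomen_phantom(n, seed = cfg$phantom_seed)
  out <- lapply(offsets, function(off) {
    if (profile == "gd_spot_sweep") {
      maps <- add_gadolinium_features(
        base,
        spots = list(list(center = c(round(n / 2), round(n / 2) - off),
                          radius = max(2, round(n / 32)))),
        strip = NULL)
    } else {
      maps <- add_gadolinium_features(
        base, spots = list(),
        strip = list(row = round(n / 2) - off,
                     col_start = round(n * 0.25), col_end = round(n * 0.75),
                     width = max(2, round(n / 40))))
    }
    res <- run_single_recon(maps, 1 / 2, cfg, setup)
    support <- as.numeric(maps$gadolinium) > 0
    mse <- colMeans((res$fit$X[support, , drop = FALSE] -
                       res$X_true[support, , drop = FALSE])^2)
    data.frame(experiment = profile, peer = 1 / 2, offset_px = off,
               bin = seq_along(mse), mse = mse)
  })
  do.call(rbind, out)
}
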