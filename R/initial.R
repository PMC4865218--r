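#' Per-bin energy basis of the effective-density attenuation model
#'
#' In the photoelectric + Compton decomposition with a single effective
#' atomic number, the attenuation separates into an energy-independent
#' effective electron density `mu_eff = rho * Z / A` (mol/cm^3) and an
#' energy factor
#' `g(eps) = N_A * alpha^4 * (8/3) * pi * r_e^2 * sqrt(32) * eps^-3.5 *
#' Z_eff^3 + N_A * f_kn(eps)` (cm^2/mol), so that
#' `mu(r, E) = mu_eff(r) * g(eps)`.
#'
#' @param spectrum An `xray_spectrum` (bin centers define the energies).
#' @param z_eff Effective atomic number (default: water, 7.42).
#' @return Numeric vector `g_k`, one entry per energy bin (cm^2/mol).
#' @export
energy_basis <- function(spectrum, z_eff = 7.42) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  pc <- physics_constants()
  eps <- spectrum$bin_centers / pc$electron_rest_energy
  c_ph <- pc$avogadro * pc$fine_structure^4 * (8 / 3) * pi *
    pc$electron_radius^2 * sqrt(32 / eps^7)
  c_co <- pc$avogadro * klein_nishina(eps)
  c_ph * z_eff^3 + c_co
}

#' Invert the polychromatic transmission equation for one path integral
#'
#' Solves `measured_I = sum_k S_k * exp(-g_k * t)` for the effective-density
#' path integral `t = integral of mu_eff along the ray`. The right-hand side
#' is strictly decreasing in `t`, so the root is unique; it is bracketed by
#' geometric growth and found by bisection to a relative intensity residual
#' below `tol`.
#'
#' @param measured_I Measured grayscale intensity (photons), vectorized over
#'   rays. Values above the blank total are clamped (with a warning), as can
#'   happen under counting noise; non-positive values are an error.
#' @param spectrum An `xray_spectrum`.
#' @param z_eff Effective atomic number used in the energy basis.
#' @param tol Relative intensity tolerance of the bisection.
#' @return Path integrals `t` (mol/cm^2), same length as `measured_I`.
#' @export
solve_effective_path <- function(measured_I, spectrum, z_eff = 7.42,
                                 tol = 1e-10) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (any(measured_I <= 0)) {
    stop("solve_effective_path: measured intensity must be > 0", call. = FALSE)
  }
  I0 <- spectrum$blank_total
  if (any(measured_I > I0 * (1 + 1e-12))) {
    warning("solve_effective_path: intensities above the blank total clamped")
  }
  y <- pmin(measured_I, I0)
  g <- energy_basis(spectrum, z_eff)
  S <- spectrum$weights
  f <- function(t) as.numeric(exp(-outer(t, g)) %*% S)
  # monotonicity guard on a coarse grid (the model guarantees it, the
  # spectrum contract is checked here)
  tg <- seq(0, 10, length.out = 6)
  if (any(diff(f(tg)) > 1e-9 * I0)) {
    stop("solve_effective_path: transmission model is not decreasing", call. = FALSE)
  }
  lo <- numeric(length(y))
  hi <- rep(1, length(y))
  for (it in 1:60) {
    bad <- f(hi) > y
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    up <- fm > y
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(abs(fm - y)) < tol * I0 && max(hi - lo) < 1e-12 * max(hi, 1)) break
  }
  t <- (lo + hi) / 2
  t[y >= I0] <- 0
  t
}

# Conjugate-gradient least squares for A x = b (CGLS), fixed iteration count.
cgls <- function(A, At, b, iterations = 50, x0 = NULL) {
  x <- if (is.null(x0)) numeric(ncol(A)) else x0
  r <- b - as.numeric(A %*% x)
  s <- as.numeric(At %*% r)
  p <- s
  gamma <- sum(s * s)
  for (it in seq_len(iterations)) {
    if (gamma <= 0) break
    q <- as.numeric(A %*% p)
    alpha <- gamma / sum(q * q)
    x <- x + alpha * p
    r <- r - alpha * q
    s <- as.numeric(At %*% r)
    gamma_new <- sum(s * s)
    p <- s + (gamma_new / gamma) * p
    gamma <- gamma_new
  }
  x
}

#' Reconstruct the effective electron-density image
#'
#' Least-squares inversion of the full-array (EID) system matrix applied to
#' the effective-density path integrals, `A_g mu_eff = t`, by conjugate
#' gradients on the least-squares problem (CGLS, fixed 50 iterations, zero
#' start), followed by clipping to nonnegative values.
#'
#' @param path_integrals One value per full-array ray (from
#'   [solve_effective_path()]).
#' @param geometry A [fanbeam_geometry()].
#' @param iterations CGLS iteration count.
#' @return `grid_n` x `grid_n` matrix of `mu_eff` (mol/cm^3).
#' @export
reconstruct_mu_eff <- function(path_integrals, geometry, iterations = 50) {
  if (length(path_integrals) != geometry$n_rays) {
    stop("reconstruct_mu_eff: need one path integral per full-array ray",
         call. = FALSE)
  }
  A <- system_matrix(geometry)
  At <- system_matrix_t(geometry)
  x <- cgls(A, At, path_integrals, iterations = iterations)
  matrix(pmax(x, 0), geometry$grid_n, geometry$grid_n)
}

#' Expand an effective-density image to per-bin attenuation images
#'
#' Outer product of the effective-density map with the per-bin energy
#' basis: `X[, k] = mu_eff * g_k`. The result has numerical rank one by
#' construction — all energy channels share a single spatial pattern.
#'
#' @param mu_eff Effective-density image (matrix or vector).
#' @param spectrum An `xray_spectrum`.
#' @param z_eff Effective atomic number used in the energy basis.
#' @return A `spectral_image` (pixels x bins).
#' @export
expand_to_channels <- function(mu_eff, spectrum, z_eff = 7.42) {
  g <- energy_basis(spectrum, z_eff)
  n <- if (is.matrix(mu_eff)) nrow(mu_eff) else as.integer(sqrt(length(mu_eff)))
  structure(outer(as.numeric(mu_eff), g), grid_n = n,
            bin_centers = spectrum$bin_centers,
            class = c("spectral_image", "matrix"))
}

#' Physics-based initial estimate of the multi-energy image
#'
#' Full initial-estimation pipeline from grayscale (EID) data: invert the
#' polychromatic transmission equation ray by ray for the effective-density
#' path integrals, reconstruct the effective-density image by CGLS, and
#' expand it to per-bin attenuation images with the water effective atomic
#' number. The result is rank one and deliberately biased for non-water
#' materials; it serves as the Taylor center for the PRISM reconstruction,
#' which corrects these errors.
#'
#' @param projections A `projection_data` object (EID intensities are used).
#' @param geometry A [fanbeam_geometry()].
#' @param z_eff Effective atomic number (default water, 7.42).
#' @param cgls_iterations CGLS iteration count for the density image.
#' @return List with `X` (the `spectral_image` estimate), `mu_eff` and
#'   `path_integrals`.
#' @export
initial_estimate <- function(projections, geometry, z_eff = 7.42,
                             cgls_iterations = 50) {
  stopifnot(inherits(projections, "projection_data"))
  t <- solve_effective_path(pmax(projections$eid_intensity, 1e-12),
                            projections$spectrum, z_eff = z_eff)
  mu_eff <- reconstruct_mu_eff(t, geometry, iterations = cgls_iterations)
  X <- expand_to_channels(mu_eff, projections$spectrum, z_eff = z_eff)
  list(X = X, mu_eff = mu_eff, path_integrals = t)
}
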