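#' Physical constants used by the attenuation model
#'
#' Returns the constants entering the photoelectric + Compton cross-section
#' model: Avogadro's number, the fine-structure constant, the classical
#' electron radius (in cm) and the electron rest energy (in keV). The reduced
#' energy used throughout the package is `epsilon = E / 511 keV`.
#'
#' @return Named list with elements `avogadro` (mol^-1), `fine_structure`,
#'   `electron_radius` (cm) and `electron_rest_energy` (keV).
#' @export
physics_constants <- function() {
  list(
    avogadro = 6.02214076e23,
    fine_structure = 0.0072973525693,
    electron_radius = 2.818e-13,
    electron_rest_energy = 511
  )
}

#' Klein-Nishina cross section per electron
#'
#' Total Compton scattering cross section per electron as a function of the
#' reduced photon energy `epsilon = E / 511 keV`. For very small `epsilon`
#' a series expansion is used to avoid catastrophic cancellation; the
#' `epsilon -> 0` limit is the Thomson cross section `(8/3) pi r_e^2`.
#'
#' @param epsilon Reduced photon energy, strictly positive (vectorized).
#' @return Cross section in cm^2 per electron.
#' @export
klein_nishina <- function(epsilon) {
  if (any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    stop("klein_nishina: epsilon must be finite and > 0", call. = FALSE)
  }
  pc <- physics_constants()
  r2 <- pc$electron_radius^2
  sigma_t <- 8 / 3 * pi * r2
  out <- numeric(length(epsilon))
  small <- epsilon < 1e-4
  if (any(small)) {
    e <- epsilon[small]
    # low-energy expansion of the Klein-Nishina total cross section
    out[small] <- sigma_t * (1 - 2 * e + 26 / 5 * e^2 - 133 / 10 * e^3)
  }
  if (any(!small)) {
    e <- epsilon[!small]
    l <- log1p(2 * e)
    out[!small] <- 2 * pi * r2 * (
      (1 + e) / e^2 * (2 * (1 + e) / (1 + 2 * e) - l / e) +
        l / (2 * e) - (1 + 3 * e) / (1 + 2 * e)^2
    )
  }
  out
}

#' Photoelectric absorption cross section per atom
#'
#' Born-approximation K-shell photoabsorption cross section,
#' `Z^4 alpha^4 (8/3) pi r_e^2 sqrt(32 / epsilon^7)`, valid for
#' `epsilon < 1` (photon energies below 511 keV).
#'
#' @param Z Atomic number (effective), `>= 1`.
#' @param epsilon Reduced photon energy in `(0, 1)` (vectorized).
#' @return Cross section in cm^2 per atom.
#' @export
photoelectric_cross_section <- function(Z, epsilon) {
  if (any(Z < 1)) stop("photoelectric_cross_section: Z must be >= 1", call. = FALSE)
  if (any(!is.finite(epsilon)) || any(epsilon <= 0) || any(epsilon >= 1)) {
    stop("photoelectric_cross_section: epsilon must lie in (0, 1)", call. = FALSE)
  }
  pc <- physics_constants()
  Z^4 * pc$fine_structure^4 * (8 / 3) * pi * pc$electron_radius^2 *
    sqrt(32 / epsilon^7)
}

#' Define a material for the attenuation model
#'
#' A material is described by its mass density, effective atomic number and
#' atomic mass; an optional K-edge is modeled as a multiplicative jump of the
#' photoelectric term at the edge energy.
#'
#' @param name Material name.
#' @param rho Mass density in g/cm^3, `> 0`.
#' @param Z Effective atomic number, `>= 1`.
#' @param A Atomic mass in g/mol, `> 0`.
#' @param k_edge_energy Optional K-edge energy in keV.
#' @param k_edge_jump_factor Optional jump factor (`> 1`) applied to the
#'   photoelectric term at and above the edge. Must be given together with
#'   `k_edge_energy`.
#' @return Object of class `material_spec`.
#' @export
material_spec <- function(name, rho, Z, A,
                          k_edge_energy = NULL, k_edge_jump_factor = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (rho <= 0 || Z < 1 || A <= 0) {
    stop("material_spec: require rho > 0, Z >= 1, A > 0", call. = FALSE)
  }
  if (is.null(k_edge_energy) != is.null(k_edge_jump_factor)) {
    stop("material_spec: k_edge_energy and k_edge_jump_factor must be given together",
         call. = FALSE)
  }
  if (!is.null(k_edge_jump_factor) && k_edge_jump_factor < 1) {
    stop("material_spec: k_edge_jump_factor must be >= 1", call. = FALSE)
  }
  structure(
    list(name = name, rho = rho, Z = Z, A = A,
         k_edge_energy = k_edge_energy,
         k_edge_jump_factor = k_edge_jump_factor),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: rho=%.4g g/cm^3, Z=%.4g, A=%.4g g/mol",
              x$name, x$rho, x$Z, x$A))
  if (!is.null(x$k_edge_energy)) {
    cat(sprintf(", K-edge %.3f keV (jump x%.3g)",
                x$k_edge_energy, x$k_edge_jump_factor))
  }
  cat("\n")
  invisible(x)
}

#' Built-in material definitions
#'
#' Water-like soft tissue (effective Z of water), a cortical-bone analogue,
#' and a dilute gadolinium contrast solution with the Gd K-edge at
#' 50.207 keV. The gadolinium density corresponds to a dilute contrast
#' agent so that a unit fraction pixel has attenuation of a few times
#' 0.01 cm^-1 in the diagnostic range.
#'
#' @param name One of `"water"`, `"bone"`, `"gadolinium"`.
#' @return A [material_spec()] object.
#' @export
default_material <- function(name = c("water", "bone", "gadolinium")) {
  name <- match.arg(name)
  switch(name,
    water = material_spec("water", rho = 1.0, Z = 7.42, A = 13.0),
    bone = material_spec("bone", rho = 1.85, Z = 13.8, A = 27.6),
    gadolinium = material_spec("gadolinium", rho = 0.005, Z = 64, A = 157.25,
                               k_edge_energy = 50.207, k_edge_jump_factor = 5)
  )
}

#' Linear attenuation coefficient of a material
#'
#' Photoelectric + Compton model:
#' `mu(E) = rho * N_A / A * (sigma_ph(Z, eps) + Z * f_kn(eps))` with
#' `eps = E / 511`. If the material carries a K-edge, the photoelectric term
#' is multiplied by the jump factor for energies at or above the edge,
#' producing the upward discontinuity characteristic of K-edge contrast
#' agents.
#'
#' @param material A [material_spec()].
#' @param energy Photon energy in keV, in `[30, 511)` (vectorized).
#' @return Linear attenuation in cm^-1.
#' @export
material_mu <- function(material, energy) {
  stopifnot(inherits(material, "material_spec"))
  if (any(energy < 30) || any(energy >= 511)) {
    stop("material_mu: energy must lie in [30, 511) keV", call. = FALSE)
  }
  pc <- physics_constants()
  eps <- energy / pc$electron_rest_energy
  sph <- photoelectric_cross_section(material$Z, eps)
  if (!is.null(material$k_edge_energy)) {
    jump <- ifelse(energy >= material$k_edge_energy,
                   material$k_edge_jump_factor, 1)
    sph <- sph * jump
  }
  sco <- material$Z * klein_nishina(eps)
  material$rho * pc$avogadro / material$A * (sph + sco)
}

#' Construct an X-ray spectrum over energy bins
#'
#' Builds the binned spectrum used for polychromatic simulation: bin edges,
#' bin center energies `E_k` and per-bin effective fluence weights
#' `S_k = I0(E_k) Q(E_k)` (detector response folded in), normalized so that
#' the blank-scan total `I = sum(S_k)` equals `total_photons`.
#'
#' Models:
#' * `"parametric"` — a filtered Kramers bremsstrahlung shape,
#'   `w(E) = (E_tube - E)/E * exp(-(E_filter/E)^3)` for `30 <= E <= E_tube`,
#'   integrated over each bin. The photoelectric-like filtration term
#'   suppresses the soft end so that most photons fall in the middle bins,
#'   as in a filtered 120 kVp tube spectrum.
#' * `"uniform"` — equal weight per bin.
#' * `"table"` — user-supplied per-bin `weights` (rescaled to the total).
#'
#' @param bin_edges Strictly increasing bin edges in keV (default: 8 bins
#'   over 30-120 keV).
#' @param model One of `"parametric"`, `"uniform"`, `"table"`.
#' @param total_photons Blank-scan photon total per ray, `> 0`.
#' @param weights Per-bin weights for `model = "table"`.
#' @param tube_kvp Tube peak energy in keV for the parametric model.
#' @param filter_scale Filtration scale energy in keV for the parametric
#'   model; larger values harden the spectrum.
#' @return Object of class `xray_spectrum` with fields `bin_edges`,
#'   `bin_centers`, `weights`, `blank_total`, `n_bins`.
#' @export
make_spectrum <- function(bin_edges = seq(30, 120, length.out = 9),
                          model = c("parametric", "uniform", "table"),
                          total_photons = 1e7,
                          weights = NULL,
                          tube_kvp = 120,
                          filter_scale = 55) {
  model <- match.arg(model)
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("make_spectrum: bin_edges must be strictly increasing with >= 2 edges",
         call. = FALSE)
  }
  if (total_photons <= 0) stop("make_spectrum: total_photons must be > 0", call. = FALSE)
  M <- length(bin_edges) - 1
  centers <- (bin_edges[-1] + bin_edges[-(M + 1)]) / 2
  w <- switch(model,
    uniform = rep(1, M),
    table = {
      if (is.null(weights) || length(weights) != M || any(weights < 0)) {
        stop("make_spectrum: table model needs one nonnegative weight per bin",
             call. = FALSE)
      }
      if (sum(weights) <= 0) stop("make_spectrum: table weights sum to zero", call. = FALSE)
      weights
    },
    parametric = {
      shape <- function(E) {
        ifelse(E < 30 | E >= tube_kvp, 0,
               (tube_kvp - E) / E * exp(-(filter_scale / E)^3))
      }
      vapply(seq_len(M), function(k) {
        stats::integrate(shape, bin_edges[k], bin_edges[k + 1],
                         rel.tol = 1e-10)$value
      }, numeric(1))
    }
  )
  w <- w / sum(w) * total_photons
  structure(
    list(bin_edges = bin_edges, bin_centers = centers, weights = w,
         blank_total = sum(w), n_bins = M),
    class = "xray_spectrum"
  )
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("<xray_spectrum> %d bins over [%.6g, %.6g] keV, blank total %.6g photons\n",
              x$n_bins, min(x$bin_edges), max(x$bin_edges), x$blank_total))
  invisible(x)
}

#' Write a spectrum to CSV
#'
#' Columns `bin_lo_keV`, `bin_hi_keV`, `weight`.
#'
#' @param spectrum An `xray_spectrum`.
#' @param path Output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  df <- data.frame(
    bin_lo_keV = spectrum$bin_edges[-(spectrum$n_bins + 1)],
    bin_hi_keV = spectrum$bin_edges[-1],
    weight = spectrum$weights
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' Inverse of [write_spectrum_csv()]; the blank total is the sum of the
#' stored weights.
#'
#' @param path CSV path with columns `bin_lo_keV`, `bin_hi_keV`, `weight`.
#' @return An `xray_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_lo_keV", "bin_hi_keV", "weight")
  if (!all(need %in% names(df))) {
    stop("read_spectrum_csv: missing required columns", call. = FALSE)
  }
  edges <- c(df$bin_lo_keV, df$bin_hi_keV[nrow(df)])
  if (!isTRUE(all.equal(df$bin_hi_keV[-nrow(df)], df$bin_lo_keV[-1]))) {
    stop("read_spectrum_csv: bins must be contiguous", call. = FALSE)
  }
  make_spectrum(edges, model = "table", total_photons = sum(df$weight),
                weights = df$weight)
}
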