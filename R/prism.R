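#' Regularization parameters for the PRISM reconstruction
#'
#' @param lambda ADMM coupling weight (`lambda > 0`).
#' @param lambda1 Nuclear-norm (low-rank) weight.
#' @param lambda2 l1 (sparsity) weight.
#' @param outer_iterations Outer (re-linearization) iterations.
#' @param inner_iterations Inner ADMM cycles per outer iteration.
#' @param cg_iterations Conjugate-gradient steps for each data-fit solve.
#' @param tol Early-exit tolerance on the relative change of the data-fit
#'   residual between outer iterations.
#' @param grayscale_weight Scale applied to the linearized grayscale
#'   equation (weights and target alike) for conditioning; `NULL` selects
#'   one over the blank-scan total, which brings the grayscale residual to
#'   the same order as the per-bin log residuals.
#' @param count_floor Photon floor applied before the PCD log transform.
#' @param reset_multiplier Reset the ADMM multiplier `D = X_L + X_S - X` at
#'   the start of every outer iteration (the literal nested scheme);
#'   `FALSE` carries `D` across outer iterations.
#' @return Object of class `prism_params`.
#' @export
prism_params <- function(lambda = 1, lambda1 = 0.01, lambda2 = 0.01,
                         outer_iterations = 1000, inner_iterations = 5,
                         cg_iterations = 10, tol = 1e-8,
                         grayscale_weight = NULL, count_floor = 0.5,
                         reset_multiplier = TRUE) {
  if (lambda <= 0 || lambda1 <= 0 || lambda2 <= 0) {
    stop("prism_params: lambda, lambda1, lambda2 must be > 0", call. = FALSE)
  }
  structure(
    list(lambda = lambda, lambda1 = lambda1, lambda2 = lambda2,
         outer_iterations = outer_iterations,
         inner_iterations = inner_iterations,
         cg_iterations = cg_iterations, tol = tol,
         grayscale_weight = grayscale_weight, count_floor = count_floor,
         reset_multiplier = reset_multiplier),
    class = "prism_params"
  )
}

#' Per-bin log transform of photon-counting data
#'
#' Converts PCD counts to line-integral estimates,
#' `Y_ck = -ln(max(count, floor) / S_k)`; the photon floor keeps zero counts
#' finite.
#'
#' @param pcd_counts PCD rays x bins count matrix.
#' @param spectrum An `xray_spectrum` (per-bin blanks `S_k`).
#' @param count_floor Minimum count substituted before the logarithm.
#' @return Matrix `Y_c` of the same shape as `pcd_counts`.
#' @export
pcd_log_transform <- function(pcd_counts, spectrum, count_floor = 0.5) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  if (any(pcd_counts < 0)) {
    stop("pcd_log_transform: counts must be nonnegative", call. = FALSE)
  }
  -log(sweep(pmax(pcd_counts, count_floor), 2, spectrum$weights, `/`))
}

#' Linearized per-bin intensities at the Taylor center
#'
#' Evaluates `I~_i(E_k) = S_k * exp(-(A_g X~[, k])_i)` over all full-array
#' rays: the per-bin transmitted intensities predicted by the current
#' estimate, which act as the weights coupling the energy bins in the
#' linearized grayscale equation.
#'
#' @param X_tilde Current multi-energy estimate (pixels x bins).
#' @param spectrum An `xray_spectrum`.
#' @param geometry A [fanbeam_geometry()].
#' @return Matrix `I~` of dimension rays x bins.
#' @export
taylor_weights <- function(X_tilde, spectrum, geometry) {
  A <- system_matrix(geometry)
  P <- as.matrix(A %*% unclass(X_tilde))
  sweep(exp(-P), 2, spectrum$weights, `*`)
}

#' Synthesized grayscale target of the linearized transmission model
#'
#' First-order Taylor expansion of the polychromatic Beer-Lambert model
#' around the current estimate turns each EID reading into a linear
#' constraint `sum_k I~_i(E_k) (A_g X[, k])_i = Y_gi` with
#' `Y_gi = sum_k I~_i(E_k) (1 + (A_g X~[, k])_i) - I_gi`.
#' The expansion is exact at its center: when the data are noise-free and
#' `X = X~` equals the image that generated them, the residual vanishes
#' identically.
#'
#' @param I_tilde Linearized intensities from [taylor_weights()].
#' @param eid_intensity Measured EID intensities `I_g` (all rays).
#' @param X_tilde The Taylor center (pixels x bins).
#' @param geometry A [fanbeam_geometry()].
#' @return Numeric vector `Y_g`, one entry per full-array ray.
#' @export
synthesize_grayscale_target <- function(I_tilde, eid_intensity, X_tilde,
                                        geometry) {
  A <- system_matrix(geometry)
  P <- as.matrix(A %*% unclass(X_tilde))
  rowSums(I_tilde * (1 + P)) - eid_intensity
}

#' Soft-thresholding operator (l1 proximal map)
#'
#' Elementwise `sign(x) * max(|x| - tau, 0)`, the proximal operator of the
#' l1 norm.
#'
#' @param x Numeric matrix or vector.
#' @param tau Threshold, `>= 0`.
#' @return Same shape as `x`.
#' @export
soft_threshold <- function(x, tau) {
  if (tau < 0) stop("soft_threshold: tau must be >= 0", call. = FALSE)
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Singular value thresholding (nuclear-norm proximal map)
#'
#' Thin SVD followed by soft-thresholding of the singular values:
#' `U max(Sigma - tau, 0) V^T`.
#'
#' @param x Numeric matrix.
#' @param tau Threshold, `>= 0`.
#' @return Matrix of the same dimension as `x`.
#' @export
svt <- function(x, tau) {
  if (tau < 0) stop("svt: tau must be >= 0", call. = FALSE)
  if (any(!is.finite(x))) stop("svt: input must be finite", call. = FALSE)
  s <- svd(x)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(x), ncol(x)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Data-fit subproblem of the extended ADMM
#'
#' Approximately minimizes
#' `||A_c X - Y_c||_F^2 + ||B X - Y_g||^2 + lambda ||X_L + X_S - X + D||_F^2`
#' over `X` by conjugate gradients on the normal equations, warm-started at
#' `X_init`. `B` is the bin-coupling grayscale operator
#' `(B X)_i = sum_k w_i(E_k) (A_g X[, k])_i` with weights
#' `w = grayscale_weight * I~`. Because the PCD rays are a subset of the
#' full-array rays, both data terms share one forward/adjoint projector
#' application per CG step.
#'
#' @param Y_c PCD log data (PCD rays x bins).
#' @param Y_g Synthesized grayscale target (all rays), already on the same
#'   scale as the weights `w`.
#' @param weights Grayscale weights `w` (rays x bins).
#' @param XL,XS,D Current low-rank part, sparse part and multiplier.
#' @param params A [prism_params()] (uses `lambda`, `cg_iterations`).
#' @param geometry A [fanbeam_geometry()].
#' @param pcd_mask Logical ray mask of the PCD module.
#' @param X_init Warm start (pixels x bins).
#' @param cg_iterations Optional override of the CG step count.
#' @param track_objective Also return the objective value after every CG
#'   step.
#' @return The updated `X` (pixels x bins); if `track_objective`, a list
#'   with elements `X` and `objective`.
#' @export
solve_data_fit <- function(Y_c, Y_g, weights, XL, XS, D, params, geometry,
                           pcd_mask, X_init, cg_iterations = NULL,
                           track_objective = FALSE) {
  A <- system_matrix(geometry)
  At <- system_matrix_t(geometry)
  lambda <- params$lambda
  n_iter <- cg_iterations %||% params$cg_iterations
  M <- ncol(X_init)
  Ycfull <- matrix(0, geometry$n_rays, M)
  Ycfull[pcd_mask, ] <- Y_c
  Tm <- XL + XS + D
  # right-hand side of the normal equations
  b <- as.matrix(At %*% (Ycfull + weights * Y_g)) + lambda * Tm
  apply_H <- function(X) {
    P <- as.matrix(A %*% X)
    s <- rowSums(weights * P)
    R <- P * pcd_mask + weights * s
    as.matrix(At %*% R) + lambda * X
  }
  objective <- function(X) {
    P <- as.matrix(A %*% X)
    sum((P[pcd_mask, ] - Y_c)^2) + sum((rowSums(weights * P) - Y_g)^2) +
      lambda * sum((XL + XS - X + D)^2)
  }
  X <- unclass(X_init)
  obj <- if (track_objective) objective(X) else NULL
  r <- b - apply_H(X)
  p <- r
  gamma <- sum(r * r)
  for (it in seq_len(n_iter)) {
    if (gamma <= 1e-300) break
    Hp <- apply_H(p)
    alpha <- gamma / sum(p * Hp)
    X <- X + alpha * p
    if (!all(is.finite(X))) {
      stop("solve_data_fit: iterate diverged (non-finite values)", call. = FALSE)
    }
    r <- r - alpha * Hp
    gamma_new <- sum(r * r)
    p <- r + (gamma_new / gamma) * p
    gamma <- gamma_new
    if (track_objective) obj <- c(obj, objective(X))
  }
  if (track_objective) list(X = X, objective = obj) else X
}

#' Hybrid PRISM reconstruction (nested re-linearized ADMM)
#'
#' The package's core solver. Each outer iteration re-linearizes the
#' polychromatic grayscale model around the current estimate (updating the
#' per-bin weights `I~` and the synthesized target `Y_g`), resets the
#' multiplier `D = X_L + X_S - X`, and runs a fixed number of inner ADMM
#' cycles: a conjugate-gradient data-fit solve for `X`, singular value
#' thresholding for the low-rank part `X_L`, soft thresholding for the
#' sparse part `X_S`, and the multiplier update `D = D + X_L + X_S - X`.
#' Iteration stops at `outer_iterations` or when the relative change of the
#' data-fit residual drops below `tol`. The returned image is `X_L + X_S`.
#'
#' @param projections A `projection_data` object.
#' @param geometry A [fanbeam_geometry()].
#' @param layout A [hybrid_layout()].
#' @param X_init Initial estimate (pixels x bins), e.g. from
#'   [initial_estimate()].
#' @param params A [prism_params()].
#' @param X_reference Optional ground truth; when given, per-iteration
#'   quadratic Taylor errors against the evolving center are complemented by
#'   errors against the truth in the diagnostics.
#' @param verbose Print progress every 25 outer iterations.
#' @return Object of class `prism_fit`: `X` (the reconstruction
#'   `X_L + X_S` as a `spectral_image`), `X_last` (the final data-fit
#'   iterate), `XL`, `XS`, `iterations` (outer iterations run), and
#'   `diagnostics` (data frame with one row per outer iteration and bin:
#'   maximum quadratic Taylor error of the update, data-fit residuals).
#' @export
run_algorithm1 <- function(projections, geometry, layout, X_init,
                           params = prism_params(), X_reference = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(projections, "projection_data"),
            inherits(params, "prism_params"))
  spectrum <- projections$spectrum
  M <- spectrum$n_bins
  pcd_mask <- projections$pcd_mask
  gs <- params$grayscale_weight %||% (1 / projections$blank_total)
  Y_c <- pcd_log_transform(projections$pcd_counts, spectrum,
                           count_floor = params$count_floor)
  X <- unclass(X_init)
  XL <- X
  XS <- matrix(0, nrow(X), ncol(X))
  D <- XL + XS - X
  tau_L <- params$lambda1 / (2 * params$lambda)
  tau_S <- params$lambda2 / (2 * params$lambda)
  diag_rows <- vector("list", params$outer_iterations)
  resid_prev <- NA_real_
  n_outer <- 0L
  A <- system_matrix(geometry)
  for (i in seq_len(params$outer_iterations)) {
    X_center <- X
    I_tilde <- taylor_weights(X_center, spectrum, geometry)
    Y_g_raw <- synthesize_grayscale_target(I_tilde, projections$eid_intensity,
                                           X_center, geometry)
    w <- I_tilde * gs
    Y_g <- Y_g_raw * gs
    if (params$reset_multiplier) D <- XL + XS - X
    for (j in seq_len(params$inner_iterations)) {
      X <- solve_data_fit(Y_c, Y_g, w, XL, XS, D, params, geometry,
                          pcd_mask, X)
      XL <- svt(-XS + X - D, tau_L)
      XS <- soft_threshold(-XL + X - D, tau_S)
      D <- D + XL + XS - X
    }
    n_outer <- i
    P_diff <- as.matrix(A %*% (X_center - X))
    quad_err <- apply(P_diff^2, 2, max)
    P_new <- as.matrix(A %*% X)
    resid_pcd <- sum((P_new[pcd_mask, ] - Y_c)^2)
    resid_gray <- sum((rowSums(w * P_new) - Y_g)^2)
    resid <- sqrt(resid_pcd + resid_gray)
    diag_rows[[i]] <- data.frame(
      iteration = i, bin = seq_len(M), max_quad_error = quad_err,
      resid_pcd = resid_pcd, resid_gray = resid_gray
    )
    if (verbose && i %% 25 == 0) {
      message(sprintf("outer %d: residual %.6g, max quad error %.3g",
                      i, resid, max(quad_err)))
    }
    if (!all(is.finite(X))) {
      stop(sprintf("run_algorithm1: non-finite state at outer iteration %d", i),
           call. = FALSE)
    }
    if (is.finite(resid_prev) &&
        abs(resid_prev - resid) <= params$tol * max(resid_prev, .Machine$double.eps)) {
      break
    }
    resid_prev <- resid
  }
  X_out <- XL + XS
  structure(
    list(
      X = structure(X_out, grid_n = geometry$grid_n,
                    bin_centers = spectrum$bin_centers,
                    class = c("spectral_image", "matrix")),
      X_last = X, XL = XL, XS = XS,
      iterations = n_outer,
      diagnostics = do.call(rbind, diag_rows[seq_len(n_outer)]),
      params = params
    ),
    class = "prism_fit"
  )
}

#' @export
print.prism_fit <- function(x, ...) {
  d <- x$diagnostics
  last <- d[d$iteration == max(d$iteration), ]
  cat(sprintf(
    "<prism_fit> %d outer iterations; final max quadratic Taylor error %.3g (worst bin), %.3g (median bin)\n",
    x$iterations, max(last$max_quad_error), stats::median(last$max_quad_error)))
  invisible(x)
}
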