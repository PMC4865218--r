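test_that("PCD log transform maps counts to line integrals with a finite floor", {
  sp <- test_spectrum()
  counts <- matrix(sp$weights, 3, 8, byrow = TRUE)
  expect_equal(pcd_log_transform(counts, sp), matrix(0, 3, 8))
  expect_equal(pcd_log_transform(counts * exp(-2), sp),
               matrix(2, 3, 8), tolerance = 1e-12)
  zeros <- matrix(0, 1, 8)
  Y0 <- pcd_log_transform(zeros, sp)
  expect_true(all(is.finite(Y0)))
  expect_equal(as.numeric(Y0), log(sp$weights / 0.5), tolerance = 1e-12)
  expect_error(pcd_log_transform(matrix(-1, 1, 8), sp), "nonnegative")
})

test_that("linearized intensities reproduce the polychromatic EID model", {
  g <- small_geometry()
  sp <- test_spectrum()
  X0 <- matrix(0, 32^2, 8)
  I0 <- taylor_weights(X0, sp, g)
  expect_equal(I0, matrix(sp$weights, g$n_rays, 8, byrow = TRUE))
  # summed over bins, the linearized intensities at X equal the noise-free
  # EID simulation of X (identical exponential model)
  maps <- make_abdomen_phantom(32, seed = 3)
  X <- compose_spectral_images(maps, sp)
  It <- taylor_weights(X, sp, g)
  pr <- simulate_hybrid_scan(X, sp, g, hybrid_layout(g, 1))
  expect_equal(rowSums(It), pr$eid_intensity, tolerance = 1e-12)
  # intensities strictly decrease when attenuation is scaled up
  It2 <- taylor_weights(1.5 * unclass(X), sp, g)
  body_rays <- rowSums(It) < 0.999 * sp$blank_total
  expect_true(all(It2[body_rays, ] < It[body_rays, ] + 1e-12))
})

test_that("grayscale synthesis is exact at the Taylor center, quadratic away from it", {
  g <- small_geometry()
  sp <- test_spectrum()
  maps <- make_abdomen_phantom(32, seed = 3)
  X <- unclass(compose_spectral_images(maps, sp))
  pr <- simulate_hybrid_scan(compose_spectral_images(maps, sp), sp, g,
                             hybrid_layout(g, 1))
  It <- taylor_weights(X, sp, g)
  Yg <- synthesize_grayscale_target(It, pr$eid_intensity, X, g)
  A <- system_matrix(g)
  model <- rowSums(It * as.matrix(A %*% X))
  expect_equal(max(abs(model - Yg)) / max(abs(Yg)), 0, tolerance = 1e-12)
  # blank identity: zero phantom, zero center
  zeroX <- matrix(0, 32^2, 8)
  pr0 <- simulate_hybrid_scan(structure(zeroX, grid_n = 32,
                                        class = c("spectral_image", "matrix")),
                              sp, g, hybrid_layout(g, 1))
  It0 <- taylor_weights(zeroX, sp, g)
  Yg0 <- synthesize_grayscale_target(It0, pr0$eid_intensity, zeroX, g)
  expect_equal(Yg0, numeric(g$n_rays), tolerance = 1e-9 * sp$blank_total)
  # the remainder grows quadratically with the perturbation
  set.seed(11)
  dX <- matrix(rnorm(length(X), sd = 1), nrow(X), ncol(X)) * 0.01 * X
  hs <- 2^seq(-3, 3)
  resid <- vapply(hs, function(h) {
    Xp <- X + h * dX
    prp <- simulate_hybrid_scan(structure(Xp, grid_n = 32,
                                          class = c("spectral_image", "matrix")),
                                sp, g, hybrid_layout(g, 1))
    Ygp <- synthesize_grayscale_target(It, prp$eid_intensity, X, g)
    modelp <- rowSums(It * as.matrix(A %*% Xp))
    sqrt(mean((modelp - Ygp)^2))
  }, numeric(1))
  slope <- coef(lm(log(resid) ~ log(hs)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.1)
})

test_that("soft thresholding and SVT match brute-force prox minimization", {
  set.seed(21)
  lambda <- 1.3
  # soft threshold: elementwise 1D minimization oracle
  for (rep in 1:3) {
    lambda2 <- runif(1, 0.2, 1)
    tau <- lambda2 / (2 * lambda)
    M <- matrix(rnorm(40), 10, 4)
    brute <- vapply(as.numeric(M), function(m) {
      stats::optimize(function(z) lambda2 * abs(z) + lambda * (z - m)^2,
                      c(-10, 10), tol = 1e-10)$minimum
    }, numeric(1))
    expect_equal(as.numeric(soft_threshold(M, tau)), brute, tolerance = 1e-6)
  }
  # SVT: BFGS minimization of the nuclear-norm objective
  for (rep in 1:3) {
    lambda1 <- runif(1, 0.3, 1)
    tau <- lambda1 / (2 * lambda)
    M <- matrix(rnorm(80), 10, 8)
    obj <- function(z) {
      Z <- matrix(z, 10, 8)
      lambda1 * sum(svd(Z)$d) + lambda * sum((Z - M)^2)
    }
    grad <- function(z) {
      Z <- matrix(z, 10, 8)
      s <- svd(Z)
      as.numeric(lambda1 * (s$u %*% t(s$v)) + 2 * lambda * (Z - M))
    }
    o <- stats::optim(as.numeric(0.9 * M), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    expect_equal(svt(M, tau), matrix(o$par, 10, 8), tolerance = 1e-6)
  }
  # analytic cases
  expect_equal(soft_threshold(1.5, 1), 0.5)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0, 2), 0), c(-2, 0, 2))
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(svt(M, 0), M, tolerance = 1e-12)
  # diag(3, 1) in a random orthogonal frame: tau = 2 leaves values (1, 0)
  qa <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  qb <- qr.Q(qr(matrix(rnorm(16), 4, 4)))[, 1:2]
  Mf <- qa %*% diag(c(3, 1)) %*% t(qb)
  expect_equal(svd(svt(Mf, 2))$d, c(1, 0, 0, 0), tolerance = 1e-10)
})

test_that("the data-fit solve honors its limits and decreases the objective", {
  g <- small_geometry()
  sp <- test_spectrum()
  maps <- make_abdomen_phantom(32, seed = 3)
  X_true <- compose_spectral_images(maps, sp)
  lay <- hybrid_layout(g, "full")
  pr <- simulate_hybrid_scan(X_true, sp, g, lay)
  Yc <- pcd_log_transform(pr$pcd_counts, sp)
  Xc <- unclass(X_true)
  It <- taylor_weights(Xc, sp, g)
  gs <- 1 / sp$blank_total
  Yg <- synthesize_grayscale_target(It, pr$eid_intensity, Xc, g) * gs
  w <- It * gs
  N <- nrow(Xc)
  set.seed(4)
  XL <- Xc + matrix(rnorm(N * 8, sd = 0.01), N, 8)
  XS <- matrix(rnorm(N * 8, sd = 0.005), N, 8)
  D <- matrix(rnorm(N * 8, sd = 0.005), N, 8)
  # lambda -> infinity: the penalty dominates and X -> XL + XS + D
  p_inf <- prism_params(lambda = 1e8)
  X_pen <- solve_data_fit(Yc, Yg, w, XL, XS, D, p_inf, g, pr$pcd_mask,
                          matrix(0, N, 8), cg_iterations = 50)
  expect_equal(X_pen, XL + XS + D, tolerance = 1e-4)
  # the quadratic objective is non-increasing along the CG iterates
  p_std <- prism_params(lambda = 1)
  res <- solve_data_fit(Yc, Yg, w, XL, XS, D, p_std, g, pr$pcd_mask,
                        matrix(0, N, 8), track_objective = TRUE)
  expect_true(all(diff(res$objective) <= 1e-8 * res$objective[1]))
  # full-PCD, noise-free, weak coupling: the consistent system recovers truth
  p_weak <- prism_params(lambda = 1e-8)
  X_fit <- solve_data_fit(Yc, Yg, w, 0 * XL, 0 * XS, 0 * D, p_weak, g,
                          pr$pcd_mask, matrix(0, N, 8), cg_iterations = 400)
  for (k in 1:8) {
    expect_lt(sqrt(mean((X_fit[, k] - Xc[, k])^2)) /
                sqrt(mean(Xc[, k]^2)), 0.01)
  }
})

test_that("the nested solver holds a consistent fixed point at the truth", {
  g <- small_geometry()
  sp <- test_spectrum()
  maps <- make_abdomen_phantom(32, seed = 3)
  X_true <- compose_spectral_images(maps, sp)
  lay <- hybrid_layout(g, 1)
  pr <- simulate_hybrid_scan(X_true, sp, g, lay)
  # with (near-)zero shrinkage the truth is an exact fixed point
  params <- prism_params(lambda1 = 1e-15, lambda2 = 1e-15,
                         outer_iterations = 10, tol = 0)
  fit <- run_algorithm1(pr, g, lay, X_true, params)
  expect_equal(fit$iterations, 10)
  rel <- max(abs(fit$X - X_true)) / max(X_true)
  expect_lt(rel, 1e-6)
  d <- fit$diagnostics
  expect_true(all(d$max_quad_error < 1e-12))
})

test_that("the solver runs with a preserved multiplier and reports diagnostics", {
  g <- small_geometry()
  sp <- test_spectrum()
  maps <- make_abdomen_phantom(32, seed = 3)
  X_true <- compose_spectral_images(maps, sp)
  lay <- hybrid_layout(g, 1 / 2)
  pr <- simulate_hybrid_scan(X_true, sp, g, lay)
  init <- initial_estimate(pr, g)
  fit <- run_algorithm1(pr, g, lay, init$X,
                        prism_params(outer_iterations = 5,
                                     reset_multiplier = FALSE))
  expect_s3_class(fit, "prism_fit")
  expect_equal(sort(unique(fit$diagnostics$iteration)), 1:5)
  expect_equal(nrow(fit$diagnostics), 5 * 8)
  expect_true(all(is.finite(fit$diagnostics$max_quad_error)))
  expect_equal(dim(fit$X), c(32^2, 8))
})
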