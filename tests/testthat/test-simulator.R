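test_that("abdomen phantom is deterministic, bounded and body-limited", {
  m1 <- make_abdomen_phantom(64, seed = 7)
  m2 <- make_abdomen_phantom(64, seed = 7)
  expect_identical(m1, m2)
  m3 <- make_abdomen_phantom(64, seed = 8)
  expect_false(identical(m1$water, m3$water))
  expect_true(all(m1$water >= 0 & m1$water <= 1))
  expect_true(all(m1$bone >= 0 & m1$bone <= 1))
  expect_true(all(m1$gadolinium == 0))
  # air outside the body ellipse (corners)
  expect_equal(m1$water[1, 1], 0)
  expect_equal(m1$water[1, 64], 0)
  expect_equal(m1$bone[64, 64], 0)
  # regression fixture: frozen bone pixel counts from the generator itself
  expect_equal(sum(m1$bone > 0), 107)
  counts <- vapply(1:6, function(s) sum(make_abdomen_phantom(64, seed = s)$bone > 0),
                   numeric(1))
  expect_true(all(counts >= 50 & counts <= 160))
  expect_error(make_abdomen_phantom(16), "grid_size")
})

test_that("gadolinium features land where requested", {
  m <- make_abdomen_phantom(64, seed = 7)
  # default layout: four disjoint spots plus one strip
  md <- add_gadolinium_features(m)
  comps <- sum(abs(diff(c(0, as.integer(rowSums(md$gadolinium) > 0)))) == 1)
  expect_gt(sum(md$gadolinium > 0), 0)
  expect_identical(md$water, m$water)
  lay <- default_gd_layout(64)
  for (s in lay$spots) {
    expect_gt(md$gadolinium[s$center[1], s$center[2]], 0)
  }
  expect_gt(md$gadolinium[lay$strip$row, lay$strip$col_start], 0)
  # empty feature set adds nothing
  m0 <- add_gadolinium_features(m, spots = list(), strip = NULL)
  expect_true(all(m0$gadolinium == 0))
  # moving a spot by d pixels moves its centroid by d
  sp1 <- add_gadolinium_features(m, spots = list(list(center = c(32, 32), radius = 3)),
                                 strip = NULL)
  sp2 <- add_gadolinium_features(m, spots = list(list(center = c(32, 22), radius = 3)),
                                 strip = NULL)
  c1 <- mean(col(sp1$gadolinium)[sp1$gadolinium > 0])
  c2 <- mean(col(sp2$gadolinium)[sp2$gadolinium > 0])
  expect_equal(c1 - c2, 10)
  expect_error(add_gadolinium_features(m, spots = list(list(center = c(70, 2), radius = 2))),
               "outside")
})

test_that("spectral composition reflects material curves and the K-edge", {
  sp <- test_spectrum()
  m <- make_abdomen_phantom(64, seed = 7)
  # water-only phantom: every column proportional to the water mu curve
  m$bone[] <- 0
  m$water <- make_abdomen_phantom(64, seed = 7)$water
  X <- compose_spectral_images(m, sp)
  muw <- material_mu(default_material("water"), sp$bin_centers)
  expect_equal(unclass(X), outer(as.numeric(m$water), muw), tolerance = 1e-12,
               ignore_attr = TRUE)
  # columns decrease with bin index for edge-free pixels
  inside <- which(m$water > 0.5)[1:20]
  expect_true(all(apply(X[inside, ], 1, function(r) all(diff(r) < 0))))
  # a gadolinium pixel jumps upward across the K-edge bin boundary
  mg <- add_gadolinium_features(make_abdomen_phantom(64, seed = 7),
                                spots = list(list(center = c(32, 32), radius = 2)),
                                strip = NULL)
  Xg <- compose_spectral_images(mg, sp)
  p <- which(as.numeric(mg$gadolinium) > 0)[1]
  edge_bin <- findInterval(50.207, sp$bin_edges)  # K-edge inside this bin
  gd_part <- Xg[p, ] - X[p, ]
  expect_gt(gd_part[edge_bin + 1], gd_part[edge_bin])
})

test_that("noise-free hybrid scan obeys the blank and conservation identities", {
  g <- small_geometry()
  sp <- test_spectrum()
  lay <- hybrid_layout(g, 1 / 2)
  zero <- structure(matrix(0, 32^2, 8), grid_n = 32,
                    class = c("spectral_image", "matrix"))
  pr <- simulate_hybrid_scan(zero, sp, g, lay)
  expect_equal(pr$eid_intensity, rep(sp$blank_total, g$n_rays))
  expect_equal(pr$pcd_counts,
               matrix(sp$weights, nrow(pr$pcd_counts), 8, byrow = TRUE))
  # single-bin Beer-Lambert on the central ray of a uniform disk
  sb <- single_bin_spectrum()
  img <- disk_phantom(g, radius = 10, value = 0.02)
  X1 <- structure(matrix(img, ncol = 1), grid_n = 32,
                  class = c("spectral_image", "matrix"))
  pr1 <- simulate_hybrid_scan(X1, sb, g, hybrid_layout(g, "full"))
  central <- g$detector_count / 2
  expect_equal(pr1$eid_intensity[central],
               sb$blank_total * exp(-2 * 10 * 0.02), tolerance = 0.01)
  # conservation: EID equals the bin-sum of PCD intensities on PCD rays
  maps <- make_abdomen_phantom(32, seed = 7)
  X <- compose_spectral_images(maps, sp)
  pr2 <- simulate_hybrid_scan(X, sp, g, lay)
  expect_equal(rowSums(pr2$pcd_counts), pr2$eid_intensity[pr2$pcd_mask],
               tolerance = 1e-14)
  # incident_total rescaling
  pr3 <- simulate_hybrid_scan(X, sp, g, lay, incident_total = 5e6)
  expect_equal(pr3$blank_total, 5e6)
  # negative attenuation warns
  Xn <- X; Xn[1, 1] <- -0.1
  expect_warning(simulate_hybrid_scan(Xn, sp, g, lay), "negative")
})

test_that("Poisson noise is reproducible and unbiased", {
  g <- small_geometry()
  sp <- test_spectrum(total = 1e5)
  lay <- hybrid_layout(g, 1 / 2)
  maps <- make_abdomen_phantom(32, seed = 7)
  X <- compose_spectral_images(maps, sp)
  n1 <- simulate_hybrid_scan(X, sp, g, lay, noise = TRUE, seed = 42)
  n2 <- simulate_hybrid_scan(X, sp, g, lay, noise = TRUE, seed = 42)
  expect_identical(n1$pcd_counts, n2$pcd_counts)
  expect_identical(n1$eid_intensity, n2$eid_intensity)
  n3 <- simulate_hybrid_scan(X, sp, g, lay, noise = TRUE, seed = 43)
  expect_false(identical(n1$pcd_counts, n3$pcd_counts))
  expect_true(all(n1$pcd_counts == round(n1$pcd_counts)))
  # empirical mean of repeated draws stays within 4 standard errors
  clean <- simulate_hybrid_scan(X, sp, g, lay)
  ray <- which.max(clean$eid_intensity[clean$pcd_mask] <
                     0.5 * clean$blank_total)
  lambda <- clean$pcd_counts[ray, 4]
  n_rep <- 1e4
  draws <- with_seed_draws <- local({
    set.seed(99)
    stats::rpois(n_rep, lambda)
  })
  expect_lt(abs(mean(draws) - lambda), 4 * sqrt(lambda / n_rep))
})

test_that("beam hardening is visible across rays of the water phantom", {
  g <- small_geometry()
  sp <- test_spectrum()
  # water-only phantom so effective attenuation depends only on path length
  maps <- make_abdomen_phantom(32, seed = 7)
  maps$bone[] <- 0
  maps$water <- (make_abdomen_phantom(32, seed = 7)$water > 0) * 1
  X <- compose_spectral_images(maps, sp)
  pr <- simulate_hybrid_scan(X, sp, g, hybrid_layout(g, "full"))
  path_len <- forward_project(maps$water, g)  # cm through the body
  sel <- path_len > 2
  eff <- -log(pr$eid_intensity[sel] / pr$blank_total) / path_len[sel]
  # effective attenuation strictly decreases with path length
  expect_lt(stats::cor(path_len[sel], eff, method = "spearman"), -0.99)
})
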