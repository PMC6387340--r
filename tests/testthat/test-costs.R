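params9 <- cost_params(hws = 2L, sigma_color = 0.12, sigma_dist = 4,
                       tau = 0.2)

test_that("adaptive weights normalize and degenerate to uniform", {
  img <- matrix(0.5, 9, 9)
  w <- adaptive_weights(img, 5, 5, 2, 0.1, 1e9)
  expect_equal(sum(w), 1)
  expect_equal(w, matrix(1 / 25, 5, 5), tolerance = 1e-9)
  w2 <- adaptive_weights(img, 5, 5, 2, 0.1, 2)
  expect_equal(which.max(w2), 13L)  # center weight maximal
})

test_that("TAD vanishes on identical images and saturates at tau", {
  img <- textured_image(9, 9, seed = 8, smooth = 0) * 0.6
  expect_equal(tad_cost(img, img, c(5, 5), 0, 0, params9), 0)
  I2 <- img + 0.3  # difference >= tau everywhere, no clipping
  expect_equal(tad_cost(img, I2, c(5, 5), 0, 0, params9), params9$tau)
})

test_that("windowed costs match their brute-force oracles", {
  set.seed(9)
  for (k in 1:25) {
    I1 <- matrix(runif(81), 9, 9)
    I2 <- matrix(runif(81), 9, 9)
    p <- c(sample(2:8, 1), sample(2:8, 1))
    d <- sample(0:2, 1); theta <- sample(c(0, 60, 120), 1)
    I2s <- oracle_shift(I2, d * cos(theta * pi / 180),
                        d * sin(theta * pi / 180))
    expect_equal(tad_cost(I1, I2, p, d, theta, params9),
                 oracle_tad(I1, I2s, p[1], p[2], params9$tau, 2, 0.12, 4),
                 tolerance = 1e-5)
    expect_equal(census_cost(I1, I2, p, d, theta, params9),
                 oracle_census(I1, I2s, p[1], p[2], 2, 2, 0.12, 4),
                 tolerance = 1e-5)
    expect_equal(ncc_cost(I1, I2, p, params9),
                 oracle_ncc(I1, I2, p[1], p[2], 2, 0.12, 4, 1e-6),
                 tolerance = 1e-5)
  }
})

test_that("census cost is invariant to a global intensity offset", {
  img <- textured_image(9, 9, seed = 10, smooth = 0) * 0.7
  expect_equal(census_cost(img, img + 0.2, c(5, 5), 0, 0, params9), 0)
})

test_that("NCC is affine-invariant and flags anti-correlation", {
  img <- textured_image(9, 9, seed = 11, smooth = 0) * 0.5
  expect_equal(ncc_cost(img, 0.8 * img + 0.1, c(5, 5), params9), 1)
  expect_equal(ncc_cost(img, 0.5 - img * 0.5, c(5, 5), params9), -1)
  expect_equal(ncc_dissimilarity(1), 0)
  expect_equal(ncc_dissimilarity(-1), 1)
  # textureless window signals 0 similarity
  expect_equal(ncc_cost(matrix(0.5, 9, 9), img, c(5, 5), params9), 0)
})

test_that("correspondence volume nails a zero-disparity scene", {
  img <- textured_image(32, 32, seed = 12)
  eis <- identical_views(img)
  vol <- correspondence_cost_volume(eis, disparity_grid(0:3), params9)
  interior <- 5:28
  expect_true(all(vol$data[interior, interior, 1] < 1e-6))
  w <- wta_depth(vol)
  expect_true(all(w$labels[interior, interior] == 0L))
})

test_that("correspondence volume recovers an integer-disparity plane", {
  sc <- generate_scene(scene_spec(c(64, 64), "fronto_plane", c(0, 5),
                                  disparity_value = 3, seed = 13))
  vol <- correspondence_cost_volume(sc$eis, disparity_grid(0:5),
                                    cost_params())
  w <- wta_depth(vol)
  interior <- 8:57
  expect_gt(mean(w$labels[interior, interior] == 3L), 0.95)
})

test_that("alpha_c = 1 reduces a pair volume to the pure TAD path", {
  img <- textured_image(24, 24, seed = 14)
  eis <- identical_views(img)
  eis$peripheral[["0"]] <- oracle_shift(img, -2, 0)  # view content at d = 2
  p_tad <- cost_params(alpha_c = 1)
  pv <- fimicdepth:::pair_cost_volume(img, eis$peripheral[["0"]], 0,
                                      disparity_grid(0:3), p_tad)
  sh <- shift_view(eis$peripheral[["0"]], 2, 0)
  expect_equal(pv$data[, , 3],
               fimicdepth:::tad_map(img, sh$image, p_tad),
               tolerance = 1e-12)
})

test_that("pure-census volumes are invariant to a global offset", {
  sc <- generate_scene(scene_spec(c(32, 32), "fronto_plane", c(0, 3),
                                  disparity_value = 1, seed = 15))
  eis1 <- sc$eis
  scale_eis <- function(eis, off) {
    eis$central <- eis$central * 0.7 + off
    eis$peripheral <- lapply(eis$peripheral, function(m) m * 0.7 + off)
    eis
  }
  e1 <- scale_eis(eis1, 0)
  e2 <- scale_eis(eis1, 0.2)
  p_cen <- cost_params(alpha_c = 0)
  v1 <- correspondence_cost_volume(e1, disparity_grid(0:3), p_cen)
  v2 <- correspondence_cost_volume(e2, disparity_grid(0:3), p_cen)
  expect_equal(v1$data, v2$data, tolerance = 1e-6)
})

test_that("guided filtering preserves constant volumes", {
  const <- matrix(0.37, 32, 32)
  out <- guided_filter(const, textured_image(32, 32, seed = 16), 8, 1e-4)
  expect_equal(out, const, tolerance = 1e-6)
})

test_that("defocus volume locates a fronto-parallel plane", {
  sc <- generate_scene(scene_spec(c(64, 64), "fronto_plane", c(0, 6),
                                  disparity_value = 3, seed = 17))
  fs <- build_focal_stack(sc$eis, 0:6)
  vol <- defocus_cost_volume(fs, sc$eis$central, cost_params())
  w <- wta_depth(vol)
  interior <- 8:57
  expect_gt(mean(w$labels[interior, interior] == 3L), 0.90)
})

test_that("degenerate stacks tie-break deterministically to the first label", {
  eis <- identical_views(matrix(0.5, 24, 24))
  fs <- build_focal_stack(eis, 0:3)
  vol <- defocus_cost_volume(fs, eis$central, cost_params())
  expect_true(all(wta_depth(vol)$labels == 0L))
})

test_that("alpha_d = 1 equals the TAD-only defocus path", {
  sc <- generate_scene(scene_spec(c(32, 32), "fronto_plane", c(0, 3),
                                  disparity_value = 1, seed = 18))
  fs <- build_focal_stack(sc$eis, 0:3)
  cp1 <- cost_params(alpha_d = 1)
  v <- defocus_cost_volume(fs, sc$eis$central, cp1)
  k <- 2L
  manual <- pmax(guided_filter(
    fimicdepth:::tad_map(sc$eis$central, fs$planes[[k]], cp1),
    sc$eis$central, cp1$guided_radius, cp1$guided_eps), 0)
  expect_equal(v$data[, , k], manual, tolerance = 1e-12)
})

test_that("cost volume container enforces its invariants", {
  expect_error(cost_volume(array(c(NA, 1:7), c(2, 2, 2)), 0:1), "finite")
  expect_error(disparity_grid(c(2, 1)), "increasing")
  expect_error(disparity_grid(3), "increasing|at least")
})
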