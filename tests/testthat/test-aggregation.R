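make_vol <- function(H, W, L, seed, kind = "correspondence") {
  set.seed(seed)
  cost_volume(array(runif(H * W * L), c(H, W, L)), seq_len(L) - 1, kind)
}

test_that("equal gammas reduce to the plain multi-scale mean", {
  img <- textured_image(32, 32, seed = 20)
  fmap <- frequency_map(img, 1, 2, 3)
  vols <- list(`1` = make_vol(32, 32, 4, 1), `2` = make_vol(16, 16, 4, 2),
               `4` = make_vol(8, 8, 4, 3))
  builder <- function(k) vols[[as.character(k)]]
  out <- multiscale_aggregate(builder, fmap,
                              multiscale_params(gamma = c(1, 1, 1) / 3))
  manual <- (vols[[1]]$data +
               upsample_volume(vols[[2]], 32, 32)$data +
               upsample_volume(vols[[3]], 32, 32)$data) / 3
  expect_equal(out$data, manual, tolerance = 1e-6)
})

test_that("gamma (1,0,0) with an all-finest frequency map is the identity", {
  img <- textured_image(24, 24, seed = 21)
  fmap <- frequency_map(img, 1, 2, 3)
  fmap$levels[] <- 2L  # every pixel in the highest-frequency level
  vols <- list(`1` = make_vol(24, 24, 3, 4), `2` = make_vol(12, 12, 3, 5),
               `4` = make_vol(6, 6, 3, 6))
  out <- multiscale_aggregate(function(k) vols[[as.character(k)]], fmap,
                              multiscale_params(gamma = c(1, 0, 0)))
  expect_equal(out$data, vols[[1]]$data, tolerance = 1e-12)
})

test_that("aggregating three identical volumes returns that volume", {
  # holds iff the applied per-pixel weights are normalized to sum 1
  img <- textured_image(16, 16, seed = 22)
  fmap <- frequency_map(img, 1, 2, 3)
  v1 <- make_vol(16, 16, 3, 7)
  vols <- list(`1` = v1,
               `2` = cost_volume(array(v1$data[seq(1, 16, 2), seq(1, 16, 2), ],
                                       c(8, 8, 3)), v1$labels, v1$kind),
               `4` = v1)
  # use full-resolution copies at every scale so upsampling is exact
  out <- multiscale_aggregate(function(k) v1, fmap,
                              multiscale_params(gamma = c(0.6, 0.3, 0.1)))
  expect_equal(out$data, v1$data, tolerance = 1e-6)
})

test_that("gamma ordering is validated", {
  expect_error(multiscale_params(gamma = c(0.1, 0.3, 0.6)), "gamma")
  expect_error(multiscale_aggregate(function(k) make_vol(8, 8, 2, 1),
                                    frequency_map(textured_image(8, 8), 1, 2, 2),
                                    multiscale_params()),
               "Fs")
})

test_that("superpixels partition a constant image into a near-regular grid", {
  seg <- segment_superpixels(matrix(0.5, 64, 64),
                             superpixel_params(approx_size = 16))
  expect_setequal(unique(as.vector(seg$labels)), 0:(seg$count - 1L))
  expect_true(abs(seg$count - 16) <= 4)
  sizes <- table(seg$labels)
  expect_true(all(sizes > 16 * 16 / 4))
})

test_that("superpixel boundaries follow a two-tone edge", {
  img <- matrix(0.1, 64, 64)
  img[, 29:64] <- 0.9
  seg <- segment_superpixels(img, superpixel_params(approx_size = 16))
  # boundary recall: segmentation boundary within 2 px of the tone edge
  lr <- seg$labels[, 28] != seg$labels[, 29]
  near <- seg$labels[, 27:30]
  has_bound <- apply(near, 1, function(v) length(unique(v)) > 1)
  expect_gte(mean(has_bound), 0.95)
  # labels do not leak across the tone boundary
  left <- unique(as.vector(seg$labels[, 1:26]))
  right <- unique(as.vector(seg$labels[, 31:64]))
  expect_length(intersect(left, right), 0)
})

test_that("peak penalty is a unit tent around unanimous labels", {
  costs <- matrix(5, 40, 7)
  costs[, 4] <- 0  # all members vote label index 4 (0-based 3)
  z <- peak_penalty(costs, superpixel_params(Np = 1, sigma_peak = 3))
  expect_equal(z[4], 1)
  expect_true(all(z >= 0 & z <= 1))
  # linear decay to zero at distance sigma
  expect_equal(z, pmax(0, 1 - abs(seq_len(7) - 4) / 3))
})

test_that("peak penalty keeps the Np strongest peaks", {
  set.seed(23)
  costs <- matrix(1, 60, 9)
  costs[1:30, 2] <- 0; costs[31:50, 7] <- 0; costs[51:60, 5] <- 0
  z <- peak_penalty(costs, superpixel_params(Np = 2, sigma_peak = 1))
  expect_equal(z[2], 1)
  expect_equal(z[7], 1)
  expect_lt(z[5], 1)
})

test_that("superpixel shaping is monotone and vanishes at rho = 0", {
  img <- textured_image(32, 32, seed = 24)
  vol <- make_vol(32, 32, 5, 8)
  seg <- segment_superpixels(img, superpixel_params(approx_size = 8))
  out0 <- superpixel_shape_volume(vol, seg,
                                  superpixel_params(approx_size = 8, rho = 0))
  expect_identical(out0$data, vol$data)
  out <- superpixel_shape_volume(vol, seg,
                                 superpixel_params(approx_size = 8, rho = 0.2))
  expect_true(all(out$data >= vol$data - 1e-12))
})

test_that("tiny superpixels with one peak approach a single depth each", {
  sc <- generate_scene(scene_spec(c(64, 64), "fronto_plane", c(0, 4),
                                  disparity_value = 2, seed = 25,
                                  noise_sigma = 0.03))
  vol <- correspondence_cost_volume(sc$eis, disparity_grid(0:4), cost_params())
  spp <- superpixel_params(approx_size = 6, compactness = 0.2, Np = 1,
                           sigma_peak = 0.5, rho = 5)
  seg <- segment_superpixels(sc$eis$central, spp)
  shaped <- superpixel_shape_volume(vol, seg, spp)
  w <- wta_depth(shaped)$labels
  agree <- vapply(split(as.vector(w), as.vector(seg$labels)),
                  function(v) {
                    modal <- which.max(tabulate(v + 1L)) - 1L
                    mean(v == modal)
                  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})
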