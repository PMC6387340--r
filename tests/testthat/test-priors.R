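test_that("frequency map of a constant image is all level zero", {
  fm <- frequency_map(matrix(0.3, 32, 32), 1, 2, 3)
  expect_true(all(fm$raw == 0))
  expect_true(all(fm$levels == 0L))
})

test_that("white noise scores higher raw frequency than a smooth gradient", {
  set.seed(5)
  noise <- matrix(runif(32 * 64), 32, 64)
  grad <- matrix(seq(0, 1, length.out = 64), 32, 64, byrow = TRUE)
  img <- cbind(grad, noise)  # 32 x 128
  fm <- frequency_map(img, 1, 2, 3)
  expect_gt(mean(fm$raw[, 65:128]), mean(fm$raw[, 1:64]))
})

test_that("three-texture phantom quantizes into ordered levels", {
  set.seed(6)
  H <- 48
  flat <- matrix(0.5, H, 48)
  coarse <- gaussian_blur(matrix(runif(H * 48), H, 48), 3)
  coarse <- (coarse - min(coarse)) / diff(range(coarse))
  fine <- matrix(runif(H * 48), H, 48)
  img <- cbind(flat, coarse, fine)
  fm <- frequency_map(img, 1, 2, 3)
  med <- c(median(fm$levels[, 1:48]), median(fm$levels[, 49:96]),
           median(fm$levels[, 97:144]))
  expect_true(med[1] <= med[2] && med[2] <= med[3])
  expect_lt(mean(fm$levels[, 1:48]), mean(fm$levels[, 49:96]))
  expect_lt(mean(fm$levels[, 49:96]), mean(fm$levels[, 97:144]))
})

test_that("frequency map rejects equal sigmas and each pixel gets one level", {
  expect_error(frequency_map(matrix(0.5, 8, 8), 1, 1, 3), "differ")
  fm <- frequency_map(textured_image(32, 32), 1, 2, 4)
  expect_true(all(fm$levels %in% 0:3))
})

test_that("failure weights are uniform on a constant image and sum to one", {
  fm <- failure_maps(matrix(0.7, 24, 24))
  for (a in c("0", "60", "120")) {
    expect_equal(fm$per_axis[[a]], matrix(1 / 3, 24, 24), tolerance = 1e-6)
  }
  img <- textured_image(24, 24, seed = 7)
  fm2 <- failure_maps(img)
  total <- fm2$per_axis[["0"]] + fm2$per_axis[["60"]] + fm2$per_axis[["120"]]
  expect_equal(total, matrix(1, 24, 24), tolerance = 1e-6)
  expect_true(all(unlist(fm2$per_axis) >= 0 & unlist(fm2$per_axis) <= 1))
})

test_that("a vertical step edge favours the horizontal epipolar axis", {
  img <- matrix(0, 32, 32)
  img[, 17:32] <- 1
  fm <- failure_maps(img)
  edge <- cbind(10:22, 16)
  w0 <- fm$per_axis[["0"]][edge]
  expect_true(all(w0 >= fm$per_axis[["60"]][edge]))
  expect_true(all(w0 >= fm$per_axis[["120"]][edge]))
})

test_that("an oriented grating shifts the weights to its transverse axis", {
  # stripes along direction theta are best matched along the transverse
  # axis; the weight argmax must track the grating orientation
  H <- 48
  xx <- matrix(seq_len(H), H, H, byrow = TRUE)
  yy <- matrix(seq_len(H), H, H)
  for (ax in c(0, 60, 120)) {
    th <- (ax + 90) * pi / 180  # stripes run along ax + 90 -> match along ax
    img <- 0.5 + 0.45 * sin(0.8 * (xx * cos(th + pi / 2) +
                                     yy * sin(th + pi / 2)))
    fm <- failure_maps(img)
    ctr <- 12:36
    means <- vapply(c("0", "60", "120"),
                    function(a) mean(fm$per_axis[[a]][ctr, ctr]), numeric(1))
    expect_equal(names(which.max(means)), as.character(ax))
  }
})

test_that("trimap thresholds classify the three bands", {
  img <- matrix(c(0, 1), 16, 16)
  tm <- build_trimap(img, c(0.2, 0.8))
  expect_true(all(unclass(tm) %in% c(0L, 2L)))
  dark <- build_trimap(matrix(0.02, 16, 16), "auto")
  expect_true(all(unclass(dark) == 0L))
  expect_error(build_trimap(img, c(0.8, 0.2)), "t_low")
})

test_that("soft-edged disk trimap confines unknowns to the boundary", {
  H <- 64
  xx <- matrix(seq_len(H), H, H, byrow = TRUE); yy <- t(xx)
  r <- sqrt((xx - 32)^2 + (yy - 32)^2)
  img <- pmin(pmax((20 - r) / 6 + 0.5, 0), 1) * 0.9 + 0.05
  tm <- build_trimap(img, c(0.3, 0.7))
  unk <- unclass(tm) == 1L
  expect_true(all(abs(r[unk] - 20) < 8))
  expect_gt(sum(unk), 0)
})

test_that("alpha matte honours hard constraints and recovers a disk mask", {
  H <- 48
  xx <- matrix(seq_len(H), H, H, byrow = TRUE); yy <- t(xx)
  r <- sqrt((xx - 24)^2 + (yy - 24)^2)
  img <- pmin(pmax((14 - r) / 5 + 0.5, 0), 1) * 0.85 + 0.05
  tm <- build_trimap(img, c(0.25, 0.75))
  mt <- alpha_matte(img, tm)
  expect_true(all(mt$alpha >= 0 & mt$alpha <= 1))
  expect_true(all(mt$alpha[unclass(tm) == 2L] == 1))
  expect_true(all(mt$alpha[unclass(tm) == 0L] == 0))
  # monotone along a radius through the soft edge
  prof <- mt$alpha[24, 24:48]
  expect_true(all(diff(prof) <= 1e-6))
  # recovered mask matches the true disk
  truth <- r <= 14
  expect_gt(mean((mt$alpha >= 0.5) == truth), 0.99)
})

test_that("fully constrained trimaps bypass the solver exactly", {
  img <- matrix(c(0.1, 0.9), 16, 16)
  tm <- build_trimap(img, c(0.4, 0.6))
  mt <- alpha_matte(img, tm)
  expect_identical(mt$alpha, (unclass(tm) == 2L) * 1)
})

test_that("degenerate trimaps are rejected", {
  tm <- build_trimap(matrix(0.01, 8, 8), c(0.3, 0.6))
  expect_error(alpha_matte(matrix(0.01, 8, 8), tm), "degenerate")
})
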