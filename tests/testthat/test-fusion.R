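rand_vol <- function(H, W, L, seed, kind = "fused") {
  set.seed(seed)
  cost_volume(array(runif(H * W * L), c(H, W, L)), seq_len(L) - 1, kind)
}

test_that("winner-takes-all matches a per-pixel argmin loop", {
  vol <- rand_vol(7, 6, 5, 30)
  expect_identical(wta_depth(vol)$labels, oracle_wta(vol$data))
  # unique zero at label 2
  v2 <- vol
  v2$data[, , 3] <- 0
  expect_true(all(wta_depth(v2)$labels == 2L))
  # all-constant: ties break to the first label
  vc <- cost_volume(array(0.5, c(4, 4, 3)), 0:2, "fused")
  expect_true(all(wta_depth(vc)$labels == 0L))
})

test_that("the absolute difference map normalizes and clips", {
  d1 <- depth_map(matrix(0L, 4, 4), 0:4)
  d2 <- depth_map(matrix(4L, 4, 4), 0:4)
  expect_true(all(absolute_difference_map(d1, d1) == 0))
  expect_true(all(absolute_difference_map(d1, d2) == 1))
  set.seed(31)
  a <- matrix(sample(0:4, 36, TRUE), 6, 6)
  b <- matrix(sample(0:4, 36, TRUE), 6, 6)
  mad <- absolute_difference_map(depth_map(a, 0:4), depth_map(b, 0:4), K = 3)
  expect_equal(mad, pmin(abs(a - b) / 3, 1))
  expect_error(absolute_difference_map(d1, d2, K = 0), "K")
})

test_that("GCP penalties anchor the agreed label and vanish elsewhere", {
  vol <- rand_vol(5, 5, 4, 32)
  gcp <- matrix(FALSE, 5, 5); gcp[2, 3] <- TRUE
  agreed <- matrix(1L, 5, 5)
  P <- gcp_penalty(vol, gcp, agreed)
  expect_equal(P[2, 3, 2], 0)            # zero at the agreed label
  expect_equal(P[2, 3, 4], 2 / 3)        # linear in label distance
  gcp_all <- matrix(TRUE, 5, 5)
  P2 <- gcp_penalty(vol, gcp_all, matrix(0L, 5, 5))
  expect_equal(max(P2), 1)               # farthest label before beta scaling
  P[2, 3, ] <- 0
  expect_true(all(P == 0))               # non-GCP pixels contribute nothing
})

test_that("the fused data term matches the elementwise mixing formula", {
  Cd <- rand_vol(6, 5, 4, 33, "defocus")
  Cc <- rand_vol(6, 5, 4, 34, "correspondence")
  set.seed(35)
  mad <- matrix(runif(30), 6, 5)
  P <- array(runif(120), c(6, 5, 4))
  fp <- fusion_params(beta = 0.7, mad_weighting = "as_printed")
  out <- build_data_term(Cd, Cc, mad, P, fp)
  manual <- array(0, c(6, 5, 4))
  for (i in 1:6) for (j in 1:5) for (k in 1:4) {
    manual[i, j, k] <- (1 - mad[i, j]) * Cd$data[i, j, k] +
      mad[i, j] * Cc$data[i, j, k] + 0.7 * P[i, j, k]
  }
  expect_equal(out$data, manual, tolerance = 1e-12)
  # endpoints
  z <- matrix(0, 6, 5)
  expect_equal(build_data_term(Cd, Cc, z, NULL, fp)$data, Cd$data)
  expect_equal(build_data_term(Cd, Cc, z + 1, NULL, fp)$data, Cc$data)
  # the prose convention swaps the two volumes
  fp2 <- fusion_params(mad_weighting = "as_prose")
  expect_equal(build_data_term(Cd, Cc, z, NULL, fp2)$data, Cc$data)
})

test_that("the max-flow backend agrees with an independent solver", {
  skip_if_not_installed("igraph")
  set.seed(29)
  for (t in 1:100) {
    n <- sample(4:12, 1)
    m <- sample(5:30, 1)
    fr <- sample(n, m, TRUE); to <- sample(n, m, TRUE)
    keep <- fr != to
    fr <- fr[keep]; to <- to[keep]
    if (length(fr) == 0) next
    cap <- round(runif(length(fr), 0.1, 5), 3)
    scap <- round(runif(n, 0, 3), 3) * rbinom(n, 1, 0.5)
    tcap <- round(runif(n, 0, 3), 3) * rbinom(n, 1, 0.5)
    src <- n + 1L; snk <- n + 2L
    gfr <- c(fr, rep(src, n), 1:n)
    gto <- c(to, 1:n, rep(snk, n))
    gcap <- c(cap, scap, tcap)
    pos <- gcap > 0
    g <- igraph::make_graph(rbind(gfr[pos], gto[pos]), n = n + 2L,
                            directed = TRUE)
    f_ref <- igraph::max_flow(g, src, snk, capacity = gcap[pos])$value
    f_bk <- fimicdepth:::cpp_maxflow(n, fr, to, cap, scap - tcap)$flow +
      sum(pmin(scap, tcap))
    expect_equal(f_bk, f_ref, tolerance = 1e-9)
  }
})

test_that("zero smoothness reduces the graph cut to WTA", {
  vol <- rand_vol(8, 8, 4, 36)
  r <- graphcut_optimize(vol, fusion_params(lambda_smooth = 0))
  expect_identical(r$labels, wta_depth(vol)$labels)
})

test_that("both cut routes reach the exhaustive optimum on small instances", {
  set.seed(37)
  combos <- as.matrix(expand.grid(rep(list(0:2), 9)))
  for (k in 1:8) {
    vol <- rand_vol(3, 3, 3, 370 + k)
    lam <- runif(1, 0.05, 0.4)
    best <- min(apply(combos, 1, function(v)
      labeling_energy(matrix(v, 3, 3), vol, lam)))
    ri <- graphcut_optimize(vol, fusion_params(lambda_smooth = lam,
                                               optimizer = "ishikawa"))
    expect_equal(labeling_energy(ri$labels, vol, lam), best,
                 tolerance = 1e-9)
    re <- graphcut_optimize(vol, fusion_params(lambda_smooth = lam,
                                               optimizer = "expansion",
                                               max_expansion_sweeps = 10))
    ee <- labeling_energy(re$labels, vol, lam)
    expect_lte(ee, attr(re, "energies")[1] + 1e-9)
  }
})

test_that("graph cut denoises a two-region labeling and lowers the energy", {
  set.seed(38)
  H <- 24; W <- 24; L <- 4
  truth <- matrix(1L, H, W); truth[, 13:24] <- 3L
  data <- array(0.5, c(H, W, L))
  for (k in 1:L) data[, , k] <- abs(truth - (k - 1)) * 0.2
  noise_idx <- sample(H * W, 40)
  for (ii in noise_idx) {
    data[ii + (sample(L, 1) - 1L) * H * W] <- -0.1  # attractive wrong label
  }
  vol <- cost_volume(pmax(data, 0), 0:3, "fused")
  r <- graphcut_optimize(vol, fusion_params(lambda_smooth = 0.3))
  en <- attr(r, "energies")
  expect_lt(en[length(en)], en[1])
  expect_gt(mean(r$labels == truth), 0.98)
})

test_that("masked-out pixels cannot drag their valid neighbours", {
  H <- 16; W <- 16
  valid <- matrix(TRUE, H, W); valid[, 9:16] <- FALSE
  data <- array(0, c(H, W, 3))
  # valid half prefers label 0; masked half strongly prefers label 2
  data[, 1:8, 1] <- 0; data[, 1:8, 2] <- 0.2; data[, 1:8, 3] <- 0.4
  data[, 9:16, 1] <- 1; data[, 9:16, 2] <- 1; data[, 9:16, 3] <- 0
  vol <- cost_volume(data, 0:2, "fused")
  r <- graphcut_optimize(vol, fusion_params(lambda_smooth = 5), valid)
  expect_true(all(r$labels[, 1:8] == 0L))
  expect_true(all(r$labels[, 9:16] == 2L))
})

test_that("post-filtering preserves constants and removes isolated outliers", {
  guide <- textured_image(24, 24, seed = 39)
  const <- depth_map(matrix(2L, 24, 24), 0:4)
  expect_true(all(postprocess(const, guide)$labels == 2L))
  # single-pixel outlier on a plane
  lab <- matrix(2L, 24, 24); lab[12, 12] <- 4L
  out <- postprocess(depth_map(lab, 0:4), matrix(0.5, 24, 24))
  expect_true(all(out$labels == 2L))
})

test_that("post-filtering keeps a depth step aligned with a guide edge", {
  H <- 32
  guide <- matrix(0.1, H, H); guide[, 17:32] <- 0.9
  lab <- matrix(1L, H, H); lab[, 17:32] <- 3L
  out <- postprocess(depth_map(lab, 0:4), guide)
  expect_true(all(out$labels[, 1:15] == 1L))
  expect_true(all(out$labels[, 18:32] == 3L))
})
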