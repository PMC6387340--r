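# Independent brute-force oracles: plain scalar loops over the printed
# formulas, sharing no code with the package internals.

clampi <- function(v, lo, hi) min(max(v, lo), hi)

# adaptive support weight of offset (r, q) at pixel (x, y)
oracle_weight <- function(ref, x, y, r, q, sc, sd) {
  ii <- clampi(x + r, 1, nrow(ref))
  jj <- clampi(y + q, 1, ncol(ref))
  exp(-(abs(ref[x, y] - ref[ii, jj]) / sc + sqrt(r^2 + q^2) / sd))
}

# normalized adaptive-weight aggregation of a raw per-pixel cost map
oracle_asw <- function(raw, ref, x, y, hws, sc, sd) {
  acc <- 0; norm <- 0
  for (r in -hws:hws) {
    for (q in -hws:hws) {
      w <- oracle_weight(ref, x, y, r, q, sc, sd)
      ii <- clampi(x + r, 1, nrow(raw))
      jj <- clampi(y + q, 1, ncol(raw))
      acc <- acc + w * raw[ii, jj]
      norm <- norm + w
    }
  }
  acc / norm
}

# truncated absolute difference between I1 and a pre-shifted I2
oracle_tad <- function(I1, I2s, x, y, tau, hws, sc, sd) {
  raw <- pmin(abs(I1 - I2s), tau)
  oracle_asw(raw, I1, x, y, hws, sc, sd)
}

# census bit string of a pixel (comparisons against the window center)
oracle_census_bits <- function(img, x, y, chws) {
  bits <- c()
  for (r in -chws:chws) {
    for (q in -chws:chws) {
      if (r == 0 && q == 0) next
      ii <- clampi(x + r, 1, nrow(img))
      jj <- clampi(y + q, 1, ncol(img))
      bits <- c(bits, img[ii, jj] < img[x, y] - 1e-9)  # tie-robust census
    }
  }
  bits
}

# aggregated normalized census Hamming cost
oracle_census <- function(I1, I2s, x, y, chws, hws, sc, sd) {
  H <- nrow(I1); W <- ncol(I1)
  ham <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      b1 <- oracle_census_bits(I1, i, j, chws)
      b2 <- oracle_census_bits(I2s, i, j, chws)
      ham[i, j] <- mean(b1 != b2)
    }
  }
  oracle_asw(ham, I1, x, y, hws, sc, sd)
}

# weighted NCC via weighted moments with adaptive weights from ref = I1
oracle_ncc <- function(I1, I2, x, y, hws, sc, sd, var_eps) {
  sw <- 0; s1 <- 0; s2 <- 0; s11 <- 0; s22 <- 0; s12 <- 0
  for (r in -hws:hws) {
    for (q in -hws:hws) {
      w <- oracle_weight(I1, x, y, r, q, sc, sd)
      ii <- clampi(x + r, 1, nrow(I1))
      jj <- clampi(y + q, 1, ncol(I1))
      a <- I1[ii, jj]; b <- I2[ii, jj]
      sw <- sw + w; s1 <- s1 + w * a; s2 <- s2 + w * b
      s11 <- s11 + w * a^2; s22 <- s22 + w * b^2; s12 <- s12 + w * a * b
    }
  }
  m1 <- s1 / sw; m2 <- s2 / sw
  v1 <- s11 / sw - m1^2; v2 <- s22 / sw - m2^2
  if (v1 < var_eps || v2 < var_eps) return(0)
  max(min((s12 / sw - m1 * m2) / sqrt(v1 * v2), 1), -1)
}

# per-pixel argmin with first-index tie break
oracle_wta <- function(data3d) {
  H <- dim(data3d)[1]; W <- dim(data3d)[2]
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j] <- which.min(data3d[i, j, ]) - 1L
    }
  }
  out
}

# bilinear sampling of img at (row + dy, col + dx), clamped
oracle_shift <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      y <- min(max(i + dy, 1), H)
      x <- min(max(j + dx, 1), W)
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1, H); x1 <- min(x0 + 1, W)
      fy <- y - y0; fx <- x - x0
      out[i, j] <- (1 - fy) * ((1 - fx) * img[y0, x0] + fx * img[y0, x1]) +
        fy * ((1 - fx) * img[y1, x0] + fx * img[y1, x1])
    }
  }
  out
}

# textured scene helper used by several tests
textured_image <- function(H, W, seed = 1, smooth = 1) {
  set.seed(seed)
  img <- matrix(runif(H * W), H, W)
  if (smooth > 0) img <- gaussian_blur(img, smooth)
  rng <- range(img)
  (img - rng[1]) / diff(rng) * 0.8 + 0.1
}

# 7 identical views as an elemental image set
identical_views <- function(img) {
  r <- floor(min(dim(img)) / 2)
  geom <- hex_geometry(c(3 * r, 3 * r), r)
  per <- setNames(replicate(6, img, simplify = FALSE),
                  as.character(c(0, 60, 120, 180, 240, 300)))
  elemental_image_set(img, per, geom)
}
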