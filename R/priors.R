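#' Difference-of-Gaussians frequency map
#'
#' Estimates the local spatial-frequency content of the reference image as
#' the magnitude of the difference between two Gaussian-blurred copies,
#' then quantizes it into `Fs` equal-population (quantile) levels. Level 0 is
#' the lowest-frequency bin; the level image later selects which resolution
#' of the multi-scale cost stack a pixel trusts most.
#'
#' @param reference grayscale image in `[0, 1]`.
#' @param sigma1,sigma2 Gaussian standard deviations in pixels; must differ.
#' @param Fs number of quantization levels (>= 2), typically equal to the
#'   number of scales of the multi-scale aggregation (3).
#' @return object of class `frequency_map`: list with `raw` (|DoG|), `levels`
#'   (integer matrix in 0..Fs-1), `Fs`, `sigma1`, `sigma2`.
#' @export
frequency_map <- function(reference, sigma1 = 1, sigma2 = 2, Fs = 3L) {
  if (sigma1 == sigma2) stop("sigma1 and sigma2 must differ")
  if (Fs < 2L) stop("Fs must be >= 2")
  raw <- abs(gaussian_blur(reference, sigma1) - gaussian_blur(reference, sigma2))
  br <- stats::quantile(raw, probs = seq_len(Fs - 1L) / Fs, names = FALSE)
  levels <- matrix(0L, nrow(raw), ncol(raw))
  for (b in br) levels <- levels + (raw > b)
  structure(list(raw = raw, levels = levels, Fs = as.integer(Fs),
                 sigma1 = sigma1, sigma2 = sigma2),
            class = "frequency_map")
}

# 3x3 Sobel derivative pair; Kx responds to horizontal gradients (vertical
# edges), Ky = t(Kx) to vertical gradients (horizontal edges)
sobel_kernels <- function() {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # cols = x direction
  list(kx = kx, ky = t(kx))
}

#' Directional failure-prediction weights for the three epipolar axes
#'
#' Correspondence search along an epipolar axis fails on structures aligned
#' with that axis (the aperture problem). For each axis theta in
#' {0, 60, 120} degrees an edge-along-theta detector is built by steering the
#' Sobel derivative pair to the direction transverse to the axis; the axis
#' weight is the normalized complement of the (lightly smoothed) detector
#' magnitude, so the axis most transverse to the local edge receives the
#' largest weight. Per pixel the three weights sum to 1; on featureless
#' regions all axes get 1/3.
#'
#' @param reference grayscale image.
#' @param smooth_sigma Gaussian smoothing of the edge magnitudes, pixels.
#' @return object of class `failure_maps`: list `per_axis` with entries
#'   `"0"`, `"60"`, `"120"` (weight matrices) and `failure` (raw magnitudes).
#' @export
failure_maps <- function(reference, smooth_sigma = 1) {
  k <- sobel_kernels()
  sx <- convolve2(reference, k$kx)
  sy <- convolve2(reference, k$ky)
  axes <- c(0, 60, 120)
  fail <- lapply(axes, function(theta) {
    phi <- (theta + 90) * pi / 180  # transverse direction = edge-along-axis
    gaussian_blur(abs(cos(phi) * sx + sin(phi) * sy), smooth_sigma)
  })
  names(fail) <- as.character(axes)
  tot <- fail[["0"]] + fail[["60"]] + fail[["120"]]
  eps <- 1e-8
  wtil <- lapply(fail, function(f) (tot - f) + eps)
  wsum <- wtil[["0"]] + wtil[["60"]] + wtil[["120"]]
  per_axis <- lapply(wtil, function(w) w / wsum)
  structure(list(per_axis = per_axis, failure = fail),
            class = "failure_maps")
}

# exhaustive two-threshold Otsu on a 256-bin histogram
otsu3 <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  centers <- (seq_len(nbins) - 0.5) / nbins
  cw <- cumsum(p)
  cm <- cumsum(p * centers)
  best <- c(-Inf, 1L, 2L)
  for (t1 in 1:(nbins - 2L)) {
    w0 <- cw[t1]
    m0 <- cm[t1]
    for (t2 in (t1 + 1L):(nbins - 1L)) {
      w1 <- cw[t2] - w0
      w2 <- 1 - cw[t2]
      if (w1 <= 0 && w2 <= 0) next
      m1 <- cm[t2] - m0
      m2 <- cm[nbins] - cm[t2]
      v <- 0
      if (w0 > 0) v <- v + m0^2 / w0
      if (w1 > 0) v <- v + m1^2 / w1
      if (w2 > 0) v <- v + m2^2 / w2
      if (v > best[1L]) best <- c(v, t1, t2)
    }
  }
  c(best[2L], best[3L]) / nbins
}

#' Three-level trimap by multi-level thresholding
#'
#' Quantizes the (focused) reference image into background (below the low
#' threshold), foreground (above the high threshold) and an unknown band in
#' between, to be resolved by [alpha_matte()]. Fluorescence scenes have a
#' dark, nearly uniform background that this isolates directly.
#'
#' @param reference grayscale image in `[0, 1]`.
#' @param thresholds numeric `c(t_low, t_high)` with `t_low < t_high`, or
#'   `"auto"` for a two-threshold (three-class) Otsu.
#' @return integer matrix of class `trimap` with values 0 (background),
#'   1 (unknown), 2 (foreground).
#' @export
build_trimap <- function(reference, thresholds = "auto") {
  if (identical(thresholds, "auto")) {
    if (diff(range(reference)) < 1e-9) {
      thresholds <- c(0.5, 0.5) + max(reference)  # constant image: background
    } else {
      thresholds <- otsu3(reference)
    }
  } else {
    if (length(thresholds) != 2L || thresholds[1L] >= thresholds[2L]) {
      stop("thresholds must satisfy t_low < t_high")
    }
  }
  tm <- matrix(1L, nrow(reference), ncol(reference))
  tm[reference < thresholds[1L]] <- 0L
  tm[reference > thresholds[2L]] <- 2L
  structure(tm, class = c("trimap", "matrix"), thresholds = thresholds)
}

# grayscale matting Laplacian (Levin-style, 3x3 windows), sparse
matting_laplacian <- function(I, eps = 1e-7) {
  H <- nrow(I); W <- ncol(I)
  ic <- 2:(H - 1L); jc <- 2:(W - 1L)
  centers <- as.vector(outer(ic, (jc - 1L) * H, `+`))  # linear indices
  off <- as.vector(outer(-1:1, (-1:1) * H, `+`))       # 3x3 window offsets
  nw <- length(centers)
  idx <- outer(centers, off, `+`)                      # nw x 9 member indices
  vals <- matrix(I[idx], nw, 9L)
  mu <- rowMeans(vals)
  v <- rowMeans(vals * vals) - mu * mu
  denom <- v + eps / 9
  dev <- vals - mu
  ti <- vector("list", 81L); tj <- ti; tx <- ti
  n <- 0L
  for (a in 1:9) {
    for (b in 1:9) {
      n <- n + 1L
      ti[[n]] <- idx[, a]
      tj[[n]] <- idx[, b]
      tx[[n]] <- (a == b) - (1 + dev[, a] * dev[, b] / denom) / 9
    }
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(H * W, H * W))
}

#' Solve an alpha matte from a trimap
#'
#' Propagates the hard trimap constraints through the unknown band with a
#' matting-Laplacian affinity (local color-line model on 3x3 windows,
#' grayscale specialization), solved as a sparse linear system. Foreground
#' and background constraints are satisfied exactly; the matte is used
#' downstream only as a validity mask and evaluation region.
#'
#' @param reference grayscale image in `[0, 1]`.
#' @param trimap a [build_trimap()] result (0/1/2 integer matrix).
#' @param eps matting-Laplacian regularization.
#' @param lambda constraint weight of the trimap pixels.
#' @return object of class `matte`: list with `alpha` in `[0, 1]`, `trimap`
#'   and `mask` (`alpha >= 0.5`).
#' @export
alpha_matte <- function(reference, trimap, eps = 1e-7, lambda = 100) {
  tm <- unclass(trimap)
  n_fg <- sum(tm == 2L); n_bg <- sum(tm == 0L)
  if (n_fg == 0L || n_bg == 0L) {
    stop("degenerate trimap: need at least one foreground and one background pixel")
  }
  if (!any(tm == 1L)) {
    alpha <- (tm == 2L) * 1
  } else {
    N <- length(tm)
    L <- matting_laplacian(reference, eps)
    constrained <- as.numeric(tm != 1L)
    b <- as.numeric(tm == 2L)
    A <- L + Matrix::Diagonal(N, lambda * constrained)
    alpha <- as.vector(Matrix::solve(A, lambda * (constrained * b)))
    alpha <- matrix(pmin(pmax(alpha, 0), 1), nrow(tm), ncol(tm))
    alpha[tm == 2L] <- 1
    alpha[tm == 0L] <- 0
  }
  alpha <- matrix(alpha, nrow(tm), ncol(tm))
  structure(list(alpha = alpha, trimap = trimap, mask = alpha >= 0.5),
            class = "matte")
}
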