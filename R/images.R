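#' Image utilities
#'
#' Images are plain numeric matrices (rows = y, columns = x) with intensities
#' in `[0, 1]`. RGB input is reduced to luma on load; 8- and 16-bit PNG and
#' TIFF are supported through the \pkg{png} and \pkg{tiff} packages.
#'
#' @name image-utils
NULL

#' Convert an image array to a grayscale matrix in [0, 1]
#'
#' 3-channel arrays are reduced with the Rec. 601 luma weights
#' (0.299, 0.587, 0.114); 4-channel arrays drop the alpha channel first.
#'
#' @param img numeric matrix or H x W x C array.
#' @return numeric matrix.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
    }
    return(img[, , 1L])
  }
  stop("unsupported image dimensions: ", paste(dim(img), collapse = "x"))
}

#' Read an image file as a grayscale [0, 1] matrix
#'
#' @param path PNG or TIFF file.
#' @return numeric matrix with intensities in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  img <- as_gray(img)
  storage.mode(img) <- "double"
  # integer formats arrive scaled to [0,1] already; guard float TIFFs
  pmin(pmax(img, 0), 1)
}

#' Write a grayscale matrix to PNG (integer) or TIFF (float, lossless)
#'
#' @param img numeric matrix; values are clipped to `[0, 1]` for PNG.
#' @param path destination; format chosen by extension.
#' @param bits PNG bit depth, 8 or 16 (ignored for TIFF, written as float32).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(img, 0), 1), target = path,
                  dpi = NULL, asp = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L, compression = "none")
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

# replicate-padding shift: out[i, j] = img[clamp(i + dr), clamp(j + dc)]
shift_replicate <- function(img, dr, dc) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  img[ri, ci, drop = FALSE]
}

#' 2-D convolution with a small kernel and replicate padding
#'
#' Correlation convention: `out(p) = sum_o k(o) * img(p + o)` with the kernel
#' indexed from its center. Intended for small (e.g. 3x3) kernels.
#'
#' @param img numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @return filtered matrix, same shape.
#' @export
convolve2 <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (a in seq_len(nrow(kernel))) {
    for (b in seq_len(ncol(kernel))) {
      k <- kernel[a, b]
      if (k != 0) out <- out + k * shift_replicate(img, a - 1L - kr, b - 1L - kc)
    }
  }
  out
}

#' Separable Gaussian blur with replicate padding
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma = 0` returns the input.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-rad):rad
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(img), ncol(img))
  for (a in seq_along(x)) out <- out + k[a] * shift_replicate(img, x[a], 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (a in seq_along(x)) out2 <- out2 + k[a] * shift_replicate(out, 0L, x[a])
  out2
}

# box mean over a (2r+1)^2 window with replicate padding, via integral image
box_mean <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq.int(1L - r, H + r), 1L), H)
  ci <- pmin(pmax(seq.int(1L - r, W + r), 1L), W)
  pad <- img[ri, ci, drop = FALSE]
  sat <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed integral image
  sat <- rbind(0, cbind(0, t(sat)))                 # (H+2r+1) x (W+2r+1)
  n <- 2L * r + 1L
  i1 <- seq_len(H); i2 <- i1 + n
  j1 <- seq_len(W); j2 <- j1 + n
  (sat[i2, j2, drop = FALSE] - sat[i1, j2, drop = FALSE] -
     sat[i2, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]) / (n * n)
}

#' Guided image filter (grayscale guide)
#'
#' Edge-preserving linear filter of He et al.; constant inputs are preserved
#' exactly. Used per cost-volume slice and on the final disparity image.
#'
#' @param p input image to filter.
#' @param guide guide image (same shape), typically the central view.
#' @param radius window radius in pixels.
#' @param eps regularization (intensity^2 units).
#' @return filtered image.
#' @export
guided_filter <- function(p, guide, radius = 8L, eps = 1e-4) {
  mI <- box_mean(guide, radius)
  mp <- box_mean(p, radius)
  corrI <- box_mean(guide * guide, radius)
  corrIp <- box_mean(guide * p, radius)
  varI <- corrI - mI * mI
  covIp <- corrIp - mI * mp
  a <- covIp / (varI + eps)
  b <- mp - a * mI
  box_mean(a, radius) * guide + box_mean(b, radius)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param H,W output size.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, H, W) {
  h <- nrow(img); w <- ncol(img)
  src_y <- pmin(pmax((seq_len(H) - 0.5) * h / H - 0.5, 0), h - 1)
  src_x <- pmin(pmax((seq_len(W) - 0.5) * w / W - 0.5, 0), w - 1)
  y0 <- pmin(floor(src_y), h - 1); fy <- src_y - y0
  x0 <- pmin(floor(src_x), w - 1); fx <- src_x - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  A <- img[y0 + 1, x0 + 1, drop = FALSE]; B <- img[y0 + 1, x1 + 1, drop = FALSE]
  C <- img[y1 + 1, x0 + 1, drop = FALSE]; D <- img[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  (1 - wy) * ((1 - wx) * A + wx * B) + wy * ((1 - wx) * C + wx * D)
}

#' Block-mean downsampling by an integer factor
#'
#' The image is replicate-padded to a multiple of `k` before averaging.
#'
#' @param img numeric matrix.
#' @param k integer factor (1 returns the input).
#' @return downsampled matrix of size `ceiling(dim(img)/k)`.
#' @export
downsample_block <- function(img, k) {
  k <- as.integer(k)
  if (k == 1L) return(img)
  H <- nrow(img); W <- ncol(img)
  H2 <- ceiling(H / k); W2 <- ceiling(W / k)
  ri <- pmin(seq_len(H2 * k), H)
  ci <- pmin(seq_len(W2 * k), W)
  pad <- img[ri, ci, drop = FALSE]
  a <- array(pad, dim = c(k, H2, k * W2))
  m <- matrix(colMeans(a), H2, k * W2)
  a2 <- array(t(m), dim = c(k, W2, H2))
  t(matrix(colMeans(a2), W2, H2))
}

#' Shift a view toward/along its epipolar direction (bilinear)
#'
#' Samples `img` at `p + t * (cos(theta), sin(theta))` in (col, row)
#' coordinates with the row axis pointing down. Returns the shifted image and
#' a validity mask flagging samples taken fully inside the frame
#' (out-of-frame samples are edge-clamped).
#'
#' @param img numeric matrix.
#' @param t shift magnitude in pixels (may be fractional).
#' @param theta_deg direction in degrees.
#' @return list with `image` and `valid` matrices.
#' @export
shift_view <- function(img, t, theta_deg) {
  th <- theta_deg * pi / 180
  cpp_bilinear_shift(img, t * cos(th), t * sin(th))
}

# per-pixel backward warp: out(p) = img(p + (dx(p), dy(p))), bilinear, clamped
bilinear_warp <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) + dx
  y <- matrix(seq_len(H) - 1, H, W) + dy
  x <- pmin(pmax(x, 0), W - 1)
  y <- pmin(pmax(y, 0), H - 1)
  x0 <- pmin(floor(x), W - 1); y0 <- pmin(floor(y), H - 1)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  at <- function(yy, xx) matrix(img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)], H, W)
  (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x1)) +
    fy * ((1 - fx) * at(y1, x0) + fx * at(y1, x1))
}
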