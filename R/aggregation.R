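#' Multi-scale aggregation parameters
#'
#' @param scales integer downscaling factors, finest first (default 1, 2, 4).
#' @param gamma length-3 weights `(gamma1, gamma2, gamma3)` applied to the
#'   scale matched to a pixel's frequency level, the adjacent scale(s) and
#'   the remaining scale(s); must satisfy `1 >= g1 >= g2 >= g3 >= 0`. The
#'   applied per-pixel weights are renormalized to sum 1. Typical values are
#'   (0.6, 0.3, 0.1); equal weights reduce to a plain multi-scale average.
#' @return object of class `multiscale_params`.
#' @export
multiscale_params <- function(scales = c(1L, 2L, 4L),
                              gamma = c(0.6, 0.3, 0.1)) {
  stopifnot(length(gamma) == 3L)
  if (!(1 >= gamma[1L] && gamma[1L] >= gamma[2L] &&
        gamma[2L] >= gamma[3L] && gamma[3L] >= 0)) {
    stop("gamma must satisfy 1 >= g1 >= g2 >= g3 >= 0")
  }
  structure(list(scales = as.integer(scales), gamma = gamma),
            class = "multiscale_params")
}

#' Upsample every slice of a cost volume to a target spatial size
#'
#' @param vol a [cost_volume()].
#' @param H,W target size.
#' @return a [cost_volume()] with bilinearly resized slices.
#' @export
upsample_volume <- function(vol, H, W) {
  L <- dim(vol$data)[3L]
  out <- array(0, c(H, W, L))
  for (k in seq_len(L)) out[, , k] <- resize_bilinear(vol$data[, , k], H, W)
  cost_volume(pmax(out, 0), vol$labels, vol$kind)
}

#' Frequency-weighted multi-scale cost aggregation
#'
#' Builds the cost volume at each scale through `volume_builder`, upsamples
#' the coarse volumes back to full resolution, and blends them per pixel
#' with weights driven by the frequency map: a pixel in the highest
#' frequency level puts `gamma1` on the full-resolution volume, pixels in
#' the lowest level trust the coarsest scale, adjacent scales get `gamma2`
#' and the rest `gamma3`; the applied weights are normalized to sum 1 per
#' pixel. With equal gammas this is the plain unweighted multi-scale mean.
#'
#' @param volume_builder function of one argument (the integer scale factor)
#'   returning a [cost_volume()] computed on images downscaled by that
#'   factor; the label count must not depend on the scale.
#' @param fmap a [frequency_map()] at full resolution with
#'   `Fs == length(params$scales)`.
#' @param params a [multiscale_params()].
#' @return a [cost_volume()] at full resolution.
#' @export
multiscale_aggregate <- function(volume_builder, fmap, params = multiscale_params()) {
  ns <- length(params$scales)
  if (fmap$Fs != ns) {
    stop("frequency map levels (Fs) must match the number of scales")
  }
  H <- nrow(fmap$levels); W <- ncol(fmap$levels)
  vols <- lapply(params$scales, volume_builder)
  for (i in seq_len(ns)) {
    d <- dim(vols[[i]]$data)
    if (d[1L] != H || d[2L] != W) vols[[i]] <- upsample_volume(vols[[i]], H, W)
  }
  L <- dim(vols[[1L]]$data)[3L]
  # matched scale index per pixel: highest frequency level -> finest scale
  matched <- fmap$Fs - 1L - fmap$levels  # 0-based scale index
  wts <- vector("list", ns)
  wsum <- matrix(0, H, W)
  g <- params$gamma
  for (i in seq_len(ns)) {
    dist <- abs(matched - (i - 1L))
    wi <- matrix(g[3L], H, W)
    wi[dist == 1L] <- g[2L]
    wi[dist == 0L] <- g[1L]
    wts[[i]] <- wi
    wsum <- wsum + wi
  }
  out <- array(0, c(H, W, L))
  for (i in seq_len(ns)) {
    wi <- wts[[i]] / wsum
    for (k in seq_len(L)) {
      out[, , k] <- out[, , k] + wi * vols[[i]]$data[, , k]
    }
  }
  cost_volume(out, vols[[1L]]$labels, vols[[1L]]$kind)
}

#' Superpixel shaping parameters
#'
#' @param approx_size approximate superpixel side length in pixels.
#' @param compactness intensity bandwidth of the SLIC distance (intensity
#'   units; smaller values follow image edges more closely).
#' @param Np maximum number of histogram peaks retained per superpixel.
#' @param sigma_peak tent half-width of the peak widening, in labels.
#' @param rho scale of the additive non-peak penalty.
#' @param iters SLIC iterations.
#' @return object of class `superpixel_params`.
#' @export
superpixel_params <- function(approx_size = 16L, compactness = 0.1,
                              Np = 3L, sigma_peak = 3, rho = 0.2,
                              iters = 5L) {
  stopifnot(Np >= 1L, sigma_peak > 0, rho >= 0, approx_size >= 2L)
  structure(list(approx_size = as.integer(approx_size),
                 compactness = compactness, Np = as.integer(Np),
                 sigma_peak = sigma_peak, rho = rho,
                 iters = as.integer(iters)),
            class = "superpixel_params")
}

#' SLIC superpixel segmentation (grayscale)
#'
#' Local k-means in (intensity, x, y) space seeded on a regular grid of
#' spacing `approx_size`, with connectivity enforcement; deterministic for a
#' given image and parameters.
#'
#' @param reference grayscale image.
#' @param params a [superpixel_params()].
#' @return object of class `superpixel_segmentation`: list with `labels`
#'   (integer matrix, 0-based, contiguous) and `count`.
#' @export
segment_superpixels <- function(reference, params = superpixel_params()) {
  if (params$approx_size >= min(dim(reference))) {
    stop("approx_size must be smaller than the image")
  }
  lab <- cpp_slic(reference, params$approx_size, params$compactness,
                  params$iters, 0.25)
  structure(list(labels = lab, count = max(lab) + 1L),
            class = "superpixel_segmentation")
}

#' Histogram-peak penalty curve of one superpixel
#'
#' Takes the winner-takes-all label of every pixel in the superpixel, builds
#' the label histogram (lightly smoothed with a 1-bin kernel), keeps the
#' `Np` strongest local maxima (ties to the lower label), and widens each
#' peak with a tent of half-width `sigma_peak`:
#' `z(t) = max_i max(0, 1 - |t - peak_i| / sigma_peak)`, so `z` is 1 at every
#' retained peak and 0 far from all of them. The additive penalty applied to
#' the cost volume is `rho * (1 - z)`.
#'
#' @param costs_in_superpixel n x L matrix of costs of the member pixels.
#' @param params a [superpixel_params()].
#' @return numeric vector `z` of length L in `[0, 1]`.
#' @export
peak_penalty <- function(costs_in_superpixel, params = superpixel_params()) {
  stopifnot(nrow(costs_in_superpixel) >= 1L)
  L <- ncol(costs_in_superpixel)
  wta <- max.col(-costs_in_superpixel, ties.method = "first")
  h <- tabulate(wta, nbins = L)
  hp <- c(h[1L], h, h[L])
  hs <- (hp[1:L] + 2 * h + hp[3:(L + 2L)]) / 4  # 1-bin smoothing
  left <- c(-Inf, hs[-L]); right <- c(hs[-1L], -Inf)
  is_peak <- hs >= left & hs >= right & hs > 0
  cand <- which(is_peak)
  cand <- cand[order(-hs[cand], cand)]
  peaks <- cand[seq_len(min(params$Np, length(cand)))]
  t <- seq_len(L)
  z <- rep(0, L)
  for (pk in peaks) {
    z <- pmax(z, pmax(0, 1 - abs(t - pk) / params$sigma_peak))
  }
  z
}

#' Shape a cost volume toward per-superpixel depth peaks
#'
#' Adds `rho * (1 - z_s(t))` to every pixel of superpixel `s`, where `z_s`
#' is the [peak_penalty()] curve of that superpixel; the penalty is
#' non-negative, so shaping never lowers any cost, and `rho = 0` is the
#' identity. Small superpixels with `Np = 1` and a narrow tent approach a
#' single-depth-per-superpixel behaviour.
#'
#' @param volume a [cost_volume()].
#' @param seg a [segment_superpixels()] result of the same spatial shape.
#' @param params a [superpixel_params()].
#' @param valid optional logical matrix (e.g. the matte mask); the label
#'   histogram of each superpixel is then built from its valid pixels only,
#'   so matted-out background pixels do not vote for peaks (superpixels
#'   with no valid pixel fall back to all members).
#' @return the shaped [cost_volume()].
#' @export
superpixel_shape_volume <- function(volume, seg, params = superpixel_params(),
                                    valid = NULL) {
  d <- dim(volume$data)
  stopifnot(all(d[1:2] == dim(seg$labels)))
  if (params$rho == 0) return(volume)
  L <- d[3L]
  mat <- matrix(volume$data, d[1L] * d[2L], L)
  labv <- as.vector(seg$labels)
  vv <- if (is.null(valid)) rep(TRUE, length(labv)) else as.vector(valid)
  groups <- split(seq_along(labv), labv)
  for (rows in groups) {
    vote <- rows[vv[rows]]
    if (length(vote) == 0L) vote <- rows
    z <- peak_penalty(mat[vote, , drop = FALSE], params)
    mat[rows, ] <- mat[rows, ] + rep(params$rho * (1 - z), each = length(rows))
  }
  cost_volume(array(mat, d), volume$labels, volume$kind)
}
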