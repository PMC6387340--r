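#' Synthetic hexagonal light-field scene specification
#'
#' Describes a textured phantom with a known per-pixel disparity field from
#' which a seven-view elemental image set is rendered: each peripheral view
#' is the central view backward-warped along that view's epipolar direction
#' by the local disparity (bilinear sampling, no occlusion rendering).
#' Serves as the ground-truth stand-in for ray-traced light-field scenes.
#'
#' @param shape `c(H, W)` image size in pixels.
#' @param phantom depth-surface family: `"fronto_plane"`, `"tilted_plane"`,
#'   `"step"`, `"fibers"` or `"disks"`.
#' @param disparity_range `c(d_min, d_max)` in pixels (labels).
#' @param texture `"noise"`, `"stripes"` or `"blobs"`.
#' @param texture_freq texture frequency parameter (cycles/pixel for
#'   stripes; controls the correlation length of noise/blob textures).
#' @param background `"none"` (fully textured frame) or `"dark"`
#'   (fluorescence-style: objects composited over a low-intensity
#'   background).
#' @param background_level intensity of the dark background.
#' @param noise_sigma Gaussian read-noise standard deviation added
#'   independently to each rendered view (intensity units).
#' @param poisson_peak expected photon count at intensity 1 for Poisson shot
#'   noise; 0 disables it.
#' @param disparity_value constant disparity of the fronto-parallel plane
#'   (defaults to the rounded mid-range).
#' @param seed integer RNG seed; the same spec and seed render byte-identical
#'   output.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256L, 256L),
                       phantom = c("fronto_plane", "tilted_plane", "step",
                                   "fibers", "disks"),
                       disparity_range = c(0, 8),
                       texture = c("noise", "stripes", "blobs"),
                       texture_freq = 0.15,
                       background = c("none", "dark"),
                       background_level = 0.05,
                       noise_sigma = 0,
                       poisson_peak = 0,
                       disparity_value = NULL,
                       seed = 1L) {
  phantom <- match.arg(phantom)
  texture <- match.arg(texture)
  background <- match.arg(background)
  if (diff(disparity_range) < 1) stop("d_max - d_min must be >= 1")
  structure(list(shape = as.integer(shape), phantom = phantom,
                 disparity_range = as.numeric(disparity_range),
                 texture = texture, texture_freq = texture_freq,
                 background = background,
                 background_level = background_level,
                 noise_sigma = noise_sigma, poisson_peak = poisson_peak,
                 disparity_value = disparity_value,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run expr with a private, restored RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

make_texture <- function(spec) {
  H <- spec$shape[1L]; W <- spec$shape[2L]
  f <- spec$texture_freq
  if (spec$texture == "noise") {
    t0 <- gaussian_blur(matrix(runif(H * W), H, W), max(0.5, 0.15 / f))
  } else if (spec$texture == "stripes") {
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    yy <- matrix(seq_len(H), H, W)
    phi <- 30 * pi / 180
    t0 <- 0.5 + 0.35 * sin(2 * pi * f * (xx * cos(phi) + yy * sin(phi)))
    t0 <- 0.75 * t0 +
      0.25 * gaussian_blur(matrix(runif(H * W), H, W), 1)
  } else {  # blobs
    t0 <- matrix(0, H, W)
    nb <- max(20L, round(H * W * f^2 / 4))
    cx <- runif(nb, 1, W); cy <- runif(nb, 1, H)
    sg <- runif(nb, 1.5, 2 / f / 10 + 2)
    amp <- runif(nb, 0.4, 1)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    yy <- matrix(seq_len(H), H, W)
    for (b in seq_len(nb)) {
      t0 <- t0 + amp[b] *
        exp(-((xx - cx[b])^2 + (yy - cy[b])^2) / (2 * sg[b]^2))
    }
    t0 <- t0 + 0.15 * gaussian_blur(matrix(runif(H * W), H, W), 1)
  }
  rng <- range(t0)
  if (diff(rng) < 1e-9) return(matrix(0.5, H, W))
  (t0 - rng[1L]) / diff(rng) * 0.8 + 0.15
}

# disparity field + object mask + central image for the phantom families
make_phantom <- function(spec, texture) {
  H <- spec$shape[1L]; W <- spec$shape[2L]
  dmin <- spec$disparity_range[1L]; dmax <- spec$disparity_range[2L]
  mask <- matrix(TRUE, H, W)
  central <- texture
  if (spec$phantom == "fronto_plane") {
    dv <- if (is.null(spec$disparity_value)) round((dmin + dmax) / 2) else
      spec$disparity_value
    D <- matrix(dv, H, W)
  } else if (spec$phantom == "tilted_plane") {
    ramp <- seq(dmin, dmax, length.out = W)
    D <- matrix(ramp, H, W, byrow = TRUE)
  } else if (spec$phantom == "step") {
    lo <- round(dmin + 0.25 * (dmax - dmin))
    hi <- round(dmin + 0.75 * (dmax - dmin))
    D <- matrix(lo, H, W)
    D[, seq.int(W %/% 2 + 1L, W)] <- hi
  } else if (spec$phantom == "fibers") {
    D <- matrix(dmin, H, W)
    obj <- matrix(FALSE, H, W)
    n_fibers <- 12L
    rad <- 2L
    for (fb in seq_len(n_fibers)) {
      x <- runif(1, W * 0.1, W * 0.9); y <- runif(1, H * 0.1, H * 0.9)
      heading <- runif(1, 0, 2 * pi)
      depth <- runif(1, dmin + 1, dmax - 1)
      nst <- round(0.9 * H)
      for (st in seq_len(nst)) {
        heading <- heading + rnorm(1, 0, 0.12)
        x <- min(max(x + cos(heading), 1 + rad), W - rad)
        y <- min(max(y + sin(heading), 1 + rad), H - rad)
        ri <- round(y) + (-rad):rad; ci <- round(x) + (-rad):rad
        obj[ri, ci] <- TRUE
        D[ri, ci] <- depth
      }
    }
    mask <- obj
    central <- ifelse(obj, pmax(texture, 0.45), spec$background_level)
  } else {  # disks
    D <- matrix(dmin, H, W)
    nd <- 4L
    depths <- seq(dmin + 1, dmax - 1, length.out = nd)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    yy <- matrix(seq_len(H), H, W)
    for (k in seq_len(nd)) {
      cx <- runif(1, W * 0.2, W * 0.8); cy <- runif(1, H * 0.2, H * 0.8)
      r <- runif(1, min(H, W) * 0.08, min(H, W) * 0.16)
      inside <- (xx - cx)^2 + (yy - cy)^2 <= r^2
      D[inside] <- depths[k]
    }
    if (spec$background == "dark") {
      obj <- D > dmin
      central <- ifelse(obj, pmax(texture, 0.45), spec$background_level)
      mask <- obj
    }
  }
  list(D = D, mask = mask, central = central)
}

#' Render a synthetic elemental image set with ground truth
#'
#' Renders the central view, warps it into the six peripheral views along
#' the hexagonal epipolar directions according to the per-pixel disparity
#' field, and adds per-view Poisson-Gaussian noise. Output is deterministic
#' for a fixed spec.
#'
#' @param spec a [scene_spec()].
#' @return list with `eis` (an [elemental_image_set()]), `truth` (the
#'   ground-truth disparity matrix at central-view geometry), `mask` (object
#'   mask) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$shape[1L]; W <- spec$shape[2L]
  if (max(abs(spec$disparity_range)) > min(H, W) / 4) {
    stop("disparity range exceeds the image margin")
  }
  with_seed(spec$seed, {
    texture <- make_texture(spec)
    ph <- make_phantom(spec, texture)
    add_noise <- function(img) {
      if (spec$poisson_peak > 0) {
        img <- matrix(rpois(length(img), pmax(img, 0) * spec$poisson_peak),
                      nrow(img)) / spec$poisson_peak
      }
      if (spec$noise_sigma > 0) {
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                            nrow(img))
      }
      pmin(pmax(img, 0), 1)
    }
    angles <- c(0, 60, 120, 180, 240, 300)
    peripheral <- lapply(angles, function(theta) {
      u <- view_unit(theta)
      add_noise(bilinear_warp(ph$central, -ph$D * u[1L], -ph$D * u[2L]))
    })
    names(peripheral) <- as.character(angles)
    central <- add_noise(ph$central)
    r <- floor(min(H, W) / 2)
    # spacing 2r + 2 keeps the rounded view disks disjoint in a mosaic
    geom <- hex_geometry(center_origin = c(3 * r + 3, 3 * r + 3),
                         view_radius = r, view_spacing = 2 * r + 2)
    side <- 2L * r
    cc <- (side + 1) / 2
    ii <- matrix(seq_len(side), side, side); jj <- t(ii)
    vmask <- (ii - cc)^2 + (jj - cc)^2 <= r^2
    # views may be non-square; validity mask applies to the square crop only
    full_mask <- matrix(TRUE, H, W)
    if (H == W) full_mask <- vmask
    eis <- elemental_image_set(central, peripheral, geom,
                               valid_mask = full_mask)
    list(eis = eis, truth = ph$D, mask = ph$mask, spec = spec)
  })
}

#' Absolute-disparity-error report
#'
#' Mean and standard deviation of `|estimate - truth|` over the masked
#' pixels — the evaluation metric for scenes with known ground truth.
#'
#' @param estimate a [depth_map()] or a disparity matrix.
#' @param truth ground-truth disparity matrix.
#' @param mask logical matrix restricting the evaluation (e.g. the matte
#'   mask); must select at least one pixel.
#' @param mask_source label recorded in the report (`"matte"` or
#'   `"ground_truth"`).
#' @return object of class `depth_error_report` with `mean_abs_error`,
#'   `std_abs_error`, `n_pixels`, `mask_source`.
#' @export
evaluate_depth <- function(estimate, truth, mask = NULL,
                           mask_source = "ground_truth") {
  disp <- if (inherits(estimate, "depth_map")) estimate$disparity else estimate
  stopifnot(all(dim(disp) == dim(truth)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(truth), ncol(truth))
  if (!any(mask)) stop("mask selects no pixels")
  err <- abs(disp - truth)[mask]
  structure(list(mean_abs_error = mean(err),
                 std_abs_error = stats::sd(err),
                 n_pixels = length(err),
                 mask_source = mask_source),
            class = "depth_error_report")
}

#' @export
print.depth_error_report <- function(x, ...) {
  cat(sprintf("<depth_error_report> mean %.4f, std %.4f over %d pixels (%s)\n",
              x$mean_abs_error, x$std_abs_error, x$n_pixels, x$mask_source))
  invisible(x)
}

#' Standard phantom suite
#'
#' Five fixed scenes of increasing difficulty (fronto-parallel plane, tilted
#' plane, depth step, fluorescence-style fibers over a dark background,
#' disks at distinct depths) at 256 x 256 with disparities in `[0, 8]`,
#' seeded deterministically from `seed`.
#'
#' @param seed base integer seed; scene k uses `seed + k`.
#' @param shape image size of every scene.
#' @return list of 5 [scene_spec()]s.
#' @export
phantom_suite <- function(seed = 1L, shape = c(256L, 256L)) {
  list(
    scene_spec(shape, "fronto_plane", c(0, 8), texture = "noise",
               disparity_value = 4, noise_sigma = 0, seed = seed + 1L),
    scene_spec(shape, "tilted_plane", c(0, 8), texture = "noise",
               noise_sigma = 0.01, seed = seed + 2L),
    scene_spec(shape, "step", c(0, 8), texture = "stripes",
               texture_freq = 0.12, noise_sigma = 0.01, seed = seed + 3L),
    scene_spec(shape, "fibers", c(0, 8), texture = "noise",
               background = "dark", noise_sigma = 0.02,
               poisson_peak = 200, seed = seed + 4L),
    scene_spec(shape, "disks", c(0, 8), texture = "blobs",
               texture_freq = 0.12, background = "none",
               noise_sigma = 0.01, seed = seed + 5L)
  )
}
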