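#' Cost-computation parameters
#'
#' @param alpha_c mixing weight between TAD and census in the correspondence
#'   cost, in `[0, 1]` (1 = pure TAD).
#' @param alpha_d mixing weight between TAD and NCC dissimilarity in the
#'   defocus cost, in `[0, 1]`.
#' @param tau truncation threshold of the absolute difference (intensity
#'   units, image range `[0, 1]`).
#' @param hws half window size of the aggregation window (pixels).
#' @param sigma_color,sigma_dist adaptive-support-weight bandwidths for the
#'   intensity and spatial terms.
#' @param census_hws half window of the census transform (2 gives the common
#'   5x5 / 24-bit census).
#' @param guided_radius,guided_eps guided-filter window radius and
#'   regularizer applied per cost-volume slice.
#' @param var_eps windows with weighted variance below this are treated as
#'   textureless by the NCC (NCC set to 0, dissimilarity 0.5).
#' @return object of class `cost_params`.
#' @export
cost_params <- function(alpha_c = 0.5, alpha_d = 0.5, tau = 0.15, hws = 2L,
                        sigma_color = 0.1, sigma_dist = 5,
                        census_hws = 2L, guided_radius = 8L,
                        guided_eps = 1e-4, var_eps = 1e-6) {
  stopifnot(alpha_c >= 0, alpha_c <= 1, alpha_d >= 0, alpha_d <= 1,
            tau > 0, hws >= 0, sigma_color > 0, sigma_dist > 0)
  structure(list(alpha_c = alpha_c, alpha_d = alpha_d, tau = tau,
                 hws = as.integer(hws), sigma_color = sigma_color,
                 sigma_dist = sigma_dist, census_hws = as.integer(census_hws),
                 guided_radius = as.integer(guided_radius),
                 guided_eps = guided_eps, var_eps = var_eps),
            class = "cost_params")
}

#' Candidate disparity labels
#'
#' @param values strictly increasing numeric vector of candidate disparities
#'   (pixels along an epipolar axis), at least 2 labels.
#' @return object of class `disparity_grid`.
#' @export
disparity_grid <- function(values) {
  if (length(values) < 2L || is.unsorted(values, strictly = TRUE)) {
    stop("disparity labels must be strictly increasing with at least 2 values")
  }
  structure(list(values = as.numeric(values), axes = c(0, 60, 120)),
            class = "disparity_grid")
}

#' Cost volume container
#'
#' @param data H x W x L array of non-negative finite costs (lower = better).
#' @param labels label values of the third dimension (disparities or focal
#'   shifts).
#' @param kind `"correspondence"`, `"defocus"` or `"fused"`.
#' @return object of class `cost_volume`.
#' @export
cost_volume <- function(data, labels,
                        kind = c("correspondence", "defocus", "fused")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 3L, dim(data)[3L] == length(labels))
  if (any(!is.finite(data)) || any(data < -1e-9)) {
    stop("cost volume must be finite and non-negative")
  }
  structure(list(data = data, labels = as.numeric(labels), kind = kind),
            class = "cost_volume")
}

#' @export
print.cost_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cost_volume:%s> %d x %d x %d labels [%s]\n", x$kind,
              d[1L], d[2L], d[3L],
              paste(range(x$labels), collapse = ", ")))
  invisible(x)
}

#' Adaptive support weights of a window
#'
#' Bilateral-style weights
#' `w(p, o) = exp(-(|I(p) - I(p+o)| / sigma_color + ||o|| / sigma_dist))`,
#' normalized to sum 1 over the `(2*hws+1)^2` window. Exposed mainly for
#' inspection and validation; the cost volumes use the same weights through
#' compiled aggregation kernels.
#'
#' @param reference grayscale image.
#' @param x,y pixel position (row, col), 1-based.
#' @param hws half window size.
#' @param sigma_color,sigma_dist bandwidths.
#' @return `(2*hws+1) x (2*hws+1)` weight matrix summing to 1.
#' @export
adaptive_weights <- function(reference, x, y, hws, sigma_color, sigma_dist) {
  stopifnot(sigma_color > 0, sigma_dist > 0)
  H <- nrow(reference); W <- ncol(reference)
  c0 <- reference[x, y]
  w <- matrix(0, 2L * hws + 1L, 2L * hws + 1L)
  for (r in -hws:hws) {
    for (q in -hws:hws) {
      ii <- min(max(x + r, 1L), H)
      jj <- min(max(y + q, 1L), W)
      w[r + hws + 1L, q + hws + 1L] <-
        exp(-(abs(c0 - reference[ii, jj]) / sigma_color +
                sqrt(r^2 + q^2) / sigma_dist))
    }
  }
  w / sum(w)
}

# shift I2 along the direction of a disparity vector (d, theta)
shift_by_disparity <- function(I2, d, theta_deg) shift_view(I2, d, theta_deg)

# full-image aggregated TAD between I1 and the shifted I2
tad_map <- function(I1, I2_shifted, params, ref = I1) {
  raw <- pmin(abs(I1 - I2_shifted), params$tau)
  cpp_asw_aggregate(raw, ref, params$hws, params$sigma_color,
                    params$sigma_dist)
}

# full-image aggregated census Hamming cost between I1 and the shifted I2
census_map <- function(I1, I2_shifted, params, ref = I1) {
  ham <- cpp_census_hamming(I1, I2_shifted, params$census_hws)
  cpp_asw_aggregate(ham, ref, params$hws, params$sigma_color,
                    params$sigma_dist)
}

#' Truncated absolute-difference cost at a pixel
#'
#' Adaptive-weight windowed sum of `min(tau, |I1 - I2|)` after shifting `I2`
#' by the disparity vector `(d, theta)` (bilinear sampling, borders by edge
#' replication).
#'
#' @param I1,I2 grayscale images (same shape).
#' @param p pixel `c(row, col)`, 1-based.
#' @param d disparity magnitude in pixels.
#' @param theta_deg epipolar direction in degrees.
#' @param params a [cost_params()].
#' @return non-negative scalar cost.
#' @export
tad_cost <- function(I1, I2, p, d, theta_deg, params = cost_params()) {
  m <- tad_map(I1, shift_by_disparity(I2, d, theta_deg)$image, params)
  m[p[1L], p[2L]]
}

#' Census-transform cost at a pixel
#'
#' Adaptive-weight windowed sum of per-pixel Hamming distances between the
#' census transforms of `I1` and the shifted `I2`, normalized by the census
#' bit count; invariant to monotone intensity changes.
#'
#' @inheritParams tad_cost
#' @return scalar cost in `[0, 1]`.
#' @export
census_cost <- function(I1, I2, p, d, theta_deg, params = cost_params()) {
  m <- census_map(I1, shift_by_disparity(I2, d, theta_deg)$image, params)
  m[p[1L], p[2L]]
}

#' Weighted normalized cross-correlation at a pixel
#'
#' Weighted NCC over the aggregation window using the adaptive support
#' weights (weighted means/variances/covariance). Windows that are
#' textureless in either image (weighted variance below `var_eps`) return 0.
#'
#' @param I1,I2 grayscale images.
#' @param p pixel `c(row, col)`.
#' @param params a [cost_params()].
#' @return scalar in `[-1, 1]`.
#' @export
ncc_cost <- function(I1, I2, p, params = cost_params()) {
  m <- cpp_weighted_ncc(I1, I2, I1, params$hws, params$sigma_color,
                        params$sigma_dist, params$var_eps)
  m[p[1L], p[2L]]
}

#' Map an NCC similarity to a dissimilarity in [0, 1]
#' @param ncc values in `[-1, 1]`.
#' @return `(1 - ncc) / 2` (0 = perfectly correlated).
#' @export
ncc_dissimilarity <- function(ncc) (1 - ncc) / 2

# cost volume of one central<->peripheral pair along its view direction
pair_cost_volume <- function(central, view, theta_deg, grid, params) {
  L <- length(grid$values)
  H <- nrow(central); W <- ncol(central)
  data <- array(0, c(H, W, L))
  valid <- array(FALSE, c(H, W, L))
  for (k in seq_len(L)) {
    sh <- shift_by_disparity(view, grid$values[k], theta_deg)
    cost <- params$alpha_c * tad_map(central, sh$image, params)
    if (params$alpha_c < 1) {
      cost <- cost + (1 - params$alpha_c) * census_map(central, sh$image, params)
    }
    data[, , k] <- cost
    valid[, , k] <- sh$valid
  }
  list(data = data, valid = valid)
}

#' Correspondence cost volume from the six view pairs
#'
#' For every central-peripheral pair a per-label cost
#' `alpha_c * TAD + (1 - alpha_c) * census` is computed along the pair's
#' epipolar direction; the six volumes are merged slice by slice by a
#' weighted average whose weights come from the failure-prediction map of
#' the pair's axis (both views of an axis share the axis weight). Samples
#' falling outside the frame are masked and the merge weights renormalized;
#' the merged volume is guided-filtered per slice with the central image as
#' guide.
#'
#' @param eis an [elemental_image_set()].
#' @param grid a [disparity_grid()].
#' @param params a [cost_params()].
#' @param fmaps a [failure_maps()] result for the central image (computed on
#'   demand when `NULL`).
#' @return a [cost_volume()] of kind `"correspondence"`.
#' @export
correspondence_cost_volume <- function(eis, grid, params = cost_params(),
                                       fmaps = NULL) {
  stopifnot(inherits(eis, "elemental_image_set"),
            inherits(grid, "disparity_grid"))
  if (is.null(fmaps)) fmaps <- failure_maps(eis$central)
  central <- eis$central
  H <- nrow(central); W <- ncol(central)
  L <- length(grid$values)
  num <- array(0, c(H, W, L))
  den <- array(0, c(H, W, L))
  unif_num <- array(0, c(H, W, L))  # fallback where no view samples validly
  for (a in names(eis$peripheral)) {
    theta <- as.numeric(a)
    axis <- as.character(view_axis(theta))
    w_axis <- fmaps$per_axis[[axis]]
    pv <- pair_cost_volume(central, eis$peripheral[[a]], theta, grid, params)
    for (k in seq_len(L)) {
      wk <- w_axis * pv$valid[, , k]
      num[, , k] <- num[, , k] + wk * pv$data[, , k]
      den[, , k] <- den[, , k] + wk
      unif_num[, , k] <- unif_num[, , k] + pv$data[, , k]
    }
  }
  merged <- ifelse(den > 0, num / pmax(den, 1e-12), unif_num / 6)
  merged <- array(merged, c(H, W, L))
  for (k in seq_len(L)) {
    merged[, , k] <- pmax(guided_filter(merged[, , k], central,
                                        params$guided_radius,
                                        params$guided_eps), 0)
  }
  cost_volume(merged, grid$values, "correspondence")
}

#' Defocus cost volume from a focal stack
#'
#' Each focal plane is compared against the central view at zero disparity:
#' `alpha_d * TAD + (1 - alpha_d) * (1 - NCC)/2`, stacked over the shift
#' labels and guided-filtered per slice with the central image as guide. The
#' plane refocused at the true depth of a pixel reproduces the central image
#' there, so the cost minimum indexes depth.
#'
#' @param stack a [build_focal_stack()] result.
#' @param central the central view (reference image).
#' @param params a [cost_params()].
#' @return a [cost_volume()] of kind `"defocus"`.
#' @export
defocus_cost_volume <- function(stack, central, params = cost_params()) {
  stopifnot(inherits(stack, "focal_stack"))
  L <- length(stack$planes)
  H <- nrow(central); W <- ncol(central)
  data <- array(0, c(H, W, L))
  for (k in seq_len(L)) {
    plane <- stack$planes[[k]]
    cost <- params$alpha_d * tad_map(central, plane, params)
    if (params$alpha_d < 1) {
      ncc <- cpp_weighted_ncc(central, plane, central, params$hws,
                              params$sigma_color, params$sigma_dist,
                              params$var_eps)
      cost <- cost + (1 - params$alpha_d) * ncc_dissimilarity(ncc)
    }
    data[, , k] <- pmax(guided_filter(cost, central, params$guided_radius,
                                      params$guided_eps), 0)
  }
  cost_volume(data, stack$shifts, "defocus")
}
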