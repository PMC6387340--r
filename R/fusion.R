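#' Fusion and optimization parameters
#'
#' @param K normalization of the absolute difference map between the two
#'   winner-takes-all depth maps, in label units; `NULL` defaults to `L - 1`
#'   so full disagreement maps to 1.
#' @param beta scale of the ground-control-point penalty in the data term.
#' @param gcp_threshold pixels whose normalized WTA disagreement is at or
#'   below this become ground control points (0 keeps only exact agreement).
#' @param lambda_smooth weight of the pairwise label-difference prior
#'   relative to the data term.
#' @param smooth_trunc truncation of the label-difference prior (`Inf` for
#'   the pure linear prior; any truncation keeps the prior metric).
#' @param max_expansion_sweeps maximum full alpha-expansion sweeps.
#' @param mad_weighting `"as_printed"` mixes the defocus volume with weight
#'   `(1 - Mad)` and the correspondence volume with `Mad`; `"as_prose"`
#'   swaps the two (keeping the defocus cue where the cues disagree).
#' @param optimizer `"auto"` minimizes the untruncated linear prior exactly
#'   with a single multi-layer (Ishikawa) cut and falls back to
#'   alpha-expansion sweeps for truncated priors; `"ishikawa"` and
#'   `"expansion"` force the respective route.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(K = NULL, beta = 0.5, gcp_threshold = 0,
                          lambda_smooth = 0.05, smooth_trunc = Inf,
                          max_expansion_sweeps = 4L,
                          mad_weighting = c("as_printed", "as_prose"),
                          optimizer = c("auto", "ishikawa", "expansion")) {
  if (length(K) == 1L && is.na(K)) K <- NULL  # NA = "use L - 1" (from configs)
  stopifnot(is.null(K) || K > 0, beta >= 0, lambda_smooth >= 0,
            gcp_threshold >= 0)
  structure(list(K = K, beta = beta, gcp_threshold = gcp_threshold,
                 lambda_smooth = lambda_smooth, smooth_trunc = smooth_trunc,
                 max_expansion_sweeps = as.integer(max_expansion_sweeps),
                 mad_weighting = match.arg(mad_weighting),
                 optimizer = match.arg(optimizer)),
            class = "fusion_params")
}

#' Depth map container
#'
#' @param labels integer matrix of 0-based label indices.
#' @param grid_values numeric label-to-disparity mapping (length L).
#' @param valid logical validity mask (e.g. the matte mask).
#' @param disparity optional real disparity image; defaults to the labels
#'   mapped through `grid_values`.
#' @return object of class `depth_map`.
#' @export
depth_map <- function(labels, grid_values, valid = NULL, disparity = NULL) {
  stopifnot(min(labels) >= 0L, max(labels) <= length(grid_values) - 1L)
  if (is.null(disparity)) {
    disparity <- matrix(grid_values[labels + 1L], nrow(labels), ncol(labels))
  }
  if (is.null(valid)) valid <- matrix(TRUE, nrow(labels), ncol(labels))
  structure(list(labels = labels, disparity = disparity, valid = valid,
                 grid_values = as.numeric(grid_values)),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d x %d, labels %d..%d, %.0f%% valid\n",
              nrow(x$labels), ncol(x$labels), min(x$labels), max(x$labels),
              100 * mean(x$valid)))
  invisible(x)
}

#' Winner-takes-all depth extraction
#'
#' Per-pixel argmin over the cost labels; ties break to the lowest label
#' index (deterministic).
#'
#' @param volume a [cost_volume()].
#' @return a [depth_map()].
#' @export
wta_depth <- function(volume) {
  d <- dim(volume$data)
  idx <- max.col(-matrix(volume$data, d[1L] * d[2L], d[3L]),
                 ties.method = "first")
  depth_map(matrix(idx - 1L, d[1L], d[2L]), volume$labels)
}

#' Normalized absolute difference between two WTA depth maps
#'
#' `Mad = |l_def - l_cor| / K` clipped to `[0, 1]`; 0 marks pixels where the
#' defocus and correspondence cues agree (candidate ground control points),
#' 1 marks maximal disagreement.
#'
#' @param d_def,d_cor [depth_map()]s on the same label grid.
#' @param K normalization in label units; default `L - 1`.
#' @return numeric matrix in `[0, 1]`.
#' @export
absolute_difference_map <- function(d_def, d_cor, K = NULL) {
  stopifnot(all(dim(d_def$labels) == dim(d_cor$labels)))
  if (is.null(K)) K <- length(d_def$grid_values) - 1
  if (K <= 0) stop("K must be > 0")
  pmin(abs(d_def$labels - d_cor$labels) / K, 1)
}

#' Ground-control-point penalty volume
#'
#' On pixels where the two cues agree (the GCP mask), the cost curve is
#' penalized linearly with the label distance from the agreed label,
#' normalized to `[0, 1]`; elsewhere the penalty is identically 0. Anchors
#' reliable pixels during the graph-cut optimization.
#'
#' @param volume a [cost_volume()] (defines the label grid and shape).
#' @param gcp_mask logical matrix of ground control points.
#' @param agreed_label integer matrix of 0-based agreed labels.
#' @return H x W x L penalty array.
#' @export
gcp_penalty <- function(volume, gcp_mask, agreed_label) {
  d <- dim(volume$data)
  L <- d[3L]
  P <- array(0, d)
  for (k in seq_len(L)) {
    P[, , k] <- gcp_mask * abs((k - 1L) - agreed_label) / (L - 1L)
  }
  P
}

#' Fused data term of the depth-estimation energy
#'
#' Elementwise per-label mix
#' `E_data = (1 - Mad) * C_def + Mad * C_cor + beta * P_gcp`
#' (the `mad_weighting = "as_prose"` option swaps the roles of the two
#' volumes so the defocus cue dominates where the cues disagree).
#'
#' @param C_def,C_cor aggregated [cost_volume()]s on the same label grid.
#' @param Mad the [absolute_difference_map()].
#' @param P the [gcp_penalty()] array (or NULL for none).
#' @param params a [fusion_params()].
#' @return a [cost_volume()] of kind `"fused"`.
#' @export
build_data_term <- function(C_def, C_cor, Mad, P = NULL,
                            params = fusion_params()) {
  d <- dim(C_def$data)
  stopifnot(all(d == dim(C_cor$data)), all(d[1:2] == dim(Mad)))
  w_cor <- if (params$mad_weighting == "as_printed") Mad else 1 - Mad
  out <- array(0, d)
  for (k in seq_len(d[3L])) {
    out[, , k] <- (1 - w_cor) * C_def$data[, , k] + w_cor * C_cor$data[, , k]
    if (!is.null(P) && params$beta > 0) {
      out[, , k] <- out[, , k] + params$beta * P[, , k]
    }
  }
  cost_volume(out, C_def$labels, "fused")
}

#' Energy of a labeling under the data + smoothness model
#'
#' `E = sum_p data(p, l(p)) + lambda * sum_{(p,q) in N4} min(|l(p)-l(q)|, trunc)`
#'
#' @param labels integer matrix of 0-based labels.
#' @param volume a [cost_volume()] providing the data term.
#' @param lambda_smooth smoothness weight.
#' @param smooth_trunc truncation of the label-difference prior.
#' @param valid optional logical matrix; smoothness edges touching an
#'   invalid (e.g. matted-out) pixel carry no cost.
#' @return scalar energy.
#' @export
labeling_energy <- function(labels, volume, lambda_smooth,
                            smooth_trunc = Inf, valid = NULL) {
  d <- dim(volume$data)
  N <- d[1L] * d[2L]
  mat <- matrix(volume$data, N, d[3L])
  data_e <- sum(mat[cbind(seq_len(N), as.vector(labels) + 1L)])
  dv <- pmin(abs(labels[-1L, , drop = FALSE] - labels[-d[1L], , drop = FALSE]),
             smooth_trunc)
  dh <- pmin(abs(labels[, -1L, drop = FALSE] - labels[, -d[2L], drop = FALSE]),
             smooth_trunc)
  if (!is.null(valid)) {
    dv <- dv * (valid[-1L, , drop = FALSE] & valid[-d[1L], , drop = FALSE])
    dh <- dh * (valid[, -1L, drop = FALSE] & valid[, -d[2L], drop = FALSE])
  }
  data_e + lambda_smooth * (sum(dv) + sum(dh))
}

# one alpha-expansion move via min-cut (BK max-flow backend).
# lab: 0-based label vector (pixel column-major order); returns updated lab.
# Binary encoding: pixels on the source side keep their label, sink side
# switches to alpha. Terminal capacities are folded per node; pairs with
# differing labels get an auxiliary node carrying the V(l1,l2) sink link.
expand_once <- function(lab, dataMat, alpha, H, W, lambda, trunc,
                        wpair = NULL) {
  N <- H * W
  d_alpha <- dataMat[, alpha + 1L]
  d_keep <- dataMat[cbind(seq_len(N), lab + 1L)]
  # neighbour index pairs (4-connectivity)
  p <- seq_len(N)
  vert1 <- p[(p - 1L) %% H < H - 1L]; vert2 <- vert1 + 1L
  hor1 <- p[p <= N - H]; hor2 <- hor1 + H
  p1 <- c(vert1, hor1); p2 <- c(vert2, hor2)
  if (is.null(wpair)) wpair <- rep(1, length(p1))
  Vfun <- function(a, b, w) lambda * w * pmin(abs(a - b), trunc)
  l1 <- lab[p1]; l2 <- lab[p2]
  same <- l1 == l2
  diffp <- which(!same)
  n_aux <- length(diffp)
  tr <- c(d_alpha - d_keep, -Vfun(l1[diffp], l2[diffp], wpair[diffp]))
  ef <- list(); et <- list(); ec <- list()
  add <- function(from, to, cap) {
    keep <- cap > 1e-12
    if (any(keep)) {
      k <- length(ef) + 1L
      ef[[k]] <<- from[keep]; et[[k]] <<- to[keep]; ec[[k]] <<- cap[keep]
    }
  }
  if (any(same)) {
    cap <- Vfun(l1[same], alpha, wpair[same])
    add(p1[same], p2[same], cap)
    add(p2[same], p1[same], cap)
  }
  if (n_aux > 0L) {
    aux <- N + seq_len(n_aux)
    a1 <- p1[diffp]; a2 <- p2[diffp]
    c1 <- Vfun(l1[diffp], alpha, wpair[diffp])
    c2 <- Vfun(alpha, l2[diffp], wpair[diffp])
    add(a1, aux, c1); add(aux, a1, c1)
    add(aux, a2, c2); add(a2, aux, c2)
  }
  fr <- unlist(ef)
  fl <- cpp_maxflow(N + n_aux,
                    if (is.null(fr)) integer(0) else fr,
                    if (is.null(fr)) integer(0) else unlist(et),
                    if (is.null(fr)) numeric(0) else unlist(ec), tr)
  keep_side <- fl$source_side[seq_len(N)]
  lab[!keep_side] <- alpha
  lab
}

# exact minimizer for the convex linear prior: one multi-layer min cut.
# Binary variables x_{p,k} = [l_p >= k] form per-pixel chains s -> v_{p,1}
# -> ... -> v_{p,L-1} -> t whose k-th arc carries D_p(k); infinite reverse
# arcs keep the cut monotone along the chain, and level-wise arcs of
# capacity lambda between neighbouring pixels charge lambda per level of
# label difference, i.e. lambda * |l_p - l_q| in total.
ishikawa_cut <- function(dataMat, H, W, lambda, wpair = NULL) {
  N <- H * W
  L <- ncol(dataMat)
  nl <- L - 1L  # layers of internal nodes per pixel
  p <- seq_len(N)
  vert1 <- p[(p - 1L) %% H < H - 1L]; vert2 <- vert1 + 1L
  hor1 <- p[p <= N - H]; hor2 <- hor1 + H
  p1 <- c(vert1, hor1); p2 <- c(vert2, hor2)
  if (is.null(wpair)) wpair <- rep(1, length(p1))
  node <- function(p, k) (k - 1L) * N + p  # k in 1..nl
  INF <- sum(dataMat) + lambda * L * (length(p1) + 1) + 1
  tr <- numeric(N * nl)
  tr[node(p, 1L)] <- tr[node(p, 1L)] + dataMat[, 1L]   # source link: l = 0
  tr[node(p, nl)] <- tr[node(p, nl)] - dataMat[, L]    # sink link: l = L-1
  ef <- vector("list", 0L); et <- ef; ec <- ef
  add <- function(from, to, cap) {
    keep <- cap > 0
    if (!any(keep)) return(invisible())
    k <- length(ef) + 1L
    ef[[k]] <<- from[keep]; et[[k]] <<- to[keep]; ec[[k]] <<- cap[keep]
  }
  if (nl > 1L) {
    for (k in 1L:(nl - 1L)) {
      add(node(p, k), node(p, k + 1L), dataMat[, k + 1L])  # cut => l = k
      add(node(p, k + 1L), node(p, k), rep(INF, N))
    }
  }
  if (lambda > 0) {
    pw <- lambda * wpair
    for (k in 1L:nl) {
      add(node(p1, k), node(p2, k), pw)
      add(node(p2, k), node(p1, k), pw)
    }
  }
  fr <- unlist(ef)
  fl <- cpp_maxflow(N * nl,
                    if (is.null(fr)) integer(0) else fr,
                    if (is.null(fr)) integer(0) else unlist(et),
                    if (is.null(fr)) numeric(0) else unlist(ec), tr)
  src_side <- fl$source_side
  # l_p = number of source-side layer nodes of pixel p
  lab <- integer(N)
  for (k in 1L:nl) lab <- lab + src_side[node(p, k)]
  lab
}

#' Multi-label graph-cut optimization of a cost volume
#'
#' Minimizes
#' `sum_p data(p, l(p)) + lambda * sum_{(p,q)} min(|l(p) - l(q)|, trunc)`
#' over the 4-connected grid. For the untruncated linear prior (the
#' default), which is convex in the label difference, the global minimum is
#' computed exactly by a single multi-layer min cut; for truncated (still
#' metric) priors, iterated alpha-expansion moves are used, initialized at
#' the winner-takes-all labeling of the data term, each move solved exactly
#' by one min cut, sweeping until no label improves or
#' `max_expansion_sweeps` is reached. In both routes the final energy never
#' exceeds the WTA initialization energy (asserted on every run).
#'
#' @param data a [cost_volume()] (typically [build_data_term()]).
#' @param params a [fusion_params()].
#' @param valid optional logical matrix (e.g. the matte mask); smoothness
#'   edges touching an invalid pixel are dropped, so matted-out regions,
#'   which carry no photometric signal, cannot drag the labels of their
#'   valid neighbours.
#' @return a [depth_map()] with attribute `"energies"`: the energy of the
#'   WTA initialization followed by the energy after optimization (per
#'   sweep for the expansion route); non-increasing.
#' @export
graphcut_optimize <- function(data, params = fusion_params(), valid = NULL) {
  d <- dim(data$data)
  H <- d[1L]; W <- d[2L]; L <- d[3L]
  stopifnot(L >= 2L)
  dataMat <- matrix(data$data, H * W, L)
  init <- wta_depth(data)
  lab <- as.vector(init$labels)
  lambda <- params$lambda_smooth
  trunc <- params$smooth_trunc
  wpair <- NULL
  if (!is.null(valid) && !all(valid)) {
    vv <- valid[-1L, , drop = FALSE] & valid[-H, , drop = FALSE]
    vh <- valid[, -1L, drop = FALSE] & valid[, -W, drop = FALSE]
    wpair <- as.numeric(c(vv, vh))
  }
  energies <- labeling_energy(init$labels, data, lambda, trunc, valid)
  use_exact <- params$optimizer == "ishikawa" ||
    (params$optimizer == "auto" && is.infinite(trunc))
  if (lambda > 0 && use_exact) {
    lab <- ishikawa_cut(dataMat, H, W, lambda, wpair)
    e <- labeling_energy(matrix(lab, H, W), data, lambda, trunc, valid)
    stopifnot(e <= energies[1L] + 1e-6)
    energies <- c(energies, e)
  } else if (lambda > 0) {
    for (sweep in seq_len(params$max_expansion_sweeps)) {
      changed <- FALSE
      for (alpha in 0:(L - 1L)) {
        new_lab <- expand_once(lab, dataMat, alpha, H, W, lambda, trunc,
                               wpair)
        if (!identical(new_lab, lab)) changed <- TRUE
        lab <- new_lab
      }
      e <- labeling_energy(matrix(lab, H, W), data, lambda, trunc, valid)
      stopifnot(e <= energies[length(energies)] + 1e-6)
      energies <- c(energies, e)
      if (!changed) break
    }
  }
  out <- depth_map(matrix(as.integer(lab), H, W), data$labels)
  attr(out, "energies") <- energies
  out
}

#' Post-filter a depth map (weighted median + guided filter)
#'
#' First a weighted median filter of the label image with integer weights
#' (1..8) quantized from guide-image affinities, then a guided filter of the
#' disparity image with the central image as guide; labels are re-quantized
#' to the nearest grid value. Removes isolated outliers while keeping depth
#' edges aligned with image edges; constant maps are unchanged.
#'
#' @param depth a [depth_map()].
#' @param guide the central view.
#' @param median_hws half window of the weighted median (>= 1).
#' @param sigma_guide affinity bandwidth for the integer weights.
#' @param guided_radius,guided_eps guided-filter parameters.
#' @return the filtered [depth_map()].
#' @export
postprocess <- function(depth, guide, median_hws = 2L, sigma_guide = 0.1,
                        guided_radius = 4L, guided_eps = 1e-3) {
  L <- length(depth$grid_values)
  lab <- cpp_weighted_median(depth$labels, guide, median_hws, L,
                             sigma_guide, 8L)
  disp <- matrix(depth$grid_values[lab + 1L], nrow(lab), ncol(lab))
  disp <- guided_filter(disp, guide, guided_radius, guided_eps)
  # re-quantize to the label grid
  qlab <- matrix(
    findInterval(disp, depth$grid_values[-L] +
                   diff(depth$grid_values) / 2),
    nrow(lab), ncol(lab))
  depth_map(qlab, depth$grid_values, valid = depth$valid, disparity = disp)
}
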