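#' Pipeline configuration
#'
#' Nested list of every tunable of the depth-estimation workflow with
#' documented defaults; any subset can be overridden through `...` (named
#' top-level blocks are deep-merged). The configuration serializes
#' losslessly to YAML with [write_config()] / [read_config()].
#'
#' Blocks:
#' \describe{
#'   \item{grid}{`d_min`, `d_max`, `step`: candidate disparity labels in
#'     pixels along an epipolar axis; the focal-stack shifts use the same
#'     values so the two cost volumes share a label grid.}
#'   \item{cost}{arguments of [cost_params()].}
#'   \item{priors}{`sigma1`, `sigma2`, `Fs` of the frequency map; `trimap`
#'     thresholds (`"auto"` or two levels); `matting` = `"auto"`, `"on"` or
#'     `"off"` (`"auto"` mattes only scenes with a dark background:
#'     background class mean below `dark_level` and covering at least
#'     `min_bg_fraction`).}
#'   \item{multiscale}{`enabled`, `gamma` (see [multiscale_params()]).}
#'   \item{superpixel}{`enabled` plus arguments of [superpixel_params()].}
#'   \item{fusion}{arguments of [fusion_params()] (`K = NA` means the
#'     label-count default `L - 1`).}
#'   \item{postprocess}{`enabled`, weighted-median and guided-filter
#'     parameters of [postprocess()].}
#' }
#'
#' @param ... named blocks overriding defaults, e.g.
#'   `grid = list(d_max = 6)`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    grid = list(d_min = 0, d_max = 8, step = 1),
    cost = list(alpha_c = 0.5, alpha_d = 0.5, tau = 0.15, hws = 2L,
                sigma_color = 0.1, sigma_dist = 5, census_hws = 2L,
                guided_radius = 8L, guided_eps = 1e-4, var_eps = 1e-6),
    priors = list(sigma1 = 1, sigma2 = 2, Fs = 3L, trimap = "auto",
                  matting = "auto", dark_level = 0.15,
                  min_bg_fraction = 0.2),
    multiscale = list(enabled = TRUE, gamma = c(0.6, 0.3, 0.1)),
    superpixel = list(enabled = TRUE, approx_size = 16L, compactness = 0.1,
                      Np = 3L, sigma_peak = 3, rho = 0.2, iters = 5L),
    fusion = list(K = NA, beta = 0.5, gcp_threshold = 0,
                  lambda_smooth = 0.05, smooth_trunc = Inf,
                  max_expansion_sweeps = 4L,
                  mad_weighting = "as_prose"),
    postprocess = list(enabled = TRUE, median_hws = 2L, sigma_guide = 0.1,
                       guided_radius = 4L, guided_eps = 1e-3)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config block: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config()` returns a [pipeline_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# decide whether the scene has a dark background worth matting
needs_matting <- function(central, trimap, priors_cfg) {
  bg <- unclass(trimap) == 0L
  frac <- mean(bg)
  frac >= priors_cfg$min_bg_fraction &&
    mean(central[bg]) < priors_cfg$dark_level &&
    any(unclass(trimap) == 2L)
}

downsample_eis <- function(eis, k) {
  if (k == 1L) return(eis)
  per <- lapply(eis$peripheral, downsample_block, k = k)
  central <- downsample_block(eis$central, k)
  elemental_image_set(pmin(pmax(central, 0), 1),
                      lapply(per, function(m) pmin(pmax(m, 0), 1)),
                      eis$geometry,
                      valid_mask = matrix(TRUE, nrow(central), ncol(central)))
}

#' Run the full depth-estimation pipeline
#'
#' Executes: priors (frequency map, failure maps, optional matte) ->
#' correspondence cost volume -> focal stack and defocus cost volume ->
#' frequency-weighted multi-scale aggregation -> superpixel peak shaping ->
#' WTA pair and normalized difference map -> fused data term with
#' ground-control-point penalties -> alpha-expansion graph cut ->
#' weighted-median + guided post-filtering -> matte-masked depth map.
#'
#' @param eis an [elemental_image_set()] (use [extract_elemental_images()]
#'   for raw mosaics).
#' @param config a [pipeline_config()].
#' @param keep_volumes keep the cost volumes in the intermediates manifest
#'   (they are dropped by default to save memory).
#' @param verbose print per-stage timing.
#' @return list with `depth` (a [depth_map()]) and `intermediates`: priors,
#'   WTA maps of both cues, the difference map, the WTA-only baseline depth
#'   map, graph-cut energies per sweep, per-stage timings and the config.
#' @export
run_pipeline <- function(eis, config = pipeline_config(),
                         keep_volumes = FALSE, verbose = FALSE) {
  stopifnot(inherits(eis, "elemental_image_set"),
            inherits(config, "pipeline_config"))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[[3L]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[[3L]] - t0
    if (verbose) message(sprintf("[%s] %.2fs", name, timings[[name]]))
    res
  }
  central <- eis$central
  grid <- disparity_grid(seq(config$grid$d_min, config$grid$d_max,
                             by = config$grid$step))
  cp <- do.call(cost_params, config$cost)

  pri <- stage("priors", {
    fmap <- frequency_map(central, config$priors$sigma1,
                          config$priors$sigma2, config$priors$Fs)
    fmaps <- failure_maps(central)
    tm <- build_trimap(central, config$priors$trimap)
    matte <- NULL
    mode <- config$priors$matting
    if (mode == "on" ||
        (mode == "auto" && needs_matting(central, tm, config$priors))) {
      matte <- alpha_matte(central, tm)
    }
    list(fmap = fmap, fmaps = fmaps, trimap = tm, matte = matte)
  })
  valid <- if (is.null(pri$matte)) {
    matrix(TRUE, nrow(central), ncol(central))
  } else {
    pri$matte$mask
  }

  cor_raw <- stage("correspondence_volume",
                   correspondence_cost_volume(eis, grid, cp, pri$fmaps))
  def_raw <- stage("defocus_volume", {
    stack <- build_focal_stack(eis, grid$values)
    defocus_cost_volume(stack, central, cp)
  })

  if (config$multiscale$enabled) {
    mp <- multiscale_params(gamma = config$multiscale$gamma)
    scaled_eis <- list()
    get_eis <- function(k) {
      key <- as.character(k)
      if (is.null(scaled_eis[[key]])) {
        scaled_eis[[key]] <<- downsample_eis(eis, k)
      }
      scaled_eis[[key]]
    }
    cor_msc <- stage("multiscale_correspondence", {
      multiscale_aggregate(function(k) {
        if (k == 1L) return(cor_raw)
        es <- get_eis(k)
        correspondence_cost_volume(es, disparity_grid(grid$values / k), cp,
                                   failure_maps(es$central))
      }, pri$fmap, mp)
    })
    def_msc <- stage("multiscale_defocus", {
      multiscale_aggregate(function(k) {
        if (k == 1L) return(def_raw)
        es <- get_eis(k)
        defocus_cost_volume(build_focal_stack(es, grid$values / k),
                            es$central, cp)
      }, pri$fmap, mp)
    })
  } else {
    cor_msc <- cor_raw
    def_msc <- def_raw
  }

  if (config$superpixel$enabled && config$superpixel$rho > 0) {
    spp <- superpixel_params(config$superpixel$approx_size,
                             config$superpixel$compactness,
                             config$superpixel$Np,
                             config$superpixel$sigma_peak,
                             config$superpixel$rho,
                             config$superpixel$iters)
    seg <- stage("superpixels", segment_superpixels(central, spp))
    cor_sp <- stage("superpixel_shaping_correspondence",
                    superpixel_shape_volume(cor_msc, seg, spp, valid))
    def_sp <- stage("superpixel_shaping_defocus",
                    superpixel_shape_volume(def_msc, seg, spp, valid))
  } else {
    seg <- NULL
    cor_sp <- cor_msc
    def_sp <- def_msc
  }

  fp <- do.call(fusion_params, config$fusion)
  fused <- stage("fusion", {
    d_cor <- wta_depth(cor_sp)
    d_def <- wta_depth(def_sp)
    mad <- absolute_difference_map(d_def, d_cor, fp$K)
    gcp_mask <- mad <= fp$gcp_threshold
    agreed <- matrix(as.integer(round((d_def$labels + d_cor$labels) / 2)),
                     nrow(mad), ncol(mad))
    P <- gcp_penalty(def_sp, gcp_mask, agreed)
    data <- build_data_term(def_sp, cor_sp, mad, P, fp)
    list(d_cor = d_cor, d_def = d_def, mad = mad, gcp_mask = gcp_mask,
         data = data)
  })
  opt <- stage("graph_cut", graphcut_optimize(fused$data, fp, valid))
  energies <- attr(opt, "energies")
  depth <- if (config$postprocess$enabled) {
    stage("postprocess",
          postprocess(opt, central,
                      median_hws = config$postprocess$median_hws,
                      sigma_guide = config$postprocess$sigma_guide,
                      guided_radius = config$postprocess$guided_radius,
                      guided_eps = config$postprocess$guided_eps))
  } else {
    opt
  }
  depth$valid <- valid

  baseline_vol <- cost_volume((cor_raw$data + def_raw$data) / 2,
                              grid$values, "fused")
  baseline <- wta_depth(baseline_vol)
  baseline$valid <- valid

  intermediates <- list(
    fmap = pri$fmap, fmaps = pri$fmaps, trimap = pri$trimap,
    matte = pri$matte, superpixels = seg,
    wta_correspondence = fused$d_cor, wta_defocus = fused$d_def,
    mad = fused$mad, gcp_mask = fused$gcp_mask,
    wta_baseline = baseline, energies = energies,
    timings = unlist(timings), config = config
  )
  if (keep_volumes) {
    intermediates$volumes <- list(correspondence_raw = cor_raw,
                                  defocus_raw = def_raw,
                                  correspondence = cor_sp,
                                  defocus = def_sp,
                                  data_term = fused$data)
  }
  list(depth = depth, intermediates = intermediates)
}

#' Write a depth map with sidecar metadata
#'
#' Writes the label image as 16-bit PNG (scaled to the label range), the
#' real disparity image as float TIFF, the validity mask as PNG, and a JSON
#' sidecar with the label grid and optional energies.
#'
#' @param depth a [depth_map()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param extra named list merged into the JSON sidecar.
#' @return invisibly, the paths written.
#' @export
write_depth_map <- function(depth, dir, prefix = "depth", extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- length(depth$grid_values)
  p1 <- file.path(dir, paste0(prefix, "_labels.png"))
  png::writePNG(depth$labels / max(L - 1L, 1L), p1)
  p2 <- file.path(dir, paste0(prefix, "_disparity.tif"))
  write_image(depth$disparity / max(abs(depth$grid_values), 1), p2)
  p3 <- file.path(dir, paste0(prefix, "_valid.png"))
  png::writePNG(depth$valid * 1, p3)
  p4 <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    c(list(grid_values = depth$grid_values,
           size = dim(depth$labels)), extra),
    p4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3, p4))
}
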