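#' Synthesize a focal stack by shift-and-sum refocusing
#'
#' For each integer shift `s`, every peripheral view is translated by `s`
#' pixels toward the image center along its view direction (the view at
#' angle `theta` moves along `(-cos(theta), -sin(theta))` in (col, row)
#' coordinates, row axis down) and averaged with the central view. The
#' fractional components arising on the 60/120-degree axes are handled by
#' bilinear interpolation. Pixels that a shifted view cannot cover are
#' excluded from the average (count normalization), so borders average only
#' the views that actually contribute.
#'
#' @param eis an [elemental_image_set()].
#' @param shifts non-empty integer vector of shifts `s`, strictly increasing.
#' @param params optional [optics_params()]; when supplied, the refocus
#'   depth of every plane is attached (micrometres).
#' @return an object of class `focal_stack`: list with `planes` (list of
#'   matrices), `shifts`, `counts` (list of contributing-view counts) and
#'   optional `refocus_depths`.
#' @export
build_focal_stack <- function(eis, shifts, params = NULL) {
  stopifnot(inherits(eis, "elemental_image_set"))
  if (length(shifts) == 0L) stop("shifts must be non-empty")
  if (is.unsorted(shifts, strictly = TRUE)) {
    stop("shifts must be strictly increasing")
  }
  planes <- vector("list", length(shifts))
  counts <- vector("list", length(shifts))
  for (k in seq_along(shifts)) {
    s <- shifts[k]
    acc <- eis$central
    cnt <- matrix(1, nrow(acc), ncol(acc))
    for (a in names(eis$peripheral)) {
      sh <- shift_view(eis$peripheral[[a]], s, as.numeric(a))
      v <- sh$valid
      acc <- acc + ifelse(v, sh$image, 0)
      cnt <- cnt + v
    }
    planes[[k]] <- acc / cnt
    counts[[k]] <- cnt
  }
  structure(
    list(planes = planes, shifts = as.numeric(shifts), counts = counts,
         refocus_depths = if (!is.null(params)) refocus_depth(params, shifts)),
    class = "focal_stack"
  )
}

#' @export
print.focal_stack <- function(x, ...) {
  cat(sprintf("<focal_stack> %d planes, shifts %s\n", length(x$planes),
              paste(x$shifts, collapse = ", ")))
  invisible(x)
}

#' Variance-of-Laplacian sharpness of an image
#'
#' Standard focus measure used to locate the best-focused plane of a stack.
#'
#' @param img numeric matrix.
#' @return scalar sharpness value.
#' @export
sharpness <- function(img) {
  lap <- convolve2(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  stats::var(as.vector(lap))
}
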