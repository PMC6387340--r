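#' Hexagonal view geometry of a FiMic mosaic
#'
#' The raw sensor image contains seven elemental images (perspective views):
#' one central and six peripheral, arranged on a hexagonal grid. Opposite
#' peripheral views form the three epipolar axes at 0, 60 and 120 degrees.
#'
#' @param center_origin numeric length-2, (row, col) of the central view
#'   center in the mosaic, 1-based.
#' @param view_radius radius of each elemental image in pixels.
#' @param view_spacing center-to-center distance between the central and each
#'   peripheral view; defaults to `2 * view_radius` (tangent disks).
#' @return an object of class `hex_geometry` with fields `center_origin`,
#'   `view_radius`, `view_spacing`, `view_angles` (degrees) and
#'   `epipolar_axes` (0, 60, 120).
#' @export
hex_geometry <- function(center_origin, view_radius,
                         view_spacing = 2 * view_radius) {
  stopifnot(length(center_origin) == 2L, view_radius >= 1,
            view_spacing > 0)
  structure(
    list(center_origin = as.numeric(center_origin),
         view_radius = as.numeric(view_radius),
         view_spacing = as.numeric(view_spacing),
         view_angles = c(0, 60, 120, 180, 240, 300),
         epipolar_axes = c(0, 60, 120)),
    class = "hex_geometry"
  )
}

#' Epipolar axis of a peripheral view angle
#' @param theta_deg view angle in degrees.
#' @return axis angle in {0, 60, 120}.
#' @export
view_axis <- function(theta_deg) theta_deg %% 180

# unit vector (dx, dy) of a view angle; row axis points down
view_unit <- function(theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th), sin(th))
}

view_center <- function(geometry, theta_deg) {
  if (is.na(theta_deg)) return(geometry$center_origin)
  u <- view_unit(theta_deg)
  # (row, col) = origin + spacing * (sin, cos)
  geometry$center_origin + geometry$view_spacing * c(u[2L], u[1L])
}

#' Seven-view elemental image set
#'
#' @param central H x W matrix, intensities in `[0, 1]`.
#' @param peripheral named list of six matrices keyed `"0"`, `"60"`, ...,
#'   `"300"`, same shape as `central`.
#' @param geometry a [hex_geometry()] (geometry of the source mosaic).
#' @param valid_mask optional logical H x W matrix flagging pixels inside the
#'   circular field of each crop; defaults to all `TRUE`.
#' @return an object of class `elemental_image_set`.
#' @export
elemental_image_set <- function(central, peripheral, geometry,
                                valid_mask = NULL) {
  stopifnot(is.matrix(central))
  angs <- c(0, 60, 120, 180, 240, 300)
  if (!setequal(names(peripheral), as.character(angs))) {
    stop("peripheral views must be keyed by angles 0,60,...,300")
  }
  peripheral <- peripheral[as.character(angs)]
  for (p in peripheral) {
    if (!all(dim(p) == dim(central))) {
      stop("all 7 elemental images must have identical shape")
    }
  }
  rng <- range(central, unlist(peripheral))
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    stop("intensities must be normalized to [0, 1]")
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(central), ncol(central))
  }
  structure(
    list(central = central, peripheral = peripheral,
         geometry = geometry, valid_mask = valid_mask),
    class = "elemental_image_set"
  )
}

#' @export
print.elemental_image_set <- function(x, ...) {
  cat(sprintf("<elemental_image_set> 7 views, %d x %d, %.0f%% of crop valid\n",
              nrow(x$central), ncol(x$central), 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Crop the seven elemental images out of a raw mosaic
#'
#' Each view is cropped as a square of side `2 * view_radius` centered on its
#' disk; pixels outside the inscribed circle are flagged in the validity
#' mask. The crop geometry must be supplied (it is a property of the optical
#' setup), it is not auto-detected.
#'
#' @param mosaic grayscale matrix (use [read_image()] for files).
#' @param geometry a [hex_geometry()].
#' @return an [elemental_image_set()].
#' @export
extract_elemental_images <- function(mosaic, geometry) {
  stopifnot(inherits(geometry, "hex_geometry"))
  mosaic <- as_gray(mosaic)
  r <- round(geometry$view_radius)
  crop1 <- function(theta) {
    ctr <- round(view_center(geometry, theta))
    rows <- (ctr[1L] - r + 1L):(ctr[1L] + r)
    cols <- (ctr[2L] - r + 1L):(ctr[2L] + r)
    if (min(rows) < 1L || min(cols) < 1L ||
        max(rows) > nrow(mosaic) || max(cols) > ncol(mosaic)) {
      stop(sprintf(
        "view at angle %s exceeds mosaic bounds (center %d,%d radius %d)",
        ifelse(is.na(theta), "center", theta), ctr[1L], ctr[2L], r))
    }
    mosaic[rows, cols, drop = FALSE]
  }
  central <- crop1(NA)
  peripheral <- lapply(geometry$view_angles, crop1)
  names(peripheral) <- as.character(geometry$view_angles)
  side <- 2L * r
  cc <- (side + 1) / 2
  ii <- matrix(seq_len(side), side, side)
  jj <- t(ii)
  mask <- (ii - cc)^2 + (jj - cc)^2 <= geometry$view_radius^2
  elemental_image_set(central, peripheral, geometry, valid_mask = mask)
}

#' Reassemble a mosaic from an elemental image set
#'
#' Inverse of [extract_elemental_images()] inside the circular validity
#' masks; used for round-trip checks and for writing synthetic mosaics.
#'
#' @param eis an [elemental_image_set()].
#' @param background fill value for pixels not covered by any view.
#' @return grayscale mosaic matrix.
#' @export
assemble_mosaic <- function(eis, background = 0) {
  g <- eis$geometry
  r <- round(g$view_radius)
  extent <- ceiling(g$center_origin + g$view_spacing + r)
  mosaic <- matrix(background, extent[1L], extent[2L])
  place1 <- function(img, theta) {
    ctr <- round(view_center(g, theta))
    rows <- (ctr[1L] - r + 1L):(ctr[1L] + r)
    cols <- (ctr[2L] - r + 1L):(ctr[2L] + r)
    patch <- mosaic[rows, cols]
    patch[eis$valid_mask] <- img[eis$valid_mask]
    mosaic[rows, cols] <<- patch
  }
  place1(eis$central, NA)
  for (a in names(eis$peripheral)) place1(eis$peripheral[[a]], as.numeric(a))
  mosaic
}
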