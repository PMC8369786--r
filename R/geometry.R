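#' Pixel calibration
#'
#' Length scale tying pixel coordinates to physical units, set from the scale
#' bar on the axial image before any area is measured.
#'
#' @param mm_per_pixel Single positive number, millimetres per pixel.
#' @return An object of class `ccar_calibration`.
#' @examples
#' cal <- calibration(0.25)
#' polygon_area(contour(c(0, 10, 10, 0), c(0, 0, 10, 10), cal))
#' @export
calibration <- function(mm_per_pixel) {
  if (!is.numeric(mm_per_pixel) || length(mm_per_pixel) != 1L ||
      !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("'mm_per_pixel' must be a single positive finite number", call. = FALSE)
  structure(list(mm_per_pixel = as.numeric(mm_per_pixel)),
            class = "ccar_calibration")
}

#' @export
print.ccar_calibration <- function(x, ...) {
  cat(sprintf("Calibration: %g mm/px (%g mm^2 per px)\n",
              x$mm_per_pixel, x$mm_per_pixel^2))
  invisible(x)
}

#' Planar contour in pixel coordinates
#'
#' An ordered vertex list outlining a structure (vertebral canal, ossified
#' mass, dural sac or cord) on an axial slice. Pixel convention: pixel centres
#' at integer coordinates, origin top-left, y increasing downward. A freehand
#' ROI is simply a densely sampled polygon, so both polygon and freehand
#' outlines enter through this one type.
#'
#' @param x,y Numeric vectors of vertex coordinates (pixels), equal length.
#' @param cal A [calibration()] object.
#' @return An object of class `ccar_contour`.
#' @export
contour <- function(x, y, cal) {
  if (!inherits(cal, "ccar_calibration"))
    stop("'cal' must be a calibration() object", call. = FALSE)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("contour vertices must be finite", call. = FALSE)
  if (nrow(unique(cbind(x, y))) < 3L)
    stop("a contour needs at least 3 distinct vertices", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y), calibration = cal),
            class = "ccar_contour")
}

#' Area enclosed by a contour
#'
#' Shoelace (Gauss) area of the vertex polygon, converted to mm^2 through the
#' calibration. The absolute value is taken, so vertex winding direction never
#' matters. Self-intersecting outlines are not detected; anatomical contours
#' are convex or nearly so and the cost of an exhaustive check is not
#' justified.
#'
#' @param contour A [contour()] object.
#' @return Area in mm^2 (non-negative scalar).
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1), calibration(1))
#' polygon_area(sq) # 1 mm^2
#' @export
polygon_area <- function(contour) {
  if (!inherits(contour, "ccar_contour"))
    stop("'contour' must be a contour() object", call. = FALSE)
  x <- contour$x
  y <- contour$y
  j <- c(seq_along(x)[-1L], 1L)
  a_px <- abs(sum(x * y[j] - x[j] * y)) / 2
  a_px * contour$calibration$mm_per_pixel^2
}

#' Area of a binary mask
#'
#' Counts set pixels and scales by the calibration; a pixel is entirely in or
#' out (no partial-pixel anti-aliasing), matching how a thresholded ROI is
#' measured.
#'
#' @param mask Matrix (or logical matrix) containing only 0/1 (or FALSE/TRUE).
#' @param cal A [calibration()] object.
#' @return Area in mm^2.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' mask_area(m, calibration(0.5)) # 16 px * 0.25 mm^2/px = 4 mm^2
#' @export
mask_area <- function(mask, cal) {
  if (!inherits(cal, "ccar_calibration"))
    stop("'cal' must be a calibration() object", call. = FALSE)
  if (is.null(dim(mask)) || length(mask) == 0L)
    stop("'mask' must be a non-empty matrix", call. = FALSE)
  v <- as.vector(mask)
  if (is.logical(v)) v <- as.integer(v)
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("'mask' must contain only 0/1 values", call. = FALSE)
  sum(v) * cal$mm_per_pixel^2
}

#' Average repeated measurements of one site
#'
#' Each structure is measured twice by each of two observers; the mean over
#' all observers and repeats is the value carried into scoring. Accepts a
#' plain numeric vector, or a data frame with columns `value` and `site`
#' (plus optional `observer`, `repeat`), in which case mixed sites are
#' rejected.
#'
#' @param measurements Numeric vector of areas (mm^2), or a data frame as
#'   described above.
#' @return Mean area in mm^2.
#' @export
average_repeats <- function(measurements) {
  if (is.data.frame(measurements)) {
    if (!all(c("value", "site") %in% names(measurements)))
      stop("measurement data frame needs 'value' and 'site' columns", call. = FALSE)
    if (length(unique(measurements$site)) > 1L)
      stop("measurements mix different sites: ",
           paste(unique(measurements$site), collapse = ", "), call. = FALSE)
    measurements <- measurements$value
  }
  if (!is.numeric(measurements) || length(measurements) < 1L)
    stop("need at least one numeric measurement", call. = FALSE)
  if (anyNA(measurements) || any(measurements < 0))
    stop("area measurements must be non-negative and non-missing", call. = FALSE)
  mean(measurements)
}

#' Reference dural-sac area from adjacent segments
#'
#' The dural-sac CSA at the compressed level cannot be read off MRI reliably,
#' so the mean of the adjacent upper and lower segment dural-sac areas stands
#' in for the normal (uncompressed) sac, assumed equal to the normal canal.
#'
#' @param upper,lower Dural-sac CSA (mm^2) one segment above/below the level
#'   of maximum compression. Vectorized.
#' @return `(upper + lower) / 2` in mm^2.
#' @export
reference_dural_sac_area <- function(upper, lower) {
  if (!is.numeric(upper) || !is.numeric(lower))
    stop("areas must be numeric", call. = FALSE)
  if (anyNA(upper) || anyNA(lower) || any(upper < 0) || any(lower < 0))
    stop("areas must be non-negative and non-missing", call. = FALSE)
  (upper + lower) / 2
}
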