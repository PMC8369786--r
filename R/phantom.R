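#' Generate a phantom slice with analytically known areas
#'
#' Builds binary masks emulating the four measured structures on one axial
#' slice: a circular bony canal, a posterior crescent-shaped ossified mass
#' (the canal disc minus an interior tangent disc, so its area is exactly
#' `pi (R^2 - r^2)`), a circular dural sac standing for the adjacent-segment
#' reference, and an elliptical cord centred in the residual free space.
#' Ground-truth areas come from the closed-form shape formulas, so the
#' rasterized masks validate the measurement chain end to end.
#'
#' Rasterization follows the geometry module's pixel convention: pixel
#' centres at integer coordinates, origin top-left, y increasing downward; a
#' pixel is set iff its centre lies inside the shape.
#'
#' @param canal_radius_mm Canal (and by default dural-sac) radius, mm.
#' @param mass_fraction Fraction of the canal occupied by the ossified mass,
#'   in `[0, 1)`; the true OCAR is `100 * mass_fraction`.
#' @param cord_semiaxes_mm Length-2 semi-axes of the cord ellipse, mm.
#' @param dural_radius_mm Dural-sac radius, mm (defaults to the canal radius,
#'   the reference-area assumption).
#' @param cal A [calibration()] object; default 0.05 mm/px so the default
#'   canal spans 320 px and rasterization error is well below 1%.
#' @param size_px Raster side length in pixels; default fits all shapes with
#'   an 8 px margin.
#' @param seed Unused randomness hook (the default phantom is deterministic);
#'   reserved for jittered variants.
#' @return Object of class `ccar_phantom`: list with `masks` (canal, mass,
#'   dural_sac, cord; 0/1 integer matrices), `calibration`, `truth` (areas
#'   in mm^2 plus true ocar/scar/ccar in percent), and `params`.
#' @examples
#' ph <- generate_phantom(canal_radius_mm = 10, mass_fraction = 0,
#'                        cord_semiaxes_mm = c(4, 4))
#' ph$truth$ccar # 84% = 100 - 0 - 100 * 16 / 100
#' @export
generate_phantom <- function(canal_radius_mm = 8, mass_fraction = 0.3,
                             cord_semiaxes_mm = c(3.2, 2.6),
                             dural_radius_mm = canal_radius_mm,
                             cal = calibration(0.05), size_px = NULL,
                             seed = NULL) {
  if (!inherits(cal, "ccar_calibration"))
    stop("'cal' must be a calibration() object", call. = FALSE)
  if (mass_fraction < 0 || mass_fraction >= 1)
    stop("'mass_fraction' must be in [0, 1)", call. = FALSE)
  if (length(cord_semiaxes_mm) != 2L || any(cord_semiaxes_mm <= 0))
    stop("'cord_semiaxes_mm' must be two positive lengths", call. = FALSE)
  if (canal_radius_mm <= 0 || dural_radius_mm <= 0)
    stop("radii must be positive", call. = FALSE)

  rc <- canal_radius_mm
  ri <- rc * sqrt(1 - mass_fraction) # interior free disc
  d <- rc - ri                        # free disc tangent anteriorly; mass is
  a <- cord_semiaxes_mm[1]            # the posterior crescent
  b <- cord_semiaxes_mm[2]
  if (max(a, b) > ri)
    stop("cord does not fit inside the mass-free region", call. = FALSE)
  if (d + max(a, b) > dural_radius_mm)
    stop("cord mask is not contained in the dural-sac region", call. = FALSE)

  mpp <- cal$mm_per_pixel
  rmax <- max(rc, dural_radius_mm)
  if (is.null(size_px)) size_px <- ceiling(2 * rmax / mpp) + 16L
  if (2 * rmax / mpp + 2 > size_px)
    stop("invalid geometry: shapes exceed the raster bounds", call. = FALSE)

  cx <- (size_px - 1) / 2
  cy <- (size_px - 1) / 2
  px <- matrix(rep(0:(size_px - 1L), size_px), size_px, byrow = TRUE) # x = col
  py <- matrix(rep(0:(size_px - 1L), size_px), size_px)               # y = row
  ellipse <- function(x0, y0, sa, sb) {
    m <- ((px - x0) * mpp / sa)^2 + ((py - y0) * mpp / sb)^2 <= 1
    matrix(as.integer(m), size_px)
  }
  canal <- ellipse(cx, cy, rc, rc)
  free <- ellipse(cx, cy - d / mpp, ri, ri)
  mass <- canal * (1L - free)
  dural <- ellipse(cx, cy, dural_radius_mm, dural_radius_mm)
  cord <- ellipse(cx, cy - d / mpp, a, b)

  canal_a <- pi * rc^2
  mass_a <- mass_fraction * pi * rc^2
  dural_a <- pi * dural_radius_mm^2
  cord_a <- pi * a * b
  ocar_t <- 100 * mass_a / canal_a
  scar_t <- 100 * cord_a / dural_a
  structure(list(
    masks = list(canal = canal, mass = mass, dural_sac = dural, cord = cord),
    calibration = cal,
    truth = list(canal_mm2 = canal_a, mass_mm2 = mass_a,
                 dural_sac_mm2 = dural_a, cord_mm2 = cord_a,
                 ocar = ocar_t, scar = scar_t, ccar = 100 - ocar_t - scar_t),
    params = list(canal_radius_mm = rc, mass_fraction = mass_fraction,
                  cord_semiaxes_mm = cord_semiaxes_mm,
                  dural_radius_mm = dural_radius_mm, size_px = size_px)
  ), class = "ccar_phantom")
}

#' @export
print.ccar_phantom <- function(x, ...) {
  cat(sprintf("Phantom slice %dx%d px at %g mm/px\n", x$params$size_px,
              x$params$size_px, x$calibration$mm_per_pixel))
  cat(sprintf("  truth: canal %.1f, mass %.1f, dural sac %.1f, cord %.1f mm^2\n",
              x$truth$canal_mm2, x$truth$mass_mm2, x$truth$dural_sac_mm2,
              x$truth$cord_mm2))
  cat(sprintf("  true OCAR %.1f%%, SCAR %.1f%%, CCAR %.1f%%\n",
              x$truth$ocar, x$truth$scar, x$truth$ccar))
  invisible(x)
}

#' Write / read a phantom as PNG masks plus a JSON sidecar
#'
#' Each mask is written as a single-channel 0/255 PNG; `phantom.json` holds
#' the calibration, ground-truth areas and shape parameters.
#'
#' @param phantom A `ccar_phantom` object.
#' @param dir Directory to write into (created if missing).
#' @return `write_phantom()`: the directory, invisibly. `read_phantom()`: a
#'   `ccar_phantom` object (masks thresholded at 0.5).
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ccar_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(phantom$masks)) {
    m <- phantom$masks[[nm]]
    storage.mode(m) <- "double" # writePNG wants real values in [0, 1]
    png::writePNG(m, file.path(dir, paste0(nm, ".png")))
  }
  sidecar <- list(mm_per_pixel = phantom$calibration$mm_per_pixel,
                  truth = phantom$truth, params = phantom$params)
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  masks <- lapply(c(canal = "canal", mass = "mass", dural_sac = "dural_sac",
                    cord = "cord"), function(nm) {
    m <- png::readPNG(file.path(dir, paste0(nm, ".png")))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(m > 0.5), nrow(m))
  })
  structure(list(masks = masks, calibration = calibration(side$mm_per_pixel),
                 truth = side$truth, params = side$params),
            class = "ccar_phantom")
}

#' Validate a phantom against its analytic ground truth
#'
#' Measures each mask with [mask_area()] and compares with the stored
#' closed-form area; also recomputes OCAR/SCAR/CCAR from the measured areas.
#'
#' @param phantom A `ccar_phantom` object or a directory written by
#'   [write_phantom()].
#' @return List with `areas` (data frame: structure, truth_mm2,
#'   measured_mm2, rel_error) and `ccar` (truth, measured).
#' @export
phantom_check <- function(phantom) {
  if (is.character(phantom)) phantom <- read_phantom(phantom)
  stopifnot(inherits(phantom, "ccar_phantom"))
  cal <- phantom$calibration
  meas <- vapply(phantom$masks, mask_area, numeric(1), cal = cal)
  truth <- unlist(phantom$truth[c("canal_mm2", "mass_mm2", "dural_sac_mm2",
                                  "cord_mm2")])
  areas <- data.frame(structure = names(phantom$masks),
                      truth_mm2 = unname(truth), measured_mm2 = unname(meas),
                      rel_error = unname(ifelse(truth > 0,
                                                abs(meas - truth) / truth, 0)))
  ccar_meas <- 100 - ocar(meas[["mass"]], meas[["canal"]]) -
    scar(meas[["cord"]], meas[["dural_sac"]])
  list(areas = areas,
       ccar = c(truth = phantom$truth$ccar, measured = unname(ccar_meas)))
}
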