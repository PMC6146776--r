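# Section rasters: 8-bit RGB images with a known physical resolution.
# Pixels are stored as a height x width x 3 numeric array with values in
# 0..255; masks are logical matrices congruent with the pixel grid.

#' Construct a section raster
#'
#' The unit of analysis: an RGB image of an H&E-stained liver section
#' together with its physical resolution in nanometers per pixel edge.
#'
#' @param pixels numeric array of dimension \code{c(height, width, 3)} with
#'   channel values in \[0, 255\].
#' @param resolution_nm_per_px positive scalar, physical edge length of one
#'   pixel in nanometers (e.g. 454 for approx. 20x magnification scans).
#' @return An object of class \code{section_raster}.
#' @export
section_raster <- function(pixels, resolution_nm_per_px) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_domain("pixels must be a height x width x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_domain("empty image")
  if (!is_scalar_num(resolution_nm_per_px) || resolution_nm_per_px <= 0)
    stop_domain("resolution_nm_per_px must be a positive scalar")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop_domain("channel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, resolution_nm_per_px = resolution_nm_per_px),
    class = "section_raster"
  )
}

#' @export
print.section_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section_raster %d x %d px, %.1f nm/px (%.0f x %.0f um)>\n",
              d[2], d[1], x$resolution_nm_per_px,
              d[2] * x$resolution_nm_per_px / 1000,
              d[1] * x$resolution_nm_per_px / 1000))
  invisible(x)
}

#' @export
dim.section_raster <- function(x) dim(x$pixels)[1:2]

#' Read a section image from PNG or TIFF
#'
#' The physical resolution can be given explicitly (which always wins) or,
#' for TIFF input, read from the file's resolution tags when present.
#'
#' @param path path to an 8-bit RGB PNG or TIFF file.
#' @param resolution_nm_per_px optional explicit resolution in nm/pixel.
#' @return A \code{\link{section_raster}}.
#' @export
read_section <- function(path, resolution_nm_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  res <- resolution_nm_per_px
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    if (is.null(res)) {
      xres <- attr(img, "x.resolution")
      unit <- attr(img, "resolution.unit")
      if (!is.null(xres) && is.finite(xres) && xres > 0) {
        # pixels per unit -> nm per pixel (unit: inch or cm; cm assumed
        # when the tag is absent, the baseline TIFF default being inch)
        nm_per_unit <- if (identical(unit, "inch")) 25.4e6 else 1e7
        res <- nm_per_unit / xres
      }
    }
  } else stop_domain("unsupported image format: ", ext)
  if (is.null(res))
    stop_domain("resolution_nm_per_px not given and not found in file")
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  section_raster(array(round(img * 255), dim(img)), res)
}

#' Write a section raster as PNG
#'
#' @param raster a \code{\link{section_raster}}.
#' @param path output path.
#' @export
write_section <- function(raster, path) {
  png::writePNG(raster$pixels / 255, path)
  invisible(path)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a 0/255 single-channel PNG back into a logical mask
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img >= 0.5
}

#' Resample a raster to a target analysis resolution
#'
#' Scores are conventionally computed at 454 nm/pixel; scans acquired at a
#' finer resolution are downsampled (bilinear) before segmentation.
#'
#' @param raster a \code{\link{section_raster}}.
#' @param target_nm_per_px target resolution; no-op if within 0.5\% of the
#'   raster's resolution.
#' @return A \code{\link{section_raster}} at the target resolution.
#' @export
resample_raster <- function(raster, target_nm_per_px = 454) {
  if (!is_scalar_num(target_nm_per_px) || target_nm_per_px <= 0)
    stop_domain("target_nm_per_px must be positive")
  ratio <- raster$resolution_nm_per_px / target_nm_per_px
  if (abs(ratio - 1) < 0.005) return(raster)
  d <- dim(raster$pixels)
  h <- max(1L, as.integer(round(d[1] * ratio)))
  w <- max(1L, as.integer(round(d[2] * ratio)))
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    out[, , ch] <- EBImage::resize(raster$pixels[, , ch], w = h, h = w)
  }
  out[out < 0] <- 0; out[out > 255] <- 255
  section_raster(out, target_nm_per_px)
}

# Per-pixel HSV saturation and value (brightness) from 0..255 RGB.
rgb_saturation_value <- function(pixels) {
  r <- pixels[, , 1]; g <- pixels[, , 2]; b <- pixels[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  list(saturation = s, value = mx / 255)
}
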