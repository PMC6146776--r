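# Fat-droplet segmentation: two-stage classification. Pixels are first
# classified white/non-white from HSV saturation and brightness; connected
# white blobs inside the tissue are then classified as macrovesicular fat
# droplets vs. other white structures (vessels, cracks) from shape features.
# The blob rule is a deterministic threshold predicate and is pluggable, so
# a learned classifier can be swapped in without touching the pipeline.

#' Segmentation configuration
#'
#' Thresholds of the rule-based pixel and blob classifiers.
#'
#' @param saturation_max maximum HSV saturation for a pixel to count as
#'   white (candidate fat/vessel/crack/background), in \[0, 1\].
#' @param brightness_min minimum HSV value (brightness) for a white pixel,
#'   in \[0, 1\].
#' @param droplet_min_diameter_um,droplet_max_diameter_um accepted range of
#'   blob equivalent diameters in micrometers. Macrovesicular droplets span
#'   roughly 5--100 um; larger round white structures are typically vessels.
#' @param min_circularity minimum \code{4 * pi * area / perimeter^2}; cracks
#'   and vessels cut at the section edge are elongated and fall below this.
#' @param min_solidity minimum area / convex-hull-area; rejects ragged or
#'   branched white structures.
#' @param closing_radius_um radius of the morphological closing used to
#'   build the tissue mask (gaps narrower than twice this are bridged).
#' @return A \code{segmentation_config} list.
#' @export
segmentation_config <- function(saturation_max = 0.25,
                                brightness_min = 0.8,
                                droplet_min_diameter_um = 5,
                                droplet_max_diameter_um = 100,
                                min_circularity = 0.5,
                                min_solidity = 0.85,
                                closing_radius_um = 50) {
  stopifnot(
    saturation_max >= 0, saturation_max <= 1,
    brightness_min >= 0, brightness_min <= 1,
    droplet_min_diameter_um > 0,
    droplet_min_diameter_um < droplet_max_diameter_um,
    min_circularity >= 0, min_circularity <= 1,
    min_solidity >= 0, min_solidity <= 1,
    closing_radius_um > 0
  )
  structure(
    list(saturation_max = saturation_max,
         brightness_min = brightness_min,
         droplet_min_diameter_um = droplet_min_diameter_um,
         droplet_max_diameter_um = droplet_max_diameter_um,
         min_circularity = min_circularity,
         min_solidity = min_solidity,
         closing_radius_um = closing_radius_um),
    class = "segmentation_config"
  )
}

#' Classify pixels as white (candidate background/fat/vessel/crack)
#'
#' A pixel is white iff its HSV saturation is at most
#' \code{config$saturation_max} and its brightness (HSV value) is at least
#' \code{config$brightness_min}. Eosin-stained tissue is saturated pink and
#' fails the saturation test; lipid vacuoles, vessel lumina, cracks and the
#' bare slide pass.
#'
#' @param raster a \code{\link{section_raster}}.
#' @param config a \code{\link{segmentation_config}}.
#' @return Logical matrix (TRUE = white).
#' @export
classify_pixels <- function(raster, config = segmentation_config()) {
  stopifnot(inherits(raster, "section_raster"))
  sv <- rgb_saturation_value(raster$pixels)
  sv$saturation <= config$saturation_max & sv$value >= config$brightness_min
}

# Euclidean-disc dilation / erosion via distance transforms; O(n) per call
# irrespective of the radius (a plain brush would be quadratic in it).
.dilate_disc <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  d <- EBImage::distmap(1 - mask)  # distance to nearest TRUE pixel
  d <= radius_px
}

.erode_disc <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  d <- EBImage::distmap(mask * 1)  # distance to nearest FALSE pixel
  d > radius_px
}

#' Compute the tissue mask of a section
#'
#' Area fractions are defined with respect to the total tissue area, which
#' must include the fat droplets and small lumina \emph{inside} the section
#' while excluding the bare slide around it. The non-white region is closed
#' with a disc of \code{closing_radius_um} and holes are filled, so droplets
#' and vessels enclosed by tissue count as tissue.
#'
#' @param raster a \code{\link{section_raster}} (provides the resolution).
#' @param white_mask logical matrix from \code{\link{classify_pixels}}.
#' @param config a \code{\link{segmentation_config}}.
#' @return Logical tissue mask.
#' @export
compute_tissue_mask <- function(raster, white_mask,
                                config = segmentation_config()) {
  stopifnot(inherits(raster, "section_raster"))
  if (!identical(dim(white_mask), dim(raster$pixels)[1:2]))
    stop_domain("mask shape mismatch")
  r_px <- config$closing_radius_um * 1000 / raster$resolution_nm_per_px
  stained <- !white_mask
  if (!any(stained)) return(stained)
  closed <- .erode_disc(.dilate_disc(stained, r_px), r_px)
  closed <- closed | stained  # closing is extensive; guard discrete EDT edge loss
  filled <- EBImage::fillHull(closed * 1L) > 0
  matrix(filled, nrow = nrow(white_mask))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find over label pairs.
label_blobs <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1, -1]          # down-right
  c_ <- lab[-nrow(lab), -1]; d <- lab[-1, -ncol(lab)]          # down-left
  pairs <- rbind(
    cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
    cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d])
  )
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

# Crofton 4-direction perimeter: pi/4 * (runs_h + runs_v + runs_diag/sqrt(2)),
# where runs_* counts maximal runs of each label along scan lines in the four
# principal directions. Near-unbiased for discs; applied identically wherever
# circularity is computed.
.crofton_perimeter <- function(lab, n) {
  count_runs <- function(cur, prev) {
    starts <- cur > 0 & cur != prev
    tabulate(cur[starts], nbins = n)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  zr <- matrix(0L, nr, 1); zc <- matrix(0L, 1, nc)
  n_h <- count_runs(lab, cbind(zr, lab[, -nc, drop = FALSE]))
  n_v <- count_runs(lab, rbind(zc, lab[-nr, , drop = FALSE]))
  # diagonal predecessors (up-left and up-right), zero-padded
  pad_ul <- matrix(0L, nr, nc)
  pad_ul[-1, -1] <- lab[-nr, -nc]
  pad_ur <- matrix(0L, nr, nc)
  pad_ur[-1, -nc] <- lab[-nr, -1]
  n_d1 <- count_runs(lab, pad_ul)
  n_d2 <- count_runs(lab, pad_ur)
  pi / 4 * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# Convex hull area of a pixel set from pixel centers (shoelace formula).
.hull_area <- function(rows, cols) {
  if (length(rows) < 3L) return(0)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Extract white blobs inside the tissue
#'
#' Connected components (8-connectivity) of the white mask that overlap the
#' tissue mask, with shape features per blob. Components entirely outside
#' the tissue (the bare slide) are discarded.
#'
#' @param white_mask,tissue_mask logical matrices of identical shape.
#' @param resolution_nm_per_px positive scalar.
#' @return A data frame with one row per blob: \code{blob_id, pixel_count,
#'   perimeter_px, circularity, solidity, equivalent_diameter_um,
#'   bbox_rmin, bbox_rmax, bbox_cmin, bbox_cmax}; the label matrix is
#'   attached as attribute \code{"labels"}.
#' @export
extract_blobs <- function(white_mask, tissue_mask, resolution_nm_per_px) {
  if (!identical(dim(white_mask), dim(tissue_mask)))
    stop_domain("mask shape mismatch")
  lab <- label_blobs(white_mask)
  n <- max(lab)
  empty <- data.frame(blob_id = integer(), pixel_count = integer(),
                      perimeter_px = numeric(), circularity = numeric(),
                      solidity = numeric(), equivalent_diameter_um = numeric(),
                      bbox_rmin = integer(), bbox_rmax = integer(),
                      bbox_cmin = integer(), bbox_cmax = integer())
  if (n == 0) {
    attr(empty, "labels") <- lab
    attr(empty, "resolution_nm_per_px") <- resolution_nm_per_px
    return(empty)
  }
  in_tissue <- sort(unique(lab[lab > 0 & tissue_mask]))
  if (!length(in_tissue)) {
    attr(empty, "labels") <- lab
    attr(empty, "resolution_nm_per_px") <- resolution_nm_per_px
    return(empty)
  }
  area <- tabulate(lab[lab > 0], nbins = n)
  perim <- .crofton_perimeter(lab, n)
  idx <- which(lab > 0)
  labv <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  keep <- labv %in% in_tissue
  by_lab <- split(data.frame(r = rows[keep], c = cols[keep]), labv[keep])
  sol <- vapply(by_lab, function(p) {
    ha <- .hull_area(p$r, p$c)
    if (ha <= 0) 1 else min(1, nrow(p) / ha)
  }, numeric(1))
  bb <- t(vapply(by_lab, function(p)
    c(min(p$r), max(p$r), min(p$c), max(p$c)), numeric(4)))
  ids <- as.integer(names(by_lab))
  a <- area[ids]; p <- perim[ids]
  out <- data.frame(
    blob_id = ids,
    pixel_count = a,
    perimeter_px = p,
    circularity = pmin(1, 4 * pi * a / p^2),
    solidity = unname(sol),
    equivalent_diameter_um = 2 * sqrt(a / pi) * resolution_nm_per_px / 1000,
    bbox_rmin = as.integer(bb[, 1]), bbox_rmax = as.integer(bb[, 2]),
    bbox_cmin = as.integer(bb[, 3]), bbox_cmax = as.integer(bb[, 4])
  )
  attr(out, "labels") <- lab
  attr(out, "resolution_nm_per_px") <- resolution_nm_per_px
  out
}

#' Default droplet acceptance rule as a blob predicate
#'
#' @param config a \code{\link{segmentation_config}}.
#' @return A function mapping a blob data frame to a logical acceptance
#'   vector; swap in any other such function for a learned classifier.
#' @export
droplet_rule <- function(config = segmentation_config()) {
  force(config)
  function(blobs) {
    blobs$equivalent_diameter_um >= config$droplet_min_diameter_um &
      blobs$equivalent_diameter_um <= config$droplet_max_diameter_um &
      blobs$circularity >= config$min_circularity &
      blobs$solidity >= config$min_solidity
  }
}

#' Classify blobs as fat droplets and build the droplet mask
#'
#' @param blobs blob table from \code{\link{extract_blobs}} (with its label
#'   matrix attribute).
#' @param tissue_mask logical tissue mask; the returned droplet mask is
#'   restricted to it.
#' @param config a \code{\link{segmentation_config}} (used when
#'   \code{predicate} is NULL).
#' @param predicate optional replacement classifier: a function from the
#'   blob table to a logical vector.
#' @return Logical droplet mask; the blob table with an \code{accepted}
#'   column is attached as attribute \code{"blobs"}.
#' @export
classify_blobs <- function(blobs, tissue_mask,
                           config = segmentation_config(),
                           predicate = NULL) {
  lab <- attr(blobs, "labels")
  if (is.null(lab)) stop_domain("blobs must come from extract_blobs()")
  if (is.null(predicate)) predicate <- droplet_rule(config)
  acc <- if (nrow(blobs)) as.logical(predicate(blobs)) else logical(0)
  blobs$accepted <- acc
  mask <- matrix(FALSE, nrow(lab), ncol(lab))
  if (any(acc)) {
    keep <- blobs$blob_id[acc]
    mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  mask <- mask & tissue_mask
  attr(mask, "blobs") <- blobs
  mask
}

#' Segment a section end to end
#'
#' Runs pixel classification, tissue-mask construction, blob extraction and
#' blob classification; deterministic given raster and config.
#'
#' @param raster a \code{\link{section_raster}}.
#' @param config a \code{\link{segmentation_config}}.
#' @param predicate optional blob classifier override (see
#'   \code{\link{classify_blobs}}).
#' @return List with \code{white}, \code{tissue}, \code{droplet} masks and
#'   the \code{blobs} table.
#' @export
segment_section <- function(raster, config = segmentation_config(),
                            predicate = NULL) {
  white <- classify_pixels(raster, config)
  tissue <- compute_tissue_mask(raster, white, config)
  blobs <- extract_blobs(white, tissue, raster$resolution_nm_per_px)
  droplet <- classify_blobs(blobs, tissue, config, predicate)
  list(white = white, tissue = tissue, droplet = droplet,
       blobs = attr(droplet, "blobs"))
}

#' Write the blob table as CSV
#'
#' Columns: \code{blob_id, pixel_count, equivalent_diameter_um,
#' circularity, solidity, accepted}.
#'
#' @param blobs blob table with an \code{accepted} column.
#' @param path output CSV path.
#' @export
write_blob_table <- function(blobs, path) {
  cols <- c("blob_id", "pixel_count", "equivalent_diameter_um",
            "circularity", "solidity", "accepted")
  write.csv(blobs[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
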