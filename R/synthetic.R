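# Synthetic H&E-like sections with ground truth. Tissue is an irregular
# eosin-pink region with channel noise; steatotic regions are either the
# whole tissue (uniform), unions of compact discs (focal) or a thresholded
# smooth random field (diffuse, standing in for lobular periodicity);
# non-overlapping white discs emulate macrovesicular droplets; vessels are
# large rimmed white ellipses and cracks thin white polylines. Everything
# is reproducible from one seed.

#' Specify a synthetic section
#'
#' @param width_px,height_px raster size in pixels.
#' @param resolution_nm_per_px physical resolution (default the 454 nm/px
#'   analysis resolution).
#' @param target_area_fraction droplet area as a fraction of tissue area,
#'   in \[0, 0.6); the generator places droplets until the realized ground
#'   truth is within 5\% relative of this target.
#' @param pattern spatial arrangement of steatotic regions:
#'   \code{"uniform"}, \code{"focal"} or \code{"diffuse"}.
#' @param steatotic_region_fraction share of the tissue inside steatotic
#'   regions (ignored for \code{"uniform"}).
#' @param droplet_median_um,droplet_sigma lognormal droplet diameter
#'   distribution (median in micrometers, log-sd).
#' @param n_vessels,n_cracks number of white confounders to render.
#' @param seed integer seed; identical specs give identical sections.
#' @return A \code{section_spec} list.
#' @export
section_spec <- function(width_px = 1024, height_px = 1024,
                         resolution_nm_per_px = 454,
                         target_area_fraction = 0.1,
                         pattern = c("uniform", "focal", "diffuse"),
                         steatotic_region_fraction = 0.35,
                         droplet_median_um = 15, droplet_sigma = 0.3,
                         n_vessels = 0, n_cracks = 0, seed = 1) {
  pattern <- match.arg(pattern)
  stopifnot(width_px >= 1, height_px >= 1, resolution_nm_per_px > 0,
            target_area_fraction >= 0, target_area_fraction < 0.6,
            steatotic_region_fraction > 0, steatotic_region_fraction <= 1,
            droplet_median_um > 0, droplet_sigma >= 0,
            n_vessels >= 0, n_cracks >= 0)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         resolution_nm_per_px = resolution_nm_per_px,
         target_area_fraction = target_area_fraction, pattern = pattern,
         steatotic_region_fraction = steatotic_region_fraction,
         droplet_median_um = droplet_median_um,
         droplet_sigma = droplet_sigma,
         n_vessels = as.integer(n_vessels), n_cracks = as.integer(n_cracks),
         seed = as.integer(seed)),
    class = "section_spec"
  )
}

# Smooth unit-variance random field: white noise blurred with a Gaussian
# kernel, then standardized. Correlation lengths are capped at 1/8 of the
# short image side (a field smoother than that is indistinguishable from a
# single gradient at section scale), and long-range blurs run on a coarse
# grid that is bilinearly upsampled, keeping the kernel small.
.smooth_field <- function(nr, nc, sigma_px) {
  sigma <- max(1, min(sigma_px, min(nr, nc) / 8))
  f <- max(1L, min(as.integer(sigma / 4), as.integer(min(nr, nc) / 64)))
  if (f > 1L) {
    cnr <- as.integer(ceiling(nr / f)); cnc <- as.integer(ceiling(nc / f))
    g <- matrix(rnorm(cnr * cnc), cnr, cnc)
    g <- EBImage::gblur(g, sigma = sigma / f)
    g <- EBImage::resize(g, w = nr, h = nc)
  } else {
    g <- EBImage::gblur(matrix(rnorm(nr * nc), nr, nc), sigma = sigma)
  }
  (g - mean(g)) / sd(g)
}

# Irregular tissue region: ellipse with a low-order sinusoidal radial
# perturbation, leaving a clear slide margin on all sides.
.tissue_region <- function(nr, nc) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ry <- 0.42 * nr; rx <- 0.42 * nc
  a1 <- runif(1, 0.02, 0.08); a2 <- runif(1, 0.02, 0.06)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  th <- atan2(y / ry, x / rx)
  scale <- 1 + a1 * sin(2 * th + p1) + a2 * sin(3 * th + p2)
  (y / ry)^2 + (x / rx)^2 <= scale^2
}

.region_mask <- function(spec, tissue) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  if (spec$pattern == "uniform") return(tissue)
  px_um <- spec$resolution_nm_per_px / 1000
  if (spec$pattern == "diffuse") {
    # correlation length ~500 um standing in for lobular periodicity
    f <- .smooth_field(nr, nc, 250 / px_um / 2)
    cut <- quantile(f[tissue], 1 - spec$steatotic_region_fraction)
    return(tissue & f >= cut)
  }
  # focal: union of compact discs grown until the requested share is met;
  # nominal 300 um focus radius, capped so small test images still show
  # several distinct foci
  region <- matrix(FALSE, nr, nc)
  target <- spec$steatotic_region_fraction * sum(tissue)
  r_px <- min(max(8, 300 / px_um), min(nr, nc) / 6)
  tries <- 0
  in_t <- which(tissue)
  while (sum(region & tissue) < target && tries < 200) {
    c_idx <- in_t[sample.int(length(in_t), 1)]
    cy <- (c_idx - 1) %% nr + 1; cx <- (c_idx - 1) %/% nr + 1
    rr <- r_px * runif(1, 0.6, 1.3)
    ys <- max(1, floor(cy - rr)):min(nr, ceiling(cy + rr))
    xs <- max(1, floor(cx - rr)):min(nc, ceiling(cx + rr))
    sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= rr^2
    region[ys, xs] <- region[ys, xs] | sub
    tries <- tries + 1
  }
  region & tissue
}

# Paint a disc into a logical matrix; returns linear indices of its pixels.
.disc_idx <- function(nr, nc, cy, cx, r) {
  ys <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
  sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  cbind(rep(ys, times = length(xs))[as.vector(sub)],
        rep(xs, each = length(ys))[as.vector(sub)])
}

#' Generate a synthetic section with ground-truth masks
#'
#' Places non-overlapping droplet discs inside the steatotic regions by
#' rejection sampling until the realized droplet area over tissue area is
#' within 5\% relative of the target, then renders the RGB raster.
#'
#' @param spec a \code{\link{section_spec}}.
#' @return List: \code{raster} (a \code{\link{section_raster}}),
#'   \code{droplet_mask}, \code{tissue_mask}, \code{region_mask} (all
#'   logical ground truth), and \code{spec}.
#' @export
generate_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  with_seed(spec$seed, {
    nr <- spec$height_px; nc <- spec$width_px
    px_um <- spec$resolution_nm_per_px / 1000
    tissue <- .tissue_region(nr, nc)
    region <- .region_mask(spec, tissue)

    occupied <- matrix(FALSE, nr, nc)   # droplets may not overlap these
    vessel <- matrix(FALSE, nr, nc)     # lumen
    rim <- matrix(FALSE, nr, nc)
    crack <- matrix(FALSE, nr, nc)

    # vessels: white elliptical lumina with a denser pink wall rim
    interior <- .erode_disc(tissue, 30 / px_um)
    in_int <- which(interior)
    for (v in seq_len(spec$n_vessels)) {
      if (!length(in_int)) break
      c_idx <- in_int[sample.int(length(in_int), 1)]
      cy <- (c_idx - 1) %% nr + 1; cx <- (c_idx - 1) %/% nr + 1
      # vessel-scale lumina (150-280 um), above the droplet size range
      a <- runif(1, 150, 280) / px_um / 2; b <- a * runif(1, 0.6, 1)
      ang <- runif(1, 0, pi)
      ys <- max(1, floor(cy - a)):min(nr, ceiling(cy + a))
      xs <- max(1, floor(cx - a)):min(nc, ceiling(cx + a))
      yy <- matrix(ys - cy, length(ys), length(xs))
      xx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
      u <- yy * cos(ang) + xx * sin(ang); w <- -yy * sin(ang) + xx * cos(ang)
      d2 <- (u / a)^2 + (w / b)^2
      vessel[ys, xs] <- vessel[ys, xs] | (d2 <= 1)
      rim[ys, xs] <- rim[ys, xs] | (d2 > 1 & d2 <= 1.45)
    }

    # cracks: thin white random-walk polylines in the tissue interior
    for (cr in seq_len(spec$n_cracks)) {
      if (!length(in_int)) break
      c_idx <- in_int[sample.int(length(in_int), 1)]
      py <- (c_idx - 1) %% nr + 1; px <- (c_idx - 1) %/% nr + 1
      ang <- runif(1, 0, 2 * pi)
      steps <- as.integer(200 / px_um)
      for (s in seq_len(steps)) {
        ang <- ang + rnorm(1, 0, 0.15)
        py <- py + sin(ang); px <- px + cos(ang)
        iy <- round(py); ix <- round(px)
        if (iy < 2 || iy > nr - 1 || ix < 2 || ix > nc - 1) break
        crack[iy + (-1:0), ix + (-1:0)] <- TRUE
      }
    }
    occupied <- .dilate_disc(vessel | rim | crack, 3 / px_um)

    # droplets by rejection sampling toward the target area fraction
    droplet <- matrix(FALSE, nr, nc)
    tissue_area <- sum(tissue)
    target_px <- spec$target_area_fraction * tissue_area
    placable <- which(region & .erode_disc(tissue, 4 / px_um))
    if (target_px > 0 && !length(placable))
      stop_domain("infeasible droplet packing: no placable steatotic area")
    realized <- 0
    attempts <- 0
    max_attempts <- 2000 + 50 * ceiling(target_px / max(1, (spec$droplet_median_um / px_um / 2)^2 * pi))
    min_r <- 2.5 / px_um / 2   # never smaller than ~2.5 um diameter
    while (realized < 0.95 * target_px && attempts < max_attempts) {
      attempts <- attempts + 1
      c_idx <- placable[sample.int(length(placable), 1)]
      cy <- (c_idx - 1) %% nr + 1; cx <- (c_idx - 1) %/% nr + 1
      d_um <- exp(log(spec$droplet_median_um) + rnorm(1, 0, spec$droplet_sigma))
      r <- d_um / px_um / 2
      if (realized + pi * r^2 > 1.05 * target_px) {
        r <- sqrt(max(0, (target_px - realized)) / pi)
        if (r < min_r) break
      }
      if (cy - r < 2 || cy + r > nr - 1 || cx - r < 2 || cx + r > nc - 1) next
      idx <- .disc_idx(nr, nc, cy, cx, r + 1)   # 1 px clearance
      if (any(occupied[idx]) || any(droplet[idx])) next
      core <- .disc_idx(nr, nc, cy, cx, r)
      if (!all(tissue[core])) next
      droplet[core] <- TRUE
      occupied[idx] <- TRUE
      realized <- realized + nrow(core)
    }
    if (target_px > 0 && realized < 0.95 * target_px)
      stop_domain(sprintf(
        "infeasible droplet packing: achieved fraction %.4f of target %.4f",
        realized / tissue_area, spec$target_area_fraction))

    # render: eosin pink tissue, white confounders and droplets, pale slide
    base <- c(235, 150, 170); wall <- c(215, 120, 150); bg <- c(250, 249, 250)
    white <- c(252, 250, 251)
    pix <- array(0, c(nr, nc, 3))
    for (ch in 1:3) {
      m <- matrix(bg[ch], nr, nc)
      m[tissue] <- base[ch]
      m[rim & tissue] <- wall[ch]
      m[(vessel | crack | droplet) & tissue] <- white[ch]
      m <- round(m + matrix(rnorm(nr * nc, 0, 4), nr, nc))
      pix[, , ch] <- pmin(255, pmax(0, m))
    }
    list(raster = section_raster(pix, spec$resolution_nm_per_px),
         droplet_mask = droplet & tissue,
         tissue_mask = tissue,
         region_mask = region,
         spec = spec)
  })
}
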