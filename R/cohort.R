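# Cohort generation: grouped synthetic studies mirroring the typical
# design of steatosis feeding experiments (several groups of sections with
# distinct mean steatosis levels, insignificant variation within groups).
# Two engines exist: a pixel renderer (generate_section per image) and a
# fast analytic tile-map engine that skips rendering and emits tile
# fraction maps directly from a cell-level model.
#
# Analytic model. Tissue is a rectangle of 8 um cells. A smooth random
# field thresholded at the steatotic-region share defines steatotic
# regions. Inside them each cell independently holds droplet matter with
# probability q (the within-region droplet density) and, when it does, a
# coverage drawn from Beta(8, 1.5); elsewhere the fraction is zero. Tile
# maps at 8 um are exactly this zero-inflated Beta field; coarser maps
# arise by block aggregation of the counts, which is what creates the
# tile-size physics: 8 um tiles saturate near the Beta mean regardless of
# q, intermediate tiles average ~q per tile, and large tiles increasingly
# mix region boundary, whose position jitters between images.
#
# Serial-section ("dataset-C") mode emulates consecutive sections of one
# liver: all images share one steatotic-region layout up to a small smooth
# per-image perturbation; groups differ only by a small monotone drift in
# q; and every image gets independent non-steatotic tissue margins of
# random width, emulating unstandardized tissue sampling.

#' Specify a synthetic cohort
#'
#' @param groups data frame with columns \code{label}, \code{n_images},
#'   \code{target_area_fraction} (group mean whole-section fraction) and
#'   \code{covariate} (ordinal; NA to omit validity analysis).
#' @param jitter_sd relative standard deviation of the per-image
#'   steatosis-level jitter around the group mean (truncated to
#'   feasibility).
#' @param template a \code{\link{section_spec}} shared by all images
#'   (its \code{target_area_fraction} and \code{seed} are overridden per
#'   image).
#' @param seed cohort seed; all randomness derives from it.
#' @param mode \code{"independent"} (each image its own layout; the
#'   feeding-study designs) or \code{"serial"} (dataset-C-like serial
#'   sections, see above).
#' @param layout_jitter serial mode: sd of the per-image smooth
#'   perturbation of the shared region field, as a fraction of the field
#'   sd.
#' @param margin_max_um serial mode: maximum width of the random
#'   non-steatotic tissue margin added per side.
#' @return A \code{cohort_spec}.
#' @export
cohort_spec <- function(groups, jitter_sd = 0.03,
                        template = section_spec(),
                        seed = 1,
                        mode = c("independent", "serial"),
                        layout_jitter = 0.15,
                        margin_max_um = 1200) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(groups),
            all(c("label", "n_images", "target_area_fraction") %in%
                  names(groups)),
            all(groups$n_images >= 2),
            all(groups$target_area_fraction >= 0),
            all(groups$target_area_fraction < 0.6),
            jitter_sd >= 0)
  if (!"covariate" %in% names(groups)) groups$covariate <- NA_real_
  structure(
    list(groups = groups, jitter_sd = jitter_sd, template = template,
         seed = as.integer(seed), mode = mode,
         layout_jitter = layout_jitter, margin_max_um = margin_max_um),
    class = "cohort_spec"
  )
}

#' Serial-section cohort specification (dataset-C-like design)
#'
#' Five groups of six serial sections of one liver with a small monotone
#' drift in the within-region droplet density between groups. The section
#' target fractions are derived from the density via the Beta coverage
#' mean and the steatotic-region share.
#'
#' @param n_groups,n_images design shape (default 5 x 6).
#' @param base_density within-region droplet-cell density of the first
#'   group.
#' @param density_step absolute drift in density per group (0 gives a null
#'   cohort with indistinguishable group means).
#' @param jitter_sd per-image relative density jitter (section-to-section
#'   variability of nearly identical serial sections).
#' @param steatotic_region_fraction share of tissue that is steatotic.
#' @param seed cohort seed.
#' @return A \code{cohort_spec} with \code{mode = "serial"}.
#' @export
cohort_spec_serial <- function(n_groups = 5, n_images = 6,
                               base_density = 0.32, density_step = 0.02,
                               jitter_sd = 0.015,
                               steatotic_region_fraction = 0.35,
                               seed = 1) {
  beta_mean <- 8 / (8 + 1.5)
  dens <- base_density + density_step * (seq_len(n_groups) - 1)
  groups <- data.frame(
    label = paste0("L", seq_len(n_groups)),
    n_images = n_images,
    target_area_fraction = dens * beta_mean * steatotic_region_fraction,
    covariate = NA_real_
  )
  tmpl <- section_spec(pattern = "diffuse",
                       steatotic_region_fraction = steatotic_region_fraction)
  cohort_spec(groups, jitter_sd = jitter_sd, template = tmpl, seed = seed,
              mode = "serial")
}

# ---- analytic tile-map engine ------------------------------------------

.block_sum <- function(m, k) {
  gi <- (seq_len(nrow(m)) - 1L) %/% k
  gj <- (seq_len(ncol(m)) - 1L) %/% k
  t(rowsum(t(rowsum(m, gi)), gj))
}

# One analytic image -> tile maps at the requested sizes.
.analytic_image <- function(frac_cells, cell_um, px_per_cell_edge,
                            tile_sizes_um, source_id) {
  tissue_cell_px <- px_per_cell_edge^2
  res_nm <- cell_um * 1000 / px_per_cell_edge
  droplet_cells <- round(frac_cells * tissue_cell_px)
  maps <- lapply(tile_sizes_um, function(ts) {
    k <- max(1L, as.integer(round(ts / cell_um)))
    dro <- .block_sum(droplet_cells, k)
    tis <- .block_sum(matrix(tissue_cell_px, nrow(frac_cells),
                             ncol(frac_cells)), k)
    tiles <- data.frame(
      row = as.vector(row(dro)) - 1L, col = as.vector(col(dro)) - 1L,
      tissue_px = as.integer(as.vector(tis)),
      droplet_px = as.integer(as.vector(dro))
    )
    new_tile_fraction_map(tiles, dim(dro), ts, res_nm, source_id)
  })
  names(maps) <- as.character(tile_sizes_um)
  maps
}

.analytic_cohort <- function(spec, tile_sizes_um, cell_um = 8,
                             core_cells = 320, px_per_cell_edge = 8,
                             beta_shape = c(8, 1.5)) {
  g <- spec$groups
  rf <- spec$template$steatotic_region_fraction
  beta_mean <- beta_shape[1] / sum(beta_shape)
  corr_sigma <- 500 / cell_um / 2     # ~500 um correlation length
  margin_max <- as.integer(round(spec$margin_max_um / cell_um))
  with_seed(spec$seed, {
    shared <- if (spec$mode == "serial")
      .smooth_field(core_cells, core_cells, corr_sigma) else NULL
    design <- list(); maps <- list(); truth <- list()
    img_i <- 0L
    for (gi in seq_len(nrow(g))) {
      q_g <- g$target_area_fraction[gi] / (beta_mean * rf)
      if (q_g >= 0.95)
        stop_domain("group ", g$label[gi], ": infeasible density ",
                    round(q_g, 3))
      for (j in seq_len(g$n_images[gi])) {
        img_i <- img_i + 1L
        id <- sprintf("img%03d", img_i)
        field <- if (spec$mode == "serial") {
          pert <- .smooth_field(core_cells, core_cells, corr_sigma)
          shared + spec$layout_jitter * pert
        } else {
          .smooth_field(core_cells, core_cells, corr_sigma)
        }
        region <- field >= quantile(field, 1 - rf)
        q <- q_g * (1 + rnorm(1, 0, spec$jitter_sd))
        q <- min(max(q, 0), 0.95)
        frac <- matrix(0, core_cells, core_cells)
        hit <- region & (matrix(runif(core_cells^2), core_cells) < q)
        frac[hit] <- rbeta(sum(hit), beta_shape[1], beta_shape[2])
        if (spec$mode == "serial" && margin_max > 0) {
          m <- sample.int(margin_max + 1L, 4, replace = TRUE) - 1L
          frac <- rbind(matrix(0, m[1], ncol(frac)), frac,
                        matrix(0, m[2], ncol(frac)))
          frac <- cbind(matrix(0, nrow(frac), m[3]), frac,
                        matrix(0, nrow(frac), m[4]))
        }
        maps[[id]] <- .analytic_image(frac, cell_um, px_per_cell_edge,
                                      tile_sizes_um, id)
        design[[img_i]] <- data.frame(source_id = id,
                                      group_label = g$label[gi],
                                      covariate = g$covariate[gi])
        truth[[id]] <- list(q = q, region_cells = sum(region))
      }
    }
    list(design = do.call(rbind, design), maps = maps, truth = truth)
  })
}

#' Generate a synthetic cohort
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param tile_maps_only if TRUE, skip rendering and emit tile fraction
#'   maps directly from the analytic cell-level model (fast path for
#'   statistical studies); otherwise render full sections.
#' @param tile_sizes_um tile sizes to emit in analytic mode (rendered mode
#'   returns sections; tile maps are computed downstream from the masks).
#' @return A list with \code{design} (data frame \code{source_id,
#'   group_label, covariate}) and either \code{maps}
#'   (\code{maps[[source_id]][[tile_size]]}) plus per-image \code{truth}
#'   (analytic mode) or \code{sections} (named list of
#'   \code{\link{generate_section}} bundles).
#' @export
generate_cohort <- function(spec, tile_maps_only = FALSE,
                            tile_sizes_um = c(8, 16, 32, 64, 128)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (tile_maps_only) return(.analytic_cohort(spec, tile_sizes_um))
  g <- spec$groups
  with_seed(spec$seed, {
    design <- list(); sections <- list()
    img_i <- 0L
    for (gi in seq_len(nrow(g))) {
      for (j in seq_len(g$n_images[gi])) {
        img_i <- img_i + 1L
        id <- sprintf("img%03d", img_i)
        taf <- g$target_area_fraction[gi] *
          (1 + rnorm(1, 0, spec$jitter_sd))
        taf <- min(max(taf, 0), 0.55)
        s <- spec$template
        s$target_area_fraction <- taf
        s$seed <- sample.int(2^30, 1)
        sections[[id]] <- generate_section(s)
        design[[img_i]] <- data.frame(source_id = id,
                                      group_label = g$label[gi],
                                      covariate = g$covariate[gi])
      }
    }
    list(design = do.call(rbind, design), sections = sections)
  })
}
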