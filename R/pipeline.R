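# End-to-end pipeline: segment each image, tile at each requested size,
# score under each spec, then run the clinimetric evaluation over the
# design. Tile maps are persisted as CSV and are the audit trail: every
# number in the evaluation table is recomputable from them alone.

#' Default score specifications
#'
#' The standard score plus mean-based focused scores over the conventional
#' tile-size sweep; optionally a percentile sweep (10th..90th) at one tile
#' size.
#'
#' @param tile_sizes_um focused-score tile sizes.
#' @param percentile_sweep if TRUE, add the nine decile percentile scores.
#' @param percentile_tile_size_um tile size of the percentile sweep.
#' @param min_steatotic_tiles definedness threshold for focused scores.
#' @return List of \code{\link{score_spec}}s.
#' @export
default_score_specs <- function(tile_sizes_um = c(8, 16, 32, 64, 128),
                                percentile_sweep = FALSE,
                                percentile_tile_size_um = 32,
                                min_steatotic_tiles = 100) {
  specs <- c(
    list(score_spec("standard", "mean", tile_size_um = min(tile_sizes_um),
                    min_steatotic_tiles = min_steatotic_tiles)),
    lapply(tile_sizes_um, function(ts)
      score_spec("focused", "mean", tile_size_um = ts,
                 min_steatotic_tiles = min_steatotic_tiles))
  )
  if (percentile_sweep) {
    specs <- c(specs, lapply(seq(10, 90, 10), function(p)
      score_spec("focused", "percentile", percentile_p = p,
                 tile_size_um = percentile_tile_size_um,
                 min_steatotic_tiles = min_steatotic_tiles)))
  }
  specs
}

#' Run the full scoring pipeline over a set of images
#'
#' For each image: resample to the analysis resolution, segment, tile at
#' each requested size and persist the tile maps; then compute every score
#' and evaluate reliability/validity over the design. Per-image failures
#' are logged and the image skipped; an empty design or a design/image
#' mismatch is a hard error.
#'
#' @param image_paths character vector of PNG/TIFF paths, or a named list
#'   of \code{\link{section_raster}}s.
#' @param design data frame (\code{source_id, group_label, covariate}) or
#'   path to a design CSV. Source ids of file images are their base names
#'   without extension.
#' @param out_dir output directory for masks, tile maps, score and
#'   evaluation CSVs; NULL writes nothing.
#' @param resolution_nm_per_px resolution of file images (TIFF tags used
#'   as fallback); ignored for in-memory rasters.
#' @param analysis_resolution_nm analysis resolution to resample to.
#' @param config a \code{\link{segmentation_config}}.
#' @param tile_sizes_um tile sizes to compute.
#' @param specs score specs (default \code{\link{default_score_specs}}).
#' @param standard_mode,interpolation see \code{\link{compute_score}}.
#' @param order_groups_by_standard see \code{\link{evaluate_scores}}.
#' @return The evaluation table (see \code{\link{evaluate_scores}}), with
#'   the per-image score table as attribute \code{"scores"} and failed
#'   image ids as attribute \code{"failed"}.
#' @export
run_pipeline <- function(image_paths, design, out_dir = NULL,
                         resolution_nm_per_px = NULL,
                         analysis_resolution_nm = 454,
                         config = segmentation_config(),
                         tile_sizes_um = c(8, 16, 32, 64, 128),
                         specs = NULL,
                         standard_mode = "exact",
                         interpolation = "linear",
                         order_groups_by_standard = FALSE) {
  if (is.character(design)) design <- read_design(design)
  if (!is.data.frame(design) || !nrow(design)) stop_domain("empty design")
  if (is.null(specs))
    specs <- default_score_specs(tile_sizes_um = tile_sizes_um)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rasters <- if (is.list(image_paths)) image_paths else {
    ids <- tools::file_path_sans_ext(basename(image_paths))
    stats::setNames(as.list(image_paths), ids)
  }
  ids <- names(rasters)
  mismatch <- setdiff(design$source_id, ids)
  if (length(mismatch))
    stop_domain("design names images not supplied: ",
                paste(mismatch, collapse = ", "))

  maps <- list(); failed <- character()
  for (id in intersect(ids, design$source_id)) {
    res <- tryCatch({
      r <- rasters[[id]]
      if (is.character(r)) r <- read_section(r, resolution_nm_per_px)
      r <- resample_raster(r, analysis_resolution_nm)
      seg <- segment_section(r, config)
      mm <- lapply(tile_sizes_um, function(ts)
        compute_tile_map(seg$droplet, seg$tissue, r$resolution_nm_per_px,
                         ts, source_id = id))
      names(mm) <- as.character(tile_sizes_um)
      if (!is.null(out_dir)) {
        write_mask(seg$droplet, file.path(out_dir, paste0(id, "_droplet.png")))
        write_mask(seg$tissue, file.path(out_dir, paste0(id, "_tissue.png")))
        write_blob_table(seg$blobs, file.path(out_dir, paste0(id, "_blobs.csv")))
        for (ts in names(mm))
          write_tile_map(mm[[ts]],
                         file.path(out_dir, sprintf("%s_tiles_%sum.csv", id, ts)))
      }
      mm
    }, error = function(e) {
      message("image ", id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, id) else maps[[id]] <- res
  }
  design <- design[!design$source_id %in% failed, , drop = FALSE]
  if (!nrow(design)) stop_domain("all images failed")

  tab <- evaluate_scores(maps, design, specs,
                         standard_mode = standard_mode,
                         interpolation = interpolation,
                         order_groups_by_standard = order_groups_by_standard)
  if (!is.null(out_dir)) {
    write.csv(tab, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    write.csv(attr(tab, "scores"), file.path(out_dir, "scores.csv"),
              row.names = FALSE)
  }
  attr(tab, "failed") <- failed
  tab
}

#' Reliability of scores across tile sizes on one cohort
#'
#' Convenience wrapper: evaluates the standard score and mean-based
#' focused scores at each tile size on an analytic cohort and returns the
#' ICC per score.
#'
#' @param cohort result of \code{\link{generate_cohort}} with
#'   \code{tile_maps_only = TRUE}.
#' @param tile_sizes_um focused tile sizes (must be present in the maps).
#' @param min_steatotic_tiles definedness threshold.
#' @return Data frame with columns \code{score} (\code{"standard"} or the
#'   tile size), \code{tile_size_um} and \code{icc}.
#' @export
tile_size_reliability <- function(cohort,
                                  tile_sizes_um = c(8, 16, 32, 64, 128),
                                  min_steatotic_tiles = 100) {
  specs <- default_score_specs(tile_sizes_um = tile_sizes_um,
                               min_steatotic_tiles = min_steatotic_tiles)
  tab <- evaluate_scores(cohort$maps, cohort$design, specs)
  data.frame(
    score = c("standard", paste0("focused_", tile_sizes_um, "um")),
    tile_size_um = c(NA, tile_sizes_um),
    icc = tab$icc
  )
}
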