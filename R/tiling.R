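# Tile fraction maps: a regular grid of square tiles of a physical edge
# length, each carrying its tissue pixel count, droplet pixel count and
# steatosis area fraction. The grid is anchored at the image origin; pixel
# rectangles are half-open, row-major, 0-based; partial right/bottom tiles
# are retained with their true pixel counts so that total tissue and
# droplet areas are conserved exactly.

#' Tile edge length in pixels
#'
#' @param tile_size_um physical tile edge in micrometers.
#' @param resolution_nm_per_px pixel edge in nanometers.
#' @return Integer edge length, \code{round(tile_size_um * 1000 /
#'   resolution_nm_per_px)} clamped to at least 1.
#' @export
tile_edge_px <- function(tile_size_um, resolution_nm_per_px) {
  if (!is_scalar_num(tile_size_um) || tile_size_um <= 0)
    stop_domain("tile_size_um must be positive")
  if (!is_scalar_num(resolution_nm_per_px) || resolution_nm_per_px <= 0)
    stop_domain("resolution_nm_per_px must be positive")
  max(1L, as.integer(round(tile_size_um * 1000 / resolution_nm_per_px)))
}

# Internal constructor; tiles with tissue_px == 0 carry no information for
# any score statistic and are not stored (the grid shape records full
# coverage of the raster extent).
new_tile_fraction_map <- function(tiles, grid_shape, tile_size_um,
                                  resolution_nm_per_px, source_id) {
  stopifnot(all(c("row", "col", "tissue_px", "droplet_px") %in% names(tiles)))
  if (any(tiles$droplet_px > tiles$tissue_px))
    stop_domain("droplet_px exceeds tissue_px")
  if (any(tiles$tissue_px < 0) || any(tiles$droplet_px < 0))
    stop_domain("negative pixel counts")
  tiles <- tiles[tiles$tissue_px > 0, , drop = FALSE]
  tiles$fraction <- ifelse(tiles$tissue_px > 0,
                           tiles$droplet_px / tiles$tissue_px, NA_real_)
  rownames(tiles) <- NULL
  structure(
    list(tiles = tiles,
         grid_shape = as.integer(grid_shape),
         tile_size_um = tile_size_um,
         resolution_nm_per_px = resolution_nm_per_px,
         source_id = source_id),
    class = "tile_fraction_map"
  )
}

#' @export
print.tile_fraction_map <- function(x, ...) {
  cat(sprintf(
    "<tile_fraction_map '%s': %d x %d grid @ %g um, %d tissue tiles, %d steatotic>\n",
    x$source_id, x$grid_shape[1], x$grid_shape[2], x$tile_size_um,
    nrow(x$tiles), sum(x$tiles$droplet_px > 0)))
  invisible(x)
}

#' Compute the per-tile steatosis fraction map of a section
#'
#' Divides congruent droplet and tissue masks into square tiles of
#' \code{tile_size_um} and counts tissue and droplet pixels per tile; a
#' tile's steatosis area fraction is droplet count over tissue count,
#' undefined (and not stored) when the tile holds no tissue.
#'
#' @param droplet_mask,tissue_mask logical matrices of identical shape.
#' @param resolution_nm_per_px pixel edge in nanometers.
#' @param tile_size_um physical tile edge in micrometers.
#' @param source_id identifier recorded in the map.
#' @return A \code{tile_fraction_map}.
#' @export
compute_tile_map <- function(droplet_mask, tissue_mask, resolution_nm_per_px,
                             tile_size_um, source_id = "section") {
  if (!identical(dim(droplet_mask), dim(tissue_mask)))
    stop_domain("mask shape mismatch")
  edge <- tile_edge_px(tile_size_um, resolution_nm_per_px)
  nr <- nrow(tissue_mask); nc <- ncol(tissue_mask)
  rows <- ceiling(nr / edge); cols <- ceiling(nc / edge)
  tr <- (seq_len(nr) - 1L) %/% edge          # tile row per pixel row
  tc <- (seq_len(nc) - 1L) %/% edge
  idx <- outer(tr, tc, function(a, b) a + rows * b) + 1L  # column-major tile id
  nt <- rows * cols
  tissue <- tabulate(idx[tissue_mask], nbins = nt)
  droplet <- tabulate(idx[droplet_mask & tissue_mask], nbins = nt)
  tid <- seq_len(nt) - 1L
  tiles <- data.frame(row = tid %% rows, col = tid %/% rows,
                      tissue_px = tissue, droplet_px = droplet)
  new_tile_fraction_map(tiles, c(rows, cols), tile_size_um,
                        resolution_nm_per_px, source_id)
}

#' Write a tile fraction map as CSV
#'
#' One row per tile with tissue, columns \code{row,col,tissue_px,droplet_px};
#' fractions are never stored, only recomputed from the counts on read. A
#' leading comment line carries the grid metadata.
#'
#' @param map a \code{tile_fraction_map}.
#' @param path output path.
#' @export
write_tile_map <- function(map, path) {
  stopifnot(inherits(map, "tile_fraction_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# tile_size_um=%s, resolution_nm_per_px=%s, grid_rows=%d, grid_cols=%d, source_id=%s",
    format(map$tile_size_um), format(map$resolution_nm_per_px),
    map$grid_shape[1], map$grid_shape[2], map$source_id), con)
  writeLines("row,col,tissue_px,droplet_px", con)
  t <- map$tiles
  if (nrow(t)) {
    writeLines(sprintf("%d,%d,%d,%d", t$row, t$col, t$tissue_px, t$droplet_px),
               con)
  }
  invisible(path)
}

#' Read a tile fraction map from CSV
#'
#' Inverse of \code{\link{write_tile_map}}; malformed rows and rows with
#' \code{droplet_px > tissue_px} are rejected with the offending row named.
#'
#' @param path CSV path.
#' @return A \code{tile_fraction_map}.
#' @export
read_tile_map <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop_domain("tile map file lacks metadata comment line")
  meta <- lines[1]
  get_meta <- function(key) {
    m <- regmatches(meta, regexec(paste0(key, "=([^,]+)"), meta))[[1]]
    if (length(m) < 2) stop_domain("metadata key missing: ", key)
    trimws(m[2])
  }
  body <- lines[-1]
  if (!length(body) || trimws(body[1]) != "row,col,tissue_px,droplet_px")
    stop_domain("tile map file lacks expected header")
  rows <- body[-1]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows)) {
    parts <- strsplit(rows, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
      stop_domain("malformed tile map row ", bad[1], ": ", rows[bad[1]])
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 4,
                byrow = TRUE)
    if (anyNA(m)) {
      bad <- which(apply(m, 1, anyNA))[1]
      stop_domain("malformed tile map row ", bad, ": ", rows[bad])
    }
    over <- which(m[, 4] > m[, 3])
    if (length(over))
      stop_domain("droplet_px > tissue_px in tile map row ", over[1], ": ",
                  rows[over[1]])
    tiles <- data.frame(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
                        tissue_px = as.integer(m[, 3]),
                        droplet_px = as.integer(m[, 4]))
  } else {
    tiles <- data.frame(row = integer(), col = integer(),
                        tissue_px = integer(), droplet_px = integer())
  }
  new_tile_fraction_map(
    tiles,
    grid_shape = c(as.integer(get_meta("grid_rows")),
                   as.integer(get_meta("grid_cols"))),
    tile_size_um = as.numeric(get_meta("tile_size_um")),
    resolution_nm_per_px = as.numeric(get_meta("resolution_nm_per_px")),
    source_id = get_meta("source_id")
  )
}
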