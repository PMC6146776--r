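# Steatosis scores. The standard score is the steatosis area fraction of
# the entire section; focused scores are summary statistics (mean or a
# percentile) over the fractions of steatotic tiles only (fraction > 0),
# and are undefined below a minimum steatotic-tile count.

#' Specify a steatosis score
#'
#' @param flavor \code{"standard"} (whole-section area fraction) or
#'   \code{"focused"} (statistic over steatotic tiles only).
#' @param statistic \code{"mean"} or \code{"percentile"}; the standard
#'   score is always a mean.
#' @param percentile_p percentile in (0, 100), required when
#'   \code{statistic = "percentile"} (the conventional sweep uses
#'   10, 20, ..., 90).
#' @param tile_size_um tile edge used for focused scores; the standard
#'   score is tile-size invariant in its exact form.
#' @param min_steatotic_tiles minimum number of steatotic tiles for a
#'   focused score to be defined (default 100; below it the statistic is
#'   considered unsound and the score undefined).
#' @return A \code{score_spec}.
#' @export
score_spec <- function(flavor = c("focused", "standard"),
                       statistic = c("mean", "percentile"),
                       percentile_p = NULL,
                       tile_size_um = 32,
                       min_steatotic_tiles = 100) {
  flavor <- match.arg(flavor)
  statistic <- match.arg(statistic)
  if (flavor == "standard" && statistic != "mean")
    stop_domain("standard score is always mean-based")
  if (statistic == "percentile") {
    if (is.null(percentile_p) || !is_scalar_num(percentile_p) ||
        percentile_p <= 0 || percentile_p >= 100)
      stop_domain("percentile_p must lie in (0, 100)")
  } else {
    percentile_p <- NA_real_
  }
  if (!is_scalar_num(tile_size_um) || tile_size_um <= 0)
    stop_domain("tile_size_um must be positive")
  if (!is_scalar_num(min_steatotic_tiles) || min_steatotic_tiles < 1)
    stop_domain("min_steatotic_tiles must be a positive integer")
  structure(
    list(flavor = flavor, statistic = statistic,
         percentile_p = percentile_p, tile_size_um = tile_size_um,
         min_steatotic_tiles = as.integer(min_steatotic_tiles)),
    class = "score_spec"
  )
}

new_score_result <- function(value, spec, n_tiles_tissue, n_tiles_steatotic,
                             source_id) {
  structure(
    list(value = value, spec = spec,
         n_tiles_tissue = as.integer(n_tiles_tissue),
         n_tiles_steatotic = as.integer(n_tiles_steatotic),
         source_id = source_id),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  lab <- if (x$spec$flavor == "standard") "standard" else {
    if (x$spec$statistic == "mean")
      sprintf("focused mean @ %g um", x$spec$tile_size_um)
    else
      sprintf("focused p%g @ %g um", x$spec$percentile_p, x$spec$tile_size_um)
  }
  cat(sprintf("<score '%s' [%s]: %s (%d tissue tiles, %d steatotic)>\n",
              x$source_id, lab,
              if (is.na(x$value)) "undefined" else format(x$value, digits = 4),
              x$n_tiles_tissue, x$n_tiles_steatotic))
  invisible(x)
}

#' Standard score: whole-section steatosis area fraction
#'
#' In \code{"exact"} mode the tissue-area-weighted ratio of total droplet
#' to total tissue pixels, which equals the whole-section area fraction and
#' is exactly tile-size invariant. \code{"tile-mean"} mode instead averages
#' the per-tile fractions unweighted (conventionally on a small 8 um grid,
#' where the two agree closely).
#'
#' @param map a \code{tile_fraction_map}.
#' @param mode \code{"exact"} or \code{"tile-mean"}.
#' @param min_steatotic_tiles carried into the result spec for reporting.
#' @return A \code{score_result}; undefined when the map holds no tissue.
#' @export
standard_score <- function(map, mode = c("exact", "tile-mean"),
                           min_steatotic_tiles = 100) {
  stopifnot(inherits(map, "tile_fraction_map"))
  mode <- match.arg(mode)
  t <- map$tiles
  spec <- score_spec("standard", "mean", tile_size_um = map$tile_size_um,
                     min_steatotic_tiles = min_steatotic_tiles)
  n_tissue <- nrow(t)
  n_ste <- sum(t$droplet_px > 0)
  if (n_tissue == 0 || sum(t$tissue_px) == 0)
    return(new_score_result(NA_real_, spec, n_tissue, n_ste, map$source_id))
  value <- switch(mode,
    "exact" = sum(t$droplet_px) / sum(t$tissue_px),
    "tile-mean" = mean(t$fraction)
  )
  new_score_result(value, spec, n_tissue, n_ste, map$source_id)
}

#' Fractions of the steatotic tiles of a map
#'
#' Steatotic tiles contain tissue and have a steatosis area fraction
#' greater than zero; multiplicity is preserved and order is not
#' meaningful.
#'
#' @param map a \code{tile_fraction_map}.
#' @return Numeric vector of fractions in (0, 1\].
#' @export
steatotic_tiles <- function(map) {
  stopifnot(inherits(map, "tile_fraction_map"))
  t <- map$tiles
  t$fraction[t$tissue_px > 0 & t$droplet_px > 0]
}

#' Percentile of a set of values
#'
#' Default \code{"linear"} mode interpolates linearly between order
#' statistics: with values sorted ascending and \code{h = (n - 1) * p /
#' 100}, the result is \code{v[floor(h) + 1] + (h - floor(h)) *
#' (v[floor(h) + 2] - v[floor(h) + 1])} (the common type-7 quantile).
#' \code{"inverted_cdf"} returns the smallest order statistic at or above
#' the requested mass (type 1).
#'
#' @param values non-empty numeric vector.
#' @param p percentile in (0, 100).
#' @param interpolation \code{"linear"} or \code{"inverted_cdf"}.
#' @return Numeric scalar between \code{min(values)} and
#'   \code{max(values)}.
#' @export
percentile <- function(values, p, interpolation = c("linear", "inverted_cdf")) {
  interpolation <- match.arg(interpolation)
  if (!length(values)) stop_domain("percentile of empty set")
  if (!is_scalar_num(p) || p <= 0 || p >= 100)
    stop_domain("p must lie in (0, 100)")
  v <- sort(values)
  n <- length(v)
  if (interpolation == "linear") {
    h <- (n - 1) * p / 100
    lo <- floor(h)
    frac <- h - lo
    if (lo + 1 >= n) return(v[n])
    v[lo + 1] + frac * (v[lo + 2] - v[lo + 1])
  } else {
    v[max(1L, as.integer(ceiling(n * p / 100)))]
  }
}

#' Focused score: statistic over steatotic tiles
#'
#' Restricts the map to steatotic tiles (fraction > 0) and returns their
#' unweighted mean or a percentile. Undefined when fewer than
#' \code{spec$min_steatotic_tiles} steatotic tiles exist, so that the
#' statistic is never estimated from an unsound sample.
#'
#' @param map a \code{tile_fraction_map}.
#' @param spec a \code{score_spec} with \code{flavor = "focused"}.
#' @param interpolation percentile mode, see \code{\link{percentile}}.
#' @return A \code{score_result}.
#' @export
focused_score <- function(map, spec = score_spec("focused", "mean"),
                          interpolation = "linear") {
  stopifnot(inherits(map, "tile_fraction_map"), inherits(spec, "score_spec"))
  if (spec$flavor != "focused") stop_domain("spec$flavor must be 'focused'")
  s <- steatotic_tiles(map)
  n_tissue <- nrow(map$tiles)
  n_ste <- length(s)
  if (n_ste < spec$min_steatotic_tiles || n_tissue == 0)
    return(new_score_result(NA_real_, spec, n_tissue, n_ste, map$source_id))
  value <- if (spec$statistic == "mean") mean(s)
           else percentile(s, spec$percentile_p, interpolation)
  new_score_result(value, spec, n_tissue, n_ste, map$source_id)
}

#' Compute any score from its specification
#'
#' Dispatches to \code{\link{standard_score}} or
#' \code{\link{focused_score}}; the map's tile size must match the spec's
#' for focused scores.
#'
#' @param map a \code{tile_fraction_map}.
#' @param spec a \code{score_spec}.
#' @param standard_mode mode for standard scores, see
#'   \code{\link{standard_score}}.
#' @param interpolation percentile mode, see \code{\link{percentile}}.
#' @return A \code{score_result}.
#' @export
compute_score <- function(map, spec, standard_mode = "exact",
                          interpolation = "linear") {
  if (spec$flavor == "standard")
    standard_score(map, mode = standard_mode,
                   min_steatotic_tiles = spec$min_steatotic_tiles)
  else
    focused_score(map, spec, interpolation)
}

#' Serialize a score result as JSON
#'
#' @param result a \code{score_result}.
#' @return A JSON string with fields \code{source_id, flavor, statistic,
#'   percentile_p, tile_size_um, min_steatotic_tiles, n_tiles_tissue,
#'   n_tiles_steatotic, value} (\code{value} null when undefined).
#' @export
score_report_json <- function(result) {
  stopifnot(inherits(result, "score_result"))
  s <- result$spec
  obj <- list(
    source_id = result$source_id,
    flavor = s$flavor,
    statistic = s$statistic,
    percentile_p = if (is.na(s$percentile_p)) NULL else s$percentile_p,
    tile_size_um = s$tile_size_um,
    min_steatotic_tiles = s$min_steatotic_tiles,
    n_tiles_tissue = result$n_tiles_tissue,
    n_tiles_steatotic = result$n_tiles_steatotic,
    value = if (is.na(result$value)) NULL else result$value
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Collect score results into a data frame (batch CSV layout)
#'
#' @param results list of \code{score_result}s.
#' @return Data frame, one row per image x spec.
#' @export
score_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    s <- r$spec
    data.frame(source_id = r$source_id, flavor = s$flavor,
               statistic = s$statistic, percentile_p = s$percentile_p,
               tile_size_um = s$tile_size_um,
               min_steatotic_tiles = s$min_steatotic_tiles,
               n_tiles_tissue = r$n_tiles_tissue,
               n_tiles_steatotic = r$n_tiles_steatotic,
               value = r$value)
  }))
}
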