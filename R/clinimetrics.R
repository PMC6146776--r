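# Clinimetric evaluation of scores: reliability as the intraclass
# correlation coefficient estimated from one-way ANOVA variance
# components, and validity as Kendall's tau-b rank correlation against an
# ordered covariate (diet index, feeding weeks), with ties handled exactly.

#' Intraclass correlation from one-way ANOVA variance components
#'
#' The ICC is the ratio of the between-group variance to the total
#' (between plus within) variance. Components are estimated from the
#' one-way ANOVA mean squares: \code{var_within = MSW},
#' \code{var_between = max(0, (MSB - MSW) / n0)} with
#' \code{n0 = (N - sum(n_i^2) / N) / (k - 1)} the effective group size for
#' unbalanced designs. A negative between component is clamped to zero
#' (ICC = 0); zero within variance with distinct group means gives
#' ICC = 1 exactly.
#'
#' @param values numeric vector of score values (no undefined values; drop
#'   them before calling, see \code{\link{evaluate_scores}}).
#' @param groups factor or vector of group labels, same length as
#'   \code{values}; every group needs at least 2 values.
#' @return An \code{icc_result} list: \code{icc, var_between, var_within,
#'   ms_between, ms_within, n0, k, N}.
#' @export
icc_oneway <- function(values, groups) {
  if (length(values) != length(groups))
    stop_domain("values and groups differ in length")
  if (anyNA(values)) stop_domain("undefined values must be excluded first")
  g <- factor(groups)
  ni <- tabulate(g)
  k <- nlevels(g)
  if (k < 2) stop_domain("at least 2 groups required")
  if (any(ni < 2)) stop_domain("every group needs at least 2 values")
  N <- length(values)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  var_within <- msw
  var_between <- max(0, (msb - msw) / n0)
  icc <- if (var_between + var_within > 0) {
    var_between / (var_between + var_within)
  } else 0
  structure(
    list(icc = icc, var_between = var_between, var_within = var_within,
         ms_between = msb, ms_within = msw, n0 = n0, k = k, N = N),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc %.4f (between %.4g, within %.4g; k=%d, N=%d)>\n",
              x$icc, x$var_between, x$var_within, x$k, x$N))
  invisible(x)
}

#' Kendall's tau-b rank correlation with tie correction
#'
#' Exact pairwise enumeration: over all n(n-1)/2 pairs, concordant and
#' discordant counts, with tie corrections
#' \code{n1 = sum(t_i (t_i - 1) / 2)} over tied x-values and likewise
#' \code{n2} for y; \code{tau_b = (C - D) / sqrt((n0 - n1) (n0 - n2))}.
#' With repeated covariate values per group the x ties are handled
#' exactly.
#'
#' @param x,y numeric vectors of equal length at least 2.
#' @return A \code{tau_result} list: \code{tau_b} (NA when either variable
#'   is entirely tied), \code{concordant, discordant, ties_x, ties_y}.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2) stop_domain("x and y must have equal length >= 2")
  if (anyNA(x) || anyNA(y)) stop_domain("missing values not allowed")
  ut <- upper.tri(matrix(0, n, n))
  dx <- sign(outer(x, x, "-"))[ut]
  dy <- sign(outer(y, y, "-"))[ut]
  conc <- sum(dx * dy > 0)
  disc <- sum(dx * dy < 0)
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- if (denom > 0) (conc - disc) / denom else NA_real_
  structure(
    list(tau_b = tau, concordant = conc, discordant = disc,
         ties_x = as.integer(n1), ties_y = as.integer(n2)),
    class = "tau_result"
  )
}

#' @export
print.tau_result <- function(x, ...) {
  cat(sprintf("<tau_b %s (C=%d, D=%d)>\n",
              if (is.na(x$tau_b)) "undefined" else sprintf("%.4f", x$tau_b),
              x$concordant, x$discordant))
  invisible(x)
}

#' Evaluate score specifications over a grouped study design
#'
#' Computes every score spec on every image, excludes undefined scores
#' (with a logged count), and summarizes per spec: the one-way ANOVA ICC
#' over groups and, when a covariate ordering is supplied, Kendall's tau-b
#' between per-image covariates and scores. A spec leaving fewer than two
#' defined values in any group is flagged and its ICC omitted. When no
#' covariate is given and \code{order_groups_by_standard} is TRUE, groups
#' are ordered by their mean standard score (useful when no natural order
#' exists).
#'
#' @param maps nested list: \code{maps[[source_id]][[as.character(tile_size_um)]]}
#'   is the \code{tile_fraction_map} of that image at that tile size.
#' @param design data frame with columns \code{source_id, group_label} and
#'   optionally \code{covariate} (numeric, repeated within group; all-NA
#'   means no validity assessment).
#' @param specs list of \code{\link{score_spec}}s.
#' @param standard_mode,interpolation passed to \code{\link{compute_score}}.
#' @param order_groups_by_standard see above.
#' @return Data frame with one row per spec: \code{flavor, statistic,
#'   percentile_p, tile_size_um, icc, tau, n_undefined, flagged}; the
#'   per-image score table is attached as attribute \code{"scores"}.
#' @export
evaluate_scores <- function(maps, design, specs,
                            standard_mode = "exact",
                            interpolation = "linear",
                            order_groups_by_standard = FALSE) {
  stopifnot(is.data.frame(design),
            all(c("source_id", "group_label") %in% names(design)))
  if (!nrow(design)) stop_domain("empty design")
  if (anyDuplicated(design$source_id))
    stop_domain("images must be assigned to exactly one group")
  missing_imgs <- setdiff(design$source_id, names(maps))
  if (length(missing_imgs))
    stop_domain("no maps for images: ", paste(missing_imgs, collapse = ", "))
  has_cov <- "covariate" %in% names(design) && any(!is.na(design$covariate))

  all_scores <- list()
  rows <- lapply(seq_along(specs), function(si) {
    spec <- specs[[si]]
    vals <- vapply(design$source_id, function(id) {
      mm <- maps[[id]]
      key <- as.character(spec$tile_size_um)
      map <- if (key %in% names(mm)) mm[[key]] else mm[[1]]
      if (spec$flavor == "focused" && !(key %in% names(mm)))
        stop_domain("image ", id, " lacks a map at ", spec$tile_size_um, " um")
      r <- compute_score(map, spec, standard_mode, interpolation)
      all_scores[[length(all_scores) + 1L]] <<- r
      r$value
    }, numeric(1))
    defined <- !is.na(vals)
    n_undef <- sum(!defined)
    if (n_undef > 0)
      message(sprintf("spec %d (%s %s @ %g um): %d undefined score(s) excluded",
                      si, spec$flavor, spec$statistic, spec$tile_size_um,
                      n_undef))
    g <- factor(design$group_label[defined])
    ok_icc <- nlevels(droplevels(g)) >= 2 &&
      all(tabulate(droplevels(g)) >= 2)
    icc <- if (ok_icc) icc_oneway(vals[defined], droplevels(g))$icc else NA_real_
    tau <- NA_real_
    if (has_cov) {
      cov <- design$covariate[defined]
      ok <- !is.na(cov)
      if (sum(ok) >= 2) tau <- kendall_tau_b(cov[ok], vals[defined][ok])$tau_b
    }
    data.frame(flavor = spec$flavor, statistic = spec$statistic,
               percentile_p = spec$percentile_p,
               tile_size_um = if (spec$flavor == "standard") NA_real_
                              else spec$tile_size_um,
               icc = icc, tau = tau, n_undefined = n_undef,
               flagged = !ok_icc || n_undef > 0)
  })
  out <- do.call(rbind, rows)

  if (order_groups_by_standard && !has_cov) {
    # rank groups by mean standard score and use the rank as covariate
    std <- score_spec("standard", "mean",
                      tile_size_um = specs[[1]]$tile_size_um)
    sv <- vapply(design$source_id, function(id) {
      compute_score(maps[[id]][[1]], std, standard_mode)$value
    }, numeric(1))
    gm <- tapply(sv, design$group_label, mean, na.rm = TRUE)
    rank_of <- rank(gm)
    design$covariate <- rank_of[as.character(design$group_label)]
    out$tau <- vapply(seq_along(specs), function(si) {
      spec <- specs[[si]]
      vals <- vapply(design$source_id, function(id) {
        mm <- maps[[id]]
        key <- as.character(spec$tile_size_um)
        map <- if (key %in% names(mm)) mm[[key]] else mm[[1]]
        compute_score(map, spec, standard_mode, interpolation)$value
      }, numeric(1))
      defined <- !is.na(vals)
      if (sum(defined) >= 2)
        kendall_tau_b(design$covariate[defined], vals[defined])$tau_b
      else NA_real_
    }, numeric(1))
  }

  attr(out, "scores") <- score_table(all_scores)
  out
}

#' Read a study design CSV
#'
#' Expected columns: \code{source_id, group_label, covariate} (covariate
#' may be blank).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_design <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "group_label") %in% names(d)))
    stop_domain("design must have columns source_id, group_label")
  if (!nrow(d)) stop_domain("empty design")
  if (!"covariate" %in% names(d)) d$covariate <- NA_real_
  d$covariate <- suppressWarnings(as.numeric(d$covariate))
  d
}
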