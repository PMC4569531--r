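#' Stand basal area
#'
#' Total cross-sectional stem area at the point of measurement per hectare,
#' `sum(pi * (dbh/200)^2) / area_ha` with DBH in cm, in m2/ha. Live stems
#' only by default, matching the baseline stand tables; basal area is
#' additive over any partition of the stem list.
#'
#' @param stems data frame of stem records (needs `dbh_cm` and `alive`).
#' @param area_ha plot area in hectares; must be positive.
#' @param include_dead if `TRUE`, dead stems are included.
#' @return Basal area in m2/ha (0 for an empty stem list).
#' @export
#' @examples
#' basal_area(data.frame(dbh_cm = 20, alive = TRUE), area_ha = 1)  # ~0.0314
basal_area <- function(stems, area_ha, include_dead = FALSE) {
  if (!is.numeric(area_ha) || length(area_ha) != 1L || is.na(area_ha) ||
      area_ha <= 0) {
    stop("'area_ha' must be a single positive number", call. = FALSE)
  }
  st <- .admitted_stems(stems, include_dead)
  if (nrow(st) == 0L) return(0)
  if (any(is.na(st$dbh_cm) | st$dbh_cm <= 0)) {
    stop("all stems must have a positive dbh_cm", call. = FALSE)
  }
  sum(pi * (st$dbh_cm / 200)^2) / area_ha
}

#' Stocking density
#'
#' Number of live stems per hectare. Every stem of a multi-stemmed tree
#' counts individually (so this overestimates the number of individual
#' trees).
#'
#' @inheritParams basal_area
#' @return Stems per hectare.
#' @export
stocking_density <- function(stems, area_ha, include_dead = FALSE) {
  if (!is.numeric(area_ha) || length(area_ha) != 1L || is.na(area_ha) ||
      area_ha <= 0) {
    stop("'area_ha' must be a single positive number", call. = FALSE)
  }
  nrow(.admitted_stems(stems, include_dead)) / area_ha
}

#' Diameter distribution in fixed-width bins
#'
#' Bins admitted stems into diameter classes of `bin_width` cm starting at
#' `min_dbh` (10 cm by default). Bins are lower-closed, upper-open
#' (`[10, 20), [20, 30), ...`), so every stem falls in exactly one bin.
#' An optional canopy-position subset reproduces the dominant/co-dominant
#' overstorey cohort view.
#'
#' @param stems data frame of stem records.
#' @param bin_width bin width in cm (default 10).
#' @param subset optional character vector of canopy positions to keep
#'   (e.g. `c("dominant", "co-dominant")`); `NULL` keeps all.
#' @param min_dbh lower edge of the first bin, cm.
#' @param include_dead include dead stems if `TRUE`.
#' @return An object of class `diameter_distribution`: list with
#'   `bin_edges` (length `nbins + 1`), `counts`, `subset_label` and `n`.
#' @export
diameter_distribution <- function(stems, bin_width = 10, subset = NULL,
                                  min_dbh = 10, include_dead = FALSE) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("'bin_width' must be a single positive number", call. = FALSE)
  }
  st <- .admitted_stems(stems, include_dead)
  label <- "all"
  if (!is.null(subset)) {
    st <- st[st$canopy_position %in% subset, , drop = FALSE]
    label <- paste(subset, collapse = "+")
  }
  dbh <- st$dbh_cm[!is.na(st$dbh_cm) & st$dbh_cm >= min_dbh]
  if (length(dbh) == 0L) {
    out <- list(bin_edges = min_dbh, counts = integer(0),
                subset_label = label, n = 0L)
    class(out) <- "diameter_distribution"
    return(out)
  }
  nbins <- max(1L, as.integer(floor((max(dbh) - min_dbh) / bin_width)) + 1L)
  idx <- as.integer(floor((dbh - min_dbh) / bin_width)) + 1L
  counts <- tabulate(idx, nbins)
  out <- list(bin_edges = min_dbh + bin_width * (0:nbins),
              counts = counts, subset_label = label, n = length(dbh))
  class(out) <- "diameter_distribution"
  out
}

#' @export
print.diameter_distribution <- function(x, ...) {
  cat(sprintf("Diameter distribution (%s): %d stems\n", x$subset_label, x$n))
  if (length(x$counts)) {
    lab <- sprintf("[%g,%g)", x$bin_edges[-length(x$bin_edges)],
                   x$bin_edges[-1])
    print(stats::setNames(x$counts, lab))
  }
  invisible(x)
}

#' @export
plot.diameter_distribution <- function(x, xlab = "DBH class (cm)",
                                       ylab = "Stems", ...) {
  lab <- sprintf("%g-%g", x$bin_edges[-length(x$bin_edges)], x$bin_edges[-1])
  graphics::barplot(x$counts, names.arg = lab, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Fit a diameter-height curve
#'
#' Least-squares fit of the site-productivity model
#' `height = a + b * ln(DBH)` (natural logarithm; heights in m, DBH in
#' cm). Pairs with a missing height or diameter are dropped; at least
#' three complete pairs are required.
#'
#' @param dbh numeric vector of diameters, cm (all positive).
#' @param height numeric vector of measured heights, m.
#' @return Object of class `height_diameter_model`: list with `intercept`
#'   (a), `slope` (b), `n`, `residual_sd` and the underlying `lm` fit.
#' @export
#' @examples
#' d <- c(15, 30, 60, 90)
#' fit_height_diameter(d, 5 + 10 * log(d))
fit_height_diameter <- function(dbh, height) {
  if (length(dbh) != length(height)) {
    stop("'dbh' and 'height' must have the same length", call. = FALSE)
  }
  keep <- !is.na(dbh) & !is.na(height)
  dbh <- dbh[keep]; height <- height[keep]
  if (length(dbh) < 3L) {
    stop("insufficient data: at least 3 complete (dbh, height) pairs required",
         call. = FALSE)
  }
  if (any(dbh <= 0)) stop("all dbh values must be positive", call. = FALSE)
  fit <- stats::lm(height ~ log(dbh))
  out <- list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    n = length(dbh),
    residual_sd = sqrt(sum(stats::residuals(fit)^2) / (length(dbh) - 2)),
    fit = fit
  )
  class(out) <- "height_diameter_model"
  out
}

#' @export
print.height_diameter_model <- function(x, ...) {
  cat(sprintf("height = %.3f + %.3f * ln(DBH)   (n = %d, residual sd = %.3f m)\n",
              x$intercept, x$slope, x$n, x$residual_sd))
  invisible(x)
}

#' @export
predict.height_diameter_model <- function(object, dbh, ...) {
  stopifnot(is.numeric(dbh), all(dbh > 0, na.rm = TRUE))
  object$intercept + object$slope * log(dbh)
}

#' Height summaries for the baseline stand table
#'
#' Mean height of dominant and co-dominant eucalypts and maximum measured
#' height of eucalypts and non-eucalypts, using measured heights only
#' (heights are recorded for a subset of stems; nothing is imputed from a
#' fitted curve). Entries with no measured stems are `NA`.
#'
#' @param stems data frame of stem records.
#' @param species_table species-guild lookup with `species` and
#'   `is_eucalypt`.
#' @param include_dead include dead stems if `TRUE`.
#' @return Named list: `mean_height_dominant_eucalypt_m`,
#'   `max_height_eucalypt_m`, `max_height_non_eucalypt_m`.
#' @export
height_summary <- function(stems, species_table, include_dead = FALSE) {
  st <- .admitted_stems(stems, include_dead)
  st <- st[!is.na(st$height_m), , drop = FALSE]
  if (nrow(st) == 0L) {
    return(list(mean_height_dominant_eucalypt_m = NA_real_,
                max_height_eucalypt_m = NA_real_,
                max_height_non_eucalypt_m = NA_real_))
  }
  euc <- .is_eucalypt(st$species, species_table, "height_summary")
  dom <- st$canopy_position %in% c("dominant", "co-dominant")
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  max_or_na <- function(x) if (length(x)) max(x) else NA_real_
  list(
    mean_height_dominant_eucalypt_m = mean_or_na(st$height_m[euc & dom]),
    max_height_eucalypt_m = max_or_na(st$height_m[euc]),
    max_height_non_eucalypt_m = max_or_na(st$height_m[!euc])
  )
}

#' Per-plot stand-structure table
#'
#' One row per plot with the baseline structural attributes split into
#' eucalypt (including *Corymbia*) and non-eucalypt components: stocking
#' density, basal area, mean dominant/co-dominant eucalypt height and
#' maximum heights. Mirrors the layout of a network baseline table.
#'
#' @param census a `forest_census`.
#' @param include_dead include dead stems if `TRUE`.
#' @return Data frame, one row per plot.
#' @export
structure_table <- function(census, include_dead = FALSE) {
  stopifnot(inherits(census, "forest_census"))
  pl <- census$plots
  rows <- lapply(seq_len(nrow(pl)), function(i) {
    st <- census$stems[census$stems$plot_id == pl$plot_id[i], , drop = FALSE]
    euc <- if (nrow(st)) {
      .is_eucalypt(st$species, census$species, "structure_table")
    } else {
      logical(0)
    }
    hs <- height_summary(st, census$species, include_dead)
    data.frame(
      plot_id = pl$plot_id[i],
      region = pl$region[i],
      stems_ha_eucalypt = stocking_density(st[euc, , drop = FALSE],
                                           pl$area_ha[i], include_dead),
      stems_ha_non_eucalypt = stocking_density(st[!euc, , drop = FALSE],
                                               pl$area_ha[i], include_dead),
      basal_area_eucalypt_m2_ha = basal_area(st[euc, , drop = FALSE],
                                             pl$area_ha[i], include_dead),
      basal_area_non_eucalypt_m2_ha = basal_area(st[!euc, , drop = FALSE],
                                                 pl$area_ha[i], include_dead),
      mean_height_dominant_eucalypt_m = hs$mean_height_dominant_eucalypt_m,
      max_height_eucalypt_m = hs$max_height_eucalypt_m,
      max_height_non_eucalypt_m = hs$max_height_non_eucalypt_m,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regional stand-structure summary
#'
#' Aggregates [structure_table()] by region: the mean and range of each
#' per-plot quantity. Mean dominant eucalypt height is reported both as
#' the mean of per-plot means (`height_dom_euc_plot_mean_m`) and pooled
#' over all measured dominant stems in the region
#' (`height_dom_euc_pooled_m`), since the two conventions differ.
#'
#' @inheritParams structure_table
#' @return Data frame, one row per region.
#' @export
region_structure_table <- function(census, include_dead = FALSE) {
  per_plot <- structure_table(census, include_dead)
  regions <- unique(per_plot$region)
  rows <- lapply(regions, function(r) {
    pp <- per_plot[per_plot$region == r, , drop = FALSE]
    plot_ids <- pp$plot_id
    st <- .admitted_stems(
      census$stems[census$stems$plot_id %in% plot_ids, , drop = FALSE],
      include_dead)
    st <- st[!is.na(st$height_m), , drop = FALSE]
    euc <- if (nrow(st)) {
      .is_eucalypt(st$species, census$species, "region_structure_table")
    } else {
      logical(0)
    }
    dom <- st$canopy_position %in% c("dominant", "co-dominant")
    pooled <- if (any(euc & dom)) mean(st$height_m[euc & dom]) else NA_real_
    data.frame(
      region = r,
      n_plots = nrow(pp),
      stems_ha_eucalypt = mean(pp$stems_ha_eucalypt),
      stems_ha_non_eucalypt = mean(pp$stems_ha_non_eucalypt),
      basal_area_eucalypt_m2_ha = mean(pp$basal_area_eucalypt_m2_ha),
      basal_area_non_eucalypt_m2_ha = mean(pp$basal_area_non_eucalypt_m2_ha),
      height_dom_euc_plot_mean_m = mean(pp$mean_height_dominant_eucalypt_m,
                                        na.rm = TRUE),
      height_dom_euc_pooled_m = pooled,
      max_height_eucalypt_m = suppressWarnings(
        max(pp$max_height_eucalypt_m, na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
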