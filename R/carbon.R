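#' Define an allometric biomass model
#'
#' A generic diameter-based allometric equation of the ln-ln form
#' `ln(AGB kg) = alpha + beta * ln(DBH cm)`, evaluated with an optional
#' multiplicative back-transform correction factor:
#' `AGB = correction_factor * exp(alpha) * DBH^beta`. One model is bound
#' to each guild scope (eucalypt or non-eucalypt); coefficients are
#' supplied by the user or loaded from a config file with
#' [read_allometry()].
#'
#' @param label free-text model name.
#' @param scope `"eucalypt"` or `"non_eucalypt"` (eucalypt covers
#'   *Eucalyptus* and *Corymbia*).
#' @param alpha intercept on the ln scale.
#' @param beta slope on the ln scale; must be positive so biomass
#'   increases with diameter.
#' @param correction_factor positive multiplier applied on the
#'   back-transform (1 = none).
#' @param source citation or provenance string.
#' @return Object of class `allometry_model`.
#' @export
allometry_model <- function(label, scope = c("eucalypt", "non_eucalypt"),
                            alpha, beta, correction_factor = 1,
                            source = "") {
  scope <- match.arg(scope)
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(correction_factor), length(correction_factor) == 1L)
  if (beta <= 0) stop("'beta' must be positive", call. = FALSE)
  if (correction_factor <= 0) {
    stop("'correction_factor' must be positive", call. = FALSE)
  }
  structure(list(label = label, scope = scope, alpha = alpha, beta = beta,
                 correction_factor = correction_factor, source = source),
            class = "allometry_model")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf("Allometry '%s' (%s): ln(AGB) = %.4g + %.4g * ln(DBH), cf = %.4g\n",
              x$label, x$scope, x$alpha, x$beta, x$correction_factor))
  if (nzchar(x$source)) cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

#' Load allometry models from a JSON config
#'
#' Reads a JSON array of allometry entries (`label`, `scope`, `alpha`,
#' `beta`, `correction_factor`, `source`) and returns a list of
#' [allometry_model()] objects named by scope, ready for [plot_agc()].
#' The package ships `inst/extdata/allometry_synthetic.json`, a
#' clearly-labelled synthetic coefficient set used by the test suite; it
#' is not an authoritative published calibration.
#'
#' @param path path to the JSON file.
#' @return Named list of `allometry_model` objects (names are scopes).
#' @export
#' @examples
#' cfg <- system.file("extdata", "allometry_synthetic.json",
#'                    package = "tallstand")
#' read_allometry(cfg)
read_allometry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  models <- lapply(seq_len(nrow(raw)), function(i) {
    allometry_model(
      label = raw$label[i], scope = raw$scope[i], alpha = raw$alpha[i],
      beta = raw$beta[i],
      correction_factor = if ("correction_factor" %in% names(raw)) {
        raw$correction_factor[i]
      } else 1,
      source = if ("source" %in% names(raw)) raw$source[i] else ""
    )
  })
  stats::setNames(models, vapply(models, `[[`, "", "scope"))
}

#' Tree-level aboveground biomass
#'
#' Evaluates an allometric model for one or more diameters:
#' `AGB = correction_factor * exp(alpha + beta * ln(DBH))` in kg.
#' Strictly increasing in DBH whenever `beta > 0`.
#'
#' @param dbh diameter(s) at the point of measurement, cm; all positive.
#' @param model an [allometry_model()].
#' @return Biomass in kg, same length as `dbh`.
#' @export
tree_agb <- function(dbh, model) {
  stopifnot(inherits(model, "allometry_model"))
  if (!is.numeric(dbh) || any(is.na(dbh)) || any(dbh <= 0)) {
    stop("'dbh' must be positive", call. = FALSE)
  }
  model$correction_factor * exp(model$alpha + model$beta * log(dbh))
}

.resolve_allometries <- function(allometries) {
  if (is.character(allometries) && length(allometries) == 1L) {
    allometries <- read_allometry(allometries)
  }
  for (scope in c("eucalypt", "non_eucalypt")) {
    m <- allometries[[scope]]
    if (is.null(m) || !inherits(m, "allometry_model")) {
      stop(sprintf("no allometry model configured for scope '%s'", scope),
           call. = FALSE)
    }
  }
  allometries
}

#' Plot-level live aboveground carbon
#'
#' Computes, for each plot, live aboveground biomass by guild scope (all
#' live stems evaluated with the eucalypt or non-eucalypt allometry
#' according to the species lookup, summed in kg and converted to t/ha)
#' and live aboveground carbon `AGC = carbon_fraction * AGB` in tC/ha.
#' Dead stems contribute nothing. Plots flagged `agc_excluded` (e.g.
#' where prominent buttressing inflates diameter-based estimates) are
#' reported with missing carbon fields and never contribute to network
#' statistics.
#'
#' @param census a `forest_census`.
#' @param allometries named list with `eucalypt` and `non_eucalypt`
#'   [allometry_model()]s, or the path to a JSON config for
#'   [read_allometry()].
#' @param carbon_fraction carbon content of dry biomass (default 0.50).
#' @return Data frame of class `carbon_summary`, one row per plot:
#'   `plot_id`, `area_ha`, `agb_eucalypt_t_ha`, `agb_non_eucalypt_t_ha`,
#'   `agc_tc_ha`, `excluded`.
#' @export
plot_agc <- function(census, allometries, carbon_fraction = 0.5) {
  stopifnot(inherits(census, "forest_census"))
  allometries <- .resolve_allometries(allometries)
  stopifnot(is.numeric(carbon_fraction), length(carbon_fraction) == 1L,
            carbon_fraction > 0)
  st <- .admitted_stems(census$stems)
  euc <- if (nrow(st)) .is_eucalypt(st$species, census$species, "plot_agc") else logical(0)
  agb_kg <- numeric(nrow(st))
  if (any(euc))  agb_kg[euc]  <- tree_agb(st$dbh_cm[euc],  allometries$eucalypt)
  if (any(!euc)) agb_kg[!euc] <- tree_agb(st$dbh_cm[!euc], allometries$non_eucalypt)

  pl <- census$plots
  rows <- lapply(seq_len(nrow(pl)), function(i) {
    if (isTRUE(pl$agc_excluded[i])) {
      return(data.frame(plot_id = pl$plot_id[i], area_ha = pl$area_ha[i],
                        agb_eucalypt_t_ha = NA_real_,
                        agb_non_eucalypt_t_ha = NA_real_,
                        agc_tc_ha = NA_real_, excluded = TRUE,
                        stringsAsFactors = FALSE))
    }
    in_p <- st$plot_id == pl$plot_id[i]
    agb_e <- sum(agb_kg[in_p & euc]) / 1000 / pl$area_ha[i]
    agb_n <- sum(agb_kg[in_p & !euc]) / 1000 / pl$area_ha[i]
    data.frame(plot_id = pl$plot_id[i], area_ha = pl$area_ha[i],
               agb_eucalypt_t_ha = agb_e, agb_non_eucalypt_t_ha = agb_n,
               agc_tc_ha = carbon_fraction * (agb_e + agb_n),
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("carbon_summary", "data.frame")
  out
}

# Normalize a diameter-class specification to a breaks vector. Accepts
# ascending breaks (last may be Inf) or a two-column matrix of
# [lower, upper) intervals, which must tile without gaps or overlaps.
.class_breaks <- function(classes) {
  if (is.matrix(classes)) {
    if (ncol(classes) != 2L) {
      stop("'classes' matrix must have two columns (lower, upper)",
           call. = FALSE)
    }
    cl <- classes[order(classes[, 1]), , drop = FALSE]
    if (any(cl[, 2] <= cl[, 1])) {
      stop("each diameter class must have upper > lower", call. = FALSE)
    }
    if (nrow(cl) > 1L && any(abs(cl[-nrow(cl), 2] - cl[-1, 1]) > 1e-9)) {
      stop("diameter classes overlap or leave gaps: they must partition the diameter range",
           call. = FALSE)
    }
    breaks <- c(cl[, 1], cl[nrow(cl), 2])
  } else {
    breaks <- as.numeric(classes)
  }
  if (length(breaks) < 2L || is.unsorted(breaks, strictly = TRUE)) {
    stop("'classes' must define strictly increasing diameter breaks",
         call. = FALSE)
  }
  breaks
}

#' Carbon partitioned by diameter class
#'
#' Splits live aboveground carbon across diameter classes (default
#' `[10,50), [50,100), [100,150), [150,Inf)` cm, lower-closed) and reports
#' both the per-hectare carbon in each class and its percentage share,
#' which sums to 100. By default only eucalypt stems are partitioned,
#' matching the overstorey carbon-distribution view; `guild` widens the
#' scope. Plots flagged `agc_excluded` are left out entirely.
#'
#' @inheritParams plot_agc
#' @param classes ascending break points in cm (last may be `Inf`), or a
#'   two-column matrix of `[lower, upper)` intervals that must partition
#'   the range without overlap.
#' @param guild which stems to partition: `"eucalypt"` (default),
#'   `"non_eucalypt"` or `"all"`.
#' @return Data frame with columns `class`, `agc_tc_ha` (per hectare of
#'   included plot area) and `share_pct`.
#' @export
agc_by_diameter_class <- function(census, allometries,
                                  classes = c(10, 50, 100, 150, Inf),
                                  carbon_fraction = 0.5,
                                  guild = c("eucalypt", "non_eucalypt", "all")) {
  stopifnot(inherits(census, "forest_census"))
  guild <- match.arg(guild)
  allometries <- .resolve_allometries(allometries)
  breaks <- .class_breaks(classes)
  if (breaks[1] > 10) {
    stop("diameter classes must cover every admitted stem: the first class starts above the 10 cm admission threshold",
         call. = FALSE)
  }

  keep_plots <- census$plots$plot_id[!isTRUE_v(census$plots$agc_excluded)]
  area <- sum(census$plots$area_ha[census$plots$plot_id %in% keep_plots])
  st <- .admitted_stems(census$stems)
  st <- st[st$plot_id %in% keep_plots, , drop = FALSE]
  euc <- if (nrow(st)) {
    .is_eucalypt(st$species, census$species, "agc_by_diameter_class")
  } else {
    logical(0)
  }
  st$agb_kg <- numeric(nrow(st))
  if (any(euc))  st$agb_kg[euc]  <- tree_agb(st$dbh_cm[euc],  allometries$eucalypt)
  if (any(!euc)) st$agb_kg[!euc] <- tree_agb(st$dbh_cm[!euc], allometries$non_eucalypt)
  st <- switch(guild,
    eucalypt = st[euc, , drop = FALSE],
    non_eucalypt = st[!euc, , drop = FALSE],
    all = st)

  if (nrow(st) && (any(st$dbh_cm < breaks[1]) ||
                   any(st$dbh_cm >= breaks[length(breaks)]))) {
    stop("diameter classes do not cover all admitted stems", call. = FALSE)
  }
  idx <- findInterval(st$dbh_cm, breaks)  # lower-closed, upper-open
  agc <- vapply(seq_len(length(breaks) - 1L), function(i) {
    carbon_fraction * sum(st$agb_kg[idx == i]) / 1000 / area
  }, numeric(1))
  total <- sum(agc)
  labels <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  data.frame(
    class = labels,
    agc_tc_ha = agc,
    share_pct = if (total > 0) 100 * agc / total else rep(NA_real_, length(agc)),
    stringsAsFactors = FALSE
  )
}

# Vectorized isTRUE: NA-safe logical test.
isTRUE_v <- function(x) !is.na(x) & x
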