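#' Precipitation-to-evaporation ratio
#'
#' `P:E = MAP / pan evaporation`, a dimensionless index of water
#' availability. Vectorized over plots.
#'
#' @param map_mm mean annual precipitation, mm/yr.
#' @param pan_evap_mm pan evaporation, mm/yr; must be positive.
#' @return P:E ratio(s).
#' @export
pe_ratio <- function(map_mm, pan_evap_mm) {
  if (!is.numeric(map_mm) || !is.numeric(pan_evap_mm)) {
    stop("'map_mm' and 'pan_evap_mm' must be numeric", call. = FALSE)
  }
  if (any(is.na(pan_evap_mm)) || any(pan_evap_mm <= 0)) {
    stop("'pan_evap_mm' must be positive", call. = FALSE)
  }
  map_mm / pan_evap_mm
}

#' Compare carbon-climate linear models by AIC
#'
#' Fits an ordinary least-squares model of plot aboveground carbon on each
#' candidate set of climate predictors (drawn from MAT, MAP and P:E,
#' always with an intercept) and ranks the candidates by the Akaike
#' Information Criterion — lower is better. AIC uses the full Gaussian
#' log-likelihood including constants, with parameter count
#' `k = predictors + intercept + variance`, the convention of mainstream
#' statistical environments, so Delta-AIC values are comparable across
#' software. Candidates within Delta-AIC < 2 of the best are flagged as
#' having equivalent support; exact ties list the simpler model first.
#' A numerically perfect fit (residual sum of squares at machine-noise
#' level) has a degenerate Gaussian likelihood and is reported with
#' `aic = -Inf`; among perfect fits the one with fewest parameters ranks
#' first.
#'
#' Plots excluded from carbon accounting must be removed before calling
#' (rows with missing `agc` are dropped).
#'
#' @param data data frame with column `agc` (tC/ha) and one column per
#'   predictor used (`mat`, `map`, `pe`).
#' @param candidates list of character vectors of predictor names; use
#'   `character(0)` for the intercept-only null model. Default compares
#'   null, MAT, MAP and P:E.
#' @return Object of class `climate_model_set`: list with `summary` (data
#'   frame `model`, `k`, `n`, `rss`, `r2`, `aic`, `delta_aic`,
#'   `equivalent_support`, sorted by AIC) and `fits` (named list of `lm`
#'   objects).
#' @export
fit_agc_climate <- function(data,
                            candidates = list(character(0), "mat", "map", "pe")) {
  stopifnot(is.data.frame(data), "agc" %in% names(data))
  data <- data[!is.na(data$agc), , drop = FALSE]
  used <- unique(unlist(candidates))
  missing <- setdiff(used, names(data))
  if (length(missing)) {
    stop(sprintf("predictor column(s) not in data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(data)
  rows <- list()
  fits <- list()
  for (cand in candidates) {
    label <- if (length(cand)) paste(cand, collapse = "+") else "null"
    p <- length(cand)
    if (n < p + 3L) {
      stop(sprintf("model '%s' needs at least %d observations, got %d",
                   label, p + 3L, n), call. = FALSE)
    }
    fml <- if (p) {
      stats::reformulate(cand, response = "agc")
    } else {
      agc ~ 1
    }
    X <- stats::model.matrix(fml, data)
    if (qr(X)$rank < ncol(X)) {
      stop(sprintf("singular design for model '%s': predictors %s are collinear",
                   label, paste(cand, collapse = ", ")), call. = FALSE)
    }
    fit <- stats::lm(fml, data = data)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((data$agc - mean(data$agc))^2)
    # a numerically perfect fit has a degenerate Gaussian likelihood;
    # report AIC = -Inf and let the parameter count break the tie, so
    # the simplest perfectly-fitting model ranks first
    perfect <- rss <= n * (1e-10 * (max(abs(data$agc)) + 1))^2
    rows[[label]] <- data.frame(
      model = label, k = p + 2L, n = n, rss = rss,
      r2 = if (tss > 0) 1 - rss / tss else 0,
      aic = if (perfect) -Inf else stats::AIC(fit),
      stringsAsFactors = FALSE
    )
    fits[[label]] <- fit
  }
  summ <- do.call(rbind, rows)
  summ <- summ[order(summ$aic, summ$k, summ$model), , drop = FALSE]
  summ$delta_aic <- summ$aic - summ$aic[1]
  summ$delta_aic[is.nan(summ$delta_aic)] <- 0
  summ$equivalent_support <- summ$delta_aic < 2
  rownames(summ) <- NULL
  structure(list(summary = summ, fits = fits), class = "climate_model_set")
}

#' @export
print.climate_model_set <- function(x, digits = 3, ...) {
  cat("Carbon-climate model comparison (ranked by AIC; lower is better)\n")
  s <- x$summary
  s$rss <- signif(s$rss, digits + 2)
  s$r2 <- round(s$r2, digits)
  s$aic <- round(s$aic, 1)
  s$delta_aic <- round(s$delta_aic, 1)
  print(s, ...)
  invisible(x)
}

#' Placement of plots within a climate envelope
#'
#' Tests whether query points lie inside the climate envelope of a
#' reference estate, defined as the convex hull of the reference cloud in
#' (MAT, MAP) space after standardizing each axis by the reference
#' standard deviation — the least-assumption envelope when no parametric
#' form is given. Points on the hull boundary count as inside. The
#' reported distance is 0 for inside points and otherwise the Euclidean
#' distance (in standardized climate units) from the query to the nearest
#' point of the hull boundary.
#'
#' @param reference data frame or matrix with columns `mat` and `map`
#'   (at least 3 non-collinear points).
#' @param query data frame or matrix of query points, same columns.
#' @return Data frame with `mat`, `map`, `inside` (logical) and
#'   `distance` (standardized units).
#' @export
climate_envelope <- function(reference, query) {
  ref <- .climate_xy(reference, "reference")
  qry <- .climate_xy(query, "query")
  if (nrow(ref) < 3L) {
    stop("degenerate envelope: reference needs at least 3 points",
         call. = FALSE)
  }
  ctr <- colMeans(ref)
  scl <- apply(ref, 2, stats::sd)
  if (any(scl == 0)) {
    stop("degenerate envelope: reference has zero variance on an axis",
         call. = FALSE)
  }
  rs <- sweep(sweep(ref, 2, ctr), 2, scl, "/")
  qs <- sweep(sweep(qry, 2, ctr), 2, scl, "/")
  hull <- grDevices::chull(rs)
  if (length(hull) < 3L) {
    stop("degenerate envelope: reference points are collinear", call. = FALSE)
  }
  hx <- rs[hull, 1]; hy <- rs[hull, 2]
  # signed area > 0 means counter-clockwise; orient consistently
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (abs(area2) < 1e-12) {
    stop("degenerate envelope: reference points are collinear", call. = FALSE)
  }
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }

  inside <- vapply(seq_len(nrow(qs)), function(i) {
    .in_convex_polygon(qs[i, 1], qs[i, 2], hx, hy)
  }, logical(1))
  dist <- vapply(seq_len(nrow(qs)), function(i) {
    if (inside[i]) 0 else .dist_to_polygon(qs[i, 1], qs[i, 2], hx, hy)
  }, numeric(1))
  data.frame(mat = qry[, 1], map = qry[, 2], inside = inside,
             distance = dist)
}

.climate_xy <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("mat", "map") %in% names(x))) {
      stop(sprintf("'%s' must have columns 'mat' and 'map'", what),
           call. = FALSE)
    }
    x <- cbind(mat = x$mat, map = x$map)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 2L) {
      stop(sprintf("'%s' must have two columns (mat, map)", what),
           call. = FALSE)
    }
    colnames(x) <- c("mat", "map")
  }
  storage.mode(x) <- "double"
  x
}

# Point inside (or on the boundary of) a counter-clockwise convex polygon:
# cross product with every edge must be non-negative.
.in_convex_polygon <- function(px, py, hx, hy, tol = 1e-9) {
  nv <- length(hx)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    if (cross < -tol) return(FALSE)
  }
  TRUE
}

.dist_to_polygon <- function(px, py, hx, hy) {
  nv <- length(hx)
  dmin <- Inf
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) ((px - hx[i]) * ex + (py - hy[i]) * ey) / len2 else 0
    t <- min(1, max(0, t))
    dx <- px - (hx[i] + t * ex); dy <- py - (hy[i] + t * ey)
    dmin <- min(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Classify a predicted stand height into productivity classes
#'
#' Assigns predicted dominant-tree heights to stand-height classes
#' (default 25-35 m, 35-45 m, >45 m) using lower-closed, upper-open
#' intervals, so a height exactly on a break belongs to the upper class.
#' Heights below the first break are labelled `"below-range"`. The
#' predicted heights come from a user-supplied height-climate model; none
#' is hard-coded here.
#'
#' @param height predicted height(s), m; must be positive.
#' @param breaks ascending class breaks in m (default `c(25, 35, 45)`).
#' @return Character vector of class labels, e.g. `"35-45 m"` or
#'   `">45 m"`.
#' @export
#' @examples
#' classify_height_class(c(20, 35, 46))
classify_height_class <- function(height, breaks = c(25, 35, 45)) {
  if (!is.numeric(height) || any(is.na(height)) || any(height <= 0)) {
    stop("'height' must be positive", call. = FALSE)
  }
  if (length(breaks) < 1L || is.unsorted(breaks, strictly = TRUE)) {
    stop("'breaks' must be strictly increasing", call. = FALSE)
  }
  nb <- length(breaks)
  labels <- c("below-range",
              if (nb > 1L) sprintf("%g-%g m", breaks[-nb], breaks[-1]),
              sprintf(">%g m", breaks[nb]))
  labels[findInterval(height, breaks) + 1L]
}
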