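#' Build an importance table from known components
#'
#' Low-level constructor: takes relative frequency, relative density and
#' relative dominance (each a percentage in \[0, 100\]) and forms the
#' importance value `IV = Frq + RDe + RDo` row-wise, sorting by IV
#' descending with alphabetical tie-break. Used both internally by
#' [importance_values()] and directly when the components are already
#' known (e.g. re-deriving IVs from a published table).
#'
#' @param taxon character vector of taxon (or guild) labels.
#' @param frq,rde,rdo numeric vectors of relative frequency, relative
#'   density and relative dominance, percentages.
#' @param guild optional character vector of guild labels per taxon.
#' @param occupancy_pct optional raw plot-occupancy percentage (share of
#'   plots in which the taxon occurs, not normalized across taxa).
#' @return Data frame of class `importance_table` with columns `taxon`,
#'   (`guild`,) `frq`, `rde`, `rdo`, `iv` (and `occupancy_pct` when
#'   given), sorted by `iv` descending.
#' @export
#' @examples
#' importance_table("Eucalyptus diversicolor", 25.7, 38.1, 61.8)
importance_table <- function(taxon, frq, rde, rdo, guild = NULL,
                             occupancy_pct = NULL) {
  n <- length(taxon)
  stopifnot(length(frq) == n, length(rde) == n, length(rdo) == n)
  if (any(c(frq, rde, rdo) < -1e-9 | c(frq, rde, rdo) > 100 + 1e-9,
          na.rm = TRUE)) {
    stop("frq, rde and rdo must be percentages in [0, 100]", call. = FALSE)
  }
  out <- data.frame(taxon = as.character(taxon), stringsAsFactors = FALSE)
  if (!is.null(guild)) out$guild <- as.character(guild)
  out$frq <- as.numeric(frq)
  out$rde <- as.numeric(rde)
  out$rdo <- as.numeric(rdo)
  out$iv <- out$frq + out$rde + out$rdo
  if (!is.null(occupancy_pct)) out$occupancy_pct <- as.numeric(occupancy_pct)
  out <- out[order(-out$iv, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, digits = 1, ...) {
  cat(sprintf("Importance values (%d taxa; IV = Frq + RDe + RDo, 0-300)\n",
              nrow(x)))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, ...)
  invisible(x)
}

#' Importance values of species or guilds
#'
#' Ranks the taxa of a forest community by the importance value: the sum
#' of relative frequency, relative density and relative dominance, each
#' expressed as a percentage so the three columns each total 100 and IV
#' totals 300 across taxa.
#'
#' For taxon i over the selected plots:
#' \itemize{
#'   \item relative density `RDe_i = 100 * n_i / sum(n)` (stem share);
#'   \item relative dominance `RDo_i = 100 * BA_i / sum(BA)` (basal-area
#'     share);
#'   \item relative frequency `Frq_i = 100 * f_i / sum(f)`, where `f_i` is
#'     the number of selected plots containing taxon i, normalized across
#'     taxa so that frequencies total 100.
#' }
#' The raw plot-occupancy percentage `100 * f_i / n_plots` is reported
#' separately as `occupancy_pct`; it is not part of IV because it does not
#' sum to 100 across taxa.
#'
#' At `level = "guild"` each guild (eucalypt, wet sclerophyll, rainforest)
#' is treated as one aggregated taxon, with frequency, stem share and
#' basal-area share normalized across the guilds present.
#'
#' @param census a `forest_census`.
#' @param plot_ids optional character vector restricting the calculation
#'   to a subset of plots (e.g. one region); `NULL` uses all plots.
#' @param level `"species"` or `"guild"`.
#' @param include_dead include dead stems if `TRUE` (live stems only by
#'   default, consistent with the baseline tables).
#' @param method `"pooled"` (default) pools stems across the selected
#'   plots; `"plot_mean"` computes per-plot stem and basal-area shares and
#'   averages them across plots (frequency is unaffected).
#' @return An [importance_table()] sorted by IV descending.
#' @export
importance_values <- function(census, plot_ids = NULL,
                              level = c("species", "guild"),
                              include_dead = FALSE,
                              method = c("pooled", "plot_mean")) {
  stopifnot(inherits(census, "forest_census"))
  level <- match.arg(level)
  method <- match.arg(method)
  if (is.null(plot_ids)) plot_ids <- census$plots$plot_id
  if (length(plot_ids) == 0L) {
    stop("empty plot subset: at least one plot is required", call. = FALSE)
  }
  st <- .admitted_stems(census$stems, include_dead)
  st <- st[st$plot_id %in% plot_ids, , drop = FALSE]
  if (nrow(st) == 0L) {
    stop("no admitted stems in the selected plots", call. = FALSE)
  }

  sp_idx <- match(st$species, census$species$species)
  if (anyNA(sp_idx)) {
    stop(sprintf("species without a guild classification: %s",
                 paste(sort(unique(st$species[is.na(sp_idx)])), collapse = ", ")),
         call. = FALSE)
  }
  guild_of <- census$species$guild[sp_idx]
  taxon <- if (level == "species") st$species else guild_of
  ba <- pi * (st$dbh_cm / 200)^2

  taxa <- sort(unique(taxon))
  f <- vapply(taxa, function(t) {
    length(unique(st$plot_id[taxon == t]))
  }, integer(1))
  frq <- 100 * f / sum(f)
  occupancy <- 100 * f / length(unique(plot_ids))

  if (method == "pooled") {
    n_i <- vapply(taxa, function(t) sum(taxon == t), numeric(1))
    ba_i <- vapply(taxa, function(t) sum(ba[taxon == t]), numeric(1))
    rde <- 100 * n_i / sum(n_i)
    rdo <- 100 * ba_i / sum(ba_i)
  } else {
    plots_here <- unique(st$plot_id)
    rde_m <- matrix(0, length(taxa), length(plots_here),
                    dimnames = list(taxa, plots_here))
    rdo_m <- rde_m
    for (p in plots_here) {
      in_p <- st$plot_id == p
      n_p <- vapply(taxa, function(t) sum(in_p & taxon == t), numeric(1))
      ba_p <- vapply(taxa, function(t) sum(ba[in_p & taxon == t]), numeric(1))
      rde_m[, p] <- 100 * n_p / sum(n_p)
      rdo_m[, p] <- 100 * ba_p / sum(ba_p)
    }
    rde <- rowMeans(rde_m)
    rdo <- rowMeans(rdo_m)
  }

  gl <- if (level == "species") {
    census$species$guild[match(taxa, census$species$species)]
  } else {
    NULL
  }
  importance_table(taxa, frq, rde, rdo, guild = gl,
                   occupancy_pct = occupancy)
}

#' Top-ranked taxa of an importance table
#'
#' First `k` rows by importance value, descending, with ties broken
#' alphabetically by taxon. Asking for more rows than exist returns the
#' whole table.
#'
#' @param table an [importance_table()].
#' @param k number of rows to keep (>= 1).
#' @return The top-`k` rows, still an `importance_table`.
#' @export
rank_species <- function(table, k) {
  stopifnot(inherits(table, "importance_table"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  ord <- order(-table$iv, table$taxon)
  out <- table[ord[seq_len(min(as.integer(k), nrow(table)))], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Species richness by guild
#'
#' Counts the distinct species recorded in the census (live or dead) in
#' each community guild — eucalypt (Euc), wet sclerophyll (Scl) and
#' rainforest (RF) — plus the overall total. Every censused species must
#' be classified in the species-guild lookup.
#'
#' @param census a `forest_census`.
#' @return List with `by_guild` (named integer vector over Euc, Scl, RF)
#'   and `total`.
#' @export
guild_richness <- function(census) {
  stopifnot(inherits(census, "forest_census"))
  st <- census$stems
  idx <- match(st$species, census$species$species)
  bad <- is.na(idx) | is.na(census$species$guild[idx])
  if (any(bad)) {
    stop(sprintf("unclassified species (no guild assignment): %s",
                 paste(sort(unique(st$species[bad])), collapse = ", ")),
         call. = FALSE)
  }
  sp <- unique(data.frame(species = st$species,
                          guild = census$species$guild[idx],
                          stringsAsFactors = FALSE))
  by_guild <- vapply(.guilds, function(g) sum(sp$guild == g), integer(1))
  list(by_guild = by_guild, total = sum(by_guild))
}
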