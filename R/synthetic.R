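# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derived sub-seed for a named stream, kept below 2^31.
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 97L + k * 7919) %% 2147483647)
}

#' Default regional design of the synthetic network
#'
#' Seven regions mirroring a continental tall-forest network: plot counts,
#' census years, and regional ranges of mean annual temperature (6.6 to
#' 20.5 degrees C overall), precipitation (853 to 1895 mm) and elevation.
#' Pan evaporation is not part of the published climate summary; the
#' defaults use realistic Australian pan-evaporation ranges that rise with
#' regional temperature (about 900 mm/yr in cool highland Tasmania to
#' about 1800 mm/yr in the tropics), so the P:E index spans roughly
#' 0.5-1.6. The understorey diameter distribution is `"skewed"`
#' (exponential-like, prolific recent recruitment) or `"peaked"` (pulsed
#' recruitment) per region, and `rf_share` is the rainforest fraction of
#' understorey stems (zero where no rainforest flora occurs).
#'
#' @return Data frame with one row per region.
#' @export
default_regions <- function() {
  data.frame(
    region = c("NNSW", "SNSW", "VIC", "FNQ", "WA", "LTAS", "HTAS"),
    n_plots = c(8L, 5L, 8L, 4L, 9L, 9L, 5L),
    census_year = c(2013L, 2014L, 2014L, 2014L, 2012L, 2013L, 2015L),
    establishment_year = c(NA, NA, 1939L, NA, 1917L, 1934L, NA),
    mat_min = c(15.3, 10.0, 10.3, 18.9, 14.8, 9.7, 6.6),
    mat_max = c(18.0, 13.1, 11.7, 20.5, 15.3, 12.4, 8.7),
    map_min = c(1323, 853, 1445, 1376, 1006, 1139, 1309),
    map_max = c(1895, 1000, 1869, 1732, 1204, 1477, 1723),
    pan_min = c(1400, 1100, 1000, 1500, 1300, 1000, 900),
    pan_max = c(1700, 1400, 1250, 1800, 1500, 1200, 1100),
    elev_min = c(75, 420, 337, 795, 93, 49, 691),
    elev_max = c(683, 955, 863, 1148, 239, 560, 910),
    understorey = c("skewed", "skewed", "peaked", "skewed", "skewed",
                    "peaked", "peaked"),
    rf_share = c(0.3, 0.1, 0.1, 0.4, 0.0, 0.3, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic census generator
#'
#' Bundles and validates every tunable of [generate_network()]. The
#' defaults describe a mature tall eucalypt forest network: a dominant
#' eucalypt overstorey cohort with lognormal diameters peaking between 50
#' and 100 cm, a dense non-eucalypt understorey, measured heights
#' following `height = a + b * ln(DBH)` with noise, and plot aboveground
#' carbon declining linearly with mean annual temperature (about 400
#' tC/ha at 6 degrees C falling by 14.3 tC/ha per degree, with 60 tC/ha
#' of plot-level noise). The carbon-temperature coupling is imposed by
#' sizing the overstorey and understorey stem counts to a per-plot carbon
#' target, so the generated stems remain internally consistent with the
#' allometric accounting.
#'
#' @param seed master integer seed; all random streams derive from it.
#' @param regions regional design, see [default_regions()].
#' @param plots_per_region optional single integer overriding every
#'   region's plot count (0 gives an empty census).
#' @param pool named integer vector: species-pool sizes per guild
#'   (`Euc`, `Scl`, `RF`).
#' @param overstorey_meanlog,overstorey_sdlog lognormal parameters of the
#'   overstorey DBH cohort, cm. The defaults (median 70 cm, sdlog 0.37)
#'   put the cohort mode near 61 cm — inside the 50-100 cm band of a
#'   mature stand — with roughly 2 percent of eucalypts above 150 cm.
#' @param understorey_scale,understorey_sdlog understorey DBH scale above
#'   the 10-cm threshold: `10 + Exp(scale)` for skewed regions,
#'   `10 + Lognormal(log(scale), sdlog)` for peaked regions.
#' @param height_overstorey,height_understorey named vectors `c(a, b, sd)`
#'   of the diameter-height model per stratum (m, m per ln cm, m).
#' @param heights_per_plot number of measured heights per plot in each
#'   stratum.
#' @param agc_at_6c expected live AGC at MAT 6 degrees C, tC/ha.
#' @param agc_mat_slope change in expected AGC per degree of MAT,
#'   tC/ha/degree (negative: warmer plots store less carbon).
#' @param agc_noise_sd plot-level AGC noise, tC/ha.
#' @param eucalypt_agc_share expected eucalypt share of plot AGC.
#' @param carbon_fraction carbon content of dry biomass.
#' @param allometry named list of [allometry_model()]s (`eucalypt`,
#'   `non_eucalypt`) used both to size the cohorts and as the matching
#'   analysis configuration; defaults are synthetic coefficients.
#' @param mortality_fraction fraction of tagged stems that are dead,
#'   added on top of the live cohort.
#' @param mortality_codes vocabulary of mortality-mechanism codes
#'   assigned to dead stems (configurable, protocol-style).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             regions = default_regions(),
                             plots_per_region = NULL,
                             pool = c(Euc = 30L, Scl = 47L, RF = 108L),
                             overstorey_meanlog = log(70),
                             overstorey_sdlog = 0.37,
                             understorey_scale = 8,
                             understorey_sdlog = 0.5,
                             height_overstorey = c(a = 7.5, b = 10, sd = 3),
                             height_understorey = c(a = 2, b = 8, sd = 2.5),
                             heights_per_plot = 15L,
                             agc_at_6c = 400,
                             agc_mat_slope = -14.3,
                             agc_noise_sd = 60,
                             eucalypt_agc_share = 0.9,
                             carbon_fraction = 0.5,
                             allometry = list(
                               eucalypt = allometry_model(
                                 "synthetic eucalypt", "eucalypt",
                                 alpha = -2.0, beta = 2.4,
                                 source = "synthetic test coefficients"),
                               non_eucalypt = allometry_model(
                                 "synthetic rainforest", "non_eucalypt",
                                 alpha = -1.8, beta = 2.3,
                                 source = "synthetic test coefficients")),
                             mortality_fraction = 0.03,
                             mortality_codes = c("SD", "SB", "SU")) {
  stopifnot(is.data.frame(regions),
            all(c("region", "n_plots", "mat_min", "mat_max", "map_min",
                  "map_max", "pan_min", "pan_max", "understorey",
                  "rf_share") %in% names(regions)))
  if (!is.null(plots_per_region)) {
    stopifnot(length(plots_per_region) == 1L, plots_per_region >= 0)
  }
  if (any(regions$mat_max <= regions$mat_min) ||
      any(regions$map_max <= regions$map_min) ||
      any(regions$pan_max <= regions$pan_min)) {
    stop("invalid config: every regional climate range must be non-degenerate",
         call. = FALSE)
  }
  if (any(pool < 1L) || !all(c("Euc", "Scl", "RF") %in% names(pool))) {
    stop("invalid config: 'pool' needs positive Euc, Scl and RF sizes",
         call. = FALSE)
  }
  stopifnot(overstorey_sdlog > 0, understorey_scale > 0,
            understorey_sdlog > 0, agc_noise_sd >= 0,
            eucalypt_agc_share > 0, eucalypt_agc_share < 1,
            carbon_fraction > 0,
            mortality_fraction >= 0, mortality_fraction < 1)
  structure(list(
    seed = as.integer(seed), regions = regions,
    plots_per_region = plots_per_region, pool = pool,
    overstorey_meanlog = overstorey_meanlog,
    overstorey_sdlog = overstorey_sdlog,
    understorey_scale = understorey_scale,
    understorey_sdlog = understorey_sdlog,
    height_overstorey = height_overstorey,
    height_understorey = height_understorey,
    heights_per_plot = as.integer(heights_per_plot),
    agc_at_6c = agc_at_6c, agc_mat_slope = agc_mat_slope,
    agc_noise_sd = agc_noise_sd,
    eucalypt_agc_share = eucalypt_agc_share,
    carbon_fraction = carbon_fraction, allometry = allometry,
    mortality_fraction = mortality_fraction,
    mortality_codes = mortality_codes
  ), class = "synthetic_config")
}

# Deterministic synthetic species pool with guild assignment.
.species_pool <- function(pool) {
  euc_genus <- rep(c("Eucalyptus", "Corymbia"), c(ceiling(pool[["Euc"]] * 0.8),
                                                  floor(pool[["Euc"]] * 0.2)))
  euc_genus <- euc_genus[seq_len(pool[["Euc"]])]
  scl_genus <- rep_len(c("Acacia", "Allocasuarina", "Pomaderris", "Olearia",
                         "Nematolepis", "Leptospermum", "Trymalium"),
                       pool[["Scl"]])
  rf_genus <- rep_len(c("Nothofagus", "Syncarpia", "Cryptocarya",
                        "Atherosperma", "Doryphora"), pool[["RF"]])
  data.frame(
    species = c(sprintf("%s synthetica%02d", euc_genus, seq_len(pool[["Euc"]])),
                sprintf("%s synthetica%02d", scl_genus, seq_len(pool[["Scl"]])),
                sprintf("%s synthetica%02d", rf_genus, seq_len(pool[["RF"]]))),
    guild = rep(c("Euc", "Scl", "RF"), pool[c("Euc", "Scl", "RF")]),
    is_eucalypt = rep(c(TRUE, FALSE, FALSE), pool[c("Euc", "Scl", "RF")]),
    stringsAsFactors = FALSE
  )
}

# Expected per-tree aboveground biomass (kg) under an allometry for the
# configured understorey diameter distribution, by numerical integration.
.expected_und_agb <- function(shape, scale, sdlog, model) {
  f <- if (shape == "skewed") {
    function(x) {
      model$correction_factor * exp(model$alpha) * (10 + x)^model$beta *
        stats::dexp(x, rate = 1 / scale)
    }
  } else {
    function(x) {
      model$correction_factor * exp(model$alpha) * (10 + x)^model$beta *
        stats::dlnorm(x, meanlog = log(scale), sdlog = sdlog)
    }
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
}

# Geometric-decay sampling weights over a species subset.
.rank_weights <- function(k, decay = 0.6) {
  w <- decay^(seq_len(k) - 1)
  w / sum(w)
}

#' Generate a synthetic census network
#'
#' Draws a complete, protocol-conformant census — plot table, stem list
#' with coordinates, canopy positions, growth stages, measured-height
#' subset and a small dead cohort with mortality codes, plus the
#' species-guild lookup — with the statistical structure the analysis
#' modules assume (see [synthetic_config()]). The result passes
#' [validate_census()] with zero violations, and a manifest records every
#' latent parameter so that downstream estimates can be checked against
#' the ground truth.
#'
#' The same configuration (including its seed) always produces an
#' identical network; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return Object of class `synthetic_network`: list with `census` (a
#'   [census()] object) and `manifest` (ground-truth parameters: the
#'   species pool, per-plot carbon targets and cohort sizes, height
#'   models, allometry and the carbon-temperature coupling). An empty
#'   design (zero plots) yields an empty census and an empty manifest.
#' @export
#' @examples
#' net <- generate_network(synthetic_config(seed = 1, plots_per_region = 1))
#' net$census
generate_network <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  regions <- config$regions
  if (!is.null(config$plots_per_region)) {
    regions$n_plots <- as.integer(config$plots_per_region)
  }
  pool <- .species_pool(config$pool)
  empty_stems <- .check_table(
    data.frame(stem_tag = character(), plot_id = character(),
               species = character(), dbh_cm = numeric(), pom_m = numeric(),
               x_m = numeric(), y_m = numeric(),
               canopy_position = character(), growth_stage = character(),
               stem_form = character(), alive = logical(),
               mortality_code = character(), height_m = numeric(),
               buttressed = logical(), stringsAsFactors = FALSE),
    .stem_columns, "stems")
  if (sum(regions$n_plots) == 0L) {
    cen <- census(
      stems = empty_stems,
      plots = .check_table(
        data.frame(plot_id = character(), region = character(),
                   area_ha = numeric(), mat_c = numeric(), map_mm = numeric(),
                   pan_evap_mm = numeric(), elevation_m = numeric(),
                   establishment_year = integer(), census_date = character(),
                   agc_excluded = logical(), stringsAsFactors = FALSE),
        .plot_columns, "plots"),
      species = pool)
    return(structure(list(census = cen, manifest = list()),
                     class = "synthetic_network"))
  }

  out <- .with_seed(config$seed, {
    euc_pool <- pool$species[pool$guild == "Euc"]
    scl_pool <- pool$species[pool$guild == "Scl"]
    rf_pool <- pool$species[pool$guild == "RF"]

    # Regional species subsets: one dominant target eucalypt per region
    # (cycling through the pool) plus companion species per guild.
    region_species <- lapply(seq_len(nrow(regions)), function(r) {
      dominant <- euc_pool[((r - 1L) %% length(euc_pool)) + 1L]
      list(
        dominant = dominant,
        euc = c(dominant, sample(setdiff(euc_pool, dominant),
                                 min(3L, length(euc_pool) - 1L))),
        scl = sample(scl_pool, min(8L, length(scl_pool))),
        rf = sample(rf_pool, min(6L, length(rf_pool)))
      )
    })
    names(region_species) <- regions$region

    mu <- config$overstorey_meanlog
    s <- config$overstorey_sdlog
    am <- config$allometry
    cf <- config$carbon_fraction
    # expected per-tree carbon (t) in each stratum, for cohort sizing
    over_tc <- cf * am$eucalypt$correction_factor *
      exp(am$eucalypt$alpha + am$eucalypt$beta * mu +
            am$eucalypt$beta^2 * s^2 / 2) / 1000
    und_tc <- vapply(unique(regions$understorey), function(shape) {
      cf * .expected_und_agb(shape, config$understorey_scale,
                             config$understorey_sdlog, am$non_eucalypt) / 1000
    }, numeric(1))

    plot_rows <- list()
    stem_rows <- list()
    target_rows <- list()
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      rsp <- region_species[[rg$region]]
      for (p in seq_len(rg$n_plots)) {
        plot_id <- sprintf("%s%02d", rg$region, p)
        mat <- stats::runif(1, rg$mat_min, rg$mat_max)
        mapv <- stats::runif(1, rg$map_min, rg$map_max)
        pan <- stats::runif(1, rg$pan_min, rg$pan_max)
        elev <- stats::runif(1, rg$elev_min, rg$elev_max)
        plot_rows[[plot_id]] <- data.frame(
          plot_id = plot_id, region = rg$region, area_ha = 1,
          mat_c = mat, map_mm = mapv, pan_evap_mm = pan, elevation_m = elev,
          establishment_year = if ("establishment_year" %in% names(rg)) {
            as.integer(rg$establishment_year)
          } else NA_integer_,
          census_date = sprintf("%d-03-01", rg$census_year),
          agc_excluded = FALSE, stringsAsFactors = FALSE)

        target <- max(60, config$agc_at_6c +
                        config$agc_mat_slope * (mat - 6) +
                        stats::rnorm(1, 0, config$agc_noise_sd))
        n_over <- max(5L, as.integer(round(
          config$eucalypt_agc_share * target / over_tc)))
        n_und <- max(0L, as.integer(round(
          (1 - config$eucalypt_agc_share) * target / und_tc[[rg$understorey]])))

        dbh_over <- pmax(10.1, stats::rlnorm(n_over, mu, s))
        dbh_und <- if (rg$understorey == "skewed") {
          10 + stats::rexp(n_und, rate = 1 / config$understorey_scale)
        } else {
          10 + stats::rlnorm(n_und, log(config$understorey_scale),
                             config$understorey_sdlog)
        }

        sp_over <- sample(rsp$euc, n_over, replace = TRUE,
                          prob = c(0.8, rep(0.2 / (length(rsp$euc) - 1),
                                            length(rsp$euc) - 1)))
        und_guild <- if (n_und > 0L && rg$rf_share > 0) {
          stats::runif(n_und) < rg$rf_share
        } else {
          rep(FALSE, n_und)
        }
        sp_und <- character(n_und)
        if (any(!und_guild)) {
          sp_und[!und_guild] <- sample(rsp$scl, sum(!und_guild), replace = TRUE,
                                       prob = .rank_weights(length(rsp$scl)))
        }
        if (any(und_guild)) {
          sp_und[und_guild] <- sample(rsp$rf, sum(und_guild), replace = TRUE,
                                      prob = .rank_weights(length(rsp$rf)))
        }

        pos_over <- sample(c("dominant", "co-dominant", "emergent"), n_over,
                           replace = TRUE, prob = c(0.5, 0.45, 0.05))
        stage_und <- sample(c("regrowth", "regenerating"), n_und,
                            replace = TRUE)

        ho <- config$height_overstorey
        hu <- config$height_understorey
        h_over <- rep(NA_real_, n_over)
        meas_o <- sample(n_over, min(config$heights_per_plot, n_over))
        h_over[meas_o] <- pmax(5, ho[["a"]] + ho[["b"]] * log(dbh_over[meas_o]) +
                                 stats::rnorm(length(meas_o), 0, ho[["sd"]]))
        h_und <- rep(NA_real_, n_und)
        if (n_und > 0L) {
          meas_u <- sample(n_und, min(config$heights_per_plot, n_und))
          h_und[meas_u] <- pmax(2, hu[["a"]] + hu[["b"]] * log(dbh_und[meas_u]) +
                                  stats::rnorm(length(meas_u), 0, hu[["sd"]]))
        }

        n_live <- n_over + n_und
        n_dead <- stats::rbinom(1, n_live, config$mortality_fraction)
        dbh_dead <- 10 + stats::rexp(n_dead, rate = 1 / config$understorey_scale)
        sp_dead <- sample(c(rsp$euc, rsp$scl), n_dead, replace = TRUE)

        n_all <- n_live + n_dead
        form <- rep(NA_character_, n_all)
        deformed <- stats::runif(n_all) < 0.05
        form[deformed] <- sample(c("broken top", "double leader"),
                                 sum(deformed), replace = TRUE)
        stem_rows[[plot_id]] <- data.frame(
          stem_tag = sprintf("%s-%04d", plot_id, seq_len(n_all)),
          plot_id = plot_id,
          species = c(sp_over, sp_und, sp_dead),
          dbh_cm = c(dbh_over, dbh_und, dbh_dead),
          pom_m = 1.3,
          x_m = stats::runif(n_all, 0, 100),
          y_m = stats::runif(n_all, 0, 100),
          canopy_position = c(pos_over, rep("suppressed", n_und),
                              rep("none", n_dead)),
          growth_stage = c(rep("mature", n_over), stage_und,
                           rep("none", n_dead)),
          stem_form = form,
          alive = rep(c(TRUE, FALSE), c(n_live, n_dead)),
          mortality_code = c(rep(NA_character_, n_live),
                             sample(config$mortality_codes, n_dead,
                                    replace = TRUE)),
          height_m = c(h_over, h_und, rep(NA_real_, n_dead)),
          buttressed = FALSE,
          stringsAsFactors = FALSE)
        target_rows[[plot_id]] <- data.frame(
          plot_id = plot_id, region = rg$region, mat_c = mat,
          target_agc_tc_ha = target, n_overstorey = n_over,
          n_understorey = n_und, n_dead = n_dead, stringsAsFactors = FALSE)
      }
    }

    plots <- do.call(rbind, plot_rows)
    stems <- do.call(rbind, stem_rows)
    rownames(plots) <- rownames(stems) <- NULL
    cen <- census(stems = stems, plots = plots, species = pool)

    censused <- unique(merge(
      data.frame(species = unique(stems$species), stringsAsFactors = FALSE),
      pool, by = "species"))
    manifest <- list(
      seed = config$seed,
      species_pool = pool,
      region_species = region_species,
      plot_targets = {
        tr <- do.call(rbind, target_rows); rownames(tr) <- NULL; tr
      },
      agc_model = list(at_6c = config$agc_at_6c,
                       mat_slope = config$agc_mat_slope,
                       noise_sd = config$agc_noise_sd,
                       eucalypt_share = config$eucalypt_agc_share,
                       carbon_fraction = config$carbon_fraction),
      height_models = list(overstorey = config$height_overstorey,
                           understorey = config$height_understorey),
      allometry = config$allometry,
      guild_richness = vapply(c("Euc", "Scl", "RF"), function(g) {
        sum(censused$guild == g)
      }, integer(1))
    )
    list(census = cen, manifest = manifest)
  })
  structure(out, class = "synthetic_network")
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat("Synthetic forest network\n")
  print(x$census)
  if (length(x$manifest)) {
    cat(sprintf("  AGC target: %.0f tC/ha at 6 degC, slope %.1f tC/ha/degC\n",
                x$manifest$agc_model$at_6c, x$manifest$agc_model$mat_slope))
  }
  invisible(x)
}

#' Generate a synthetic hemispherical photograph
#'
#' Draws an intensity grid whose pixels are independently canopy (dark,
#' uniform 20-110) with probability `target_cover`/100 or sky (bright,
#' uniform 150-250) otherwise, so the expected [canopy_fraction()] at the
#' default threshold of 125 equals the target cover.
#'
#' @param target_cover desired expected canopy cover, percent in
#'   \[0, 100\].
#' @param dim image dimensions `c(rows, cols)`.
#' @param seed optional seed (caller's RNG state is preserved).
#' @param station_id,plot_id identifiers attached to the image.
#' @return A [canopy_image()].
#' @export
generate_canopy_image <- function(target_cover, dim = c(512L, 512L),
                                  seed = NULL, station_id = NA_integer_,
                                  plot_id = NA_character_) {
  stopifnot(is.numeric(target_cover), length(target_cover) == 1L,
            target_cover >= 0, target_cover <= 100,
            length(dim) == 2L, all(dim >= 1))
  px <- .with_seed(seed, {
    n <- prod(dim)
    dark <- stats::runif(n) < target_cover / 100
    val <- numeric(n)
    val[dark] <- stats::runif(sum(dark), 20, 110)
    val[!dark] <- stats::runif(sum(!dark), 150, 250)
    matrix(val, nrow = dim[1], ncol = dim[2])
  })
  canopy_image(px, station_id = station_id, plot_id = plot_id)
}

#' Simulate plot carbon along a temperature gradient
#'
#' Draws a plot table in which aboveground carbon is a linear function of
#' mean annual temperature with Gaussian noise, while precipitation and
#' the P:E index are independent nuisance climate variables drawn over
#' the study's observed ranges. Used for power and recovery checks of the
#' carbon-climate model selection.
#'
#' @param n number of plots (default 46: a 48-plot network minus two
#'   carbon-excluded plots).
#' @param mat_range,map_range,pe_range uniform sampling ranges of the
#'   three climate variables.
#' @param agc_at_6c expected AGC at MAT 6 degrees C, tC/ha.
#' @param mat_slope AGC change per degree, tC/ha/degree.
#' @param noise_sd residual AGC noise, tC/ha.
#' @param seed optional seed (caller's RNG state is preserved).
#' @return Data frame with columns `agc`, `mat`, `map`, `pe`.
#' @export
simulate_agc_climate <- function(n = 46L, mat_range = c(6.6, 20.5),
                                 map_range = c(853, 1895),
                                 pe_range = c(0.5, 1.6),
                                 agc_at_6c = 400, mat_slope = -14.3,
                                 noise_sd = 60, seed = NULL) {
  stopifnot(n >= 3L)
  .with_seed(seed, {
    mat <- stats::runif(n, mat_range[1], mat_range[2])
    data.frame(
      agc = agc_at_6c + mat_slope * (mat - 6) + stats::rnorm(n, 0, noise_sd),
      mat = mat,
      map = stats::runif(n, map_range[1], map_range[2]),
      pe = stats::runif(n, pe_range[1], pe_range[2])
    )
  })
}
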