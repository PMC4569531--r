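# Fixtures built in code: a small hand-written census and a randomized
# conformant census used by the property-style tests.

make_species_table <- function() {
  data.frame(
    species = c("Eucalyptus regnans", "Eucalyptus obliqua",
                "Corymbia maculata", "Acacia melanoxylon",
                "Pomaderris apetala", "Nothofagus cunninghamii"),
    guild = c("Euc", "Euc", "Euc", "Scl", "Scl", "RF"),
    is_eucalypt = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

make_plots_table <- function() {
  data.frame(
    plot_id = c("P1", "P2"),
    region = c("VIC", "VIC"),
    area_ha = c(1, 1),
    mat_c = c(11.1, 10.8),
    map_mm = c(1624, 1500),
    pan_evap_mm = c(1100, 1080),
    elevation_m = c(600, 550),
    establishment_year = c(1939L, NA_integer_),
    census_date = c("2014-03-01", "2014-03-02"),
    agc_excluded = c(FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

make_stem <- function(stem_tag, plot_id = "P1",
                      species = "Eucalyptus regnans", dbh_cm = 65,
                      pom_m = 1.3, x_m = 50, y_m = 50,
                      canopy_position = "dominant", growth_stage = "mature",
                      stem_form = NA_character_, alive = TRUE,
                      mortality_code = NA_character_, height_m = NA_real_,
                      buttressed = FALSE) {
  data.frame(stem_tag = stem_tag, plot_id = plot_id, species = species,
             dbh_cm = dbh_cm, pom_m = pom_m, x_m = x_m, y_m = y_m,
             canopy_position = canopy_position, growth_stage = growth_stage,
             stem_form = stem_form, alive = alive,
             mortality_code = mortality_code, height_m = height_m,
             buttressed = buttressed, stringsAsFactors = FALSE)
}

small_census <- function(stems = NULL) {
  if (is.null(stems)) {
    stems <- rbind(
      make_stem("T001", dbh_cm = 65, height_m = 55),
      make_stem("T002", dbh_cm = 40, species = "Acacia melanoxylon",
                canopy_position = "suppressed", growth_stage = "regrowth"),
      make_stem("T003", plot_id = "P2", dbh_cm = 90,
                species = "Eucalyptus obliqua", height_m = 60)
    )
  }
  census(stems = stems, plots = make_plots_table(),
         species = make_species_table())
}

# Randomized conformant census: a few plots, random species mix,
# uniform diameters. Deterministic given the seed.
random_census <- function(seed, n_plots = 3L, n_stems = 120L) {
  set.seed(seed)
  sp <- make_species_table()
  plots <- data.frame(
    plot_id = sprintf("R%02d", seq_len(n_plots)),
    region = "SIM", area_ha = 1,
    mat_c = runif(n_plots, 7, 20), map_mm = runif(n_plots, 900, 1800),
    pan_evap_mm = runif(n_plots, 900, 1700),
    elevation_m = runif(n_plots, 50, 1100),
    establishment_year = NA_integer_, census_date = "2014-01-01",
    agc_excluded = FALSE, stringsAsFactors = FALSE
  )
  alive <- runif(n_stems) > 0.05
  stems <- data.frame(
    stem_tag = sprintf("R-%04d", seq_len(n_stems)),
    plot_id = sample(plots$plot_id, n_stems, replace = TRUE),
    species = sample(sp$species, n_stems, replace = TRUE),
    dbh_cm = runif(n_stems, 10, 150),
    pom_m = 1.3,
    x_m = runif(n_stems, 0, 100), y_m = runif(n_stems, 0, 100),
    canopy_position = sample(c("suppressed", "dominant", "co-dominant",
                               "emergent"), n_stems, replace = TRUE),
    growth_stage = sample(c("regrowth", "regenerating", "mature"),
                          n_stems, replace = TRUE),
    stem_form = NA_character_,
    alive = alive,
    mortality_code = ifelse(alive, NA_character_, "SD"),
    height_m = ifelse(runif(n_stems) < 0.3, runif(n_stems, 15, 80), NA_real_),
    buttressed = FALSE,
    stringsAsFactors = FALSE
  )
  census(stems = stems, plots = plots, species = sp)
}

synthetic_allometries <- function() {
  list(
    eucalypt = allometry_model("euc", "eucalypt", alpha = -2.0, beta = 2.4),
    non_eucalypt = allometry_model("ne", "non_eucalypt", alpha = -1.8,
                                   beta = 2.3)
  )
}

write_census_files <- function(cen, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(
    census = file.path(dir, "stems.csv"),
    plots = file.path(dir, "plots.csv"),
    species = file.path(dir, "species.csv")
  )
  write_census(cen, paths$census, paths$plots, paths$species)
  paths
}
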