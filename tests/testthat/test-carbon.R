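test_that("tree biomass follows the ln-ln allometry", {
  ident <- allometry_model("id", "eucalypt", alpha = 0, beta = 1)
  expect_equal(tree_agb(37.2, ident), 37.2, tolerance = 1e-12)
  near_flat <- allometry_model("c", "eucalypt", alpha = log(2), beta = 1e-12)
  expect_equal(tree_agb(5, near_flat), 2, tolerance = 1e-9)
  expect_equal(tree_agb(500, near_flat), 2, tolerance = 1e-9)
  # log-form and power-form evaluations agree
  m <- allometry_model("gen", "eucalypt", alpha = -2.0, beta = 2.4)
  expect_equal(tree_agb(50, m), exp(-2) * 50^2.4, tolerance = 1e-12)
  expect_error(tree_agb(-3, m), "positive")
  expect_error(allometry_model("bad", "eucalypt", alpha = 1, beta = -1),
               "beta")
  expect_error(allometry_model("bad", "eucalypt", alpha = 1, beta = 1,
                               correction_factor = 0), "correction_factor")
})

test_that("biomass is strictly increasing in diameter when beta > 0", {
  m <- allometry_model("gen", "eucalypt", alpha = -2.0, beta = 2.4,
                       correction_factor = 1.1)
  d <- sort(runif(50, 10, 200))
  expect_true(all(diff(tree_agb(d, m)) > 0))
})

test_that("the shipped synthetic allometry config loads by scope", {
  cfg <- system.file("extdata", "allometry_synthetic.json",
                     package = "tallstand")
  models <- read_allometry(cfg)
  expect_setequal(names(models), c("eucalypt", "non_eucalypt"))
  expect_s3_class(models$eucalypt, "allometry_model")
  expect_gt(models$eucalypt$beta, 0)
})

test_that("plot carbon converts units and applies the carbon fraction", {
  # one stem engineered to weigh exactly 1000 kg
  m <- allometry_model("unit", "eucalypt", alpha = log(1000) - log(20),
                       beta = 1)
  ne <- allometry_model("ne", "non_eucalypt", alpha = -1.8, beta = 2.3)
  cen <- small_census(make_stem("T1", dbh_cm = 20))
  cs <- plot_agc(cen, list(eucalypt = m, non_eucalypt = ne))
  row <- cs[cs$plot_id == "P1", ]
  expect_equal(row$agb_eucalypt_t_ha, 1, tolerance = 1e-12)
  expect_equal(row$agc_tc_ha, 0.5, tolerance = 1e-12)
  # linear in the carbon fraction
  cs47 <- plot_agc(cen, list(eucalypt = m, non_eucalypt = ne),
                   carbon_fraction = 0.47)
  expect_equal(cs47$agc_tc_ha[cs47$plot_id == "P1"], 0.47,
               tolerance = 1e-12)
})

test_that("excluded plots propagate the flag with missing carbon fields", {
  plots <- make_plots_table()
  plots$agc_excluded[plots$plot_id == "P2"] <- TRUE
  st <- rbind(make_stem("T1"), make_stem("T2", plot_id = "P2"))
  cen <- census(st, plots, make_species_table())
  cs <- plot_agc(cen, synthetic_allometries())
  expect_true(cs$excluded[cs$plot_id == "P2"])
  expect_true(is.na(cs$agc_tc_ha[cs$plot_id == "P2"]))
  expect_false(is.na(cs$agc_tc_ha[cs$plot_id == "P1"]))
})

test_that("a missing allometry scope is a configuration error", {
  cen <- small_census()
  expect_error(plot_agc(cen, list(eucalypt = synthetic_allometries()$eucalypt)),
               "non_eucalypt")
})

test_that("plot carbon equals an independent scalar-loop sum", {
  net <- generate_network(synthetic_config(seed = 9, plots_per_region = 3))
  al <- synthetic_allometries()
  cf <- 0.5
  cs <- plot_agc(net$census, al, carbon_fraction = cf)
  cen <- net$census
  # oracle: one scalar pass over the stem list, independent of the
  # vectorized implementation path
  acc <- setNames(numeric(nrow(cen$plots)), cen$plots$plot_id)
  for (i in seq_len(nrow(cen$stems))) {
    s <- cen$stems[i, ]
    if (!s$alive) next
    is_euc <- cen$species$is_eucalypt[cen$species$species == s$species]
    m <- if (is_euc) al$eucalypt else al$non_eucalypt
    acc[[s$plot_id]] <- acc[[s$plot_id]] +
      m$correction_factor * exp(m$alpha + m$beta * log(s$dbh_cm))
  }
  for (p in cen$plots$plot_id) {
    area <- cen$plots$area_ha[cen$plots$plot_id == p]
    expected <- cf * acc[[p]] / 1000 / area
    expect_equal(cs$agc_tc_ha[cs$plot_id == p], expected, tolerance = 1e-9)
  }
})

test_that("diameter-class carbon partitions sum to the plot total", {
  net <- generate_network(synthetic_config(seed = 13, plots_per_region = 2))
  al <- synthetic_allometries()
  by_class <- agc_by_diameter_class(net$census, al, guild = "all")
  cs <- plot_agc(net$census, al)
  total_per_ha <- sum(cs$agc_tc_ha * cs$area_ha) / sum(cs$area_ha)
  expect_equal(sum(by_class$agc_tc_ha), total_per_ha, tolerance = 1e-9)
  expect_equal(sum(by_class$share_pct), 100, tolerance = 1e-9)

  # group-by oracle on the eucalypt-only default
  euc_class <- agc_by_diameter_class(net$census, al)
  st <- net$census$stems
  st <- st[st$alive, ]
  is_euc <- net$census$species$is_eucalypt[match(st$species,
                                                 net$census$species$species)]
  st <- st[is_euc, ]
  breaks <- c(10, 50, 100, 150, Inf)
  oracle <- vapply(seq_len(4), function(b) {
    sel <- st$dbh_cm >= breaks[b] & st$dbh_cm < breaks[b + 1]
    0.5 * sum(exp(-2.0 + 2.4 * log(st$dbh_cm[sel]))) / 1000 /
      sum(net$census$plots$area_ha)
  }, numeric(1))
  expect_equal(euc_class$agc_tc_ha, oracle, tolerance = 1e-9)
})

test_that("degenerate class layouts are rejected", {
  cen <- small_census()
  al <- synthetic_allometries()
  overlap <- rbind(c(10, 60), c(50, 100), c(100, Inf))
  expect_error(agc_by_diameter_class(cen, al, classes = overlap), "overlap")
  expect_error(agc_by_diameter_class(cen, al, classes = c(10, 10, 50)),
               "strictly increasing")
  expect_error(agc_by_diameter_class(cen, al, classes = c(20, 50, Inf)),
               "cover")
})

test_that("single-class and equal-split layouts give trivial shares", {
  st <- rbind(make_stem("T1", dbh_cm = 30), make_stem("T2", dbh_cm = 40))
  cen <- census(st, make_plots_table(), make_species_table())
  one <- agc_by_diameter_class(cen, synthetic_allometries(),
                               classes = c(10, Inf))
  expect_equal(one$share_pct, 100)

  # two stems with identical biomass in different classes -> 50/50
  m <- allometry_model("c", "eucalypt", alpha = log(500), beta = 1e-12)
  ne <- synthetic_allometries()$non_eucalypt
  st2 <- rbind(make_stem("T1", dbh_cm = 30), make_stem("T2", dbh_cm = 80))
  cen2 <- census(st2, make_plots_table(), make_species_table())
  half <- agc_by_diameter_class(cen2, list(eucalypt = m, non_eucalypt = ne),
                                classes = c(10, 50, Inf))
  expect_equal(half$share_pct, c(50, 50), tolerance = 1e-6)
})

test_that("carbon is additive over plots and stems", {
  cen <- random_census(21, n_plots = 4, n_stems = 160)
  al <- synthetic_allometries()
  cs <- plot_agc(cen, al)
  # splitting the census by plots and recombining preserves totals
  total <- sum(cs$agc_tc_ha * cs$area_ha)
  parts <- vapply(cen$plots$plot_id, function(p) {
    sub <- census(cen$stems[cen$stems$plot_id == p, , drop = FALSE],
                  cen$plots[cen$plots$plot_id == p, , drop = FALSE],
                  cen$species)
    s <- plot_agc(sub, al)
    s$agc_tc_ha * s$area_ha
  }, numeric(1))
  expect_equal(sum(parts), total, tolerance = 1e-9)
})
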