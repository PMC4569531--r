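test_that("basal area matches closed forms and rejects bad areas", {
  one <- make_stem("T1", dbh_cm = 20)
  expect_equal(basal_area(one, 1), pi * 0.01, tolerance = 1e-12)
  expect_equal(basal_area(one[0, ], 1), 0)
  # 100 stems whose individual cross-section is 0.25 m2 -> 25 m2/ha
  many <- do.call(rbind, lapply(1:100, function(i) {
    make_stem(sprintf("T%03d", i), dbh_cm = 56.419)
  }))
  expect_equal(basal_area(many, 1), 25, tolerance = 1e-4)
  expect_error(basal_area(one, 0), "positive")
  expect_error(basal_area(one, -2), "positive")
})

test_that("basal area is additive over any partition of the stems", {
  cen <- random_census(42, n_stems = 200)
  st <- cen$stems
  total <- basal_area(st, 1)
  set.seed(1)
  part <- sample(1:3, nrow(st), replace = TRUE)
  pieces <- vapply(1:3, function(g) basal_area(st[part == g, ], 1), numeric(1))
  expect_equal(sum(pieces), total, tolerance = 1e-12)
})

test_that("stocking density counts live stems per hectare", {
  st <- do.call(rbind, lapply(1:172, function(i) {
    make_stem(sprintf("S%03d", i))
  }))
  expect_equal(stocking_density(st, 1), 172)
  expect_equal(stocking_density(st[1:86, ], 0.5), 172)
  mixed <- rbind(
    do.call(rbind, lapply(1:5, function(i) make_stem(sprintf("L%d", i)))),
    do.call(rbind, lapply(1:2, function(i) {
      make_stem(sprintf("D%d", i), alive = FALSE, mortality_code = "SD",
                canopy_position = "none", growth_stage = "none")
    }))
  )
  expect_equal(stocking_density(mixed, 1), 5)
  expect_equal(stocking_density(mixed, 1, include_dead = TRUE), 7)
})

test_that("diameter bins are lower-closed and start at 10 cm", {
  st <- rbind(make_stem("T1", dbh_cm = 10.5), make_stem("T2", dbh_cm = 19.9),
              make_stem("T3", dbh_cm = 20.0))
  dd <- diameter_distribution(st)
  expect_equal(dd$bin_edges, c(10, 20, 30))
  expect_equal(dd$counts, c(2L, 1L))

  pos <- rep(c("dominant", "suppressed"), c(4, 8))
  st2 <- do.call(rbind, lapply(seq_along(pos), function(i) {
    make_stem(sprintf("U%02d", i), dbh_cm = 10 + i, canopy_position = pos[i])
  }))
  sub <- diameter_distribution(st2, subset = c("dominant", "co-dominant"))
  expect_equal(sum(sub$counts), 4L)
  expect_equal(sub$subset_label, "dominant+co-dominant")
})

test_that("binning agrees with a brute-force histogram oracle", {
  set.seed(7)
  dbh <- rlnorm(500, log(70), 0.4)
  dbh <- dbh[dbh >= 10]
  st <- do.call(rbind, lapply(seq_along(dbh), function(i) {
    make_stem(sprintf("L%04d", i), dbh_cm = dbh[i])
  }))
  dd <- diameter_distribution(st, bin_width = 10)
  # oracle: scalar loop over stems and bins
  edges <- dd$bin_edges
  oracle <- integer(length(edges) - 1L)
  for (d in dbh) {
    for (b in seq_len(length(edges) - 1L)) {
      if (d >= edges[b] && d < edges[b + 1]) oracle[b] <- oracle[b] + 1L
    }
  }
  expect_equal(dd$counts, oracle)
  expect_equal(sum(dd$counts), length(dbh))
})

test_that("bin counts always sum to the admitted stem count", {
  for (seed in 1:100) {
    cen <- random_census(seed, n_stems = 50)
    dd <- diameter_distribution(cen$stems)
    expect_equal(sum(dd$counts), sum(cen$stems$alive))
  }
})

test_that("the diameter-height fit recovers noiseless coefficients exactly", {
  d <- c(12, 20, 35, 50, 70, 90, 120)
  fit <- fit_height_diameter(d, 5 + 10 * log(d))
  expect_equal(fit$intercept, 5, tolerance = 1e-8)
  expect_equal(fit$slope, 10, tolerance = 1e-8)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)
  expect_equal(predict(fit, 50), 5 + 10 * log(50), tolerance = 1e-8)

  flat <- fit_height_diameter(d, rep(30, length(d)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 30)

  expect_error(fit_height_diameter(c(10, 20), c(15, 20)), "insufficient")
  expect_error(fit_height_diameter(c(-1, 20, 30), c(15, 20, 25)), "positive")
})

test_that("the noisy fit matches a closed-form normal-equations oracle", {
  set.seed(3)
  n <- 200
  dbh <- runif(n, 10, 150)
  height <- 8 + 9.5 * log(dbh) + rnorm(n, 0, 2)
  fit <- fit_height_diameter(dbh, height)
  X <- cbind(1, log(dbh))
  beta <- solve(t(X) %*% X, t(X) %*% height)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-8)
  expect_equal(fit$slope, beta[2], tolerance = 1e-8)
  rss <- sum((height - X %*% beta)^2)
  expect_equal(fit$residual_sd, sqrt(rss / (n - 2)), tolerance = 1e-8)
})

test_that("coefficient error shrinks as the sample grows", {
  mean_abs_err <- function(n) {
    errs <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      dbh <- runif(n, 10, 150)
      h <- 8 + 9.5 * log(dbh) + rnorm(n, 0, 2)
      abs(fit_height_diameter(dbh, h)$slope - 9.5)
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(50, 500, 5000), mean_abs_err, numeric(1))
  expect_lt(e[3], e[1])
  expect_lt(e[3], 0.05)
  expect_lt(e[2], 0.2)
})

test_that("height summaries use measured heights only", {
  st <- rbind(
    make_stem("T1", height_m = 45),
    make_stem("T2", height_m = 55, canopy_position = "co-dominant"),
    make_stem("T3", height_m = 70, canopy_position = "emergent"),
    make_stem("T4", species = "Acacia melanoxylon",
              canopy_position = "suppressed")  # no measured height
  )
  hs <- height_summary(st, make_species_table())
  expect_equal(hs$mean_height_dominant_eucalypt_m, 50)
  expect_equal(hs$max_height_eucalypt_m, 70)
  expect_true(is.na(hs$max_height_non_eucalypt_m))
})

test_that("height summaries equal a brute-force scan on mixed data", {
  cen <- random_census(11, n_stems = 150)
  st <- cen$stems
  hs <- height_summary(st, cen$species)
  # oracle: explicit scalar scan
  is_euc <- cen$species$is_eucalypt[match(st$species, cen$species$species)]
  best_max_e <- best_max_n <- NA_real_
  dom_heights <- numeric(0)
  for (i in seq_len(nrow(st))) {
    if (!st$alive[i] || is.na(st$height_m[i])) next
    h <- st$height_m[i]
    if (is_euc[i]) {
      if (is.na(best_max_e) || h > best_max_e) best_max_e <- h
      if (st$canopy_position[i] %in% c("dominant", "co-dominant")) {
        dom_heights <- c(dom_heights, h)
      }
    } else if (is.na(best_max_n) || h > best_max_n) {
      best_max_n <- h
    }
  }
  expect_equal(hs$max_height_eucalypt_m, best_max_e)
  expect_equal(hs$max_height_non_eucalypt_m, best_max_n)
  expect_equal(hs$mean_height_dominant_eucalypt_m, mean(dom_heights))
})

test_that("the structure table summarises each plot and region", {
  net <- generate_network(synthetic_config(seed = 4, plots_per_region = 2))
  tab <- structure_table(net$census)
  expect_equal(nrow(tab), nrow(net$census$plots))
  expect_true(all(tab$basal_area_eucalypt_m2_ha > 0))
  reg <- region_structure_table(net$census)
  expect_equal(sort(reg$region), sort(unique(net$census$plots$region)))
  expect_true(all(c("height_dom_euc_plot_mean_m", "height_dom_euc_pooled_m")
                  %in% names(reg)))
})
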