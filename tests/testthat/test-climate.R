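test_that("the P:E ratio is an element-wise division", {
  expect_equal(pe_ratio(1000, 1000), 1.0)
  expect_equal(pe_ratio(500, 1000), 0.5)
  expect_error(pe_ratio(500, 0), "positive")
  set.seed(2)
  mapv <- runif(30, 800, 1900)
  pan <- runif(30, 900, 1800)
  out <- pe_ratio(mapv, pan)
  oracle <- vapply(seq_along(mapv), function(i) mapv[i] / pan[i], numeric(1))
  expect_equal(out, oracle, tolerance = 1e-15)
})

test_that("noiseless linear carbon data is recovered exactly", {
  mat <- 6:20
  d <- data.frame(agc = 400 - 14 * (mat - 6), mat = mat,
                  map = runif(15, 900, 1800), pe = runif(15, 0.5, 1.5))
  fits <- fit_agc_climate(d)
  expect_equal(fits$summary$model[1], "mat")
  co <- coef(fits$fits$mat)
  expect_equal(unname(co[1]), 400 + 14 * 6, tolerance = 1e-8)
  expect_equal(unname(co[2]), -14, tolerance = 1e-8)
  expect_equal(fits$summary$r2[1], 1, tolerance = 1e-12)
})

test_that("a constant response is best explained by the null model", {
  set.seed(8)
  d <- data.frame(agc = rep(300, 20), mat = runif(20, 6, 20),
                  map = runif(20, 900, 1800), pe = runif(20, 0.5, 1.5))
  fits <- fit_agc_climate(d)
  expect_equal(fits$summary$model[1], "null")
  expect_equal(fits$summary$r2[fits$summary$model == "null"], 0)
})

test_that("AIC matches the direct Gaussian log-likelihood formula", {
  # fixed 10-plot fixture
  d <- data.frame(
    agc = c(396, 360, 341, 309, 282, 266, 231, 214, 182, 165),
    mat = c(6.5, 8.0, 9.5, 11.0, 12.5, 14.0, 15.5, 17.0, 18.5, 20.0),
    map = c(1500, 900, 1750, 1100, 1420, 1333, 980, 1610, 1240, 1055),
    pe = c(1.5, 0.7, 1.4, 0.9, 1.2, 1.1, 0.6, 1.3, 1.0, 0.8)
  )
  fits <- fit_agc_climate(d, candidates = list(character(0), "mat", "map",
                                               "pe", c("mat", "map")))
  n <- nrow(d)
  for (i in seq_len(nrow(fits$summary))) {
    s <- fits$summary[i, ]
    k <- s$k  # predictors + intercept + variance
    aic_oracle <- n * (log(2 * pi) + log(s$rss / n) + 1) + 2 * k
    expect_equal(s$aic, aic_oracle, tolerance = 1e-8)
  }
  expect_equal(fits$summary$delta_aic[1], 0)
  expect_true(all(diff(fits$summary$aic) >= 0))
})

test_that("rank-deficient designs are rejected with the predictors named", {
  d <- data.frame(agc = rnorm(10, 300, 10), mat = 1:10, map = 2 * (1:10))
  d$mat2 <- d$mat
  expect_error(fit_agc_climate(d, candidates = list(c("mat", "mat2"))),
               "collinear")
})

test_that("AIC ranking is invariant to adding a constant to the response", {
  set.seed(31)
  d <- data.frame(agc = rnorm(30, 300, 50), mat = runif(30, 6, 20),
                  map = runif(30, 900, 1800), pe = runif(30, 0.5, 1.5))
  r1 <- fit_agc_climate(d)$summary
  d2 <- d; d2$agc <- d2$agc + 500
  r2 <- fit_agc_climate(d2)$summary
  expect_equal(r1$model, r2$model)
  expect_equal(r1$aic, r2$aic, tolerance = 1e-8)
})

test_that("the temperature model is selected and its slope recovered", {
  winners <- character(200)
  slopes <- numeric(200)
  for (r in 1:200) {
    d <- simulate_agc_climate(n = 46, seed = 20000 + r)
    fits <- fit_agc_climate(d)
    winners[r] <- fits$summary$model[1]
    slopes[r] <- unname(coef(fits$fits$mat)[2])
  }
  expect_gte(mean(winners == "mat"), 0.90)
  expect_lt(abs(mean(slopes) - (-14.3)), 1)
})

test_that("envelope membership matches trivial geometric cases", {
  ref <- data.frame(mat = c(6, 20, 6, 20), map = c(850, 850, 1900, 1900))
  inside_pt <- climate_envelope(ref, data.frame(mat = 13, map = 1300))
  expect_true(inside_pt$inside)
  expect_equal(inside_pt$distance, 0)
  corner <- climate_envelope(ref, ref[1, ])
  expect_true(corner$inside)
  expect_equal(corner$distance, 0)
  hot <- climate_envelope(ref, data.frame(mat = 40, map = 1300))
  expect_false(hot$inside)
  expect_gt(hot$distance, 0)
  expect_error(climate_envelope(ref[1:2, ], ref[1, ]), "degenerate")
  collinear <- data.frame(mat = c(6, 10, 14), map = c(900, 1100, 1300))
  expect_error(climate_envelope(collinear, ref[1, ]), "degenerate")
})

test_that("envelope membership agrees with a half-plane oracle", {
  set.seed(21)
  ref <- data.frame(mat = runif(25, 6, 20), map = runif(25, 850, 1900))
  qry <- data.frame(mat = runif(50, 2, 24), map = runif(50, 600, 2200))
  got <- climate_envelope(ref, qry)

  # oracle: exhaustive supporting-line check on standardized coordinates.
  # A point is inside the hull iff for every pair of reference points whose
  # connecting line has all reference points on one side, the query lies on
  # that same side.
  rs <- scale(as.matrix(ref), center = TRUE, scale = apply(ref, 2, sd))
  qs <- scale(as.matrix(qry), center = attr(rs, "scaled:center"),
              scale = attr(rs, "scaled:scale"))
  n <- nrow(rs)
  oracle_inside <- rep(TRUE, nrow(qs))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ex <- rs[j, 1] - rs[i, 1]; ey <- rs[j, 2] - rs[i, 2]
      side <- (rs[, 1] - rs[i, 1]) * ey - (rs[, 2] - rs[i, 2]) * ex
      if (all(side >= -1e-9)) keep_sign <- 1
      else if (all(side <= 1e-9)) keep_sign <- -1
      else next
      qside <- (qs[, 1] - rs[i, 1]) * ey - (qs[, 2] - rs[i, 2]) * ex
      oracle_inside <- oracle_inside & (keep_sign * qside >= -1e-9)
    }
  }
  expect_equal(got$inside, oracle_inside)
  expect_true(all(got$distance[got$inside] == 0))
  expect_true(all(got$distance[!got$inside] > 0))
})

test_that("height classes follow the lower-closed convention", {
  expect_equal(classify_height_class(46), ">45 m")
  expect_equal(classify_height_class(35), "35-45 m")
  expect_equal(classify_height_class(25), "25-35 m")
  expect_equal(classify_height_class(20), "below-range")
  grid <- seq(20, 80, by = 0.5)
  got <- classify_height_class(grid)
  # oracle: explicit interval scan
  oracle <- vapply(grid, function(h) {
    if (h < 25) "below-range"
    else if (h < 35) "25-35 m"
    else if (h < 45) "35-45 m"
    else ">45 m"
  }, character(1))
  expect_equal(got, oracle)
  expect_error(classify_height_class(-1), "positive")
})
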