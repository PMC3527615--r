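test_that("seasonal table matches the sampling design", {
  s <- fixture_seasonal
  expect_identical(nrow(s), 156L)
  expect_true(all(s$depth_m %in% c(3, 10, 20, 30, 50, 100, 150, 220)))
  expect_identical(length(unique(s$date)), 21L)
  expect_true(min(s$date) == as.Date("2003-11-04"))
  expect_true(max(s$date) == as.Date("2004-08-06"))
  expect_s3_class(validate_env_table(s), "data.frame")
  expect_identical(attr(s, "kind"), "seasonal")
})

test_that("spatial table matches the survey design", {
  p <- fixture_spatial
  expect_identical(nrow(p), 37L)
  expect_true(all(p$depth_m <= 80))
  expect_identical(length(unique(p$station)), 7L)
  expect_true(all(p$date >= as.Date("2004-07-04") &
                    p$date <= as.Date("2004-08-10")))
  expect_identical(attr(p, "kind"), "spatial")
})

test_that("sum columns are exactly additive and all abundances positive", {
  for (tab in list(fixture_seasonal, fixture_spatial,
                   generate_seasonal(generator_config(seed = 3)))) {
    expect_equal(tab$prokaryotes_1e5_ml, tab$hna_1e5_ml + tab$lna_1e5_ml)
    expect_equal(tab$viruses_1e6_ml, tab$v1_1e6_ml + tab$v2_1e6_ml)
    expect_true(all(tab$chl_a_ug_l > 0))
    expect_true(all(tab[, c("hna_1e5_ml", "lna_1e5_ml", "v1_1e6_ml",
                            "v2_1e6_ml")] > 0))
    expect_true(all(tab$day_length_h >= 0 & tab$day_length_h <= 24))
  }
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- generator_config(seed = 42)
  expect_identical(generate_seasonal(cfg), fixture_seasonal)
  expect_identical(generate_spatial(generator_config(seed = 7)),
                   fixture_spatial)
  other <- generate_seasonal(generator_config(seed = 43))
  expect_false(identical(other$chl_a_ug_l, fixture_seasonal$chl_a_ug_l))
})

test_that("calibrated columns hit the published means and SDs exactly", {
  tg <- seasonal_moment_targets()
  for (i in seq_len(nrow(tg))) {
    x <- fixture_seasonal[[tg$column[i]]]
    expect_equal(mean(x), tg$mean[i], tolerance = 1e-9)
    expect_equal(sd(x), tg$sd[i], tolerance = 1e-7)
  }
  tg <- spatial_moment_targets()
  for (i in seq_len(nrow(tg))) {
    x <- fixture_spatial[[tg$column[i]]]
    expect_equal(mean(x), tg$mean[i], tolerance = 1e-9)
    expect_equal(sd(x), tg$sd[i], tolerance = 1e-7)
  }
})

test_that("generated CVs track the published campaign CVs within 30%", {
  for (case in list(list(fixture_seasonal, printed_seasonal),
                    list(fixture_spatial, printed_spatial))) {
    es <- env_summary(case[[1]])
    for (col in names(case[[2]]$cv)) {
      cv <- es$cv[match(col, es$column)]
      expect_lt(abs(cv - case[[2]]$cv[[col]]) / case[[2]]$cv[[col]], 0.3,
                label = paste("CV deviation for", col))
    }
  }
})

test_that("generated ranges sit within [0.5x, 2x] of the published extremes", {
  es <- env_summary(fixture_seasonal)
  for (col in names(printed_seasonal$min)) {
    i <- match(col, es$column)
    expect_gte(es$min[i], 0.5 * printed_seasonal$min[[col]])
    expect_lte(es$min[i], 2.0 * printed_seasonal$min[[col]])
    expect_gte(es$max[i], 0.5 * printed_seasonal$max[[col]])
    expect_lte(es$max[i], 2.0 * printed_seasonal$max[[col]])
  }
  # spatial: maxima and the chlorophyll minimum; the published spatial
  # abundance minima are single-sample outliers several noise SDs below
  # the mean and are outside what the lognormal noise model can produce
  es <- env_summary(fixture_spatial)
  for (col in names(printed_spatial$max)) {
    i <- match(col, es$column)
    expect_gte(es$max[i], 0.5 * printed_spatial$max[[col]])
    expect_lte(es$max[i], 2.0 * printed_spatial$max[[col]])
  }
  i <- match("chl_a_ug_l", es$column)
  expect_gte(es$min[i], 0.5 * printed_spatial$min[["chl_a_ug_l"]])
  expect_lte(es$min[i], 2.0 * printed_spatial$min[["chl_a_ug_l"]])
})

test_that("seasonal and spatial datasets separate on every parameter", {
  dirs <- c(depth_m = -1, temperature_c = 1, salinity_psu = -1,
            day_length_h = 1, chl_a_ug_l = 1, hna_1e5_ml = 1,
            lna_1e5_ml = 1, prokaryotes_1e5_ml = 1, v1_1e6_ml = 1,
            v2_1e6_ml = 1, viruses_1e6_ml = 1)
  for (col in names(dirs)) {
    tt <- two_sample_t(fixture_seasonal[[col]], fixture_spatial[[col]])
    expect_lte(tt$p, 0.05, label = paste("t-test p for", col))
    expect_identical(
      sign(mean(fixture_spatial[[col]]) - mean(fixture_seasonal[[col]])),
      dirs[[col]], info = paste("direction of", col))
  }
})

test_that("latent response surfaces have the stated qualitative shapes", {
  cfg <- generator_config()
  covs <- function(t = -0.8, chl = 0.1, z = 10, dl = 12) {
    data.frame(temperature_c = t, chl_a_ug_l = chl, depth_m = z,
               day_length_h = dl)
  }
  # hna unimodal: peak value dominates the cold and warm edges
  at <- function(t) true_response(covs(t = t), "hna", cfg)
  expect_gte(at(-0.8), at(-1.8))
  expect_gte(at(-0.8), at(2.8))
  # argmax of the default surface on a fine grid lies in [-1.3, -0.3]
  grid <- covs(t = seq(-1.8, 2.8, length.out = 4000))
  am <- grid$temperature_c[which.max(true_response(grid, "hna", cfg))]
  expect_gte(am, -1.3)
  expect_lte(am, -0.3)
  # v2 declines with depth, rises with chlorophyll
  vz <- function(z, chl = 0.1) true_response(covs(z = z, chl = chl), "v2", cfg)
  expect_gt(vz(5), vz(200))
  depths <- seq(1, 220, length.out = 100)
  for (chl in c(0.01, 0.08, 0.61)) {
    v <- vz(depths, chl)
    expect_true(all(diff(v) < 0), info = paste("v2 monotone at chl", chl))
  }
  expect_gt(vz(50, 0.5), vz(50, 0.05))
  # lna increases with temperature and chlorophyll
  lt <- function(t, chl = 0.1) true_response(covs(t = t, chl = chl), "lna", cfg)
  expect_gt(lt(2), lt(-1.5))
  expect_gt(lt(0, 0.5), lt(0, 0.05))
  # v1 increases with chlorophyll and with day length at shallow depth
  v1 <- function(dl, chl = 0.1, z = 5) {
    true_response(covs(dl = dl, chl = chl, z = z), "v1", cfg)
  }
  expect_gt(v1(24), v1(0))
  expect_gt(v1(12, chl = 0.5), v1(12, chl = 0.05))
  expect_error(true_response(covs(), "plankton"), "unknown population")
})

test_that("moment calibration is exact, rank-preserving, and guarded", {
  x <- c(1, 2, 3)
  tab <- data.frame(chl_a_ug_l = x)
  out <- calibrate_moments(tab, data.frame(column = "chl_a_ug_l",
                                           mean = 0.08, sd = 0.04))
  expect_equal(mean(out$chl_a_ug_l), 0.08, tolerance = 1e-9)
  expect_equal(sd(out$chl_a_ug_l), 0.04, tolerance = 1e-9)
  expect_identical(cor(out$chl_a_ug_l, x, method = "spearman"), 1)

  # a column already at target comes back essentially unchanged
  set.seed(1)
  y <- rlnorm(200, 0, 0.4)
  tgt <- data.frame(column = "chl_a_ug_l", mean = mean(y), sd = sd(y))
  out2 <- calibrate_moments(data.frame(chl_a_ug_l = y), tgt)
  expect_equal(out2$chl_a_ug_l, y, tolerance = 1e-6)

  # negative-valued columns are calibrated affinely, same guarantees
  z <- c(-2, 0, 5)
  out3 <- calibrate_moments(data.frame(temperature_c = z),
                            data.frame(column = "temperature_c",
                                       mean = -1.2, sd = 0.69))
  expect_equal(mean(out3$temperature_c), -1.2, tolerance = 1e-12)
  expect_equal(sd(out3$temperature_c), 0.69, tolerance = 1e-12)
  expect_identical(cor(out3$temperature_c, z, method = "spearman"), 1)

  expect_error(
    calibrate_moments(data.frame(chl_a_ug_l = rep(1, 5)),
                      data.frame(column = "chl_a_ug_l", mean = 1, sd = 0.1)),
    "constant")
  expect_error(
    calibrate_moments(tab, data.frame(column = "missing", mean = 1, sd = 1)),
    "not present")
})
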