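test_that("free enumeration yields the full 700-candidate grid", {
  specs <- enumerate_candidates("hna")
  expect_identical(nrow(specs), 700L)    # (5 + 10 + 10) * 14 * 2
  sizes <- lengths(specs$inputs)
  expect_true(all(sizes %in% 1:3))
  expect_true(all(specs$hidden %in% 2:15))
  # the reference architecture is present: {chl_a, temperature} FFW x 14
  has <- vapply(seq_len(nrow(specs)), function(i) {
    setequal(specs$inputs[[i]], c("chl_a", "temperature")) &&
      specs$type[i] == "ffw"
  }, logical(1))
  expect_identical(sum(has), 14L)
  expect_error(enumerate_candidates("plankton"))
  expect_error(enumerate_candidates("hna", combos = list(c("chl_a", "bogus"))),
               "invalid")
  restricted <- enumerate_candidates("v2", combos = list("depth"),
                                     hidden = c(2, 4))
  expect_identical(nrow(restricted), 4L)
})

test_that("restart screening is deterministic and respects the minimum", {
  parts <- split_train_test(fixture_seasonal, seed = 1)
  scaler <- fit_scaler(fixture_seasonal,
                       c("chl_a_ug_l", "temperature_c", "hna_1e5_ml"))
  specs <- enumerate_candidates("hna", combos = list(c("chl_a", "temperature")),
                                types = "ffw", hidden = c(2, 3))
  res <- phase1(specs, parts$train, parts$test, scaler, restarts = 3,
                master_seed = 5, max_iter = 15)
  expect_s3_class(res, "ann_candidates")
  expect_identical(nrow(res), 2L)
  expect_true(all(diff(res$rmse) >= 0))    # sorted leaderboard
  # rerun is identical
  res2 <- phase1(specs, parts$train, parts$test, scaler, restarts = 3,
                 master_seed = 5, max_iter = 15)
  expect_identical(res$rmse, res2$rmse)
  expect_identical(res$seed, res2$seed)
  # the reported best is the min over the individual restarts
  key <- arcticann:::spec_key("hna", "ffw", 2, c("chl_a", "temperature"))
  singles <- vapply(1:3, function(r) {
    f <- ann_fit(hna_1e5_ml ~ chl_a_ug_l + temperature_c, parts$train,
                 test = parts$test, type = "ffw", hidden = 2, max_iter = 15,
                 seed = child_seed(5, key, r), scaler = scaler)
    f$converged_rmse
  }, numeric(1))
  expect_equal(res$rmse[res$hidden == 2], min(singles))
  # restarts = 1 equals a single training run
  res1 <- phase1(specs[1, ], parts$train, parts$test, scaler, restarts = 1,
                 master_seed = 5, max_iter = 15)
  expect_equal(res1$rmse, singles[1])
})

test_that("phase 2 extends phase 1's restart streams and never loses", {
  parts <- split_train_test(fixture_seasonal, seed = 1)
  scaler <- fit_scaler(fixture_seasonal,
                       c("chl_a_ug_l", "temperature_c", "lna_1e5_ml"))
  specs <- enumerate_candidates("lna", combos = list(c("chl_a", "temperature")),
                                types = "rbf", hidden = 3)
  r1 <- phase1(specs, parts$train, parts$test, scaler, restarts = 2,
               master_seed = 9, max_iter = 10)
  r2 <- phase2(r1, parts$train, parts$test, scaler, restarts = 6,
               master_seed = 9, max_iter = 10)
  expect_identical(nrow(r2), nrow(r1))
  expect_lte(r2$rmse, r1$rmse)
  expect_error(phase2(r1[0, ], parts$train, parts$test, scaler), "non-empty")
})

test_that("child seeds are stable, architecture-anchored and in range", {
  s1 <- child_seed(1, "a|ffw|4|chl_a", 1)
  expect_identical(s1, child_seed(1, "a|ffw|4|chl_a", 1))
  expect_false(s1 == child_seed(1, "a|ffw|4|chl_a", 2))
  expect_false(s1 == child_seed(2, "a|ffw|4|chl_a", 1))
  expect_false(s1 == child_seed(1, "a|rbf|4|chl_a", 1))
  seeds <- vapply(1:500, function(r) child_seed(7, "k", r), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("spatial evaluation regresses observed on predicted", {
  parts <- split_train_test(fixture_seasonal, seed = 1)
  fit <- ann_fit(v2_1e6_ml ~ depth_m + chl_a_ug_l, parts$train,
                 test = parts$test, type = "ffw", hidden = 3,
                 max_iter = 20, seed = 3)
  ev <- evaluate_spatial(fit, fixture_spatial)
  expect_s3_class(ev, "linfit")
  expect_identical(ev$n, 37L)
  # a perfect predictor (identity network on the response column itself)
  # gives slope 1, intercept 0, r2 1
  identity_scaler <- structure(
    list(columns = "v2_1e6_ml",
         mean = c(v2_1e6_ml = 0), sd = c(v2_1e6_ml = 1)),
    class = "ann_scaler")
  oracle <- structure(
    list(type = "linear", hidden = 0L, inputs = "v2_1e6_ml",
         response = "v2_1e6_ml",
         net = ann_network("linear", 1, theta = c(1, 0)),
         scaler = identity_scaler),
    class = "ann")
  pf <- suppressWarnings(evaluate_spatial(oracle, fixture_spatial))
  expect_equal(pf$slope, 1)
  expect_equal(pf$intercept, 0, tolerance = 1e-9)
  expect_equal(pf$r2, 1)
  expect_error(evaluate_spatial(fit, fixture_spatial[1:2, ]), "3 evaluation")
})

test_that("shifting predictions moves the intercept by -c * slope", {
  set.seed(17)
  pred <- rnorm(40, 5, 2)
  obs <- 1.2 * pred + rnorm(40, 0, 0.5)
  base <- linfit(pred, obs)
  shifted <- linfit(pred + 3, obs)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-12)
  expect_equal(shifted$intercept, base$intercept - 3 * base$slope,
               tolerance = 1e-9)
  expect_error(linfit(rep(2, 40), obs), "zero variance")
})

test_that("selection implements slope-closest-to-1 gated on r-squared", {
  results <- data.frame(r2_spatial = c(0.559, 0.45, 0.60),
                        k_spatial = c(1.213, 1.00, 0.70),
                        rmse = c(0.7, 0.6, 0.5))
  sel <- select_best(results)
  expect_true(sel$admissible)
  expect_identical(sel$which, 1L)    # 0.45 fails the gate; |1.213-1| < |0.7-1|
  # no candidate passes the gate -> explicit no-admissible-model outcome
  none <- select_best(data.frame(r2_spatial = c(0.3, 0.5),
                                 k_spatial = c(1, 1), rmse = c(1, 1)))
  expect_false(none$admissible)
  expect_identical(none$which, NA_integer_)
  # single passing candidate is returned
  one <- select_best(data.frame(r2_spatial = 0.8, k_spatial = 2, rmse = 1))
  expect_true(one$admissible)
  expect_identical(one$which, 1L)
  # ties on |k - 1| break by smaller RMSE
  tie <- select_best(data.frame(r2_spatial = c(0.7, 0.7),
                                k_spatial = c(1.2, 0.8),
                                rmse = c(0.9, 0.4)))
  expect_identical(tie$which, 2L)
})

test_that("total abundance is the aligned element-wise sum", {
  expect_identical(total_abundance(2, 3), 5)
  expect_identical(total_abundance(numeric(3), numeric(3)), numeric(3))
  expect_error(total_abundance(1:3, 1:4), "aligned")
})
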