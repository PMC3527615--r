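test_that("rmse is the root mean squared residual", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, -4), c(0, 0)), sqrt((9 + 16) / 2))
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(rmse(3 * (x - y) + y, y), 3 * rmse(x, y))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("LM on a linear model converges to the OLS solution", {
  set.seed(5)
  X <- matrix(rnorm(120), 60, 2)
  y <- 1.5 * X[, 1] - 0.7 * X[, 2] + 2 + rnorm(60, 0.3)
  net <- ann_init(ann_network("linear", 2), X)
  rec <- train_lm(net, X, y, max_iter = 25)
  ols <- lm.fit(cbind(X, 1), y)
  expect_lt(abs(tail(rec$rmse_train, 1) - sqrt(mean(ols$residuals^2))), 1e-6)
  final <- rec$theta[nrow(rec$theta), ]
  expect_equal(final, unname(ols$coefficients), tolerance = 1e-5)
})

test_that("a network that already interpolates stays at zero error", {
  set.seed(6)
  X <- matrix(rnorm(40), 20, 2)
  net <- ann_init(ann_network("ffw", 2, 3), X)
  y <- ann_forward(net, X)
  rec <- train_lm(net, X, y, max_iter = 10)
  expect_true(all(rec$rmse_train < 1e-12))
})

test_that("training error is non-increasing and the record is complete", {
  set.seed(7)
  X <- matrix(rnorm(100), 50, 2)
  y <- sin(X[, 1]) + 0.5 * X[, 2] + rnorm(50, 0, 0.1)
  net <- ann_init(ann_network("ffw", 2, 4), X)
  rec <- train_lm(net, X[1:40, ], y[1:40], X[41:50, ], y[41:50],
                  max_iter = 30)
  expect_identical(nrow(rec$theta), 31L)
  expect_length(rec$rmse_train, 31)
  expect_length(rec$rmse_test, 31)
  expect_true(all(is.finite(rec$rmse_train)))
  expect_true(all(diff(rec$rmse_train) <= 1e-12))  # only accepted steps move
  expect_false(rec$failed)
  # test data never influence the update: same train, different test
  set.seed(8); net2 <- ann_init(ann_network("ffw", 2, 4), X)
  recA <- train_lm(net2, X[1:40, ], y[1:40], X[41:50, ], y[41:50],
                   max_iter = 15)
  recB <- train_lm(net2, X[1:40, ], y[1:40], X[41:45, ], y[41:45] + 100,
                   max_iter = 15)
  expect_identical(recA$theta, recB$theta)
})

test_that("reconstitution returns the earliest combined-RMSE minimum", {
  skeleton <- ann_network("linear", 1)
  fake <- structure(list(
    theta = matrix(1:3, 3, 2),
    rmse_train = c(0.5, 0.4, 0.45),
    rmse_test = c(0.5, 0.4, 0.45),
    net = skeleton, failed = FALSE), class = "ann_record")
  best <- reconstitute(fake)
  expect_identical(attr(best, "iteration"), 1L)
  expect_identical(best$theta, c(2L, 2L))
  # monotone decreasing -> final iteration
  fake$rmse_train <- c(3, 2, 1); fake$rmse_test <- c(3, 2, 1)
  expect_identical(attr(reconstitute(fake), "iteration"), 2L)
  # tie -> earlier iteration
  fake$rmse_train <- c(0.8, 0.8, 0.9); fake$rmse_test <- c(0, 0, 0)
  expect_identical(attr(reconstitute(fake), "iteration"), 0L)
  # no test data: criterion reduces to training RMSE
  fake$rmse_test <- rep(NA_real_, 3)
  expect_equal(combined_rmse(fake), fake$rmse_train)
})

test_that("reconstituted combined RMSE is the record minimum", {
  set.seed(9)
  X <- matrix(rnorm(80), 40, 2)
  y <- X[, 1]^2 + rnorm(40, 0, 0.2)
  net <- ann_init(ann_network("rbf", 2, 3), X)
  rec <- train_lm(net, X[1:30, ], y[1:30], X[31:40, ], y[31:40],
                  max_iter = 25)
  best <- reconstitute(rec)
  expect_equal(attr(best, "rmse"), min(combined_rmse(rec)))
  expect_true(all(attr(best, "rmse") <= combined_rmse(rec)))
})

test_that("early stopping protects an oversized network from over-training", {
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 150
    X <- cbind(runif(n, -2, 2), runif(n, -2, 2))
    truth <- ann_init(ann_network("ffw", 2, 3), X)
    y <- ann_forward(truth, X) + rnorm(n, 0, 0.3)
    tr <- sample(n, 110)
    net <- ann_init(ann_network("ffw", 2, 15), X[tr, ])
    rec <- train_lm(net, X[tr, ], y[tr], X[-tr, ], y[-tr], max_iter = 100)
    i <- which.min(combined_rmse(rec))
    if (rec$rmse_test[i] <= tail(rec$rmse_test, 1)) wins <- wins + 1
  }
  expect_gte(wins, 18)   # >= 90% of replicates
})

test_that("a trained 3-unit network recovers a known smooth surface", {
  set.seed(99)
  n <- 150
  X <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  truth <- ann_init(ann_network("ffw", 2, 3), X)
  y <- ann_forward(truth, X) + rnorm(n, 0, 0.05)
  tr <- sample(n, 110)
  grid <- as.matrix(expand.grid(seq(-2, 2, length.out = 20),
                                seq(-2, 2, length.out = 20)))
  mu_grid <- ann_forward(truth, grid)
  r2s <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    net <- ann_init(ann_network("ffw", 2, 3), X[tr, ])
    rec <- train_lm(net, X[tr, ], y[tr], X[-tr, ], y[-tr], max_iter = 100)
    cor(ann_forward(reconstitute(rec), grid), mu_grid)^2
  }, numeric(1))
  expect_gte(max(r2s), 0.95)           # best of restarts always recovers
  expect_gte(mean(r2s >= 0.95), 0.8)   # and most individual restarts do
})
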