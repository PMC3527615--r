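#' Root-mean-squared error
#'
#' @param predictions,observations equal-length numeric vectors.
#' @return `sqrt(mean((predictions - observations)^2))`.
#' @export
rmse <- function(predictions, observations) {
  if (length(predictions) != length(observations) ||
      length(predictions) < 1) {
    stop("'predictions' and 'observations' must have equal length >= 1")
  }
  sqrt(mean((predictions - observations)^2))
}

#' Train a network by Levenberg-Marquardt with a full training record
#'
#' Runs exactly `max_iter` outer Levenberg-Marquardt iterations on the
#' training data. Each outer iteration proposes the damped Gauss-Newton
#' step `delta = -(J'J + mu I)^-1 J'r` on the training residuals; the step
#' is accepted if it decreases the training sum of squares, whereupon `mu`
#' is divided by 10. Otherwise `mu` is multiplied by 10 and the step
#' re-proposed, up to 10 inner attempts per iteration (the parameters are
#' left unchanged for that iteration if all attempts fail). The test data
#' are evaluated at every iteration but never influence the update.
#'
#' The returned record holds, for iterations 0..`max_iter`, the parameter
#' snapshot and the train/test RMSE, which is what early stopping by
#' [reconstitute()] consumes.
#'
#' @param net an initialized `"ann_network"`.
#' @param x_train,y_train training inputs (n x d matrix) and targets.
#' @param x_test,y_test held-out data monitored for early stopping; may be
#'   `NULL`, in which case the combined criterion reduces to training RMSE.
#' @param max_iter number of outer iterations (100 in the reference
#'   protocol).
#' @param mu0,mu_min,mu_max initial damping and its bounds.
#' @return object of class `"ann_record"`: list with `theta` (a
#'   `(max_iter + 1) x n_params` snapshot matrix), `rmse_train`,
#'   `rmse_test`, `mu` (damping after each iteration), `net` (the network
#'   skeleton), and `failed` (`TRUE` if the normal equations were singular
#'   at every damping level at some iteration).
#' @export
train_lm <- function(net, x_train, y_train, x_test = NULL, y_test = NULL,
                     max_iter = 100L, mu0 = 1e-2, mu_min = 1e-12,
                     mu_max = 1e12) {
  x_train <- .as_input_matrix(x_train, net$d)
  stopifnot(nrow(x_train) >= 1, length(y_train) == nrow(x_train))
  has_test <- !is.null(x_test)
  if (has_test) {
    x_test <- .as_input_matrix(x_test, net$d)
    stopifnot(length(y_test) == nrow(x_test))
  }
  if (is.null(net$theta)) stop("network must be initialized before training")

  p <- n_params(net)
  theta <- net$theta
  snapshots <- matrix(NA_real_, max_iter + 1, p)
  rmse_tr <- rmse_te <- rep(NA_real_, max_iter + 1)
  mu_trace <- rep(NA_real_, max_iter + 1)
  failed <- FALSE

  eval_rmse <- function(theta) {
    net$theta <- theta
    tr <- rmse(ann_forward(net, x_train), y_train)
    te <- if (has_test) rmse(ann_forward(net, x_test), y_test) else NA_real_
    c(tr, te)
  }

  snapshots[1, ] <- theta
  e <- eval_rmse(theta)
  rmse_tr[1] <- e[1]
  rmse_te[1] <- e[2]
  mu <- mu0
  mu_trace[1] <- mu
  sse <- e[1]^2 * nrow(x_train)

  for (it in seq_len(max_iter)) {
    net$theta <- theta
    r <- ann_forward(net, x_train) - y_train
    J <- ann_jacobian(net, x_train)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    solved_any <- FALSE
    for (attempt in seq_len(10)) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, p), -g),
        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        solved_any <- TRUE
        theta_new <- theta + drop(delta)
        net$theta <- theta_new
        pred <- ann_forward(net, x_train)
        sse_new <- sum((pred - y_train)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new
          sse <- sse_new
          mu <- max(mu / 10, mu_min)
          accepted <- TRUE
          break
        }
      }
      mu <- min(mu * 10, mu_max)
    }
    if (!solved_any) failed <- TRUE
    snapshots[it + 1, ] <- theta
    e <- eval_rmse(theta)
    rmse_tr[it + 1] <- e[1]
    rmse_te[it + 1] <- e[2]
    mu_trace[it + 1] <- mu
  }

  structure(list(theta = snapshots, rmse_train = rmse_tr,
                 rmse_test = rmse_te, mu = mu_trace,
                 net = ann_network(net$type, net$d,
                                   if (net$type == "linear") 5L else net$h),
                 failed = failed),
            class = "ann_record")
}

#' Combined train + test RMSE trajectory of a training record
#'
#' @param record an `"ann_record"`.
#' @return numeric vector over iterations 0..max_iter; equals the training
#'   RMSE when the record has no test data.
#' @export
combined_rmse <- function(record) {
  if (all(is.na(record$rmse_test))) record$rmse_train
  else record$rmse_train + record$rmse_test
}

#' Reconstitute a network at the combined-RMSE minimum
#'
#' Training is taken to have converged at the iteration where the sum of
#' training and test RMSE is minimal; the corresponding parameter snapshot
#' is retrieved from the record. Ties break toward the earliest iteration.
#'
#' @param record an `"ann_record"` from [train_lm()].
#' @return the network with `theta` restored from the snapshot; the
#'   0-based converged iteration index is attached as attribute
#'   `"iteration"`, its combined RMSE as `"rmse"`.
#' @export
reconstitute <- function(record) {
  comb <- combined_rmse(record)
  if (!length(comb)) stop("empty training record")
  i <- which.min(comb)   # earliest index on ties
  net <- record$net
  net$theta <- record$theta[i, ]
  attr(net, "iteration") <- i - 1L
  attr(net, "rmse") <- comb[i]
  net
}
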