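#' Fit a regression neural network with early stopping
#'
#' The central fitting function of the package. Standardizes the covariates
#' and the response to zero mean and unit variance (scaler fitted on the
#' union of `data` and `test`, matching the protocol of scaling all
#' seasonal data before training), draws a random initialization anchored
#' in the data range, trains by Levenberg-Marquardt for `max_iter`
#' iterations while recording train/test RMSE at every iteration, and
#' reconstitutes the parameters at the minimum of the combined (train +
#' test) RMSE.
#'
#' @param formula a formula such as `hna_1e5_ml ~ chl_a_ug_l +
#'   temperature_c`; only plain column references are supported.
#' @param data training data frame.
#' @param test held-out data frame used solely for the early-stopping
#'   record; `NULL` disables cross-validated stopping.
#' @param type network family, `"ffw"`, `"rbf"` or `"linear"`.
#' @param hidden hidden units / basis functions (2..15).
#' @param max_iter outer Levenberg-Marquardt iterations.
#' @param seed integer seed for the random initialization; `NULL` uses the
#'   current random stream.
#' @param scaler optionally, a prefitted `"ann_scaler"` covering all model
#'   columns (used by the search machinery so every candidate shares one
#'   scaler); by default a scaler is fitted from the supplied data.
#' @return object of class `"ann"`, with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot`.
#' @examples
#' tab <- generate_seasonal(generator_config(seed = 42))
#' parts <- split_train_test(tab, seed = 1)
#' fit <- ann_fit(hna_1e5_ml ~ chl_a_ug_l + temperature_c,
#'                data = parts$train, test = parts$test,
#'                type = "ffw", hidden = 4, max_iter = 30, seed = 1)
#' summary(fit)
#' @export
ann_fit <- function(formula, data, test = NULL,
                    type = c("ffw", "rbf", "linear"), hidden = 5L,
                    max_iter = 100L, seed = NULL, scaler = NULL) {
  type <- match.arg(type)
  response <- all.vars(formula[[2]])
  inputs <- setdiff(all.vars(formula[[3]]), ".")
  if (length(response) != 1 || length(inputs) < 1) {
    stop("formula must have one response and at least one covariate")
  }
  cols <- c(inputs, response)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("column(s) not in data: ", paste(missing, collapse = ", "))
  }

  if (is.null(scaler)) {
    pool <- if (is.null(test)) data[cols] else
      rbind(data[cols], test[cols])
    scaler <- fit_scaler(pool, cols)
  }
  sc_train <- apply_scaler(scaler, data[cols])
  x_train <- as.matrix(sc_train[inputs])
  y_train <- sc_train[[response]]
  x_test <- y_test <- NULL
  if (!is.null(test)) {
    sc_test <- apply_scaler(scaler, test[cols])
    x_test <- as.matrix(sc_test[inputs])
    y_test <- sc_test[[response]]
  }

  if (!is.null(seed)) set.seed(seed)
  net <- ann_init(ann_network(type, length(inputs), hidden), x_train)
  record <- train_lm(net, x_train, y_train, x_test, y_test,
                     max_iter = max_iter)
  best <- reconstitute(record)

  obj <- structure(
    list(call = match.call(), formula = formula, type = type,
         hidden = best$h, inputs = inputs, response = response,
         net = best, record = record, scaler = scaler,
         converged_iteration = attr(best, "iteration"),
         converged_rmse = attr(best, "rmse"),
         seed = seed,
         train_range = apply(x_train, 2, range)),
    class = "ann")
  obj$fitted_train <- predict(obj, data)
  obj$observed_train <- data[[response]]
  if (!is.null(test)) {
    obj$fitted_test <- predict(obj, test)
    obj$observed_test <- test[[response]]
  }
  obj
}

#' @export
print.ann <- function(x, ...) {
  cat(sprintf("%s network: %s ~ %s\n",
              toupper(x$type), x$response, paste(x$inputs, collapse = " + ")))
  if (x$type != "linear") {
    cat(sprintf("  %d hidden units, %d parameters\n",
                x$hidden, n_params(x$net)))
  }
  cat(sprintf("  converged at iteration %d of %d (combined RMSE %.4f)\n",
              x$converged_iteration, length(x$record$rmse_train) - 1L,
              x$converged_rmse))
  invisible(x)
}

#' @export
coef.ann <- function(object, ...) {
  theta <- object$net$theta
  blocks <- ann_unpack(object$net)
  nm <- unlist(lapply(names(blocks), function(b) {
    len <- length(blocks[[b]])
    if (len == 1) b else paste0(b, seq_len(len))
  }))
  stats::setNames(theta, nm)
}

#' Predict abundances from a fitted network
#'
#' Covariates are standardized with the model's scaler, the network
#' evaluated, and predictions mapped back to natural abundance units.
#' Predictions are deliberately not clipped at zero: negative values are a
#' meaningful diagnostic of extrapolation beyond the training support.
#'
#' @param object an `"ann"` fit.
#' @param newdata data frame containing the model's covariate columns.
#' @param ... unused.
#' @return numeric vector of predictions in natural units.
#' @export
predict.ann <- function(object, newdata, ...) {
  missing <- setdiff(object$inputs, names(newdata))
  if (length(missing)) {
    stop("newdata lacks column(s): ", paste(missing, collapse = ", "))
  }
  sc <- apply_scaler(object$scaler, newdata[object$inputs])
  yhat <- ann_forward(object$net, as.matrix(sc))
  invert_scaler(object$scaler, yhat, object$response)
}

#' @export
fitted.ann <- function(object, ...) object$fitted_train

#' @export
residuals.ann <- function(object, ...) {
  object$observed_train - object$fitted_train
}

#' Summarize a fitted network
#'
#' Reports the converged iteration, RMSE on the scaled training/test data
#' at convergence, and the observed-versus-predicted least-squares
#' regression on the pooled train + test rows in natural units (slope,
#' intercept, r-squared) -- the quantities the model-selection protocol
#' judges candidates by.
#'
#' @param object an `"ann"` fit.
#' @param ... unused.
#' @return object of class `"summary.ann"`.
#' @export
summary.ann <- function(object, ...) {
  obs <- c(object$observed_train, object$observed_test)
  pred <- c(object$fitted_train, object$fitted_test)
  fit <- tryCatch(linfit(pred, obs), error = function(e) NULL)
  i <- object$converged_iteration + 1L
  structure(list(
    model = object,
    rmse_train = object$record$rmse_train[i],
    rmse_test = object$record$rmse_test[i],
    obs_vs_pred = fit), class = "summary.ann")
}

#' @export
print.summary.ann <- function(x, ...) {
  print(x$model)
  cat(sprintf("  RMSE at convergence: train %.4f, test %s\n",
              x$rmse_train,
              ifelse(is.na(x$rmse_test), "-", sprintf("%.4f", x$rmse_test))))
  if (!is.null(x$obs_vs_pred)) {
    f <- x$obs_vs_pred
    cat(sprintf(
      "  observed vs predicted (train+test): r2 %.3f, y = %.3f + %.3f x\n",
      f$r2, f$intercept, f$slope))
  }
  invisible(x)
}

#' Diagnostic plot of a fitted network
#'
#' Left panel: train/test RMSE trajectories over the Levenberg-Marquardt
#' iterations with the reconstitution point marked. Right panel: observed
#' versus predicted abundances with the 1:1 line.
#'
#' @param x an `"ann"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ann <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  iters <- seq_along(x$record$rmse_train) - 1L
  graphics::plot(iters, x$record$rmse_train, type = "l",
                 xlab = "iteration", ylab = "RMSE (scaled units)",
                 ylim = range(c(x$record$rmse_train, x$record$rmse_test),
                              na.rm = TRUE), ...)
  if (!all(is.na(x$record$rmse_test))) {
    graphics::lines(iters, x$record$rmse_test, lty = 2)
  }
  graphics::abline(v = x$converged_iteration, col = "grey60")
  graphics::legend("topright", legend = c("train", "test"), lty = 1:2,
                   bty = "n")
  obs <- c(x$observed_train, x$observed_test)
  pred <- c(x$fitted_train, x$fitted_test)
  graphics::plot(pred, obs, xlab = "predicted", ylab = "observed", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a fitted network to JSON / restore it
#'
#' Stores the family, architecture, parameter vector, formula and scaler so
#' a fit can be reloaded and used for prediction without the training data.
#'
#' @param object an `"ann"` fit.
#' @param path file path of the JSON document.
#' @return `write_ann` returns `path` invisibly; `read_ann` returns an
#'   `"ann"` object (without the training record).
#' @export
write_ann <- function(object, path) {
  stopifnot(inherits(object, "ann"))
  payload <- list(
    type = object$type, hidden = object$hidden,
    inputs = object$inputs, response = object$response,
    theta = object$net$theta,
    converged_iteration = object$converged_iteration,
    converged_rmse = object$converged_rmse,
    scaler = list(columns = object$scaler$columns,
                  mean = as.list(object$scaler$mean),
                  sd = as.list(object$scaler$sd)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(list(columns = payload$scaler$columns,
                           mean = unlist(payload$scaler$mean),
                           sd = unlist(payload$scaler$sd)),
                      class = "ann_scaler")
  net <- ann_network(payload$type, length(payload$inputs),
                     if (payload$type == "linear") 5L else payload$hidden,
                     theta = payload$theta)
  structure(
    list(call = NULL,
         formula = stats::reformulate(payload$inputs, payload$response),
         type = payload$type, hidden = payload$hidden,
         inputs = payload$inputs, response = payload$response,
         net = net, record = NULL, scaler = scaler,
         converged_iteration = payload$converged_iteration,
         converged_rmse = payload$converged_rmse),
    class = "ann")
}
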