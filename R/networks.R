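#' Construct a regression network
#'
#' Builds the parameter container for one of the three supported regression
#' families:
#'
#' * `"ffw"` -- one sigmoid hidden layer and a linear output unit. Bias
#'   terms (a fixed input of 1) feed both the hidden and the output layer:
#'   `yhat = sum_j w2_j * sigmoid(w1_j . x + b1_j) + b2`.
#'   Parameter count `h * (d + 1) + (h + 1)`.
#' * `"rbf"` -- a weighted sum of isotropic Gaussian bumps plus an output
#'   bias (the only bias in this family):
#'   `yhat = sum_j w_j * exp(-||x - c_j||^2 / (2 * lambda_j^2)) + b`.
#'   Parameter count `h * (d + 2) + 1`.
#' * `"linear"` -- `yhat = w . x + b`, the degenerate member used as a
#'   closed-form baseline and in optimizer checks. Parameter count `d + 1`.
#'
#' Parameters live in a single numeric vector `theta`; [ann_unpack()] and
#' [ann_pack()] convert between the vector and named blocks.
#'
#' @param type `"ffw"`, `"rbf"` or `"linear"`.
#' @param n_inputs number of input covariates `d`.
#' @param hidden number of hidden units / basis functions `h` (2..15 for the
#'   nonlinear families; ignored for `"linear"`).
#' @param theta optional parameter vector of the correct length; if `NULL`
#'   the network is created unparameterized and must be initialized with
#'   [ann_init()].
#' @return object of class `"ann_network"`.
#' @export
ann_network <- function(type = c("ffw", "rbf", "linear"), n_inputs,
                        hidden = 5L, theta = NULL) {
  type <- match.arg(type)
  stopifnot(n_inputs >= 1)
  hidden <- as.integer(hidden)
  if (type != "linear" && (hidden < 2 || hidden > 15)) {
    stop("'hidden' must lie in [2, 15]")
  }
  net <- structure(list(type = type, d = as.integer(n_inputs),
                        h = if (type == "linear") 0L else hidden,
                        theta = NULL),
                   class = "ann_network")
  if (!is.null(theta)) {
    if (length(theta) != n_params(net)) {
      stop("theta has length ", length(theta), "; expected ", n_params(net))
    }
    if (!all(is.finite(theta))) stop("theta must be finite")
    net$theta <- as.numeric(theta)
  }
  net
}

#' Number of free parameters of a network
#' @param net an `"ann_network"`.
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  d <- net$d
  h <- net$h
  as.integer(switch(net$type,
                    ffw = h * (d + 1) + (h + 1),
                    rbf = h * (d + 2) + 1,
                    linear = d + 1))
}

#' Convert between the parameter vector and named blocks
#'
#' `ann_unpack` splits `theta` into the family's named parameter blocks
#' (weight matrices are `h x d`, stored column-major); `ann_pack` is its
#' inverse, so `ann_pack(net, ann_unpack(net, v)) == v`.
#'
#' @param net an `"ann_network"`.
#' @param theta parameter vector (defaults to the one stored in `net`).
#' @return `ann_unpack`: a named list of blocks; `ann_pack`: a numeric
#'   vector.
#' @export
ann_unpack <- function(net, theta = net$theta) {
  d <- net$d
  h <- net$h
  switch(net$type,
    ffw = list(W1 = matrix(theta[seq_len(h * d)], h, d),
               b1 = theta[h * d + seq_len(h)],
               w2 = theta[h * (d + 1) + seq_len(h)],
               b2 = theta[h * (d + 2) + 1]),
    rbf = list(C = matrix(theta[seq_len(h * d)], h, d),
               lambda = theta[h * d + seq_len(h)],
               w = theta[h * (d + 1) + seq_len(h)],
               b = theta[h * (d + 2) + 1]),
    linear = list(w = theta[seq_len(d)], b = theta[d + 1]))
}

#' @rdname ann_unpack
#' @param blocks a named list as produced by `ann_unpack`.
#' @export
ann_pack <- function(net, blocks) {
  switch(net$type,
         ffw = c(as.numeric(blocks$W1), blocks$b1, blocks$w2, blocks$b2),
         rbf = c(as.numeric(blocks$C), blocks$lambda, blocks$w, blocks$b),
         linear = c(blocks$w, blocks$b))
}

#' Forward evaluation of a network
#'
#' @param net a parameterized `"ann_network"`.
#' @param X numeric matrix (n x d) of inputs in the units the network was
#'   trained in (normally standardized covariates).
#' @return numeric vector of n predictions.
#' @export
ann_forward <- function(net, X) {
  X <- .as_input_matrix(X, net$d)
  if (is.null(net$theta)) stop("network is not parameterized")
  p <- ann_unpack(net)
  switch(net$type,
    ffw = {
      A <- X %*% t(p$W1) + matrix(p$b1, nrow(X), net$h, byrow = TRUE)
      S <- stats::plogis(A)
      drop(S %*% p$w2) + p$b2
    },
    rbf = {
      Phi <- .rbf_basis(X, p)$Phi
      drop(Phi %*% p$w) + p$b
    },
    linear = drop(X %*% p$w) + p$b)
}

.as_input_matrix <- function(X, d) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = d)
  if (ncol(X) != d) {
    stop("input matrix has ", ncol(X), " columns; network expects ", d)
  }
  storage.mode(X) <- "double"
  X
}

.rbf_basis <- function(X, p) {
  # squared distances to every center, n x h
  D2 <- outer(rowSums(X^2), rowSums(p$C^2), "+") - 2 * X %*% t(p$C)
  D2[D2 < 0] <- 0
  Phi <- exp(sweep(D2, 2, -2 * p$lambda^2, "/"))
  list(D2 = D2, Phi = Phi)
}

#' Jacobian of the residuals with respect to the parameters
#'
#' Analytic derivatives `d(yhat_i - y_i)/d theta_k = d yhat_i / d theta_k`
#' for every parameter of the network, in the same order as `theta`.
#' This is the workhorse of the Levenberg-Marquardt update.
#'
#' @param net a parameterized `"ann_network"`.
#' @param X numeric matrix (n x d).
#' @return numeric matrix (n x n_params).
#' @export
ann_jacobian <- function(net, X) {
  X <- .as_input_matrix(X, net$d)
  if (is.null(net$theta) || !all(is.finite(net$theta))) {
    stop("network parameters must be finite")
  }
  n <- nrow(X)
  d <- net$d
  h <- net$h
  p <- ann_unpack(net)
  switch(net$type,
    ffw = {
      A <- X %*% t(p$W1) + matrix(p$b1, n, h, byrow = TRUE)
      S <- stats::plogis(A)
      G <- S * (1 - S) * matrix(p$w2, n, h, byrow = TRUE)  # d yhat / d a_j
      J <- matrix(0, n, n_params(net))
      for (k in seq_len(d)) {
        J[, (k - 1) * h + seq_len(h)] <- G * X[, k]        # W1[, k]
      }
      J[, h * d + seq_len(h)] <- G                          # b1
      J[, h * (d + 1) + seq_len(h)] <- S                    # w2
      J[, h * (d + 2) + 1] <- 1                             # b2
      J
    },
    rbf = {
      bas <- .rbf_basis(X, p)
      Phi <- bas$Phi
      WPhi <- Phi * matrix(p$w, n, h, byrow = TRUE)
      inv_l2 <- matrix(1 / p$lambda^2, n, h, byrow = TRUE)
      J <- matrix(0, n, n_params(net))
      for (k in seq_len(d)) {                               # C[, k]
        diff_k <- outer(X[, k], p$C[, k], "-")
        J[, (k - 1) * h + seq_len(h)] <- WPhi * diff_k * inv_l2
      }
      J[, h * d + seq_len(h)] <-                            # lambda
        WPhi * bas$D2 * matrix(1 / p$lambda^3, n, h, byrow = TRUE)
      J[, h * (d + 1) + seq_len(h)] <- Phi                  # w
      J[, h * (d + 2) + 1] <- 1                             # b
      J
    },
    linear = cbind(X, 1))
}

#' Random initialization of a network from the data range
#'
#' Nonlinear parameters are randomized within the range of the input data:
#' for FFW networks each hidden unit's direction weights are drawn
#' Uniform(-1, 1) and its bias is set so the unit's sigmoid inflection
#' surface passes through a point drawn uniformly inside the per-dimension
#' data box; for RBF networks the centers are uniform within the
#' per-dimension range and the widths uniform in \[0.2, 2\] times the mean
#' per-dimension spread. Linear parameters (output weights and biases) are
#' iid Uniform(-1, 1). Uses the R random stream; seed with `set.seed()`.
#'
#' @param net an `"ann_network"` (parameterized or not).
#' @param X training input matrix whose per-column ranges anchor the draw.
#' @return the network with a freshly drawn `theta`.
#' @export
ann_init <- function(net, X) {
  X <- .as_input_matrix(X, net$d)
  if (nrow(X) == 0) stop("training data must be non-empty")
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (any(hi - lo <= 0)) {
    stop("degenerate (zero-range) input column; cannot initialize")
  }
  d <- net$d
  h <- net$h
  blocks <- switch(net$type,
    ffw = {
      W1 <- matrix(stats::runif(h * d, -1, 1), h, d)
      # anchor each unit's inflection surface at a point inside the data box
      P <- sapply(seq_len(d), function(k) stats::runif(h, lo[k], hi[k]))
      P <- matrix(P, h, d)
      list(W1 = W1, b1 = -rowSums(W1 * P),
           w2 = stats::runif(h, -1, 1), b2 = stats::runif(1, -1, 1))
    },
    rbf = {
      C <- sapply(seq_len(d), function(k) stats::runif(h, lo[k], hi[k]))
      list(C = matrix(C, h, d),
           lambda = stats::runif(h, 0.2, 2) * mean(hi - lo),
           w = stats::runif(h, -1, 1), b = stats::runif(1, -1, 1))
    },
    linear = list(w = stats::runif(d, -1, 1), b = stats::runif(1, -1, 1)))
  net$theta <- ann_pack(net, blocks)
  net
}
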