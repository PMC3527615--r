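#' Linear least-squares regression with uncertainty
#'
#' Ordinary least squares of `y` on `x` returning the quantities the model
#' evaluation protocol needs: intercept and slope with their standard
#' errors, the coefficient of determination (squared Pearson correlation),
#' the residual SD and the sample size.
#'
#' @param x predictor (e.g. model predictions).
#' @param y response (e.g. observed abundances).
#' @return object of class `"linfit"`.
#' @export
linfit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) {
    stop("degenerate fit: predictor has zero variance")
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  cf <- s$coefficients
  structure(list(
    intercept = unname(cf[1, 1]), slope = unname(cf[2, 1]),
    se_intercept = unname(cf[1, 2]), se_slope = unname(cf[2, 2]),
    r2 = s$r.squared, n = length(x), sigma = s$sigma),
    class = "linfit")
}

#' @export
print.linfit <- function(x, ...) {
  cat(sprintf("y = %.4f + %.4f x  (r2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r2, x$n))
  cat(sprintf("  SE(intercept) = %.4f, SE(slope) = %.4f\n",
              x$se_intercept, x$se_slope))
  invisible(x)
}

#' Test a regression coefficient against a theoretical value
#'
#' Computes `t = |b - B| / Sb` with `n - 2` degrees of freedom, i.e. the
#' t-statistic of the fitted slope (or intercept) against a constant
#' theoretical value `B` -- typically 1 for the slope and 0 for the
#' intercept of an observed-versus-predicted regression. A theoretical
#' constant carries no sampling SD, so its SD term is zero.
#'
#' @param fit a `"linfit"`.
#' @param which `"slope"` or `"intercept"`.
#' @param value the theoretical value `B`.
#' @return list with `t`, the two-tailed `p`, and `df = n - 2`.
#' @export
t_vs_theory <- function(fit, which = c("slope", "intercept"), value) {
  which <- match.arg(which)
  b <- fit[[which]]
  se <- fit[[paste0("se_", which)]]
  df <- fit$n - 2
  if (se == 0) {
    if (b == value) return(list(t = 0, p = 1, df = df))
    return(list(t = Inf, p = 0, df = df))
  }
  t <- abs(b - value) / se
  list(t = t, p = 2 * stats::pt(-t, df = df), df = df)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided Student's t-test for a difference in means
#' between two samples (Welch's unpooled variant available via
#' `var_equal = FALSE`).
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param var_equal pool the variances (classical Student's test)?
#' @return list with `t` and `p`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(c(a, b)) == 0) return(list(t = 0, p = 1))
  res <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(res$statistic), p = res$p.value)
}

#' Stepwise multiple linear regression (p-value criterion)
#'
#' Bidirectional stepwise selection: at each round the excluded predictor
#' with the smallest partial-F p-value enters if that p-value is at most
#' `alpha_enter`, then any included predictor whose p-value exceeds
#' `alpha_remove` is removed (worst first); the loop runs to a fixed point.
#' With a single-predictor step the partial F equals the squared coefficient
#' t, so the coefficient t-test p-values drive both directions. If nothing
#' enters, the intercept-only model is returned (a valid result).
#'
#' @param y response vector.
#' @param X data frame of offered predictors.
#' @param alpha_enter,alpha_remove entry/removal thresholds (0.05 in the
#'   reference protocol).
#' @return object of class `"smlr"`: the selected predictors, their
#'   coefficient table (estimate, SE, t, p), the overall F-ratio and its
#'   p-value, r-squared, and the underlying `lm` fit.
#' @export
smlr <- function(y, X, alpha_enter = 0.05, alpha_remove = 0.05) {
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  if (length(y) <= ncol(X) + 2) {
    stop("need n > number of predictors + 2")
  }
  dat <- cbind(.y = y, X)
  selected <- character(0)
  pool <- names(X)
  repeat {
    changed <- FALSE
    # forward entry
    candidates <- setdiff(pool, selected)
    if (length(candidates)) {
      pvals <- vapply(candidates, function(v) {
        f <- stats::lm(stats::reformulate(c(selected, v), ".y"), data = dat)
        stats::coef(summary(f))[v, "Pr(>|t|)"]
      }, numeric(1))
      if (min(pvals) <= alpha_enter) {
        selected <- c(selected, candidates[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward removal
    repeat {
      if (!length(selected)) break
      f <- stats::lm(stats::reformulate(selected, ".y"), data = dat)
      pv <- stats::coef(summary(f))[selected, "Pr(>|t|)", drop = TRUE]
      if (max(pv) > alpha_remove) {
        selected <- setdiff(selected, selected[which.max(pv)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  form <- if (length(selected)) stats::reformulate(selected, ".y") else
    stats::as.formula(".y ~ 1")
  fit <- stats::lm(form, data = dat)
  s <- summary(fit)
  fstat <- if (is.null(s$fstatistic)) c(value = NA_real_) else s$fstatistic
  structure(list(
    selected = selected,
    coefficients = stats::coef(s),
    f_ratio = unname(fstat[1]),
    p_overall = if (is.na(fstat[1])) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    r2 = s$r.squared,
    fit = fit), class = "smlr")
}

#' @export
print.smlr <- function(x, ...) {
  if (length(x$selected)) {
    cat("SMLR model:", paste(x$selected, collapse = " + "), "\n")
    cat(sprintf("  F = %.1f, r2 = %.3f, p = %.3g\n",
                x$f_ratio, x$r2, x$p_overall))
  } else {
    cat("SMLR model: intercept only (no predictor entered)\n")
  }
  invisible(x)
}

#' @export
predict.smlr <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Per-column summary statistics of a table
#'
#' Average, SD (n-1), minimum, maximum, coefficient of variation
#' (`100 * SD / |Avg|`) and sample size for every numeric column -- the
#' layout of a campaign summary table.
#'
#' @param table a data frame.
#' @return data frame with one row per numeric column and columns
#'   `column`, `avg`, `sd`, `min`, `max`, `cv`, `n`.
#' @export
env_summary <- function(table) {
  cols <- names(table)[vapply(table, is.numeric, logical(1))]
  out <- do.call(rbind, lapply(cols, function(col) {
    x <- table[[col]]
    m <- mean(x)
    s <- stats::sd(x)
    data.frame(column = col, avg = m, sd = s, min = min(x), max = max(x),
               cv = if (m == 0) NA_real_ else 100 * s / abs(m),
               n = length(x))
  }))
  rownames(out) <- NULL
  out
}
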