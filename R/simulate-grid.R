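#' Simulate abundances over a grid of environmental conditions
#'
#' Evaluates a fitted model at every node of a rectangular grid spanned by
#' the given axes, holding any remaining model input fixed. Predictions are
#' returned in natural abundance units and deliberately not clipped at
#' zero: negative values flag conditions outside what the data support.
#' Nodes lying outside the model's training range, or in empty bins of a
#' data-support histogram when one is supplied, are marked as
#' extrapolations.
#'
#' @param model an `"ann"` fit.
#' @param axes named list defining the grid: each element is either a
#'   numeric vector of levels or a length-2 `c(min, max)` expanded to
#'   `n_points` equally spaced values. Names are schema columns.
#' @param fixed named list of constant values for model inputs not on an
#'   axis. `names(axes)` plus `names(fixed)` must cover the model's inputs
#'   exactly.
#' @param support optional schema data frame (normally the seasonal table);
#'   grid nodes falling in empty bins of its histogram over the axis
#'   variables are flagged as extrapolation.
#' @param n_points grid resolution for `c(min, max)` axes.
#' @param bins number of bins per axis for the support histogram.
#' @return object of class `"ann_grid"`: `axes` (expanded), `values` and
#'   `extrapolated` arrays with `dim = lengths(axes)`, plus `fixed` and the
#'   model's response name.
#' @export
simulate_grid <- function(model, axes, fixed = list(), support = NULL,
                          n_points = 50L, bins = 12L) {
  stopifnot(length(axes) >= 1, !is.null(names(axes)), all(names(axes) != ""))
  covered <- c(names(axes), names(fixed))
  if (!setequal(covered, model$inputs)) {
    stop("axes + fixed must cover exactly the model inputs: ",
         paste(model$inputs, collapse = ", "))
  }
  axes <- lapply(axes, function(a) {
    if (length(a) == 2 && is.null(dim(a))) seq(a[1], a[2],
                                               length.out = n_points)
    else as.numeric(a)
  })
  grid <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))
  for (v in names(fixed)) grid[[v]] <- fixed[[v]]
  pred <- predict(model, grid)
  dims <- unname(lengths(axes))

  extra <- rep(FALSE, nrow(grid))
  rng <- model$train_range
  if (!is.null(rng)) {
    sc <- apply_scaler(model$scaler, grid[model$inputs])
    for (j in seq_along(model$inputs)) {
      out_of <- sc[[j]] < rng[1, j] - 1e-9 | sc[[j]] > rng[2, j] + 1e-9
      extra <- extra | out_of
    }
    if (any(extra)) {
      warning(sum(extra), " grid node(s) lie outside the training range; ",
              "flagged as extrapolation")
    }
  }
  if (!is.null(support)) {
    hist <- support_histogram(support, names(axes), bins = bins)
    idx <- mapply(function(v, brk) {
      findInterval(grid[[v]], brk, rightmost.closed = TRUE,
                   all.inside = TRUE)
    }, names(axes), hist$breaks, SIMPLIFY = FALSE)
    flat <- do.call(cbind, idx)
    extra <- extra | (hist$counts[flat] == 0)
  }

  structure(list(
    axes = axes,
    values = array(pred, dim = dims),
    extrapolated = array(extra, dim = dims),
    fixed = fixed, response = model$response),
    class = "ann_grid")
}

#' Sum two simulation grids node-wise
#'
#' Total abundance grids (all prokaryotes, all viruses) are the node-wise
#' sum of the component population grids, which must share identical axes.
#'
#' @param grid_a,grid_b `"ann_grid"` objects on identical axes.
#' @return an `"ann_grid"` whose values are the sums; a node is flagged as
#'   extrapolation if it is in either component.
#' @export
total_grid <- function(grid_a, grid_b) {
  same <- identical(names(grid_a$axes), names(grid_b$axes)) &&
    all(mapply(function(a, b) length(a) == length(b) &&
                 max(abs(a - b)) < 1e-12, grid_a$axes, grid_b$axes))
  if (!isTRUE(same)) stop("grids have mismatching axes")
  structure(list(
    axes = grid_a$axes,
    values = grid_a$values + grid_b$values,
    extrapolated = grid_a$extrapolated | grid_b$extrapolated,
    fixed = grid_a$fixed,
    response = paste(grid_a$response, grid_b$response, sep = "+")),
    class = "ann_grid")
}

#' Data-support histogram over simulation axes
#'
#' Bins a table over one or two (or more) variables with equal-width bins
#' spanning each variable's data range. Counts always sum to the number of
#' rows. Zero-count bins mark regions of the simulation space where model
#' predictions rest on extrapolation.
#'
#' @param table a data frame.
#' @param vars character vector of column names (1-D or 2-D typical).
#' @param bins bins per variable.
#' @return list with `counts` (array, `dim = rep(bins, length(vars))`) and
#'   `breaks` (list of break vectors).
#' @export
support_histogram <- function(table, vars, bins = 12L) {
  stopifnot(all(vars %in% names(table)), bins >= 1)
  n <- nrow(table)
  breaks <- lapply(vars, function(v) {
    r <- if (n > 0) range(table[[v]]) else c(0, 1)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  })
  names(breaks) <- vars
  counts <- array(0L, dim = rep(bins, length(vars)))
  if (n > 0) {
    idx <- mapply(function(v, brk) {
      findInterval(table[[v]], brk, rightmost.closed = TRUE,
                   all.inside = TRUE)
    }, vars, breaks, SIMPLIFY = FALSE)
    flat <- do.call(cbind, idx)
    tab <- table(apply(flat, 1, paste, collapse = ","))
    for (cell in names(tab)) {
      ij <- as.integer(strsplit(cell, ",")[[1]])
      counts[matrix(ij, 1)] <- as.integer(tab[[cell]])
    }
  }
  list(counts = counts, breaks = breaks)
}

#' Heat-map display of a 2-D simulation grid
#'
#' @param x an `"ann_grid"` over exactly two axes.
#' @param ... passed to [graphics::image()].
#' @export
plot.ann_grid <- function(x, ...) {
  if (length(x$axes) != 2) stop("plotting requires a 2-D grid")
  graphics::image(x$axes[[1]], x$axes[[2]], x$values,
                  xlab = names(x$axes)[1], ylab = names(x$axes)[2],
                  main = x$response, ...)
  invisible(x)
}
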