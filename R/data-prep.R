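#' Split a table into training and test subsets
#'
#' Random, seeded 80/20 (by default) partition used before network training.
#' The split can be stratified so that every level of a grouping column
#' (sampling date, by default) is represented in both subsets where group
#' sizes permit; within the constraint the assignment is random. Train size
#' is exactly `round(fraction * nrow(table))`.
#'
#' @param table a data frame with at least 5 rows.
#' @param fraction fraction of rows assigned to the training set, in (0, 1).
#' @param seed integer seed making the partition reproducible.
#' @param stratify_by column name to stratify on, or `NULL` for a simple
#'   random split.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1L,
                             stratify_by = "date") {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("'table' must be a non-empty data frame")
  }
  if (nrow(table) < 5) stop("'table' must have at least 5 rows")
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(table)
  n_train <- round(fraction * n)
  set.seed(seed)

  if (is.null(stratify_by)) {
    idx <- sample.int(n, n_train)
  } else {
    if (!stratify_by %in% names(table)) {
      stop("stratification column '", stratify_by, "' not present")
    }
    groups <- split(seq_len(n), table[[stratify_by]])
    sizes <- lengths(groups)
    quota <- floor(fraction * sizes)
    remainder <- n_train - sum(quota)
    if (remainder > 0) {
      frac_part <- fraction * sizes - quota
      # largest-remainder allocation; random among ties
      extra <- order(frac_part + stats::runif(length(groups)) * 1e-9,
                     decreasing = TRUE)[seq_len(remainder)]
      quota[extra] <- quota[extra] + 1
    }
    idx <- unlist(mapply(function(rows, k) {
      if (k == 0) integer(0) else sample(rows, k)
    }, groups, quota, SIMPLIFY = FALSE), use.names = FALSE)
  }
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Zero-mean / unit-variance column scaler
#'
#' `fit_scaler` records each column's mean and SD (n-1 denominator) on the
#' fitting data; `apply_scaler` standardizes those columns of any table;
#' `invert_scaler` maps values of a single column back to natural units.
#' The transform is affine, so applying a scaler fitted on one dataset to
#' another preserves ordering, and invert(apply(x)) = x to machine
#' precision.
#'
#' @param table data frame to fit on.
#' @param columns character vector of numeric columns to scale.
#' @return `fit_scaler`: an object of class `"ann_scaler"` (named means and
#'   SDs); `apply_scaler`: the table with scaled columns; `invert_scaler`:
#'   a numeric vector in natural units.
#' @export
fit_scaler <- function(table, columns) {
  stopifnot(all(columns %in% names(table)))
  m <- vapply(table[columns], mean, numeric(1))
  s <- vapply(table[columns], stats::sd, numeric(1))
  if (any(s == 0)) {
    stop("zero-variance column(s): ",
         paste(columns[s == 0], collapse = ", "))
  }
  structure(list(columns = columns, mean = m, sd = s), class = "ann_scaler")
}

#' @rdname fit_scaler
#' @param scaler an `"ann_scaler"`.
#' @export
apply_scaler <- function(scaler, table) {
  for (col in intersect(scaler$columns, names(table))) {
    table[[col]] <- (table[[col]] - scaler$mean[[col]]) / scaler$sd[[col]]
  }
  table
}

#' @rdname fit_scaler
#' @param values numeric vector in scaled units.
#' @param column which column's scaling to invert.
#' @export
invert_scaler <- function(scaler, values, column) {
  if (!column %in% scaler$columns) stop("column '", column, "' not in scaler")
  values * scaler$sd[[column]] + scaler$mean[[column]]
}

#' @rdname fit_scaler
#' @export
scale_values <- function(scaler, values, column) {
  if (!column %in% scaler$columns) stop("column '", column, "' not in scaler")
  (values - scaler$mean[[column]]) / scaler$sd[[column]]
}

#' Natural-log transform policy for statistical analyses
#'
#' Applies the natural logarithm to depth, chlorophyll and every abundance
#' column present, leaving temperature, salinity and day length untouched
#' (they may legitimately be zero or negative).
#'
#' @param table a schema data frame (subsets of columns are allowed).
#' @return the transformed table.
#' @export
log_policy <- function(table) {
  cols <- intersect(c("depth_m", "chl_a_ug_l", .abundance_columns),
                    names(table))
  for (col in cols) {
    if (any(table[[col]] <= 0)) {
      stop("column '", col, "' has non-positive values; cannot log-transform")
    }
    table[[col]] <- log(table[[col]])
  }
  table
}
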