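#' @name env_table
#' @title The environmental/abundance table schema
#'
#' @description
#' All dataset-level functions in this package operate on a plain
#' `data.frame` with one row per water sample and the columns
#'
#' \tabular{ll}{
#' `station` \tab station identifier (character) \cr
#' `date` \tab sampling date (`Date`) \cr
#' `depth_m` \tab sampling depth, m \cr
#' `temperature_c` \tab water temperature, deg C \cr
#' `salinity_psu` \tab salinity, psu \cr
#' `day_length_h` \tab hours from sunrise to sunset, \[0, 24\] \cr
#' `chl_a_ug_l` \tab chlorophyll-a, ug/L \cr
#' `hna_1e5_ml` \tab high nucleic-acid cells, 1e5/mL \cr
#' `lna_1e5_ml` \tab low nucleic-acid cells, 1e5/mL \cr
#' `prokaryotes_1e5_ml` \tab total prokaryotes = HNA + LNA, 1e5/mL \cr
#' `v1_1e6_ml` \tab high-fluorescence viruses, 1e6/mL \cr
#' `v2_1e6_ml` \tab low-fluorescence viruses, 1e6/mL \cr
#' `viruses_1e6_ml` \tab total viruses = V1 + V2, 1e6/mL \cr
#' }
#'
#' The two sum columns are definitional and recomputed rather than measured.
#' A `kind` attribute tags a table as `"seasonal"` (fixed-station time
#' series) or `"spatial"` (summer survey).
NULL

#' Column names of the environmental table schema
#' @return character vector of the thirteen schema column names, in order.
#' @export
env_table_columns <- function() {
  c("station", "date", "depth_m", "temperature_c", "salinity_psu",
    "day_length_h", "chl_a_ug_l", "hna_1e5_ml", "lna_1e5_ml",
    "prokaryotes_1e5_ml", "v1_1e6_ml", "v2_1e6_ml", "viruses_1e6_ml")
}

# short covariate/population labels used in architecture specs -> columns
.covariate_columns <- c(
  chl_a       = "chl_a_ug_l",
  day_length  = "day_length_h",
  depth       = "depth_m",
  salinity    = "salinity_psu",
  temperature = "temperature_c"
)

.population_columns <- c(
  hna = "hna_1e5_ml",
  lna = "lna_1e5_ml",
  v1  = "v1_1e6_ml",
  v2  = "v2_1e6_ml"
)

.abundance_columns <- c("hna_1e5_ml", "lna_1e5_ml", "prokaryotes_1e5_ml",
                        "v1_1e6_ml", "v2_1e6_ml", "viruses_1e6_ml")

#' Validate an environmental table against the schema
#'
#' Checks column presence, numeric types, strict positivity of abundances
#' and chlorophyll, the day-length range, and row-wise additivity of the two
#' sum columns (warning if violated beyond `1e-6`).
#'
#' @param table a data frame.
#' @param additivity_tol tolerance for `prokaryotes = hna + lna` and
#'   `viruses = v1 + v2` before a warning is raised.
#' @return the table, invisibly, if structurally valid; otherwise an error
#'   naming the offending column (and row where applicable).
#' @export
validate_env_table <- function(table, additivity_tol = 1e-6) {
  missing <- setdiff(env_table_columns(), names(table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(env_table_columns(), c("station", "date"))
  for (col in num_cols) {
    if (!is.numeric(table[[col]])) {
      stop("column '", col, "' is not numeric")
    }
    if (anyNA(table[[col]])) {
      stop("column '", col, "' contains missing values (row ",
           which(is.na(table[[col]]))[1], ")")
    }
  }
  for (col in c(.abundance_columns, "chl_a_ug_l")) {
    bad <- which(table[[col]] <= 0)
    if (length(bad)) {
      stop("column '", col, "' must be strictly positive (row ", bad[1], ")")
    }
  }
  if (any(table$day_length_h < 0 | table$day_length_h > 24)) {
    stop("column 'day_length_h' must lie in [0, 24]")
  }
  if (any(abs(table$prokaryotes_1e5_ml -
              (table$hna_1e5_ml + table$lna_1e5_ml)) > additivity_tol)) {
    warning("additivity violated: prokaryotes_1e5_ml != hna + lna")
  }
  if (any(abs(table$viruses_1e6_ml -
              (table$v1_1e6_ml + table$v2_1e6_ml)) > additivity_tol)) {
    warning("additivity violated: viruses_1e6_ml != v1 + v2")
  }
  invisible(table)
}

#' Read / write an environmental table as CSV
#'
#' The CSV uses exactly the schema header of [env_table_columns()]. Values
#' round-trip at full double precision (15 significant digits).
#'
#' @param path file path.
#' @param kind optional dataset tag (`"seasonal"` or `"spatial"`) attached
#'   as the `kind` attribute on read.
#' @return `read_env_table` returns the validated data frame;
#'   `write_env_table` returns `path` invisibly.
#' @export
read_env_table <- function(path, kind = NULL) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(env_table_columns(), names(table))
  if (length(missing)) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(env_table_columns(), c("station", "date"))
  for (col in num_cols) {
    if (!is.numeric(table[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(table[[col]]))))[1]
      stop("non-numeric value in column '", col, "', row ", bad)
    }
  }
  table$date <- as.Date(table$date)
  validate_env_table(table)
  if (!is.null(kind)) attr(table, "kind") <- kind
  table
}

#' @rdname read_env_table
#' @param table a schema-conforming data frame.
#' @export
write_env_table <- function(table, path) {
  validate_env_table(table)
  out <- table[, env_table_columns()]
  out$date <- format(out$date, "%Y-%m-%d")
  for (col in setdiff(names(out), c("station", "date"))) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
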