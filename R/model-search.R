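#' Enumerate candidate network architectures
#'
#' Builds the full candidate list for one output population: every subset
#' of 1-3 of the five covariates (`chl_a`, `day_length`, `depth`,
#' `salinity`, `temperature`), crossed with hidden-unit counts and network
#' families. At the defaults this yields `(5 + 10 + 10) * 14 * 2 = 700`
#' specifications.
#'
#' @param output population short name: `"hna"`, `"lna"`, `"v1"` or `"v2"`.
#' @param inputs covariate short names to draw subsets from.
#' @param combos optional list of character vectors restricting the input
#'   subsets (overrides free enumeration); each must be a subset of
#'   `inputs` of size 1-3.
#' @param types network families to include.
#' @param hidden vector of hidden-unit counts (within 2..15).
#' @param max_size maximal input-subset size.
#' @return data frame of class `"ann_spec_list"` with columns `output`,
#'   `type`, `hidden` and the list-column `inputs`.
#' @export
enumerate_candidates <- function(output,
                                 inputs = names(.covariate_columns),
                                 combos = NULL,
                                 types = c("ffw", "rbf"),
                                 hidden = 2:15,
                                 max_size = 3) {
  stopifnot(output %in% names(.population_columns),
            all(inputs %in% names(.covariate_columns)),
            all(hidden >= 2), all(hidden <= 15))
  if (is.null(combos)) {
    combos <- unlist(lapply(seq_len(max_size), function(k) {
      utils::combn(inputs, k, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    ok <- vapply(combos, function(s) {
      all(s %in% inputs) && length(s) >= 1 && length(s) <= max_size
    }, logical(1))
    if (!all(ok)) stop("invalid input combination(s) supplied")
  }
  grid <- expand.grid(combo = seq_along(combos), type = types,
                      hidden = hidden, stringsAsFactors = FALSE)
  out <- data.frame(output = output, type = grid$type, hidden = grid$hidden,
                    stringsAsFactors = FALSE)
  out$inputs <- combos[grid$combo]
  class(out) <- c("ann_spec_list", "data.frame")
  out
}

# stable identifier for a spec; anchors the per-restart seed stream so that
# phase 2 extends phase 1's draws for the same architecture
spec_key <- function(output, type, hidden, inputs) {
  paste(output, type, hidden, paste(sort(inputs), collapse = "+"), sep = "|")
}

.string_hash <- function(s) {
  v <- utf8ToInt(s)
  sum(v * 31^(seq_along(v) %% 8)) %% 214748329
}

#' Derive a child seed for one restart of one architecture
#'
#' All randomness in the search flows from a single master seed through
#' this map; the restart stream of an architecture does not depend on which
#' phase (or which shortlist) it appears in, so a 1000-restart screen
#' reuses and extends the draws of a 100-restart screen.
#'
#' @param master master integer seed.
#' @param key spec key string (from the architecture's fields).
#' @param restart 1-based restart index.
#' @return an integer seed in \[1, 2^31).
#' @export
child_seed <- function(master, key, restart) {
  as.integer((as.numeric(master) * 48271 + .string_hash(key) * 7919 +
                as.numeric(restart) * 69621) %% 2147483563 + 1)
}

#' Random-restart screen over candidate architectures
#'
#' For every architecture in `specs`, initializes and trains `restarts`
#' networks (each from its own derived seed), reconstitutes each at its
#' combined-RMSE minimum, and keeps the restart with the smallest combined
#' RMSE. `phase1` and `phase2` are the same screen at different depths: the
#' protocol first screens every candidate with `restarts = 100`, then
#' re-screens the shortlisted architectures with `restarts = 1000`. Because
#' the restart seed stream is architecture-anchored (see [child_seed()]),
#' the phase-2 result for a spec can never be worse than phase 1's.
#'
#' @param specs an `"ann_spec_list"` from [enumerate_candidates()].
#' @param train,test unscaled schema data frames (the 80/20 split).
#' @param scaler an `"ann_scaler"` fitted on the full seasonal table over
#'   all covariate and abundance columns.
#' @param restarts number of random initializations per architecture.
#' @param master_seed master seed anchoring all restart draws.
#' @param max_iter Levenberg-Marquardt iterations per training run.
#' @return data frame of class `"ann_candidates"`: one row per architecture
#'   with `output`, `type`, `hidden`, `inputs` (list), `rmse` (best
#'   combined RMSE at convergence), `seed` (winning restart's seed),
#'   `iteration`, `failed`, and the fitted `"ann"` objects in the
#'   list-column `model`. Architectures whose restarts all failed
#'   numerically are flagged and excluded.
#' @export
search_candidates <- function(specs, train, test, scaler, restarts = 100L,
                              master_seed = 1L, max_iter = 100L) {
  stopifnot(inherits(specs, "ann_spec_list"), nrow(specs) >= 1,
            restarts >= 1)
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    input_cols <- unname(.covariate_columns[sp$inputs[[1]]])
    output_col <- unname(.population_columns[[sp$output]])
    form <- stats::reformulate(input_cols, output_col)
    key <- spec_key(sp$output, sp$type, sp$hidden, sp$inputs[[1]])
    best <- NULL
    best_rmse <- Inf
    best_seed <- NA_integer_
    any_ok <- FALSE
    for (r in seq_len(restarts)) {
      seed <- child_seed(master_seed, key, r)
      fit <- ann_fit(form, data = train, test = test, type = sp$type,
                     hidden = sp$hidden, max_iter = max_iter, seed = seed,
                     scaler = scaler)
      if (fit$record$failed || !is.finite(fit$converged_rmse)) next
      any_ok <- TRUE
      if (fit$converged_rmse < best_rmse) {
        best_rmse <- fit$converged_rmse
        best <- fit
        best_seed <- seed
      }
    }
    rows[[i]] <- list(output = sp$output, type = sp$type,
                      hidden = sp$hidden, inputs = sp$inputs[[1]],
                      rmse = best_rmse, seed = best_seed,
                      iteration = if (any_ok) best$converged_iteration
                                  else NA_integer_,
                      failed = !any_ok, model = best)
  }
  out <- data.frame(
    output = vapply(rows, `[[`, character(1), "output"),
    type = vapply(rows, `[[`, character(1), "type"),
    hidden = vapply(rows, `[[`, numeric(1), "hidden"),
    rmse = vapply(rows, `[[`, numeric(1), "rmse"),
    seed = vapply(rows, `[[`, numeric(1), "seed"),
    iteration = vapply(rows, function(r) as.numeric(r$iteration), numeric(1)),
    failed = vapply(rows, `[[`, logical(1), "failed"),
    stringsAsFactors = FALSE)
  out$inputs <- lapply(rows, `[[`, "inputs")
  out$model <- lapply(rows, `[[`, "model")
  out <- out[!out$failed, , drop = FALSE]
  if (!nrow(out)) stop("every architecture failed numerically")
  out <- out[order(out$rmse), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ann_candidates", "data.frame")
  out
}

#' @rdname search_candidates
#' @export
phase1 <- function(specs, train, test, scaler, restarts = 100L,
                   master_seed = 1L, max_iter = 100L) {
  search_candidates(specs, train, test, scaler, restarts, master_seed,
                    max_iter)
}

#' @rdname search_candidates
#' @param shortlist an `"ann_candidates"` table (typically the top rows of
#'   the phase-1 leaderboard) or an `"ann_spec_list"`.
#' @export
phase2 <- function(shortlist, train, test, scaler, restarts = 1000L,
                   master_seed = 1L, max_iter = 100L) {
  if (!nrow(shortlist)) stop("shortlist must be non-empty")
  if (inherits(shortlist, "ann_candidates")) {
    specs <- shortlist[, c("output", "type", "hidden", "inputs")]
    class(specs) <- c("ann_spec_list", "data.frame")
  } else {
    specs <- shortlist
  }
  search_candidates(specs, train, test, scaler, restarts, master_seed,
                    max_iter)
}

#' Evaluate a model on the independent spatial survey
#'
#' Predicts abundances for the evaluation table in natural units and
#' regresses observed on predicted. The regression's slope `k` and
#' r-squared are the quantities the selection rule consumes.
#'
#' @param model an `"ann"` fit (or anything with a `predict` method and
#'   `response` field).
#' @param spatial the evaluation schema data frame (>= 3 rows).
#' @return a `"linfit"` of observed (y) on predicted (x).
#' @export
evaluate_spatial <- function(model, spatial) {
  if (nrow(spatial) < 3) stop("need at least 3 evaluation rows")
  pred <- predict(model, spatial)
  obs <- spatial[[model$response]]
  linfit(pred, obs)
}

#' Select the best candidate by the slope rule
#'
#' Among candidates whose evaluation r-squared exceeds `r2_min`, picks the
#' one whose evaluation slope is closest to 1; ties break toward the
#' smaller combined training RMSE. If no candidate passes the r-squared
#' gate the result is an explicit no-admissible-model outcome.
#'
#' @param results data frame with (at least) columns `r2_spatial`,
#'   `k_spatial` and `rmse`; typically an [search_candidates()] leaderboard
#'   augmented with evaluation statistics.
#' @param r2_min the r-squared gate (0.5 in the reference protocol).
#' @return object of class `"ann_selection"`: `admissible` flag, the index
#'   `which` of the chosen row (NA when inadmissible), and the chosen row.
#' @export
select_best <- function(results, r2_min = 0.5) {
  stopifnot(nrow(results) >= 1,
            all(c("r2_spatial", "k_spatial", "rmse") %in% names(results)))
  pass <- which(results$r2_spatial > r2_min & is.finite(results$k_spatial))
  if (!length(pass)) {
    return(structure(list(admissible = FALSE, which = NA_integer_,
                          chosen = NULL, r2_min = r2_min),
                     class = "ann_selection"))
  }
  dist <- abs(results$k_spatial[pass] - 1)
  best <- pass[order(dist, results$rmse[pass])][1]
  structure(list(admissible = TRUE, which = best,
                 chosen = results[best, , drop = FALSE], r2_min = r2_min),
            class = "ann_selection")
}

#' @export
print.ann_selection <- function(x, ...) {
  if (!x$admissible) {
    cat(sprintf("no admissible model (no candidate with r2 > %.2f)\n",
                x$r2_min))
  } else {
    ch <- x$chosen
    cat(sprintf(
      "selected %s %s, %d units, inputs {%s}: k-spatial %.3f, r2-spatial %.3f\n",
      ch$output, toupper(ch$type), as.integer(ch$hidden),
      paste(ch$inputs[[1]], collapse = ", "), ch$k_spatial, ch$r2_spatial))
  }
  invisible(x)
}

#' Total abundance by summing component model predictions
#'
#' Totals (all prokaryotes, all viruses) are obtained by summing the
#' predictions of the two component models row-wise, never by a separate
#' total model.
#'
#' @param pred_a,pred_b aligned prediction vectors in natural units.
#' @return element-wise sum.
#' @export
total_abundance <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) {
    stop("prediction vectors must be aligned")
  }
  pred_a + pred_b
}
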