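#' Configuration for the synthetic Arctic data generator
#'
#' Bundles every tunable of the synthetic seasonal (fixed-station time
#' series, n = 156) and spatial (summer survey, n = 37) dataset generators:
#' the per-column moment targets the tables are calibrated to, the latent
#' response-surface parameters linking covariates to the four population
#' abundances, and the multiplicative log-scale noise.
#'
#' Default moment targets are the published summary moments of the field
#' campaign the generator emulates (Franklin Bay seasonal station and the
#' Mackenzie shelf / Amundsen Gulf summer survey). Units follow the schema
#' in [env_table_columns()].
#'
#' @param seed integer seed; the same seed reproduces a table bit-identically.
#' @param sigma_log SD of the multiplicative lognormal abundance noise.
#' @param noise_share fraction of the log-noise variance shared by all four
#'   populations of a sample (water-sample-level effects); induces the
#'   positive covariance between populations that the summed total columns
#'   inherit.
#' @param chl_ref reference chlorophyll (ug/L) at which the chlorophyll
#'   factor of every response surface equals 1.
#' @param hna_peak_t,hna_width_t,hna_chl_exp,hna_chl_mix HNA surface:
#'   Gaussian temperature optimum (deg C), its width, the chlorophyll power,
#'   and the weight of the chlorophyll term in the additive mix.
#' @param lna_t_mid,lna_t_scale,lna_chl_exp LNA surface: midpoint and scale
#'   of the increasing logistic temperature term, chlorophyll power.
#' @param v1_chl_exp,v1_depth_scale,v1_dl_base,v1_dl_depth V1 surface:
#'   chlorophyll power, e-folding depth (m) of the decline, baseline of the
#'   day-length factor, and the depth scale (m) over which the day-length
#'   effect fades.
#' @param v2_depth_scale,v2_chl_exp,v2_chl_depth,v2_dl_coef V2 surface:
#'   e-folding depth (m) of the depth decline, chlorophyll power, e-folding
#'   depth (m) over which the chlorophyll effect is attenuated, day-length
#'   weight.
#' @param seasonal_targets,spatial_targets data frames with columns
#'   `column`, `mean`, `sd`: calibration targets passed to
#'   [calibrate_moments()].
#' @return a list of class `"generator_config"`.
#' @seealso [generate_seasonal()], [generate_spatial()], [true_response()]
#' @export
generator_config <- function(seed = 1L,
                             sigma_log = 0.35,
                             noise_share = 0.5,
                             chl_ref = 0.08,
                             hna_peak_t = -0.8, hna_width_t = 1.3,
                             hna_chl_exp = 0.85, hna_chl_mix = 0.6,
                             lna_t_mid = -0.5, lna_t_scale = 0.9,
                             lna_chl_exp = 0.30,
                             v1_chl_exp = 0.7, v1_depth_scale = 180,
                             v1_dl_base = 0.45, v1_dl_depth = 60,
                             v2_depth_scale = 140, v2_chl_exp = 0.6,
                             v2_chl_depth = 160, v2_dl_coef = 0.15,
                             seasonal_targets = seasonal_moment_targets(),
                             spatial_targets = spatial_moment_targets()) {
  stopifnot(sigma_log >= 0, noise_share >= 0, noise_share <= 1, chl_ref > 0,
            hna_width_t > 0, hna_chl_mix >= 0, hna_chl_mix <= 1,
            lna_t_scale > 0, v1_depth_scale > 0, v1_dl_depth > 0,
            v2_depth_scale > 0, v2_chl_depth > 0)
  for (t in list(seasonal_targets, spatial_targets)) {
    stopifnot(is.data.frame(t), all(c("column", "mean", "sd") %in% names(t)),
              all(t$sd > 0))
  }
  structure(
    list(seed = as.integer(seed), sigma_log = sigma_log,
         noise_share = noise_share, chl_ref = chl_ref,
         hna_peak_t = hna_peak_t, hna_width_t = hna_width_t,
         hna_chl_exp = hna_chl_exp, hna_chl_mix = hna_chl_mix,
         lna_t_mid = lna_t_mid, lna_t_scale = lna_t_scale,
         lna_chl_exp = lna_chl_exp,
         v1_chl_exp = v1_chl_exp, v1_depth_scale = v1_depth_scale,
         v1_dl_base = v1_dl_base, v1_dl_depth = v1_dl_depth,
         v2_depth_scale = v2_depth_scale, v2_chl_exp = v2_chl_exp,
         v2_chl_depth = v2_chl_depth, v2_dl_coef = v2_dl_coef,
         seasonal_targets = seasonal_targets,
         spatial_targets = spatial_targets),
    class = "generator_config")
}

#' Published moment targets for the two datasets
#'
#' Per-column mean and SD of the seasonal (n = 156) and spatial (n = 37)
#' field datasets, used as default calibration targets by the generator.
#' Columns with a fixed sampling design (depth) or computed deterministically
#' (day length) are not calibrated and are not listed.
#'
#' @return data frame with columns `column`, `mean`, `sd`.
#' @export
seasonal_moment_targets <- function() {
  data.frame(
    column = c("temperature_c", "salinity_psu", "chl_a_ug_l",
               "hna_1e5_ml", "lna_1e5_ml", "v1_1e6_ml", "v2_1e6_ml"),
    mean = c(-1.20, 31.90, 0.08, 2.22, 2.05, 0.93, 5.26),
    sd   = c(0.69, 1.63, 0.10, 1.62, 1.08, 0.81, 3.17))
}

#' @rdname seasonal_moment_targets
#' @export
spatial_moment_targets <- function() {
  data.frame(
    column = c("temperature_c", "salinity_psu", "chl_a_ug_l",
               "hna_1e5_ml", "lna_1e5_ml", "v1_1e6_ml", "v2_1e6_ml"),
    mean = c(1.04, 28.78, 0.49, 6.84, 4.93, 1.86, 12.80),
    sd   = c(2.93, 4.33, 0.60, 3.31, 2.44, 1.44, 5.75))
}

#' Noise-free expected abundance surfaces
#'
#' Evaluates the latent response surface that links covariates to the
#' expected abundance of one of the four flow-cytometric populations.
#' These surfaces define the "truth" of the synthetic world and encode the
#' qualitative ecology the models are expected to recover:
#'
#' * `hna` -- unimodal in temperature with its maximum just below 0 deg C
#'   (default -0.8, within the -1.3..-0.3 band) plus an additive increasing
#'   chlorophyll term;
#' * `lna` -- increasing in temperature (saturating logistic) and in Chl-a;
#' * `v1` -- increasing in Chl-a and, at shallow depth, in day length;
#'   declining with depth; the day-length effect fades below ~60 m;
#' * `v2` -- strictly decreasing in depth, increasing in Chl-a, with the
#'   chlorophyll effect attenuated at depth, and a weak day-length term.
#'
#' @param covariates data frame with the covariate columns the population
#'   needs (`temperature_c`, `chl_a_ug_l`, `depth_m`, `day_length_h`).
#' @param population one of `"hna"`, `"lna"`, `"v1"`, `"v2"`.
#' @param cfg a [generator_config()].
#' @return numeric vector of expected abundances (natural units, positive).
#' @export
true_response <- function(covariates, population, cfg = generator_config()) {
  if (!population %in% names(.population_columns)) {
    stop("unknown population '", population,
         "'; must be one of hna, lna, v1, v2")
  }
  chl <- covariates$chl_a_ug_l / cfg$chl_ref
  switch(population,
    hna = {
      bump <- exp(-((covariates$temperature_c - cfg$hna_peak_t) /
                      cfg$hna_width_t)^2)
      2.22 * ((1 - cfg$hna_chl_mix) * bump +
                cfg$hna_chl_mix * chl^cfg$hna_chl_exp)
    },
    lna = {
      t_term <- stats::plogis((covariates$temperature_c - cfg$lna_t_mid) /
                                cfg$lna_t_scale)
      2.05 * (0.4 + 1.2 * t_term) * chl^cfg$lna_chl_exp
    },
    v1 = {
      dl_exp <- 2 * exp(-covariates$depth_m / cfg$v1_dl_depth)
      dl_term <- (cfg$v1_dl_base +
                    (1 - cfg$v1_dl_base) * covariates$day_length_h / 24)^dl_exp
      0.93 * chl^cfg$v1_chl_exp * dl_term *
        exp(-covariates$depth_m / cfg$v1_depth_scale)
    },
    v2 = {
      z <- covariates$depth_m
      5.26 * ((0.85 - cfg$v2_dl_coef - 0.55) * exp(-z / cfg$v2_depth_scale) +
                0.55 * chl^cfg$v2_chl_exp * exp(-z / cfg$v2_chl_depth) +
                cfg$v2_dl_coef * covariates$day_length_h / 24)
    })
}

#' Rank-preserving moment calibration of table columns
#'
#' Maps each targeted column onto the requested mean and SD. Strictly
#' positive columns are transformed by a power law `y = s * x^b` (an affine
#' map on the log scale) whose exponent is solved so the coefficient of
#' variation matches the target and whose scale fixes the mean; other
#' columns get a plain affine map. Both maps are strictly increasing, so
#' ranks (and hence any monotone structure) are preserved. The two sum
#' columns (`prokaryotes_1e5_ml`, `viruses_1e6_ml`) are recomputed afterwards
#' so additivity stays exact.
#'
#' @param table a schema data frame (extra columns are carried through).
#' @param targets data frame with columns `column`, `mean`, `sd`.
#' @return the calibrated table; empirical mean and SD of each targeted
#'   column match the targets to within `1e-9` relative error.
#' @export
calibrate_moments <- function(table, targets) {
  stopifnot(all(targets$sd > 0))
  for (i in seq_len(nrow(targets))) {
    col <- targets$column[i]
    if (!col %in% names(table)) stop("column '", col, "' not present")
    x <- table[[col]]
    if (stats::sd(x) == 0) {
      stop("column '", col, "' is constant; cannot calibrate to sd > 0")
    }
    table[[col]] <- .calibrate_column(x, targets$mean[i], targets$sd[i])
  }
  if (all(c("hna_1e5_ml", "lna_1e5_ml") %in% names(table))) {
    table$prokaryotes_1e5_ml <- table$hna_1e5_ml + table$lna_1e5_ml
  }
  if (all(c("v1_1e6_ml", "v2_1e6_ml") %in% names(table))) {
    table$viruses_1e6_ml <- table$v1_1e6_ml + table$v2_1e6_ml
  }
  table
}

.calibrate_column <- function(x, mean_t, sd_t) {
  if (all(x > 0) && mean_t > 0) {
    lz <- log(x) - mean(log(x))
    cv_target <- sd_t / mean_t
    cv_of <- function(b) {
      y <- exp(b * lz)
      stats::sd(y) / mean(y)
    }
    # CV(b) is continuous, 0 at b = 0 and increasing; bracket then root-find
    hi <- 1
    while (cv_of(hi) < cv_target && hi < 64) hi <- hi * 2
    if (cv_of(hi) < cv_target) {
      stop("cannot reach target CV ", signif(cv_target, 4),
           " by a log-affine map")
    }
    b <- stats::uniroot(function(b) cv_of(b) - cv_target,
                        lower = 1e-8, upper = hi,
                        tol = .Machine$double.eps^0.75)$root
    y <- exp(b * lz)
    y * (mean_t / mean(y))
  } else {
    mean_t + sd_t * (x - mean(x)) / stats::sd(x)
  }
}

#' Generate the synthetic seasonal dataset
#'
#' Emulates a fixed Arctic station (70.05 deg N, 126.5 deg W) sampled on 21
#' dates spanning 2003-11-04 to 2004-08-06 at the eight fixed depths 3, 10,
#' 20, 30, 50, 100, 150 and 220 m. Twelve randomly chosen date-by-depth
#' cells are dropped (occasional sampling failure), leaving exactly 156
#' rows. Day length is computed with [day_length()]; temperature, salinity
#' and chlorophyll follow smooth seasonal/depth fields plus noise;
#' abundances are `true_response * exp(noise)`. All stochastic columns are
#' then moment-calibrated to the configured targets and the sum columns
#' recomputed.
#'
#' @param cfg a [generator_config()].
#' @return a schema data frame with 156 rows, `kind` attribute `"seasonal"`.
#' @export
generate_seasonal <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  lat <- 70.05
  lon <- -126.5
  dates <- as.Date(round(seq(as.numeric(as.Date("2003-11-04")),
                             as.numeric(as.Date("2004-08-06")),
                             length.out = 21)), origin = "1970-01-01")
  depths <- c(3, 10, 20, 30, 50, 100, 150, 220)
  grid <- expand.grid(date = dates, depth_m = depths)
  drop <- sample.int(nrow(grid), 12)
  grid <- grid[-drop, , drop = FALSE]
  n <- nrow(grid)

  doy <- as.integer(strftime(grid$date, "%j"))
  warm <- exp(-((doy - 205) / 45)^2)   # summer surface warming, peaks late Jul
  bloom <- exp(-((doy - 195) / 40)^2)  # phytoplankton bloom window

  temperature <- -1.68 + 4.6 * warm * exp(-grid$depth_m / 14) +
    stats::rnorm(n, 0, 0.12)
  # summer meltwater/runoff freshening tracks the warming signal closely,
  # so salinity is a low-noise seasonal proxy at the fixed station
  salinity <- 31.8 + 0.006 * grid$depth_m -
    5.5 * warm * exp(-grid$depth_m / 9) - 0.6 * bloom +
    stats::rnorm(n, 0, 0.10)
  chl <- exp(log(0.022) - 0.004 * grid$depth_m +
               2.9 * bloom * exp(-((grid$depth_m - 15) / 28)^2) +
               stats::rnorm(n, 0, 0.45))

  table <- data.frame(
    station = "FB", date = grid$date, depth_m = grid$depth_m,
    temperature_c = temperature, salinity_psu = salinity,
    day_length_h = day_length(grid$date, lat, lon),
    chl_a_ug_l = chl, stringsAsFactors = FALSE)

  # calibrate covariates first so the abundances respond to the calibrated
  # fields, then draw abundances and calibrate those
  cov_targets <- cfg$seasonal_targets[
    cfg$seasonal_targets$column %in%
      c("temperature_c", "salinity_psu", "chl_a_ug_l"), ]
  table <- calibrate_moments(table, cov_targets)
  table <- .add_abundances(table, cfg, cfg$seasonal_targets)

  rownames(table) <- NULL
  attr(table, "kind") <- "seasonal"
  validate_env_table(table)
  table
}

#' Generate the synthetic spatial dataset
#'
#' Emulates a 37-sample summer survey (2004-07-04 to 2004-08-10) at 7
#' stations between 69.5-71.5 deg N and 138.6-122.3 deg W, sampled from the
#' surface to at most 80 m. Relative to the seasonal table the survey is
#' warmer, fresher (river influence grows toward the western stations),
#' shallower, has near-continuous daylight, and is more productive; all
#' stochastic columns are calibrated to the configured spatial targets.
#'
#' @param cfg a [generator_config()].
#' @return a schema data frame with 37 rows, `kind` attribute `"spatial"`.
#' @export
generate_spatial <- function(cfg = generator_config()) {
  set.seed(cfg$seed + 1L)
  n_st <- 7
  st_lat <- stats::runif(n_st, 69.5, 71.5)
  st_lon <- stats::runif(n_st, -138.6, -122.3)
  st_bottom <- stats::runif(n_st, 50, 80)
  st_river <- 0.3 + 0.7 * (-(st_lon + 122.3) / 16.3)  # 1 near the Mackenzie
  st_warm <- stats::runif(n_st, 0.5, 1.05)
  # station occupation dates stratified over the cruise window (plus jitter)
  # so early-July polar day and mid-August sunsets both appear
  window <- as.Date(c("2004-07-04", "2004-08-10"))
  span <- as.numeric(diff(window))
  st_date <- window[1] +
    round((seq_len(n_st) - 1) / (n_st - 1) * span +
            stats::runif(n_st, -3, 3))
  st_date <- pmin(pmax(st_date, window[1]), window[2])

  n <- 37
  st <- c(seq_len(n_st), sample.int(n_st, n - n_st, replace = TRUE))
  depth <- pmax(1, round(stats::runif(n, 1, st_bottom[st])))
  # one near-bottom cast per station; the rest spread over the water column
  depth[seq_len(n_st)] <- round(st_bottom * stats::runif(n_st, 0.85, 1))

  temperature <- -1.5 + 13.5 * st_warm[st] * exp(-depth / 16) +
    stats::rnorm(n, 0, 0.2)
  # on the shelf the freshwater signal follows distance to the river plume,
  # not local warming, decoupling salinity from the seasonal covariation
  salinity <- 31.5 - 9 * st_river[st] * (0.4 + 0.6 * exp(-depth / 30)) +
    stats::rnorm(n, 0, 0.6)
  chl <- 0.05 + exp(log(0.12) + 3.0 * exp(-((depth - 18) / 14)^2) +
                      stats::rnorm(n, 0, 0.45))

  table <- data.frame(
    station = sprintf("S%d", st), date = st_date[st], depth_m = depth,
    temperature_c = temperature, salinity_psu = salinity,
    day_length_h = day_length(st_date[st], st_lat[st], st_lon[st]),
    chl_a_ug_l = chl, stringsAsFactors = FALSE)

  cov_targets <- cfg$spatial_targets[
    cfg$spatial_targets$column %in%
      c("temperature_c", "salinity_psu", "chl_a_ug_l"), ]
  table <- calibrate_moments(table, cov_targets)
  table <- .add_abundances(table, cfg, cfg$spatial_targets)

  rownames(table) <- NULL
  attr(table, "kind") <- "spatial"
  validate_env_table(table)
  table
}

# draw noisy abundances from the latent surfaces and calibrate them;
# sum columns are computed after the noise, never noised independently
.add_abundances <- function(table, cfg, targets) {
  n <- nrow(table)
  shared <- stats::rnorm(n)   # water-sample-level effect, common to all pops
  for (pop in names(.population_columns)) {
    mu <- true_response(table, pop, cfg)
    eps <- cfg$sigma_log * (sqrt(cfg$noise_share) * shared +
                              sqrt(1 - cfg$noise_share) * stats::rnorm(n))
    table[[.population_columns[[pop]]]] <- mu * exp(eps)
  }
  ab_targets <- targets[targets$column %in% .population_columns, ]
  table$prokaryotes_1e5_ml <- table$hna_1e5_ml + table$lna_1e5_ml
  table$viruses_1e6_ml <- table$v1_1e6_ml + table$v2_1e6_ml
  calibrate_moments(table, ab_targets)
}
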