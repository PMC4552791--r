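#' Configuration for the synthetic lake-study generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe a temperate-humid lowland lake district: a mean annual
#' air temperature of 8.1 degrees C, about 585 mm of annual precipitation,
#' lakes with multi-year hydrological memory, and roughly twenty riparian
#' alder per site whose ring widths mix a negative-exponential age trend, a
#' site-common hydroclimatic signal and tree-level lognormal noise. The
#' signal/noise defaults are calibrated so that detrended chronologies reach
#' an inter-series correlation (RBAR) of roughly 0.3-0.5, the range typical
#' of closed-canopy riparian stands.
#'
#' @param n_trees Trees per site (>= 2).
#' @param n_sites Number of study sites.
#' @param start_year,end_year Calendar span of the simulation.
#' @param mean_annual_temp Mean annual air temperature, degrees C.
#' @param annual_precip Mean annual precipitation sum, mm.
#' @param temp_seasonal_amplitude Amplitude of the seasonal temperature
#'   sinusoid (peak in July), degrees C.
#' @param temp_noise_sd Gaussian sd of monthly temperature noise, degrees C.
#' @param precip_month_shape Gamma shape of monthly precipitation totals;
#'   larger values give steadier months.
#' @param latitude Site latitude in degrees, used for the Thornthwaite
#'   day-length correction inside the lake-level generator.
#' @param lake_memory_phi AR(1) coefficient of the monthly lake level,
#'   in `[0, 1)`. Values near 1 give the multi-year memory that makes
#'   long-scale SPEI the best level predictor.
#' @param lake_balance_beta Lake-level response, gauge units per mm of
#'   monthly climatic water-balance anomaly.
#' @param lake_noise_sd Gauge-unit sd of monthly lake-level noise.
#' @param lake_datum Stationary mean level, gauge units.
#' @param signal_strength Fraction in `[0, 1]` scaling the site-common
#'   hydroclimatic signal in ring widths.
#' @param age_trend_rate Decay rate (1/years) of the negative-exponential
#'   age trend.
#' @param noise_sd_log Lognormal sigma of tree-level ring-width noise.
#' @param initial_width Juvenile ring width (mm) at age zero.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output. Per-site/per-tree sub-streams are derived from it so adding a
#'   site never perturbs existing series.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_trees = 5, start_year = 1950, end_year = 2000)
#' clim <- generate_monthly_climate(cfg)
synth_config <- function(n_trees = 20,
                         n_sites = 1,
                         start_year = 1900,
                         end_year = 2013,
                         mean_annual_temp = 8.1,
                         annual_precip = 585,
                         temp_seasonal_amplitude = 9,
                         temp_noise_sd = 1,
                         precip_month_shape = 4,
                         latitude = 53.5,
                         lake_memory_phi = 0.95,
                         lake_balance_beta = 0.05,
                         lake_noise_sd = 1,
                         lake_datum = 60,
                         signal_strength = 0.25,
                         age_trend_rate = 0.02,
                         noise_sd_log = 0.25,
                         initial_width = 3,
                         seed = 42L) {
  if (!is.numeric(start_year) || !is.numeric(end_year) ||
      start_year >= end_year) {
    abort("`start_year` must be strictly before `end_year`.")
  }
  check_number(n_trees, "n_trees", lower = 2)
  check_number(n_sites, "n_sites", lower = 1)
  check_number(signal_strength, "signal_strength", lower = 0, upper = 1)
  check_number(lake_memory_phi, "lake_memory_phi", lower = 0, upper = 1,
               closed_upper = FALSE)
  check_number(annual_precip, "annual_precip", lower = 0)
  check_number(temp_noise_sd, "temp_noise_sd", lower = 0)
  check_number(precip_month_shape, "precip_month_shape", lower = 0,
               closed_lower = FALSE)
  check_number(lake_noise_sd, "lake_noise_sd", lower = 0)
  check_number(age_trend_rate, "age_trend_rate", lower = 0)
  check_number(noise_sd_log, "noise_sd_log", lower = 0)
  check_number(initial_width, "initial_width", lower = 0,
               closed_lower = FALSE)
  check_number(latitude, "latitude", lower = -66.5, upper = 66.5,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(seed, "seed")

  structure(
    list(
      n_trees = as.integer(n_trees), n_sites = as.integer(n_sites),
      start_year = as.integer(start_year), end_year = as.integer(end_year),
      mean_annual_temp = mean_annual_temp, annual_precip = annual_precip,
      temp_seasonal_amplitude = temp_seasonal_amplitude,
      temp_noise_sd = temp_noise_sd,
      precip_month_shape = precip_month_shape,
      latitude = latitude,
      lake_memory_phi = lake_memory_phi,
      lake_balance_beta = lake_balance_beta,
      lake_noise_sd = lake_noise_sd, lake_datum = lake_datum,
      signal_strength = signal_strength,
      age_trend_rate = age_trend_rate, noise_sd_log = noise_sd_log,
      initial_width = initial_width,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d site(s) x %d trees, %d-%d\n",
              x$n_sites, x$n_trees, x$start_year, x$end_year))
  cat(sprintf("  climate: %.1f degC, %.0f mm/yr; lake phi = %.2f; signal = %.2f\n",
              x$mean_annual_temp, x$annual_precip,
              x$lake_memory_phi, x$signal_strength))
  invisible(x)
}

site_ids <- function(config) sprintf("S%d", seq_len(config$n_sites))

#' Generate synthetic monthly climate
#'
#' Monthly mean temperature is the annual mean plus a seasonal sinusoid
#' peaking in July plus Gaussian noise. Monthly precipitation totals are
#' gamma-distributed around a mildly summer-peaked seasonal mean whose
#' twelve monthly means sum to the configured annual total. Each site draws
#' from its own random sub-stream.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `site_id`, `year`, `month`, `tmean`
#'   (degrees C) and `precip` (mm, non-negative).
#' @export
generate_monthly_climate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  years <- config$start_year:config$end_year
  n_yr <- length(years)
  m <- rep(1:12, times = n_yr)
  seasonal_t <- config$temp_seasonal_amplitude * cos(2 * pi * (m - 7) / 12)
  # precipitation seasonality: modest summer maximum, annual sum preserved
  precip_mu <- (config$annual_precip / 12) *
    (1 + 0.25 * cos(2 * pi * (m - 7) / 12))

  purrr::map_dfr(seq_len(config$n_sites), function(s) {
    with_local_seed(substream_seed(config$seed, s, 0), {
      tmean <- config$mean_annual_temp + seasonal_t +
        rnorm(length(m), 0, config$temp_noise_sd)
      precip <- stats::rgamma(length(m),
                              shape = config$precip_month_shape,
                              scale = precip_mu / config$precip_month_shape)
      tibble(
        site_id = site_ids(config)[s],
        year = rep(years, each = 12L),
        month = as.integer(m),
        tmean = tmean,
        precip = precip
      )
    })
  })
}

#' Generate a synthetic monthly lake-level series
#'
#' The monthly level follows a first-order autoregression around a fixed
#' datum, forced by the monthly climatic water-balance anomaly
#' `D = precip - PET` (Thornthwaite PET at the configured latitude):
#' `L_m = datum + phi * (L_{m-1} - datum) + beta * (D_m - mean(D)) + noise`.
#' With `phi` near 1 the level integrates the balance over many years,
#' which is what makes long accumulation scales of SPEI good level
#' predictors.
#'
#' @param climate Monthly climate tibble from [generate_monthly_climate()];
#'   must cover the configured period for every site.
#' @param config A [synth_config()].
#' @return A tibble with columns `site_id`, `kind` (`"lake_level"`),
#'   `year`, `month`, `level` (gauge units).
#' @export
generate_lake_level <- function(climate, config) {
  stopifnot(inherits(config, "synth_config"))
  check_cols(climate, c("site_id", "year", "month", "tmean", "precip"),
             "climate")

  climate %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$year, .data$month)
      if (min(df$year) > config$start_year ||
          max(df$year) < config$end_year) {
        abort("`climate` does not cover the configured period.")
      }
      pet <- thornthwaite_pet(
        mutate(df, site_id = key$site_id),
        latitude = config$latitude
      )$pet
      d <- df$precip - pet
      innov_seed <- substream_seed(
        config$seed, match(key$site_id, site_ids(config)), 1
      )
      eps <- with_local_seed(innov_seed,
                             rnorm(length(d), 0, config$lake_noise_sd))
      innov <- config$lake_balance_beta * (d - mean(d)) + eps
      lvl <- config$lake_datum +
        as.numeric(stats::filter(innov, config$lake_memory_phi,
                                 method = "recursive"))
      tibble(kind = "lake_level", year = df$year, month = df$month,
             level = lvl)
    }) %>%
    ungroup() %>%
    select("site_id", "kind", "year", "month", "level")
}

#' Generate synthetic ring-width series for a site's trees
#'
#' Each tree's annual width is
#' `width_t = A * exp(-rate * age) * (1 + s * z_t) * lognormal noise`,
#' where `z_t` is the standardized water-year mean of the supplied hydro
#' series (the site-common hydroclimatic signal) and `s` is
#' `signal_strength`. Germination years are staggered uniformly over the
#' first 30% of the period so sample depth grows through time. Widths are
#' strictly positive (the signal factor is floored at 0.05).
#'
#' @param hydro Monthly level tibble (one site) from
#'   [generate_lake_level()], covering the tree lifespans.
#' @param config A [synth_config()].
#' @param site Site index used to derive the random sub-streams and the
#'   series ids.
#' @return A long ring-width tibble with columns `series_id`, `site_id`,
#'   `year`, `width_mm`.
#' @export
generate_tree_rings <- function(hydro, config, site = 1L) {
  stopifnot(inherits(config, "synth_config"))
  check_cols(hydro, c("site_id", "year", "month", "level"), "hydro")
  if (dplyr::n_distinct(hydro$site_id) != 1L) {
    abort("`hydro` must contain a single site; map over sites to do more.")
  }

  wy <- water_year_mean(hydro, value_col = "level")
  wy <- filter(wy, .data$complete)
  z <- setNames((wy$value - mean(wy$value)) / sd(wy$value), wy$water_year)

  span <- config$end_year - config$start_year + 1L
  first_possible <- config$start_year + 1L # first complete water year
  sid <- hydro$site_id[[1]]

  purrr::map_dfr(seq_len(config$n_trees), function(j) {
    tree_seed <- substream_seed(config$seed, site, j + 1L)
    with_local_seed(tree_seed, {
      germ <- first_possible +
        as.integer(floor(runif(1) * floor(0.3 * span)))
      yrs <- germ:config$end_year
      if (!all(as.character(yrs) %in% names(z))) {
        abort("`hydro` does not cover the tree lifespans.")
      }
      age <- seq_along(yrs)
      signal <- pmax(1 + config$signal_strength * z[as.character(yrs)], 0.05)
      noise <- exp(rnorm(length(yrs), 0, config$noise_sd_log))
      tibble(
        series_id = sprintf("%s%02d", sid, j),
        site_id = sid,
        year = yrs,
        width_mm = config$initial_width *
          exp(-config$age_trend_rate * age) * unname(signal) * noise
      )
    })
  })
}

#' Simulate a complete multi-site lake study
#'
#' Convenience wrapper running [generate_monthly_climate()],
#' [generate_lake_level()] and [generate_tree_rings()] for every site of
#' the configuration.
#'
#' @param config A [synth_config()].
#' @return A list with tibbles `climate`, `hydro`, `rings` and the
#'   `config` used.
#' @export
simulate_lake_study <- function(config = synth_config()) {
  climate <- generate_monthly_climate(config)
  hydro <- generate_lake_level(climate, config)
  rings <- purrr::map_dfr(seq_len(config$n_sites), function(s) {
    generate_tree_rings(
      filter(hydro, .data$site_id == site_ids(config)[s]),
      config, site = s
    )
  })
  list(climate = climate, hydro = hydro, rings = rings, config = config)
}
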