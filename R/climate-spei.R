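#' Thornthwaite potential evapotranspiration
#'
#' Classic monthly Thornthwaite PET. The annual heat index
#' `I = sum (T_i / 5)^1.514` is computed from the per-calendar-month mean
#' temperatures of the record (months with mean T > 0), the exponent
#' `a(I)` is the standard cubic polynomial, and
#' `PET_m = 16 * K_m * (10 T_m / I)^a` with the day-length correction
#' `K_m = (N_m / 12) * (days_m / 30)` from latitude and mid-month solar
#' declination. Months with `T <= 0` get PET = 0. February counts 28.25
#' civil days.
#'
#' @param climate Tibble with columns `site_id`, `year`, `month`, `tmean`
#'   (and possibly more); at least 12 months per site.
#' @param latitude Latitude in degrees, inside (-66.5, 66.5).
#' @return The input tibble with a `pet` column (mm/month) appended.
#' @export
#' @examples
#' cfg <- synth_config(n_trees = 2, start_year = 1990, end_year = 1995)
#' clim <- generate_monthly_climate(cfg)
#' head(thornthwaite_pet(clim, latitude = 53.5))
thornthwaite_pet <- function(climate, latitude = 53.5) {
  check_cols(climate, c("site_id", "year", "month", "tmean"), "climate")
  check_number(latitude, "latitude", lower = -66.5, upper = 66.5,
               closed_lower = FALSE, closed_upper = FALSE)
  if (any(climate$month < 1 | climate$month > 12)) {
    abort("`month` must lie in 1..12.")
  }

  mlen <- days_in_month()
  mid_doy <- cumsum(mlen) - mlen / 2
  decl <- 0.4093 * sin(2 * pi * mid_doy / 365.25 - 1.405)
  phi <- latitude * pi / 180
  cos_ws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  daylen <- 24 / pi * acos(cos_ws)
  k_corr <- (daylen / 12) * (mlen / 30)

  climate %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 12L) {
        abort("Thornthwaite PET needs at least 12 months per site.")
      }
      normals <- tapply(df$tmean, df$month, mean)
      warm <- normals[normals > 0]
      heat_index <- sum((warm / 5)^1.514)
      if (!is.finite(heat_index) || heat_index <= 0) {
        df$pet <- 0
        return(df)
      }
      a <- 6.75e-7 * heat_index^3 - 7.71e-5 * heat_index^2 +
        1.792e-2 * heat_index + 0.49239
      t_pos <- pmax(df$tmean, 0)
      pet <- 16 * k_corr[df$month] * (10 * t_pos / heat_index)^a
      df$pet <- ifelse(df$tmean <= 0, 0, pet)
      df
    }) %>%
    ungroup() %>%
    select(dplyr::all_of(c("site_id", setdiff(names(climate), "site_id"))),
           "pet")
}

#' Monthly climatic water balance
#'
#' `D_m = P_m - PET_m`, the monthly difference between precipitation and
#' potential evapotranspiration.
#'
#' @param climate Tibble with `precip` and `pet` columns (e.g. the output
#'   of [thornthwaite_pet()]).
#' @return The input with a `wb` column (mm/month) appended.
#' @export
water_balance <- function(climate) {
  check_cols(climate, c("precip", "pet"), "climate")
  mutate(climate, wb = .data$precip - .data$pet)
}

#' Accumulate a monthly series over a trailing window
#'
#' `X_m = sum_{j=0}^{k-1} D_{m-j}`: the k-month trailing sum ending in
#' month m. The first `k - 1` months are undefined, as is any month whose
#' trailing window spans a gap in the record.
#'
#' @param monthly Tibble with `year`, `month` and the value column
#'   (optionally `site_id`, handled per site).
#' @param k Accumulation scale in months (>= 1).
#' @param value_col Name of the column to accumulate.
#' @return A tibble with one row per month of the spanned calendar range
#'   and an `acc` column (NA where undefined).
#' @export
accumulate_balance <- function(monthly, k, value_col = "wb") {
  check_cols(monthly, c("year", "month", value_col), "monthly")
  check_number(k, "k", lower = 1)
  k <- as.integer(k)
  if (!"site_id" %in% names(monthly)) monthly$site_id <- "S1"

  monthly %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$year, .data$month)
      if (anyDuplicated(month_index(df$year, df$month)) > 0) {
        abort("duplicate (year, month) in `monthly`.")
      }
      grid <- full_month_grid(df$year, df$month)
      x <- rep(NA_real_, nrow(grid))
      x[match(month_index(df$year, df$month),
              month_index(grid$year, grid$month))] <- df[[value_col]]
      acc <- as.numeric(stats::filter(x, rep(1, k), sides = 1))
      tibble(year = grid$year, month = grid$month, acc = acc)
    }) %>%
    ungroup()
}

full_month_grid <- function(year, month) {
  idx <- seq(min(month_index(year, month)), max(month_index(year, month)))
  tibble(year = as.integer(idx %/% 12L), month = as.integer(idx %% 12L + 1L))
}

#' Fit a three-parameter log-logistic distribution by probability-weighted
#' moments
#'
#' Uses the unbiased PWM estimators `b0`, `b1`, `b2` of the ordered sample
#' and the closed-form solution for the log-logistic family with CDF
#' `F(x) = 1 / (1 + (scale / (x - origin))^shape)`. If the estimated
#' origin exceeds the sample minimum it is re-anchored just below the
#' minimum with a warning, so the fitted CDF is defined on the whole
#' sample.
#'
#' @param x Numeric sample, at least 20 values, not all equal.
#' @return A list with elements `shape`, `scale`, `origin`.
#' @export
#' @examples
#' x <- 50 * (runif(500) / (1 - runif(500)))^(1 / 3) # log-logistic(3, 50, 0)
#' fit_loglogistic_pwm(x)
fit_loglogistic_pwm <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 20L) {
    abort("log-logistic PWM fit needs at least 20 finite values.")
  }
  if (sd(x) == 0) {
    abort("degenerate sample: zero variance.")
  }
  xs <- sort(x)
  n <- length(xs)
  i <- seq_len(n)
  b0 <- mean(xs)
  b1 <- mean(xs * (i - 1) / (n - 1))
  b2 <- mean(xs * (i - 1) * (i - 2) / ((n - 1) * (n - 2)))

  shape <- (2 * b1 - b0) / (6 * b2 - 6 * b1 + b0)
  if (!is.finite(shape) || shape <= 1) {
    abort("log-logistic PWM fit failed: estimated shape <= 1.")
  }
  g <- gamma(1 + 1 / shape) * gamma(1 - 1 / shape)
  scale <- (2 * b1 - b0) * shape / g
  origin <- b0 - scale * g
  if (origin >= min(xs)) {
    warn("PWM origin exceeds the sample minimum; re-anchoring below it.")
    origin <- min(xs) - 1e-8 * max(1, abs(min(xs)))
  }
  list(shape = shape, scale = scale, origin = origin)
}

ploglogistic <- function(x, fit) {
  p <- ifelse(x > fit$origin,
              1 / (1 + (fit$scale / (x - fit$origin))^fit$shape),
              0)
  pmin(pmax(p, 1e-9), 1 - 1e-9)
}

# Monthly fitting with a reflection fallback: long accumulations are
# near-symmetric and can show slightly negative L-skewness, where the
# log-logistic PWM solution has no valid shape. Fitting the negated
# sample and complementing the CDF keeps the transform monotone and the
# calibration standardized.
fit_spei_month <- function(x) {
  fit <- tryCatch(fit_loglogistic_pwm(x), error = function(e) NULL)
  if (!is.null(fit)) {
    fit$reflected <- FALSE
    return(fit)
  }
  fit <- fit_loglogistic_pwm(-x)
  fit$reflected <- TRUE
  fit
}

spei_transform <- function(x, fit) {
  if (isTRUE(fit$reflected)) {
    qnorm(1 - ploglogistic(-x, fit))
  } else {
    qnorm(ploglogistic(x, fit))
  }
}

#' Standardized Precipitation-Evapotranspiration Index
#'
#' For each calendar month and accumulation scale `k`, the k-month trailing
#' sum of the climatic water balance is fitted (over the calibration
#' period) with a three-parameter log-logistic distribution via
#' probability-weighted moments, and transformed to a standard-normal
#' deviate: `SPEI = qnorm(F(x))`. Fitting each calendar month separately
#' removes the seasonal cycle from the index. Values outside the
#' calibration period are standardized by the calibration fit.
#'
#' @param wb Tibble with `site_id`, `year`, `month`, `wb` (e.g. from
#'   [water_balance()]).
#' @param scales Integer accumulation scales in months; default the
#'   package grid 6, 12, 24, 36, 48, 60, 72.
#' @param calibration Length-2 numeric `c(first_year, last_year)` or NULL
#'   for the full record. Each calendar month needs at least 20
#'   calibration values at each scale.
#' @return A long tibble `site_id`, `year`, `month`, `scale_k`, `spei`
#'   (NA for the first `k - 1` months and across gaps), with the
#'   calibration period attached as attribute `calibration`.
#' @export
spei <- function(wb, scales = c(6, 12, 24, 36, 48, 60, 72),
                 calibration = NULL) {
  check_cols(wb, c("site_id", "year", "month", "wb"), "wb")
  if (is.null(calibration)) calibration <- range(wb$year)

  out <- purrr::map_dfr(scales, function(k) {
    acc <- accumulate_balance(wb, k = k, value_col = "wb")
    acc %>%
      group_by(.data$site_id) %>%
      dplyr::group_modify(function(df, key) {
        z <- rep(NA_real_, nrow(df))
        for (m in 1:12) {
          sel <- df$month == m
          cal <- sel & df$year >= calibration[1] &
            df$year <= calibration[2] & is.finite(df$acc)
          if (sum(cal) < 20L) {
            abort(sprintf(
              "insufficient calibration data for month %d at scale %d (%d values, need 20).",
              m, k, sum(cal)
            ))
          }
          fit <- fit_spei_month(df$acc[cal])
          z[sel] <- spei_transform(df$acc[sel], fit)
        }
        tibble(year = df$year, month = df$month,
               scale_k = as.integer(k), spei = z)
      }) %>%
      ungroup()
  })
  attr(out, "calibration") <- as.integer(calibration)
  out
}

#' Aggregate a monthly series over hydrological water years
#'
#' Water year `t` runs from October of calendar year `t - 1` through
#' September of year `t`. Each water year's value is the mean of its
#' available months; years with fewer than `min_months` months are flagged
#' incomplete (and should be excluded from model fitting, which
#' [build_predictor_table()] does by default).
#'
#' @param monthly Tibble with `year`, `month` and a value column
#'   (optionally `site_id`).
#' @param value_col Name of the value column (default the first column
#'   that is none of `site_id`, `kind`, `variable`, `year`, `month`).
#' @param min_months Months required for a water year to count as
#'   complete (default 12).
#' @return Tibble with `site_id` (if present), `water_year`, `value`,
#'   `n_months`, `complete`.
#' @export
water_year_mean <- function(monthly, value_col = NULL, min_months = 12) {
  check_cols(monthly, c("year", "month"), "monthly")
  if (is.null(value_col)) {
    value_col <- setdiff(names(monthly),
                         c("site_id", "kind", "variable", "year", "month",
                           "scale_k"))[1]
  }
  check_cols(monthly, value_col, "monthly")
  grouping <- intersect(c("site_id", "kind", "variable", "scale_k"),
                        names(monthly))

  monthly %>%
    mutate(water_year = water_year_of(.data$year, .data$month)) %>%
    filter(!is.na(.data[[value_col]])) %>%
    group_by(dplyr::across(dplyr::all_of(c(grouping, "water_year")))) %>%
    summarise(
      value = mean(.data[[value_col]]),
      n_months = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(complete = .data$n_months >= min_months) %>%
    arrange(dplyr::across(dplyr::all_of(c(grouping, "water_year"))))
}
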