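#' Average cores to tree level
#'
#' Dendro sampling usually takes two increment cores per tree; downstream
#' detrending operates on the per-tree mean series. Cores are grouped by a
#' `tree_id` column if present, otherwise by the series id with a single
#' trailing letter stripped (the common `<site><tree><core letter>`
#' labelling). Years covered by only one core carry that core's value.
#'
#' @param rw Long ring-width tibble with `series_id`, `site_id`, `year`,
#'   `width_mm`.
#' @return A tibble of the same shape with one series per tree (the tree
#'   id becomes the `series_id`).
#' @export
average_cores_per_tree <- function(rw) {
  check_cols(rw, c("series_id", "site_id", "year", "width_mm"), "rw")
  if (!"tree_id" %in% names(rw)) {
    rw <- mutate(rw,
                 tree_id = stringr::str_replace(.data$series_id,
                                                "[A-Za-z]$", ""))
  }
  rw %>%
    group_by(.data$site_id, .data$tree_id, .data$year) %>%
    summarise(width_mm = mean(.data$width_mm), .groups = "drop") %>%
    rename(series_id = "tree_id") %>%
    select("series_id", "site_id", "year", "width_mm") %>%
    arrange(.data$site_id, .data$series_id, .data$year)
}

# ---- smoothing-spline detrending ------------------------------------------

# Cache of calibrated smoothing parameters, keyed by
# (series length, wavelength, cutoff).
spline_lambda_cache <- new.env(parent = emptyenv())

# Amplitude of `fitted` at the given period, by least-squares projection
# onto the sine/cosine pair.
projected_amplitude <- function(fitted_vals, period) {
  t <- seq_along(fitted_vals)
  s <- sin(2 * pi * t / period)
  c_ <- cos(2 * pi * t / period)
  cf <- coef(lm(fitted_vals ~ s + c_))
  sqrt(cf[["s"]]^2 + cf[["c_"]]^2)
}

spline_fit <- function(y, lambda) {
  t <- seq_along(y)
  fit <- smooth.spline(t, y, lambda = lambda, all.knots = TRUE,
                       keep.data = FALSE)
  predict(fit, t)$y
}

# Smoothing parameter whose filter passes `cutoff` of the amplitude of a
# sinusoid with the given period, found by bisection on log(lambda). The
# response is measured on the same equally spaced annual grid the series
# uses, so the calibration is self-verifying.
spline_lambda_for_cutoff <- function(n, wavelength, cutoff) {
  key <- sprintf("%d_%g_%g", n, wavelength, cutoff)
  hit <- spline_lambda_cache[[key]]
  if (!is.null(hit)) return(hit)

  target <- sin(2 * pi * seq_len(n) / wavelength)
  response <- function(loglam) {
    projected_amplitude(spline_fit(target, exp(loglam)), wavelength)
  }
  lo <- -35; hi <- 15 # response ~1 at lo, ~0 at hi
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    if (response(mid) > cutoff) lo <- mid else hi <- mid
  }
  lambda <- exp((lo + hi) / 2)
  spline_lambda_cache[[key]] <- lambda
  lambda
}

#' Frequency response of the detrending spline
#'
#' Numerically measured amplitude response of the calibrated smoothing
#' spline: the ratio of fitted to input amplitude for a unit sinusoid of
#' the given period, on an annual grid of length `n`. Used to verify the
#' 50% cutoff calibration and to sweep the filter's response.
#'
#' @param period Sinusoid period in years (may be a vector).
#' @param wavelength Wavelength (years) at which the filter is calibrated
#'   to pass `cutoff` of the amplitude.
#' @param cutoff Target amplitude response at `wavelength`.
#' @param n Series length in years.
#' @return Numeric vector of amplitude ratios in `[0, 1]`.
#' @export
#' @examples
#' spline_amplitude_response(c(5, 30, 100), wavelength = 30, n = 300)
spline_amplitude_response <- function(period, wavelength = 30,
                                      cutoff = 0.5, n = 300) {
  lambda <- spline_lambda_for_cutoff(n, wavelength, cutoff)
  vapply(period, function(p) {
    y <- sin(2 * pi * seq_len(n) / p)
    min(1, projected_amplitude(spline_fit(y, lambda), p))
  }, numeric(1))
}

#' Detrend ring-width series with a cubic smoothing spline
#'
#' Fits each series with a cubic smoothing spline whose smoothing
#' parameter is calibrated (by bisection on a numerically measured
#' frequency response) so that the filter passes `amplitude_cutoff` of the
#' amplitude of a sinusoid with period `wavelength_years` — the standard
#' "50% frequency cutoff at 30 years" dendro detrending. Ring-width
#' indices are observed / fitted values; fitted values below a small
#' positive floor (1e-6 mm) are clamped with a warning so ratio indices
#' stay defined.
#'
#' @param rw Long ring-width tibble (`series_id`, `site_id`, `year`,
#'   `width_mm`); each series must span at least `wavelength_years / 2`
#'   years.
#' @param wavelength_years Period (years) at which the filter response
#'   equals `amplitude_cutoff`. Default 30.
#' @param amplitude_cutoff Target response, default 0.5.
#' @return Tibble `series_id`, `site_id`, `year`, `rwi` with
#'   `method = "spline_detrended"` column.
#' @export
detrend_spline <- function(rw, wavelength_years = 30,
                           amplitude_cutoff = 0.5) {
  check_cols(rw, c("series_id", "site_id", "year", "width_mm"), "rw")
  rw %>%
    group_by(.data$series_id, .data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$year)
      n <- nrow(df)
      if (n < wavelength_years / 2) {
        abort(sprintf(
          "series `%s` is too short to detrend (%d < %g years).",
          key$series_id, n, wavelength_years / 2
        ))
      }
      if (any(df$width_mm <= 0)) {
        abort(sprintf("series `%s` has non-positive widths.",
                      key$series_id))
      }
      lambda <- spline_lambda_for_cutoff(n, wavelength_years,
                                         amplitude_cutoff)
      fitted_vals <- spline_fit(df$width_mm, lambda)
      if (any(fitted_vals <= 0)) {
        warn(sprintf(
          "series `%s`: %d non-positive spline predictions clamped to 1e-6 mm.",
          key$series_id, sum(fitted_vals <= 0)
        ))
        fitted_vals <- pmax(fitted_vals, 1e-6)
      }
      tibble(year = df$year, rwi = df$width_mm / fitted_vals)
    }) %>%
    ungroup() %>%
    mutate(method = "spline_detrended") %>%
    select("series_id", "site_id", "year", "rwi", "method")
}

#' Standardize ring-width series by their horizontal mean
#'
#' Divides each series by its own arithmetic mean, retaining all
#' low-frequency variability. Indices of every series average to exactly 1.
#'
#' @inheritParams detrend_spline
#' @return Tibble `series_id`, `site_id`, `year`, `rwi` with
#'   `method = "horizontal_standardized"`.
#' @export
standardize_horizontal <- function(rw) {
  check_cols(rw, c("series_id", "site_id", "year", "width_mm"), "rw")
  rw %>%
    group_by(.data$series_id, .data$site_id) %>%
    mutate(rwi = .data$width_mm / mean(.data$width_mm)) %>%
    ungroup() %>%
    mutate(method = "horizontal_standardized") %>%
    select("series_id", "site_id", "year", "rwi", "method") %>%
    arrange(.data$site_id, .data$series_id, .data$year)
}

#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate with the Tukey biweight:
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (0 otherwise), where
#' `u_i = (x_i - m) / (c * MAD)`. Starts from the median and iterates to a
#' fixed point (1e-8) or 50 iterations. If the MAD is zero the median is
#' returned.
#'
#' @param values Numeric vector with at least one finite value.
#' @param c Tuning constant, default 9 (the chronology-building
#'   convention).
#' @return The biweight location estimate (scalar).
#' @export
#' @examples
#' biweight_mean(c(1, 1, 1, 100)) # outlier fully downweighted
biweight_mean <- function(values, c = 9) {
  x <- values[is.finite(values)]
  if (length(x) == 0L) abort("`values` has no finite entries.")
  if (length(x) == 1L) return(x)
  m <- median(x)
  s <- median(abs(x - m))
  if (s == 0) return(m)
  for (iter in 1:50) {
    u <- (x - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-8) return(m_new)
    m <- m_new
  }
  m
}

#' Build a site master chronology
#'
#' Per-year Tukey biweight mean of the available ring-width indices, with
#' the per-year sample depth and a running EPS (centered window, see
#' [running_eps()]) attached.
#'
#' @param rwi Index tibble (`series_id`, `site_id`, `year`, `rwi`,
#'   `method`) from [detrend_spline()] or [standardize_horizontal()];
#'   needs at least two overlapping series per site.
#' @param eps_window Window (years) for the running EPS, default 30.
#' @return Tibble `site_id`, `year`, `value`, `sample_depth`,
#'   `running_eps`, `method`.
#' @export
build_chronology <- function(rwi, eps_window = 30) {
  check_cols(rwi, c("series_id", "site_id", "year", "rwi"), "rwi")
  method <- if ("method" %in% names(rwi)) rwi$method[1] else NA_character_

  rwi %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$series_id) < 2L) {
        abort(sprintf("site `%s` needs at least 2 series.", key$site_id))
      }
      chron <- df %>%
        group_by(.data$year) %>%
        summarise(value = biweight_mean(.data$rwi),
                  sample_depth = dplyr::n(), .groups = "drop")
      reps <- running_eps(mutate(df, site_id = key$site_id),
                          window = eps_window)
      left_join(chron, select(reps, "year", "running_eps"), by = "year")
    }) %>%
    ungroup() %>%
    mutate(method = method) %>%
    arrange(.data$site_id, .data$year)
}
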