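# Chronology quality statistics: RBAR, MS, AC1, EPS, running EPS.

rwi_wide <- function(rwi, period = NULL) {
  if (!is.null(period)) {
    rwi <- filter(rwi, .data$year >= period[1], .data$year <= period[2])
  }
  wide <- rwi %>%
    select("series_id", "year", "rwi") %>%
    tidyr::pivot_wider(names_from = "series_id", values_from = "rwi") %>%
    arrange(.data$year)
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$year
  mat
}

# Mean pairwise Pearson correlation of the columns of `mat`, counting only
# pairs with at least `min_overlap` common rows.
pairwise_rbar <- function(mat, min_overlap) {
  if (ncol(mat) < 2L) return(NA_real_)
  overlap <- crossprod(!is.na(mat))
  suppressWarnings(
    r <- cor(mat, use = "pairwise.complete.obs")
  )
  keep <- upper.tri(r) & overlap >= min_overlap & is.finite(r)
  if (!any(keep)) return(NA_real_)
  mean(r[keep])
}

#' Mean inter-series correlation (RBAR)
#'
#' Arithmetic mean of all pairwise Pearson correlations between ring-width
#' index series, computed on complete pairwise overlap within the stated
#' period. Pairs overlapping fewer than `min_overlap` years are excluded.
#'
#' @param rwi Index tibble (`series_id`, `year`, `rwi`); typically one
#'   site.
#' @param period Optional `c(first, last)` calendar years.
#' @param min_overlap Minimum pairwise overlap in years (default 20).
#' @return Scalar RBAR in `[-1, 1]`, or NA (with a warning) if no pair
#'   qualifies.
#' @export
rbar <- function(rwi, period = NULL, min_overlap = 20) {
  check_cols(rwi, c("series_id", "year", "rwi"), "rwi")
  out <- pairwise_rbar(rwi_wide(rwi, period), min_overlap)
  if (is.na(out)) warn("no series pair with sufficient overlap; RBAR undefined.")
  out
}

#' Mean sensitivity of an annual series
#'
#' The mean relative change from one year to the next:
#' `mean of 2 |x_t - x_{t-1}| / (x_t + x_{t-1})`. Consecutive pairs
#' summing to zero are skipped with a warning.
#'
#' @param x Numeric annual series, length >= 2.
#' @return Scalar mean sensitivity (>= 0).
#' @export
#' @examples
#' mean_sensitivity(c(1, 3, 1, 3)) # 1
mean_sensitivity <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) abort("mean sensitivity needs at least 2 values.")
  num <- 2 * abs(diff(x))
  den <- x[-1] + x[-length(x)]
  if (any(den == 0)) {
    warn(sprintf("%d consecutive pair(s) summing to 0 skipped.",
                 sum(den == 0)))
  }
  keep <- den != 0
  mean(num[keep] / den[keep])
}

#' First-order autocorrelation
#'
#' Lag-1 Pearson autocorrelation of an annual series.
#'
#' @param x Numeric series, length >= 3 with non-zero variance.
#' @return Scalar in `[-1, 1]`, NA if the variance is zero.
#' @export
autocorr1 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) abort("lag-1 autocorrelation needs at least 3 values.")
  if (sd(x) == 0) return(NA_real_)
  cor(x[-1], x[-length(x)])
}

#' Expressed population signal (EPS)
#'
#' `EPS = n * rbar / (n * rbar + (1 - rbar))`: the agreement between a
#' chronology of `n` trees and a hypothetical chronology of infinitely
#' many. Values above 0.85 are the conventional reliability threshold.
#' A non-positive `rbar` yields a non-positive EPS, which should be
#' treated as unreliable.
#'
#' @param rbar_value Mean inter-series correlation.
#' @param n_trees Number of trees (>= 1).
#' @return Scalar EPS (<= 1).
#' @export
#' @examples
#' eps(0.3, 10) # 3 / 3.7
eps <- function(rbar_value, n_trees) {
  if (any(n_trees < 1)) abort("`n_trees` must be >= 1.")
  n_trees * rbar_value / (n_trees * rbar_value + (1 - rbar_value))
}

#' Running EPS over a moving window
#'
#' For every year of a site's span, EPS is computed from the RBAR and the
#' number of series inside a centered window (default 30 years),
#' restricted to series covering at least two thirds of it. At the series
#' margins the window is truncated; years whose truncated window is
#' shorter than 20 years, or where fewer than two series qualify, are
#' undefined.
#'
#' @param rwi Index tibble (`series_id`, `site_id`, `year`, `rwi`).
#' @param window Window length in years (>= 10), default 30.
#' @param min_pair_overlap Minimum in-window overlap for a pair to enter
#'   the windowed RBAR, default 10.
#' @return Tibble `site_id`, `year`, `n_series`, `rbar_window`,
#'   `running_eps` (NA where undefined).
#' @export
running_eps <- function(rwi, window = 30, min_pair_overlap = 10) {
  check_cols(rwi, c("series_id", "site_id", "year", "rwi"), "rwi")
  check_number(window, "window", lower = 10)
  half_lo <- floor(window / 2) - 1L
  half_hi <- ceiling(window / 2)

  rwi %>%
    group_by(.data$site_id) %>%
    dplyr::group_modify(function(df, key) {
      mat <- rwi_wide(df)
      yrs <- as.integer(rownames(mat))
      purrr::map_dfr(seq_along(yrs), function(i) {
        y <- yrs[i]
        w0 <- max(y - half_hi, min(yrs))
        w1 <- min(y + half_lo, max(yrs))
        wlen <- w1 - w0 + 1L
        out <- tibble(year = y, n_series = NA_integer_,
                      rbar_window = NA_real_, running_eps = NA_real_)
        if (wlen < 20L) return(out)
        sub <- mat[yrs >= w0 & yrs <= w1, , drop = FALSE]
        cover <- colSums(!is.na(sub))
        sub <- sub[, cover >= ceiling(2 / 3 * wlen), drop = FALSE]
        if (ncol(sub) < 2L) return(out)
        rb <- pairwise_rbar(sub, min_pair_overlap)
        if (is.na(rb)) return(out)
        n <- ncol(sub)
        tibble(year = y, n_series = n, rbar_window = rb,
               running_eps = eps(rb, n))
      })
    }) %>%
    ungroup()
}

#' Site chronology statistics table
#'
#' Computes the standard chronology quality statistics for both index
#' variants — spline-detrended and horizontal-standardized — over a common
#' period: RBAR, mean sensitivity and first-order autocorrelation (per
#' tree series, averaged), the master chronology's AC1, and EPS from RBAR
#' and the number of series. Mirrors the usual site-characteristics table
#' of dendro studies.
#'
#' @param rw Long ring-width tibble (tree level; average cores first with
#'   [average_cores_per_tree()]).
#' @param period `c(first, last)` calendar years; default the common
#'   overlap of all series per site.
#' @param min_overlap Minimum pairwise overlap for RBAR.
#' @return Tibble with one row per site and variant: `site_id`,
#'   `variant`, `n_series`, `first_year`, `last_year`, `rbar`, `ms`,
#'   `ac1`, `ac1_master`, `eps`.
#' @export
chronology_stats <- function(rw, period = NULL, min_overlap = 20) {
  check_cols(rw, c("series_id", "site_id", "year", "width_mm"), "rw")
  variants <- list(
    detrended = detrend_spline(rw),
    standardized = standardize_horizontal(rw)
  )
  purrr::imap_dfr(variants, function(rwi, vname) {
    rwi %>%
      group_by(.data$site_id) %>%
      dplyr::group_modify(function(df, key) {
        per <- period %||% c(
          max(tapply(df$year, df$series_id, min)),
          min(tapply(df$year, df$series_id, max))
        )
        dfp <- filter(df, .data$year >= per[1], .data$year <= per[2])
        by_series <- split(dfp[order(dfp$year), ], dfp$series_id[order(dfp$year)])
        rb <- pairwise_rbar(rwi_wide(dfp), min_overlap)
        n <- dplyr::n_distinct(dfp$series_id)
        master <- dfp %>%
          group_by(.data$year) %>%
          summarise(value = biweight_mean(.data$rwi), .groups = "drop")
        tibble(
          variant = vname,
          n_series = n,
          first_year = per[1], last_year = per[2],
          rbar = rb,
          ms = mean(vapply(by_series, function(s) mean_sensitivity(s$rwi),
                           numeric(1))),
          ac1 = mean(vapply(by_series, function(s) autocorr1(s$rwi),
                            numeric(1))),
          ac1_master = autocorr1(master$value),
          eps = eps(rb, n)
        )
      }) %>%
      ungroup()
  })
}
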