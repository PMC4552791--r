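# Lagged linear lake/groundwater-level reconstruction from RWI and SPEI
# predictor pools.

#' Build the aligned annual predictor table
#'
#' One row per water year `t` with the target level, the ring-width index
#' of years `t` (`rwi_t`) and `t + 1` (`rwi_tp1`, allowing lagged growth
#' responses), and the water-year mean of each SPEI accumulation scale
#' (`spei_12`, ..., `spei_72`). Rows with any missing value are dropped
#' and counted (attribute `dropped_rows`); incomplete water years of the
#' target are excluded.
#'
#' @param chronology Site chronology tibble (`year`, `value`), typically
#'   the horizontal-standardized master so low-frequency variation is
#'   retained.
#' @param spei Long SPEI tibble from [spei()] (or NULL to fit RWI models
#'   only).
#' @param target Water-year target tibble from [water_year_mean()]
#'   (`water_year`, `value`, `complete`), e.g. lake or groundwater level.
#' @return Tibble `water_year`, `target`, `rwi_t`, `rwi_tp1`, `spei_k`
#'   columns; at least 15 complete rows or an error.
#' @export
build_predictor_table <- function(chronology, spei = NULL, target) {
  check_cols(chronology, c("year", "value"), "chronology")
  check_cols(target, c("water_year", "value"), "target")
  if ("complete" %in% names(target)) {
    target <- filter(target, .data$complete)
  }

  tab <- tibble(water_year = as.integer(target$water_year),
                target = target$value) %>%
    left_join(select(chronology, rwi_t = "value", year = "year"),
              by = c(water_year = "year")) %>%
    left_join(
      select(chronology, rwi_tp1 = "value", year = "year") %>%
        mutate(year = .data$year - 1L),
      by = c(water_year = "year")
    )

  if (!is.null(spei)) {
    check_cols(spei, c("year", "month", "scale_k", "spei"), "spei")
    wy <- water_year_mean(spei, value_col = "spei") %>%
      filter(.data$complete) %>%
      mutate(name = sprintf("spei_%d", .data$scale_k)) %>%
      select("water_year", "name", "value") %>%
      tidyr::pivot_wider(names_from = "name", values_from = "value")
    tab <- left_join(tab, wy, by = "water_year")
  }

  complete <- stats::complete.cases(tab)
  dropped <- sum(!complete)
  tab <- tab[complete, ]
  if (nrow(tab) < 15L) {
    abort(sprintf(
      "only %d complete water years (need 15) — fit would be unstable.",
      nrow(tab)
    ))
  }
  attr(tab, "dropped_rows") <- dropped
  tab
}

#' Construct a reconstruction model object
#'
#' Builds a `recon_model` from explicit coefficients — used both
#' internally by [fit_recon()] and directly to encode published model
#' equations (e.g. `LL = 14.4390 x SPEI_24 + 60.0453`) for worked
#' examples.
#'
#' @param coefficients Named numeric vector: `"(Intercept)"` plus one
#'   slope per predictor (gauge units per predictor unit).
#' @param target Label: `"lake_level"` or `"groundwater"`.
#' @param calibration_period Optional `c(first, last)` water years.
#' @param r2,p_value,n Optional fit statistics.
#' @return An object of class `recon_model`.
#' @export
#' @examples
#' m <- recon_model(c(`(Intercept)` = 60.0453, spei_24 = 14.4390),
#'                  target = "lake_level")
#' predict(m, tibble::tibble(water_year = 2000L, spei_24 = 0))
recon_model <- function(coefficients, target = "lake_level",
                        calibration_period = NULL, r2 = NA_real_,
                        p_value = NA_real_, n = NA_integer_) {
  if (!"(Intercept)" %in% names(coefficients)) {
    abort("`coefficients` must include an \"(Intercept)\" term.")
  }
  structure(
    list(
      target = target,
      predictors = setdiff(names(coefficients), "(Intercept)"),
      coefficients = coefficients,
      calibration_period = calibration_period,
      r2 = r2, p_value = p_value, n = n
    ),
    class = "recon_model"
  )
}

#' Fit an OLS reconstruction model
#'
#' Ordinary least squares of the water-year target on a predictor subset
#' from the RWI pool (`rwi_t`, `rwi_tp1`) or the SPEI pool (`spei_k`
#' columns), with intercept. Reports plain R-squared and the two-sided
#' F-test p-value. Collinear predictor sets (condition number > 1e8) are
#' rejected.
#'
#' @param table Predictor table from [build_predictor_table()] (>= 15
#'   rows).
#' @param predictors Character vector of predictor column names.
#' @param target_label Stored target label.
#' @return A [recon_model()] with fit statistics and calibration period.
#' @export
fit_recon <- function(table, predictors, target_label = "lake_level") {
  check_cols(table, c("water_year", "target", predictors), "table")
  if (nrow(table) < 15L) abort("need at least 15 rows to fit.")
  mm <- as.matrix(table[predictors])
  if (kappa(cbind(1, mm), exact = TRUE) > 1e8) {
    abort("collinear predictors (condition number > 1e8).")
  }
  fml <- stats::reformulate(predictors, response = "target")
  fit <- lm(fml, data = table)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  recon_model(
    coefficients = coef(fit),
    target = target_label,
    calibration_period = range(table$water_year),
    r2 = sm$r.squared,
    p_value = p,
    n = nrow(table)
  )
}

#' Fit the full candidate pools
#'
#' Fits every model variant of the standard design: the RWI pool
#' (`rwi_t`, `rwi_tp1`, `rwi_t + rwi_tp1`) and the SPEI pool (one model
#' per available accumulation scale, single predictor each).
#'
#' @inheritParams fit_recon
#' @return A tibble with columns `pool`, `predictors` (list), `r2`,
#'   `p_value` and `model` (list of [recon_model()]).
#' @export
fit_reconstruction_models <- function(table, target_label = "lake_level") {
  spei_cols <- grep("^spei_\\d+$", names(table), value = TRUE)
  rwi_sets <- purrr::keep(list("rwi_t", "rwi_tp1", c("rwi_t", "rwi_tp1")),
                          ~ all(.x %in% names(table)))
  candidates <- c(
    purrr::map(rwi_sets, ~ list(pool = "rwi", predictors = .x)),
    purrr::map(spei_cols, ~ list(pool = "spei", predictors = .x))
  )
  if (length(candidates) == 0L) abort("no candidate predictors in `table`.")
  purrr::map_dfr(candidates, function(cand) {
    m <- fit_recon(table, cand$predictors, target_label = target_label)
    tibble(pool = cand$pool, predictors = list(cand$predictors),
           r2 = m$r2, p_value = m$p_value, model = list(m))
  })
}

max_lag_or_scale <- function(predictors) {
  vals <- dplyr::case_when(
    predictors == "rwi_t" ~ 0,
    predictors == "rwi_tp1" ~ 1,
    TRUE ~ suppressWarnings(as.numeric(sub("^spei_", "", predictors)))
  )
  max(vals)
}

#' Select the best model of a candidate pool
#'
#' Maximum calibration R-squared; ties broken by fewer predictors, then
#' by smaller maximum lag (RWI pool) or accumulation scale (SPEI pool).
#' Pools should be selected separately (pass one pool's models).
#'
#' @param models A list of [recon_model()]s, or the tibble returned by
#'   [fit_reconstruction_models()] (optionally filtered to one pool).
#' @return The selected [recon_model()].
#' @export
select_best <- function(models) {
  if (is.data.frame(models)) models <- models$model
  if (length(models) == 0L) abort("no candidate models.")
  r2 <- vapply(models, function(m) m$r2, numeric(1))
  npred <- vapply(models, function(m) length(m$predictors), numeric(1))
  lag <- vapply(models, function(m) max_lag_or_scale(m$predictors),
                numeric(1))
  ord <- order(-r2, npred, lag)
  models[[ord[1]]]
}

#' Reliability window of a chronology
#'
#' The maximal contiguous run of years satisfying both reconstruction
#' gates: sample depth of at least `min_trees` and running EPS of at
#' least `eps_threshold`. Years with undefined running EPS fail the gate.
#'
#' @param chronology Chronology tibble with `year`, `sample_depth`,
#'   `running_eps` (one site).
#' @param min_trees Minimum trees per year (default 10).
#' @param eps_threshold Running-EPS threshold (default 0.85).
#' @return A list of class `recon_window` with `first_year`, `last_year`
#'   (NA if no year qualifies) and `n_years`.
#' @export
reconstruction_window <- function(chronology, min_trees = 10,
                                  eps_threshold = 0.85) {
  check_cols(chronology, c("year", "sample_depth", "running_eps"),
             "chronology")
  chronology <- arrange(chronology, .data$year)
  ok <- chronology$sample_depth >= min_trees &
    !is.na(chronology$running_eps) &
    chronology$running_eps >= eps_threshold
  if (!any(ok)) {
    return(structure(list(first_year = NA_integer_, last_year = NA_integer_,
                          n_years = 0L),
                     class = "recon_window"))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  structure(
    list(
      first_year = as.integer(chronology$year[starts[best]]),
      last_year = as.integer(chronology$year[ends[best]]),
      n_years = as.integer(runs$lengths[best])
    ),
    class = "recon_window"
  )
}

#' @export
print.recon_window <- function(x, ...) {
  if (x$n_years == 0L) {
    cat("<recon_window> empty (no year passes both gates)\n")
  } else {
    cat(sprintf("<recon_window> %d-%d (%d years)\n",
                x$first_year, x$last_year, x$n_years))
  }
  invisible(x)
}

#' Predict (reconstruct) water levels from a model
#'
#' `yhat_t = intercept + sum(slope_i * x_{i,t})` over the rows of
#' `newdata`, optionally restricted to a reliability window. Rows with a
#' missing predictor yield NA (a gap in the reconstruction).
#'
#' @param object A [recon_model()].
#' @param newdata Tibble with `water_year` and the model's predictor
#'   columns.
#' @param window Optional [reconstruction_window()] restricting the
#'   output years.
#' @param ... Unused.
#' @return Tibble `water_year`, `fitted`.
#' @export
predict.recon_model <- function(object, newdata, window = NULL, ...) {
  check_cols(newdata, c("water_year", object$predictors), "newdata")
  if (!is.null(window) && window$n_years > 0L) {
    newdata <- filter(newdata, .data$water_year >= window$first_year,
                      .data$water_year <= window$last_year)
  }
  x <- as.matrix(newdata[object$predictors])
  slopes <- object$coefficients[object$predictors]
  fitted <- object$coefficients[["(Intercept)"]] +
    as.numeric(x %*% slopes)
  tibble(water_year = newdata$water_year, fitted = fitted)
}

#' Split-sample verification of a reconstruction model
#'
#' Refits the model on the early part of the record and evaluates it on
#' the held-out late part: holdout R-squared (about the holdout mean, so
#' it can be negative) and the reduction of error (RE, about the
#' calibration mean). Standard dendrohydrological practice when the
#' paper-style calibration R-squared alone would overstate skill.
#'
#' @param table Predictor table (>= 20 rows).
#' @param predictors Predictor columns to fit.
#' @param holdout_fraction Fraction of the latest rows held out
#'   (default 0.3).
#' @return Tibble with `calibration_r2`, `holdout_r2`,
#'   `reduction_of_error`, `n_calibration`, `n_holdout`; or NULL with a
#'   warning if the holdout would have fewer than 5 rows.
#' @export
verify_recon <- function(table, predictors, holdout_fraction = 0.3) {
  check_cols(table, c("water_year", "target", predictors), "table")
  if (nrow(table) < 20L) abort("verification needs at least 20 rows.")
  table <- arrange(table, .data$water_year)
  n_hold <- floor(nrow(table) * holdout_fraction)
  if (n_hold < 5L) {
    warn("fewer than 5 holdout rows; verification skipped.")
    return(NULL)
  }
  cal <- head(table, nrow(table) - n_hold)
  hold <- tail(table, n_hold)
  m <- fit_recon(cal, predictors)
  pred <- predict(m, hold)$fitted
  sse <- sum((hold$target - pred)^2)
  tibble(
    calibration_r2 = m$r2,
    holdout_r2 = 1 - sse / sum((hold$target - mean(hold$target))^2),
    reduction_of_error = 1 - sse / sum((hold$target - mean(cal$target))^2),
    n_calibration = nrow(cal),
    n_holdout = n_hold
  )
}

#' @export
print.recon_model <- function(x, ...) {
  eq <- paste(
    sprintf("%.4f x %s", x$coefficients[x$predictors],
            toupper(x$predictors)),
    collapse = " + "
  )
  cat(sprintf("<recon_model> %s = %s + %.4f\n", x$target, eq,
              x$coefficients[["(Intercept)"]]))
  if (is.finite(x$r2)) {
    cat(sprintf("  R2 = %.2f, p = %.3g, n = %d (%d-%d)\n", x$r2,
                x$p_value, x$n, x$calibration_period[1],
                x$calibration_period[2]))
  }
  invisible(x)
}

#' Serialize / read a reconstruction model as structured text
#'
#' Writes target, predictors, coefficients, calibration period and fit
#' statistics as a `key: value` text file; `read_recon_model()` is the
#' inverse.
#'
#' @param model A [recon_model()].
#' @param path File path.
#' @return The writer returns `path` invisibly; the reader a
#'   [recon_model()].
#' @export
write_recon_model <- function(model, path) {
  stopifnot(inherits(model, "recon_model"))
  lines <- c(
    sprintf("target: %s", model$target),
    sprintf("predictors: %s", paste(model$predictors, collapse = ",")),
    sprintf("coef_%s: %.10g", names(model$coefficients),
            model$coefficients),
    sprintf("calibration_period: %s",
            paste(model$calibration_period %||% NA, collapse = ",")),
    sprintf("r2: %.10g", model$r2),
    sprintf("p_value: %.10g", model$p_value),
    sprintf("n: %d", model$n)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_recon_model
#' @export
read_recon_model <- function(path) {
  lines <- readLines(path)
  kv <- stringr::str_match(lines, "^([^:]+): ?(.*)$")
  vals <- setNames(kv[, 3], kv[, 2])
  coef_keys <- grep("^coef_", names(vals), value = TRUE)
  coefs <- setNames(as.numeric(vals[coef_keys]),
                    sub("^coef_", "", coef_keys))
  per <- suppressWarnings(as.integer(strsplit(vals[["calibration_period"]],
                                              ",")[[1]]))
  recon_model(
    coefficients = coefs,
    target = vals[["target"]],
    calibration_period = if (anyNA(per)) NULL else per,
    r2 = as.numeric(vals[["r2"]]),
    p_value = as.numeric(vals[["p_value"]]),
    n = as.integer(vals[["n"]])
  )
}
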