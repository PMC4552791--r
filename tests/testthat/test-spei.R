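# Thornthwaite PET, water balance, accumulation, SPEI, water years.

test_that("PET is zero in freezing months and positive otherwise", {
  clim <- constant_climate(1990:1995, tmean = -2)
  expect_equal(thornthwaite_pet(clim)$pet, rep(0, nrow(clim)))

  warm <- constant_climate(1990:1995, tmean = 10)
  expect_true(all(thornthwaite_pet(warm)$pet > 0))
})

test_that("at the equator PET varies only with the month's day count", {
  clim <- constant_climate(1990:1995, tmean = 10)
  pet <- thornthwaite_pet(clim, latitude = 0)$pet
  mlen <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  daily <- pet[1:12] / mlen
  expect_equal(daily, rep(daily[1], 12), tolerance = 1e-6)
})

test_that("PET matches an independently hand-coded evaluation", {
  # oracle: direct transcription of the published formula, scalar code
  oracle_pet <- function(tmean_monthly, lat_deg) {
    heat <- sum((tmean_monthly[tmean_monthly > 0] / 5)^1.514)
    a <- 6.75e-7 * heat^3 - 7.71e-5 * heat^2 + 1.792e-2 * heat + 0.49239
    mlen <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    out <- numeric(12)
    for (m in 1:12) {
      jday <- sum(mlen[seq_len(m)]) - mlen[m] / 2
      delta <- 0.4093 * sin(2 * pi * jday / 365.25 - 1.405)
      ws <- acos(min(1, max(-1, -tan(lat_deg * pi / 180) * tan(delta))))
      k <- (24 / pi * ws / 12) * (mlen[m] / 30)
      out[m] <- if (tmean_monthly[m] <= 0) 0 else {
        16 * k * (10 * tmean_monthly[m] / heat)^a
      }
    }
    out
  }
  clim <- constant_climate(1990:1995, tmean = 10)
  got <- thornthwaite_pet(clim, 53.5)$pet[1:12]
  expect_equal(got, oracle_pet(rep(10, 12), 53.5), tolerance = 1e-10)
  expect_equal(sum((rep(10, 12) / 5)^1.514), 12 * 2^1.514)
})

test_that("PET increases with temperature and rejects polar latitudes", {
  clim5 <- constant_climate(1990:1995, tmean = 5)
  clim15 <- constant_climate(1990:1995, tmean = 15)
  expect_true(all(thornthwaite_pet(clim15)$pet > thornthwaite_pet(clim5)$pet))
  expect_error(thornthwaite_pet(clim5, latitude = 70), "latitude")
})

test_that("the water balance is precipitation minus PET", {
  clim <- constant_climate(1990:1992, tmean = 10, precip = 50)
  pet <- thornthwaite_pet(clim)
  wb <- water_balance(pet)
  expect_equal(wb$wb, wb$precip - wb$pet)
  expect_equal(water_balance(dplyr::mutate(pet, precip = pet))$wb,
               rep(0, nrow(pet)))
})

test_that("accumulation equals a brute-force windowed sum", {
  withr::local_seed(41)
  monthly <- constant_climate(1990:1999) |>
    dplyr::mutate(wb = rnorm(dplyr::n()))
  acc <- accumulate_balance(monthly, k = 6)
  naive <- vapply(seq_len(nrow(monthly)), function(i) {
    if (i < 6) NA_real_ else sum(monthly$wb[(i - 5):i])
  }, numeric(1))
  expect_equal(acc$acc, naive)

  expect_equal(accumulate_balance(monthly, k = 1)$acc, monthly$wb)
  const <- dplyr::mutate(monthly, wb = 2)
  expect_equal(accumulate_balance(const, k = 12)$acc[12:120],
               rep(24, 109))
})

test_that("a gap poisons exactly the windows that span it", {
  monthly <- constant_climate(1990:1999) |>
    dplyr::mutate(wb = 1) |>
    dplyr::filter(!(year == 1995 & month == 6))
  acc <- accumulate_balance(monthly, k = 3)
  gap_idx <- which(acc$year == 1995 & acc$month %in% 6:8)
  expect_true(all(is.na(acc$acc[gap_idx])))
  expect_equal(acc$acc[acc$year == 1995 & acc$month == 9], 3)
})

test_that("log-logistic PWM fitting recovers planted parameters", {
  withr::local_seed(42)
  u <- runif(50000)
  x <- 50 * (u / (1 - u))^(1 / 3) # shape 3, scale 50, origin 0
  fit <- fit_loglogistic_pwm(x)
  expect_lt(abs(fit$shape - 3) / 3, 0.05)
  expect_lt(abs(fit$scale - 50) / 50, 0.05)
  expect_lt(abs(fit$origin) / 50, 0.05)
})

test_that("affine transforms move scale and origin but not shape", {
  withr::local_seed(43)
  u <- runif(2000)
  x <- 10 * (u / (1 - u))^(1 / 2.5)
  f1 <- fit_loglogistic_pwm(x)
  f2 <- fit_loglogistic_pwm(3 * x + 7)
  expect_equal(f2$shape, f1$shape, tolerance = 1e-10)
  expect_equal(f2$scale, 3 * f1$scale, tolerance = 1e-10)
  expect_equal(f2$origin, 3 * f1$origin + 7, tolerance = 1e-8)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_loglogistic_pwm(rnorm(19)), "20")
  expect_error(fit_loglogistic_pwm(rep(1, 30)), "zero variance")
})

test_that("SPEI is standardized per calendar month over calibration", {
  cfg <- synth_config(n_trees = 2, start_year = 1900, end_year = 1999,
                      seed = 44L)
  wb <- water_balance(thornthwaite_pet(generate_monthly_climate(cfg)))
  sp <- spei(wb, scales = c(6, 24, 72))
  stats_by_month <- sp |>
    dplyr::filter(!is.na(spei)) |>
    dplyr::group_by(scale_k, month) |>
    dplyr::summarise(mu = mean(spei), sigma = sd(spei), .groups = "drop")
  expect_true(all(abs(stats_by_month$mu) <= 0.05))
  expect_true(all(abs(stats_by_month$sigma - 1) <= 0.1))
  # persistence grows with the accumulation scale
  ac_by_scale <- sp |>
    dplyr::filter(!is.na(spei)) |>
    dplyr::group_by(scale_k) |>
    dplyr::summarise(ac = autocorr1(spei)) |>
    dplyr::arrange(scale_k)
  expect_true(all(diff(ac_by_scale$ac) > 0))
})

test_that("the calibration median maps to SPEI near zero", {
  # long record so the sample median is a precise estimate of the
  # distribution median the fit sends to F = 0.5
  cfg <- synth_config(n_trees = 2, start_year = 1, end_year = 2000,
                      seed = 45L)
  wb <- water_balance(thornthwaite_pet(generate_monthly_climate(cfg)))
  acc <- accumulate_balance(wb, 6)
  sp <- spei(wb, scales = 6)
  joined <- dplyr::inner_join(acc, sp, by = c("site_id", "year", "month"))
  for (m in c(3, 9)) {
    sub <- dplyr::filter(joined, month == m, !is.na(acc))
    med_row <- which.min(abs(sub$acc - median(sub$acc)))
    expect_lt(abs(sub$spei[med_row]), 0.05)
  }
})

test_that("SPEI is monotone in the accumulation within a month", {
  cfg <- synth_config(n_trees = 2, start_year = 1920, end_year = 1999,
                      seed = 46L)
  wb <- water_balance(thornthwaite_pet(generate_monthly_climate(cfg)))
  acc <- accumulate_balance(wb, 12)
  sp <- spei(wb, scales = 12)
  joined <- dplyr::inner_join(acc, sp, by = c("site_id", "year", "month")) |>
    dplyr::filter(month == 7, !is.na(acc))
  ord <- order(joined$acc)
  expect_true(all(diff(joined$spei[ord]) > 0))
})

test_that("an off-calibration wet extreme exceeds all calibration SPEI", {
  cfg <- synth_config(n_trees = 2, start_year = 1920, end_year = 2000,
                      seed = 47L)
  wb <- water_balance(thornthwaite_pet(generate_monthly_climate(cfg)))
  # calibrate on 1920-1990, then plant an unprecedented wet final July
  wet <- dplyr::mutate(
    wb, wb = ifelse(year == 2000 & month == 7, max(wb) * 12, wb)
  )
  sp <- spei(wet, scales = 6, calibration = c(1920, 1990))
  cal_max <- max(sp$spei[sp$year <= 1990 & sp$month == 7], na.rm = TRUE)
  extreme <- sp$spei[sp$year == 2000 & sp$month == 7]
  expect_gt(extreme, cal_max)
})

test_that("insufficient calibration data names the month and scale", {
  cfg <- synth_config(n_trees = 2, start_year = 1990, end_year = 1999,
                      seed = 48L)
  wb <- water_balance(thornthwaite_pet(generate_monthly_climate(cfg)))
  expect_error(spei(wb, scales = 6), "month 1 at scale 6")
})

test_that("water years span October through September", {
  # Oct 1999 belongs to water year 2000, Sep 2000 to 2000, Oct 2000 to 2001
  monthly <- tibble::tibble(
    site_id = "S1",
    year = c(1999, 2000, 2000),
    month = c(10, 9, 10),
    level = c(1, 2, 3)
  )
  wy <- water_year_mean(monthly, value_col = "level", min_months = 1)
  expect_equal(wy$water_year, c(2000, 2001))
  expect_equal(wy$value, c(1.5, 3))
})

test_that("water-year means are arithmetic and completeness is flagged", {
  full <- constant_climate(1998:2001, tmean = 0, precip = 0) |>
    dplyr::mutate(level = 0)
  full$level[full$year == 1999 & full$month == 10] <- 12
  wy <- water_year_mean(full, value_col = "level")
  expect_equal(wy$value[wy$water_year == 2000], 1)
  expect_true(wy$complete[wy$water_year == 2000])
  expect_false(wy$complete[wy$water_year == 1998]) # Jan-Sep only
  const <- water_year_mean(dplyr::mutate(full, level = 7),
                           value_col = "level")
  expect_true(all(const$value == 7))
})
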