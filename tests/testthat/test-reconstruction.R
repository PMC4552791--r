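# Predictor tables, OLS fits, model selection, gates, prediction,
# verification.

make_table <- function(n = 40, seed = 61) {
  withr::local_seed(seed)
  tibble::tibble(
    water_year = seq(1961, length.out = n),
    target = rnorm(n),
    rwi_t = rnorm(n),
    rwi_tp1 = rnorm(n),
    spei_24 = rnorm(n),
    spei_72 = rnorm(n)
  )
}

test_that("the predictor table keeps lag bookkeeping straight", {
  chron <- tibble::tibble(site_id = "S1", year = 1961:2000,
                          value = seq(1, 2, length.out = 40))
  target <- tibble::tibble(water_year = 1961:2000, value = rnorm(40),
                           complete = TRUE)
  tab <- build_predictor_table(chron, spei = NULL, target = target)
  # rwi_tp1 for water year 2000 would need the 2001 ring: row dropped
  expect_false(2000 %in% tab$water_year)
  expect_equal(attr(tab, "dropped_rows"), 1)
  expect_equal(tab$rwi_tp1[tab$water_year == 1980],
               chron$value[chron$year == 1981])
  expect_equal(tab$rwi_t[tab$water_year == 1980],
               chron$value[chron$year == 1980])

  # a target gap removes exactly that row
  gapped <- dplyr::filter(target, water_year != 1970)
  tab2 <- build_predictor_table(chron, NULL, gapped)
  expect_false(1970 %in% tab2$water_year)

  short <- dplyr::slice_head(target, n = 14)
  expect_error(build_predictor_table(chron, NULL, short), "unstable")
})

test_that("OLS recovers an exactly planted published equation", {
  tab <- make_table()
  tab$target <- 14.4390 * tab$spei_24 + 60.0453
  # noiseless fixture: lm warns about the perfect fit, which is the point
  m <- suppressWarnings(fit_recon(tab, "spei_24"))
  expect_equal(unname(m$coefficients["spei_24"]), 14.4390,
               tolerance = 1e-6)
  expect_equal(unname(m$coefficients["(Intercept)"]), 60.0453,
               tolerance = 1e-6)
  expect_equal(m$r2, 1, tolerance = 1e-9)
})

test_that("an unrelated predictor explains essentially nothing", {
  withr::local_seed(62)
  tab <- tibble::tibble(water_year = 1:10000, target = rnorm(10000),
                        spei_24 = rnorm(10000))
  m <- fit_recon(tab, "spei_24")
  expect_lt(m$r2, 0.001)
  expect_gt(m$p_value, 0.001)
})

test_that("planted slopes are recovered within 10% on average", {
  withr::local_seed(63)
  slopes <- vapply(1:200, function(rep) {
    x <- rnorm(40)
    # noise sd for planted R2 ~ 0.6: var(signal)/0.6 - var(signal)
    y <- 30 * x + rnorm(40, 0, 30 * sqrt(1 / 0.6 - 1))
    tab <- tibble::tibble(water_year = 1:40, target = y, spei_24 = x)
    unname(fit_recon(tab, "spei_24")$coefficients["spei_24"])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 30) / 30, 0.1)
})

test_that("collinear predictors are rejected", {
  tab <- make_table()
  tab$rwi_tp1 <- tab$rwi_t * 2
  expect_error(fit_recon(tab, c("rwi_t", "rwi_tp1")), "collinear")
})

test_that("residuals are orthogonal to predictors and R2 grows nested", {
  tab <- make_table(seed = 64)
  tab$target <- tab$rwi_t - 0.5 * tab$rwi_tp1 + rnorm(40)
  for (preds in list("rwi_t", c("rwi_t", "rwi_tp1"))) {
    m <- fit_recon(tab, preds)
    resid <- tab$target - predict(m, tab)$fitted
    for (p in preds) expect_lt(abs(sum(resid * tab[[p]])), 1e-8)
  }
  r2_1 <- fit_recon(tab, "rwi_t")$r2
  r2_2 <- fit_recon(tab, c("rwi_t", "rwi_tp1"))$r2
  expect_gte(r2_2, r2_1)
})

test_that("model selection follows R2 then parsimony then lag", {
  tab <- make_table(seed = 65)
  tab$target <- 2 * tab$spei_24 + rnorm(40, 0, 0.5)
  mods <- fit_reconstruction_models(tab)
  expect_setequal(unique(mods$pool), c("rwi", "spei"))
  best_spei <- select_best(dplyr::filter(mods, pool == "spei"))
  expect_equal(best_spei$predictors, "spei_24")

  # ties: same R2, fewer predictors wins; then smaller lag
  m1 <- recon_model(c(`(Intercept)` = 0, rwi_t = 1), r2 = 0.5)
  m2 <- recon_model(c(`(Intercept)` = 0, rwi_t = 1, rwi_tp1 = 1),
                    r2 = 0.5)
  m3 <- recon_model(c(`(Intercept)` = 0, rwi_tp1 = 1), r2 = 0.5)
  expect_equal(select_best(list(m2, m1, m3))$predictors, "rwi_t")
  expect_equal(select_best(list(m2))$predictors, c("rwi_t", "rwi_tp1"))
})

test_that("encoded published models evaluate at their intercepts", {
  ll <- recon_model(c(`(Intercept)` = 60.0453, spei_24 = 14.4390),
                    target = "lake_level")
  gw <- recon_model(c(`(Intercept)` = 60.3187, spei_72 = 0.3564),
                    target = "groundwater")
  at_zero <- tibble::tibble(water_year = 2000L, spei_24 = 0, spei_72 = 0)
  expect_equal(predict(ll, at_zero)$fitted, 60.0453)
  expect_equal(predict(gw, at_zero)$fitted, 60.3187)

  flat <- recon_model(c(`(Intercept)` = 5, rwi_t = 0))
  tab <- tibble::tibble(water_year = 1:20, rwi_t = rnorm(20))
  expect_equal(predict(flat, tab)$fitted, rep(5, 20))
})

test_that("the reliability window respects both gates", {
  chron <- tibble::tibble(
    site_id = "S1", year = 1901:2000, value = 1,
    sample_depth = 15L, running_eps = 0.9
  )
  w <- reconstruction_window(chron)
  expect_equal(c(w$first_year, w$last_year), c(1901, 2000))

  dip <- chron
  dip$sample_depth[dip$year == 1950] <- 9L
  w2 <- reconstruction_window(dip)
  expect_equal(c(w2$first_year, w2$last_year), c(1951, 2000))

  low_eps <- chron
  low_eps$running_eps[low_eps$year > 1980] <- 0.7
  w3 <- reconstruction_window(low_eps)
  expect_equal(c(w3$first_year, w3$last_year), c(1901, 1980))

  none <- dplyr::mutate(chron, sample_depth = 5L)
  expect_equal(reconstruction_window(none)$n_years, 0)
})

test_that("a staggered synthetic stand gates the window inside the span", {
  cfg <- synth_config(seed = 66L)
  sim <- simulate_lake_study(cfg)
  chron <- suppressWarnings(
    build_chronology(standardize_horizontal(average_cores_per_tree(sim$rings)))
  )
  w <- reconstruction_window(chron)
  expect_gt(w$n_years, 0)
  expect_gt(w$first_year, min(chron$year))
  inside <- dplyr::filter(chron, year >= w$first_year,
                          year <= w$last_year)
  expect_true(all(inside$sample_depth >= 10))
  expect_true(all(inside$running_eps >= 0.85))
})

test_that("verification is exact for noiseless models and honest on null", {
  tab <- make_table(seed = 67)
  tab$target <- 3 * tab$spei_72 + 1
  v <- suppressWarnings(verify_recon(tab, "spei_72"))
  expect_equal(v$holdout_r2, 1, tolerance = 1e-9)
  expect_equal(v$reduction_of_error, 1, tolerance = 1e-9)

  withr::local_seed(68)
  null_r2 <- vapply(1:100, function(rep) {
    tab <- tibble::tibble(water_year = 1:40, target = rnorm(40),
                          spei_24 = rnorm(40))
    verify_recon(tab, "spei_24")$holdout_r2
  }, numeric(1))
  expect_lte(mean(null_r2), 0)
})

test_that("holdout R2 tracks calibration R2 for a real signal", {
  withr::local_seed(69)
  gaps <- vapply(1:100, function(rep) {
    x <- rnorm(60)
    y <- x + rnorm(60, 0, sqrt(1 / 0.6 - 1))
    tab <- tibble::tibble(water_year = 1:60, target = y, spei_24 = x)
    v <- verify_recon(tab, "spei_24")
    v$holdout_r2 - v$calibration_r2
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.15)
})

test_that("models round-trip through text serialization and tidiers", {
  tab <- make_table(seed = 70)
  tab$target <- 2 * tab$rwi_t + rnorm(40, 0, 0.3)
  m <- fit_recon(tab, "rwi_t", target_label = "lake_level")
  path <- withr::local_tempfile(fileext = ".txt")
  write_recon_model(m, path)
  back <- read_recon_model(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-9)
  expect_equal(back$r2, m$r2, tolerance = 1e-9)
  expect_equal(back$calibration_period, m$calibration_period)

  td <- tidy(m)
  expect_setequal(td$term, c("(Intercept)", "rwi_t"))
  g <- glance(m)
  expect_equal(g$nobs, 40)
  expect_equal(g$r.squared, m$r2)
})
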