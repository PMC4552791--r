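# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# A small, fast generator configuration.
small_config <- function(...) {
  synth_config(n_trees = 8, start_year = 1940, end_year = 2010,
               seed = 20260925L, ...)
}

# Common-factor stand: n series of length t_len with pairwise correlation
# rho, plus the common signal z. Returns a long rwi tibble and z.
common_factor_stand <- function(n, rho, t_len, first_year = 1901,
                                site_id = "S1") {
  z <- rnorm(t_len)
  yrs <- seq(first_year, length.out = t_len)
  rwi <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      series_id = sprintf("%s%02d", site_id, i),
      site_id = site_id,
      year = yrs,
      rwi = sqrt(rho) * z + sqrt(1 - rho) * rnorm(t_len)
    )
  })
  list(rwi = rwi, z = z, years = yrs)
}

# Brute-force EPS oracle: empirical squared correlation between the mean
# of n simulated series and the common signal, averaged over replicates.
eps_bruteforce <- function(n, rho, reps = 200, t_len = 300) {
  mean(vapply(seq_len(reps), function(r) {
    z <- rnorm(t_len)
    mat <- sqrt(rho) * z +
      sqrt(1 - rho) * matrix(rnorm(t_len * n), t_len, n)
    cor(rowMeans(mat), z)^2
  }, numeric(1)))
}

# Monthly climate grid with constant values, one site.
constant_climate <- function(years, tmean = 10, precip = 50,
                             site_id = "S1") {
  tidyr::crossing(year = years, month = 1:12) |>
    dplyr::mutate(site_id = site_id, tmean = tmean, precip = precip) |>
    dplyr::select(site_id, year, month, tmean, precip)
}

# Full predictor-table fixture from the default-sized synthetic study.
synthetic_predictor_table <- function(config) {
  sim <- simulate_lake_study(config)
  trees <- average_cores_per_tree(sim$rings)
  chron <- suppressWarnings(build_chronology(standardize_horizontal(trees)))
  wb <- water_balance(thornthwaite_pet(sim$climate, config$latitude))
  sp <- spei(wb)
  target <- water_year_mean(sim$hydro, value_col = "level")
  list(
    table = build_predictor_table(chron, sp, target),
    chronology = chron,
    sim = sim
  )
}
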