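# Shared growth variation across trees and its monthly climate correlates.

#' Principal component analysis of detrended tree-ring series
#'
#' PCA of the years-by-series matrix (series as variables, years as
#' observations) over a common period. Variables are centered and, by
#' default, scaled to unit variance (correlation PCA, the dendro
#' convention for index series of comparable variance). Scores represent
#' common growth variation; loadings give each tree's association with a
#' component.
#'
#' @param rwi Detrended index tibble (`series_id`, `site_id`, `year`,
#'   `rwi`); at least 3 series, all complete over `period`.
#' @param period `c(first, last)` calendar years.
#' @param scale. Scale series to unit variance (default TRUE).
#' @return An object of class `tree_pca`: list with tibbles `scores`
#'   (`year`, `PC1`, ...), `loadings` (`series_id`, `site_id`, `PC1`,
#'   ...), `explained_variance`, and the `period`.
#' @export
pca_trees <- function(rwi, period, scale. = TRUE) {
  check_cols(rwi, c("series_id", "site_id", "year", "rwi"), "rwi")
  sub <- filter(rwi, .data$year >= period[1], .data$year <= period[2])
  n_years <- period[2] - period[1] + 1
  counts <- sub %>%
    group_by(.data$series_id) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  bad <- counts$series_id[counts$n < n_years]
  if (length(bad) > 0L) {
    abort(paste0("series incomplete over the period: ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(counts) < 3L) abort("PCA needs at least 3 series.")

  mat <- rwi_wide(sub)
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  sites <- distinct(sub, .data$series_id, .data$site_id)

  structure(
    list(
      scores = bind_cols(tibble(year = as.integer(rownames(mat))),
                         as_tibble(pc$x)),
      loadings = bind_cols(
        tibble(series_id = rownames(pc$rotation)),
        as_tibble(pc$rotation)
      ) %>%
        left_join(sites, by = "series_id") %>%
        select("series_id", "site_id", dplyr::everything()),
      explained_variance = tibble(
        component = colnames(pc$x),
        explained = expl
      ),
      period = as.integer(period),
      scaled = scale.
    ),
    class = "tree_pca"
  )
}

#' @export
print.tree_pca <- function(x, ...) {
  cat(sprintf("<tree_pca> %d series, %d-%d\n",
              nrow(x$loadings), x$period[1], x$period[2]))
  ev <- head(x$explained_variance, 3)
  cat(sprintf("  %s\n", paste(sprintf("%s %.1f%%", ev$component,
                                      100 * ev$explained),
                              collapse = ", ")))
  invisible(x)
}

#' Monthly correlation function of annual scores with a climate variable
#'
#' Pearson correlation of an annual series (e.g. PC scores) with each
#' monthly value over the standard dendro window: May of the previous
#' year through September of the current year (17 monthly windows). The
#' score of year `t` is paired with months May..December of year `t - 1`
#' and January..September of year `t`. Significance is a per-month
#' two-sided test at p < 0.05 with no multiple-testing correction.
#'
#' @param scores Tibble with `year` and a score column.
#' @param monthly Monthly tibble with `year`, `month` and a value column.
#' @param score_col,value_col Column names; defaults `"PC1"` and the
#'   first non-index column of `monthly`.
#' @return A tibble with 17 rows: `month_label` (e.g. `"prev May"`),
#'   `relative_year` (-1 or 0), `month`, `n`, `r`, `p_value`,
#'   `significant`.
#' @export
monthly_correlations <- function(scores, monthly, score_col = "PC1",
                                 value_col = NULL) {
  check_cols(scores, c("year", score_col), "scores")
  check_cols(monthly, c("year", "month"), "monthly")
  if (is.null(value_col)) {
    value_col <- setdiff(names(monthly),
                         c("site_id", "kind", "variable", "year", "month",
                           "scale_k"))[1]
  }
  check_cols(monthly, value_col, "monthly")

  window <- tibble(
    relative_year = c(rep(-1L, 8), rep(0L, 9)),
    month = c(5:12, 1:9)
  )
  labels <- c(paste("prev", month.abb[5:12]),
              paste("curr", month.abb[1:9]))

  purrr::pmap_dfr(
    list(window$relative_year, window$month, labels),
    function(rel, m, lab) {
      mon <- filter(monthly, .data$month == m) %>%
        mutate(score_year = .data$year - rel)
      joined <- dplyr::inner_join(
        select(scores, "year", score = dplyr::all_of(score_col)),
        select(mon, "score_year", value = dplyr::all_of(value_col)),
        by = c(year = "score_year")
      ) %>%
        filter(is.finite(.data$score), is.finite(.data$value))
      if (nrow(joined) < 10L) {
        abort(sprintf("fewer than 10 overlapping years for %s.", lab))
      }
      ct <- cor.test(joined$score, joined$value)
      tibble(month_label = lab, relative_year = rel, month = m,
             n = nrow(joined), r = unname(ct$estimate),
             p_value = ct$p.value, significant = ct$p.value < 0.05)
    }
  )
}

#' Cross-site chronology correlations
#'
#' Pearson correlation (with p-values) between every pair of site master
#' chronologies over a common period — the regional-vs-local signal test.
#'
#' @param chronology Chronology tibble (`site_id`, `year`, `value`) for
#'   two or more sites.
#' @param period Optional `c(first, last)` years; default full overlap.
#' @param min_overlap Minimum overlapping years per pair (default 10);
#'   pairs below it are returned with NA.
#' @return Tibble `site_a`, `site_b`, `n`, `r`, `p_value`.
#' @export
cross_site_correlation <- function(chronology, period = NULL,
                                   min_overlap = 10) {
  check_cols(chronology, c("site_id", "year", "value"), "chronology")
  if (!is.null(period)) {
    chronology <- filter(chronology, .data$year >= period[1],
                         .data$year <= period[2])
  }
  sites <- sort(unique(chronology$site_id))
  if (length(sites) < 2L) abort("need at least two sites.")
  pairs <- utils::combn(sites, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- filter(chronology, .data$site_id == p[1])
    b <- filter(chronology, .data$site_id == p[2])
    j <- dplyr::inner_join(select(a, "year", va = "value"),
                           select(b, "year", vb = "value"), by = "year")
    if (nrow(j) < min_overlap) {
      return(tibble(site_a = p[1], site_b = p[2], n = nrow(j),
                    r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(j$va, j$vb)
    tibble(site_a = p[1], site_b = p[2], n = nrow(j),
           r = unname(ct$estimate), p_value = ct$p.value)
  })
}
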