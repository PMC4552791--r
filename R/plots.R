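# ggplot2 graphics for the main result types.

#' Plot a site chronology with its sample depth
#'
#' Index values as a line, per-year sample depth as a shaded area on a
#' secondary axis, faceted by site.
#'
#' @param chronology Chronology tibble from [build_chronology()].
#' @return A ggplot object.
#' @export
plot_chronology <- function(chronology) {
  check_cols(chronology, c("site_id", "year", "value", "sample_depth"),
             "chronology")
  depth_scale <- max(chronology$value, na.rm = TRUE) /
    max(chronology$sample_depth, na.rm = TRUE)
  ggplot2::ggplot(chronology, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$sample_depth * depth_scale),
                       fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_id), ncol = 1) +
    ggplot2::scale_y_continuous(
      "ring-width index",
      sec.axis = ggplot2::sec_axis(~ . / depth_scale, name = "trees")
    ) +
    ggplot2::labs(x = "year") +
    ggplot2::theme_minimal()
}

#' Plot SPEI series across accumulation scales
#'
#' Monthly SPEI as bars (wet positive, dry negative), faceted by scale.
#'
#' @param spei_tbl Long SPEI tibble from [spei()].
#' @return A ggplot object.
#' @export
plot_spei <- function(spei_tbl) {
  check_cols(spei_tbl, c("year", "month", "scale_k", "spei"), "spei_tbl")
  df <- mutate(spei_tbl, time = .data$year + (.data$month - 0.5) / 12,
               sign = ifelse(.data$spei >= 0, "wet", "dry"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$spei,
                                   fill = .data$sign)) +
    ggplot2::geom_col(width = 1 / 12, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(wet = "steelblue",
                                          dry = "firebrick")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$scale_k)) +
    ggplot2::labs(x = "year", y = "SPEI") +
    ggplot2::theme_minimal()
}

#' Plot a monthly correlation function
#'
#' Bar chart of the 17 monthly Pearson correlations (previous May through
#' current September), with significant months highlighted.
#'
#' @param corfun Tibble from [monthly_correlations()].
#' @return A ggplot object.
#' @export
plot_monthly_correlations <- function(corfun) {
  check_cols(corfun, c("month_label", "r", "significant"), "corfun")
  corfun <- mutate(corfun,
                   month_label = factor(.data$month_label,
                                        levels = .data$month_label))
  ggplot2::ggplot(corfun, ggplot2::aes(x = .data$month_label, y = .data$r,
                                       fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' PCA biplot-style loading plot
#'
#' Loadings of each tree-ring series on the first two components,
#' coloured by site — the visual check for site separation.
#'
#' @param object A [pca_trees()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tree_pca
#' @export
autoplot.tree_pca <- function(object, ...) {
  ev <- object$explained_variance$explained
  ggplot2::ggplot(object$loadings,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$site_id)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = "site"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs reconstructed water levels
#'
#' @param observed Tibble `water_year`, `value` (observed levels).
#' @param ... Named tibbles `water_year`, `fitted` from
#'   [predict.recon_model()]; names become legend labels.
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(observed, ...) {
  check_cols(observed, c("water_year", "value"), "observed")
  recons <- rlang::list2(...)
  df <- bind_rows(
    tibble(water_year = observed$water_year, level = observed$value,
           series = "observed"),
    purrr::imap_dfr(recons, function(r, nm) {
      tibble(water_year = r$water_year, level = r$fitted, series = nm)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$water_year, y = .data$level,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "water year", y = "level (gauge units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
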