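# broom-style tidiers for fitted objects.

#' Tidy a reconstruction model
#'
#' One row per model term with its coefficient, in gauge units per
#' predictor unit.
#'
#' @param x A [recon_model()].
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @method tidy recon_model
#' @export
tidy.recon_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' Glance at a reconstruction model
#'
#' @param x A [recon_model()].
#' @param ... Unused.
#' @return One-row tibble with `target`, `predictors`, `r.squared`,
#'   `p.value`, `nobs`, `calibration_start`, `calibration_end`.
#' @method glance recon_model
#' @export
glance.recon_model <- function(x, ...) {
  tibble(
    target = x$target,
    predictors = paste(x$predictors, collapse = "+"),
    r.squared = x$r2,
    p.value = x$p_value,
    nobs = x$n,
    calibration_start = (x$calibration_period %||% c(NA, NA))[1],
    calibration_end = (x$calibration_period %||% c(NA, NA))[2]
  )
}

#' Tidy a tree-ring PCA
#'
#' @param x A [pca_trees()] result.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return The requested tibble: per-year scores, per-series loadings, or
#'   per-component explained-variance fractions.
#' @method tidy tree_pca
#' @export
tidy.tree_pca <- function(x, matrix = c("scores", "loadings",
                                        "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         eigenvalues = x$explained_variance)
}

#' Glance at a tree-ring PCA
#'
#' @param x A [pca_trees()] result.
#' @param ... Unused.
#' @return One-row tibble with the period, number of series, and the
#'   variance fractions of the first two components.
#' @method glance tree_pca
#' @export
glance.tree_pca <- function(x, ...) {
  tibble(
    n_series = nrow(x$loadings),
    first_year = x$period[1],
    last_year = x$period[2],
    pc1_explained = x$explained_variance$explained[1],
    pc2_explained = x$explained_variance$explained[2]
  )
}
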