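# Internal helpers shared across modules.

check_cols <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` must contain column%s %s.",
      arg, if (length(missing) > 1L) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  arg,
                  if (closed_lower) "[" else "(", format(lower),
                  format(upper), if (closed_upper) "]" else ")"))
  }
  invisible(x)
}

# Evaluate `expr` under a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Deterministic sub-stream seeds so adding a site/tree never perturbs the
# streams of existing ones.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  primes <- c(104729, 7919, 613)[seq_along(idx)]
  as.integer((seed + sum(idx * primes)) %% 2147483647)
}

# Water year t runs October (t - 1) .. September t.
water_year_of <- function(year, month) {
  ifelse(month >= 10L, year + 1L, year)
}

month_index <- function(year, month) year * 12L + (month - 1L)

days_in_month <- function() {
  c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
}
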