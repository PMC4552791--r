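# Tucson/RWL decadal format and long-format monthly CSV I/O.

#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the classic decadal format: an 8-character series id, the
#' decade's first year, and up to ten integer ring widths per line. Units
#' are normalized to mm by the stop-marker convention: a terminal `999`
#' marks 0.01 mm units, a terminal `-9999` marks 0.001 mm units.
#'
#' @param path File path.
#' @return Long ring-width tibble `series_id`, `site_id`, `year`,
#'   `width_mm` (the site id is the leading alphabetic part of the series
#'   id). An empty file yields an empty tibble with a warning.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(sprintf("`%s` contains no series.", path))
    return(tibble(series_id = character(), site_id = character(),
                  year = integer(), width_mm = double()))
  }

  acc <- list()
  open <- list() # per-id: list(first_year, values, done)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    id <- trimws(substr(line, 1, 8))
    rest <- strsplit(trimws(substr(line, 9, nchar(line))), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(rest))
    if (id == "" || length(vals) < 2L || anyNA(vals)) {
      abort(sprintf("malformed decade line %d in `%s`.", ln, path))
    }
    decade_year <- vals[1]
    vals <- vals[-1]
    st <- open[[id]]
    if (is.null(st)) {
      st <- list(first_year = as.integer(decade_year), values = numeric(),
                 stop = NA_real_)
    } else {
      expected <- st$first_year + length(st$values)
      if (decade_year != expected) {
        abort(sprintf(
          "non-monotone years for series `%s` at line %d (expected %d, found %d).",
          id, ln, expected, as.integer(decade_year)
        ))
      }
    }
    hit_stop <- which(vals %in% c(999, -9999))
    if (length(hit_stop) > 0L) {
      st$stop <- vals[hit_stop[1]]
      st$values <- c(st$values, vals[seq_len(hit_stop[1] - 1L)])
      acc[[length(acc) + 1L]] <- st_to_tibble(id, st)
      open[[id]] <- NULL
    } else {
      st$values <- c(st$values, vals)
      open[[id]] <- st
    }
  }
  for (id in names(open)) {
    warn(sprintf("series `%s` has no stop marker; assuming 0.01 mm units.",
                 id))
    st <- open[[id]]
    st$stop <- 999
    acc[[length(acc) + 1L]] <- st_to_tibble(id, st)
  }
  bind_rows(acc)
}

st_to_tibble <- function(id, st) {
  divisor <- if (identical(st$stop, -9999)) 1000 else 100
  if (any(st$values < 0)) {
    abort(sprintf("series `%s` contains negative ring widths.", id))
  }
  site <- stringr::str_extract(id, "^[A-Za-z]+")
  tibble(
    series_id = id,
    site_id = if (is.na(site)) id else site,
    year = st$first_year + seq_along(st$values) - 1L,
    width_mm = st$values / divisor
  )
}

#' Write ring-width series to a Tucson/RWL decadal file
#'
#' Emits the dominant community dialect: integer widths in units of
#' `precision` mm, ten values per decade line, stop marker `999` for
#' 0.01 mm (or `-9999` for 0.001 mm) after the final value. Series ids
#' longer than 8 characters are truncated with a warning.
#'
#' @param rw Long ring-width tibble (`series_id`, `year`, `width_mm`;
#'   years contiguous per series).
#' @param path Output file path.
#' @param precision Measurement unit in mm: 0.01 (default) or 0.001.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rw, path, precision = 0.01) {
  check_cols(rw, c("series_id", "year", "width_mm"), "rw")
  if (!precision %in% c(0.01, 0.001)) {
    abort("`precision` must be 0.01 or 0.001 mm.")
  }
  stop_marker <- if (precision == 0.01) 999 else -9999

  out <- character()
  for (id in unique(rw$series_id)) {
    df <- arrange(filter(rw, .data$series_id == id), .data$year)
    if (any(diff(df$year) != 1L)) {
      abort(sprintf("series `%s` has non-contiguous years.", id))
    }
    wid <- id
    if (nchar(wid) > 8L) {
      wid <- substr(wid, 1, 8)
      warn(sprintf("series id `%s` truncated to `%s`.", id, wid))
    }
    ints <- as.integer(round(df$width_mm / precision))
    years <- df$year
    tokens <- c(ints, stop_marker)
    tok_year <- c(years, max(years) + 1L)
    row_of <- tok_year %/% 10L
    for (dec in unique(row_of)) {
      sel <- row_of == dec
      out <- c(out, paste0(
        formatC(wid, width = -8),
        formatC(tok_year[sel][1], width = 4),
        paste0(formatC(tokens[sel], width = 6), collapse = "")
      ))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a long-format monthly CSV
#'
#' Reads `year,month,value` (gauge series) or `year,month,tmean,precip`
#' (climate) files into the package's monthly tibble shapes. Months are
#' validated (1-12, no duplicates); missing months remain gaps and are
#' never interpolated.
#'
#' @param path File path.
#' @param kind One of `"climate"`, `"lake_level"`, `"groundwater"`.
#' @param site_id Site label attached to the records.
#' @return For climate, a tibble `site_id`, `year`, `month`, `tmean`,
#'   `precip`; for gauge kinds, `site_id`, `kind`, `year`, `month`,
#'   `level`.
#' @export
read_monthly_csv <- function(path, kind = c("climate", "lake_level",
                                            "groundwater"),
                             site_id = "S1") {
  kind <- match.arg(kind)
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  check_cols(df, c("year", "month"), "path")
  if (any(df$month < 1 | df$month > 12)) {
    abort(sprintf("`%s`: month outside 1..12.", path))
  }
  if (anyDuplicated(month_index(df$year, df$month)) > 0) {
    abort(sprintf("`%s`: duplicated (year, month).", path))
  }
  df <- arrange(df, .data$year, .data$month)
  if (kind == "climate") {
    check_cols(df, c("tmean", "precip"), "path")
    if (any(df$precip < 0, na.rm = TRUE)) {
      abort(sprintf("`%s`: negative precipitation.", path))
    }
    tibble(site_id = site_id, year = as.integer(df$year),
           month = as.integer(df$month), tmean = df$tmean,
           precip = df$precip)
  } else {
    check_cols(df, "value", "path")
    tibble(site_id = site_id, kind = kind, year = as.integer(df$year),
           month = as.integer(df$month), level = df$value)
  }
}

#' Write a monthly series to long-format CSV
#'
#' Inverse of [read_monthly_csv()]: gauge series as `year,month,value`,
#' climate as `year,month,tmean,precip`.
#'
#' @param monthly Monthly tibble (climate or gauge shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monthly_csv <- function(monthly, path) {
  check_cols(monthly, c("year", "month"), "monthly")
  if ("level" %in% names(monthly)) {
    readr::write_csv(
      select(rename(monthly, value = "level"), "year", "month", "value"),
      path
    )
  } else {
    check_cols(monthly, c("tmean", "precip"), "monthly")
    readr::write_csv(select(monthly, "year", "month", "tmean", "precip"),
                     path)
  }
  invisible(path)
}

#' Write / read a generator configuration as a key-value text file
#'
#' Serializes a [synth_config()] as one `key: value` pair per line
#' (Debian-control style), so a simulation's conditions can be archived
#' next to its outputs.
#'
#' @param config A [synth_config()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [synth_config()].
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  write.dcf(data.frame(lapply(unclass(config), format), check.names = FALSE),
            path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  do.call(synth_config, lapply(raw, as.numeric))
}
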