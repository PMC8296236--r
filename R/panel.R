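#' Construct a city panel
#'
#' A city panel is one city's daily warm-season mortality/weather series:
#' strictly increasing May-September dates over the baseline years,
#' non-negative integer daily death counts (NA marks a missing day), and one
#' column per available temperature metric. `dow` (day of week, Monday = 1)
#' and `time_index` (consecutive in-season day counter over the whole panel,
#' no winter gaps) are derived on construction.
#'
#' @param city_id,country_id identifiers.
#' @param dates `Date` vector, strictly increasing.
#' @param deaths daily death counts; non-negative integers or `NA`.
#' @param metrics data.frame of per-day metric values (columns named as in
#'   [metric_names()]; any subset).
#' @param meta optional list of provenance notes (warnings, fallbacks).
#' @return object of class `city_panel`.
#' @export
city_panel <- function(city_id, country_id, dates, deaths, metrics,
                       meta = list()) {
  dates <- as.Date(dates)
  n <- length(dates)
  stopifnot(is.data.frame(metrics), nrow(metrics) == n, length(deaths) == n)
  if (n > 1 && any(diff(dates) <= 0))
    stop("dates must be strictly increasing")
  mon <- as.integer(format(dates, "%m"))
  if (any(mon < 5L | mon > 9L))
    stop("all dates must fall in the May-September warm season")
  ok <- !is.na(deaths)
  if (any(deaths[ok] < 0) || any(deaths[ok] != round(deaths[ok])))
    stop("deaths must be non-negative integers (NA = missing)")
  df <- data.frame(
    date = dates,
    year = as.integer(format(dates, "%Y")),
    deaths = as.integer(round(deaths)),
    dow = as.integer(format(dates, "%u")),   # 1 = Monday .. 7 = Sunday
    time_index = seq_len(n)
  )
  for (m in names(metrics)) df[[m]] <- as.numeric(metrics[[m]])
  structure(list(city_id = as.character(city_id),
                 country_id = as.character(country_id),
                 data = df,
                 metrics = names(metrics),
                 meta = meta),
            class = "city_panel")
}

#' @export
print.city_panel <- function(x, ...) {
  cat("<city_panel> ", x$city_id, " (", x$country_id, "): ",
      nrow(x$data), " days, ",
      length(unique(x$data$year)), " seasons, metrics: ",
      paste(x$metrics, collapse = ", "), "\n", sep = "")
  if (length(x$meta$warnings))
    cat("  warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Read a city panel from CSV
#'
#' Canonical dialect: comma-separated, UTF-8, header row, `.` decimal, one
#' row per day, ISO-8601 dates. Expected columns: `city`, `date`, `deaths`,
#' optionally `country`, the metric columns, and/or raw humidity columns
#' (`rh_mean`, `rh_max_time`, `rh_min_time` or `dewpoint_*`) from which the
#' apparent-temperature metrics are derived when absent. Rows outside the
#' configured season months or baseline years are dropped; gaps inside a
#' season are filled with explicit `NA`-marker rows. Duplicate dates and
#' non-integer death counts are hard errors; a metric with more than 10%
#' missing days is recorded as a warning in the panel metadata.
#'
#' @param path CSV file path.
#' @param config a [study_config()]; controls season window, baseline years
#'   and the apparent-temperature formula.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(deaths = "n_dead")`.
#' @param country_id country identifier; defaults to a `country` column if
#'   present, else `"XX"`.
#' @return a validated [city_panel()].
#' @export
read_city_panel <- function(path, config = study_config(), schema = NULL,
                            country_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop("schema column not found in file: ", schema[[canon]])
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  need <- c("date", "deaths")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("CSV lacks required columns: ", paste(missing_cols, collapse = ", "))
  dates <- as.Date(raw$date)
  if (anyNA(dates)) stop("unparseable dates (expect ISO-8601)")
  if (anyDuplicated(dates)) {
    dup <- dates[duplicated(dates)][1]
    stop("duplicate date in panel: ", format(dup))
  }
  ok <- !is.na(raw$deaths)
  if (any(raw$deaths[ok] != round(raw$deaths[ok])))
    stop("non-integer death counts")

  keep <- as.integer(format(dates, "%m")) %in% config$season_months &
    as.integer(format(dates, "%Y")) %in% config$baseline_years
  raw <- raw[keep, , drop = FALSE]
  dates <- dates[keep]
  if (!nrow(raw)) stop("no rows inside the configured season window")
  o <- order(dates)
  raw <- raw[o, , drop = FALSE]
  dates <- dates[o]

  # fill internal in-season gaps with explicit missing markers
  yr <- as.integer(format(dates, "%Y"))
  full <- do.call(c, lapply(unique(yr), function(y) {
    seq(min(dates[yr == y]), max(dates[yr == y]), by = "day")
  }))
  full <- sort(unique(full))
  gaps <- sum(!full %in% dates)
  idx <- match(full, dates)

  meta <- list(warnings = character(0), fallbacks = character(0))
  if (gaps > 0)
    meta$warnings <- c(meta$warnings,
                       sprintf("%d missing in-season dates filled with NA markers", gaps))

  have_app <- all(c("tmean_app", "tmax_app", "tmin_app") %in% names(raw))
  plain <- intersect(c("tmean", "tmax", "tmax_day", "tmin", "tmin_night"),
                     names(raw))
  if (!have_app && all(c("tmean", "tmax", "tmax_day", "tmin", "tmin_night")
                       %in% names(raw)) &&
      any(c("rh_mean", "dewpoint_mean") %in% names(raw))) {
    derived <- derive_metrics(raw, formula = config$apparent_formula)
    meta$fallbacks <- attr(derived, "fallbacks")
    metrics <- derived[idx, , drop = FALSE]
  } else {
    cols <- intersect(metric_names(), names(raw))
    metrics <- raw[idx, cols, drop = FALSE]
  }
  rownames(metrics) <- NULL

  for (m in intersect(config$metrics, names(metrics))) {
    fmiss <- mean(is.na(metrics[[m]]))
    if (fmiss > 0.10)
      meta$warnings <- c(meta$warnings,
                         sprintf("metric %s has %.1f%% missing days", m, 100 * fmiss))
  }

  cid <- if ("city" %in% names(raw)) as.character(raw$city[1]) else
    sub("\\.csv$", "", basename(path))
  if (is.null(country_id))
    country_id <- if ("country" %in% names(raw)) as.character(raw$country[1]) else "XX"

  city_panel(cid, country_id, full, raw$deaths[idx], metrics, meta)
}

#' Write a city panel to CSV (canonical dialect)
#'
#' Inverse of [read_city_panel()]: comma-separated, header row, ISO dates.
#' Reading the written file back reproduces the panel.
#'
#' @param panel a [city_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_city_panel <- function(panel, path) {
  stopifnot(inherits(panel, "city_panel"))
  df <- data.frame(city = panel$city_id, country = panel$country_id,
                   date = format(panel$data$date), deaths = panel$data$deaths)
  for (m in panel$metrics) df[[m]] <- panel$data[[m]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Season block labels of a panel
#'
#' Lag windows must not cross from one warm season into the previous one;
#' the year label is the season block identifier.
#'
#' @param panel a [city_panel()].
#' @return integer vector of season (year) labels per row.
#' @export
season_blocks <- function(panel) panel$data$year
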