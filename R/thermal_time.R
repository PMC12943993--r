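#' Daily growing-degree-day increment
#'
#' Thermal-time increment for one day from its temperature extremes:
#' `max(0, (tmax + tmin)/2 - t_base)`. Days whose mean temperature falls below
#' the base temperature contribute zero (the increment is never negative).
#' The default base temperature is 10 degrees C, the conventional threshold for
#' rice development.
#'
#' @param tmax Daily maximum air temperature (degrees C). Vectorised.
#' @param tmin Daily minimum air temperature (degrees C). Vectorised.
#' @param t_base Base temperature (degrees C), default 10.
#' @param date Optional date labels used in error messages when `tmax < tmin`.
#' @return Numeric vector of daily GDD increments (degree C days), all `>= 0`.
#' @examples
#' daily_gdd(30, 20)        # 15
#' daily_gdd(12, 4)         # 0: mean 8 below the 10 C base
#' @export
daily_gdd <- function(tmax, tmin, t_base = 10, date = NULL) {
  if (!is.numeric(tmax) || !is.numeric(tmin)) {
    stop_spadgdd("`tmax` and `tmin` must be numeric.", "invalid_input")
  }
  if (!is_number(t_base)) {
    stop_spadgdd("`t_base` must be a single finite number.", "invalid_input")
  }
  bad <- which(is.finite(tmax) & is.finite(tmin) & tmax < tmin)
  if (length(bad) > 0L) {
    lab <- if (!is.null(date)) as.character(date[bad[1]]) else paste0("position ", bad[1])
    stop_spadgdd(
      sprintf(
        "tmax < tmin at %s (tmax = %g, tmin = %g).",
        lab, tmax[bad[1]], tmin[bad[1]]
      ),
      "invalid_input"
    )
  }
  pmax(0, (tmax + tmin) / 2 - t_base)
}

#' Cumulative growing degree days over a date window
#'
#' Sums [daily_gdd()] over all days from `start_date` to `end_date`, both
#' endpoints included. The weather series must cover the window with
#' contiguous daily records.
#'
#' @param weather A daily weather table as returned by [read_weather()]:
#'   columns `date` (Date), `tmax_c`, `tmin_c`, one row per day, strictly
#'   increasing dates with no gaps.
#' @param start_date,end_date Window endpoints (`Date` or coercible);
#'   `start_date <= end_date`. Agronomically, `start_date` is the sowing date
#'   and `end_date` a sampling date.
#' @param t_base Base temperature (degrees C), default 10.
#' @return Cumulative GDD (degree C days), a single non-negative number.
#' @examples
#' w <- tibble::tibble(
#'   date = as.Date("2020-05-01") + 0:2,
#'   tmax_c = c(30, 12, 25), tmin_c = c(20, 4, 15)
#' )
#' cumulative_gdd(w, "2020-05-01", "2020-05-03")  # 15 + 0 + 10 = 25
#' @export
cumulative_gdd <- function(weather, start_date, end_date, t_base = 10) {
  weather <- validate_weather(weather)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    stop_spadgdd("`start_date` must be on or before `end_date`.", "invalid_input")
  }
  if (start_date < min(weather$date) || end_date > max(weather$date)) {
    stop_spadgdd(
      sprintf(
        "weather series [%s, %s] does not cover the window [%s, %s].",
        min(weather$date), max(weather$date), start_date, end_date
      ),
      "coverage"
    )
  }
  idx <- weather$date >= start_date & weather$date <= end_date
  sum(daily_gdd(weather$tmax_c[idx], weather$tmin_c[idx],
    t_base = t_base, date = weather$date[idx]
  ))
}

# validates the daily-weather contract shared by cumulative_gdd and the
# synthetic generator: required columns, tmax >= tmin, strictly increasing
# contiguous dates
validate_weather <- function(weather) {
  weather <- as_tibble(weather)
  need <- c("date", "tmax_c", "tmin_c")
  missing_cols <- setdiff(need, names(weather))
  if (length(missing_cols) > 0L) {
    stop_spadgdd(
      paste0("weather table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      "schema"
    )
  }
  weather$date <- as.Date(weather$date)
  if (nrow(weather) == 0L) {
    stop_spadgdd("weather table is empty.", "invalid_input")
  }
  if (anyNA(weather$date) || anyNA(weather$tmax_c) || anyNA(weather$tmin_c)) {
    stop_spadgdd("weather table contains missing dates or temperatures.", "invalid_input")
  }
  d <- diff(as.integer(weather$date))
  if (any(d <= 0)) {
    stop_spadgdd("weather dates must be strictly increasing.", "invalid_input")
  }
  if (any(d > 1)) {
    gap_after <- weather$date[which(d > 1)]
    gaps <- unlist(lapply(which(d > 1), function(i) {
      as.character(seq(weather$date[i] + 1, weather$date[i + 1] - 1, by = "day"))
    }))
    stop_spadgdd(
      paste0(
        "weather series has gaps; missing day(s): ",
        paste(head(gaps, 10L), collapse = ", "),
        if (length(gaps) > 10L) sprintf(" (and %d more)", length(gaps) - 10L) else ""
      ),
      "gap", missing_dates = gaps
    )
  }
  bad <- which(weather$tmax_c < weather$tmin_c)
  if (length(bad) > 0L) {
    stop_spadgdd(
      sprintf(
        "tmax < tmin at %s (tmax = %g, tmin = %g).",
        weather$date[bad[1]], weather$tmax_c[bad[1]], weather$tmin_c[bad[1]]
      ),
      "invalid_input"
    )
  }
  weather
}

#' Read a daily weather CSV
#'
#' Expects columns `date` (ISO-8601), `tmax_c`, `tmin_c`, one row per day,
#' with a header. The series must be contiguous (no missing days) and
#' strictly increasing in date.
#'
#' @param path Path to the CSV file.
#' @return A validated weather tibble.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) {
    stop_spadgdd(sprintf("weather file not found: %s", path), "io")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      tmax_c = readr::col_double(),
      tmin_c = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  validate_weather(raw)
}
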