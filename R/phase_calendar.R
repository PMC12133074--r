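#' Default pandemic phase specification
#'
#' ISO-8601 week spans defining the prepandemic baseline (subphase `"0"`,
#' all of 2019 plus 2020 weeks 1-8) and the thirteen pandemic subphases
#' `1a`..`6b` used throughout the package. Main phases follow the Dutch
#' restrictive-measure framework; subphase boundaries sit at turning points
#' of the national infection rates.
#'
#' @return A tibble with columns `subphase`, `iso_year`, `week_start`,
#'   `week_end`.
#' @export
default_phase_spec <- function() {
  tibble::tribble(
    ~subphase, ~iso_year, ~week_start, ~week_end,
    "0",  2019L,  1L, 52L,
    "0",  2020L,  1L,  8L,
    "1a", 2020L,  9L, 13L,
    "1b", 2020L, 14L, 22L,
    "2a", 2020L, 23L, 28L,
    "2b", 2020L, 29L, 40L,
    "3a", 2020L, 41L, 44L,
    "3b", 2020L, 45L, 53L,
    "3c", 2021L,  1L,  3L,
    "4",  2021L,  4L, 17L,
    "5a", 2021L, 18L, 26L,
    "5b", 2021L, 27L, 43L,
    "6a", 2021L, 44L, 48L,
    "6b", 2021L, 49L, 52L
  )
}

#' Subphase identifiers in chronological order
#' @return Character vector `"0"`, `"1a"`, ..., `"6b"`.
#' @export
subphase_levels <- function() {
  c("0", "1a", "1b", "2a", "2b", "3a", "3b", "3c", "4", "5a", "5b", "6a", "6b")
}

#' Meteorological season of a date
#'
#' Winter = Dec-Feb (dummy S1), spring = Mar-May (reference season S2),
#' summer = Jun-Aug (S3), autumn = Sep-Nov (S4).
#'
#' @param dates Date vector.
#' @return Factor with levels `winter`, `spring`, `summer`, `autumn`.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  factor(s, levels = c("winter", "spring", "summer", "autumn"))
}

iso_year <- function(dates) as.integer(format(as.Date(dates), "%G"))
iso_week <- function(dates) as.integer(format(as.Date(dates), "%V"))

is_weekday <- function(dates) as.integer(format(as.Date(dates), "%u")) <= 5L

#' Build the weekday phase calendar
#'
#' Maps every weekday in `date_range` to exactly one subphase and one
#' meteorological season, and assigns the within-subphase time index `t`
#' (0-based count of weekdays since the subphase's first weekday; weekends
#' never enter the analysed series, so subphase time is measured in
#' weekdays).
#'
#' @param phase_spec Tibble as returned by [default_phase_spec()]: one row
#'   per (subphase, ISO year) with inclusive ISO week spans.
#' @param date_range Length-2 Date (or coercible) vector, inclusive.
#' @return A tibble (`phase_calendar`) with columns `date`, `subphase`
#'   (factor), `season` (factor), `t` (integer).
#' @details Errors if `phase_spec` leaves any weekday in range unmapped or maps
#'   one to several subphases; the offending ISO weeks are listed.
#' @export
build_phase_calendar <- function(phase_spec = default_phase_spec(),
                                 date_range = c("2019-01-01", "2021-12-31")) {
  date_range <- as.Date(date_range)
  if (length(date_range) != 2L || any(is.na(date_range)) ||
      date_range[1] > date_range[2]) {
    stop("`date_range` must be two non-missing dates in increasing order",
         call. = FALSE)
  }
  days <- seq(date_range[1], date_range[2], by = "day")
  days <- days[is_weekday(days)]
  key <- paste(iso_year(days), iso_week(days))

  spec_weeks <- do.call(rbind, lapply(seq_len(nrow(phase_spec)), function(i) {
    data.frame(
      subphase = phase_spec$subphase[i],
      key = paste(phase_spec$iso_year[i],
                  seq(phase_spec$week_start[i], phase_spec$week_end[i]))
    )
  }))
  dup <- unique(spec_weeks$key[duplicated(spec_weeks$key)])
  if (length(dup) > 0L) {
    stop("phase spec assigns ISO weeks to more than one subphase: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  idx <- match(key, spec_weeks$key)
  if (anyNA(idx)) {
    stop("phase spec leaves ISO weeks uncovered: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  }

  lev <- unique(phase_spec$subphase)
  cal <- tibble::tibble(
    date = days,
    subphase = factor(spec_weeks$subphase[idx], levels = lev),
    season = season_of(days)
  )
  cal <- cal[order(cal$date), ]
  cal$t <- stats::ave(rep(1L, nrow(cal)), cal$subphase, FUN = seq_along) - 1L
  class(cal) <- c("phase_calendar", class(cal))
  cal
}

#' Look up the subphase of given dates
#'
#' @param calendar A [build_phase_calendar()] result.
#' @param dates Date vector; must be weekdays covered by the calendar.
#' @return Character vector of subphase ids.
#' @export
subphase_of <- function(calendar, dates) {
  i <- match(as.Date(dates), calendar$date)
  if (anyNA(i)) {
    stop("dates not covered by the calendar (weekend or out of range): ",
         paste(format(as.Date(dates)[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  as.character(calendar$subphase[i])
}

#' Bundled Dutch public holidays 2019-2021
#'
#' Configurable default used when excluding holiday contacts; replace with
#' your own list for other countries or periods.
#'
#' @return Date vector.
#' @export
default_holidays <- function() {
  path <- system.file("extdata", "holidays_nl_2019_2021.csv",
                      package = "prenatalITS", mustWork = TRUE)
  as.Date(utils::read.csv(path, stringsAsFactors = FALSE)$date)
}
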