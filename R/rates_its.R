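#' Normalized daily contact rates
#'
#' Converts included contacts into the analysed series: for every weekday in
#' the denominator table, `rate = 1000 * contacts / registered pregnant
#' patients`. Weekends and holidays are absent by construction (they are
#' excluded upstream and carry no denominator row).
#'
#' @param contacts Included contact tibble (post exclusion cascade).
#' @param denominators Tibble (`date`, `denominator`): registered pregnant
#'   patients per weekday. Either the synthetic truth series or a series
#'   built with [build_denominators()].
#' @param calendar A [build_phase_calendar()] result covering all dates.
#' @return A `daily_rate_series` tibble: `date`, `subphase`, `season`, `t`,
#'   `n_contacts`, `denominator`, `rate`, `smoothed` (initialised to the raw
#'   rate until [smooth_centered()] is applied).
#' @export
compute_daily_rates <- function(contacts, denominators, calendar) {
  denominators$date <- as.Date(denominators$date)
  i <- match(denominators$date, calendar$date)
  if (anyNA(i)) {
    stop("denominator dates outside the phase calendar: ",
         paste(utils::head(format(denominators$date[is.na(i)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  cdate <- as.Date(contacts$date)
  missing_d <- setdiff(as.character(cdate), as.character(denominators$date))
  if (length(missing_d) > 0L) {
    stop("contacts on dates with no denominator: ",
         paste(utils::head(missing_d, 5L), collapse = ", "), call. = FALSE)
  }
  cnt <- table(factor(as.character(cdate), levels = as.character(denominators$date)))
  n <- as.integer(cnt)
  if (any(n > 0 & denominators$denominator <= 0)) {
    bad <- denominators$date[n > 0 & denominators$denominator <= 0][1]
    stop("zero denominator with nonzero contacts on ", format(bad), call. = FALSE)
  }
  ord <- order(denominators$date)
  rate <- ifelse(denominators$denominator > 0,
                 1000 * n / denominators$denominator, 0)
  out <- tibble::tibble(
    date = denominators$date,
    subphase = calendar$subphase[i],
    season = calendar$season[i],
    t = calendar$t[i],
    n_contacts = n,
    denominator = denominators$denominator,
    rate = rate
  )[ord, ]
  out$smoothed <- out$rate
  class(out) <- c("daily_rate_series", class(out))
  out
}

#' Centered moving average over weekday positions
#'
#' The stabilising smoother applied before segment fitting: a centered mean
#' over `window` consecutive series positions (default 15 weekdays = 3
#' calendar weeks of weekdays). At the series edges the window shrinks
#' symmetrically (`truncate = TRUE`), which preserves exactly linear input;
#' with `truncate = FALSE` edge positions where the full window does not fit
#' are returned as `NA`.
#'
#' @param x Numeric vector or a `daily_rate_series`.
#' @param window Odd positive integer window length, in series positions.
#' @param truncate Shrink the window symmetrically at the edges?
#' @return Same type as `x`; for a series, the `smoothed` column is
#'   replaced.
#' @export
smooth_centered <- function(x, window = 15L, truncate = TRUE) {
  if (inherits(x, "daily_rate_series")) {
    x$smoothed <- smooth_centered(x$rate, window = window, truncate = truncate)
    return(x)
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (!truncate && window > n) {
    stop("window (", window, ") exceeds series length (", n,
         ") and truncation is disabled", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hw <- min(h, i - 1L, n - i)
    if (!truncate && hw < h) {
      out[i] <- NA_real_
    } else {
      out[i] <- (cs[i + hw + 1L] - cs[i - hw]) / (2L * hw + 1L)
    }
  }
  out
}

season_dummy_name <- c(winter = "winter", summer = "summer", autumn = "autumn")

#' Fit the seasonal segment regression for one subphase
#'
#' Ordinary least squares of the (smoothed) daily rate on within-subphase
#' time and seasonal intercept dummies,
#' `Y_t = b0 + b1 * t + b2 * winter + b3 * summer + b4 * autumn`,
#' with spring as the reference season. Because `t` starts at 0 on the
#' subphase's first weekday, `b0` and its SE are the level at the start of
#' the subphase. Dummies for seasons that do not occur in the subphase are
#' dropped and flagged absent; if spring itself is absent the subphase's
#' chronologically first season becomes the reference (its level is absorbed
#' into the intercept).
#'
#' @param series A `daily_rate_series` restricted to one subphase (or a
#'   tibble with `t`, `season`, and the response column).
#' @param response Column fitted, `"smoothed"` (default) or `"rate"`.
#' @param robust_se Replace the OLS standard errors by Newey-West
#'   heteroskedasticity-and-autocorrelation-consistent ones
#'   ([sandwich::NeweyWest()]). Off by default: the reference analysis
#'   inspects autocorrelation diagnostics without correcting.
#' @return A `segment_fit`: list with `subphase`, `n`, `terms` (tibble of
#'   `term`, `estimate`, `se`), `r_squared`, `adj_r_squared`,
#'   `reference_season`, `absent_seasons`, and the underlying `model`.
#' @export
fit_segment <- function(series, response = c("smoothed", "rate"),
                        robust_se = FALSE) {
  response <- match.arg(response)
  y <- series[[response]]
  n <- length(y)
  subphase <- as.character(series$subphase[1]) %||% NA_character_
  present <- as.character(unique(series$season))
  ref <- if ("spring" %in% present) "spring" else
    as.character(series$season[order(series$t)][1])
  dummies <- setdiff(intersect(c("winter", "summer", "autumn"), present), ref)
  absent <- setdiff(c("winter", "spring", "summer", "autumn"), present)

  p <- 2L + length(dummies)
  if (n < p + 2L) {
    stop("subphase ", subphase, ": ", n, " observations for ", p,
         " coefficients; need at least ", p + 2L, call. = FALSE)
  }
  df <- data.frame(y = y, t = series$t)
  for (d in dummies) df[[d]] <- as.numeric(series$season == d)
  fml <- stats::as.formula(paste("y ~ t", paste(c("", dummies), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("subphase ", subphase, ": rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # noise-free input is a designed use; keep summary() quiet about it
  sm <- suppressWarnings(summary(fit))
  est <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  if (robust_se) {
    se <- sqrt(diag(sandwich::NeweyWest(fit)))
  }
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) {
    r2 <- NA_real_
    adj <- NA_real_
  } else {
    rss <- sum(stats::residuals(fit)^2)
    r2 <- 1 - rss / tss
    adj <- 1 - (1 - r2) * (n - 1) / (n - length(est))
  }
  term_names <- c("intercept", "slope", dummies)
  terms <- tibble::tibble(
    term = term_names,
    estimate = unname(est),
    se = unname(se)
  )
  structure(list(
    subphase = subphase,
    n = n,
    terms = terms,
    r_squared = r2,
    adj_r_squared = adj,
    reference_season = ref,
    absent_seasons = absent,
    model = fit
  ), class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("Segment fit, subphase %s (n = %d, reference season %s)\n",
              x$subphase, x$n, x$reference_season))
  print(as.data.frame(x$terms), row.names = FALSE)
  cat(sprintf("R-squared %.3f, adjusted %.3f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

fit_term <- function(fit, parameter) {
  i <- match(parameter, fit$terms$term)
  if (is.na(i)) {
    stop("parameter '", parameter, "' not estimated in subphase ",
         fit$subphase, call. = FALSE)
  }
  fit$terms[i, ]
}

#' Compare a subphase coefficient to the prepandemic baseline
#'
#' Two-independent-estimates Wald comparison:
#' `z = (b_p - b_0) / sqrt(SE_p^2 + SE_0^2)`, with a two-sided P value from
#' the standard normal. The reference analysis reports z scores without
#' stating a formula; this convention is the package's documented choice.
#'
#' @param fit_p,fit_0 `segment_fit`s of the pandemic subphase and baseline.
#' @param parameter `"intercept"` or `"slope"` (any estimated term works).
#' @return Tibble `subphase`, `parameter`, `estimate`, `baseline`, `z`, `p`.
#' @export
compare_to_baseline <- function(fit_p, fit_0, parameter = "intercept") {
  a <- fit_term(fit_p, parameter)
  b <- fit_term(fit_0, parameter)
  z <- (a$estimate - b$estimate) / sqrt(a$se^2 + b$se^2)
  tibble::tibble(
    subphase = fit_p$subphase,
    parameter = parameter,
    estimate = a$estimate,
    baseline = b$estimate,
    z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
}

#' Autocorrelation diagnostics for a segment fit
#'
#' Residual autocorrelation function, for the visual assessment the analysis
#' prescribes (no correction is applied by default; see the `robust_se`
#' option of [fit_segment()]).
#'
#' @param fit A `segment_fit`.
#' @param lag_max Maximum lag.
#' @return Tibble `lag`, `acf`.
#' @export
autocorrelation_diagnostics <- function(fit, lag_max = 20L) {
  a <- stats::acf(stats::residuals(fit$model), lag.max = lag_max,
                  plot = FALSE, demean = TRUE)
  tibble::tibble(lag = as.integer(a$lag[, 1, 1]), acf = as.numeric(a$acf[, 1, 1]))
}

#' Run the full interrupted time-series chain
#'
#' Rates, smoothing, one seasonal segment fit per subphase, and
#' intercept/slope z-comparisons of every pandemic subphase against the
#' baseline subphase.
#'
#' @inheritParams compute_daily_rates
#' @param window Moving-average window ([smooth_centered()]); `1` disables
#'   smoothing.
#' @param smooth_scope Smooth across the full series (default, the smoother
#'   then bridges subphase boundaries) or within each subphase.
#' @param baseline Subphase id of the prepandemic reference.
#' @param robust_se Passed to [fit_segment()].
#' @return List with `series` (the smoothed `daily_rate_series`), `fits`
#'   (named list of `segment_fit`), `fit_table` (one row per subphase in the
#'   published-table layout), `comparisons` (two rows per pandemic
#'   subphase).
#' @export
run_its <- function(contacts, denominators, calendar, window = 15L,
                    smooth_scope = c("series", "subphase"),
                    baseline = "0", robust_se = FALSE) {
  smooth_scope <- match.arg(smooth_scope)
  series <- compute_daily_rates(contacts, denominators, calendar)
  if (smooth_scope == "series") {
    series <- smooth_centered(series, window = window)
  } else {
    series$smoothed <- stats::ave(series$rate, as.character(series$subphase),
                                  FUN = function(v) smooth_centered(v, window = window))
  }
  phases <- levels(droplevels(series$subphase))
  if (!baseline %in% phases) {
    stop("baseline subphase '", baseline, "' has no observations", call. = FALSE)
  }
  fits <- lapply(phases, function(sp) {
    fit_segment(series[series$subphase == sp, ], robust_se = robust_se)
  })
  names(fits) <- phases

  comparisons <- dplyr::bind_rows(lapply(setdiff(phases, baseline), function(sp) {
    dplyr::bind_rows(
      compare_to_baseline(fits[[sp]], fits[[baseline]], "intercept"),
      compare_to_baseline(fits[[sp]], fits[[baseline]], "slope")
    )
  }))

  fit_table <- dplyr::bind_rows(lapply(fits, function(f) {
    g <- function(term) {
      i <- match(term, f$terms$term)
      c(est = if (is.na(i)) NA_real_ else f$terms$estimate[i],
        se = if (is.na(i)) NA_real_ else f$terms$se[i])
    }
    b0 <- g("intercept"); b1 <- g("slope")
    w <- g("winter"); s <- g("summer"); a <- g("autumn")
    tibble::tibble(
      subphase = f$subphase, n = f$n,
      intercept = b0["est"], intercept_se = b0["se"],
      slope = b1["est"], slope_se = b1["se"],
      winter = w["est"], winter_se = w["se"],
      summer = s["est"], summer_se = s["se"],
      autumn = a["est"], autumn_se = a["se"],
      reference_season = f$reference_season,
      r_squared = f$r_squared, adj_r_squared = f$adj_r_squared
    )
  }))
  if (nrow(comparisons) > 0L) {
    cz <- tidyr::pivot_wider(
      comparisons[, c("subphase", "parameter", "z", "p")],
      names_from = "parameter", values_from = c("z", "p")
    )
    fit_table <- dplyr::left_join(fit_table, cz, by = "subphase")
  }
  list(series = series, fits = fits, fit_table = fit_table,
       comparisons = comparisons)
}

#' Denominator series from selection output
#'
#' Registered pregnant patients per weekday. In the default `per_year` mode
#' a woman counts on day `d` when she is labelled pregnant with at least one
#' confirmed contact in the calendar year of `d` and her practice
#' registration covers `d`; `per_episode` instead counts women whose
#' confirmed-contact span covers `d`.
#'
#' @param patients Included patient tibble.
#' @param labels Contact-label tibble from [label_cohort()].
#' @param calendar Phase calendar; its (weekday) dates define the series.
#' @param holidays Dates dropped from the series.
#' @param mode `"per_year"` (default) or `"per_episode"`.
#' @return Tibble `date`, `denominator`.
#' @export
build_denominators <- function(patients, labels, calendar,
                               holidays = default_holidays(),
                               mode = c("per_year", "per_episode")) {
  mode <- match.arg(mode)
  dates <- calendar$date[!(calendar$date %in% as.Date(holidays))]
  confirmed <- labels[startsWith(labels$status, "confirmed"), ]
  confirmed <- confirmed[confirmed$patient_id %in% patients$patient_id, ]
  cdate <- as.Date(confirmed$date %||% NA)
  if (is.null(confirmed$date)) {
    stop("labels must carry a `date` column to build denominators", call. = FALSE)
  }
  rs <- as.Date(patients$registration_start)
  re <- as.Date(patients$registration_end)
  re[is.na(re)] <- max(dates)
  active <- function(ids, d) {
    i <- match(ids, patients$patient_id)
    sum(rs[i] <= d & re[i] >= d)
  }
  if (mode == "per_year") {
    yr <- format(cdate, "%Y")
    by_year <- split(confirmed$patient_id, yr)
    denom <- vapply(seq_along(dates), function(k) {
      ids <- unique(by_year[[format(dates[k], "%Y")]] %||% character())
      active(ids, dates[k])
    }, numeric(1))
  } else {
    span <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(patient_id = confirmed$patient_id, date = cdate),
                      .data$patient_id),
      first = min(.data$date), last = max(.data$date), .groups = "drop"
    )
    denom <- vapply(seq_along(dates), function(k) {
      ids <- span$patient_id[span$first <= dates[k] & span$last >= dates[k]]
      active(ids, dates[k])
    }, numeric(1))
  }
  tibble::tibble(date = dates, denominator = as.integer(denom))
}
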