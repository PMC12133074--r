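#' Contact-type proportions over time
#'
#' Per-weekday shares of the four contact types among included contacts.
#' Raw proportions are smoothed per type with the centered moving average
#' and renormalised so the smoothed shares still sum to 1 on every date.
#'
#' @param contacts Included contact tibble with a valid `contact_type` in
#'   clinic / home_visit / telephone / digital.
#' @param calendar Phase calendar (subphase annotation).
#' @param window Moving-average window in weekdays ([smooth_centered()]).
#' @param by `"date"` (default): per-weekday shares with smoothing;
#'   `"subphase"`: one aggregate share per subphase, unsmoothed.
#' @return A `contact_mix_series` tibble in long form: `date`, `subphase`,
#'   `contact_type`, `n`, `proportion`, `smoothed` (per-subphase aggregation
#'   omits `date` and `smoothed`).
#' @export
contact_type_proportions <- function(contacts, calendar, window = 15L,
                                     by = c("date", "subphase")) {
  by <- match.arg(by)
  types <- c("clinic", "home_visit", "telephone", "digital")
  bad <- setdiff(unique(contacts$contact_type), types)
  if (length(bad) > 0L) {
    stop("unknown contact type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (by == "subphase") {
    sp <- subphase_of(calendar, contacts$date)
    tab <- table(factor(sp, levels = levels(calendar$subphase)),
                 factor(contacts$contact_type, levels = types))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    prop <- tab / rowSums(tab)
    return(tibble::tibble(
      subphase = rep(rownames(tab), times = length(types)),
      contact_type = rep(types, each = nrow(tab)),
      n = as.integer(tab),
      proportion = as.numeric(prop)
    ))
  }
  dates <- sort(unique(as.Date(contacts$date)))
  tab <- table(factor(as.character(contacts$date), levels = as.character(dates)),
               factor(contacts$contact_type, levels = types))
  n_mat <- matrix(as.integer(tab), nrow = length(dates),
                  dimnames = list(as.character(dates), types))
  total <- rowSums(n_mat)
  prop <- n_mat / ifelse(total == 0, 1, total)
  sm <- apply(prop, 2, smooth_centered, window = window)
  sm <- matrix(sm, nrow = length(dates), dimnames = dimnames(prop))
  sm <- sm / rowSums(sm)
  out <- tibble::tibble(
    date = rep(dates, times = length(types)),
    subphase = rep(subphase_of(calendar, dates), times = length(types)),
    contact_type = rep(types, each = length(dates)),
    n = as.integer(n_mat),
    proportion = as.numeric(prop),
    smoothed = as.numeric(sm)
  )
  class(out) <- c("contact_mix_series", class(out))
  out
}

#' Locally weighted linear smoothing (LOESS-style)
#'
#' At each point the `ceiling(span * n)` nearest neighbours (in `x`) are fit
#' with a weighted polynomial of degree `degree` and the fitted value at the
#' point is returned. Default weights are tricube in the scaled distance to
#' the bandwidth (the distance of the farthest neighbour); `"uniform"` gives
#' an unweighted local fit, under which `span = 1, degree = 1` reproduces
#' the global least-squares line exactly. A local linear fit reproduces
#' exactly linear input for any span and either weight choice.
#'
#' @param x,y Numeric vectors; `x` need not be equally spaced.
#' @param span Fraction of points per local fit, in (0, 1].
#' @param degree Local polynomial degree, 0 or 1.
#' @param weights `"tricube"` (default) or `"uniform"`.
#' @return Numeric vector of fitted values at the input `x`.
#' @export
loess_smooth <- function(x, y, span = 0.75, degree = 1L,
                         weights = c("tricube", "uniform")) {
  weights <- match.arg(weights)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (is.na(span) || span <= 0 || span > 1) {
    stop("`span` must lie in (0, 1]", call. = FALSE)
  }
  degree <- as.integer(degree)
  if (!degree %in% c(0L, 1L)) stop("`degree` must be 0 or 1", call. = FALSE)
  q <- max(ceiling(span * n), degree + 2L)
  if (q > n) stop("too few points for the requested span/degree", call. = FALSE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    nb <- order(d)[seq_len(q)]
    h <- max(d[nb])
    w <- if (weights == "uniform" || h == 0) {
      rep(1, q)
    } else {
      (1 - pmin(d[nb] / h, 1)^3)^3
    }
    pos <- w > 0
    xs <- x[nb][pos]; ys <- y[nb][pos]; ws <- w[pos]
    if (degree == 0L || length(unique(xs)) < 2L) {
      out[i] <- sum(ws * ys) / sum(ws)
    } else {
      xm <- sum(ws * xs) / sum(ws)
      ym <- sum(ws * ys) / sum(ws)
      sxx <- sum(ws * (xs - xm)^2)
      b1 <- if (sxx > 0) sum(ws * (xs - xm) * (ys - ym)) / sxx else 0
      out[i] <- ym + b1 * (x[i] - xm)
    }
  }
  out
}

#' Likelihood-ratio goodness-of-fit (G) test
#'
#' `G = 2 * sum(O * log(O / E))` over cells with observed counts, referred
#' to a chi-square distribution with `cells - 1` degrees of freedom. With
#' `expected = NULL` an equal-counts null is used.
#'
#' @param observed Nonnegative counts.
#' @param expected Expected counts summing to `sum(observed)`; `NULL` for
#'   the equal-expectation null.
#' @return Tibble `g`, `df`, `p`.
#' @export
g_test <- function(observed, expected = NULL) {
  if (any(is.na(observed)) || any(observed < 0)) {
    stop("`observed` must be nonnegative counts", call. = FALSE)
  }
  if (is.null(expected)) {
    expected <- rep(sum(observed) / length(observed), length(observed))
  }
  if (length(expected) != length(observed)) {
    stop("`observed` and `expected` lengths differ", call. = FALSE)
  }
  if (abs(sum(expected) - sum(observed)) > 1e-8 * max(1, sum(observed))) {
    stop("expected counts must sum to the observed total", call. = FALSE)
  }
  if (any(expected == 0 & observed > 0)) {
    stop("expected cell is 0 where observed > 0", call. = FALSE)
  }
  pos <- observed > 0
  g <- 2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
  df <- length(observed) - 1L
  tibble::tibble(g = g, df = df, p = stats::pchisq(g, df, lower.tail = FALSE))
}

#' Year-level descriptive summary of the pregnancy cohort
#'
#' Per calendar year: pregnant women with at least one included contact,
#' total contacts, mean (SD) contacts per patient, mean (SD) ICPC
#' registrations per contact and mean (SD) age, plus a total row over the
#' union of the per-year populations (which may overlap across years). The
#' across-year comparisons of women and contact counts use [g_test()] with
#' an equal-counts null. SDs use the n-1 denominator; age is completed years
#' at mid-year (July 1), and at the study midpoint for the total row.
#'
#' @param patients Included patient tibble (birth dates used for age).
#' @param contacts Included contact tibble.
#' @return List with `summary` (one row per year + `"total"`) and `g_tests`
#'   (rows `pregnant_women`, `contacts`).
#' @export
descriptive_summary <- function(patients, contacts) {
  contacts$date <- as.Date(contacts$date)
  yr <- format(contacts$date, "%Y")
  years <- sort(unique(yr))
  regs <- lengths(split_icpc(contacts$icpc_codes))
  bd <- as.Date(patients$birth_date)[match(contacts$patient_id, patients$patient_id)]

  # sample SD (n-1); a single observation has zero spread by convention here
  sd0 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(0)
    stats::sd(v)
  }
  row_for <- function(sel, label, age_ref) {
    ids <- unique(contacts$patient_id[sel])
    per_patient <- as.integer(table(contacts$patient_id[sel]))
    ages <- floor(as.numeric(age_ref - bd[sel][!duplicated(contacts$patient_id[sel])]) / 365.25)
    tibble::tibble(
      period = label,
      pregnant_women = length(ids),
      contacts = sum(sel),
      contacts_per_patient_mean = mean(per_patient),
      contacts_per_patient_sd = sd0(per_patient),
      registrations_per_contact_mean = mean(regs[sel]),
      registrations_per_contact_sd = sd0(regs[sel]),
      age_mean = mean(ages, na.rm = TRUE),
      age_sd = sd0(ages)
    )
  }
  rows <- lapply(years, function(y) {
    row_for(yr == y, y, as.Date(sprintf("%s-07-01", y)))
  })
  mid <- mean(range(contacts$date))
  total <- row_for(rep(TRUE, nrow(contacts)), "total", mid)
  summary_tbl <- dplyr::bind_rows(c(rows, list(total)))

  g_tests <- dplyr::bind_rows(
    dplyr::mutate(
      g_test(summary_tbl$pregnant_women[summary_tbl$period != "total"]),
      quantity = "pregnant_women", .before = 1),
    dplyr::mutate(
      g_test(summary_tbl$contacts[summary_tbl$period != "total"]),
      quantity = "contacts", .before = 1)
  )
  list(summary = summary_tbl, g_tests = g_tests)
}

#' Cohort share of screened women
#'
#' Percentage of screened women labelled pregnant; the worked-example
#' arithmetic of the published population characteristics (e.g. 10,985 of
#' 78,941 screened women = 13.9%).
#'
#' @param n_pregnant,n_screened Counts.
#' @return Percentage (0-100).
#' @export
cohort_share <- function(n_pregnant, n_screened) {
  if (n_screened <= 0) stop("`n_screened` must be positive", call. = FALSE)
  100 * n_pregnant / n_screened
}

#' Published cohort counts bundled for worked examples
#'
#' Screened and included counts of a Dutch GP-network pregnancy cohort
#' (2019-2021), shipped as plain data for the README/vignette arithmetic.
#'
#' @return Tibble `period`, `screened_women`, `screened_contacts`,
#'   `pregnant_women`, `contacts`.
#' @export
published_cohort_counts <- function() {
  path <- system.file("extdata", "cohort_counts.csv",
                      package = "prenatalITS", mustWork = TRUE)
  readr::read_csv(path, col_types = "ciiii", na = "NA", progress = FALSE)
}
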