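#' Reference configuration for coefficient-recovery studies
#'
#' A one-year, three-subphase design used to check that the ITS chain
#' recovers known generating coefficients: segments of roughly 110, 90 and
#' 60 weekdays spanning several seasons, intercepts and slopes on the scale
#' of the published fits (intercepts 8-11 per 1000 per weekday, |slope| up
#' to 0.08). Segment lengths are kept at 60+ weekdays so that +/-2 SE bands
#' have close to nominal normal coverage; the full 13-subphase calendar
#' (with 15-20-weekday subphases) can be studied by passing a
#' [simulation_config()] directly to [recovery_study()].
#'
#' @param n_patients Population size (default 5000).
#' @param seed Seed.
#' @return A [simulation_config()].
#' @export
recovery_config <- function(n_patients = 5000, seed = 1) {
  spec <- tibble::tribble(
    ~subphase, ~iso_year, ~week_start, ~week_end,
    "A", 2019L,  1L, 22L,
    "B", 2019L, 23L, 40L,
    "C", 2019L, 41L, 52L
  )
  params <- tibble::tribble(
    ~subphase, ~intercept, ~slope,
    "A", 10.20, -0.005,
    "B",  8.20,  0.040,
    "C",  9.40, -0.080
  ) |>
    dplyr::mutate(winter = 0.4, summer = -0.6, autumn = 0.2)
  mix <- default_contact_type_mix()[1, -1]
  simulation_config(
    n_patients = n_patients,
    date_range = c("2019-01-01", "2019-12-29"),
    phase_spec = spec,
    phase_rate_params = params,
    contact_type_mix = dplyr::bind_cols(tibble::tibble(subphase = c("A", "B", "C")),
                                        dplyr::bind_rows(mix, mix, mix)),
    code_multipliers = default_code_multipliers()[0, ],
    background_rate = 0,
    out_of_hours_rate = 0,
    exclusion_fractions = c(
      died_in_period = 0, deregistered = 0, dereg_reason_without_date = 0,
      unknown_birth_date = 0, registered_under_minimum = 0,
      pseudonymization_incomplete = 0),
    seed = seed
  )
}

# true values of the terms fit_segment estimates, given the generating
# parameters and the seasons actually present in the subphase's series
expected_segment_terms <- function(params, series_sub) {
  sp <- as.character(series_sub$subphase[1])
  row <- params[params$subphase == sp, ]
  offset <- c(winter = row$winter, spring = 0, summer = row$summer,
              autumn = row$autumn)
  present <- as.character(unique(series_sub$season))
  ref <- if ("spring" %in% present) "spring" else
    as.character(series_sub$season[order(series_sub$t)][1])
  dummies <- setdiff(intersect(c("winter", "summer", "autumn"), present), ref)
  tibble::tibble(
    subphase = sp,
    term = c("intercept", "slope", dummies),
    true = c(row$intercept + offset[[ref]], row$slope,
             offset[dummies] - offset[[ref]])
  )
}

#' Noise-free rate series implied by a configuration
#'
#' The deterministic daily contact-rate series `intensity(t)` of a
#' generating configuration (no Poisson noise), as a `daily_rate_series`
#' ready for [fit_segment()].
#'
#' @param config A [simulation_config()].
#' @return A `daily_rate_series` with `rate` equal to the generating
#'   intensity.
#' @export
noise_free_rates <- function(config) {
  cal <- build_phase_calendar(config$phase_spec, config$date_range)
  cal <- cal[!(cal$date %in% config$holidays), ]
  out <- tibble::tibble(
    date = cal$date, subphase = cal$subphase, season = cal$season, t = cal$t,
    n_contacts = NA_integer_, denominator = 1000L,
    rate = phase_intensity(cal, config$phase_rate_params)
  )
  out$smoothed <- out$rate
  class(out) <- c("daily_rate_series", class(out))
  out
}

#' Noise-free coefficient recovery
#'
#' Fits every subphase of the exact (noise-free) intensity series and
#' returns estimated vs generating coefficients; with `window = 1` the OLS
#' fit reproduces the generating values to numerical precision.
#'
#' @param config A [simulation_config()].
#' @param window Smoothing window applied before fitting (1 = none).
#' @return Tibble `subphase`, `term`, `true`, `estimate`, `error`.
#' @export
noise_free_recovery <- function(config = recovery_config(), window = 1L) {
  series <- smooth_centered(noise_free_rates(config), window = window)
  dplyr::bind_rows(lapply(levels(droplevels(series$subphase)), function(sp) {
    sub <- series[series$subphase == sp, ]
    fit <- fit_segment(sub)
    truth <- expected_segment_terms(config$phase_rate_params, sub)
    merged <- dplyr::inner_join(truth, fit$terms, by = "term")
    tibble::tibble(
      subphase = sp, term = merged$term, true = merged$true,
      estimate = merged$estimate, error = merged$estimate - merged$true
    )
  }))
}

#' Simulation study of coefficient recovery and SE calibration
#'
#' Repeatedly simulates a synthetic cohort from known generating
#' coefficients, refits the segmented seasonal model on the raw (unsmoothed)
#' rates, and records whether each generating coefficient lies within
#' +/-2 estimated SEs of its estimate. Fitting raw rates keeps the OLS
#' standard errors approximately valid; the moving average would induce
#' strong serial correlation and invalidate them (see the package vignette).
#'
#' @param config Generating configuration ([recovery_config()] by default).
#' @param n_reps Number of replicates.
#' @param base_seed Integer; replicate r uses seed `base_seed + r`.
#' @param window Smoothing window for the fitted series (default 1 = raw).
#' @return Tibble `rep`, `subphase`, `term`, `true`, `estimate`, `se`,
#'   `covered`.
#' @export
recovery_study <- function(config = recovery_config(), n_reps = 100,
                           base_seed = 1, window = 1L) {
  cal <- build_phase_calendar(config$phase_spec, config$date_range)
  dplyr::bind_rows(lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- as.integer((base_seed + r) %% 2147483629)
    sim <- simulate_ehr(cfg)
    keep <- sim$truth$contacts$truth_pregnant &
      sim$contacts$in_office_hours
    its <- run_its(sim$contacts[keep, ], sim$truth$denominators, cal,
                   window = window, baseline = levels(cal$subphase)[1])
    dplyr::bind_rows(lapply(its$fits, function(f) {
      sub <- its$series[its$series$subphase == f$subphase, ]
      truth <- expected_segment_terms(cfg$phase_rate_params, sub)
      merged <- dplyr::inner_join(truth, f$terms, by = "term")
      tibble::tibble(
        rep = r, subphase = f$subphase, term = merged$term,
        true = merged$true, estimate = merged$estimate, se = merged$se,
        covered = abs(merged$estimate - merged$true) <= 2 * merged$se
      )
    }))
  }))
}

#' Summarise a recovery study into per-coefficient coverage
#'
#' @param study Output of [recovery_study()].
#' @return Tibble `subphase`, `term`, `true`, `coverage`, `n_reps`.
#' @export
recovery_coverage <- function(study) {
  dplyr::summarise(
    dplyr::group_by(study, .data$subphase, .data$term),
    true = .data$true[1],
    coverage = mean(.data$covered),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
}
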