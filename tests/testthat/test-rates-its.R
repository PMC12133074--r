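`%||%` <- function(a, b) if (is.null(a)) b else a

make_series <- function(n, season = "spring", rate = NULL, start_t = 0L) {
  s <- tibble::tibble(
    date = seq(as.Date("2019-03-04"), by = "day", length.out = n),
    subphase = factor("0"),
    season = factor(rep_len(season, n),
                    levels = c("winter", "spring", "summer", "autumn")),
    t = seq(start_t, length.out = n),
    rate = rate %||% rep(0, n),
    smoothed = rate %||% rep(0, n)
  )
  class(s) <- c("daily_rate_series", class(s))
  s
}

test_that("daily rates are contacts per 1000 registered pregnant patients", {
  cal <- build_phase_calendar()
  denoms <- tibble::tibble(date = as.Date(c("2019-03-04", "2019-03-05")),
                           denominator = c(500L, 500L))
  contacts <- fix_contacts("P001", rep("2019-03-05", 5))
  s <- compute_daily_rates(contacts, denoms, cal)
  expect_equal(s$rate, c(0, 10))
  expect_equal(s$n_contacts, c(0L, 5L))
  # zero denominator with contacts names the date
  denoms0 <- tibble::tibble(date = as.Date("2019-03-05"), denominator = 0L)
  expect_error(compute_daily_rates(contacts, denoms0, cal), "2019-03-05")
  # contacts on a date without denominator
  expect_error(
    compute_daily_rates(fix_contacts("P001", "2019-06-03"), denoms, cal),
    "2019-06-03")
})

test_that("mean synthetic rate stays in Poisson bounds of the intensity", {
  params <- default_rate_params()
  params$intercept <- 10; params$slope <- 0
  params$winter <- 0; params$summer <- 0; params$autumn <- 0
  cfg <- simulation_config(n_patients = 4000, seed = 13,
                           phase_rate_params = params,
                           background_rate = 0, out_of_hours_rate = 0,
                           exclusion_fractions = c(
                             died_in_period = 0, deregistered = 0,
                             dereg_reason_without_date = 0,
                             unknown_birth_date = 0,
                             registered_under_minimum = 0,
                             pseudonymization_incomplete = 0))
  sim <- simulate_ehr(cfg)
  cal <- build_phase_calendar()
  s <- compute_daily_rates(sim$contacts, sim$truth$denominators, cal)
  # total contacts ~ Poisson(sum lambda_d); translate the exact 99% interval
  # to the mean rate scale
  lam <- sum(10 * s$denominator / 1000)
  mean_bounds <- qpois(c(0.005, 0.995), lam) / sum(s$denominator / 1000)
  expect_gte(mean(s$rate), mean_bounds[1])
  expect_lte(mean(s$rate), mean_bounds[2])
})

test_that("centered moving average matches a brute-force window loop", {
  expect_equal(smooth_centered(c(0, 0, 0, 15, 0, 0, 0), window = 3),
               c(0, 0, 5, 5, 5, 0, 0))
  expect_equal(smooth_centered(rep(7, 10), window = 5), rep(7, 10))
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_identical(smooth_centered(x, window = 1), x)
  set.seed(1)
  for (w in c(3, 5, 15)) {
    x <- rnorm(40)
    brute <- vapply(seq_along(x), function(i) {
      h <- min((w - 1) / 2, i - 1, length(x) - i)
      mean(x[(i - h):(i + h)])
    }, numeric(1))
    expect_equal(smooth_centered(x, window = w), brute, tolerance = 1e-12)
  }
  expect_error(smooth_centered(1:5, window = 4), "odd")
  expect_error(smooth_centered(1:5, window = 7, truncate = FALSE), "exceeds")
  # no truncation: edges where the full window does not fit are NA
  s <- smooth_centered(1:9, window = 5, truncate = FALSE)
  expect_true(all(is.na(s[c(1, 2, 8, 9)])))
  expect_equal(s[3:7], 3:7)
  # the smoother preserves exactly linear input (truncated symmetric edges)
  lin <- 2 + 0.3 * (0:59)
  expect_equal(smooth_centered(lin, window = 15), lin, tolerance = 1e-12)
})

test_that("segment fit recovers a noise-free seasonal design exactly", {
  # spring then summer, Y = 10 + 0.05 t + 0.5 * summer
  n <- 40
  season <- rep(c("spring", "summer"), each = 20)
  t <- 0:(n - 1)
  y <- 10 + 0.05 * t + 0.5 * (season == "summer")
  s <- make_series(n, season = season, rate = y)
  fit <- fit_segment(s)
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(est[["intercept"]], 10, tolerance = 1e-8)
  expect_equal(est[["slope"]], 0.05, tolerance = 1e-8)
  expect_equal(est[["summer"]], 0.5, tolerance = 1e-8)
  expect_identical(fit$reference_season, "spring")
  expect_true(all(c("winter", "autumn") %in% fit$absent_seasons))
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("a constant series yields zero slope and undefined R-squared", {
  s <- make_series(10, rate = rep(4, 10))
  fit <- fit_segment(s)
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(est[["intercept"]], 4, tolerance = 1e-10)
  expect_equal(est[["slope"]], 0, tolerance = 1e-10)
  expect_true(is.na(fit$r_squared))
  expect_true(is.na(fit$adj_r_squared))
})

test_that("a subphase without spring re-references to its first season", {
  # winter-only subphase: no season dummies, intercept absorbs winter
  s <- make_series(12, season = "winter", rate = 9 + 0.1 * (0:11))
  fit <- fit_segment(s)
  expect_identical(fit$reference_season, "winter")
  expect_identical(fit$terms$term, c("intercept", "slope"))
  expect_equal(fit$terms$estimate[1], 9, tolerance = 1e-8)
  # autumn then winter (no spring): autumn is the reference
  y <- 5 + 0.02 * (0:29) + 0.3 * rep(c(0, 1), each = 15)
  s2 <- make_series(30, season = rep(c("autumn", "winter"), each = 15),
                    rate = y)
  fit2 <- fit_segment(s2)
  expect_identical(fit2$reference_season, "autumn")
  est <- setNames(fit2$terms$estimate, fit2$terms$term)
  expect_equal(est[["winter"]], 0.3, tolerance = 1e-8)
})

test_that("OLS matches an explicit normal-equations solver on random designs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(12:50, 1)
    season <- sample(c("winter", "spring", "summer", "autumn"), n,
                     replace = TRUE)
    # ensure all four seasons occur so the design is full and spring-referenced
    season[1:4] <- c("winter", "spring", "summer", "autumn")
    y <- rnorm(n)
    s <- make_series(n, season = season, rate = y)
    fit <- fit_segment(s)
    X <- cbind(1, s$t, season == "winter", season == "summer",
               season == "autumn")
    oracle <- ols_normal_equations(X, y)
    ord <- match(c("intercept", "slope", "winter", "summer", "autumn"),
                 fit$terms$term)
    expect_equal(fit$terms$estimate[ord], oracle$beta, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$terms$se[ord], oracle$se, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("too few observations or degenerate designs raise errors", {
  s <- make_series(3, rate = c(1, 2, 3))
  expect_error(fit_segment(s), "at least")
  s2 <- make_series(10, rate = rnorm(10))
  s2$t <- rep(0L, 10)  # time constant -> collinear with intercept
  expect_error(fit_segment(s2), "collinear")
})

test_that("baseline z-comparisons follow the Wald form and antisymmetry", {
  mk_fit <- function(b0, se0, b1, se1) {
    structure(list(subphase = "x",
                   terms = tibble::tibble(
                     term = c("intercept", "slope"),
                     estimate = c(b0, b1), se = c(se0, se1))),
              class = "segment_fit")
  }
  f1 <- mk_fit(1.0, 0.1, 0, 1)
  f0 <- mk_fit(0.5, 0.1, 0, 1)
  cmp <- compare_to_baseline(f1, f0, "intercept")
  expect_equal(cmp$z, 0.5 / sqrt(0.02), tolerance = 1e-6)
  expect_equal(cmp$z, 3.5355, tolerance = 1e-4)
  expect_equal(cmp$p, 2 * pnorm(-0.5 / sqrt(0.02)), tolerance = 1e-10)
  expect_equal(cmp$p, 4.07e-4, tolerance = 1e-2)
  # identical fits: z = 0, P = 1
  same <- compare_to_baseline(f0, f0, "slope")
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # swapping the fits negates z
  expect_equal(compare_to_baseline(f0, f1, "intercept")$z, -cmp$z)
  expect_error(compare_to_baseline(f0, f1, "summer"), "not estimated")
})

test_that("run_its produces one fit per subphase and two comparisons each", {
  cfg <- recovery_config(n_patients = 1200, seed = 8)
  sim <- simulate_ehr(cfg)
  cal <- build_phase_calendar(cfg$phase_spec, cfg$date_range)
  its <- run_its(sim$contacts[sim$truth$contacts$truth_pregnant &
                                sim$contacts$in_office_hours, ],
                 sim$truth$denominators, cal, window = 15, baseline = "A")
  expect_identical(sort(names(its$fits)), c("A", "B", "C"))
  expect_identical(nrow(its$fit_table), 3L)
  expect_identical(nrow(its$comparisons), 4L)  # 2 non-baseline x 2 parameters
  expect_setequal(unique(its$comparisons$subphase), c("B", "C"))
  # baseline row carries no z columns
  base_row <- its$fit_table[its$fit_table$subphase == "A", ]
  expect_true(is.na(base_row$z_intercept))
  # deterministic rerun
  its2 <- run_its(sim$contacts[sim$truth$contacts$truth_pregnant &
                                 sim$contacts$in_office_hours, ],
                  sim$truth$denominators, cal, window = 15, baseline = "A")
  expect_identical(its$fit_table, its2$fit_table)
})

test_that("autocorrelation diagnostics and robust SEs are available", {
  set.seed(2)
  s <- make_series(60, rate = 10 + cumsum(rnorm(60, sd = 0.2)))
  s <- smooth_centered(s, window = 15)
  fit <- fit_segment(s)
  ac <- autocorrelation_diagnostics(fit, lag_max = 10)
  expect_identical(nrow(ac), 11L)
  expect_equal(ac$acf[1], 1)
  # smoothing induces strong positive lag-1 autocorrelation
  expect_gt(ac$acf[2], 0.5)
  robust <- fit_segment(s, robust_se = TRUE)
  expect_gt(robust$terms$se[2], fit$terms$se[2])
})
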