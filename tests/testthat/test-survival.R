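test_that("product-limit estimate matches the hand-computed worked example", {
  rec <- tibble::tibble(time = c(5, 10, 15, 20),
                        event = c(FALSE, TRUE, TRUE, FALSE))
  km <- km_estimate(rec)
  # events at 10 (3 at risk) and 15 (2 at risk):
  # S(10) = 1 - 1/3 = 2/3;  S(15) = 2/3 * (1 - 1/2) = 1/3;  S(20) = S(15)
  expect_identical(km$time, c(10, 15))
  expect_equal(km$survival, c(2/3, 1/3))
  expect_identical(km$n_risk, c(3L, 2L))
  expect_identical(attr(km, "n"), 4L)
})

test_that("degenerate inputs: all-censored and single-event cohorts", {
  allc <- km_estimate(tibble::tibble(time = c(3, 8, 9), event = FALSE))
  expect_identical(nrow(allc), 0L)       # no factors: S stays 1 everywhere
  expect_identical(attr(allc, "n_events"), 0L)

  one <- km_estimate(tibble::tibble(time = 7, event = TRUE))
  expect_identical(one$time, 7)
  expect_equal(one$survival, 0)

  expect_error(km_estimate(tibble::tibble(time = -1, event = TRUE)),
               "non-negative")
  expect_error(km_estimate(tibble::tibble(time = numeric(), event = logical())),
               "at least one")
})

test_that("estimates agree with the reference implementation to 1e-9", {
  skip_if_not_installed("survival")
  for (seed in 1:10) {
    rec <- withr::with_seed(seed, tibble::tibble(
      time = round(rexp(40, 0.1), 4),
      event = runif(40) < 0.7
    ))
    km <- km_estimate(rec)
    fit <- survival::survfit(survival::Surv(rec$time, rec$event) ~ 1)
    idx <- match(km$time, fit$time)
    expect_false(anyNA(idx))
    expect_equal(km$survival, fit$surv[idx], tolerance = 1e-9)
    expect_equal(km$n_risk, fit$n.risk[idx])
    expect_equal(km$n_event, fit$n.event[idx])
    # Greenwood standard errors match too
    expect_equal(km$std_err, fit$std.err[idx] * fit$surv[idx],
                 tolerance = 1e-7)
  }
})

test_that("curves are monotone and scale-invariant", {
  for (seed in c(2, 9)) {
    rec <- withr::with_seed(seed, tibble::tibble(
      time = rexp(30, 0.2), event = runif(30) < 0.6))
    km <- km_estimate(rec)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$n_risk) <= 0))
    km_scaled <- km_estimate(dplyr::mutate(rec, time = time * 365.25))
    expect_equal(km_scaled$survival, km$survival)
  }
})

test_that("turning an event into a censoring can only raise later survival", {
  rec <- withr::with_seed(4, tibble::tibble(
    time = rexp(25, 0.2), event = runif(25) < 0.8))
  km0 <- km_estimate(rec)
  ev_rows <- which(rec$event)
  for (i in ev_rows[1:5]) {
    rec2 <- rec
    rec2$event[i] <- FALSE
    km2 <- km_estimate(rec2)
    s2_at <- vapply(km0$time, function(t) {
      past <- km2$survival[km2$time <= t]
      if (length(past)) past[length(past)] else 1
    }, 0)
    expect_true(all(s2_at >= km0$survival - 1e-12))
  }
})

test_that("log-rank statistic is zero for identical groups, positive otherwise", {
  base <- tibble::tibble(time = c(5, 10, 15, 20),
                         event = c(FALSE, TRUE, TRUE, FALSE))
  same <- dplyr::bind_rows(dplyr::mutate(base, group = "a"),
                           dplyr::mutate(base, group = "b"))
  lr <- logrank_test(same)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_identical(lr$df, 1L)

  worse <- dplyr::bind_rows(
    dplyr::mutate(base, group = "a"),
    tibble::tibble(time = rep(1, 4), event = TRUE, group = "b"))
  expect_gt(logrank_test(worse)$statistic, 0)
  expect_error(logrank_test(dplyr::mutate(base, group = "only")),
               "two groups")
})

test_that("log-rank agrees with the reference implementation", {
  skip_if_not_installed("survival")
  for (seed in 1:10) {
    rec <- withr::with_seed(seed, tibble::tibble(
      time = c(rexp(30, 0.1), rexp(30, 0.18)),
      event = runif(60) < 0.75,
      group = rep(c("a", "b"), each = 30)
    ))
    lr <- logrank_test(rec)
    sd <- survival::survdiff(
      survival::Surv(time, event) ~ group, data = rec)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-6)
    expect_equal(unname(lr$summary$observed), unname(sd$obs))
    expect_equal(unname(lr$summary$expected), unname(sd$exp), tolerance = 1e-9)
  }
  # three groups: k-1 degrees of freedom, same statistic as the reference
  rec3 <- withr::with_seed(99, tibble::tibble(
    time = rexp(90, 0.1), event = runif(90) < 0.7,
    group = rep(c("a", "b", "c"), each = 30)))
  lr3 <- logrank_test(rec3)
  sd3 <- survival::survdiff(survival::Surv(time, event) ~ group, data = rec3)
  expect_identical(lr3$df, 2L)
  expect_equal(lr3$statistic, sd3$chisq, tolerance = 1e-6)
})

test_that("survival records build from flattened tables with vocab mapping", {
  tbl <- tibble::tibble(
    individual_id = sprintf("I%02d", 1:10),
    followup_time = c(NA, NA, 3:10),
    vital_status = c("alive", "dead", "alive", "dead", "Alive", "Dead",
                     "alive", "dead", "alive", "dead"),
    age = c(40, 70, 55, 61, 45, 80, 59, 62, 30, 75)
  )
  expect_warning(
    rec <- build_survival_records(tbl, "followup_time", "vital_status"),
    "Dropped 2")
  expect_identical(nrow(rec), 8L)
  expect_identical(attr(rec, "n_dropped"), 2L)
  expect_identical(rec$event, rep(c(FALSE, TRUE), 4))

  # numeric threshold rule
  rec2 <- suppressWarnings(build_survival_records(
    tbl, "followup_time", "vital_status",
    group = list(column = "age", threshold = 60)))
  expect_setequal(unique(rec2$group), c("<60", ">=60"))

  # unmapped status strings drop their rows and are reported
  tbl$vital_status[5] <- "lost-to-followup"
  expect_warning(
    rec3 <- build_survival_records(tbl, "followup_time", "vital_status"),
    "lost-to-followup")
  expect_identical(nrow(rec3), 7L)

  expect_error(
    suppressWarnings(build_survival_records(
      tibble::tibble(t = NA_real_, s = "dead"), "t", "s")),
    "No usable records")
  expect_error(build_survival_records(tbl, "nope", "vital_status"),
               "'nope' not found")
})

test_that("plot-ready step coordinates duplicate curve points from (0, 1)", {
  rec <- tibble::tibble(time = c(5, 10, 15, 20),
                        event = c(FALSE, TRUE, TRUE, FALSE))
  km <- km_estimate(rec, group = "g1")
  pd <- km_plot_data(km)
  expect_identical(pd$time[1], 0)
  expect_identical(pd$survival[1], 1)
  expect_identical(nrow(pd), 1L + 2L * nrow(km))
  # the step drops at each event time: survival before == previous level
  expect_equal(pd$survival[pd$time == 10], c(1, 2/3))
  expect_equal(pd$survival[pd$time == 15], c(2/3, 1/3))

  p <- survival_plot(km_by_group(dplyr::mutate(rec, group = "a")))
  expect_s3_class(p, "ggplot")
})

test_that("KM curves tidy, glance and export cleanly", {
  rec <- tibble::tibble(time = c(2, 4, 6, 8), event = c(TRUE, TRUE, TRUE, FALSE))
  km <- km_estimate(rec, group = "g")
  td <- tidy(km)
  expect_identical(td$group, rep("g", nrow(km)))
  gl <- glance(km)
  expect_identical(gl$n, 4L)
  expect_identical(gl$median_survival, 4)   # first time S <= 0.5
  path <- withr::local_tempfile(fileext = ".tsv")
  write_km_tsv(km, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("group", "time", "survival", "at_risk", "n_events"))
  expect_equal(back$survival, km$survival)
})
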