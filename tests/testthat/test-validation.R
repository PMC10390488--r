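test_that("Kaplan-Meier estimate matches hand computation and closed forms", {
  # all censored: survival stays at 1
  allc <- event_table(time = c(2, 5, 9), event = 0)
  km <- km_estimate(allc)
  expect_true(all(km$surv == 1))

  # two subjects, one event at t = 1, one censored later
  two <- event_table(time = c(1, 4), event = c(1, 0))
  km2 <- km_estimate(two)
  expect_equal(survival_at(km2, 1), 0.5)
  expect_equal(survival_at(km2, 0.5), 1)

  # distinct event times without censoring: S after k-th event = 1 - k/n
  tt <- sort(runif(12, 1, 40))
  kmn <- km_estimate(event_table(time = tt, event = 1))
  expect_equal(survival_at(kmn, tt), 1 - seq_len(12) / 12, tolerance = 1e-12)

  # ties and censoring agree with the hand-rolled product limit
  set.seed(31)
  t3 <- sample(1:8, 40, replace = TRUE)
  e3 <- rbinom(40, 1, 0.7)
  km3 <- km_estimate(event_table(time = t3, event = e3))
  hand <- km_by_hand(t3, e3)
  expect_equal(survival_at(km3, hand$time), hand$surv, tolerance = 1e-12)
  expect_error(km_estimate(event_table(time = numeric(0))), "empty|positive")
})

test_that("TTP inference removes each death at most once within tolerance", {
  expect_equal(infer_ttp(c(2, 3, 5), c(3, 9), tol = 0), c(2, 5))
  expect_equal(infer_ttp(c(4, 4), 4, tol = 0), 4)
  expect_equal(infer_ttp(c(1, 2, 3), c(7, 8), tol = 0), c(1, 2, 3))
  expect_equal(infer_ttp(c(2, 3.4), 3.2, tol = 0.25), 2)
  # output length identity
  set.seed(2)
  for (i in 1:20) {
    pfs <- round(runif(30, 1, 24), 1)
    os <- round(runif(10, 1, 24), 1)
    out <- infer_ttp(pfs, os, tol = 0.05)
    matched <- 30 - length(out)
    expect_gte(matched, 0); expect_lte(matched, 10)
  }
  expect_error(infer_ttp(1:3, 1:2, tol = -1), "tol")
})

test_that("log-rank agrees with the first-principles statistic", {
  a <- event_table(time = c(1, 2), event = 1)
  b <- event_table(time = c(3, 4), event = 1)
  got <- logrank(a, b)
  expect_equal(got$statistic, logrank_by_hand(c(1, 2), c(1, 1),
                                              c(3, 4), c(1, 1)),
               tolerance = 1e-9)
  same <- event_table(time = c(1, 3, 7, 9), event = c(1, 1, 0, 1))
  eq <- logrank(same, same)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1, tolerance = 1e-12)
  nocens <- event_table(time = c(1, 2, 5), event = 0)
  expect_message(res <- logrank(nocens, nocens), "no events")
  expect_equal(res$p, 1)
})

test_that("bootstrap prediction band has the documented degenerate and
          scaling behavior", {
  set.seed(14)
  # large pool so the without-replacement correction stays negligible
  ev <- event_table(time = rexp(4000, log(2) / 9), event = 1)

  one <- bootstrap_pi(ev, n_real = 100, B = 1, seed = 1)
  expect_equal(one$lo, one$hi, tolerance = 1e-12)

  const <- event_table(time = rep(7, 50), event = 1)
  zw <- bootstrap_pi(const, n_real = 20, B = 50, seed = 2)
  expect_equal(zw$lo, zw$hi, tolerance = 1e-12)

  # band contains the pointwise median resample at any level >= 0.5
  band <- bootstrap_pi(ev, n_real = 100, B = 200, seed = 3, level = 0.5)
  expect_true(all(band$lo <= band$median + 1e-12))
  expect_true(all(band$hi >= band$median - 1e-12))

  # width shrinks like 1/sqrt(n_real): log-log slope near -1/2
  ns <- c(40, 120, 360)
  widths <- vapply(ns, function(n) {
    b <- bootstrap_pi(ev, n_real = n, B = 300, seed = 4)
    keep <- b$grid > 3 & b$grid < 18
    mean(b$hi[keep] - b$lo[keep])
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.15)
  expect_error(bootstrap_pi(ev, n_real = 9000, B = 10), "exceeds")
})

test_that("raw coverage counts observed step points inside the band", {
  obs <- km_estimate(event_table(time = 1:10, event = 1))
  full <- structure(list(grid = c(0, 15), lo = c(0, 0), hi = c(1, 1),
                         median = c(0.5, 0.5), B = 1, level = 0.95),
                    class = "km_band")
  expect_equal(raw_coverage(obs, full), 100)
  none <- structure(list(grid = c(0, 15), lo = c(-2, -2), hi = c(-1, -1),
                         median = c(-1.5, -1.5), B = 1, level = 0.95),
                    class = "km_band")
  expect_equal(raw_coverage(obs, none), 0)
  # exactly half the step points inside: S after events 1..10 is 0.9..0
  half <- structure(list(grid = c(0, 15), lo = c(0.45, 0.45), hi = c(1, 1),
                         median = c(0.7, 0.7), B = 1, level = 0.95),
                    class = "km_band")
  expect_equal(raw_coverage(obs, half), 50)
  disj <- structure(list(grid = c(100, 110), lo = c(0, 0), hi = c(1, 1),
                         median = c(0.5, 0.5), B = 1, level = 0.95),
                    class = "km_band")
  expect_error(raw_coverage(obs, disj), "disjoint")
})

test_that("bootstrapped log-rank negativity calibrates under null and
          detects gross mismatch", {
  set.seed(77)
  vp <- event_table(time = rexp(1200, log(2) / 9), event = 1)
  single <- bootstrapped_logrank(vp, event_table(time = rexp(159, log(2) / 9),
                                                 event = 1),
                                 n_tests = 1, seed = 1)
  expect_true(single %in% c(0, 100))

  null_pct <- bootstrapped_logrank(vp,
                                   event_table(time = rexp(159, log(2) / 9),
                                               event = 1),
                                   n_tests = 300, seed = 2)
  expect_gte(null_pct, 80)

  fast <- event_table(time = rexp(159, log(2) / 4.5), event = 1)
  power_pct <- bootstrapped_logrank(vp, fast, n_tests = 200, seed = 3)
  expect_lte(power_pct, 5)
})

test_that("the validation report assembles both metrics against the
          thresholds", {
  set.seed(55)
  vp <- event_table(time = rexp(1000, log(2) / 9), event = 1)
  obs <- event_table(time = rexp(150, log(2) / 9), event = 1)
  rep0 <- validate_vpop(vp, obs, n_bootstrap_pi = 200, n_lr_tests = 200,
                        coverage_threshold = 0, lr_threshold = 0, seed = 9)
  expect_true(rep0$pass)
  expect_equal(rep0$n_real, 150)
  expect_output(print(rep0), "raw coverage")

  f <- tempfile(fileext = ".json")
  write_report(rep0, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$n_lr_tests, 200)
  expect_true(is.numeric(back$raw_coverage_pct))
  unlink(f)

  # digitized-curve input path: coverage only, log-rank not computed
  curve <- km_estimate(obs)
  curve$n_risk <- c(150, curve$n_risk[-1])
  repc <- validate_vpop(vp, curve, n_bootstrap_pi = 100, seed = 10)
  expect_true(is.na(repc$lr_negative_pct))
})
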