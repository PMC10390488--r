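test_that("progression detection applies both RECIST thresholds", {
  days <- seq(0, 300, by = 1)

  # monotone decrease: censored at follow-up end
  dec <- fake_traj(days, 1.5 * exp(-0.002 * days))
  res <- detect_progression(dec, reference = "baseline")
  expect_equal(res$event, 0L)
  expect_equal(res$ttp_days, 300)

  # r0 = 1: the absolute criterion binds (1.25 cm > 1.2 cm)
  ramp <- fake_traj(days, 1 + 0.25 * days / 100)
  res <- detect_progression(ramp, reference = "baseline")
  expect_equal(res$event, 1L)
  expect_equal(res$ttp_days, 100)

  # r0 = 2: the relative criterion binds (2.4 cm > 2.25 cm)
  ramp2 <- fake_traj(days, 2 + 0.4 * days / 200)
  res2 <- detect_progression(ramp2, reference = "baseline")
  expect_equal(res2$ttp_days, 200)

  expect_error(detect_progression(fake_traj(0, 1)), "two points")
})

test_that("nadir reference never reports later progression than baseline on
          dipping curves", {
  set.seed(11)
  days <- seq(0, 600, by = 2)
  for (i in 1:20) {
    nadir_t <- runif(1, 50, 300)
    depth <- runif(1, 0.5, 0.95)
    regrow <- runif(1, 0.004, 0.02)
    r <- ifelse(days < nadir_t,
                1.5 * (depth + (1 - depth) * (1 - days / nadir_t)),
                1.5 * depth * exp(regrow * (days - nadir_t)))
    tr <- fake_traj(days, r)
    tn <- detect_progression(tr, reference = "nadir")
    tb <- detect_progression(tr, reference = "baseline")
    expect_lte(tn$ttp, tb$ttp)
  }
})

test_that("reported progression time is the earliest grid time satisfying
          both criteria (re-scan oracle)", {
  set.seed(23)
  days <- seq(0, 400, by = 4)
  for (i in 1:50) {
    r <- 1.2 * exp(cumsum(rnorm(length(days), 0, 0.02)))
    tr <- fake_traj(days, r)
    for (ref in c("baseline", "nadir")) {
      got <- detect_progression(tr, reference = ref)
      want <- rescan_progression(days, r, ref)
      expect_equal(got$ttp_days, want$t)
      expect_equal(got$event, want$event)
    }
  }
})

test_that("percent radius change is exact arithmetic", {
  days <- seq(0, 400, by = 1)
  flat <- fake_traj(days, rep(1.3, length(days)))
  expect_equal(percent_change_radius(flat, 6), 0)
  shrink <- fake_traj(days, seq(1, 0.8, length.out = length(days)))
  expect_equal(percent_change_radius(shrink, 400 / 30.4375), -20,
               tolerance = 0.2)
  grow <- fake_traj(days, seq(1, 1.5, length.out = length(days)))
  expect_equal(percent_change_radius(grow, 400 / 30.4375), 50,
               tolerance = 0.2)
  expect_error(percent_change_radius(flat, 999), "span")
})

test_that("individual TTP match uses the inclusive visit-interval window", {
  expect_true(individual_ttp_match(9, 9))
  expect_true(individual_ttp_match(7, 9))
  expect_false(individual_ttp_match(6, 9))
  expect_false(individual_ttp_match(9.5, 9))
  # fraction of matches is 1 when predictions equal observations
  obs <- c(3, 6, 12, 20)
  expect_equal(mean(individual_ttp_match(obs, obs)), 1)
  frac <- mean(individual_ttp_match(c(2, 5.5, 9, 21), obs))
  expect_gte(frac, 0); expect_lte(frac, 1)
  expect_error(individual_ttp_match(-1, 5), "positive")
})

test_that("simulate_outcomes produces one consistent record per patient", {
  pop <- sample_population(vpop_spec(), 8, seed = 5)
  out <- simulate_outcomes(as_virtual_patients(pop), follow_up_months = 18,
                           dt_out = 7)
  expect_equal(nrow(out), 8)
  expect_true(all(out$ttp_months > 0))
  expect_true(all(out$event %in% 0:1))
  expect_true(all(out$ttp_months[out$event == 0] >= 18 - 0.3))
  expect_true(all(out$nadir_radius_cm <= out$baseline_radius_cm + 1e-9))
  f <- tempfile(fileext = ".csv")
  write_outcomes(out, f)
  back <- read_outcomes(f)
  expect_equal(back$ttp_months, out$ttp_months)
  unlink(f)
})
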