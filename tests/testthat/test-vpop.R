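test_that("sd estimation from quantile intervals", {
  expect_equal(estimate_sd_from_quantiles(-1.96, 1.96, 0.95), 1,
               tolerance = 1e-3)
  # linearity under scaling
  s1 <- estimate_sd_from_quantiles(-2, 2, 0.9)
  s3 <- estimate_sd_from_quantiles(-6, 6, 0.9)
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
  # age range 36-89 as a central 99% interval
  expect_equal(estimate_sd_from_quantiles(36, 89, 0.99), 53 / (2 * qnorm(0.995)))
  expect_equal(estimate_sd_from_quantiles(36, 89, 0.99), 10.29,
               tolerance = 0.01)
  expect_error(estimate_sd_from_quantiles(5, 5, 0.95), "q_hi")
  expect_error(estimate_sd_from_quantiles(0, 1, 1), "coverage")
})

test_that("population sampling is reproducible, respects edge cases and
          emits only the two common EGFR variants", {
  spec <- vpop_spec()
  expect_equal(nrow(sample_population(spec, 0, seed = 1)), 0)

  a <- sample_population(spec, 50, seed = 99)
  b <- sample_population(spec, 50, seed = 99)
  expect_identical(a, b)

  marg <- default_marginals()
  marg$kras <- marginal_categorical(c(TRUE, FALSE), c(0, 1))
  none <- sample_population(vpop_spec(marg), 500, seed = 3)
  expect_equal(sum(none$kras), 0)

  big <- sample_population(spec, 20000, seed = 12)
  expect_true(all(big$egfr_variant %in% c("exon19del", "L858R")))
  expect_equal(mean(big$egfr_variant == "exon19del"), 93 / 159,
               tolerance = 0.012)
  expect_true(all(big$age >= 36 & big$age <= 89))
  expect_true(all(big$f_res >= 0 & big$f_res < 1))
})

test_that("empirical marginals recover the specification within binomial
          error", {
  spec <- vpop_spec()
  n <- 4000
  hits <- 0; total <- 0
  for (seed in 1:5) {
    pop <- sample_population(spec, n, seed = seed)
    checks <- list(
      c(mean(pop$sex == "male"), 53 / 159),
      c(mean(pop$smoking == "never"), 106 / 159),
      c(mean(pop$ethnicity == "asian"), 88 / 159),
      c(mean(pop$stage == "IIIb"), 3 / 159),
      c(mean(pop$kras), 0.025))
    for (ch in checks) {
      total <- total + 1
      tol <- 4 * sqrt(ch[2] * (1 - ch[2]) / n)
      if (abs(ch[1] - ch[2]) < tol) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.99 - 1e-9)
})

test_that("Gaussian copula induces the requested rank correlation", {
  marg <- default_marginals()[c("age", "r0")]
  R <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(names(marg), names(marg)))
  pop <- sample_population(vpop_spec(marg, copula = R), 4000, seed = 8)
  expect_equal(cor(pop$age, pop$r0, method = "spearman"), 0.68,
               tolerance = 0.05)
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(names(marg), names(marg)))
  expect_error(vpop_spec(marg, copula = bad), "semi-definite")
})

test_that("Fisher 2x2 matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), fisher_enum(10, 0, 0, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_message(p0 <- fisher_exact_2x2(0, 0, 0, 0), "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  set.seed(4)
  for (i in 1:60) {
    cells <- rpois(4, sample(c(2, 8, 20), 1))
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 fisher_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("baseline comparison mixes Fisher and t tests and is
          self-consistent", {
  real <- luxlung7_baseline()
  # identical continuous samples give t-test p = 1
  x <- real$continuous$age
  expect_equal(stats::t.test(x, x)$p.value, 1)

  ok <- 0
  for (seed in 1:12) {
    pop <- sample_population(vpop_spec(), 1190, seed = seed)
    cmp <- compare_baselines(pop, real)
    expect_setequal(cmp$characteristic,
                    c("sex", "egfr_variant", "smoking", "ethnicity",
                      "stage", "age"))
    expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
    if (all(cmp$p_value > 0.05)) ok <- ok + 1
  }
  # mirrors the trial-arm concordance: no significant baseline difference
  expect_gte(ok / 12, 0.95 - 1e-9)
})

test_that("population files round-trip with their seed header", {
  pop <- sample_population(vpop_spec(), 25, seed = 77)
  f <- tempfile(fileext = ".csv")
  write_population(pop, f)
  expect_true(grepl("# seed: 77", readLines(f, n = 1)))
  back <- read_population(f)
  expect_equal(nrow(back), 25)
  expect_equal(attr(back, "seed"), 77L)
  expect_equal(back$r0, pop$r0, tolerance = 1e-9)
  unlink(f)
})
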