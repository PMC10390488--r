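test_that("sphere geometry converts both ways", {
  expect_equal(radius_from_volume(0), 0)
  expect_equal(radius_from_volume(4 * pi / 3), 1)
  V <- c(0.01, 1, 14.1, 523)
  expect_equal(volume_from_radius(radius_from_volume(V)), V,
               tolerance = 1e-12)
  expect_error(radius_from_volume(-1), ">= 0")
  # radius is non-decreasing in volume
  expect_true(all(diff(radius_from_volume(seq(0, 50, by = 0.5))) >= 0))
})

test_that("viable fraction follows the rim-shell formula", {
  expect_equal(viable_fraction(0.1, 0.2), 1)
  expect_equal(viable_fraction(1, 0), 0)
  expect_equal(viable_fraction(0.4, 0.2), 0.875)  # r = 2 * d_rim
  expect_true(all(viable_fraction(seq(0, 5, 0.1), 0.2) >= 0))
  expect_true(all(viable_fraction(seq(0, 5, 0.1), 0.2) <= 1))
})

test_that("clone derivatives conserve cell bookkeeping and have the right
          limits", {
  gp <- growth_params()
  # extinction is absorbing
  z <- matrix(0, 2, 5, dimnames = list(NULL, c("P", "Q", "D", "K", "I")))
  expect_equal(unname(clone_derivatives(z, gp)), unname(z))

  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:4, 1)
    st <- cbind(P = runif(n, 0, 1e10), Q = runif(n, 0, 1e10),
                D = runif(n, 0, 5e9), K = runif(n, 1e9, 1e12),
                I = runif(n, 0, 3))
    s <- runif(n, 0, 2); inh <- runif(n)
    d <- clone_derivatives(st, gp, s, inh)
    # d(P+Q+D)/dt = proliferation inflow - clearance outflow
    N_tot <- sum(st[, "P"] + st[, "Q"])
    V_tot <- gp$v_cell * sum(st[, 1:3])
    phi <- viable_fraction(radius_from_volume(V_tot), gp$d_rim)
    prolif <- gp$lambda_prolif * s * phi * (1 - (st[, "P"] + st[, "Q"]) / st[, "K"]) * st[, "P"]
    expect_equal(rowSums(d[, c("P", "Q", "D"), drop = FALSE]),
                 prolif - gp$k_cl * st[, "D"], tolerance = 1e-10)
  }

  # tiny tumor, no death/drug/immune: exponential-growth limit dP ~ (lambda*s - delta0)*P
  gp0 <- growth_params(delta_q = 0, k_pq = 0.1, kappa_I = 0)
  tiny <- cbind(P = 1e4, Q = 0, D = 0, K = 1e12, I = 0)
  d <- clone_derivatives(tiny, gp0, s_c = 1.2, inh_c = 0)
  expect_equal(unname(d[1, "P"]),
               (gp0$lambda_prolif * 1.2 - gp0$delta0) * 1e4,
               tolerance = 1e-6)

  # saturation: clone at its own carrying capacity has zero proliferation term
  sat <- cbind(P = 4e9, Q = 1e9, D = 0, K = 5e9, I = 0)
  gp1 <- growth_params(delta0 = 0, delta_q = 0, k_pq = 0, k_qp = 0,
                       kappa_I = 0, gamma_drug = 0)
  dsat <- clone_derivatives(sat, gp1, s_c = 1, inh_c = 0)
  expect_equal(unname(dsat[1, "P"]), 0, tolerance = 1e-10)
  expect_error(clone_derivatives(cbind(P = -1, Q = 0, D = 0, K = 1, I = 0), gp),
               "non-negative")
})

test_that("build_clones conserves baseline volume and splits by f_res", {
  gp <- growth_params()
  p <- virtual_patient(r0 = 1, f_res = 0.1)
  cl <- build_clones(p, gp)
  total <- sum(cl$states[, c("P", "Q", "D")])
  expect_equal(total * gp$v_cell, 4 * pi / 3, tolerance = 1e-9)
  expect_equal(total, (4 * pi / 3) / gp$v_cell, tolerance = 1e-9)
  viable <- rowSums(cl$states[, c("P", "Q")])
  expect_equal(viable[2] / viable[1], 0.1 / 0.9, tolerance = 1e-9)

  z <- build_clones(virtual_patient(f_res = 0), gp)
  expect_equal(sum(z$states[2, c("P", "Q", "D")]), 0)
  expect_error(virtual_patient(f_res = 1), "f_res")
  expect_error(virtual_patient(f_res = -0.1), "f_res")
})

test_that("frozen dynamics leave all states constant", {
  gp <- growth_params(lambda_prolif = 0, delta0 = 0, delta_q = 0,
                      alpha_ang = 0, rho_imm = 0, kappa_I = 0,
                      gamma_drug = 0)
  # all cells proliferative and within the rim so quiescence exchange is off
  p <- virtual_patient(r0 = 0.1, prolif_frac0 = 1, f_res = 0.01)
  tr <- simulate_tumor(p, gp = gp, t_end = 100, dt_out = 10,
                       pk_mode = "none")
  for (k in seq_along(tr$time)) {
    expect_equal(tr$states[k, , ], tr$states[1, , ], tolerance = 1e-8)
  }
})

test_that("single-clone growth in the phi = 1 regime matches the logistic
          closed form", {
  gp <- growth_params(lambda_prolif = 0.1, delta0 = 0, delta_q = 0,
                      k_cl = 0, alpha_ang = 0, rho_imm = 0, kappa_I = 0,
                      gamma_drug = 0, d_rim = 1e6)
  sp <- signaling_params(s0 = 1, g_egfr = c(exon19del = 0, L858R = 0))
  p <- virtual_patient(r0 = 0.5, prolif_frac0 = 1, f_res = 0)
  k_cap0 <- 10
  tr <- simulate_tumor(p, gp = gp, sp = sp, t_end = 400, dt_out = 2,
                       pk_mode = "none", k_cap0 = k_cap0)
  N0 <- volume_from_radius(0.5) / gp$v_cell
  expected <- logistic_closed_form(tr$time, N0, k_cap0 * N0,
                                   gp$lambda_prolif)
  simulated <- tr$states[, 1, "P"]
  expect_lt(max(abs(simulated - expected) / expected), 1e-4)
})

test_that("compiled and R engines agree", {
  p <- virtual_patient(kras = TRUE, f_res = 0.02)
  a <- simulate_tumor(p, t_end = 200, dt_out = 5)
  b <- simulate_tumor(p, t_end = 200, dt_out = 5, engine = "R")
  expect_equal(a$radius, b$radius, tolerance = 1e-8)
  c1 <- simulate_tumor(p, t_end = 200, dt_out = 5, pk_mode = "superposition")
  c2 <- simulate_tumor(p, t_end = 200, dt_out = 5, pk_mode = "superposition",
                       engine = "R")
  expect_equal(c1$radius, c2$radius, tolerance = 1e-6)
})

test_that("simulated states stay non-negative across random patients", {
  pop <- sample_population(vpop_spec(), 200, seed = 915)
  patients <- as_virtual_patients(pop)
  for (p in patients) {
    tr <- simulate_tumor(p, t_end = 420, dt_out = 14)
    expect_true(all(tr$states >= 0))
    expect_true(all(is.finite(tr$radius)))
  }
})

test_that("strengthening the immune system never increases the radius", {
  p <- virtual_patient(f_res = 0.01)
  base <- simulate_tumor(p, t_end = 600, dt_out = 7)
  for (over in list(list(kappa_I = 0.016), list(rho_imm = 0.4))) {
    q <- p; q$growth_overrides <- over
    up <- simulate_tumor(q, t_end = 600, dt_out = 7)
    expect_true(all(up$radius <= base$radius + 1e-6))
  }
})

test_that("trajectory object is consistent and exports the documented
          columns", {
  tr <- quick_traj(t_end = 210)
  expect_s3_class(tr, "tumor_trajectory")
  expect_equal(tr$radius, radius_from_volume(tr$volume), tolerance = 1e-12)
  expect_true(all(diff(tr$time) > 0))
  df <- as.data.frame(tr)
  expect_true(all(c("patient_id", "t_days", "radius_cm", "V_total_cm3",
                    "clone1_P", "clone2_D") %in% names(df)))
  expect_equal(nrow(df), length(tr$time))
  expect_error(simulate_tumor(virtual_patient(), t_end = -1), "t_end")
})
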