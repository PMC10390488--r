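# Independent reference computations used as oracles across the suite.

# brute-force Bateman superposition: explicit sum over doses
brute_force_conc <- function(t, pk, n_doses, start = 0) {
  A <- pk$F_bio * pk$dose * pk$ka / (pk$Vd * (pk$ka - pk$ke))
  vapply(t, function(ti) {
    s <- 0
    for (i in seq_len(n_doses) - 1) {
      td <- ti - start - i * pk$interval
      if (td > 0) s <- s + A * (exp(-pk$ke * td) - exp(-pk$ka * td))
    }
    max(s, 0)
  }, numeric(1))
}

# full hypergeometric enumeration of the two-sided Fisher exact p
fisher_enum <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  supp <- lo:hi
  pr <- stats::dhyper(supp, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# product-limit estimator computed by direct recursion
km_by_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    r <- sum(time >= ut[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  list(time = ut, surv = out)
}

# two-group log-rank statistic from first principles (O - E vs V)
logrank_by_hand <- function(tA, eA, tB, eB) {
  times <- sort(unique(c(tA[eA == 1], tB[eB == 1])))
  O <- E <- V <- 0
  for (tt in times) {
    nA <- sum(tA >= tt); nB <- sum(tB >= tt); n <- nA + nB
    dA <- sum(tA == tt & eA == 1); dB <- sum(tB == tt & eB == 1)
    d <- dA + dB
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# logistic growth closed form
logistic_closed_form <- function(t, N0, K, r) {
  K * N0 * exp(r * t) / (K + N0 * (exp(r * t) - 1))
}

# a fast, small default patient simulation for tests
quick_traj <- function(patient = virtual_patient(), t_end = 913,
                       dt_out = 7, ...) {
  simulate_tumor(patient, t_end = t_end, dt_out = dt_out, ...)
}

# synthetic radius trajectory wrapped as a tumor_trajectory
fake_traj <- function(time_days, radius_cm, id = "fx") {
  structure(list(time = time_days, radius = radius_cm,
                 volume = volume_from_radius(radius_cm),
                 states = NULL, patient_id = id, n_clones = 2L),
            class = "tumor_trajectory")
}

# exhaustive earliest-progression re-scan (independent of the implementation)
rescan_progression <- function(time, radius, reference, rel = 0.2,
                               abs_diam = 0.5) {
  ref <- if (reference == "baseline") rep(radius[1], length(radius))
         else cummin(radius)
  for (i in seq_along(time)[-1]) {
    if (radius[i] >= (1 + rel) * ref[i] &&
        radius[i] - ref[i] >= abs_diam / 2) {
      return(list(t = time[i], event = 1L))
    }
  }
  list(t = time[length(time)], event = 0L)
}
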