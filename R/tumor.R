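#' Sphere radius from volume
#'
#' @param V volume in cm^3 (vectorized, >= 0).
#' @return radius in cm, `(3V / (4*pi))^(1/3)`.
#' @export
radius_from_volume <- function(V) {
  if (any(V < 0)) stop("'V' must be >= 0", call. = FALSE)
  (3 * V / (4 * pi))^(1 / 3)
}

#' Sphere volume from radius
#'
#' @param r radius in cm (vectorized, >= 0).
#' @return volume in cm^3.
#' @export
volume_from_radius <- function(r) {
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  4 / 3 * pi * r^3
}

#' Viable fraction of a spheroid with a proliferative rim
#'
#' Living, proliferation-competent cells occupy the outer shell of depth
#' `d_rim` (the viable depth); the fraction of the sphere volume inside
#' that shell is `1 - ((r - d_rim)/r)^3` for `r > d_rim` and 1
#' otherwise.
#'
#' @param r tumor radius, cm (vectorized, >= 0).
#' @param d_rim viable rim depth, cm (>= 0).
#' @return fraction in `[0, 1]`.
#' @export
viable_fraction <- function(r, d_rim) {
  if (any(r < 0) || d_rim < 0) stop("radius and rim depth must be >= 0",
                                    call. = FALSE)
  ifelse(r <= d_rim, 1, 1 - ((r - d_rim) / r)^3)
}

#' Time derivatives of all clone states
#'
#' The per-clone five-state system (states P proliferating, Q quiescent,
#' D dead, K carrying capacity, I immune pressure), given each clone's
#' current proliferation-signal multiplier `s_c` and drug inhibition
#' `inh_c`:
#'
#' * `dP = lambda*s*phi*(1 - (P+Q)/K)*P - k_pq*(1-phi)*P + k_qp*phi*Q -
#'   (delta0 + kappa_I*I + gamma_drug*inh)*P`
#' * `dQ = k_pq*(1-phi)*P - k_qp*phi*Q - (delta_q + kappa_I*I)*Q`
#' * `dD = (delta0 + kappa_I*I + gamma_drug*inh)*P +
#'   (delta_q + kappa_I*I)*Q - k_cl*D`
#' * `dK = alpha_ang*(P+Q)*(1 - K/K_max)`
#' * `dI = rho_imm*N_tot/(h_imm + N_tot) - d_imm*I`
#'
#' with `N_tot` the total viable cells over clones, `phi` the
#' [viable_fraction()] at the radius of the total (viable + dead) tumor
#' volume.  Competition for the neo-angiogenic carrying capacity is
#' clone-local (each clone against its own `K_c`, which starts
#' proportional to the clone's size and expands with its
#' neo-angiogenesis); clones interact through the shared spheroid
#' geometry (`phi`) and through immune recruitment driven by the total
#' burden.
#'
#' @param states matrix n_clones x 5 with columns P, Q, D, K, I
#'   (non-negative).
#' @param gp [growth_params()].
#' @param s_c per-clone signal multipliers (recycled).
#' @param inh_c per-clone *effective* inhibition fractions (target
#'   inhibition times the clone's [drug_effect_retention()]; recycled).
#'   Resistance mutations attenuate both the signal loss and the
#'   drug-induced death, which acts downstream of the signaling block.
#' @return matrix of the same shape with the time derivatives (1/day).
#' @export
clone_derivatives <- function(states, gp, s_c = 1, inh_c = 0) {
  if (!is.matrix(states) || ncol(states) != 5L) {
    stop("'states' must be an n_clones x 5 matrix", call. = FALSE)
  }
  if (any(!is.finite(states)) || any(states[, 1:3] < 0)) {
    stop("states must be finite and non-negative", call. = FALSE)
  }
  n <- nrow(states)
  s_c <- rep_len(s_c, n); inh_c <- rep_len(inh_c, n)
  P <- states[, 1]; Q <- states[, 2]; D <- states[, 3]
  K <- states[, 4]; I <- states[, 5]
  N_tot <- sum(P + Q)
  V_tot <- gp$v_cell * sum(P + Q + D)
  r <- radius_from_volume(V_tot)
  phi <- viable_fraction(r, gp$d_rim)
  kill_p <- gp$delta0 + gp$kappa_I * I + gp$gamma_drug * inh_c
  kill_q <- gp$delta_q + gp$kappa_I * I
  comp <- ifelse(K > 0, 1 - (P + Q) / K, 0)   # empty clone: 0/0 guard
  dP <- gp$lambda_prolif * s_c * phi * comp * P -
    gp$k_pq * (1 - phi) * P + gp$k_qp * phi * Q - kill_p * P
  dQ <- gp$k_pq * (1 - phi) * P - gp$k_qp * phi * Q - kill_q * Q
  dD <- kill_p * P + kill_q * Q - gp$k_cl * D
  dK <- gp$alpha_ang * (P + Q) * (1 - K / gp$K_max)
  dI <- gp$rho_imm * N_tot / (gp$h_imm + N_tot) - gp$d_imm * I
  out <- cbind(P = dP, Q = dQ, D = dD, K = dK, I = dI)
  rownames(out) <- rownames(states)
  out
}

# assemble the padded parameter vector consumed by the compiled RHS
.max_clones <- 16L

.build_parms <- function(clones, gp, sp, pk, pd, reg, pk_mode) {
  n <- length(clones$profiles)
  ic50 <- eff <- s0tot <- numeric(.max_clones)
  for (c in seq_len(n)) {
    pr <- clones$profiles[[c]]
    ic50[c] <- ic50_effective(pd, pr)
    eff[c] <- drug_effect_retention(pr, sp)
    s0tot[c] <- baseline_signal(pr, sp)
  }
  mode_code <- switch(pk_mode, none = 0, average = 1, superposition = 2)
  A <- pk$F_bio * pk$dose * pk$ka / (pk$Vd * (pk$ka - pk$ke))
  c(n, gp$v_cell, gp$d_rim, gp$K_max,
    gp$lambda_prolif, gp$k_pq, gp$k_qp, gp$delta0, gp$delta_q, gp$k_cl,
    gp$kappa_I, gp$gamma_drug, gp$alpha_ang, gp$rho_imm, gp$h_imm, gp$d_imm,
    mode_code, A, pk$ka * 24, pk$ke * 24, reg$interval_h[1] / 24,
    reg$start_day[1], reg$end_day[1], steady_state_cavg(pk),
    pd$Imax, pd$hill,
    ic50, eff, s0tot)
}

# R reference implementation of the compiled RHS (general regimens)
.rhs_r <- function(t, y, ctx) {
  n <- length(ctx$clones$profiles)
  states <- matrix(pmax(y, 0), nrow = n, ncol = 5, byrow = TRUE)
  C <- 0
  if (ctx$pk_mode != "none") {
    for (b in seq_len(nrow(ctx$reg))) {
      blk <- ctx$reg[b, ]
      pkb <- ctx$pk
      pkb$dose <- blk$dose_mg; pkb$interval <- blk$interval_h
      nmax <- if (is.finite(blk$end_day)) {
        floor((blk$end_day - blk$start_day) * 24 / blk$interval_h) + 1
      } else Inf
      C <- C + if (ctx$pk_mode == "average") {
        cb <- effective_concentration(t * 24, pkb, start = blk$start_day * 24)
        if (is.finite(blk$end_day) && t > blk$end_day) {
          cend <- effective_concentration(blk$end_day * 24, pkb,
                                          start = blk$start_day * 24)
          cend * exp(-pkb$ke * 24 * (t - blk$end_day))
        } else cb
      } else {
        concentration(t * 24, pkb, start = blk$start_day * 24, n_doses = nmax)
      }
    }
  }
  inh_c <- vapply(ctx$clones$profiles, function(pr)
    inhibition(C, ctx$pd, pr), numeric(1))
  eff_c <- vapply(ctx$clones$profiles, function(pr)
    drug_effect_retention(pr, ctx$sp), numeric(1))
  s_c <- mapply(function(pr, ih) signal_multiplier(pr, min(ih, 1), ctx$sp),
                ctx$clones$profiles, inh_c)
  d <- clone_derivatives(states, ctx$gp, s_c, eff_c * inh_c)
  list(as.vector(t(d)))
}

#' Simulate the tumor trajectory of one virtual patient
#'
#' Integrates the per-clone five-state system with a stiff-capable
#' solver (lsoda; relative tolerance 1e-6, absolute tolerance 1e-3
#' cells) on a uniform output grid, and derives total volume and radius
#' at every output time.  The default drug driver is the smooth
#' infusion-equivalent exposure (`pk_mode = "average"`); the exact
#' oscillating Bateman superposition is available with
#' `pk_mode = "superposition"` and an untreated run with
#' `pk_mode = "none"`.
#'
#' Small negative undershoots (above `-10 * atol`) are clamped to zero;
#' larger undershoots abort with an error reporting the last valid
#' time.
#'
#' @param patient a [virtual_patient()]; its `*_overrides` are applied
#'   to the corresponding parameter sets.
#' @param gp,sp,pk,pd parameter objects ([growth_params()],
#'   [signaling_params()], [pk_params()], [pd_params()]).
#' @param reg a [regimen()].
#' @param t_end simulation end, days.
#' @param dt_out output grid spacing, days (default 1: daily follow-up
#'   of the radius).
#' @param pk_mode `"average"`, `"superposition"` or `"none"`.
#' @param engine `"compiled"` (C right-hand side; single-block regimens)
#'   or `"R"` (reference implementation, any regimen).
#' @param rtol,atol solver tolerances.
#' @param k_cap0 initial carrying-capacity multiple, see
#'   [build_clones()].
#' @return object of class `tumor_trajectory`: list with `time` (days),
#'   `volume` (cm^3), `radius` (cm), `states` (array time x clone x
#'   state), `patient_id`, `n_clones`.
#' @export
simulate_tumor <- function(patient, gp = growth_params(),
                           sp = signaling_params(), pk = pk_params(),
                           pd = pd_params(), reg = regimen(),
                           t_end = 900, dt_out = 1,
                           pk_mode = c("average", "superposition", "none"),
                           engine = c("compiled", "R"),
                           rtol = 1e-6, atol = 1e-3, k_cap0 = 2) {
  stopifnot(inherits(patient, "virtual_patient"))
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  pk_mode <- match.arg(pk_mode)
  engine <- match.arg(engine)
  gp <- update_params(gp, patient$growth_overrides)
  pk <- update_params(pk, patient$pk_overrides)
  pd <- update_params(pd, patient$pd_overrides)
  if (length(patient$signaling_overrides)) {
    sp <- update_params(sp, patient$signaling_overrides)
  }
  clones <- build_clones(patient, gp, k_cap0 = k_cap0)
  n <- length(clones$profiles)
  y0 <- as.vector(t(clones$states))
  times <- seq(0, t_end, by = dt_out)
  if (engine == "compiled" && nrow(reg) == 1L) {
    parms <- .build_parms(clones, gp, sp, pk, pd, reg, pk_mode)
    out <- deSolve::ode(y = y0, times = times, func = "tumor_derivs",
                        parms = parms, dllname = "luadsim",
                        initfunc = "tumor_initmod", nout = 2,
                        outnames = c("V_cm3", "r_cm"),
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    ctx <- list(clones = clones, gp = gp, sp = sp, pk = pk, pd = pd,
                reg = reg, pk_mode = pk_mode)
    out <- deSolve::ode(y = y0, times = times, func = .rhs_r, parms = ctx,
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  if (nrow(out) < length(times)) {
    stop(sprintf("integration failed at t = %.3f days (last valid time)",
                 out[nrow(out), 1]), call. = FALSE)
  }
  y <- out[, 1 + seq_len(5 * n), drop = FALSE]
  if (min(y) < -10 * atol) {
    stop(sprintf("state undershoot below tolerance at t = %.1f days",
                 out[which(y < -10 * atol, arr.ind = TRUE)[1, 1], 1]),
         call. = FALSE)
  }
  y[y < 0] <- 0
  states <- array(y, dim = c(length(times), 5, n),
                  dimnames = list(NULL, c("P", "Q", "D", "K", "I"), NULL))
  states <- aperm(states, c(1, 3, 2))
  volume <- gp$v_cell * rowSums(states[, , "P", drop = FALSE] +
                                states[, , "Q", drop = FALSE] +
                                states[, , "D", drop = FALSE])
  structure(list(time = times, volume = volume,
                 radius = radius_from_volume(volume),
                 states = states, patient_id = patient$id, n_clones = n),
            class = "tumor_trajectory")
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<tumor_trajectory> patient %s: %d clones, ",
                     "%d time points over %.0f days\n",
                     "  radius %.2f -> %.2f cm (nadir %.2f cm at day %.0f)\n"),
              x$patient_id, x$n_clones, length(x$time), max(x$time),
              x$radius[1], x$radius[length(x$radius)], min(x$radius),
              x$time[which.min(x$radius)]))
  invisible(x)
}

#' @export
as.data.frame.tumor_trajectory <- function(x, ...) {
  df <- data.frame(patient_id = x$patient_id, t_days = x$time,
                   radius_cm = x$radius, V_total_cm3 = x$volume)
  for (c in seq_len(x$n_clones)) {
    for (st in c("P", "Q", "D")) {
      df[[sprintf("clone%d_%s", c, st)]] <- x$states[, c, st]
    }
  }
  df
}

#' Write one or more trajectories to a delimited text file
#'
#' @param trajs a `tumor_trajectory` or list of them.
#' @param file output path (CSV).
#' @return the written data frame, invisibly.
#' @export
write_trajectories <- function(trajs, file) {
  if (inherits(trajs, "tumor_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, as.data.frame))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
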