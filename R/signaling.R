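#' Stimulus-response surge parameters
#'
#' In vitro, pathway activation downstream of EGFR/cMET after a growth
#' factor stimulus rises to a single maximum and decays.  The surge is
#' parameterized directly by the two quantities reported for such
#' experiments: the peak activation level and the time of the peak.
#'
#' @param A_max peak activation as a fraction of maximal phosphorylation,
#'   in `[0, 1]`.
#' @param tau time of the peak in minutes (> 0).
#' @return object of class `surge_params`.
#' @export
surge_params <- function(A_max, tau) {
  if (!is.numeric(A_max) || A_max < 0 || A_max > 1) {
    stop("'A_max' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be > 0", call. = FALSE)
  structure(list(A_max = A_max, tau = tau), class = "surge_params")
}

#' Surge activation curve A_max * (t/tau) * exp(1 - t/tau)
#'
#' The simplest two-parameter unimodal curve whose free parameters are
#' exactly the calibrated observables: it is 0 at `t = 0`, attains its
#' maximum `A_max` exactly at `t = tau`, and decays exponentially
#' afterwards.
#'
#' @param t time since stimulus, minutes (vectorized, >= 0).
#' @param p a [surge_params()] object.
#' @return activation level(s) in `[0, A_max]`.
#' @export
surge_activation <- function(t, p) {
  stopifnot(inherits(p, "surge_params"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  p$A_max * (t / p$tau) * exp(1 - t / p$tau)
}

#' Signaling parameters for the proliferation-signal multiplier
#'
#' The in vivo signaling submodel is algebraic: per clone it converts
#' the mutation profile and the current drug inhibition into a
#' dimensionless proliferation-signal multiplier.  Activating EGFR
#' variants add a constitutive gain `g_egfr`; resistance mutations
#' (T790M, KRAS) attenuate the drug's effect on the signal by a factor
#' `1 - rho_res` each.  The four in vitro signaling observables are the
#' pERK/pAKT surges under EGF/HGF stimulation.
#'
#' @param s0 baseline signal (> 0).
#' @param g_egfr named vector of constitutive gains per EGFR variant.
#' @param rho_res named vector in `[0, 1]`: attenuation of the drug
#'   effect contributed by each resistance mutation.
#' @param surge named list of [surge_params()] for the in vitro
#'   read-outs (`pERK_EGF`, `pAKT_EGF`, `pERK_HGF`, `pAKT_HGF`).
#' @return object of class `signaling_params`.
#' @export
signaling_params <- function(s0 = 1,
                             g_egfr = c(exon19del = 0.5, L858R = 0.5),
                             rho_res = c(t790m = 0.9, kras = 0.85),
                             surge = list(
                               pERK_EGF = surge_params(0.95, 7),
                               pAKT_EGF = surge_params(0.85, 12),
                               pERK_HGF = surge_params(0.70, 10),
                               pAKT_HGF = surge_params(0.90, 15))) {
  if (!is.numeric(s0) || s0 <= 0) stop("'s0' must be > 0", call. = FALSE)
  if (any(rho_res < 0 | rho_res > 1)) {
    stop("'rho_res' entries must lie in [0, 1]", call. = FALSE)
  }
  structure(list(s0 = s0, g_egfr = g_egfr, rho_res = rho_res, surge = surge),
            class = "signaling_params")
}

#' Drug-effect retention factor of a clone
#'
#' `eff = prod(1 - rho_res)` over the resistance mutations present; the
#' drug attenuates the proliferation signal by `eff * inhibition`.  A
#' clone with no resistance mutations has `eff = 1` (full drug effect).
#'
#' @param profile a [mutation_profile()].
#' @param p a [signaling_params()].
#' @return scalar in `[0, 1]`.
#' @export
drug_effect_retention <- function(profile, p = signaling_params()) {
  stopifnot(inherits(profile, "mutation_profile"))
  eff <- 1
  if (profile$t790m && "t790m" %in% names(p$rho_res)) {
    eff <- eff * (1 - p$rho_res[["t790m"]])
  }
  if (profile$kras && "kras" %in% names(p$rho_res)) {
    eff <- eff * (1 - p$rho_res[["kras"]])
  }
  eff
}

#' Proliferation-signal multiplier of a clone
#'
#' `s = s0 * (1 + g_egfr + m_prolif) * (1 - eff * inhibition)` where
#' `eff` is the clone's [drug_effect_retention()].  Non-increasing in
#' the inhibition; clones carrying resistance mutations retain a
#' strictly positive signal even under complete target inhibition.
#'
#' @param profile a [mutation_profile()].
#' @param inhibition current drug inhibition, fraction in `[0, 1]`
#'   (vectorized).
#' @param p a [signaling_params()].
#' @return signal multiplier(s) `>= 0`.
#' @export
signal_multiplier <- function(profile, inhibition, p = signaling_params()) {
  stopifnot(inherits(profile, "mutation_profile"))
  if (any(inhibition < 0 | inhibition > 1)) {
    stop("'inhibition' must lie in [0, 1]", call. = FALSE)
  }
  g <- p$g_egfr[[profile$egfr_variant]]
  eff <- drug_effect_retention(profile, p)
  pmax(p$s0 * (1 + g + profile$m_prolif) * (1 - eff * inhibition), 0)
}

#' Baseline signal amplitude of a clone (drug-free multiplier)
#'
#' @param profile a [mutation_profile()].
#' @param p a [signaling_params()].
#' @return `s0 * (1 + g_egfr + m_prolif)`.
#' @export
baseline_signal <- function(profile, p = signaling_params()) {
  signal_multiplier(profile, 0, p)
}

#' Write in vitro stimulus-response curves to a delimited text file
#'
#' One row per (read-out, time) pair with columns `readout`, `time_min`,
#' `activation` — the visual-predictive-check export of the in vitro
#' mode.
#'
#' @param p a [signaling_params()].
#' @param file output path.
#' @param times evaluation grid in minutes.
#' @return the written data frame, invisibly.
#' @export
write_stimulus_response <- function(p, file, times = seq(0, 120, by = 1)) {
  stopifnot(inherits(p, "signaling_params"))
  df <- do.call(rbind, lapply(names(p$surge), function(nm) {
    data.frame(readout = nm, time_min = times,
               activation = surge_activation(times, p$surge[[nm]]))
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
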