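#' Gefitinib pharmacokinetic parameters (one-compartment oral model)
#'
#' Defaults are package-chosen values representative of published
#' gefitinib population kinetics (terminal half-life about two days,
#' large apparent distribution volume), not values printed in any single
#' source: dose 250 mg once daily, bioavailability 0.6, absorption
#' half-life about 1.4 h, elimination half-life 48 h, Vd 1400 L.
#'
#' @param dose dose per administration, mg.
#' @param interval dosing interval, hours.
#' @param F_bio oral bioavailability fraction in `(0, 1]`.
#' @param ka first-order absorption rate, 1/h.
#' @param ke first-order elimination rate, 1/h (must differ from `ka`).
#' @param Vd apparent distribution volume, L.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(dose = 250, interval = 24, F_bio = 0.6,
                      ka = 0.5, ke = log(2) / 48, Vd = 1400) {
  vals <- c(dose = dose, interval = interval, F_bio = F_bio,
            ka = ka, ke = ke, Vd = Vd)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all PK parameters must be positive and finite", call. = FALSE)
  }
  if (F_bio > 1) stop("'F_bio' must lie in (0, 1]", call. = FALSE)
  if (abs(ka - ke) < 1e-12) {
    stop("degenerate kinetics: 'ka' must differ from 'ke'", call. = FALSE)
  }
  structure(as.list(vals), class = "pk_params")
}

#' Pharmacodynamic (Emax) inhibition parameters
#'
#' Effective potency is mutation-dependent: the IC50 is multiplied by
#' the potency multiplier of every mutation present in the clone's
#' profile.  The exon 19 deletion is the reference (multiplier 1) and is
#' more gefitinib-sensitive than L858R; T790M strongly reduces binding;
#' KRAS acts downstream but is given an apparent potency shift as well.
#' Multiplier values are package calibration choices.
#'
#' @param Imax maximal inhibition fraction in `(0, 1]`.
#' @param IC50_base baseline half-maximal concentration, mg/L.
#' @param hill Hill coefficient (> 0).
#' @param multipliers named non-negative potency multipliers per
#'   mutation (`exon19del`, `L858R`, `t790m`, `kras`, `pik3ca`).
#' @return object of class `pd_params`.
#' @export
pd_params <- function(Imax = 0.95, IC50_base = 0.02, hill = 1,
                      multipliers = c(exon19del = 1, L858R = 1.6,
                                      t790m = 25, kras = 4, pik3ca = 1)) {
  if (!is.numeric(Imax) || Imax <= 0 || Imax > 1) {
    stop("'Imax' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(hill) || hill <= 0) stop("'hill' must be > 0", call. = FALSE)
  if (!is.numeric(IC50_base) || IC50_base <= 0) {
    stop("'IC50_base' must be > 0", call. = FALSE)
  }
  if (any(multipliers < 0)) stop("multipliers must be >= 0", call. = FALSE)
  structure(list(Imax = Imax, IC50_base = IC50_base, hill = hill,
                 multipliers = multipliers), class = "pd_params")
}

#' Treatment regimen
#'
#' A regimen is a table of dosing blocks; the default is 250 mg
#' gefitinib every 24 h from day 0 onwards.
#'
#' @param start_day,end_day first and last day of the block (days;
#'   `end_day = Inf` for open-ended).
#' @param dose_mg dose per administration, mg.
#' @param interval_h dosing interval, hours.
#' @return data frame of class `regimen`.
#' @export
regimen <- function(start_day = 0, dose_mg = 250, interval_h = 24,
                    end_day = Inf) {
  df <- data.frame(start_day = start_day, dose_mg = dose_mg,
                   interval_h = interval_h, end_day = end_day)
  if (any(df$dose_mg < 0) || any(df$interval_h <= 0) ||
      any(df$end_day < df$start_day)) {
    stop("invalid regimen block", call. = FALSE)
  }
  class(df) <- c("regimen", "data.frame")
  df
}

# exponentially-weighted dose superposition, numerically stable
# closed form of sum_{i=0}^{n-1} exp(-k * (t - i * tau)) for t >= (n-1) * tau
geo_sum <- function(k, t, tau, n) {
  u <- t - (n - 1) * tau
  (exp(-k * u) - exp(-k * (u + n * tau))) / (1 - exp(-k * tau))
}

#' Plasma concentration under repeated oral dosing
#'
#' Exact superposition of single-dose Bateman curves
#' `F*D*ka / (Vd*(ka-ke)) * (exp(-ke*s) - exp(-ka*s))` over all doses
#' administered up to `t`, evaluated with a numerically stable geometric
#' closed form (equivalent to brute-force superposition to machine
#' precision).
#'
#' @param t time, hours (vectorized).
#' @param pk a [pk_params()].
#' @param start time of the first dose, hours.
#' @param n_doses maximal number of doses administered (default
#'   unlimited).
#' @return concentration in mg/L; 0 before the first dose.
#' @export
concentration <- function(t, pk, start = 0, n_doses = Inf) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  A <- pk$F_bio * pk$dose * pk$ka / (pk$Vd * (pk$ka - pk$ke))
  tr <- t - start
  out <- numeric(length(t))
  on <- tr > 0
  if (any(on)) {
    n <- pmin(floor(tr[on] / pk$interval) + 1, n_doses)
    out[on] <- A * (geo_sum(pk$ke, tr[on], pk$interval, n) -
                    geo_sum(pk$ka, tr[on], pk$interval, n))
  }
  pmax(out, 0)
}

#' Smooth infusion-equivalent concentration for repeated dosing
#'
#' Replaces the within-interval Bateman fluctuation by its zero-order
#' infusion equivalent (same average exposure): the concentration rises
#' as `Css * (1 - exp(-ke * t))` towards the steady-state average
#' `Css = F*D / (ke * Vd * tau)`.  Used as the default drug driver for
#' the tumor ODEs, where the slow growth dynamics respond to average
#' exposure; the exact oscillating profile is available via
#' [concentration()].
#'
#' @inheritParams concentration
#' @return concentration in mg/L.
#' @export
effective_concentration <- function(t, pk, start = 0) {
  stopifnot(inherits(pk, "pk_params"))
  css <- steady_state_cavg(pk)
  tr <- t - start
  ifelse(tr > 0, css * (1 - exp(-pk$ke * tr)), 0)
}

#' Steady-state average concentration F*D / (ke * Vd * tau)
#'
#' @param pk a [pk_params()].
#' @return mg/L.
#' @export
steady_state_cavg <- function(pk) {
  pk$F_bio * pk$dose / (pk$ke * pk$Vd * pk$interval)
}

#' Effective IC50 of a clone
#'
#' `IC50_base` multiplied by the potency multiplier of every mutation
#' present in the profile (the EGFR variant's multiplier always
#' applies).
#'
#' @param pd a [pd_params()].
#' @param profile a [mutation_profile()].
#' @return effective IC50 in mg/L.
#' @export
ic50_effective <- function(pd, profile) {
  stopifnot(inherits(pd, "pd_params"), inherits(profile, "mutation_profile"))
  m <- pd$multipliers
  ic <- pd$IC50_base * m[[profile$egfr_variant]]
  if (profile$t790m && "t790m" %in% names(m)) ic <- ic * m[["t790m"]]
  if (profile$kras && "kras" %in% names(m)) ic <- ic * m[["kras"]]
  if (profile$pik3ca && "pik3ca" %in% names(m)) ic <- ic * m[["pik3ca"]]
  ic
}

#' Emax target inhibition at a given concentration
#'
#' `Imax * C^h / (IC50_eff^h + C^h)` with the clone's mutation-adjusted
#' IC50.
#'
#' @param C plasma concentration, mg/L (vectorized, >= 0).
#' @param pd a [pd_params()].
#' @param profile a [mutation_profile()].
#' @return inhibition fraction in `[0, Imax]`.
#' @export
inhibition <- function(C, pd, profile = mutation_profile("exon19del")) {
  if (any(C < 0)) stop("'C' must be >= 0", call. = FALSE)
  ic <- ic50_effective(pd, profile)
  ch <- C^pd$hill
  ifelse(C > 0, pd$Imax * ch / (ic^pd$hill + ch), 0)
}
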