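#' Synthetic reference-trial scenario
#'
#' Defines the generative process of a synthetic reference dataset that
#' stands in for a digitized trial arm: progression and death times per
#' subject, follow-up censoring, and the derived PFS/OS/TTP event
#' tables.  The default scenario is a 159-patient arm shaped like the
#' gefitinib reference trial (Weibull progression with median about 9
#' months, exponential death with median about 24 months, 30-month
#' follow-up), yielding roughly 119 progression events.
#'
#' @param n_patients arm size.
#' @param follow_up_months administrative censoring time.
#' @param progression_dist list describing the progression-time
#'   distribution: `list(family = "weibull", shape, median)` or
#'   `list(family = "exponential", median)` (months).
#' @param death_median_months median of the exponential death process
#'   (`Inf` for no deaths).
#' @param censor_rate additional random (drop-out) censoring hazard per
#'   month (0 for none).
#' @param seed integer seed used by [generate_reference_dataset()].
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_patients = 159, follow_up_months = 30,
                          progression_dist = list(family = "weibull",
                                                  shape = 1.4, median = 9),
                          death_median_months = 24,
                          censor_rate = 0, seed = 20301) {
  if (n_patients <= 0 || follow_up_months <= 0) {
    stop("'n_patients' and 'follow_up_months' must be > 0", call. = FALSE)
  }
  if (censor_rate < 0) stop("'censor_rate' must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 follow_up_months = follow_up_months,
                 progression_dist = progression_dist,
                 death_median_months = death_median_months,
                 censor_rate = censor_rate, seed = seed),
            class = "scenario_spec")
}

.draw_progression <- function(dist, n) {
  switch(dist$family,
    weibull = {
      scale <- dist$median / log(2)^(1 / dist$shape)
      stats::rweibull(n, shape = dist$shape, scale = scale)
    },
    exponential = stats::rexp(n, rate = log(2) / dist$median),
    stop("unknown progression family ", dist$family, call. = FALSE))
}

#' Generate a synthetic reference dataset (PFS, OS, TTP and digitized
#' curves)
#'
#' Each subject receives a latent progression time and a latent death
#' time; PFS is the first of the two, OS is death, and TTP is the
#' progression time.  All three are right-censored at follow-up (and at
#' an optional random drop-out time).  The PFS/OS tables are internally
#' consistent with the TTP table: [infer_ttp()] applied to the
#' generated PFS/OS event times recovers exactly the progression events
#' of subjects who progressed before dying.  "Digitized" curves are the
#' Kaplan-Meier estimates of the event tables sampled on a regular time
#' grid with at-risk counts, as produced by digitizing a published
#' figure.
#'
#' @param spec a [scenario_spec()].
#' @param out_dir optional directory; when given, writes
#'   `pfs_events.csv`, `os_events.csv`, `ttp_events.csv` and
#'   `*_curve.csv` files (synthetic stand-ins for digitized trial
#'   curves).
#' @param grid_by time resolution of the digitized curves, months.
#' @return list with event tables `pfs`, `os`, `ttp`, digitized
#'   `curves` (list of `survival_curve`), and `latent` (the generating
#'   times per subject).
#' @export
generate_reference_dataset <- function(spec = scenario_spec(),
                                       out_dir = NULL, grid_by = 0.25) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  t_prog <- .draw_progression(spec$progression_dist, n)
  t_death <- if (is.finite(spec$death_median_months)) {
    stats::rexp(n, rate = log(2) / spec$death_median_months)
  } else rep(Inf, n)
  t_cens <- if (spec$censor_rate > 0) {
    pmin(stats::rexp(n, rate = spec$censor_rate), spec$follow_up_months)
  } else rep(spec$follow_up_months, n)

  mk <- function(tt) {
    obs <- pmin(tt, t_cens)
    event_table(id = sprintf("s%03d", seq_len(n)),
                time = pmax(obs, 1e-6), event = as.integer(tt <= t_cens))
  }
  pfs <- mk(pmin(t_prog, t_death))
  os <- mk(t_death)
  # TTP: progression observed only if it precedes death and censoring
  ttp <- event_table(id = sprintf("s%03d", seq_len(n)),
                     time = pmax(pmin(t_prog, t_death, t_cens), 1e-6),
                     event = as.integer(t_prog <= pmin(t_death, t_cens)))

  grid <- seq(0, spec$follow_up_months, by = grid_by)
  digitize <- function(ev) {
    km <- km_estimate(ev)
    structure(list(time = grid, surv = survival_at(km, grid),
                   n_risk = vapply(grid, function(g) sum(ev$time >= g),
                                   numeric(1)),
                   n_event = rep(NA_integer_, length(grid))),
              class = "survival_curve")
  }
  curves <- list(pfs = digitize(pfs), os = digitize(os), ttp = digitize(ttp))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pfs, file.path(out_dir, "pfs_events.csv"),
                     row.names = FALSE)
    utils::write.csv(os, file.path(out_dir, "os_events.csv"),
                     row.names = FALSE)
    utils::write.csv(ttp, file.path(out_dir, "ttp_events.csv"),
                     row.names = FALSE)
    for (nm in names(curves)) {
      write_digitized_curve(curves[[nm]],
                            file.path(out_dir,
                                      sprintf("%s_curve_synthetic.csv", nm)))
    }
  }
  list(pfs = pfs, os = os, ttp = ttp, curves = curves,
       latent = data.frame(t_prog = t_prog, t_death = t_death,
                           t_cens = t_cens))
}
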