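DAYS_PER_MONTH <- 365.25 / 12

#' Detect RECIST progression on a simulated radius trajectory
#'
#' Progression is an increase of the largest tumor dimension by at least
#' 20% and by at least 0.5 cm.  The model tracks the radius, so the
#' absolute criterion translates to 0.25 cm on the radius.  The
#' reference is either the baseline radius or the running nadir (RECIST
#' 1.1 convention; the default).  The earliest output-grid time at which
#' both criteria hold is the progression time; otherwise the patient is
#' right-censored at the end of follow-up.
#'
#' @param traj a [simulate_tumor()] trajectory.
#' @param reference `"nadir"` or `"baseline"`.
#' @param rel_threshold relative increase threshold (default 0.20).
#' @param abs_threshold_diameter absolute increase threshold on the
#'   diameter, cm (default 0.5).
#' @return list with `ttp` (months), `event` (1 progression, 0
#'   censored), `ttp_days`, `reference`.
#' @export
detect_progression <- function(traj, reference = c("nadir", "baseline"),
                               rel_threshold = 0.2,
                               abs_threshold_diameter = 0.5) {
  stopifnot(inherits(traj, "tumor_trajectory"))
  reference <- match.arg(reference)
  r <- traj$radius
  t <- traj$time
  if (length(r) < 2L) stop("trajectory must have at least two points",
                           call. = FALSE)
  r_ref <- if (reference == "baseline") rep(r[1], length(r)) else cummin(r)
  hit <- r >= (1 + rel_threshold) * r_ref &
    (r - r_ref) >= abs_threshold_diameter / 2
  hit[1] <- FALSE
  idx <- which(hit)
  if (length(idx)) {
    list(ttp = t[idx[1]] / DAYS_PER_MONTH, event = 1L, ttp_days = t[idx[1]],
         reference = reference)
  } else {
    list(ttp = t[length(t)] / DAYS_PER_MONTH, event = 0L,
         ttp_days = t[length(t)], reference = reference)
  }
}

#' Percent change of the tumor radius versus baseline
#'
#' @param traj a [simulate_tumor()] trajectory.
#' @param t_months evaluation time in months; must lie within the
#'   simulated span.  The radius is taken at the nearest output grid
#'   point.
#' @return percent change `100 * (r(t) - r(0)) / r(0)`.
#' @export
percent_change_radius <- function(traj, t_months = 6) {
  stopifnot(inherits(traj, "tumor_trajectory"))
  td <- t_months * DAYS_PER_MONTH
  if (td < 0 || td > max(traj$time) + 1e-9) {
    stop("'t_months' outside the simulated span", call. = FALSE)
  }
  i <- which.min(abs(traj$time - td))
  100 * (traj$radius[i] - traj$radius[1]) / traj$radius[1]
}

#' Individual predicted-versus-observed TTP match
#'
#' A prediction matches when it falls within the observation-time
#' uncertainty window of the observed TTP: medical visits occur every
#' `visit_interval` months, so a progression reported at a visit
#' actually occurred during the preceding interval.  The match window is
#' `[observed - visit_interval, observed]`, boundaries inclusive.
#'
#' @param predicted_ttp,observed_ttp months (vectorized, > 0).
#' @param visit_interval months between medical visits (default 2).
#' @return logical vector of matches.
#' @export
individual_ttp_match <- function(predicted_ttp, observed_ttp,
                                 visit_interval = 2) {
  if (any(predicted_ttp <= 0) || any(observed_ttp <= 0) ||
      visit_interval <= 0) {
    stop("times and visit interval must be positive", call. = FALSE)
  }
  predicted_ttp >= observed_ttp - visit_interval &
    predicted_ttp <= observed_ttp
}

#' Simulate outcomes for a virtual population
#'
#' Runs [simulate_tumor()] for each patient and derives the per-patient
#' outcome record: TTP with censoring at end of follow-up, baseline and
#' nadir radius, and the 6-month radius change.
#'
#' @param patients list of [virtual_patient()] objects (e.g. from
#'   [as_virtual_patients()]).
#' @param follow_up_months follow-up cut-off; also the simulation span.
#' @param dt_out output grid, days.
#' @param reference progression reference policy, see
#'   [detect_progression()].
#' @param change_at_months evaluation time of the radius-change column.
#' @param ... further arguments to [simulate_tumor()].
#' @return data frame of class `patient_outcomes` with columns
#'   `patient_id`, `ttp_months`, `event`, `baseline_radius_cm`,
#'   `nadir_radius_cm`, `change_6mo_pct`, `kras_flag`.
#' @export
simulate_outcomes <- function(patients, follow_up_months = 30, dt_out = 1,
                              reference = c("nadir", "baseline"),
                              change_at_months = 6, ...) {
  reference <- match.arg(reference)
  t_end <- follow_up_months * DAYS_PER_MONTH
  rows <- lapply(patients, function(p) {
    traj <- simulate_tumor(p, t_end = t_end, dt_out = dt_out, ...)
    prog <- detect_progression(traj, reference = reference)
    data.frame(patient_id = p$id,
               ttp_months = prog$ttp,
               event = prog$event,
               baseline_radius_cm = traj$radius[1],
               nadir_radius_cm = min(traj$radius),
               change_6mo_pct = percent_change_radius(
                 traj, min(change_at_months, follow_up_months)),
               kras_flag = p$kras)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("patient_outcomes", "data.frame")
  out
}

#' Read/write outcome tables
#'
#' Delimited-text outcome tables are the interface between simulation,
#' validation and plotting.
#'
#' @param outcomes a data frame with at least `patient_id`,
#'   `ttp_months`, `event`.
#' @param file path.
#' @return `write_outcomes` returns the data invisibly; `read_outcomes`
#'   returns the data frame.
#' @export
write_outcomes <- function(outcomes, file) {
  utils::write.csv(outcomes, file, row.names = FALSE)
  invisible(outcomes)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(file) {
  df <- utils::read.csv(file)
  need <- c("patient_id", "ttp_months", "event")
  if (!all(need %in% names(df))) {
    stop("outcome table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
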