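#' Event table constructor
#'
#' @param id subject identifiers.
#' @param time event or censoring times, months (> 0).
#' @param event 1 = event observed, 0 = right censored.
#' @return data frame of class `event_table`.
#' @export
event_table <- function(id = seq_along(time), time, event = 1) {
  time <- as.numeric(time)
  event <- as.integer(rep_len(event, length(time)))
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) stop("event flags must be 0/1", call. = FALSE)
  df <- data.frame(id = rep_len(id, length(time)), time = time, event = event)
  class(df) <- c("event_table", "data.frame")
  df
}

.as_event_table <- function(x) {
  if (inherits(x, "patient_outcomes") ||
      all(c("patient_id", "ttp_months", "event") %in% names(x))) {
    return(event_table(x$patient_id, x$ttp_months, x$event))
  }
  if (all(c("time", "event") %in% names(x))) {
    return(event_table(x$id %||% seq_len(nrow(x)), x$time, x$event))
  }
  stop("cannot interpret input as an event table", call. = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()]: censored times reduce the
#' risk set without producing steps.
#'
#' @param events an `event_table` (or outcome table with `ttp_months` /
#'   `event` columns).
#' @return object of class `survival_curve`: list with `time`, `surv`,
#'   `n_risk`, `n_event` (step-function values at the observed times,
#'   with S(0) = 1 prepended).
#' @export
km_estimate <- function(events) {
  ev <- .as_event_table(events)
  if (nrow(ev) == 0L) stop("empty event table", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ev)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(nrow(ev), fit$n.risk),
                 n_event = c(0, fit$n.event)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  med <- survival_quantile(x, 0.5)
  cat(sprintf("<survival_curve> %d time points, median %.2f months\n",
              length(x$time), med))
  invisible(x)
}

#' Evaluate a survival curve (right-continuous step function)
#'
#' @param curve a `survival_curve`.
#' @param times evaluation times.
#' @return survival probabilities at `times`.
#' @export
survival_at <- function(curve, times) {
  stats::stepfun(curve$time[-1], curve$surv)(times)
}

#' Quantile of a survival curve (e.g. median at p = 0.5)
#'
#' @param curve a `survival_curve`.
#' @param p survival probability threshold.
#' @return earliest time with `S(t) <= p`, or `NA` if never reached.
#' @export
survival_quantile <- function(curve, p = 0.5) {
  i <- which(curve$surv <= p)
  if (length(i)) curve$time[i[1]] else NA_real_
}

#' Infer progression times from PFS and OS event lists
#'
#' Progression-free survival events include deaths; under the
#' assumption that a patient who died before progression contributes
#' the same time to both lists, each OS (death) time removes at most
#' one PFS event within matching tolerance `tol`, leaving the
#' progression events.
#'
#' @param pfs_events,os_events numeric vectors of event times, months.
#' @param tol matching tolerance, months (default 0: exact matching;
#'   for digitized curves use half the curve's time resolution).
#' @return vector of inferred progression (TTP) event times.
#' @export
infer_ttp <- function(pfs_events, os_events, tol = 0) {
  if (tol < 0) stop("'tol' must be >= 0", call. = FALSE)
  pfs <- sort(as.numeric(pfs_events))
  removed <- logical(length(pfs))
  for (d in sort(as.numeric(os_events))) {
    cand <- which(!removed & abs(pfs - d) <= tol + 1e-12)
    if (length(cand)) {
      removed[cand[which.min(abs(pfs[cand] - d))]] <- TRUE
    }
  }
  pfs[!removed]
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square with one degree of freedom,
#' via [survival::survdiff()].  If neither group has any event the test
#' is undefined and p = 1 is returned with a message.
#'
#' @param groupA,groupB event tables.
#' @return list with `statistic` and `p`.
#' @export
logrank <- function(groupA, groupB) {
  a <- .as_event_table(groupA); b <- .as_event_table(groupB)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty",
                                           call. = FALSE)
  if (sum(a$event) + sum(b$event) == 0L) {
    message("no events in either group: log-rank undefined, p = 1")
    return(list(statistic = 0, p = 1))
  }
  df <- rbind(data.frame(time = a$time, event = a$event, g = 0L),
              data.frame(time = b$time, event = b$event, g = 1L))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Bootstrapped pointwise prediction interval for the Kaplan-Meier curve
#'
#' Draws `B` subsamples of size `n_real` from the virtual-population
#' outcomes (without replacement by default, mirroring subsampling of a
#' 10x population), estimates the Kaplan-Meier curve of each, and
#' returns the pointwise `(1-level)/2` and `1-(1-level)/2` empirical
#' percentiles on a common time grid.
#'
#' @param vpop_outcomes outcomes of the full virtual population.
#' @param n_real subsample size (the real population's size).
#' @param B number of resamples (default 1000).
#' @param level interval level (default 0.95).
#' @param seed integer seed or `NULL`.
#' @param grid common evaluation grid; defaults to the event times of
#'   the full virtual population.
#' @param replace draw with replacement instead.
#' @return object of class `km_band`: list with `grid`, `lo`, `hi`,
#'   `median` (pointwise resample median), `B`, `level`.
#' @export
bootstrap_pi <- function(vpop_outcomes, n_real, B = 1000, level = 0.95,
                         seed = NULL, grid = NULL, replace = FALSE) {
  ev <- .as_event_table(vpop_outcomes)
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  if (!replace && n_real > nrow(ev)) {
    stop("'n_real' exceeds the virtual population size", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- sort(unique(c(0, ev$time)))
  S <- matrix(NA_real_, nrow = B, ncol = length(grid))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(ev), n_real, replace = replace)
    S[b, ] <- survival_at(km_estimate(ev[idx, ]), grid)
  }
  alpha <- (1 - level) / 2
  qs <- apply(S, 2, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE, type = 7)
  structure(list(grid = grid, lo = qs[1, ], hi = qs[3, ], median = qs[2, ],
                 B = B, level = level), class = "km_band")
}

#' Raw coverage of an observed curve by a prediction band
#'
#' Evaluates the observed Kaplan-Meier step function at each of its own
#' step times and returns the percentage of those points lying inside
#' the band (inclusive).  A time-integrated variant weights each step
#' by the time until the next one.
#'
#' @param observed a `survival_curve` (or event table, converted via
#'   [km_estimate()]).
#' @param band a `km_band` from [bootstrap_pi()].
#' @param weighted if `TRUE`, weight step points by the following
#'   inter-step interval instead of counting them equally.
#' @return coverage percentage in \[0, 100\].
#' @export
raw_coverage <- function(observed, band, weighted = FALSE) {
  if (!inherits(observed, "survival_curve")) observed <- km_estimate(observed)
  ts <- observed$time[observed$time > 0]
  ss <- observed$surv[observed$time > 0]
  if (length(ts) == 0L) stop("observed curve has no step points", call. = FALSE)
  if (min(ts) > max(band$grid) || max(ts) < min(band$grid)) {
    stop("observed curve and band have disjoint time ranges", call. = FALSE)
  }
  lo <- stats::stepfun(band$grid[-1], band$lo)(ts)
  hi <- stats::stepfun(band$grid[-1], band$hi)(ts)
  inside <- ss >= lo - 1e-12 & ss <= hi + 1e-12
  if (weighted) {
    w <- diff(c(ts, max(ts) + mean(diff(c(0, ts)))))
    100 * sum(w * inside) / sum(w)
  } else {
    100 * mean(inside)
  }
}

#' Bootstrapped log-rank negativity
#'
#' Repeats `n_tests` log-rank tests, each comparing the real event
#' table with a subsample of size `|real|` drawn from the
#' virtual-population outcomes (without replacement by default), and
#' returns the percentage of non-significant tests (p > 0.05).
#'
#' @param vpop_outcomes virtual-population outcomes.
#' @param real real-population event table.
#' @param n_tests number of tests (default 7000: 5000 plus 2000 for
#'   convergence).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed or `NULL`.
#' @param replace subsample with replacement instead.
#' @return percentage of negative (non-significant) tests.
#' @export
bootstrapped_logrank <- function(vpop_outcomes, real, n_tests = 7000,
                                 alpha = 0.05, seed = NULL, replace = FALSE) {
  ev <- .as_event_table(vpop_outcomes)
  re <- .as_event_table(real)
  if (n_tests < 1) stop("'n_tests' must be >= 1", call. = FALSE)
  if (nrow(re) == 0L) stop("real event table is empty", call. = FALSE)
  if (!replace && nrow(re) > nrow(ev)) {
    stop("real population larger than the virtual population", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  neg <- 0L
  for (i in seq_len(n_tests)) {
    idx <- sample.int(nrow(ev), nrow(re), replace = replace)
    if (logrank(ev[idx, ], re)$p > alpha) neg <- neg + 1L
  }
  100 * neg / n_tests
}

#' Five-step virtual-population validation protocol
#'
#' Assembles the two validation metrics — raw coverage of the observed
#' Kaplan-Meier curve by the bootstrapped 95% prediction interval of
#' the simulated curve, and the percentage of negative bootstrapped
#' log-rank tests — and applies the pre-defined 80%/80% thresholds.
#'
#' @param vpop_outcomes outcomes of the simulated virtual population.
#' @param observed the real arm: an event table or a `survival_curve`
#'   (e.g. from a digitized trial curve read with
#'   [read_digitized_curve()]).
#' @param n_bootstrap_pi resamples for the prediction interval.
#' @param n_lr_tests number of bootstrapped log-rank tests.
#' @param level prediction-interval level.
#' @param coverage_threshold,lr_threshold validation thresholds
#'   (percent).
#' @param seed integer seed or `NULL`.
#' @param replace subsample with replacement.
#' @return object of class `validation_report`.
#' @export
validate_vpop <- function(vpop_outcomes, observed,
                          n_bootstrap_pi = 1000, n_lr_tests = 7000,
                          level = 0.95, coverage_threshold = 80,
                          lr_threshold = 80, seed = NULL, replace = FALSE) {
  ev <- .as_event_table(vpop_outcomes)
  obs_curve <- if (inherits(observed, "survival_curve")) observed
               else km_estimate(observed)
  if (!is.null(seed)) set.seed(seed)
  n_real <- if (inherits(observed, "survival_curve")) {
    max(observed$n_risk)
  } else {
    nrow(.as_event_table(observed))
  }
  band <- bootstrap_pi(ev, n_real = n_real, B = n_bootstrap_pi,
                       level = level, replace = replace)
  cov <- raw_coverage(obs_curve, band)
  lr <- if (inherits(observed, "survival_curve")) {
    NA_real_
  } else {
    bootstrapped_logrank(ev, observed, n_tests = n_lr_tests,
                         replace = replace)
  }
  pass_cov <- cov >= coverage_threshold
  pass_lr <- if (is.na(lr)) NA else lr >= lr_threshold
  structure(list(raw_coverage_pct = cov, lr_negative_pct = lr,
                 coverage_threshold = coverage_threshold,
                 lr_threshold = lr_threshold,
                 n_bootstrap_pi = n_bootstrap_pi, n_lr_tests = n_lr_tests,
                 level = level, n_real = n_real, n_vpop = nrow(ev),
                 pass_coverage = pass_cov, pass_lr = pass_lr,
                 pass = isTRUE(pass_cov) && isTRUE(pass_lr),
                 seed = seed, band = band),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  raw coverage: %.1f%% (threshold %g%%) -> %s\n",
              x$raw_coverage_pct, x$coverage_threshold,
              if (isTRUE(x$pass_coverage)) "pass" else "FAIL"))
  if (is.na(x$lr_negative_pct)) {
    cat("  bootstrapped log-rank: not computed (observed curve only)\n")
  } else {
    cat(sprintf("  negative log-rank tests: %.1f%% (threshold %g%%) -> %s\n",
                x$lr_negative_pct, x$lr_threshold,
                if (isTRUE(x$pass_lr)) "pass" else "FAIL"))
  }
  cat(sprintf("  virtual n = %d, real n = %d, PI resamples = %d, LR tests = %d\n",
              x$n_vpop, x$n_real, x$n_bootstrap_pi, x$n_lr_tests))
  cat(sprintf("  overall: %s\n", if (x$pass) "VALIDATED" else "not validated"))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report a `validation_report`.
#' @param file path.
#' @return the file path, invisibly.
#' @export
write_report <- function(report, file) {
  stopifnot(inherits(report, "validation_report"))
  x <- unclass(report)
  x$band <- NULL
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Read or write a digitized survival curve file
#'
#' Delimited text with columns `time_months`, `survival`, `n_risk`
#' (the format produced by curve digitization).
#'
#' @param file path.
#' @return a `survival_curve`.
#' @export
read_digitized_curve <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  need <- c("time_months", "survival", "n_risk")
  if (!all(need %in% names(df))) {
    stop("digitized curve must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  o <- order(df$time_months)
  structure(list(time = df$time_months[o], surv = df$survival[o],
                 n_risk = df$n_risk[o],
                 n_event = rep(NA_integer_, nrow(df))),
            class = "survival_curve")
}

#' @rdname read_digitized_curve
#' @param curve a `survival_curve`.
#' @export
write_digitized_curve <- function(curve, file) {
  df <- data.frame(time_months = curve$time, survival = curve$surv,
                   n_risk = curve$n_risk)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
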