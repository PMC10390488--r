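#' Estimate a standard deviation from a quantile interval
#'
#' When only a central interval (for instance a reported range treated
#' as a central coverage interval) is available, the normal-theory
#' estimate is `sd = (q_hi - q_lo) / (2 * z)` with `z` the standard
#' normal quantile at `(1 + coverage) / 2`.
#'
#' @param q_lo,q_hi interval bounds (`q_hi > q_lo`).
#' @param coverage central probability mass of the interval, in (0, 1).
#' @return estimated standard deviation.
#' @examples
#' estimate_sd_from_quantiles(-1.96, 1.96, 0.95)  # 1
#' @export
estimate_sd_from_quantiles <- function(q_lo, q_hi, coverage = 0.95) {
  if (!is.numeric(q_lo) || !is.numeric(q_hi) || q_hi <= q_lo) {
    stop("need 'q_hi' > 'q_lo'", call. = FALSE)
  }
  if (coverage <= 0 || coverage >= 1) stop("'coverage' must be in (0, 1)",
                                           call. = FALSE)
  (q_hi - q_lo) / (2 * stats::qnorm((1 + coverage) / 2))
}

# marginal descriptor distribution constructors -------------------------------

.marginal_categorical <- function(levels, probs) {
  if (length(levels) != length(probs)) stop("levels/probs length mismatch",
                                            call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("categorical probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  list(type = "categorical", levels = levels, probs = probs)
}

.marginal_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  list(type = "truncnorm", mean = mean, sd = sd, lower = lower, upper = upper)
}

.marginal_lognormal <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  if (sdlog <= 0) stop("sdlog must be > 0", call. = FALSE)
  list(type = "lognormal", meanlog = meanlog, sdlog = sdlog,
       lower = lower, upper = upper)
}

.marginal_quantile <- function(m, u) {
  switch(m$type,
    categorical = {
      cp <- cumsum(m$probs)
      m$levels[findInterval(u, c(0, utils::head(cp, -1)),
                            rightmost.closed = TRUE)]
    },
    truncnorm = {
      plo <- stats::pnorm(m$lower, m$mean, m$sd)
      phi <- stats::pnorm(m$upper, m$mean, m$sd)
      stats::qnorm(plo + u * (phi - plo), m$mean, m$sd)
    },
    lognormal = {
      plo <- stats::plnorm(m$lower, m$meanlog, m$sdlog)
      phi <- stats::plnorm(m$upper, m$meanlog, m$sdlog)
      stats::qlnorm(plo + u * (phi - plo), m$meanlog, m$sdlog)
    },
    stop("unknown marginal type ", m$type, call. = FALSE))
}

#' Virtual-population descriptor specification
#'
#' Marginal distributions per descriptor, an optional Gaussian-copula
#' rank-correlation matrix, and the population size rule (10 times the
#' number of real patients with a progression event).  The default spec
#' mirrors the baseline characteristics of the gefitinib arm of a
#' 159-patient reference trial: sex 33.3% male; age truncated normal
#' with median 63 on support [36, 89], sd estimated treating the range
#' as a central 99% interval; EGFR exon 19 deletion 58.5% versus L858R;
#' smoking never/former/current 66.7/11.9/21.4%; ethnicity 55.3% Asian;
#' stage IIIb 1.9%.  Descriptors not reported in trial baselines (KRAS
#' prevalence 2.5%, PIK3CA 4%, tumor geometry and mechanistic rates)
#' use general-population defaults.
#'
#' @param marginals named list of marginal specs (see
#'   [marginal_categorical()], [marginal_truncnorm()],
#'   [marginal_lognormal()]).
#' @param copula rank-correlation matrix over the descriptors (row and
#'   column names must match marginal names) or `NULL` for
#'   independence.
#' @param size_multiplier virtual/real size ratio (default 10).
#' @return object of class `vpop_spec`.
#' @export
vpop_spec <- function(marginals = default_marginals(), copula = NULL,
                      size_multiplier = 10) {
  stopifnot(is.list(marginals), length(names(marginals)) == length(marginals))
  if (!is.null(copula)) {
    nm <- names(marginals)
    if (!is.matrix(copula) || !identical(rownames(copula), nm) ||
        !identical(colnames(copula), nm)) {
      stop("'copula' must be a matrix with descriptor row/col names",
           call. = FALSE)
    }
    ev <- eigen(copula, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("'copula' must be positive semi-definite",
                              call. = FALSE)
  }
  structure(list(marginals = marginals, copula = copula,
                 size_multiplier = size_multiplier), class = "vpop_spec")
}

#' @rdname vpop_spec
#' @param levels,probs categorical levels and probabilities.
#' @export
marginal_categorical <- function(levels, probs) .marginal_categorical(levels, probs)

#' @rdname vpop_spec
#' @param mean,sd,lower,upper truncated-normal parameters.
#' @export
marginal_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  .marginal_truncnorm(mean, sd, lower, upper)
}

#' @rdname vpop_spec
#' @param meanlog,sdlog log-scale parameters.
#' @export
marginal_lognormal <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  .marginal_lognormal(meanlog, sdlog, lower, upper)
}

#' Default descriptor marginals (reference-trial baselines plus
#' general-population mechanistic variability)
#'
#' @param p_exon19 probability of the exon 19 deletion (58.5% matches
#'   the reference trial; use 0.5 for the sensitivity-analysis
#'   population).
#' @return named list of marginals for [vpop_spec()].
#' @export
default_marginals <- function(p_exon19 = 93 / 159) {
  list(
    sex = .marginal_categorical(c("male", "female"), c(53, 106) / 159),
    age = .marginal_truncnorm(63, estimate_sd_from_quantiles(36, 89, 0.99),
                              36, 89),
    egfr_variant = .marginal_categorical(c("exon19del", "L858R"),
                                         c(p_exon19, 1 - p_exon19)),
    smoking = .marginal_categorical(c("never", "former", "current"),
                                    c(106, 19, 34) / 159),
    ethnicity = .marginal_categorical(c("asian", "non_asian"),
                                      c(88, 71) / 159),
    stage = .marginal_categorical(c("IIIb", "IV"), c(3, 156) / 159),
    kras = .marginal_categorical(c(TRUE, FALSE), c(0.025, 0.975)),
    pik3ca = .marginal_categorical(c(TRUE, FALSE), c(0.04, 0.96)),
    r0 = .marginal_lognormal(log(1.5), 0.25, 0.7, 4),
    prolif_frac0 = .marginal_truncnorm(0.6, 0.1, 0.2, 0.9),
    f_res = .marginal_lognormal(log(0.006), 1.3, 1e-6, 0.3),
    m_prolif = .marginal_truncnorm(0, 0.2, -0.5, 0.5),
    lambda_prolif = .marginal_lognormal(log(0.14), 0.15, 0.03, 0.5),
    delta0 = .marginal_lognormal(log(0.004), 0.2, 5e-4, 0.05),
    alpha_ang = .marginal_lognormal(log(0.065), 0.5, 0.008, 0.4),
    rho_imm = .marginal_lognormal(log(0.2), 0.8, 0.01, 2),
    kappa_I = .marginal_lognormal(log(0.008), 0.8, 3e-4, 0.08),
    d_rim = .marginal_lognormal(log(0.2), 0.15, 0.05, 0.6)
  )
}

#' Sample a virtual population from a descriptor specification
#'
#' Draws `n` descriptor vectors by a Gaussian copula (identity
#' correlation by default, i.e. independent marginals).  Reproducible
#' for a fixed `seed`; only the two common EGFR variants are emitted.
#'
#' @param spec a [vpop_spec()].
#' @param n number of virtual patients.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return data frame (one row per patient, one column per descriptor,
#'   plus `id`) with attribute `seed`.
#' @export
sample_population <- function(spec = vpop_spec(), n, seed = NULL) {
  stopifnot(inherits(spec, "vpop_spec"))
  if (!is.numeric(n) || n < 0) stop("'n' must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  nm <- names(spec$marginals)
  k <- length(nm)
  if (n == 0L) {
    u <- matrix(numeric(0), nrow = 0, ncol = k, dimnames = list(NULL, nm))
  } else if (is.null(spec$copula)) {
    u <- matrix(stats::runif(n * k), nrow = n, ncol = k,
                dimnames = list(NULL, nm))
  } else {
    L <- chol(spec$copula + diag(1e-10, k))
    z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% L
    u <- stats::pnorm(z)
    colnames(u) <- nm
  }
  cols <- lapply(nm, function(d) .marginal_quantile(spec$marginals[[d]], u[, d]))
  names(cols) <- nm
  df <- data.frame(id = sprintf("vp%04d", seq_len(n)), cols,
                   stringsAsFactors = FALSE)
  attr(df, "seed") <- seed
  df
}

#' Convert sampled descriptor rows into virtual patients
#'
#' Mechanistic descriptor columns (`lambda_prolif`, `delta0`,
#' `alpha_ang`, `rho_imm`, `kappa_I`, `d_rim`) become growth-parameter
#' overrides; the remaining columns populate the [virtual_patient()]
#' fields they name.
#'
#' @param pop data frame from [sample_population()].
#' @return list of [virtual_patient()] objects.
#' @export
as_virtual_patients <- function(pop) {
  growth_cols <- intersect(c("lambda_prolif", "delta0", "alpha_ang",
                             "rho_imm", "kappa_I", "d_rim"), names(pop))
  lapply(seq_len(nrow(pop)), function(i) {
    row <- pop[i, ]
    go <- as.list(row[growth_cols])
    virtual_patient(
      id = as.character(row$id),
      sex = as.character(row$sex %||% "female"),
      age = as.numeric(row$age %||% 63),
      smoking = as.character(row$smoking %||% "never"),
      ethnicity = as.character(row$ethnicity %||% "asian"),
      stage = as.character(row$stage %||% "IV"),
      egfr_variant = as.character(row$egfr_variant %||% "exon19del"),
      kras = isTRUE(as.logical(row$kras %||% FALSE)),
      pik3ca = isTRUE(as.logical(row$pik3ca %||% FALSE)),
      m_prolif = as.numeric(row$m_prolif %||% 0),
      r0 = as.numeric(row$r0 %||% 1.5),
      prolif_frac0 = as.numeric(row$prolif_frac0 %||% 0.6),
      f_res = as.numeric(row$f_res %||% 0.006),
      growth_overrides = go)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test: the p-value sums the probabilities of all
#' tables (at fixed margins) whose probability does not exceed that of
#' the observed table (up to a relative tolerance of 1e-7).  Degenerate
#' tables with an all-zero margin return p = 1 with a message.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    message("degenerate 2x2 table (all-zero margin): p = 1")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Real-population baseline table
#'
#' Observed per-characteristic counts of a real trial arm, the format
#' consumed by [compare_baselines()].  `luxlung7_baseline()` returns
#' the gefitinib reference arm used throughout the package: categorical
#' counts over 159 patients and a deterministic quantile reconstruction
#' of the 159 ages from the reported median 63 and range 36-89.
#'
#' @param categorical named list; each element is a named integer
#'   vector of counts per level.
#' @param continuous named list of numeric vectors (individual values,
#'   possibly reconstructed from summaries).
#' @return object of class `baseline_table`.
#' @export
baseline_table <- function(categorical, continuous = list()) {
  stopifnot(is.list(categorical))
  if (any(vapply(categorical, function(x) any(x < 0), logical(1)))) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(list(categorical = categorical, continuous = continuous),
            class = "baseline_table")
}

#' @rdname baseline_table
#' @export
luxlung7_baseline <- function() {
  age_m <- .marginal_truncnorm(63, estimate_sd_from_quantiles(36, 89, 0.99),
                               36, 89)
  ages <- .marginal_quantile(age_m, stats::ppoints(159))
  baseline_table(
    categorical = list(
      sex = c(male = 53, female = 106),
      egfr_variant = c(exon19del = 93, L858R = 66),
      smoking = c(never = 106, former = 19, current = 34),
      ethnicity = c(asian = 88, non_asian = 71),
      stage = c(IIIb = 3, IV = 156)),
    continuous = list(age = ages))
}

#' Compare virtual-population baselines against a real population
#'
#' Categorical characteristics are compared with the two-sided Fisher
#' exact test (r x c tables via the exact network algorithm, falling
#' back to the large-sample chi-square test with a message when the
#' exact computation is infeasible); continuous characteristics with
#' the two-sided two-sample t-test.  Levels absent from both groups are
#' dropped with a message.
#'
#' @param vpop data frame from [sample_population()].
#' @param real a [baseline_table()].
#' @param workspace_limit total count above which r x c tables fall
#'   back to chi-square.
#' @return data frame with columns `characteristic`, `test`, `p_value`.
#' @export
compare_baselines <- function(vpop, real, workspace_limit = 1e6) {
  stopifnot(inherits(real, "baseline_table"))
  rows <- list()
  for (ch in names(real$categorical)) {
    if (!ch %in% names(vpop)) next
    counts <- real$categorical[[ch]]
    vt <- table(factor(as.character(vpop[[ch]]), levels = names(counts)))
    tab <- rbind(real = counts, virtual = as.integer(vt))
    keep <- colSums(tab) > 0
    if (!all(keep)) {
      message("dropping empty level(s) of ", ch, ": ",
              paste(names(counts)[!keep], collapse = ", "))
      tab <- tab[, keep, drop = FALSE]
    }
    p <- if (ncol(tab) < 2L) {
      1
    } else if (sum(tab) > workspace_limit) {
      message("characteristic ", ch,
              ": falling back to chi-square (table too large for exact test)")
      stats::chisq.test(tab)$p.value
    } else {
      tryCatch(stats::fisher.test(tab)$p.value,
               error = function(e) {
                 message("characteristic ", ch,
                         ": falling back to chi-square (", conditionMessage(e),
                         ")")
                 stats::chisq.test(tab)$p.value
               })
    }
    rows[[ch]] <- data.frame(characteristic = ch, test = "fisher",
                             p_value = p)
  }
  for (ch in names(real$continuous)) {
    if (!ch %in% names(vpop)) next
    p <- stats::t.test(as.numeric(vpop[[ch]]),
                       as.numeric(real$continuous[[ch]]))$p.value
    rows[[ch]] <- data.frame(characteristic = ch, test = "t", p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sampled population to a delimited text file
#'
#' One row per patient, one column per descriptor; the sampling seed is
#' recorded in a `# seed:` header line.
#'
#' @param pop data frame from [sample_population()].
#' @param file path.
#' @return the data invisibly.
#' @export
write_population <- function(pop, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", attr(pop, "seed") %||% "NA"), con)
  utils::write.csv(pop, con, row.names = FALSE)
  invisible(pop)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  first <- readLines(file, n = 1)
  df <- utils::read.csv(file, comment.char = "#")
  if (grepl("^# seed:", first)) {
    sd <- sub("^# seed: ", "", first)
    attr(df, "seed") <- if (sd == "NA") NULL else as.integer(sd)
  }
  df
}
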