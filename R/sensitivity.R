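#' Tornado (median-split) sensitivity analysis
#'
#' For each descriptor, patients are split at the descriptor's median
#' into a low-value and a high-value category (ties to the low
#' category), and the impact of each category is the relative shift of
#' the category's median output versus the overall median output:
#' `100 * (median(output in category) - overall median) / overall
#' median`.  Descriptors are ranked by `max(|impact_low|,
#' |impact_high|)` and the `top_k` most impactful are returned.  The
#' split makes no distributional assumption about how a descriptor
#' affects the output.
#'
#' @param outputs numeric vector of per-patient output values (e.g.
#'   TTP in months or 6-month radius change).
#' @param descriptors data frame or matrix of per-patient descriptor
#'   values, rows aligned with `outputs`.  Factors and logicals are
#'   coerced to numeric codes for the median split; constant
#'   descriptors get zero impact with a message.
#' @param top_k number of entries to return (default 10).
#' @return data frame with columns `descriptor`, `impact_low_pct`,
#'   `impact_high_pct`, `rank`, ordered by rank.
#' @export
tornado <- function(outputs, descriptors, top_k = 10) {
  outputs <- as.numeric(outputs)
  if (nrow(as.data.frame(descriptors)) != length(outputs)) {
    stop("'outputs' and 'descriptors' must be aligned", call. = FALSE)
  }
  med_out <- stats::median(outputs)
  if (!is.finite(med_out) || med_out == 0) {
    stop("overall median output is zero or undefined: relative impact undefined",
         call. = FALSE)
  }
  descriptors <- as.data.frame(descriptors)
  rows <- lapply(names(descriptors), function(d) {
    x <- descriptors[[d]]
    if (is.character(x)) x <- factor(x)
    x <- as.numeric(x)
    mx <- stats::median(x, na.rm = TRUE)
    low <- x <= mx
    # ties to the low category; if the median is the maximum (majority at
    # the top value) that rule degenerates, so assign ties to high instead
    if (all(low)) low <- x < mx
    if (all(low) || !any(low)) {
      message("descriptor ", d, " is (nearly) constant: impact 0")
      return(data.frame(descriptor = d, impact_low_pct = 0,
                        impact_high_pct = 0))
    }
    data.frame(
      descriptor = d,
      impact_low_pct = 100 * (stats::median(outputs[low]) - med_out) / med_out,
      impact_high_pct = 100 * (stats::median(outputs[!low]) - med_out) / med_out)
  })
  out <- do.call(rbind, rows)
  score <- pmax(abs(out$impact_low_pct), abs(out$impact_high_pct))
  out <- out[order(-score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Run the tornado analysis on a freshly simulated population
#'
#' Generates a virtual population under the sensitivity configuration
#' (general-population descriptors with a 50/50 EGFR-variant split, a
#' single flattened parameterization shared by the clones), simulates
#' all patients, and ranks the descriptors by their impact on the
#' requested output.
#'
#' @param n population size (default 5000).
#' @param output `"ttp"` (months, censored at follow-up) or
#'   `"radius_change"` (6-month percent change).
#' @param seed integer seed.
#' @param top_k entries to return.
#' @param follow_up_months,dt_out simulation span and output grid.
#' @param spec descriptor specification; defaults to the
#'   general-population spec with 50/50 EGFR variants.
#' @return list with `table` (the ranked tornado entries), `outputs`,
#'   `population`.
#' @export
tornado_analysis <- function(n = 5000, output = c("ttp", "radius_change"),
                             seed = 1, top_k = 10, follow_up_months = 30,
                             dt_out = 7,
                             spec = vpop_spec(default_marginals(p_exon19 = 0.5))) {
  output <- match.arg(output)
  pop <- sample_population(spec, n, seed = seed)
  outcomes <- simulate_outcomes(as_virtual_patients(pop),
                                follow_up_months = follow_up_months,
                                dt_out = dt_out)
  y <- if (output == "ttp") outcomes$ttp_months else outcomes$change_6mo_pct
  desc <- pop[, setdiff(names(pop), "id"), drop = FALSE]
  list(table = tornado(y, desc, top_k = top_k), outputs = y,
       population = pop, output = output)
}

#' Write a tornado table to a delimited text file
#'
#' @param table data frame from [tornado()].
#' @param file path.
#' @return the data invisibly.
#' @export
write_tornado <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(table)
}
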