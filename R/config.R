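#' Default simulator configuration
#'
#' Nested list of every tunable parameter group: growth, signaling, PK,
#' PD, regimen, simulation control, clinical read-out, virtual
#' population and validation settings.  A YAML rendering of this
#' configuration ships with the package
#' (`system.file("extdata", "default_config.yaml", package = "luadsim")`)
#' and is regenerated from these defaults, so the R constructors remain
#' the single source of truth.
#'
#' @return nested named list of class `luadsim_config`.
#' @export
default_config <- function() {
  sp <- signaling_params()
  structure(list(
    growth = unclass(growth_params()),
    signaling = list(s0 = sp$s0, g_egfr = as.list(sp$g_egfr),
                     rho_res = as.list(sp$rho_res),
                     surge = lapply(sp$surge, unclass)),
    pk = unclass(pk_params()),
    pd = {
      pd <- pd_params()
      list(Imax = pd$Imax, IC50_base = pd$IC50_base, hill = pd$hill,
           multipliers = as.list(pd$multipliers))
    },
    regimen = list(start_day = 0, dose_mg = 250, interval_h = 24,
                   end_day = Inf),
    simulation = list(follow_up_months = 30, dt_out_days = 1,
                      pk_mode = "average", rtol = 1e-6, atol = 1e-3,
                      k_cap0 = 2),
    clinical = list(reference = "nadir", rel_threshold = 0.2,
                    abs_threshold_diameter = 0.5, visit_interval_months = 2),
    vpop = list(size_multiplier = 10, marginals = default_marginals()),
    validation = list(n_bootstrap_pi = 1000, n_lr_tests = 7000,
                      level = 0.95, coverage_threshold = 80,
                      lr_threshold = 80)),
    class = "luadsim_config")
}

#' Read / write a configuration file (YAML)
#'
#' @param config a `luadsim_config` list.
#' @param file path to a YAML configuration.
#' @return `read_config` returns the configuration; `write_config` the
#'   path, invisibly.
#' @export
write_config <- function(config, file) {
  cfg <- rapply(unclass(config),
                function(x) if (identical(x, Inf)) ".inf" else x,
                how = "replace")
  yaml::write_yaml(cfg, file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  cfg <- rapply(cfg, function(x) if (identical(x, ".inf")) Inf else x,
                how = "replace")
  base <- unclass(default_config())
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        merge_into(base[[nm]], new[[nm]])
      } else new[[nm]]
    }
    base
  }
  structure(merge_into(base, cfg), class = "luadsim_config")
}

#' Materialize parameter objects from a configuration
#'
#' @param config a `luadsim_config`.
#' @return list with `gp`, `sp`, `pk`, `pd`, `reg` parameter objects
#'   plus the `simulation`, `clinical`, `vpop`, `validation` sections.
#' @export
config_params <- function(config = default_config()) {
  sg <- config$signaling
  list(
    gp = do.call(growth_params, config$growth),
    sp = signaling_params(
      s0 = sg$s0, g_egfr = unlist(sg$g_egfr), rho_res = unlist(sg$rho_res),
      surge = lapply(sg$surge, function(s) surge_params(s$A_max, s$tau))),
    pk = do.call(pk_params, config$pk),
    pd = pd_params(Imax = config$pd$Imax, IC50_base = config$pd$IC50_base,
                   hill = config$pd$hill,
                   multipliers = unlist(config$pd$multipliers)),
    reg = do.call(regimen, config$regimen),
    simulation = config$simulation,
    clinical = config$clinical,
    vpop = config$vpop,
    validation = config$validation)
}

#' Rebuild a [vpop_spec()] from a configuration's vpop section
#'
#' @param config a `luadsim_config`.
#' @return a [vpop_spec()].
#' @export
config_vpop_spec <- function(config = default_config()) {
  marg <- lapply(config$vpop$marginals, function(m) {
    m$probs <- unlist(m$probs)
    m$levels <- unlist(m$levels)
    if (identical(m$type, "categorical") &&
        all(as.character(m$levels) %in% c("TRUE", "FALSE"))) {
      m$levels <- as.logical(m$levels)
    }
    m
  })
  vpop_spec(marginals = marg,
            size_multiplier = config$vpop$size_multiplier %||% 10)
}
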