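#' Tumor growth parameters (one clone-shared set, 15 parameters)
#'
#' Rates are per day; lengths in cm; cell counts in cells.  Defaults are
#' the package's human-setting calibration, chosen so that a typical
#' sensitive+resistant virtual patient under daily gefitinib shows a
#' moderate initial shrinkage followed by relapse, with a median time to
#' progression of roughly eight to nine months.
#'
#' @param lambda_prolif baseline proliferation rate (1/day).
#' @param delta0 baseline death rate of proliferating cells (1/day).
#' @param delta_q death rate of quiescent cells (1/day).
#' @param k_pq quiescence entry rate (1/day), active outside the viable rim.
#' @param k_qp quiescence exit rate (1/day), active inside the viable rim.
#' @param k_cl clearance rate of dead cells (1/day).
#' @param v_cell volume of one cell (cm^3).
#' @param d_rim viable rim depth (cm): maximal depth from the spheroid
#'   surface at which cells still proliferate.
#' @param K_max maximal carrying capacity (cells).
#' @param alpha_ang neo-angiogenic carrying-capacity growth rate (1/day).
#' @param rho_imm immune recruitment rate (1/day).
#' @param h_imm immune half-saturation tumor burden (cells).
#' @param d_imm immune pressure decay rate (1/day).
#' @param kappa_I immune kill coefficient (1/day per unit pressure).
#' @param gamma_drug drug-induced death coefficient (1/day at full
#'   inhibition).
#' @return named list of class `growth_params` with exactly these 15
#'   entries.
#' @export
growth_params <- function(lambda_prolif = 0.14,
                          delta0 = 0.004,
                          delta_q = 0.003,
                          k_pq = 0.1,
                          k_qp = 0.05,
                          k_cl = 0.05,
                          v_cell = 1e-9,
                          d_rim = 0.2,
                          K_max = 1e12,
                          alpha_ang = 0.065,
                          rho_imm = 0.2,
                          h_imm = 1e10,
                          d_imm = 0.1,
                          kappa_I = 0.008,
                          gamma_drug = 0.01) {
  gp <- list(lambda_prolif = lambda_prolif, delta0 = delta0,
             delta_q = delta_q, k_pq = k_pq, k_qp = k_qp, k_cl = k_cl,
             v_cell = v_cell, d_rim = d_rim, K_max = K_max,
             alpha_ang = alpha_ang, rho_imm = rho_imm, h_imm = h_imm,
             d_imm = d_imm, kappa_I = kappa_I, gamma_drug = gamma_drug)
  bad <- vapply(gp, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("growth parameters must be single non-negative finite numbers: ",
         paste(names(gp)[bad], collapse = ", "), call. = FALSE)
  }
  structure(gp, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params> (per-clone 5-state model, 15 parameters)\n")
  print(unlist(x))
  invisible(x)
}

#' Update a parameter object with named overrides
#'
#' @param params a parameter object ([growth_params()], [pk_params()],
#'   [pd_params()] or [signaling_params()]).
#' @param overrides named list or vector of replacement values; unknown
#'   names are an error.
#' @return params with the overrides applied and revalidated.
#' @export
update_params <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- unclass(params)
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (is.numeric(out[[nm]]) && length(out[[nm]]) == 1L) val <- as.numeric(val)
    out[[nm]] <- val
  }
  do.call(class(params)[1], as.list(out))
}
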