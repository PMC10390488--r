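#' Experimental setting with a reference organism mass
#'
#' The same model structure is used across in vitro, mouse-xenograft and
#' human simulations; rate parameters are translated between settings by
#' allometric scaling against the setting's reference mass.  Reference
#' masses are 2.63 g for the in vitro spheroid system, 23 g for the
#' mouse, and 70 kg for the (default) human.
#'
#' @param name one of `"in_vitro"`, `"mouse"`, `"human"`.
#' @param reference_mass reference organism mass in grams; defaults to
#'   the setting's standard value.
#' @return an object of class `setting` with fields `name` and
#'   `reference_mass`.
#' @examples
#' setting("mouse")$reference_mass   # 23 g
#' @export
setting <- function(name = c("human", "mouse", "in_vitro"),
                    reference_mass = NULL) {
  name <- match.arg(name)
  default_mass <- c(in_vitro = 2.63, mouse = 23, human = 70000)
  if (is.null(reference_mass)) reference_mass <- default_mass[[name]]
  if (!is.numeric(reference_mass) || length(reference_mass) != 1L ||
      !is.finite(reference_mass) || reference_mass <= 0) {
    stop("'reference_mass' must be a single positive finite number", call. = FALSE)
  }
  structure(list(name = name, reference_mass = reference_mass),
            class = "setting")
}

#' @export
print.setting <- function(x, ...) {
  cat(sprintf("<setting> %s (reference mass %g g)\n", x$name, x$reference_mass))
  invisible(x)
}

#' Allometric power-law scaling Z = a * M^b
#'
#' @param a allometric coefficient, in the units of the scaled quantity.
#' @param b allometric exponent (dimensionless).
#' @param M organism mass in grams; must be positive.
#' @return the scaled quantity `a * M^b` (vectorized over any argument).
#' @examples
#' allometric_scale(1, 0.75, 23)   # metabolic-type scaling at mouse mass
#' @export
allometric_scale <- function(a, b, M) {
  if (any(!is.finite(M)) || any(M <= 0)) {
    stop("mass 'M' must be positive and finite", call. = FALSE)
  }
  a * M^b
}

#' Allometric rules for rescaling a parameter set
#'
#' A rule is the allometric exponent applied to a named rate parameter.
#' First-order rates conventionally scale with exponent -1/4 and
#' capacities (cell numbers) with exponent 1; exponents are configurable
#' per parameter.
#'
#' @param exponents named numeric vector, one exponent per parameter to
#'   rescale.
#' @return named numeric vector of class `allometry_rules`.
#' @export
allometry_rules <- function(exponents) {
  if (is.null(names(exponents)) || any(!nzchar(names(exponents)))) {
    stop("'exponents' must be a fully named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(exponents))) stop("exponents must be finite", call. = FALSE)
  structure(as.numeric(exponents), names = names(exponents),
            class = "allometry_rules")
}

#' Default allometric rules for the growth-parameter rates
#'
#' Every first-order rate gets exponent -1/4 and the maximal carrying
#' capacity gets exponent 1 (classic metabolic scaling); geometric
#' quantities (cell volume, rim depth) and the dimensionless
#' half-saturation are left unscaled.
#'
#' @return an [allometry_rules()] object covering the rate parameters of
#'   [growth_params()].
#' @export
default_allometry_rules <- function() {
  rates <- c("lambda_prolif", "delta0", "delta_q", "k_pq", "k_qp", "k_cl",
             "alpha_ang", "rho_imm", "d_imm", "kappa_I", "gamma_drug")
  ex <- stats::setNames(rep(-0.25, length(rates)), rates)
  ex["K_max"] <- 1
  ex["h_imm"] <- 1
  allometry_rules(ex)
}

#' Rescale a parameter set between settings by allometry
#'
#' Each parameter named in `rules` is multiplied by
#' `(M_to / M_from)^b`; parameters without a rule are returned
#' unchanged.  Rate parameters (units 1/time) must all be covered by a
#' rule; pass exponent 0 to pin a rate.
#'
#' @param params named numeric vector or a parameter object such as
#'   [growth_params()] (any named list of scalars).
#' @param from,to [setting()] objects.
#' @param rules an [allometry_rules()] object; defaults to
#'   [default_allometry_rules()].
#' @return params of the same class with scaled entries.
#' @export
rescale_params <- function(params, from, to, rules = default_allometry_rules()) {
  stopifnot(inherits(from, "setting"), inherits(to, "setting"))
  ratio <- to$reference_mass / from$reference_mass
  nm <- intersect(names(rules), names(params))
  out <- params
  for (p in nm) out[[p]] <- params[[p]] * ratio^rules[[p]]
  out
}
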