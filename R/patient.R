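#' Mutation profile of one tumor clone
#'
#' The population is assumed to contain only the two common activating
#' EGFR variants (exon 19 deletion, exon 21 L858R).  Optional flags mark
#' the secondary gatekeeper mutation T790M and KRAS / PIK3CA
#' co-mutations; `m_prolif` is the aggregate effect of further implicit
#' mutations on the cell-proliferation hallmark, expressed as an
#' additive offset to the proliferation signal.
#'
#' @param egfr_variant `"exon19del"` or `"L858R"`.
#' @param t790m,kras,pik3ca logical co-mutation flags.
#' @param m_prolif dimensionless proliferation-signal offset.
#' @return object of class `mutation_profile`.
#' @export
mutation_profile <- function(egfr_variant = c("exon19del", "L858R"),
                             t790m = FALSE, kras = FALSE, pik3ca = FALSE,
                             m_prolif = 0) {
  egfr_variant <- match.arg(egfr_variant)
  stopifnot(is.logical(t790m), is.logical(kras), is.logical(pik3ca),
            is.numeric(m_prolif), length(m_prolif) == 1L, is.finite(m_prolif))
  structure(list(egfr_variant = egfr_variant, t790m = isTRUE(t790m),
                 kras = isTRUE(kras), pik3ca = isTRUE(pik3ca),
                 m_prolif = m_prolif),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  flags <- c("T790M", "KRAS", "PIK3CA")[c(x$t790m, x$kras, x$pik3ca)]
  cat(sprintf("<mutation_profile> EGFR %s%s, m_prolif = %g\n", x$egfr_variant,
              if (length(flags)) paste0(" + ", paste(flags, collapse = "+")) else "",
              x$m_prolif))
  invisible(x)
}

#' Construct a virtual patient
#'
#' A virtual patient is one sampled descriptor vector: demographics,
#' mutation profile, tumor geometry at baseline and mechanistic
#' parameter overrides.  The default tumor is two clones sharing the
#' patient's EGFR variant: a gefitinib-sensitive major clone and a
#' T790M-carrying resistant subclone holding the fraction `f_res` of
#' baseline cells.  Richer clone structures (up to 16 clones) can be
#' given explicitly via `clones`.
#'
#' @param id patient identifier.
#' @param sex `"male"` or `"female"`.
#' @param age years.
#' @param smoking `"never"`, `"former"` or `"current"`.
#' @param ethnicity `"asian"` or `"non_asian"`.
#' @param stage `"IIIb"` or `"IV"`.
#' @param egfr_variant EGFR variant shared by all default clones.
#' @param kras,pik3ca patient-level co-mutation flags (applied to every
#'   default clone).
#' @param m_prolif implicit-mutation proliferation offset (all clones).
#' @param r0 initial tumor radius, cm (> 0).
#' @param prolif_frac0 initial proliferative fraction of viable cells.
#' @param f_res initial cell fraction of the resistant subclone, in
#'   `[0, 1)`.
#' @param clones optional list of `list(profile = mutation_profile,
#'   fraction = x)` entries overriding the default two-clone structure;
#'   fractions must sum to 1.
#' @param growth_overrides,pk_overrides,pd_overrides,signaling_overrides
#'   named lists of parameter overrides applied on top of the
#'   configuration defaults at simulation time.
#' @return object of class `virtual_patient`.
#' @export
virtual_patient <- function(id = "vp1",
                            sex = c("female", "male"),
                            age = 63,
                            smoking = c("never", "former", "current"),
                            ethnicity = c("asian", "non_asian"),
                            stage = c("IV", "IIIb"),
                            egfr_variant = c("exon19del", "L858R"),
                            kras = FALSE, pik3ca = FALSE, m_prolif = 0,
                            r0 = 1.5, prolif_frac0 = 0.6, f_res = 0.006,
                            clones = NULL,
                            growth_overrides = list(),
                            pk_overrides = list(),
                            pd_overrides = list(),
                            signaling_overrides = list()) {
  sex <- match.arg(sex); smoking <- match.arg(smoking)
  ethnicity <- match.arg(ethnicity); stage <- match.arg(stage)
  egfr_variant <- match.arg(egfr_variant)
  if (!is.numeric(r0) || r0 <= 0) stop("'r0' must be > 0", call. = FALSE)
  if (!is.numeric(f_res) || f_res < 0 || f_res >= 1) {
    stop("'f_res' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(prolif_frac0) || prolif_frac0 < 0 || prolif_frac0 > 1) {
    stop("'prolif_frac0' must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(clones)) {
    clones <- list(
      list(profile = mutation_profile(egfr_variant, t790m = FALSE,
                                      kras = kras, pik3ca = pik3ca,
                                      m_prolif = m_prolif),
           fraction = 1 - f_res),
      list(profile = mutation_profile(egfr_variant, t790m = TRUE,
                                      kras = kras, pik3ca = pik3ca,
                                      m_prolif = m_prolif),
           fraction = f_res))
  } else {
    fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
    if (abs(sum(fr) - 1) > 1e-9) stop("clone fractions must sum to 1", call. = FALSE)
    if (length(clones) < 2L || length(clones) > 16L) {
      stop("clone count must lie in [2, 16]", call. = FALSE)
    }
  }
  structure(list(id = id, sex = sex, age = age, smoking = smoking,
                 ethnicity = ethnicity, stage = stage,
                 egfr_variant = egfr_variant, kras = isTRUE(kras),
                 pik3ca = isTRUE(pik3ca), m_prolif = m_prolif,
                 r0 = r0, prolif_frac0 = prolif_frac0, f_res = f_res,
                 clones = clones,
                 growth_overrides = growth_overrides,
                 pk_overrides = pk_overrides,
                 pd_overrides = pd_overrides,
                 signaling_overrides = signaling_overrides),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf(paste0("<virtual_patient> %s: %s, %.0f y, %s smoker, %s, ",
                     "stage %s\n  EGFR %s%s, r0 = %.2f cm, f_res = %.3g, ",
                     "%d clones\n"),
              x$id, x$sex, x$age, x$smoking, x$ethnicity, x$stage,
              x$egfr_variant,
              if (x$kras) " + KRAS" else "", x$r0, x$f_res, length(x$clones)))
  invisible(x)
}

#' Build initial clone states for a virtual patient
#'
#' Splits the baseline spherical tumor volume `(4/3) * pi * r0^3` over
#' the patient's clones according to their fractions.  Each clone starts
#' with proliferating fraction `prolif_frac0` of its viable cells, no
#' dead cells, a carrying capacity proportional to its initial size and
#' immune pressure at its recruitment/decay equilibrium for the baseline
#' burden.
#'
#' @param patient a [virtual_patient()].
#' @param gp [growth_params()] (used for cell volume, immune equilibrium
#'   and the carrying-capacity cap).
#' @param k_cap0 initial carrying capacity of each clone as a multiple
#'   of the clone's own initial viable cells (default 2): a
#'   treatment-naive clone sits below but near its angiogenic capacity,
#'   and further expansion is gated by neo-angiogenesis (`alpha_ang`).
#' @return list with `states` (matrix n_clones x 5, columns P, Q, D, K,
#'   I), `profiles` (list of [mutation_profile()]) and `fractions`.
#' @export
build_clones <- function(patient, gp = growth_params(), k_cap0 = 2) {
  stopifnot(inherits(patient, "virtual_patient"))
  V0 <- 4 / 3 * pi * patient$r0^3
  N0 <- V0 / gp$v_cell
  fr <- vapply(patient$clones, function(cl) cl$fraction, numeric(1))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("clone fractions must be non-negative and sum to 1", call. = FALSE)
  }
  pf <- patient$prolif_frac0
  I_eq <- gp$rho_imm * N0 / (gp$h_imm + N0) / max(gp$d_imm, 1e-12)
  n <- length(fr)
  states <- matrix(0, nrow = n, ncol = 5,
                   dimnames = list(NULL, c("P", "Q", "D", "K", "I")))
  states[, "P"] <- fr * N0 * pf
  states[, "Q"] <- fr * N0 * (1 - pf)
  states[, "K"] <- pmin(pmax(k_cap0 * fr * N0, 1), gp$K_max)
  states[, "I"] <- I_eq
  list(states = states,
       profiles = lapply(patient$clones, function(cl) cl$profile),
       fractions = fr)
}
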