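# Standard-state and solvent-cage corrections applied to tabulated barriers.
#
# Gas-phase free energies refer to a 1 atm standard state; solution kinetics
# use 1 M. For a bimolecular step the conversion lowers the barrier by
# RT ln(V_M). A second term accounts for the reduced entropy loss when the
# encounter pair is assembled inside a solvent cage. Omitting both
# underestimates a bimolecular rate constant by a factor V_M * 200 / e
# (about 1800 at 298.15 K).

#' Standard-state correction (1 atm to 1 M)
#'
#' For a process that converts `molecularity` moles of reactants into one
#' transition state, the barrier changes by -(molecularity - 1) RT ln(V_M),
#' where V_M is the 1 atm ideal-gas molar volume in L mol^-1. Unimolecular
#' steps are unaffected.
#'
#' @param molecularity 1 or 2.
#' @param temperature Temperature in K.
#' @param molar_volume_L Molar volume in L mol^-1; defaults to RT/P at
#'   (temperature, 1 atm), 24.465 at 298.15 K.
#' @return Correction in kcal mol^-1 (<= 0): -1.894 for a bimolecular step
#'   at 298.15 K.
#' @export
standard_state_correction <- function(molecularity, temperature = 298.15,
                                      molar_volume_L = NULL) {
  if (!all(molecularity %in% c(1L, 2L))) {
    stop("molecularity must be 1 or 2")
  }
  if (is.null(molar_volume_L)) molar_volume_L <- molar_volume(temperature)
  -(molecularity - 1) * rt_kcal(temperature) * log(molar_volume_L)
}

#' Solvent-cage correction
#'
#' Free-energy correction for assembling n reactant moles into one caged
#' encounter complex: -RT [ln(n * 10^(2(n-1))) - (n - 1)]. Zero for n = 1;
#' -RT (ln 200 - 1) = -2.547 kcal mol^-1 for n = 2 at 298.15 K.
#'
#' @param n_reactants Number of reactant moles (>= 1).
#' @param temperature Temperature in K.
#' @return Correction in kcal mol^-1 (<= 0).
#' @export
cage_correction <- function(n_reactants, temperature = 298.15) {
  if (!all(n_reactants >= 1)) stop("n_reactants must be >= 1")
  n <- n_reactants
  -rt_kcal(temperature) * (log(n * 10^(2 * (n - 1))) - (n - 1))
}

#' Apply solution-phase corrections to tabulated activation energies
#'
#' Adds the standard-state and cage terms to uncorrected barriers. A
#' corrected barrier below zero is clamped to zero (the TST prefactor is the
#' physical ceiling; diffusion capping handles the rest) and flagged.
#'
#' @param dG_act_kcal Uncorrected activation free energies, kcal mol^-1.
#' @param molecularity Integer vector, 1 or 2 (recycled).
#' @param temperature Temperature(s) in K (recycled).
#' @param molar_volume_L Optional molar volume override, L mol^-1.
#' @param options Correction toggles from [rate_options()].
#' @return data.frame with columns `dG_standard_state`, `dG_cage`,
#'   `dG_total`, `dG_act_corrected`, `clamped`.
#' @examples
#' corrected_barrier(11.2)  # 6.759 kcal/mol after both corrections
#' @export
corrected_barrier <- function(dG_act_kcal, molecularity = 2L,
                              temperature = 298.15, molar_volume_L = NULL,
                              options = rate_options()) {
  if (any(is.na(dG_act_kcal))) {
    stop("dG_act_kcal is required (supply a Marcus barrier for SET upstream)")
  }
  n <- max(length(dG_act_kcal), length(molecularity), length(temperature))
  dG_act_kcal <- rep_len(dG_act_kcal, n)
  molecularity <- rep_len(molecularity, n)
  temperature <- rep_len(temperature, n)
  ss <- if (options$apply_standard_state) {
    standard_state_correction(molecularity, temperature, molar_volume_L)
  } else rep(0, n)
  cage <- if (options$apply_cage) {
    ifelse(molecularity > 1, cage_correction(molecularity, temperature), 0)
  } else rep(0, n)
  raw <- dG_act_kcal + ss + cage
  clamped <- options$clamp_negative_barriers & raw < 0
  data.frame(
    dG_standard_state = ss,
    dG_cage = cage,
    dG_total = ss + cage,
    dG_act_corrected = ifelse(clamped, 0, raw),
    clamped = clamped
  )
}

#' Rate-enhancement factor implied by the solution-phase corrections
#'
#' The multiplicative factor by which a bimolecular rate constant would be
#' underestimated if both corrections were skipped:
#' exp(-dG_total / RT) = V_M * 200 / e, about 1800 at 298.15 K.
#'
#' @param temperature Temperature in K.
#' @param molar_volume_L Optional molar volume override, L mol^-1.
#' @return Dimensionless fold factor.
#' @export
correction_rate_factor <- function(temperature = 298.15,
                                   molar_volume_L = NULL) {
  total <- standard_state_correction(2L, temperature, molar_volume_L) +
    cage_correction(2L, temperature)
  exp(-total / rt_kcal(temperature))
}
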