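# Full per-channel chain: barrier (tabulated or Marcus), solution-phase
# corrections, tunneling, TST, diffusion capping.

#' Pipeline options
#'
#' Defaults follow standard QM-ORSA practice: both corrections on,
#' negative corrected barriers clamped to zero, path degeneracy applied to
#' the thermal rate before Collins-Kimball coupling, kappa = 1 unless an
#' imaginary frequency is supplied, and direct-oxidation channels excluded
#' from branching ratios and overall sums.
#'
#' @param apply_standard_state Apply the 1 atm -> 1 M correction.
#' @param apply_cage Apply the solvent-cage correction.
#' @param clamp_negative_barriers Clamp negative corrected barriers to zero.
#' @param sigma_convention Where path degeneracy enters: `"thermal"`
#'   multiplies the thermal rate before diffusion coupling (each symmetric
#'   site is an independent reactive funnel sharing one encounter pair);
#'   `"post"` multiplies the coupled apparent rate.
#' @param diffusion_threshold A channel is flagged diffusion-controlled when
#'   k_thermal >= threshold * k_D.
#' @param include_ox Include direct chalcogen oxidation in branching ratios
#'   and overall sums.
#' @param reaction_distances Optional data.frame of encounter-distance
#'   overrides with columns `antioxidant`, `radical`, `mechanism`, `medium`,
#'   `reaction_distance` (m).
#' @param kappa_map Optional data.frame injecting imaginary frequencies per
#'   channel: columns `antioxidant`, `radical`, `mechanism`, `site`,
#'   `medium`, `imag_freq_cm`.
#' @param marcus_hints Optional data.frame of Marcus-region hints for
#'   reorganization-energy inference: columns `antioxidant`, `radical`,
#'   `medium`, `region`.
#' @return A list of class `qm_options`.
#' @export
rate_options <- function(apply_standard_state = TRUE, apply_cage = TRUE,
                         clamp_negative_barriers = TRUE,
                         sigma_convention = c("thermal", "post"),
                         diffusion_threshold = 1.0, include_ox = FALSE,
                         reaction_distances = NULL, kappa_map = NULL,
                         marcus_hints = NULL) {
  structure(list(
    apply_standard_state = isTRUE(apply_standard_state),
    apply_cage = isTRUE(apply_cage),
    clamp_negative_barriers = isTRUE(clamp_negative_barriers),
    sigma_convention = match.arg(sigma_convention),
    diffusion_threshold = diffusion_threshold,
    include_ox = isTRUE(include_ox),
    reaction_distances = reaction_distances,
    kappa_map = kappa_map,
    marcus_hints = marcus_hints
  ), class = "qm_options")
}

.lookup_override <- function(df, keys, value_col) {
  if (is.null(df) || nrow(df) == 0) return(NA_real_)
  hit <- rep(TRUE, nrow(df))
  for (k in names(keys)) {
    if (k %in% names(df)) hit <- hit & df[[k]] == keys[[k]]
  }
  if (!any(hit)) return(NA_real_)
  df[[value_col]][which(hit)[1]]
}

.pick_lambda <- function(dG_rxn, dG_act, hint = NA_character_) {
  roots <- infer_lambda(dG_rxn, dG_act)
  if (nrow(roots) == 0) return(list(lambda = NA_real_, region = NA_character_))
  if (!is.na(hint) && hint %in% roots$region) {
    i <- which(roots$region == hint)[1]
  } else {
    # ambiguous without a hint: both roots reproduce the same barrier, so
    # default to the normal-region branch (the larger root)
    i <- if ("normal" %in% roots$region) {
      which(roots$region == "normal")[1]
    } else 1L
  }
  list(lambda = roots$lambda[i], region = roots$region[i])
}

#' Compute per-channel rate constants
#'
#' Runs the full chain for every channel: Marcus barrier for SET channels
#' that carry a reorganization energy instead of a tabulated barrier,
#' standard-state and cage corrections, Wigner tunneling, the Eyring
#' thermal rate, the Smoluchowski diffusion rate from the species' Stokes
#' radii, and Collins-Kimball coupling. Channels without an activation
#' energy (e.g. thermodynamic-screening rows) get NA rates and a note.
#'
#' @param channels Channel table (see [reaction_channel()]).
#' @param media Named list of [medium_spec()] objects keyed by medium label.
#' @param species Named list of [species_spec()] objects keyed by name.
#' @param options Pipeline options from [rate_options()].
#' @return The channel table augmented with `lambda_used`, `marcus_region`,
#'   `dG_act_corrected`, `clamped`, `kappa`, `k_thermal` (degeneracy-weighted
#'   under the default sigma convention), `k_D`, `k_app`,
#'   `diffusion_limited`, `note`.
#' @export
channel_rates <- function(channels, media, species,
                          options = rate_options()) {
  viol <- validate_channels(channels)
  if (any(viol$severity == "error")) {
    stop("invalid channel table: ",
         paste(unique(viol$rule[viol$severity == "error"]), collapse = "; "))
  }
  n <- nrow(channels)
  out <- channels
  out$lambda_used <- NA_real_
  out$marcus_region <- NA_character_
  out$dG_act_corrected <- NA_real_
  out$clamped <- NA
  out$kappa <- NA_real_
  out$k_thermal <- NA_real_
  out$k_D <- NA_real_
  out$k_app <- NA_real_
  out$diffusion_limited <- NA
  out$note <- ""

  for (i in seq_len(n)) {
    ch <- channels[i, ]
    med <- media[[ch$medium]]
    if (is.null(med)) stop("unknown medium: ", ch$medium)
    temp <- med$temperature

    dg_act <- ch$dG_act_kcal
    if (ch$mechanism == "SET") {
      if (!is.na(ch$lambda_kcal)) {
        mb <- marcus_barrier(ch$dG_rxn_kcal, ch$lambda_kcal)
        if (is.na(dg_act)) dg_act <- mb$dG_act
        out$lambda_used[i] <- ch$lambda_kcal
        out$marcus_region[i] <- mb$region
      } else if (!is.na(dg_act) && !is.na(ch$dG_rxn_kcal)) {
        hint <- .lookup_override(
          options$marcus_hints,
          list(antioxidant = ch$antioxidant, radical = ch$radical,
               medium = ch$medium), "region")
        pick <- .pick_lambda(ch$dG_rxn_kcal, max(dg_act, 0), hint)
        out$lambda_used[i] <- pick$lambda
        out$marcus_region[i] <- pick$region
      }
    }
    if (is.na(dg_act)) {
      out$note[i] <- "no activation energy; channel not rated"
      next
    }

    freq <- .lookup_override(
      options$kappa_map,
      list(antioxidant = ch$antioxidant, radical = ch$radical,
           mechanism = ch$mechanism, site = ch$site, medium = ch$medium),
      "imag_freq_cm")
    if (is.na(freq)) freq <- ch$imag_freq_cm
    kap <- wigner_kappa(freq, temp)
    out$kappa[i] <- kap

    corr <- corrected_barrier(dg_act, ch$molecularity, temp,
                              med$molar_volume_L, options)
    out$dG_act_corrected[i] <- corr$dG_act_corrected
    out$clamped[i] <- corr$clamped
    if (corr$dG_act_corrected < 0) {
      out$note[i] <- "negative corrected barrier kept (clamping disabled)"
    }

    k_path <- eyring_rate(max(corr$dG_act_corrected, 0), kap, temp) *
      exp(-min(corr$dG_act_corrected, 0) / rt_kcal(temp))
    sig <- ch$sigma
    k_th <- if (options$sigma_convention == "thermal") sig * k_path else k_path

    r_a <- species[[ch$radical]]$stokes_radius
    r_b <- species[[ch$antioxidant]]$stokes_radius
    if (ch$molecularity == 2L && !is.na(r_a) && !is.na(r_b)) {
      r_ab <- .lookup_override(
        options$reaction_distances,
        list(antioxidant = ch$antioxidant, radical = ch$radical,
             mechanism = ch$mechanism, medium = ch$medium),
        "reaction_distance")
      if (is.na(r_ab)) r_ab <- r_a + r_b
      k_d <- diffusion_rate(r_a, r_b, med$viscosity, temp, r_ab)
      k_app <- collins_kimball(k_th, k_d)
      out$k_D[i] <- k_d
      out$diffusion_limited[i] <- k_th >= options$diffusion_threshold * k_d
    } else {
      k_app <- k_th
      out$diffusion_limited[i] <- FALSE
      if (ch$molecularity == 2L) {
        out$note[i] <- "no Stokes radii; rate not diffusion-capped"
      }
    }
    if (options$sigma_convention == "post") k_app <- sig * k_app
    out$k_thermal[i] <- k_th
    out$k_app[i] <- k_app
  }
  out
}
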