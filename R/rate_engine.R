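# Per-channel rate physics: Eyring-Polanyi TST with Wigner tunneling,
# Marcus electron-transfer barriers, Smoluchowski/Stokes-Einstein diffusion
# rates, and Collins-Kimball coupling.

#' Wigner tunneling transmission coefficient
#'
#' kappa = 1 + (1/24) (h c nu / kB T)^2 from the magnitude of the
#' transition-state imaginary frequency. Absent or zero frequency means no
#' tunneling correction (kappa = 1).
#'
#' @param imag_freq_cm Imaginary-frequency magnitude in cm^-1 (>= 0 or NA).
#' @param temperature Temperature in K.
#' @return Dimensionless kappa >= 1.
#' @examples
#' wigner_kappa(2000)  # ~4.88 at 298.15 K
#' @export
wigner_kappa <- function(imag_freq_cm, temperature = 298.15) {
  nu <- ifelse(is.na(imag_freq_cm), 0, imag_freq_cm)
  if (any(nu < 0)) stop("imag_freq_cm must be a non-negative magnitude")
  hc_kB <- physical_constants()$hc_over_kB
  1 + (hc_kB * nu / temperature)^2 / 24
}

#' Eyring-Polanyi thermal rate constant
#'
#' k = kappa (kB T / h) exp(-dG_act / RT). For bimolecular channels under
#' the 1 M standard state the numeric value is in M^-1 s^-1 (s^-1 for
#' unimolecular).
#'
#' @param dG_act_corrected Corrected activation free energy, kcal mol^-1
#'   (>= 0).
#' @param kappa Transmission coefficient (>= 1).
#' @param temperature Temperature in K.
#' @return Thermal rate constant.
#' @examples
#' eyring_rate(0)          # prefactor only, 6.212e12
#' eyring_rate(6.759)      # ~6.9e7
#' @export
eyring_rate <- function(dG_act_corrected, kappa = 1, temperature = 298.15) {
  if (any(dG_act_corrected < 0)) {
    stop("dG_act_corrected must be >= 0 (clamp upstream)")
  }
  if (any(kappa < 1)) stop("kappa must be >= 1")
  const <- physical_constants()
  kappa * const$kB * temperature / const$h *
    exp(-dG_act_corrected / rt_kcal(temperature))
}

#' Marcus electron-transfer barrier
#'
#' dG_act = (lambda / 4) (1 + dG_rxn / lambda)^2. The reaction sits in the
#' inverted region when it is exergonic beyond the reorganization energy
#' (dG_rxn < 0 and |dG_rxn| > lambda); the activationless boundary
#' |dG_rxn| = lambda is classified normal.
#'
#' @param dG_rxn_kcal Reaction free energy, kcal mol^-1.
#' @param lambda_kcal Reorganization energy, kcal mol^-1 (> 0).
#' @return data.frame with columns `dG_act` (kcal mol^-1) and `region`
#'   ("normal" or "inverted").
#' @examples
#' marcus_barrier(-13.0, 10.911)  # ~0.1 kcal/mol, inverted
#' @export
marcus_barrier <- function(dG_rxn_kcal, lambda_kcal) {
  if (any(is.na(lambda_kcal)) || any(lambda_kcal <= 0)) {
    stop("lambda_kcal must be positive")
  }
  dG_act <- lambda_kcal / 4 * (1 + dG_rxn_kcal / lambda_kcal)^2
  region <- ifelse(dG_rxn_kcal < 0 & abs(dG_rxn_kcal) > lambda_kcal,
                   "inverted", "normal")
  data.frame(dG_act = dG_act, region = region, stringsAsFactors = FALSE)
}

#' Invert the Marcus relation for the reorganization energy
#'
#' Solves (lambda / 4)(1 + dG_rxn / lambda)^2 = dG_act for lambda, i.e. the
#' quadratic lambda^2 + (2 dG_rxn - 4 dG_act) lambda + dG_rxn^2 = 0. Zero,
#' one or two positive real roots exist; each is labeled with its Marcus
#' region. Needed because published work states the region per reaction but
#' rarely prints lambda.
#'
#' @param dG_rxn_kcal Reaction free energy, kcal mol^-1 (scalar).
#' @param dG_act_kcal Marcus activation free energy, kcal mol^-1 (>= 0,
#'   scalar).
#' @return data.frame with columns `lambda` and `region`, zero rows when no
#'   admissible root exists.
#' @examples
#' infer_lambda(-13.0, 0.1)  # roots ~15.49 (normal) and ~10.91 (inverted)
#' @export
infer_lambda <- function(dG_rxn_kcal, dG_act_kcal) {
  stopifnot(length(dG_rxn_kcal) == 1, length(dG_act_kcal) == 1)
  if (is.na(dG_act_kcal) || dG_act_kcal < 0) stop("dG_act_kcal must be >= 0")
  g <- dG_rxn_kcal
  a <- dG_act_kcal
  disc <- (2 * g - 4 * a)^2 - 4 * g^2   # = 16 a (a - g)
  empty <- data.frame(lambda = numeric(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (disc < 0) return(empty)
  # numerically stable quadratic roots: the large root has no cancellation,
  # the small one follows from the product of roots (= g^2)
  p <- 4 * a - 2 * g
  big <- (p + sqrt(disc)) / 2
  roots <- if (big > 0) unique(c(big, g^2 / big)) else numeric(0)
  roots <- roots[roots > 0]
  if (length(roots) == 0) return(empty)
  out <- marcus_barrier(g, roots)
  data.frame(lambda = roots, region = out$region, stringsAsFactors = FALSE)
}

#' Smoluchowski diffusion-limited rate constant
#'
#' Steady-state encounter rate k_D = 4 pi R_AB D_AB N_A with mutual
#' diffusion coefficient D_AB = D_A + D_B from Stokes-Einstein
#' D = kB T / (6 pi eta a). Computed in SI and converted to M^-1 s^-1.
#'
#' @param radius_A,radius_B Stokes radii in m (> 0).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#' @param temperature Temperature in K.
#' @param reaction_distance Encounter distance R_AB in m; defaults to the
#'   contact distance radius_A + radius_B. Effective distances from
#'   transition-state geometries may be shorter than contact.
#' @return k_D in M^-1 s^-1.
#' @examples
#' diffusion_rate(2e-10, 2e-10, viscosity = 8.91e-4)  # ~7.42e9, radius-free
#' @export
diffusion_rate <- function(radius_A, radius_B, viscosity,
                           temperature = 298.15,
                           reaction_distance = radius_A + radius_B) {
  if (any(radius_A <= 0) || any(radius_B <= 0) || any(viscosity <= 0) ||
      any(reaction_distance <= 0)) {
    stop("radii, viscosity and reaction_distance must be positive")
  }
  const <- physical_constants()
  d_a <- const$kB * temperature / (6 * pi * viscosity * radius_A)
  d_b <- const$kB * temperature / (6 * pi * viscosity * radius_B)
  4 * pi * reaction_distance * (d_a + d_b) * const$N_A * 1000
}

#' Collins-Kimball coupling of thermal and diffusion rates
#'
#' k_app = k_D k / (k_D + k): the harmonic-mean interpolation between the
#' activation-controlled (k << k_D) and diffusion-controlled (k >> k_D)
#' regimes.
#'
#' @param k_thermal Thermal (TST) rate constant, M^-1 s^-1 (> 0).
#' @param k_D Diffusion rate constant, M^-1 s^-1 (> 0).
#' @return Apparent rate constant k_app <= min(k_thermal, k_D).
#' @export
collins_kimball <- function(k_thermal, k_D) {
  if (any(k_thermal <= 0) || any(k_D <= 0)) {
    stop("k_thermal and k_D must be positive")
  }
  k_D * k_thermal / (k_D + k_thermal)
}
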