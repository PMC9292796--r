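# Seeded generator of random channel tables with the statistical structure
# of the curated dataset, plus a brute-force single-expression oracle that
# provides stored ground-truth rates for property testing.

#' Default free-energy ranges for the synthetic generator
#'
#' Uniform-draw ranges (kcal mol^-1) per mechanism and polarity class,
#' spanning the values observed in the curated dataset: e.g. aqueous SET
#' barriers in [0, 15], lipid SET in [40, 66]; amino-site hydrogen transfer
#' exergonic, aromatic-site transfer endergonic for peroxyl radicals.
#'
#' @return Nested list: `dG_act[[mechanism]][[polarity]]`,
#'   `dG_rxn[[...]]` and special entries for the amino/aromatic split.
#' @export
synthetic_ranges <- function() {
  list(
    dG_act = list(
      HAT = list(aqueous = c(0, 1), lipid = c(6, 20)),
      RAF = list(aqueous = c(4, 29), lipid = c(8, 32)),
      SET = list(aqueous = c(0, 15), lipid = c(40, 66)),
      OX  = list(aqueous = c(12, 35), lipid = c(20, 43))
    ),
    dG_rxn = list(
      HAT_amino = list(aqueous = c(-40, -2), lipid = c(-38, -0.4)),
      HAT_aromatic_HO = list(aqueous = c(-10, -5), lipid = c(-8, -5)),
      HAT_aromatic_peroxyl = list(aqueous = c(22, 27), lipid = c(24, 29)),
      RAF = list(aqueous = c(-14, 20), lipid = c(-13, 23)),
      SET = list(aqueous = c(-17, 14), lipid = c(28, 55)),
      OX  = list(aqueous = c(-26, -7), lipid = c(-13, 0))
    ),
    imag_freq = c(500, 3500)
  )
}

#' Specification for a synthetic channel table
#'
#' A single integer seed fully determines the generated dataset; no global
#' random state leaks (the RNG state is saved and restored).
#'
#' @param seed Integer seed.
#' @param n_antioxidants Number of synthetic antioxidants.
#' @param radicals Radical labels; names containing "OO" are treated as
#'   peroxyl-like for the endergonic aromatic-site structure, the first
#'   label as the small reactive radical.
#' @param mechanisms Subset of HAT, RAF, SET, OX.
#' @param ranges Free-energy ranges as in [synthetic_ranges()].
#' @param set_polar_only Generate SET channels only in the aqueous medium
#'   (the structure observed in polar/apolar free-energy data); the lipid
#'   range is used when this is FALSE.
#' @return A list of class `qm_generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_antioxidants = 3L,
                           radicals = c("HO", "HOO", "CH3OO"),
                           mechanisms = c("HAT", "RAF", "SET"),
                           ranges = synthetic_ranges(),
                           set_polar_only = FALSE) {
  stopifnot(length(mechanisms) > 0, all(mechanisms %in% .mechanisms),
            n_antioxidants >= 1)
  for (m in names(ranges$dG_act)) {
    for (p in names(ranges$dG_act[[m]])) {
      r <- ranges$dG_act[[m]][[p]]
      stopifnot(is.finite(r), r[1] <= r[2])
    }
  }
  structure(list(seed = as.integer(seed),
                 n_antioxidants = as.integer(n_antioxidants),
                 radicals = radicals, mechanisms = mechanisms,
                 ranges = ranges, set_polar_only = isTRUE(set_polar_only)),
            class = "qm_generator_spec")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Brute-force single-expression apparent rate constant
#'
#' The full per-channel chain written as one closed-form expression with no
#' intermediate pipeline types: corrections, clamp, Wigner factor, Eyring
#' rate, degeneracy, Stokes-Einstein/Smoluchowski diffusion and
#' Collins-Kimball coupling. Serves as the independent ground truth the
#' staged implementation is tested against.
#'
#' @param dG_act_kcal Uncorrected activation free energy, kcal mol^-1.
#' @param sigma Path degeneracy.
#' @param molecularity 1 or 2.
#' @param imag_freq_cm Imaginary-frequency magnitude (NA = no tunneling).
#' @param temperature K.
#' @param viscosity Pa s.
#' @param radius_A,radius_B Stokes radii, m.
#' @param reaction_distance Encounter distance, m.
#' @return Apparent rate constant, M^-1 s^-1.
#' @export
oracle_rate <- function(dG_act_kcal, sigma = 1, molecularity = 2,
                        imag_freq_cm = NA_real_, temperature = 298.15,
                        viscosity = 8.91e-4, radius_A = 2.2e-10,
                        radius_B = 3.6e-10,
                        reaction_distance = radius_A + radius_B) {
  (4 * pi * reaction_distance *
     (1.380649e-23 * temperature / (6 * pi * viscosity * radius_A) +
        1.380649e-23 * temperature / (6 * pi * viscosity * radius_B)) *
     6.02214076e23 * 1000) *
    (sigma * (1 + (1.43877 * ifelse(is.na(imag_freq_cm), 0, imag_freq_cm) /
                     temperature)^2 / 24) *
       1.380649e-23 * temperature / 6.62607015e-34 *
       exp(-pmax(dG_act_kcal + (molecularity - 1) *
                   (-(8.31446261815324 / 4184) * temperature *
                      log(8.31446261815324 * temperature / 101325 * 1000) -
                      (8.31446261815324 / 4184) * temperature *
                        (log(200) - 1)), 0) /
             ((8.31446261815324 / 4184) * temperature))) /
    ((4 * pi * reaction_distance *
        (1.380649e-23 * temperature / (6 * pi * viscosity * radius_A) +
           1.380649e-23 * temperature / (6 * pi * viscosity * radius_B)) *
        6.02214076e23 * 1000) +
       (sigma * (1 + (1.43877 * ifelse(is.na(imag_freq_cm), 0,
                                       imag_freq_cm) /
                        temperature)^2 / 24) *
          1.380649e-23 * temperature / 6.62607015e-34 *
          exp(-pmax(dG_act_kcal + (molecularity - 1) *
                      (-(8.31446261815324 / 4184) * temperature *
                         log(8.31446261815324 * temperature / 101325 *
                               1000) -
                         (8.31446261815324 / 4184) * temperature *
                           (log(200) - 1)), 0) /
                ((8.31446261815324 / 4184) * temperature))))
}

#' Generate a synthetic channel dataset with stored ground truth
#'
#' Draws channels uniformly within the spec's ranges while preserving the
#' structural features of the curated data: the amino site is exergonic for
#' hydrogen transfer, aromatic sites are endergonic for peroxyl radicals,
#' ring sites carry degeneracy 2, and every SET channel receives a
#' reorganization energy consistent with its drawn (dG_rxn, dG_act) pair
#' via [infer_lambda()]. Ground-truth apparent rates are computed with the
#' single-expression [oracle_rate()] and stored.
#'
#' @param spec A `qm_generator_spec`.
#' @return A list of class `qm_synthetic`: `channels`, `media`, `species`,
#'   `truth` (data.frame with `k_app_true`), `spec`.
#' @export
generate_channels <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "qm_generator_spec"))
  .with_seed(spec$seed, {
    media <- list(
      water = medium_spec("water", 298.15, 8.91e-4, "aqueous"),
      lipid = medium_spec("lipid", 298.15, 8.62e-4, "lipid")
    )
    antiox <- paste0("A", seq_len(spec$n_antioxidants))
    rad_radii <- setNames(
      runif(length(spec$radicals), 2.0e-10, 3.0e-10), spec$radicals)
    species <- c(
      setNames(lapply(antiox, function(a) {
        species_spec(a, "antioxidant", stokes_radius = 3.5e-10)
      }), antiox),
      setNames(lapply(spec$radicals, function(r) {
        species_spec(r, "radical", stokes_radius = rad_radii[[r]])
      }), spec$radicals)
    )
    rng <- spec$ranges
    draw <- function(r) runif(1, r[1], r[2])
    rows <- list()
    for (a in antiox) for (r in spec$radicals) {
      for (med in names(media)) for (mech in spec$mechanisms) {
        pol <- media[[med]]$polarity_class
        if (mech == "SET" && spec$set_polar_only && pol != "aqueous") next
        sites <- switch(mech,
          HAT = c("1", "2", "3", "4", "5"),
          RAF = c("2a", "2", "3", "4", "5", "5a"),
          "none")
        for (s in sites) {
          peroxyl <- grepl("OO", r)
          g <- if (mech == "HAT" && s == "1") {
            draw(rng$dG_rxn$HAT_amino[[pol]])
          } else if (mech == "HAT" && peroxyl) {
            draw(rng$dG_rxn$HAT_aromatic_peroxyl[[pol]])
          } else if (mech == "HAT") {
            draw(rng$dG_rxn$HAT_aromatic_HO[[pol]])
          } else draw(rng$dG_rxn[[mech]][[pol]])
          a_rng <- rng$dG_act[[mech]][[pol]]
          # a real Marcus reorganization energy requires dG_act >= dG_rxn
          if (mech == "SET") a_rng[1] <- min(max(a_rng[1], g), a_rng[2])
          dga <- draw(a_rng)
          freq <- if (mech == "HAT") draw(rng$imag_freq) else NA_real_
          lam <- NA_real_
          if (mech == "SET") {
            roots <- infer_lambda(g, dga)
            if (nrow(roots) > 0) lam <- roots$lambda[nrow(roots)]
          }
          rows[[length(rows) + 1]] <- reaction_channel(
            a, r, mech, s, med, dG_act_kcal = dga, dG_rxn_kcal = g,
            lambda_kcal = lam, imag_freq_cm = freq)
        }
      }
    }
    channels <- do.call(rbind, rows)
    truth <- vapply(seq_len(nrow(channels)), function(i) {
      ch <- channels[i, ]
      oracle_rate(ch$dG_act_kcal, ch$sigma, ch$molecularity,
                  ch$imag_freq_cm,
                  temperature = media[[ch$medium]]$temperature,
                  viscosity = media[[ch$medium]]$viscosity,
                  radius_A = species[[ch$radical]]$stokes_radius,
                  radius_B = species[[ch$antioxidant]]$stokes_radius)
    }, numeric(1))
    structure(list(channels = channels, media = media, species = species,
                   truth = data.frame(k_app_true = truth), spec = spec),
              class = "qm_synthetic")
  })
}

#' Perturb the free energies of a synthetic dataset
#'
#' Adds seeded uniform noise in +/- `magnitude` kcal mol^-1 to all
#' activation and reaction free energies, then recomputes the stored ground
#' truth. Used to verify the input-rounding error budget: a +/-0.05
#' kcal mol^-1 perturbation moves an activation-controlled rate by at most
#' a factor exp(0.05/RT) = 1.088.
#'
#' @param dataset A `qm_synthetic`.
#' @param magnitude Half-width of the uniform noise, kcal mol^-1 (>= 0).
#' @param seed Seed for the noise draw (default derived from the spec).
#' @return A perturbed `qm_synthetic`.
#' @export
perturb <- function(dataset, magnitude, seed = dataset$spec$seed + 1L) {
  stopifnot(inherits(dataset, "qm_synthetic"), magnitude >= 0)
  if (magnitude == 0) return(dataset)
  .with_seed(seed, {
    ch <- dataset$channels
    n <- nrow(ch)
    ch$dG_act_kcal <- ch$dG_act_kcal + runif(n, -magnitude, magnitude)
    ch$dG_act_kcal <- pmax(ch$dG_act_kcal, 0)
    ch$dG_rxn_kcal <- ch$dG_rxn_kcal + runif(n, -magnitude, magnitude)
    out <- dataset
    out$channels <- ch
    out$truth <- data.frame(k_app_true = vapply(seq_len(n), function(i) {
      row <- ch[i, ]
      oracle_rate(row$dG_act_kcal, row$sigma, row$molecularity,
                  row$imag_freq_cm,
                  temperature = dataset$media[[row$medium]]$temperature,
                  viscosity = dataset$media[[row$medium]]$viscosity,
                  radius_A = dataset$species[[row$radical]]$stokes_radius,
                  radius_B = dataset$species[[row$antioxidant]]$stokes_radius)
    }, numeric(1)))
    out
  })
}
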