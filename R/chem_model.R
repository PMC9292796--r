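# Domain containers: media, species, reaction channel tables.

#' Canonical channel-table column names
#'
#' The delimited channel-table format has one header row and exactly these
#' columns; empty cells encode absent optional values.
#' @return Character vector of the twelve canonical column names.
#' @export
channel_columns <- function() {
  c("antioxidant", "radical", "mechanism", "site", "medium",
    "dG_act_kcal", "dG_rxn_kcal", "lambda_kcal", "imag_freq_cm",
    "sigma", "molecularity", "ring_opening")
}

.mechanisms <- c("HAT", "RAF", "SET", "OX")
.known_sites <- c("1", "2", "2a", "3", "4", "5", "5a", "none")
.ring_sites <- c("2", "2a", "3", "4", "5", "5a")

#' Describe a solvent medium
#'
#' @param name Label, e.g. "water".
#' @param temperature Temperature in K (default 298.15).
#' @param viscosity Dynamic viscosity in Pa s.
#' @param polarity_class "aqueous" or "lipid"; gates single-electron-transfer
#'   feasibility in the synthetic generator and is carried through reports.
#' @param molar_volume_L Molar volume in L mol^-1 for the standard-state
#'   conversion; defaults to RT/P at (temperature, 1 atm).
#' @return A list of class `qm_medium`.
#' @export
medium_spec <- function(name, temperature = 298.15, viscosity,
                        polarity_class = c("aqueous", "lipid"),
                        molar_volume_L = NULL) {
  polarity_class <- match.arg(polarity_class)
  stopifnot(temperature > 0, viscosity > 0)
  if (is.null(molar_volume_L)) molar_volume_L <- molar_volume(temperature)
  structure(list(name = name, temperature = temperature,
                 viscosity = viscosity, polarity_class = polarity_class,
                 molar_volume_L = molar_volume_L),
            class = "qm_medium")
}

#' Describe a reacting species
#'
#' @param name Label, e.g. "PS" or "HO".
#' @param role "antioxidant" or "radical".
#' @param stokes_radius Hydrodynamic (Stokes) radius in m, used by the
#'   Stokes-Einstein diffusion coefficient. Optional; channels without radii
#'   on both partners cannot be diffusion-capped.
#' @param chalcogen Chalcogen center of an antioxidant: "S", "Se", "Te", or
#'   "none".
#' @return A list of class `qm_species`.
#' @export
species_spec <- function(name, role = c("antioxidant", "radical"),
                         stokes_radius = NA_real_,
                         chalcogen = c("none", "S", "Se", "Te")) {
  role <- match.arg(role)
  chalcogen <- match.arg(chalcogen)
  if (!is.na(stokes_radius) &&
      (stokes_radius <= 0.5e-10 || stokes_radius >= 20e-10)) {
    stop("stokes_radius must lie in (0.5, 20) Angstrom, expressed in m")
  }
  structure(list(name = name, role = role, stokes_radius = stokes_radius,
                 chalcogen = chalcogen),
            class = "qm_species")
}

#' Build a reaction-channel table
#'
#' One row per elementary scavenging channel. Missing optional values are
#' `NA`. Default path degeneracy follows the tricyclic scaffold symmetry:
#' ring sites (2, 2a, 3, 4, 5, 5a) come in symmetric pairs (sigma = 2),
#' the amino site 1 and site-free mechanisms are unique (sigma = 1).
#'
#' @param antioxidant,radical,mechanism,site,medium Character vectors.
#' @param dG_act_kcal Activation free energy, kcal mol^-1 (uncorrected;
#'   optional for SET when `lambda_kcal` is given).
#' @param dG_rxn_kcal Reaction free energy, kcal mol^-1.
#' @param lambda_kcal Marcus reorganization energy, kcal mol^-1 (SET only).
#' @param imag_freq_cm Magnitude of the transition-state imaginary frequency
#'   in cm^-1 (sign conventions vary upstream, so a magnitude is stored).
#' @param sigma Reaction path degeneracy (positive integer); `NA` picks the
#'   symmetry default for the site.
#' @param molecularity 1 or 2 (default 2).
#' @param ring_opening Logical; the adduct destroys the central ring
#'   (allowed only for RAF at site 5a).
#' @return A `data.frame` with the canonical channel columns.
#' @export
reaction_channel <- function(antioxidant, radical, mechanism, site = "none",
                             medium, dG_act_kcal = NA_real_,
                             dG_rxn_kcal = NA_real_, lambda_kcal = NA_real_,
                             imag_freq_cm = NA_real_, sigma = NA_integer_,
                             molecularity = 2L, ring_opening = FALSE) {
  n <- max(lengths(list(antioxidant, radical, mechanism, site, medium,
                        dG_act_kcal, dG_rxn_kcal)))
  df <- data.frame(
    antioxidant = rep_len(as.character(antioxidant), n),
    radical = rep_len(as.character(radical), n),
    mechanism = rep_len(as.character(mechanism), n),
    site = rep_len(as.character(site), n),
    medium = rep_len(as.character(medium), n),
    dG_act_kcal = rep_len(as.numeric(dG_act_kcal), n),
    dG_rxn_kcal = rep_len(as.numeric(dG_rxn_kcal), n),
    lambda_kcal = rep_len(as.numeric(lambda_kcal), n),
    imag_freq_cm = rep_len(as.numeric(imag_freq_cm), n),
    sigma = rep_len(as.integer(sigma), n),
    molecularity = rep_len(as.integer(molecularity), n),
    ring_opening = rep_len(as.logical(ring_opening), n),
    stringsAsFactors = FALSE
  )
  df$sigma <- ifelse(is.na(df$sigma), default_sigma(df$site), df$sigma)
  df
}

#' Symmetry-default path degeneracy for a site label
#'
#' @param site Character vector of site labels.
#' @return Integer degeneracies: 2 for the paired ring sites, 1 otherwise.
#' @export
default_sigma <- function(site) {
  ifelse(site %in% .ring_sites, 2L, 1L)
}

#' Validate a channel table
#'
#' Pure validation: returns a data.frame of violations (empty when the table
#' is well formed) instead of raising. Unknown site labels are reported as
#' warnings (`severity = "warning"`), not errors, so the engine generalizes
#' beyond the shipped scaffold.
#'
#' @param channels Channel table as from [reaction_channel()] or
#'   [read_channel_table()].
#' @return data.frame with columns `row`, `field`, `severity`, `rule`.
#' @examples
#' ch <- reaction_channel("PS", "HO", "HAT", "1", "water",
#'                        dG_act_kcal = 0, dG_rxn_kcal = -39.9)
#' validate_channels(ch)   # zero rows
#' @export
validate_channels <- function(channels) {
  stopifnot(is.data.frame(channels))
  missing_cols <- setdiff(channel_columns(), names(channels))
  if (length(missing_cols) > 0) {
    return(data.frame(row = NA_integer_, field = missing_cols,
                      severity = "error",
                      rule = "required column missing",
                      stringsAsFactors = FALSE))
  }
  v <- list()
  bad <- function(rows, field, rule, severity = "error") {
    if (length(rows) == 0) return(NULL)
    data.frame(row = rows, field = field, severity = severity, rule = rule,
               stringsAsFactors = FALSE)
  }
  idx <- seq_len(nrow(channels))
  v[[length(v) + 1]] <- bad(idx[!channels$mechanism %in% .mechanisms],
    "mechanism", "mechanism must be one of HAT, RAF, SET, OX")
  v[[length(v) + 1]] <- bad(idx[is.na(channels$sigma) | channels$sigma < 1],
    "sigma", "sigma must be a positive integer")
  v[[length(v) + 1]] <- bad(idx[!channels$molecularity %in% c(1L, 2L)],
    "molecularity", "molecularity must be 1 or 2")
  set <- channels$mechanism == "SET"
  v[[length(v) + 1]] <- bad(idx[set & channels$site != "none"],
    "site", "SET channels are site-free (site must be 'none')")
  v[[length(v) + 1]] <- bad(idx[set & !is.na(channels$imag_freq_cm)],
    "imag_freq_cm", "SET has no nuclear saddle point, no imaginary frequency")
  v[[length(v) + 1]] <- bad(
    idx[!is.na(channels$imag_freq_cm) & channels$imag_freq_cm < 0],
    "imag_freq_cm", "imaginary frequency is stored as a positive magnitude")
  v[[length(v) + 1]] <- bad(
    idx[!is.na(channels$lambda_kcal) & channels$lambda_kcal <= 0],
    "lambda_kcal", "reorganization energy must be positive")
  v[[length(v) + 1]] <- bad(
    idx[channels$ring_opening &
          !(channels$mechanism == "RAF" & channels$site == "5a")],
    "ring_opening", "ring opening is only possible for RAF at site 5a")
  v[[length(v) + 1]] <- bad(idx[!channels$site %in% .known_sites],
    "site", "site label outside the reference scaffold set", "warning")
  out <- do.call(rbind, v)
  if (is.null(out)) {
    out <- data.frame(row = integer(0), field = character(0),
                      severity = character(0), rule = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$row), , drop = FALSE]
}

#' Read a channel table from delimited text
#'
#' Comma-delimited with a "." decimal separator; scientific notation is
#' accepted. Empty cells become `NA`. Extra columns (e.g. provenance) are
#' preserved after the canonical twelve.
#'
#' @param path File path.
#' @return Channel table data.frame.
#' @export
read_channel_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(site = "character"))
  missing_cols <- setdiff(channel_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("channel table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("dG_act_kcal", "dG_rxn_kcal", "lambda_kcal", "imag_freq_cm")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$sigma <- as.integer(df$sigma)
  df$molecularity <- as.integer(df$molecularity)
  df$ring_opening <- as.logical(df$ring_opening)
  extra <- setdiff(names(df), channel_columns())
  df[, c(channel_columns(), extra), drop = FALSE]
}

#' Write a channel table as delimited text
#'
#' Writes exactly the canonical columns, `NA` as empty cells, full double
#' precision.
#'
#' @param channels Channel table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_table <- function(channels, path) {
  out <- channels[, channel_columns(), drop = FALSE]
  # shortest decimal representation that round-trips to the same double
  fmt_num <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) return("")
      s <- sprintf("%.15g", v)
      if (as.numeric(s) == v) s else sprintf("%.17g", v)
    }, character(1))
  }
  fmt_int <- function(x) ifelse(is.na(x), "", as.character(x))
  for (col in c("dG_act_kcal", "dG_rxn_kcal", "lambda_kcal", "imag_freq_cm")) {
    out[[col]] <- fmt_num(out[[col]])
  }
  out$sigma <- fmt_int(out$sigma)
  out$molecularity <- fmt_int(out$molecularity)
  out$ring_opening <- ifelse(out$ring_opening, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
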