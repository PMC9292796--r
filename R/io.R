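# Run configuration, end-to-end compute entry point, and report writers.
# The command-line wrapper in inst/cli/qmorsa.R is a thin shell over these.

#' Read a run configuration document
#'
#' YAML with `media:` and `species:` blocks (same fields as [medium_spec()]
#' and [species_spec()]) and optional `options:`, `marcus_region_hints:` and
#' `reaction_distances:` blocks.
#'
#' @param path YAML file path.
#' @return list with `media`, `species`, `options` (a `qm_options`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$media) || is.null(cfg$species)) {
    stop("run config must define media: and species: blocks")
  }
  opt_args <- cfg$options
  if (is.null(opt_args)) opt_args <- list()
  opt_args$marcus_hints <- .hints_from_config(cfg$marcus_region_hints)
  if (!is.null(cfg$reaction_distances)) {
    opt_args$reaction_distances <- do.call(rbind, lapply(
      cfg$reaction_distances, function(x) {
        data.frame(antioxidant = x$antioxidant, radical = x$radical,
                   mechanism = x$mechanism, medium = x$medium,
                   reaction_distance = as.numeric(x$reaction_distance),
                   stringsAsFactors = FALSE)
      }))
  }
  list(media = .media_from_config(cfg$media),
       species = .species_from_config(cfg$species),
       options = do.call(rate_options, opt_args))
}

#' Run the full pipeline on a channel table
#'
#' Validation errors abort with row/field diagnostics; every default
#' substituted for a missing optional quantity (Stokes radius, imaginary
#' frequency) is recorded in the per-channel `note` column. Identical
#' (input, config) pairs give byte-identical outputs.
#'
#' @param channels Channel table or path to one.
#' @param media,species Named lists as from [read_run_config()].
#' @param options Pipeline options.
#' @return list of class `qm_run` with `rates`, `report`, `violations`.
#' @export
run_compute <- function(channels, media, species,
                        options = rate_options()) {
  if (is.character(channels)) channels <- read_channel_table(channels)
  if (nrow(channels) == 0) stop("no channels in input")
  viol <- validate_channels(channels)
  if (any(viol$severity == "error")) {
    bad <- viol[viol$severity == "error", ]
    stop("channel validation failed:\n",
         paste(sprintf("  row %s, %s: %s", bad$row, bad$field, bad$rule),
               collapse = "\n"))
  }
  rates <- channel_rates(channels, media, species, options)
  structure(list(rates = rates,
                 report = scavenging_report(rates, options),
                 violations = viol),
            class = "qm_run")
}

#' @export
print.qm_run <- function(x, ...) {
  cat("Scavenging kinetics run:", nrow(x$rates), "channels,",
      nrow(x$report), "report rows\n")
  print(format_report(x$report))
  invisible(x)
}

#' Format a report for display
#'
#' Rates at 3 significant figures in the published style; branching ratios
#' as integer percentages. Machine output keeps full precision
#' ([write_report()] with `format = "structured"`).
#'
#' @param report Report data.frame from [scavenging_report()].
#' @param sig_figs Significant figures for rates.
#' @return data.frame of formatted strings.
#' @export
format_report <- function(report, sig_figs = 3) {
  data.frame(
    antioxidant = report$antioxidant, radical = report$radical,
    medium = report$medium, mechanism = report$mechanism,
    k_app = sprintf(paste0("%.", sig_figs - 1, "e"), report$k_app_sum),
    gamma = ifelse(is.na(report$gamma_int), "",
                   sprintf("%d%%", as.integer(report$gamma_int))),
    diffusion_limited = ifelse(report$diffusion_limited_any, "[a]", ""),
    stringsAsFactors = FALSE
  )
}

#' Write a report to disk
#'
#' @param report Report data.frame from [scavenging_report()].
#' @param path Output path.
#' @param format `"delimited"` writes the display table (3 significant
#'   figures); `"structured"` writes full-precision CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("delimited", "structured")) {
  format <- match.arg(format)
  out <- if (format == "delimited") format_report(report) else report
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
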