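# Mechanism-level sums, branching ratios, and overall scavenging activity.

#' Round half away from zero
#'
#' Reporting convention for integer branching-ratio percentages (86.5 -> 87,
#' not banker's rounding).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Sum apparent rate constants per mechanism
#'
#' Degeneracy-weighted site contributions are already folded into `k_app`
#' by [channel_rates()]; the mechanism total is their plain sum. Channels
#' without rates (no activation energy) are excluded.
#'
#' @param rates Output of [channel_rates()] for a single
#'   (antioxidant, radical, medium) context.
#' @param mechanism One of "HAT", "RAF", "SET", "OX".
#' @return One-row data.frame: `mechanism`, `k_app_sum` (M^-1 s^-1),
#'   `n_channels`, `diffusion_limited_any`.
#' @export
sum_mechanism <- function(rates, mechanism) {
  ctx <- unique(rates[, c("antioxidant", "radical", "medium")])
  if (nrow(ctx) > 1) {
    stop("channels from mixed (antioxidant, radical, medium) contexts")
  }
  sel <- rates[rates$mechanism == mechanism & !is.na(rates$k_app), ,
               drop = FALSE]
  data.frame(
    mechanism = mechanism,
    k_app_sum = sum(sel$k_app),
    n_channels = nrow(sel),
    diffusion_limited_any = any(sel$diffusion_limited %in% TRUE),
    stringsAsFactors = FALSE
  )
}

#' Branching ratios across mechanisms
#'
#' Gamma_i = 100 k_i / sum_j k_j, the percentage contribution of each
#' mechanism to the overall activity. Exact values are returned; reports
#' round them to integers with [round_half_away()].
#'
#' @param k_app_sums Numeric vector of mechanism-level apparent rate sums
#'   (at least one must be positive).
#' @return Percentages summing to exactly 100.
#' @examples
#' branching_ratios(c(HAT = 2.61e9, RAF = 6.94e10, SET = 8.53e9))
#' @export
branching_ratios <- function(k_app_sums) {
  if (any(k_app_sums < 0)) stop("rate sums must be non-negative")
  total <- sum(k_app_sums)
  if (total <= 0) stop("all mechanism sums are zero; no branching defined")
  100 * k_app_sums / total
}

#' Overall scavenging activity
#'
#' The global antioxidant activity for one (antioxidant, radical, medium)
#' context: the sum of the mechanism-level apparent rate constants.
#'
#' @param k_app_sums Numeric vector of mechanism-level sums.
#' @return Overall rate constant in M^-1 s^-1 (0 for an empty vector).
#' @export
overall_activity <- function(k_app_sums) {
  if (length(k_app_sums) == 0) return(0)
  sum(k_app_sums)
}

#' Mechanism summaries, branching ratios and overall rates for all contexts
#'
#' Aggregates per-channel rates into the row structure of a kinetics report:
#' one row per (antioxidant, radical, medium, mechanism) plus one "overall"
#' row per context. Direct-oxidation (OX) channels are computed and reported
#' but excluded from branching ratios and the overall sum unless
#' `options$include_ox` is set.
#'
#' @param rates Output of [channel_rates()] (any number of contexts).
#' @param options Pipeline options from [rate_options()].
#' @return data.frame with columns `antioxidant`, `radical`, `medium`,
#'   `mechanism` ("overall" rows included), `k_app_sum`, `gamma`
#'   (exact percent, NA for OX and overall), `gamma_int` (reporting
#'   rounding), `diffusion_limited_any`.
#' @export
scavenging_report <- function(rates, options = rate_options()) {
  ctxs <- unique(rates[, c("antioxidant", "radical", "medium")])
  rows <- list()
  for (j in seq_len(nrow(ctxs))) {
    ctx <- ctxs[j, ]
    sub <- rates[rates$antioxidant == ctx$antioxidant &
                   rates$radical == ctx$radical &
                   rates$medium == ctx$medium, , drop = FALSE]
    mechs <- intersect(.mechanisms, unique(sub$mechanism))
    summ <- do.call(rbind, lapply(mechs, function(m) sum_mechanism(sub, m)))
    in_total <- summ$mechanism != "OX" | options$include_ox
    gamma <- rep(NA_real_, nrow(summ))
    if (any(summ$k_app_sum[in_total] > 0)) {
      gamma[in_total] <- branching_ratios(summ$k_app_sum[in_total])
    }
    block <- data.frame(
      antioxidant = ctx$antioxidant, radical = ctx$radical,
      medium = ctx$medium, mechanism = summ$mechanism,
      k_app_sum = summ$k_app_sum, gamma = gamma,
      gamma_int = round_half_away(gamma),
      diffusion_limited_any = summ$diffusion_limited_any,
      stringsAsFactors = FALSE
    )
    overall <- data.frame(
      antioxidant = ctx$antioxidant, radical = ctx$radical,
      medium = ctx$medium, mechanism = "overall",
      k_app_sum = overall_activity(summ$k_app_sum[in_total]),
      gamma = NA_real_, gamma_int = NA_real_,
      diffusion_limited_any = any(summ$diffusion_limited_any[in_total]),
      stringsAsFactors = FALSE
    )
    rows[[j]] <- rbind(block, overall)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
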