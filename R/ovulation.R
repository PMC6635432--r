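# Ovulation-day estimation from decoded posteriors: point estimate,
# uncertainty, confidence score, temperature-shift magnitude, and the
# reliability gate.

#' Estimated ovulation day from a posterior
#'
#' The most likely day of the cycle in which the chain is in the ovulation
#' state: the argmax over days of the `Ovu` posterior. Ties break to the
#' earliest day.
#'
#' @param posterior Days x states posterior matrix (from
#'   [forward_backward()] / [decode_cycle()]).
#' @return 1-based cycle day, or `NA` if `Ovu` carries no mass anywhere.
#' @export
estimate_ovulation_day <- function(posterior) {
  p <- posterior[, "Ovu"]
  if (sum(p) <= 0) return(NA_integer_)
  which.max(p)
}

#' Uncertainty of the ovulation estimate
#'
#' Standard deviation of the day index under the (re)normalized distribution
#' of the `Ovu` state's posterior mass across days; interpretable as a
#' +/- day confidence band on the ovulation estimate.
#'
#' @inheritParams estimate_ovulation_day
#' @return Nonnegative days, or `NA` when `Ovu` carries no mass.
#' @export
ovulation_uncertainty <- function(posterior) {
  p <- posterior[, "Ovu"]
  z <- sum(p)
  if (z <= 0) return(NA_real_)
  p <- p / z
  t <- seq_along(p)
  mu <- sum(t * p)
  sqrt(sum((t - mu)^2 * p))
}

#' Observation confidence score around the estimated ovulation day
#'
#' A \[0, 1\] indicator of how complete and consistent the observations are in
#' the 5-day window centred on the estimated ovulation day (clipped to the
#' cycle): `0.5 *` fraction of window days with a BBT record `+ 0.3 *`
#' fraction with a mucus record `+ 0.2 *` temperature-time consistency,
#' where time consistency is `max(0, 1 - sd(bbt_time)/60 min)` (1 when fewer
#' than two timed records exist in the window, since no inconsistency is
#' observed). Weights and window are package defaults, exposed as arguments.
#'
#' @param cycle A `fam_cycle`.
#' @param ovulation_day Estimated ovulation day (1-based).
#' @param window Half-width in days of the window (default 2, i.e. ~5 days).
#' @param weights Numeric `c(bbt, mucus, time)` summing to 1.
#' @return Score in \[0, 1\].
#' @export
confidence_score <- function(cycle, ovulation_day, window = 2,
                             weights = c(bbt = 0.5, mucus = 0.3, time = 0.2)) {
  stopifnot(!is.na(ovulation_day))
  lo <- max(1, ovulation_day - window)
  hi <- min(cycle$length_days, ovulation_day + window)
  win_days <- lo:hi
  d <- cycle$days[cycle$days$cycle_day %in% win_days, ]
  n_win <- length(win_days)
  frac_bbt <- sum(!is.na(d$bbt_value)) / n_win
  frac_mucus <- sum(!is.na(d$mucus)) / n_win
  times <- d$bbt_time_minutes[!is.na(d$bbt_time_minutes)]
  time_consistency <- if (length(times) >= 2) max(0, 1 - stats::sd(times) / 60) else 1
  if (frac_bbt == 0 && frac_mucus == 0) return(0)
  unname(weights["bbt"] * frac_bbt + weights["mucus"] * frac_mucus +
           weights["time"] * time_consistency)
}

#' Post-ovulatory temperature-shift magnitude
#'
#' Median delta-BBT over the post-ovulatory window (days `ovu+2` to `ovu+6`)
#' minus the median over the pre-ovulatory window (days `ovu-5` to `ovu-1`),
#' both clipped to the cycle and each requiring at least `min_n` BBT values.
#' Windows are package defaults, exposed as arguments.
#'
#' @param cycle A `fam_cycle`.
#' @param ovulation_day Estimated ovulation day.
#' @param pre_window,post_window Day offsets relative to `ovulation_day`.
#' @param min_n Minimum BBT count per window.
#' @return Shift in degC, or `NA` when either window has too few BBT values.
#' @export
temperature_shift <- function(cycle, ovulation_day,
                              pre_window = c(-5, -1), post_window = c(2, 6),
                              min_n = 2) {
  stopifnot(!is.na(ovulation_day))
  db <- delta_bbt(cycle)
  win_med <- function(w) {
    days <- (ovulation_day + w[1]):(ovulation_day + w[2])
    days <- days[days >= 1 & days <= cycle$length_days]
    v <- db$delta_bbt[db$cycle_day %in% days]
    if (length(v) < min_n) return(NA_real_)
    stats::median(v)
  }
  win_med(post_window) - win_med(pre_window)
}

#' Reliability gate for an ovulation estimate
#'
#' A standard cycle's ovulation estimate is *reliable* when all of: the
#' uncertainty is at most +/-1.5 days, the temperature shift is at least
#' 0.15 degC (equivalently 0.27 degF), and the confidence score is at least
#' 0.75. A missing component (e.g. a shift that could not be computed because
#' a window clipped below two BBT values) fails its criterion.
#'
#' @param ovulation_day,uncertainty_days,temp_shift_c,confidence Components.
#' @param thresholds Named numeric: `uncertainty` (days), `temp_shift`
#'   (degC), `confidence`.
#' @return An `ovulation_estimate` list: `ovulation_day`,
#'   `uncertainty_days`, `confidence_score`, `temp_shift_c`, `reliable`,
#'   `reasons` (failed criteria).
#' @export
reliability_gate <- function(ovulation_day, uncertainty_days, temp_shift_c,
                             confidence,
                             thresholds = c(uncertainty = 1.5, temp_shift = 0.15,
                                            confidence = 0.75)) {
  reasons <- character()
  if (is.na(ovulation_day)) reasons <- c(reasons, "no_ovulation")
  if (is.na(uncertainty_days) || uncertainty_days > thresholds[["uncertainty"]]) {
    reasons <- c(reasons, "uncertainty")
  }
  if (is.na(temp_shift_c) || temp_shift_c < thresholds[["temp_shift"]]) {
    reasons <- c(reasons, "temp_shift")
  }
  if (is.na(confidence) || confidence < thresholds[["confidence"]]) {
    reasons <- c(reasons, "confidence")
  }
  structure(
    list(
      ovulation_day = ovulation_day,
      uncertainty_days = uncertainty_days,
      confidence_score = confidence,
      temp_shift_c = temp_shift_c,
      reliable = length(reasons) == 0,
      reasons = reasons
    ),
    class = "ovulation_estimate"
  )
}

#' Full ovulation estimate for one decoded cycle
#'
#' Combines the posterior-based point estimate and uncertainty with the
#' observation-based confidence score and temperature-shift magnitude, and
#' applies the reliability gate.
#'
#' @param cycle A `fam_cycle`.
#' @param decoded Matching `decoded_cycle` from [decode_cycle()].
#' @param thresholds Passed to [reliability_gate()].
#' @return An `ovulation_estimate`.
#' @export
estimate_cycle <- function(cycle, decoded,
                           thresholds = c(uncertainty = 1.5, temp_shift = 0.15,
                                          confidence = 0.75)) {
  ovu <- estimate_ovulation_day(decoded$posterior)
  unc <- ovulation_uncertainty(decoded$posterior)
  conf <- if (is.na(ovu)) NA_real_ else confidence_score(cycle, ovu)
  shift <- if (is.na(ovu)) NA_real_ else temperature_shift(cycle, ovu)
  reliability_gate(ovu, unc, shift, conf, thresholds)
}

#' Estimate ovulation for a cohort
#'
#' @param cycles List of `fam_cycle`.
#' @param decoded Matching list from [decode_cycles()].
#' @param thresholds Passed to [reliability_gate()].
#' @return Tibble, one row per cycle: identifiers, cycle length, estimate
#'   components, `reliable`, and comma-joined `reasons`.
#' @export
estimate_cycles <- function(cycles, decoded,
                            thresholds = c(uncertainty = 1.5, temp_shift = 0.15,
                                           confidence = 0.75)) {
  stopifnot(length(cycles) == length(decoded))
  dplyr::bind_rows(lapply(seq_along(cycles), function(i) {
    est <- estimate_cycle(cycles[[i]], decoded[[i]], thresholds)
    tibble::tibble(
      user_id = cycles[[i]]$user_id,
      cycle_index = cycles[[i]]$cycle_index,
      length_days = cycles[[i]]$length_days,
      ovulation_day = as.integer(est$ovulation_day),
      uncertainty_days = est$uncertainty_days,
      confidence_score = est$confidence_score,
      temp_shift_c = est$temp_shift_c,
      reliable = est$reliable,
      reasons = paste(est$reasons, collapse = ",")
    )
  }))
}
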