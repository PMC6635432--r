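# Per-cycle-day descriptive profiles: cycle-relative temperature (delta-BBT)
# and category reporting frequencies, indexed from cycle start or cycle end.

.cycle_bbt <- function(cycle) {
  d <- cycle$days
  ok <- !is.na(d$bbt_value) & !(!is.na(d$bbt_questionable) & d$bbt_questionable)
  d[ok, c("cycle_day", "bbt_value")]
}

#' Per-cycle reference temperature
#'
#' The 25th percentile (linear-interpolation quantile, the `stats::quantile()`
#' type-7 default) of the cycle's BBT values. Values flagged questionable are
#' excluded: the flag marks unreliable readings.
#'
#' @param cycle A `fam_cycle`.
#' @return Reference temperature in degC, or `NA` if the cycle has no usable
#'   BBT value.
#' @export
cycle_reference_temperature <- function(cycle) {
  b <- .cycle_bbt(cycle)
  if (nrow(b) == 0) return(NA_real_)
  unname(stats::quantile(b$bbt_value, 0.25, type = 7))
}

#' Cycle-relative temperatures (delta-BBT)
#'
#' Each usable BBT value minus the cycle's reference temperature: the relative
#' rise, not the absolute temperature, carries the ovulation signal.
#'
#' @param cycle A `fam_cycle`.
#' @return Tibble with `cycle_day` and `delta_bbt` (empty when the cycle has
#'   no usable BBT).
#' @export
delta_bbt <- function(cycle) {
  ref <- cycle_reference_temperature(cycle)
  b <- .cycle_bbt(cycle)
  tibble::tibble(cycle_day = b$cycle_day, delta_bbt = b$bbt_value - ref)
}

#' Day index counted from the end of the cycle
#'
#' The last day of a cycle (the day before the next menstruation) is day -1,
#' the first day is `-length`.
#'
#' @param cycle_day 1-based day from cycle start.
#' @param length_days Cycle length.
#' @return Negative integer index.
#' @export
from_end_index <- function(cycle_day, length_days) cycle_day - length_days - 1L

#' Aggregate per-cycle-day profiles over a set of standard cycles
#'
#' Computes, per day index (counted either from the start of the cycle, first
#' menstruation day = 1, or from its end, last day = -1):
#'
#' * the delta-BBT profile: median, 10/25/75/90 percentiles and observation
#'   count; and
#' * category reporting frequencies: for each observation category (bleeding
#'   levels, mucus fertility grades, cervix openness, vaginal sensation), the
#'   number of cycles reporting it that day divided by the **total number of
#'   cycles supplied** — the denominator is the fixed standard-cycle count,
#'   not the per-day count, so sparsely tracked days show low frequencies.
#'
#' @param cycles List of `fam_cycle` (intended: one dialect's standard cycles).
#' @param indexing `"from_start"` or `"from_end"`.
#' @param max_days Profile depth in days (default 40); longer cycles
#'   contribute only their in-range days.
#' @return List with `delta_bbt` (tibble: day, n, p10, p25, median, p75, p90)
#'   and `frequencies` (tibble: day, feature, category, n_cycles, frequency),
#'   plus `n_cycles`, the fixed denominator.
#' @export
aggregate_profiles <- function(cycles, indexing = c("from_start", "from_end"),
                               max_days = 40) {
  indexing <- match.arg(indexing)
  n_cycles <- length(cycles)
  if (n_cycles == 0) {
    return(list(delta_bbt = tibble::tibble(), frequencies = tibble::tibble(),
                n_cycles = 0L))
  }
  per_cycle <- lapply(cycles, function(cy) {
    d <- cy$days
    db <- delta_bbt(cy)
    d <- dplyr::left_join(d, db, by = "cycle_day")
    d$mucus_grade <- mucus_fertility_grade(d$mucus, d$mucus_quantity)
    d$day <- if (indexing == "from_start") d$cycle_day
             else from_end_index(d$cycle_day, cy$length_days)
    d
  })
  all_days <- dplyr::bind_rows(per_cycle)
  keep <- if (indexing == "from_start") {
    all_days$day >= 1 & all_days$day <= max_days
  } else {
    all_days$day <= -1 & all_days$day >= -max_days
  }
  all_days <- all_days[keep, , drop = FALSE]

  db <- all_days[!is.na(all_days$delta_bbt), c("day", "delta_bbt")]
  delta_profile <- db |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      p10 = stats::quantile(.data$delta_bbt, 0.10, type = 7),
      p25 = stats::quantile(.data$delta_bbt, 0.25, type = 7),
      median = stats::median(.data$delta_bbt),
      p75 = stats::quantile(.data$delta_bbt, 0.75, type = 7),
      p90 = stats::quantile(.data$delta_bbt, 0.90, type = 7),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$day)

  denom <- n_cycles
  freq_features <- c("bleeding", "mucus_grade", "cervix_openness", "vaginal_sensation")
  freqs <- lapply(freq_features, function(f) {
    v <- all_days[!is.na(all_days[[f]]), c("day", f)]
    if (nrow(v) == 0) return(NULL)
    names(v)[2] <- "category"
    v |>
      dplyr::count(.data$day, .data$category, name = "n_cycles") |>
      dplyr::mutate(feature = f, frequency = .data$n_cycles / denom)
  })
  freqs <- dplyr::bind_rows(freqs)
  if (nrow(freqs) > 0) {
    freqs <- freqs[, c("day", "feature", "category", "n_cycles", "frequency")] |>
      dplyr::arrange(.data$feature, .data$day, .data$category)
  }
  list(delta_bbt = delta_profile, frequencies = freqs, n_cycles = n_cycles)
}
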