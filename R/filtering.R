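# Cycle-selection criteria defining "standard cycles": finished cycles of
# regular users with usable FAM body-sign records.

.fam_sign_days <- function(cycle) {
  d <- cycle$days
  which(!is.na(d$bbt_value) | !is.na(d$mucus) | !is.na(d$cervix_height) |
          !is.na(d$cervix_firmness) | !is.na(d$cervix_openness))
}

# Largest run of unlogged days, counting the boundary runs before the first
# and after the last logged day (a cycle logged only on day 20 of 28 has
# gaps of 19 and 8).
.max_observation_gap <- function(cycle) {
  logged <- cycle$days$cycle_day
  if (length(logged) == 0) return(cycle$length_days)
  bounds <- c(0L, logged, cycle$length_days + 1L)
  max(diff(bounds) - 1L)
}

# Period-like bleeding away from the cycle boundaries: >=2 consecutive days
# of medium-or-heavier bleeding starting after day 7 and ending before the
# last 5 days. Undefined in the source data dictionaries; this operational
# definition separates menses-like events from spotting.
.has_midcycle_bleeding <- function(cycle) {
  d <- cycle$days
  heavy_days <- sort(d$cycle_day[!is.na(d$bleeding) & d$bleeding %in% c("medium", "heavy")])
  if (length(heavy_days) < 2) return(FALSE)
  runs <- split(heavy_days, cumsum(c(1, diff(heavy_days) != 1)))
  for (r in runs) {
    if (length(r) >= 2 && min(r) > 7 && max(r) < cycle$length_days - 5 + 1) return(TRUE)
  }
  FALSE
}

# Proxy for the Sympto app's proprietary ovulatory-cycle determination, used
# only when the per-cycle flag is absent: a sustained BBT rise exists, i.e.
# three consecutive logged BBT values at least 0.15 degC above the cycle's
# reference temperature.
.stm_ovulatory_proxy <- function(cycle) {
  db <- delta_bbt(cycle)
  if (nrow(db) < 3) return(FALSE)
  v <- db$delta_bbt >= 0.15
  any(v[-c(1, 2)] & v[-c(1, length(v))] & v[-c(length(v) - 1, length(v))])
}

#' Standard-cycle criteria for one cycle
#'
#' Applies the inclusion criteria defining a *standard cycle*. Shared
#' criteria (all dialects): (a) not the user's first cycle nor an on-going
#' (chronologically last) cycle; (b) no observation gap longer than 15 days,
#' boundary gaps included; (c) at least one FAM body sign (BBT, cervical
#' mucus or cervix position) recorded; (d) for cycles longer than 40 days,
#' no mid-cycle period-like bleeding. Kindara adds: at least 8 days with FAM
#' observations, and cycle length at least 4 days longer than the number of
#' bleeding days. Sympto adds: the cycle was determined ovulatory by the
#' app's sympto-thermal algorithm (the per-cycle flag when provided, else a
#' documented sustained-BBT-rise proxy), and no breastfeeding or
#' peri-menopause declaration.
#'
#' @param cycle A `fam_cycle`.
#' @param dialect Rule set to apply; defaults to the cycle's own dialect
#'   (canonical cycles get the shared criteria only).
#' @return List with `standard` (logical) and `criteria` (named logical map,
#'   all of which must hold).
#' @export
is_standard_cycle <- function(cycle, dialect = cycle$app_dialect) {
  d <- cycle$days
  crit <- c(
    not_first_or_ongoing = cycle$cycle_index > 1 && !cycle$is_last_of_user,
    gap_le_15 = .max_observation_gap(cycle) <= 15,
    has_fam_sign = length(.fam_sign_days(cycle)) >= 1,
    no_midcycle_bleeding = cycle$length_days <= 40 || !.has_midcycle_bleeding(cycle)
  )
  if (dialect == "kindara") {
    n_bleed <- sum(!is.na(d$bleeding) & d$bleeding != "none")
    crit <- c(crit,
      fam_obs_ge_8 = length(.fam_sign_days(cycle)) >= 8,
      length_ge_bleeding_plus_4 = cycle$length_days >= n_bleed + 4
    )
  } else if (dialect == "sympto") {
    ovu_flag <- cycle$stm_ovulatory_flag
    if (is.na(ovu_flag)) ovu_flag <- .stm_ovulatory_proxy(cycle)
    crit <- c(crit,
      stm_ovulatory = ovu_flag,
      no_breastfeeding_perimenopause = !cycle$breastfeeding && !cycle$perimenopause
    )
  }
  list(standard = all(crit), criteria = crit)
}

#' Per-cycle filter report for a cohort
#'
#' One row per cycle with a boolean column per criterion and the final
#' `standard` flag (the conjunction of its dialect's criteria). The report
#' is order-independent: it depends only on each cycle in isolation.
#'
#' @param cycles List of `fam_cycle`.
#' @return Tibble with `user_id`, `cycle_index`, `length_days`, one column
#'   per criterion, `standard`, `tracking_frequency` and `any_sex`; the
#'   attribute `"criterion_counts"` holds the number of cycles failing each
#'   criterion.
#' @export
filter_report <- function(cycles) {
  rows <- lapply(cycles, function(cy) {
    r <- is_standard_cycle(cy)
    tibble::tibble(
      user_id = cy$user_id, cycle_index = cy$cycle_index,
      length_days = cy$length_days,
      !!!as.list(r$criteria),
      standard = r$standard,
      tracking_frequency = tracking_frequency(cy),
      any_sex = has_any_sex_logged(cy)
    )
  })
  rep <- dplyr::bind_rows(rows)
  crit_cols <- setdiff(names(rep), c("user_id", "cycle_index", "length_days",
                                     "standard", "tracking_frequency", "any_sex"))
  counts <- vapply(crit_cols, function(cc) sum(!rep[[cc]], na.rm = TRUE), 0L)
  attr(rep, "criterion_counts") <- counts
  rep
}

#' Subset a cohort to its standard cycles
#'
#' @param cycles List of `fam_cycle`.
#' @param report Optional precomputed [filter_report()].
#' @return List of the cycles whose `standard` flag is `TRUE`.
#' @export
standard_cycles <- function(cycles, report = NULL) {
  if (is.null(report)) report <- filter_report(cycles)
  cycles[report$standard]
}

#' Tracking frequency of a cycle
#'
#' Number of days with at least one logged field divided by the cycle length.
#'
#' @param cycle A `fam_cycle`.
#' @return Fraction in \[0, 1\].
#' @export
tracking_frequency <- function(cycle) {
  stopifnot(cycle$length_days >= 1)
  nrow(cycle$days) / cycle$length_days
}

#' Was any sexual intercourse logged in the cycle?
#'
#' True iff any day carries a non-empty sex record (any token counts,
#' including insemination).
#'
#' @param cycle A `fam_cycle`.
#' @return Logical.
#' @export
has_any_sex_logged <- function(cycle) {
  any(!is.na(cycle$days$sex) & cycle$days$sex != "")
}
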