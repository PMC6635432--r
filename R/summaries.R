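# Cohort-level tables: per-app counts across selection stages, phase-duration
# summaries, and ovulation-aligned mean state-probability profiles.

.stages <- c("full", "standard", "reliable")

#' Count users, cycles and observation-days per app and selection stage
#'
#' Observation-days are days with at least one logged field. The `standard`
#' stage uses the [filter_report()] flags; `reliable` additionally requires
#' the gate flag from [estimate_cycles()] (matched by user and cycle index).
#'
#' @param cycles List of `fam_cycle`.
#' @param report [filter_report()] of `cycles`.
#' @param estimates Optional [estimate_cycles()] tibble for the standard
#'   cycles (when absent the `reliable` stage is skipped).
#' @return Tibble: `app`, `stage`, `n_users`, `n_cycles`, `n_obs_days`.
#' @export
cohort_counts <- function(cycles, report, estimates = NULL) {
  base <- tibble::tibble(
    app = vapply(cycles, function(cy) cy$app_dialect, ""),
    user_id = vapply(cycles, function(cy) cy$user_id, ""),
    cycle_index = vapply(cycles, function(cy) cy$cycle_index, 0L),
    obs_days = vapply(cycles, function(cy) nrow(cy$days), 0L),
    standard = report$standard
  )
  if (!is.null(estimates)) {
    rel <- estimates[estimates$reliable, c("user_id", "cycle_index")]
    rel$reliable_flag <- TRUE
    base <- dplyr::left_join(base, rel, by = c("user_id", "cycle_index"))
    base$reliable <- !is.na(base$reliable_flag) & base$standard
  }
  one_stage <- function(df, stage) {
    df |>
      dplyr::group_by(.data$app) |>
      dplyr::summarise(
        stage = stage,
        n_users = dplyr::n_distinct(.data$user_id),
        n_cycles = dplyr::n(),
        n_obs_days = sum(.data$obs_days),
        .groups = "drop"
      )
  }
  out <- one_stage(base, "full")
  out <- dplyr::bind_rows(out, one_stage(base[base$standard, ], "standard"))
  if (!is.null(estimates)) {
    out <- dplyr::bind_rows(out, one_stage(base[base$reliable, ], "reliable"))
  }
  out[, c("app", "stage", "n_users", "n_cycles", "n_obs_days")]
}

#' Derive the per-app / per-stage cohort table from raw counts
#'
#' Adds, per app and selection stage (`full`, `standard`, `reliable`):
#' the average number of cycles per user (2 decimals) and the fraction of
#' the app's full dataset retained, by users, cycles and observation-days
#' (integer percent; blank on the `full` rows). Appends a `Total` row per
#' stage whose counts are exact integer sums of the app rows and whose
#' derived statistics are recomputed from those sums.
#'
#' @param counts Tibble with `app`, `stage`, `n_users`, `n_cycles`,
#'   `n_obs_days` (as from [cohort_counts()], or externally supplied
#'   published counts).
#' @return Tibble with the derived columns `avg_cycles_per_user`,
#'   `pct_users`, `pct_cycles`, `pct_obs_days`.
#' @export
cohort_table <- function(counts) {
  stopifnot(all(c("app", "stage", "n_users", "n_cycles", "n_obs_days") %in%
                  names(counts)))
  apps <- unique(counts$app)
  totals <- counts |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      app = "Total",
      n_users = sum(.data$n_users),
      n_cycles = sum(.data$n_cycles),
      n_obs_days = sum(.data$n_obs_days),
      .groups = "drop"
    )
  tab <- dplyr::bind_rows(counts, totals)
  full <- tab[tab$stage == "full", c("app", "n_users", "n_cycles", "n_obs_days")]
  names(full) <- c("app", "full_users", "full_cycles", "full_obs")
  tab <- dplyr::left_join(tab, full, by = "app")
  tab$avg_cycles_per_user <- round(tab$n_cycles / tab$n_users, 2)
  pct <- function(num, den) as.integer(round(100 * num / den))
  tab$pct_users <- ifelse(tab$stage == "full", NA_integer_,
                          pct(tab$n_users, tab$full_users))
  tab$pct_cycles <- ifelse(tab$stage == "full", NA_integer_,
                           pct(tab$n_cycles, tab$full_cycles))
  tab$pct_obs_days <- ifelse(tab$stage == "full", NA_integer_,
                             pct(tab$n_obs_days, tab$full_obs))
  tab$app <- factor(tab$app, levels = c(apps, "Total"))
  tab$stage <- factor(tab$stage, levels = .stages)
  tab <- dplyr::arrange(tab, .data$app, .data$stage)
  tab$app <- as.character(tab$app)
  tab$stage <- as.character(tab$stage)
  tab[, c("app", "stage", "n_users", "n_cycles", "n_obs_days",
          "avg_cycles_per_user", "pct_users", "pct_cycles", "pct_obs_days")]
}

#' Luteal phase duration
#'
#' Number of days between the ovulation day (excluded) and the first day of
#' the next cycle (excluded): cycle length minus ovulation day.
#'
#' @param length_days Cycle length.
#' @param ovulation_day Estimated ovulation day, in `[1, length_days]`.
#' @return Days (>= 0).
#' @export
luteal_duration <- function(length_days, ovulation_day) {
  if (any(is.na(ovulation_day)) || any(ovulation_day < 1) ||
      any(ovulation_day > length_days)) {
    stop("ovulation_day must be within [1, length_days]")
  }
  length_days - ovulation_day
}

#' Phase-duration summary over reliable cycles
#'
#' Follicular duration is defined as the estimated ovulation day itself
#' (days 1..ovu), so follicular + luteal equals the cycle length on every
#' row. Reports medians, 5/95% quantiles, and the fractions of cycles with
#' ovulation on days 14-15, luteal phase <= 10 days, and luteal phase of
#' 12-13 days.
#'
#' @param estimates [estimate_cycles()] tibble; only rows with
#'   `reliable == TRUE` are used.
#' @return List with `n`, `durations` (per-cycle tibble), `medians`,
#'   `quantiles` (5/95% per measure) and `fractions`.
#' @export
phase_summary <- function(estimates) {
  rel <- estimates[estimates$reliable & !is.na(estimates$ovulation_day), ]
  if (nrow(rel) == 0) {
    return(list(n = 0L, durations = tibble::tibble(), medians = numeric(),
                quantiles = tibble::tibble(), fractions = numeric()))
  }
  durations <- tibble::tibble(
    user_id = rel$user_id, cycle_index = rel$cycle_index,
    cycle_length = rel$length_days,
    follicular = rel$ovulation_day,
    luteal = luteal_duration(rel$length_days, rel$ovulation_day)
  )
  q <- function(x) stats::quantile(x, c(0.05, 0.95), type = 7)
  measures <- c("cycle_length", "follicular", "luteal")
  quantiles <- dplyr::bind_rows(lapply(measures, function(m) {
    v <- q(durations[[m]])
    tibble::tibble(measure = m, q05 = v[1], q95 = v[2])
  }))
  list(
    n = nrow(durations),
    durations = durations,
    medians = vapply(durations[measures], stats::median, 0),
    quantiles = quantiles,
    fractions = c(
      ovulation_day_14_15 = mean(durations$follicular %in% c(14, 15)),
      luteal_le_10 = mean(durations$luteal <= 10),
      luteal_12_13 = mean(durations$luteal %in% c(12, 13))
    )
  )
}

#' Ovulation-aligned mean state-probability profiles
#'
#' For reliable cycles, re-indexes each day as `cycle_day - ovulation_day`
#' and averages the per-day state posteriors per index within cycle-length
#' bins of `bin_width` days; each cycle falls in exactly one bin. Empty bins
#' are simply absent.
#'
#' @param decoded List of `decoded_cycle` aligned with the rows of
#'   `estimates`.
#' @param estimates [estimate_cycles()] tibble.
#' @param bin_width Cycle-length bin width in days (default 3).
#' @return Tibble: `length_bin` (label), `day_from_ovulation`, `state`,
#'   `mean_probability`, `n_cycles`.
#' @export
ovulation_aligned_profiles <- function(decoded, estimates, bin_width = 3) {
  stopifnot(length(decoded) == nrow(estimates))
  keep <- which(estimates$reliable & !is.na(estimates$ovulation_day))
  if (length(keep) == 0) return(tibble::tibble())
  rows <- lapply(keep, function(i) {
    post <- decoded[[i]]$posterior
    len <- nrow(post)
    ovu <- estimates$ovulation_day[i]
    lo <- floor((len - 1) / bin_width) * bin_width + 1
    tibble::tibble(
      length_bin = sprintf("%d-%d", lo, lo + bin_width - 1),
      day_from_ovulation = rep(seq_len(len) - ovu, times = ncol(post)),
      state = rep(colnames(post), each = len),
      probability = as.vector(post)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$length_bin, .data$day_from_ovulation, .data$state) |>
    dplyr::summarise(
      mean_probability = mean(.data$probability),
      n_cycles = dplyr::n(),
      .groups = "drop"
    )
}
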