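# Canonical data model for fertility-awareness (FAM) self-tracking data and
# readers/writers for the two supported app dialects plus a canonical CSV.

#' Canonical category sets for daily FAM observations
#'
#' The canonical vocabulary every dialect is normalized into. Bleeding and
#' mucus quantity are ordinal (listed lowest to highest); the others are
#' unordered categories.
#'
#' @return Named list of character vectors.
#' @export
fam_categories <- function() {
  list(
    bleeding          = c("none", "spotting", "light", "medium", "heavy"),
    mucus             = c("none", "sticky", "creamy", "eggwhite", "watery"),
    mucus_quantity    = c("little", "medium", "lots"),
    cervix_height     = c("low", "medium", "high"),
    cervix_firmness   = c("firm", "medium", "soft"),
    cervix_openness   = c("closed", "medium", "open"),
    vaginal_sensation = c("dry", "dry_sticky", "wet_moist", "wet_lubricative"),
    sex               = c("protected", "unprotected", "withdrawal", "insemination"),
    goal              = c("conception", "contraception", "observation", "unknown")
  )
}

# Columns of the per-day observation table inside a cycle, in canonical form.
.day_columns <- c(
  "cycle_day", "bbt_value", "bbt_time_minutes", "bbt_questionable",
  "bleeding", "mucus", "mucus_quantity",
  "cervix_height", "cervix_firmness", "cervix_openness",
  "vaginal_sensation", "sex"
)

.empty_days <- function() {
  tibble::tibble(
    cycle_day = integer(), bbt_value = numeric(), bbt_time_minutes = numeric(),
    bbt_questionable = logical(), bleeding = character(), mucus = character(),
    mucus_quantity = character(), cervix_height = character(),
    cervix_firmness = character(), cervix_openness = character(),
    vaginal_sensation = character(), sex = character()
  )
}

#' Construct a daily observation table
#'
#' Builds the canonical per-day table stored in a [new_cycle()] object. Absent
#' fields are `NA`; `sex` is a `"+"`-joined string of sex tokens (e.g.
#' `"protected+unprotected"`) or `NA` when nothing was logged.
#'
#' @param cycle_day Integer vector (1-based day within the cycle).
#' @param ... Named vectors for any subset of the remaining day columns.
#' @return A tibble with one row per logged day.
#' @export
daily_observations <- function(cycle_day, ...) {
  extra <- list(...)
  bad <- setdiff(names(extra), .day_columns)
  if (length(bad) > 0) {
    stop("unknown observation field(s): ", paste(bad, collapse = ", "))
  }
  n <- length(cycle_day)
  out <- .empty_days()[rep(NA_integer_, n), ]
  out$cycle_day <- as.integer(cycle_day)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  validate_days(out)
  out
}

validate_days <- function(days) {
  cats <- fam_categories()
  stopifnot(all(days$cycle_day >= 1))
  if (anyDuplicated(days$cycle_day)) stop("duplicated cycle_day in observation table")
  bbt <- days$bbt_value[!is.na(days$bbt_value)]
  if (length(bbt) > 0 && (any(bbt < 34) || any(bbt > 40))) {
    stop("bbt_value outside plausibility window [34, 40] degC")
  }
  for (f in c("bleeding", "mucus", "mucus_quantity", "cervix_height",
              "cervix_firmness", "cervix_openness", "vaginal_sensation")) {
    v <- days[[f]][!is.na(days[[f]])]
    if (length(v) > 0 && !all(v %in% cats[[f]])) {
      stop("invalid token(s) in ", f, ": ",
           paste(unique(setdiff(v, cats[[f]])), collapse = ", "))
    }
  }
  # quantity only meaningful for quantity-bearing mucus categories
  qb <- !is.na(days$mucus_quantity)
  if (any(qb & (is.na(days$mucus) | days$mucus == "none"))) {
    stop("mucus_quantity present without a quantity-bearing mucus category")
  }
  sx <- days$sex[!is.na(days$sex)]
  if (length(sx) > 0) {
    toks <- unlist(strsplit(sx, "+", fixed = TRUE))
    if (!all(toks %in% cats$sex)) {
      stop("invalid sex token(s): ", paste(setdiff(toks, cats$sex), collapse = ", "))
    }
  }
  invisible(days)
}

#' Construct a cycle
#'
#' A cycle runs from the first day of menses to the day before the next
#' menses. `days` holds at most one row per `cycle_day`; days with no logged
#' fields are simply absent from the table.
#'
#' @param user_id Opaque user identifier.
#' @param cycle_index 1-based ordinal of the cycle within the user's history.
#' @param length_days Cycle length in days (>= 1).
#' @param days Observation table from [daily_observations()] (may be empty).
#' @param app_dialect `"sympto"`, `"kindara"` or `"canonical"`.
#' @param goal User's family-planning goal.
#' @param is_last_of_user Is this the user's chronologically last (possibly
#'   on-going) cycle?
#' @param stm_ovulatory_flag Sympto's ovulatory-cycle determination (logical,
#'   `NA` when not provided; a proxy is derived at filter time, see
#'   [is_standard_cycle()]).
#' @param breastfeeding,perimenopause Sympto per-cycle declarations
#'   (absent means `FALSE`).
#' @return An object of class `fam_cycle`.
#' @export
new_cycle <- function(user_id, cycle_index, length_days, days = .empty_days(),
                      app_dialect = "canonical", goal = "unknown",
                      is_last_of_user = FALSE, stm_ovulatory_flag = NA,
                      breastfeeding = FALSE, perimenopause = FALSE) {
  stopifnot(length_days >= 1)
  if (!app_dialect %in% c("sympto", "kindara", "canonical")) {
    stop("unknown dialect: ", app_dialect)
  }
  if (!goal %in% fam_categories()$goal) stop("unknown goal: ", goal)
  days <- days[order(days$cycle_day), , drop = FALSE]
  validate_days(days)
  if (nrow(days) > 0 && max(days$cycle_day) > length_days) {
    stop("observation beyond cycle length (cycle_day > length_days)")
  }
  structure(
    list(
      user_id = as.character(user_id),
      cycle_index = as.integer(cycle_index),
      length_days = as.integer(length_days),
      days = days,
      app_dialect = app_dialect,
      goal = goal,
      is_last_of_user = isTRUE(is_last_of_user),
      stm_ovulatory_flag = as.logical(stm_ovulatory_flag),
      breastfeeding = isTRUE(breastfeeding),
      perimenopause = isTRUE(perimenopause)
    ),
    class = "fam_cycle"
  )
}

#' @export
print.fam_cycle <- function(x, ...) {
  cat(sprintf("<fam_cycle> user %s, cycle %d, %d days (%s, goal: %s), %d logged days\n",
              x$user_id, x$cycle_index, x$length_days, x$app_dialect, x$goal,
              nrow(x$days)))
  invisible(x)
}

#' Convert a temperature from Fahrenheit to Celsius
#'
#' @param temp_f Temperature(s) in degrees Fahrenheit.
#' @return Temperature(s) in degrees Celsius (unrounded).
#' @export
fahrenheit_to_celsius <- function(temp_f) (temp_f - 32) / 1.8

#' @rdname fahrenheit_to_celsius
#' @export
celsius_to_fahrenheit <- function(temp_c) temp_c * 1.8 + 32

#' Convert a temperature difference from Fahrenheit to Celsius
#'
#' Differences scale by 1/1.8 only (no offset): a 0.27 degF shift equals a
#' 0.15 degC shift.
#'
#' @param delta_f Temperature difference(s) in degF.
#' @return Temperature difference(s) in degC.
#' @export
fahrenheit_to_celsius_delta <- function(delta_f) {
  stopifnot(all(is.finite(delta_f)))
  delta_f / 1.8
}

#' Group a mucus observation into a fertility grade
#'
#' Collapses (category, quantity) pairs into the low/high-fertility grouping
#' used throughout the cohort profiles and the HMM emissions: large amounts of
#' egg-white-like and medium or large amounts of watery mucus are "high"
#' fertility mucus; little watery, little or medium egg-white, and any sticky
#' or creamy mucus are "low".
#'
#' @param mucus Canonical mucus category vector.
#' @param quantity Canonical quantity vector (may be `NA`).
#' @return Character vector in `{none, low, high}` (`NA` when mucus is `NA`).
#' @export
mucus_fertility_grade <- function(mucus, quantity) {
  out <- rep(NA_character_, length(mucus))
  out[!is.na(mucus) & mucus == "none"] <- "none"
  obs <- !is.na(mucus) & mucus != "none"
  q <- ifelse(is.na(quantity), "little", quantity)  # unstated quantity read as low
  high <- obs & ((mucus == "eggwhite" & q == "lots") |
                 (mucus == "watery" & q %in% c("medium", "lots")))
  out[obs] <- "low"
  out[high] <- "high"
  out
}

# ---- dialect mapping tables -------------------------------------------------

# Sympto reports mucus on a 2-level scale; canonicalized to (category,
# quantity) pairs preserving the low/high fertility grouping.
.sympto_mucus_to_canonical <- list(
  "0" = c(NA_character_, NA_character_),   # explicit "no mucus"
  "1" = c("creamy", "little"),        # little creamy/egg-white-like
  "2" = c("eggwhite", "lots")         # large egg-white-like, watery
)

# Sympto's single 3-level cervix score expands to the three canonical axes.
.sympto_cervix_to_canonical <- list(
  "closed_firm_low" = c("low", "firm", "closed"),
  "medium"          = c("medium", "medium", "medium"),
  "open_soft_high"  = c("high", "soft", "open")
)

.sympto_sensation_to_canonical <- c(
  dry = "dry", wet = "wet_moist", very_wet = "wet_lubricative"
)

.kindara_sensation_to_canonical <- c(
  dry = "dry", dry_sticky = "dry_sticky",
  wet_moist = "wet_moist", wet_lubricate = "wet_lubricative"
)

.parse_clock <- function(x) {
  # "HH:MM" -> minutes after midnight
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x != ""
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed clock time: ", x[ok][bad][1])
    h <- as.numeric(vapply(parts, `[`, "", 1L))
    m <- as.numeric(vapply(parts, `[`, "", 2L))
    out[ok] <- h * 60 + m
  }
  out
}

.format_clock <- function(mins) {
  ifelse(is.na(mins), NA_character_,
         sprintf("%02d:%02d", floor(mins / 60) %% 24, round(mins) %% 60))
}

.check_tokens <- function(x, allowed, field, rows) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("row %d: unknown token '%s' in field '%s'", rows[i], x[i], field))
  }
  x
}

# ---- readers ---------------------------------------------------------------

#' Read cycles from a dialect CSV
#'
#' Reads a delimited file with one row per user-day and returns canonical
#' cycles. Column layouts per dialect:
#'
#' * **canonical**: `user_id, cycle_index, cycle_day, cycle_length, goal,
#'   is_last_of_user, stm_ovulatory, breastfeeding, perimenopause, bbt_c,
#'   bbt_time_minutes, bbt_questionable, bleeding, mucus, mucus_quantity,
#'   cervix_height, cervix_firmness, cervix_openness, vaginal_sensation, sex`
#'   (categories as in [fam_categories()], temperatures in degC).
#' * **sympto**: `..., temperature_c, temp_time` (HH:MM), `bleeding_score`
#'   (0-3), `mucus_score` (0-2), `cervix` (`closed_firm_low`/`medium`/
#'   `open_soft_high`), `sensation` (`dry`/`wet`/`very_wet`), `sex`
#'   (withdrawal is recorded by the app as unprotected), plus `stm_ovulatory`,
#'   `breastfeeding`, `perimenopause`.
#' * **kindara**: `..., temperature_f, temp_time` (HH:MM),
#'   `questionable`, `menstruation`, `fluid`, `fluid_amount`, `cervix_height`,
#'   `cervix_firmness`, `cervix_openness`, `sensation` (`dry`/`dry_sticky`/
#'   `wet_moist`/`wet_lubricate`), `sex` (`+`-joined, may include
#'   `withdrawal`/`insemination`).
#'
#' Fahrenheit temperatures are converted to Celsius without rounding; Sympto
#' bleeding scores 1-3 map to light/medium/heavy; unknown tokens raise an
#' error naming the row and field.
#'
#' @param path CSV file path.
#' @param dialect `"sympto"`, `"kindara"` or `"canonical"`.
#' @return List of `fam_cycle` objects.
#' @seealso [write_cycles()]
#' @export
read_cycles <- function(path, dialect) {
  if (!dialect %in% c("sympto", "kindara", "canonical")) {
    stop("unknown dialect: ", dialect)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) return(list())
  for (col in c("user_id", "cycle_index", "cycle_day", "cycle_length")) {
    if (!col %in% names(raw)) stop("missing required column: ", col)
  }
  rows <- seq_len(nrow(raw))
  canon <- switch(dialect,
    canonical = .decode_canonical(raw, rows),
    sympto    = .decode_sympto(raw, rows),
    kindara   = .decode_kindara(raw, rows)
  )
  .assemble_cycles(canon, dialect)
}

.num <- function(x) suppressWarnings(as.numeric(x))
.lgl <- function(x) {
  out <- rep(NA, length(x))
  out[!is.na(x) & toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
  out[!is.na(x) & toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
  out
}
.col <- function(raw, nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))

.decode_canonical <- function(raw, rows) {
  cats <- fam_categories()
  tibble::tibble(
    user_id = raw$user_id,
    cycle_index = as.integer(raw$cycle_index),
    cycle_day = as.integer(raw$cycle_day),
    cycle_length = as.integer(raw$cycle_length),
    goal = .col(raw, "goal"),
    is_last_of_user = .lgl(.col(raw, "is_last_of_user")),
    stm_ovulatory = .lgl(.col(raw, "stm_ovulatory")),
    breastfeeding = .lgl(.col(raw, "breastfeeding")),
    perimenopause = .lgl(.col(raw, "perimenopause")),
    bbt_value = .num(.col(raw, "bbt_c")),
    bbt_time_minutes = .num(.col(raw, "bbt_time_minutes")),
    bbt_questionable = .lgl(.col(raw, "bbt_questionable")),
    bleeding = .check_tokens(.col(raw, "bleeding"), cats$bleeding, "bleeding", rows),
    mucus = .check_tokens(.col(raw, "mucus"), cats$mucus, "mucus", rows),
    mucus_quantity = .check_tokens(.col(raw, "mucus_quantity"), cats$mucus_quantity,
                                   "mucus_quantity", rows),
    cervix_height = .check_tokens(.col(raw, "cervix_height"), cats$cervix_height,
                                  "cervix_height", rows),
    cervix_firmness = .check_tokens(.col(raw, "cervix_firmness"), cats$cervix_firmness,
                                    "cervix_firmness", rows),
    cervix_openness = .check_tokens(.col(raw, "cervix_openness"), cats$cervix_openness,
                                    "cervix_openness", rows),
    vaginal_sensation = .check_tokens(.col(raw, "vaginal_sensation"),
                                      cats$vaginal_sensation, "vaginal_sensation", rows),
    sex = .col(raw, "sex")
  )
}

.decode_sympto <- function(raw, rows) {
  bleed_raw <- .check_tokens(.col(raw, "bleeding_score"), c("0", "1", "2", "3"),
                             "bleeding_score", rows)
  bleeding <- unname(c("0" = "none", "1" = "light", "2" = "medium",
                       "3" = "heavy")[bleed_raw])
  mucus_raw <- .check_tokens(.col(raw, "mucus_score"), names(.sympto_mucus_to_canonical),
                             "mucus_score", rows)
  mucus <- rep(NA_character_, nrow(raw)); mq <- rep(NA_character_, nrow(raw))
  ok <- !is.na(mucus_raw)
  if (any(ok)) {
    mapped <- vapply(mucus_raw[ok], function(k) .sympto_mucus_to_canonical[[k]],
                     character(2))
    mucus[ok] <- ifelse(is.na(mapped[1, ]), "none", mapped[1, ])
    mq[ok] <- mapped[2, ]
  }
  cervix_raw <- .check_tokens(.col(raw, "cervix"), names(.sympto_cervix_to_canonical),
                              "cervix", rows)
  ch <- cf <- co <- rep(NA_character_, nrow(raw))
  ok <- !is.na(cervix_raw)
  if (any(ok)) {
    mapped <- vapply(cervix_raw[ok], function(k) .sympto_cervix_to_canonical[[k]],
                     character(3))
    ch[ok] <- mapped[1, ]; cf[ok] <- mapped[2, ]; co[ok] <- mapped[3, ]
  }
  sens_raw <- .check_tokens(.col(raw, "sensation"),
                            names(.sympto_sensation_to_canonical), "sensation", rows)
  sex_raw <- .col(raw, "sex")
  sex <- vapply(sex_raw, function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    toks <- unlist(strsplit(s, "+", fixed = TRUE))
    if (!all(toks %in% c("protected", "unprotected", "withdrawal"))) {
      stop("unknown sex token in sympto file: ", s)
    }
    toks[toks == "withdrawal"] <- "unprotected"  # app convention
    paste(sort(unique(toks)), collapse = "+")
  }, "", USE.NAMES = FALSE)
  tibble::tibble(
    user_id = raw$user_id,
    cycle_index = as.integer(raw$cycle_index),
    cycle_day = as.integer(raw$cycle_day),
    cycle_length = as.integer(raw$cycle_length),
    goal = .col(raw, "goal"),
    is_last_of_user = .lgl(.col(raw, "is_last_of_user")),
    stm_ovulatory = .lgl(.col(raw, "stm_ovulatory")),
    breastfeeding = .lgl(.col(raw, "breastfeeding")),
    perimenopause = .lgl(.col(raw, "perimenopause")),
    bbt_value = .num(.col(raw, "temperature_c")),
    bbt_time_minutes = .parse_clock(.col(raw, "temp_time")),
    bbt_questionable = NA,          # not recorded by this app
    bleeding = bleeding,
    mucus = mucus,
    mucus_quantity = mq,
    cervix_height = ch, cervix_firmness = cf, cervix_openness = co,
    vaginal_sensation = unname(.sympto_sensation_to_canonical[sens_raw]),
    sex = sex
  )
}

.decode_kindara <- function(raw, rows) {
  cats <- fam_categories()
  sens_raw <- .check_tokens(.col(raw, "sensation"),
                            names(.kindara_sensation_to_canonical), "sensation", rows)
  sex_raw <- .col(raw, "sex")
  sex <- vapply(sex_raw, function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    toks <- unlist(strsplit(s, "+", fixed = TRUE))
    if (!all(toks %in% cats$sex)) stop("unknown sex token in kindara file: ", s)
    paste(sort(unique(toks)), collapse = "+")
  }, "", USE.NAMES = FALSE)
  tibble::tibble(
    user_id = raw$user_id,
    cycle_index = as.integer(raw$cycle_index),
    cycle_day = as.integer(raw$cycle_day),
    cycle_length = as.integer(raw$cycle_length),
    goal = .col(raw, "goal"),
    is_last_of_user = .lgl(.col(raw, "is_last_of_user")),
    stm_ovulatory = NA,
    breastfeeding = NA,
    perimenopause = NA,
    bbt_value = fahrenheit_to_celsius(.num(.col(raw, "temperature_f"))),
    bbt_time_minutes = .parse_clock(.col(raw, "temp_time")),
    bbt_questionable = .lgl(.col(raw, "questionable")),
    bleeding = .check_tokens(.col(raw, "menstruation"), cats$bleeding,
                             "menstruation", rows),
    mucus = .check_tokens(.col(raw, "fluid"), cats$mucus, "fluid", rows),
    mucus_quantity = .check_tokens(.col(raw, "fluid_amount"), cats$mucus_quantity,
                                   "fluid_amount", rows),
    cervix_height = .check_tokens(.col(raw, "cervix_height"), cats$cervix_height,
                                  "cervix_height", rows),
    cervix_firmness = .check_tokens(.col(raw, "cervix_firmness"), cats$cervix_firmness,
                                    "cervix_firmness", rows),
    cervix_openness = .check_tokens(.col(raw, "cervix_openness"), cats$cervix_openness,
                                    "cervix_openness", rows),
    vaginal_sensation = unname(.kindara_sensation_to_canonical[sens_raw]),
    sex = sex
  )
}

.assemble_cycles <- function(canon, dialect) {
  canon$goal[is.na(canon$goal)] <- "unknown"
  keys <- paste(canon$user_id, canon$cycle_index, sep = "\r")
  split_idx <- split(seq_len(nrow(canon)), factor(keys, levels = unique(keys)))
  lapply(split_idx, function(idx) {
    block <- canon[idx, , drop = FALSE]
    # keep only days with at least one logged field
    has_obs <- rowSums(!is.na(block[, c("bbt_value", "bleeding", "mucus",
                                        "cervix_height", "cervix_firmness",
                                        "cervix_openness", "vaginal_sensation",
                                        "sex")])) > 0
    days <- block[has_obs, .day_columns, drop = FALSE]
    new_cycle(
      user_id = block$user_id[1],
      cycle_index = block$cycle_index[1],
      length_days = block$cycle_length[1],
      days = days,
      app_dialect = dialect,
      goal = block$goal[1],
      is_last_of_user = isTRUE(block$is_last_of_user[1]),
      stm_ovulatory_flag = block$stm_ovulatory[1],
      breastfeeding = isTRUE(block$breastfeeding[1]),
      perimenopause = isTRUE(block$perimenopause[1])
    )
  }) |> unname()
}

# ---- writers ---------------------------------------------------------------

#' Write cycles to a dialect CSV
#'
#' Inverse of [read_cycles()]. Temperatures are rounded at write time only:
#' 0.01 degC (canonical), 0.05 degC (sympto, the app's reporting precision),
#' 0.01 degF (kindara). The sympto dialect is lossy by design (its mucus and
#' cervix scales are coarser than the canonical ones); canonical and kindara
#' round-trip exactly up to temperature rounding.
#'
#' @param cycles List of `fam_cycle`.
#' @param path Output CSV path.
#' @param dialect Target dialect.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(cycles, path, dialect) {
  if (!dialect %in% c("sympto", "kindara", "canonical")) {
    stop("unknown dialect: ", dialect)
  }
  rows <- lapply(cycles, function(cy) {
    d <- cy$days
    if (nrow(d) == 0) return(NULL)
    base <- tibble::tibble(
      user_id = cy$user_id, cycle_index = cy$cycle_index,
      cycle_day = d$cycle_day, cycle_length = cy$length_days,
      goal = cy$goal, is_last_of_user = cy$is_last_of_user
    )
    if (dialect == "canonical") {
      dplyr::bind_cols(base, tibble::tibble(
        stm_ovulatory = cy$stm_ovulatory_flag,
        breastfeeding = cy$breastfeeding, perimenopause = cy$perimenopause,
        bbt_c = round(d$bbt_value, 2), bbt_time_minutes = d$bbt_time_minutes,
        bbt_questionable = d$bbt_questionable,
        bleeding = d$bleeding, mucus = d$mucus, mucus_quantity = d$mucus_quantity,
        cervix_height = d$cervix_height, cervix_firmness = d$cervix_firmness,
        cervix_openness = d$cervix_openness,
        vaginal_sensation = d$vaginal_sensation, sex = d$sex
      ))
    } else if (dialect == "sympto") {
      grade <- mucus_fertility_grade(d$mucus, d$mucus_quantity)
      mucus_score <- ifelse(is.na(grade), NA_character_,
                            c(none = "0", low = "1", high = "2")[grade])
      cervix <- ifelse(is.na(d$cervix_openness), NA_character_,
                       c(closed = "closed_firm_low", medium = "medium",
                         open = "open_soft_high")[d$cervix_openness])
      sens <- ifelse(is.na(d$vaginal_sensation), NA_character_,
                     c(dry = "dry", dry_sticky = "dry", wet_moist = "wet",
                       wet_lubricative = "very_wet")[d$vaginal_sensation])
      sex <- vapply(d$sex, function(s) {
        if (is.na(s)) return(NA_character_)
        toks <- unlist(strsplit(s, "+", fixed = TRUE))
        toks[toks %in% c("withdrawal", "insemination")] <- "unprotected"
        paste(sort(unique(toks)), collapse = "+")
      }, "", USE.NAMES = FALSE)
      dplyr::bind_cols(base, tibble::tibble(
        stm_ovulatory = cy$stm_ovulatory_flag,
        breastfeeding = cy$breastfeeding, perimenopause = cy$perimenopause,
        temperature_c = round(d$bbt_value / 0.05) * 0.05,
        temp_time = .format_clock(round(d$bbt_time_minutes / 30) * 30),
        bleeding_score = ifelse(is.na(d$bleeding), NA_character_,
                                c(none = "0", spotting = "1", light = "1",
                                  medium = "2", heavy = "3")[d$bleeding]),
        mucus_score = mucus_score, cervix = cervix, sensation = sens, sex = sex
      ))
    } else {  # kindara
      sens <- ifelse(is.na(d$vaginal_sensation), NA_character_,
                     c(dry = "dry", dry_sticky = "dry_sticky",
                       wet_moist = "wet_moist",
                       wet_lubricative = "wet_lubricate")[d$vaginal_sensation])
      dplyr::bind_cols(base, tibble::tibble(
        temperature_f = round(celsius_to_fahrenheit(d$bbt_value), 2),
        temp_time = .format_clock(d$bbt_time_minutes),
        questionable = d$bbt_questionable,
        menstruation = d$bleeding, fluid = d$mucus, fluid_amount = d$mucus_quantity,
        cervix_height = d$cervix_height, cervix_firmness = d$cervix_firmness,
        cervix_openness = d$cervix_openness, sensation = sens, sex = d$sex
      ))
    }
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) out <- tibble::tibble(
    user_id = character(), cycle_index = integer(), cycle_day = integer(),
    cycle_length = integer(), goal = character(), is_last_of_user = logical()
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# ---- user metadata ---------------------------------------------------------

#' Construct a user metadata table
#'
#' @param user_id Character vector of user identifiers.
#' @param birth_year,weight_kg,height_cm,menarche_age_years,country Optional
#'   per-user fields (`NA` allowed).
#' @return A tibble, one row per user.
#' @export
user_meta <- function(user_id, birth_year = NA, weight_kg = NA, height_cm = NA,
                      menarche_age_years = NA, country = NA) {
  tibble::tibble(
    user_id = as.character(user_id),
    birth_year = as.numeric(birth_year),
    weight_kg = as.numeric(weight_kg),
    height_cm = as.numeric(height_cm),
    menarche_age_years = as.numeric(menarche_age_years),
    country = as.character(country)
  )
}

#' Blank implausible user metadata values
#'
#' Values of very low plausibility (e.g. a height of 45 cm) are blanked, not
#' dropped: the user row is retained, and cycles of such users stay in the
#' analysis. Plausibility windows: height in \[120, 220\] cm, weight in
#' \[30, 200\] kg, menarche age in \[8, 20\] years, birth year in
#' \[1940, 2015\].
#'
#' @param users Tibble from [user_meta()].
#' @return Same-shaped tibble with implausible values set to `NA`.
#' @export
clean_user_meta <- function(users) {
  blank <- function(x, lo, hi) ifelse(!is.na(x) & (x < lo | x > hi), NA_real_, x)
  users$height_cm <- blank(users$height_cm, 120, 220)
  users$weight_kg <- blank(users$weight_kg, 30, 200)
  users$menarche_age_years <- blank(users$menarche_age_years, 8, 20)
  users$birth_year <- blank(users$birth_year, 1940, 2015)
  users
}

#' Body-mass index
#'
#' Weight divided by squared height in metres.
#'
#' @param weight_kg Weight in kilograms (> 0).
#' @param height_cm Height in centimetres (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
      any(!is.na(height_cm) & height_cm <= 0)) {
    stop("weight and height must be positive")
  }
  weight_kg / (height_cm / 100)^2
}
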