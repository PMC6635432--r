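# End-to-end orchestration: synth -> filter -> describe -> decode ->
# estimate -> summarize, with a machine-readable run manifest.

#' Published cohort sizes for the two app datasets
#'
#' Reference counts (users, cycles, observation-days) for the Sympto and
#' Kindara cohorts at each selection stage, as published for these datasets.
#' Useful as external input to [cohort_table()], whose derived statistics
#' (averages, percentages) can then be recomputed and checked against the
#' published table.
#'
#' @return Tibble in the [cohort_counts()] layout.
#' @export
published_cohort_counts <- function() {
  tibble::tribble(
    ~app,      ~stage,     ~n_users, ~n_cycles, ~n_obs_days,
    "sympto",  "full",       13674L,    79535L,    1622270L,
    "sympto",  "standard",    5860L,    39896L,     949358L,
    "sympto",  "reliable",    5116L,    28453L,     670989L,
    "kindara", "full",      199293L,  2652889L,   32053183L,
    "kindara", "standard",  125170L,   719182L,   15987512L,
    "kindara", "reliable",   27378L,    80708L,    2248666L
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: generate (or read) a cohort, filter to standard cycles,
#' compute descriptive profiles, decode every standard cycle with the HMM,
#' estimate ovulation with the reliability gate, and write cohort summaries.
#' All stage outputs land in `out_dir` as CSV, plus `manifest.json` recording
#' the seed, configuration digest and per-stage row counts (the selection
#' flowchart in numbers).
#'
#' @param out_dir Output directory (created if needed).
#' @param synth_config A [synthetic_config()]; alternatively supply
#'   `cycles_csv` to read an existing cohort.
#' @param cycles_csv Optional path to a dialect CSV to analyse instead of
#'   generating data.
#' @param dialect Dialect of the cohort.
#' @param hmm_spec An `hmm_spec`, or a YAML path for [read_hmm_spec()];
#'   `NULL` uses [default_hmm_spec()] for the dialect.
#' @param thresholds Reliability-gate thresholds.
#' @param verbose Log stage progress to stderr.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         synth_config = synthetic_config(),
                         cycles_csv = NULL,
                         dialect = "canonical",
                         hmm_spec = NULL,
                         thresholds = c(uncertainty = 1.5, temp_shift = 0.15,
                                        confidence = 0.75),
                         verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[cyclehmm] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (is.null(hmm_spec)) {
    hmm_spec <- default_hmm_spec(if (dialect == "sympto") "sympto" else dialect)
  } else if (is.character(hmm_spec)) {
    if (!file.exists(hmm_spec)) stop("HMM spec file not found: ", hmm_spec)
    hmm_spec <- read_hmm_spec(hmm_spec)
  }
  validate_hmm_spec(hmm_spec)

  if (is.null(cycles_csv)) {
    say("synth: generating %d users (seed %d)", synth_config$n_users,
        synth_config$rng_seed)
    cohort <- stage("synth", generate_cycles(synth_config, dialect))
    cycles <- cohort$cycles
    stage("synth", write_synthetic_cohort(cohort, file.path(out_dir, "synth"), dialect))
  } else {
    if (!file.exists(cycles_csv)) stop("cycles file not found: ", cycles_csv)
    say("read: %s (%s)", cycles_csv, dialect)
    cycles <- stage("read", read_cycles(cycles_csv, dialect))
  }

  say("filter: %d cycles", length(cycles))
  report <- stage("filter", filter_report(cycles))
  readr::write_csv(report, file.path(out_dir, "filter_report.csv"),
                   na = "", progress = FALSE)
  std <- cycles[report$standard]
  say("filter: %d standard cycles", length(std))

  say("describe: per-cycle-day profiles")
  stage("describe", {
    for (idx in c("from_start", "from_end")) {
      prof <- aggregate_profiles(std, indexing = idx)
      readr::write_csv(prof$delta_bbt,
                       file.path(out_dir, paste0("delta_bbt_", idx, ".csv")),
                       na = "", progress = FALSE)
      readr::write_csv(prof$frequencies,
                       file.path(out_dir, paste0("frequencies_", idx, ".csv")),
                       na = "", progress = FALSE)
    }
  })

  say("decode: %d standard cycles", length(std))
  decoded <- stage("decode", decode_cycles(std, hmm_spec))
  decoded_tbl <- dplyr::bind_rows(lapply(decoded, function(dc) {
    tibble::tibble(
      user_id = dc$user_id, cycle_index = dc$cycle_index,
      cycle_day = seq_along(dc$viterbi_path),
      viterbi_state = dc$viterbi_path,
      !!!stats::setNames(as.data.frame(dc$posterior),
                         paste0("p_", colnames(dc$posterior)))
    )
  }))
  readr::write_csv(decoded_tbl, file.path(out_dir, "decoded.csv"),
                   na = "", progress = FALSE)

  say("estimate: ovulation + reliability gate")
  estimates <- stage("estimate", estimate_cycles(std, decoded, thresholds))
  readr::write_csv(estimates, file.path(out_dir, "estimates.csv"),
                   na = "", progress = FALSE)

  say("summarize: cohort tables")
  counts <- stage("summarize", cohort_counts(cycles, report, estimates))
  tab <- cohort_table(counts)
  readr::write_csv(tab, file.path(out_dir, "cohort_table.csv"),
                   na = "", progress = FALSE)
  ph <- stage("summarize", phase_summary(estimates))
  if (ph$n > 0) {
    readr::write_csv(ph$durations, file.path(out_dir, "phase_durations.csv"),
                     na = "", progress = FALSE)
    aligned <- ovulation_aligned_profiles(decoded, estimates)
    readr::write_csv(aligned, file.path(out_dir, "ovulation_aligned_profiles.csv"),
                     na = "", progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cyclehmm")),
    dialect = dialect,
    seed = if (is.null(cycles_csv)) synth_config$rng_seed else NA,
    input = if (is.null(cycles_csv)) "synthetic" else unname(tools::md5sum(cycles_csv)),
    thresholds = as.list(thresholds),
    counts = list(
      total_cycles = length(cycles),
      standard_cycles = length(std),
      reliable_cycles = sum(estimates$reliable),
      n_users = length(unique(vapply(cycles, function(cy) cy$user_id, "")))
    ),
    phase_medians = if (ph$n > 0) as.list(ph$medians) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
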