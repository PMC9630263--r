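# End-to-end orchestration (simulate -> process -> stats) and the
# command-line entry point.

#' Run the full pipeline
#'
#' Simulates a session (or reads one from disk), processes every trial into
#' the 14 outcome variables, and runs the paired statistical analysis.
#' Deterministic given the configuration and seed; structured logs record
#' the filter cutoffs chosen per trial and every exclusion with a reason
#' code.
#'
#' @param config a list with optional elements:
#'   * `input_dir`: read trials from disk instead of simulating;
#'   * `session`: a [session_config()] (or list of its arguments);
#'   * `seed`: integer seed for the simulation (default 1);
#'   * `filter`: a [filter_config()] (or list of its arguments);
#'   * `onset_factor`, `contact_threshold_n`: impulse-phase thresholds;
#'   * `pairing_mode`, `d_method`, `designs`: see [run_analysis()];
#'   * `out_dir`: if set, write `trials/`, `results.csv` and `report.csv`
#'     there;
#'   * `log_file`: if set, append JSON-lines log records.
#' @return list with `results` (per-trial variables), `report`
#'   (the [run_analysis()] table), `exclusions`, `cutoffs` and `seed`.
#' @export
run_pipeline <- function(config = list()) {
  seed <- if (!is.null(config$seed)) config$seed else 1L
  fcfg <- config$filter
  if (is.null(fcfg)) fcfg <- filter_config()
  if (!inherits(fcfg, "filter_config")) fcfg <- do.call(filter_config, fcfg)
  if (!is.null(config$input_dir)) {
    trials <- read_trial_dir(config$input_dir)
  } else {
    scfg <- config$session
    if (is.null(scfg)) scfg <- session_config()
    if (!inherits(scfg, "session_config")) scfg <- do.call(session_config, scfg)
    trials <- simulate_session(scfg, seed = seed, compute_truth = FALSE)
  }
  onset <- if (!is.null(config$onset_factor)) config$onset_factor else 1.05
  thr <- if (!is.null(config$contact_threshold_n)) config$contact_threshold_n else 10
  results <- process_trials(trials, filter = fcfg, onset_factor = onset,
                            contact_threshold_n = thr)
  pairing <- if (!is.null(config$pairing_mode)) config$pairing_mode else "subject_mean"
  dmeth <- if (!is.null(config$d_method)) config$d_method else "pooled"
  designs <- if (!is.null(config$designs)) config$designs else
    c("rule", "laterality", "rule_within_dominant", "rule_within_nondominant")
  report <- run_analysis(results, designs = designs, pairing_mode = pairing,
                         d_method = dmeth)
  excl <- attr(results, "exclusions")
  cuts <- attr(results, "cutoffs")
  if (!is.null(config$log_file)) {
    con <- file(config$log_file, "a")
    on.exit(close(con))
    for (i in seq_len(nrow(excl)))
      writeLines(jsonlite::toJSON(c(list(event = "exclusion"),
                                    as.list(excl[i, ])), auto_unbox = TRUE), con)
    if (!is.null(cuts))
      for (i in seq_len(nrow(cuts)))
        writeLines(jsonlite::toJSON(c(list(event = "filter_cutoff"),
                                      as.list(cuts[i, ])), auto_unbox = TRUE),
                   con)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(config$input_dir))
      write_trial_dir(trials, file.path(config$out_dir, "trials"))
    write_results(results, file.path(config$out_dir, "results.csv"))
    utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
  }
  list(results = results, report = report, exclusions = excl,
       cutoffs = cuts, seed = seed)
}

cli_parse_flags <- function(args) {
  flags <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[[i + 1L]], "--"))
        stop("divekin: flag ", a, " needs a value")
      flags[[substring(a, 3L)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

cli_cutoff <- function(s) {
  if (is.null(s) || s == "auto") "auto"
  else if (s == "none") "none"
  else as.numeric(s)
}

#' Command-line interface
#'
#' Subcommands:
#' * `divekin simulate --out DIR [--seed N] [--config cfg.json]` -- write a
#'   synthetic session (per-trial `cm.csv`/`grf.csv`, `trials.json`,
#'   `truth.csv`);
#' * `divekin process --in DIR --out results.csv [--cutoff auto|none|HZ]` --
#'   compute the 14 variables per trial;
#' * `divekin stats --in results.csv --out report.csv
#'   [--pairing subject_mean|trial_matched] [--d pooled|paired_diff]` --
#'   run the paired comparisons.
#'
#' An executable wrapper is installed under `inst/cli/divekin`.
#'
#' @param args character vector of command-line arguments (default: the
#'   trailing arguments of the Rscript call).
#' @return the subcommand's main result, invisibly.
#' @export
divekin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: divekin simulate|process|stats [flags]")
  cmd <- args[[1L]]
  pa <- cli_parse_flags(args[-1L])
  fl <- pa$flags
  if (cmd == "simulate") {
    if (is.null(fl$out)) stop("divekin simulate: --out DIR is required")
    seed <- if (!is.null(fl$seed)) as.integer(fl$seed) else 1L
    scfg <- if (!is.null(fl$config)) {
      do.call(session_config, jsonlite::read_json(fl$config, simplifyVector = TRUE))
    } else session_config()
    trials <- simulate_session(scfg, seed = seed)
    write_trial_dir(trials, fl$out)
    message(sprintf("divekin: wrote %d trials to %s", length(trials), fl$out))
    invisible(trials)
  } else if (cmd == "process") {
    if (is.null(fl[["in"]]) || is.null(fl$out))
      stop("divekin process: --in DIR and --out results.csv are required")
    fcfg <- filter_config(cutoff_hz = cli_cutoff(fl$cutoff))
    trials <- read_trial_dir(fl[["in"]])
    results <- process_trials(trials, filter = fcfg)
    write_results(results, fl$out)
    excl <- attr(results, "exclusions")
    message(sprintf("divekin: %d trials analysed, %d excluded",
                    nrow(results), nrow(excl)))
    invisible(results)
  } else if (cmd == "stats") {
    if (is.null(fl[["in"]]) || is.null(fl$out))
      stop("divekin stats: --in results.csv and --out report.csv are required")
    results <- read_results(fl[["in"]])
    pairing <- if (!is.null(fl$pairing)) fl$pairing else "subject_mean"
    dmeth <- if (!is.null(fl$d)) fl$d else "pooled"
    report <- run_analysis(results, pairing_mode = pairing, d_method = dmeth)
    utils::write.csv(report, fl$out, row.names = FALSE)
    message(sprintf("divekin: wrote %d comparisons to %s", nrow(report), fl$out))
    invisible(report)
  } else {
    stop("divekin: unknown subcommand '", cmd,
         "' (expected simulate, process or stats)")
  }
}
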