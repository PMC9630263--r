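# Disk formats: a trials.json manifest plus per-trial cm.csv / grf.csv
# (units declared in the headers), a truth.csv ground-truth table for
# synthetic sessions, and the tidy results CSV.  Numbers are written with
# 17 significant digits so round trips are lossless to double precision.

CM_HEADER <- c("t[s]", "x[m]", "y[m]", "z[m]")
GRF_HEADER <- c("t[s]", "fx[N]", "fy[N]", "fz[N]")

write_numeric_csv <- function(df, path, header) {
  out <- vapply(df, function(col) formatC(col, digits = 17, format = "g"),
                character(nrow(df)))
  out <- matrix(out, nrow = nrow(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
}

read_numeric_csv <- function(path, expected_header) {
  if (!file.exists(path)) stop("missing file: ", path)
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  if (!identical(trimws(hdr), expected_header))
    stop(sprintf("%s: unit/column mismatch in header (expected '%s', found '%s')",
                 path, paste(expected_header, collapse = ","),
                 paste(hdr, collapse = ",")))
  df <- utils::read.csv(path, header = TRUE, col.names = expected_header,
                        check.names = FALSE)
  if (anyNA(df)) stop(path, ": malformed numeric rows (NA after parsing)")
  if (any(diff(df[[1L]]) <= 0)) stop(path, ": non-monotone time column")
  df
}

series_to_df <- function(s) {
  data.frame(t = series_time(s), s$values)
}

df_to_series <- function(df) {
  t <- df[[1L]]
  rate <- 1 / stats::median(diff(t))
  m <- as.matrix(df[, -1L])
  colnames(m) <- sub("\\[.*$", "", colnames(m))  # strip unit suffixes
  uniform_series(m, rate = rate, t0 = t[1L])
}

#' Write a session of trials to a directory
#'
#' Layout: `trials.json` manifest, one subdirectory per trial holding
#' `cm.csv` (`t[s],x[m],y[m],z[m]`) and `grf.csv` (`t[s],fx[N],fy[N],fz[N]`),
#' and, when ground truth is present, a `truth.csv` table.
#'
#' @param trials list of [trial_record()]s.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_trial_dir <- function(trials, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(trials, function(tr) {
    list(trial_id = tr$trial_id, subject_id = tr$subject_id,
         body_mass_kg = tr$body_mass_kg, rule = tr$rule, side = tr$side,
         iplag_score = tr$iplag_score, quality = tr$quality,
         dir = tr$trial_id)
  })
  jsonlite::write_json(manifest, file.path(path, "trials.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  truth_rows <- list()
  for (tr in trials) {
    td <- file.path(path, tr$trial_id)
    dir.create(td, showWarnings = FALSE)
    write_numeric_csv(series_to_df(tr$cm), file.path(td, "cm.csv"), CM_HEADER)
    write_numeric_csv(series_to_df(tr$grf), file.path(td, "grf.csv"), GRF_HEADER)
    if (!is.null(tr$truth)) {
      tv <- tr$truth
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        trial_id = tr$trial_id,
        as.list(vapply(dive_variable_names(), function(v) tv[[v]], numeric(1))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(truth_rows)) {
    tdf <- do.call(rbind, truth_rows)
    num <- vapply(tdf[-1L], function(col) formatC(col, digits = 17, format = "g"),
                  character(nrow(tdf)))
    utils::write.table(data.frame(trial_id = tdf$trial_id, num,
                                  check.names = FALSE),
                       file.path(path, "truth.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a directory of trials
#'
#' Validates the manifest and every channel file: unit-declaring headers,
#' monotone time, no missing samples.  Malformed trials are rejected with a
#' diagnostic naming the file.
#'
#' @param path directory written by [write_trial_dir()] (or matching its
#'   layout).
#' @return list of [trial_record()]s.
#' @export
read_trial_dir <- function(path) {
  mf <- file.path(path, "trials.json")
  if (!file.exists(mf)) stop("read_trial_dir: no trials.json manifest in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  lapply(manifest, function(m) {
    td <- file.path(path, m$dir)
    cm <- tryCatch(df_to_series(read_numeric_csv(file.path(td, "cm.csv"),
                                                 CM_HEADER)),
                   error = function(e) stop(sprintf(
                     "read_trial_dir: trial '%s': %s", m$trial_id,
                     conditionMessage(e)), call. = FALSE))
    grf <- tryCatch(df_to_series(read_numeric_csv(file.path(td, "grf.csv"),
                                                  GRF_HEADER)),
                    error = function(e) stop(sprintf(
                      "read_trial_dir: trial '%s': %s", m$trial_id,
                      conditionMessage(e)), call. = FALSE))
    trial_record(m$trial_id, m$subject_id, m$body_mass_kg, m$rule, m$side,
                 m$iplag_score, m$quality, cm = cm, grf = grf)
  })
}

#' Write / read the tidy results table
#'
#' One row per analysed trial: identifiers, metadata and the 14 outcome
#' variables.  Units are documented in `#`-prefixed header comments; the
#' round trip is lossless to double precision.
#'
#' @param rows data.frame from [process_trials()].
#' @param path CSV file path.
#' @return `path` invisibly (write) / the parsed data.frame (read).
#' @export
write_results <- function(rows, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("write_results: cannot open ", path))
  on.exit(close(con))
  writeLines(c("# divekin trial results",
               "# units: VD,MLD,APD,RD in m; AV,PV in m/s; VPF,MLPF,APPF,RPF in xBW; VI,MLI,API,RI in xBW.s"),
             con)
  num_cols <- vapply(rows, is.numeric, logical(1))
  out <- rows
  for (j in which(num_cols))
    out[[j]] <- formatC(rows[[j]], digits = 17, format = "g")
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("read_results: missing file ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (v in intersect(c("body_mass_kg", dive_variable_names()), names(df)))
    df[[v]] <- as.numeric(df[[v]])
  df
}

#' Read a ground-truth table
#'
#' @param path `truth.csv` written by [write_trial_dir()].
#' @return data.frame with `trial_id` and the 14 exact outcome values.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in dive_variable_names()) df[[v]] <- as.numeric(df[[v]])
  df
}
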