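# Patch-clamp diary: JSONL event log of patch attempts and report
# generation.

#' Append a patch attempt record to the diary
#'
#' One JSON line per attempt; the round trip through [read_diary()] is
#' lossless field-for-field.
#'
#' @param record a `patch_attempt_record` from [run_autopatch()].
#' @param path diary file (JSON Lines); created if absent.
#' @return `path`, invisibly.
#' @export
diary_append <- function(record, path) {
  stopifnot(inherits(record, "patch_attempt_record"))
  payload <- list(target_um = record$target_um, outcome = record$outcome,
                  Rs_Mohm = record$Rs_Mohm, phase_log = record$phase_log)
  line <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", dataframe = "rows")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(as.character(line), con)
  invisible(path)
}

#' Read the diary back
#'
#' Corrupt lines are skipped with a warning and counted in the
#' `n_corrupt` attribute.
#'
#' @param path diary file.
#' @return A list of `patch_attempt_record` objects.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stopf("no such diary: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  n_corrupt <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$outcome)) {
      n_corrupt <- n_corrupt + 1L
      warnf("skipping corrupt diary line %d", i)
      next
    }
    out[[length(out) + 1]] <- structure(
      list(target_um = as.numeric(rec$target_um), outcome = rec$outcome,
           Rs_Mohm = if (is.null(rec$Rs_Mohm)) NA_real_ else as.numeric(rec$Rs_Mohm),
           phase_log = as.data.frame(rec$phase_log)),
      class = "patch_attempt_record")
  }
  attr(out, "n_corrupt") <- n_corrupt
  out
}

#' Aggregate the diary into a report
#'
#' Counts attempts per outcome class and averages per-phase durations;
#' optionally writes the report as JSON and the outcome table as CSV.
#'
#' @param diary_path diary file.
#' @param report_path optional output path (without extension); when given,
#'   `<report_path>.json` and `<report_path>.csv` are written.
#' @return A list with `n_attempts`, `n_corrupt`, `outcomes` (data frame
#'   `outcome, n`), `mean_Rs_Mohm` over successful attempts and
#'   `phase_durations_s` (data frame `phase, mean_s`).
#' @export
generate_report <- function(diary_path, report_path = NULL) {
  recs <- read_diary(diary_path)
  outc <- vapply(recs, `[[`, character(1), "outcome")
  tab <- as.data.frame(table(outcome = outc), stringsAsFactors = FALSE)
  names(tab) <- c("outcome", "n")
  rs <- vapply(recs, function(r)
    if (identical(r$outcome, "WHOLE_CELL")) r$Rs_Mohm else NA_real_,
    numeric(1))
  dur <- do.call(rbind, lapply(recs, function(r) {
    lg <- r$phase_log
    if (!nrow(lg)) return(NULL)
    agg <- stats::aggregate(time_s ~ phase, data = lg,
                            FUN = function(t) max(t) - min(t))
    names(agg) <- c("phase", "dur_s")
    agg
  }))
  phase_dur <- if (!is.null(dur) && nrow(dur)) {
    m <- stats::aggregate(dur_s ~ phase, data = dur, FUN = mean)
    names(m) <- c("phase", "mean_s")
    m
  } else data.frame(phase = character(), mean_s = numeric())
  rep <- list(n_attempts = length(recs),
              n_corrupt = attr(recs, "n_corrupt") %||% 0L,
              outcomes = tab,
              mean_Rs_Mohm = if (any(!is.na(rs))) mean(rs, na.rm = TRUE) else NA_real_,
              phase_durations_s = phase_dur)
  if (!is.null(report_path)) {
    jsonlite::write_json(rep, paste0(report_path, ".json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    utils::write.csv(tab, paste0(report_path, ".csv"), row.names = FALSE)
  }
  rep
}
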