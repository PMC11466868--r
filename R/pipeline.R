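# End-to-end orchestration: preprocess every recognized signal file in a day
# directory, extract the kind's full feature catalogue, write features, gap
# reports and a run manifest. Per-signal failures are isolated so one corrupt
# stream never blocks the others.

#' Extract the full feature catalogue for one preprocessed signal
#'
#' Dispatches on the signal kind: heart rate / beat-to-beat intervals get the
#' HRV catalogue, SpO2 the oximetry catalogue, respiration rate the
#' breath-to-breath catalogue. Cumulative counters report the daily total and
#' per-interval summaries; intensity minutes passes through as a daily
#' scalar.
#'
#' @param signal A preprocessed regular [ts_signal()] (or the raw daily
#'   summary for intensity minutes).
#' @param config A [pipeline_config()].
#' @return A [feature_record()].
#' @export
extract_features <- function(signal, config = pipeline_config()) {
  info <- kind_info(signal$kind)
  if (signal$kind %in% c("heart_rate", "bbi")) {
    return(hrv_features(signal, config))
  }
  if (signal$kind == "spo2") return(spo2_features(signal, config))
  if (signal$kind == "respiration_rate") return(resp_features(signal, config))
  v <- signal$values[!is.na(signal$values)]
  if (info$aggregation == "cumulative") {
    total <- attr(signal, "daily_total")
    if (is.null(total) || is.na(total)) total <- sum(v)
    feats <- list(Total = total,
                  Max_Interval = if (length(v)) max(v) else NA_real_,
                  Mean_Interval = if (length(v)) mean(v) else NA_real_,
                  Active_Intervals = sum(v > 0))
  } else {  # intensity_minutes daily summary: pass-through scalar
    feats <- list(Total = if (length(v)) v[length(v)] else NA_real_)
  }
  feature_record(signal$kind, signal$day, feats,
                 metadata = list(n_samples = length(v)))
}

#' Run the full pipeline over a day directory
#'
#' Looks for one file per signal (`<kind>.csv` or `<kind>.json`) in
#' `input_dir`, preprocesses each per its kind, extracts the kind's feature
#' catalogue, and writes per-signal feature CSVs, gap reports, a combined
#' JSON feature file and a run manifest into `output_dir`. Missing signals
#' are skipped with a notice; a failing signal is logged and the others are
#' still processed.
#'
#' @param input_dir Directory with per-signal day files.
#' @param output_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The run manifest (invisibly): config snapshot, per-signal
#'   preprocessing reports, output paths, package version, seed, and a
#'   `status` of `"ok"`, `"partial"` or `"failed"`.
#' @export
run_pipeline <- function(input_dir, output_dir, config = pipeline_config()) {
  kinds <- signal_kinds()$kind
  paths <- stats::setNames(rep(NA_character_, length(kinds)), kinds)
  for (k in kinds) {
    for (ext in c("csv", "json")) {
      p <- file.path(input_dir, paste0(k, ".", ext))
      if (file.exists(p)) { paths[k] <- p; break }
    }
  }
  if (all(is.na(paths))) {
    stop("no recognized signal files in ", input_dir,
         " (expected <kind>.csv or <kind>.json)", call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  records <- list(); reports <- list(); failures <- character()
  outputs <- list()
  for (k in kinds) {
    if (is.na(paths[k])) {
      message("signal '", k, "' not present; skipped")
      next
    }
    res <- tryCatch({
      raw <- read_signal(paths[k], k)
      pp <- preprocess(raw, config)
      rec <- extract_features(pp$signal, config)
      fpath <- file.path(output_dir, paste0(k, "_features.csv"))
      write_features(list(rec), fpath, "csv")
      gpath <- file.path(output_dir, paste0(k, "_gaps.csv"))
      write_gap_report(pp$report$gaps, gpath)
      ev <- attr(rec, "events")
      if (!is.null(ev)) {
        utils::write.csv(ev, file.path(output_dir, paste0(k, "_events.csv")),
                         row.names = FALSE)
      }
      list(record = rec, report = pp$report,
           files = list(features = fpath, gaps = gpath))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("signal '", k, "' failed: ", conditionMessage(res),
              call. = FALSE)
      failures <- c(failures, k)
    } else {
      records[[k]] <- res$record
      reports[[k]] <- res$report[c("n_raw", "n_grid", "n_filled",
                                   "n_unfilled", "denoise_window_used")]
      outputs[[k]] <- res$files
    }
  }
  if (length(records) > 0) {
    write_features(unname(records),
                   file.path(output_dir, "features.json"), "json")
  }
  manifest <- list(
    config = config[setdiff(names(config), "spectral_bands")],
    spectral_bands = config$spectral_bands,
    reports = reports,
    outputs = outputs,
    failures = failures,
    version = as.character(utils::packageVersion("wearsig")),
    seed = config$rng_seed,
    status = if (length(records) == 0) "failed"
             else if (length(failures) > 0) "partial" else "ok"
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
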