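# File I/O: signal ingestion with plausibility filtering, feature-record
# serialization, gap reports. Timestamps on disk are ISO-8601 local times
# ("YYYY-MM-DDTHH:MM:SS[.ffffff]", "T" or space separator); in memory they are
# seconds since local midnight of the covered day.

# Parse ISO-8601 local timestamps to (day, seconds-since-midnight) without
# going through POSIXct, so fractional seconds survive exactly.
parse_iso_local <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}):(\\d{2}):(\\d{2}(?:\\.\\d+)?)$", x))
  bad <- vapply(m, length, 1L) != 5L
  day <- rep(NA_character_, length(x))
  secs <- rep(NA_real_, length(x))
  ok <- which(!bad)
  if (length(ok) > 0) {
    parts <- do.call(rbind, m[ok])
    day[ok] <- parts[, 2]
    secs[ok] <- as.numeric(parts[, 3]) * 3600 +
      as.numeric(parts[, 4]) * 60 + as.numeric(parts[, 5])
  }
  list(day = day, seconds = secs, bad = which(bad))
}

format_iso_local <- function(day, seconds) {
  if (is.na(day)) day <- "1970-01-01"
  h <- floor(seconds / 3600)
  m <- floor((seconds - 3600 * h) / 60)
  s <- seconds - 3600 * h - 60 * m
  # drop trailing zeros in fractional seconds but keep whole seconds as SS
  ss <- sprintf("%09.6f", s)
  ss <- sub("\\.?0+$", "", ss)
  if (!grepl("\\.", ss) && nchar(ss) < 2) ss <- sprintf("%02d", as.integer(s))
  sprintf("%sT%02d:%02d:%s", day, h, m, ss)
}

#' Read one signal-day from a CSV or JSON export
#'
#' CSV files carry a `timestamp,value` header with ISO-8601 local timestamps;
#' JSON files carry a single object `{signal_type: [[timestamp, value], ...]}`
#' from which the requested kind is taken. The file must cover a single
#' calendar day. Values outside the physiological plausibility range of the
#' kind (heart rate 20-250 bpm, SpO2 50-100%, respiration 4-60 breaths/min,
#' counters non-negative) are dropped with a warning. Cumulative counters
#' (steps, calories) are converted from running totals to per-interval
#' increments; decreases (counter resets) are clipped at zero.
#'
#' @param path Path to the file.
#' @param kind Signal kind name.
#' @return An irregular [ts_signal()]; for cumulative kinds the values are
#'   per-interval increments and the daily total is kept in the
#'   `daily_total` attribute.
#' @export
read_signal <- function(path, kind) {
  info <- kind_info(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- obj[[kind]]
    if (is.null(rows)) stop("no data for signal '", kind, "' in ", path,
                            call. = FALSE)
    ts_raw <- vapply(rows, function(r) as.character(r[[1]]), "")
    val_raw <- vapply(rows, function(r) as.character(r[[2]]), "")
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    if (!all(c("timestamp", "value") %in% names(df))) {
      stop("expected columns 'timestamp,value' in ", path, call. = FALSE)
    }
    ts_raw <- df$timestamp
    val_raw <- df$value
  }
  if (length(ts_raw) == 0) stop("no data", call. = FALSE)

  parsed <- parse_iso_local(ts_raw)
  if (length(parsed$bad) > 0) {
    stop("unparseable timestamp at row ", parsed$bad[1], ": '",
         ts_raw[parsed$bad[1]], "'", call. = FALSE)
  }
  values <- suppressWarnings(as.numeric(val_raw))
  if (anyNA(values)) {
    stop("unparseable value at row ", which(is.na(values))[1], ": '",
         val_raw[which(is.na(values))[1]], "'", call. = FALSE)
  }
  if (length(unique(parsed$day)) > 1) {
    stop("file mixes calendar days (", paste(unique(parsed$day), collapse = ", "),
         "); split input per day before reading", call. = FALSE)
  }
  tsec <- parsed$seconds
  if (length(tsec) > 1 && any(diff(tsec) <= 0)) {
    bad <- which(diff(tsec) <= 0)[1] + 1L
    stop("timestamps out of order at row ", bad, call. = FALSE)
  }

  # plausibility filter (never reorders survivors)
  keep <- values >= info$lo & values <= info$hi
  if (any(!keep)) {
    warning(sum(!keep), " value(s) outside plausible range [", info$lo, ", ",
            info$hi, "] dropped for ", kind, call. = FALSE)
    tsec <- tsec[keep]; values <- values[keep]
  }
  if (length(values) == 0) stop("no data", call. = FALSE)

  daily_total <- NA_real_
  if (info$aggregation == "cumulative") {
    if (any(diff(values) < 0)) {
      warning("cumulative ", kind,
              " counter decreases; resets clipped at zero", call. = FALSE)
    }
    daily_total <- values[length(values)]
    values <- pmax(0, diff(c(0, values)))
  }
  sig <- ts_signal(kind, tsec, values, is_regular = FALSE,
                   day = unique(parsed$day))
  attr(sig, "daily_total") <- daily_total
  sig
}

#' Write a signal-day to CSV
#'
#' Only present samples are written (absent grid points are omitted), as
#' `timestamp,value` rows with ISO-8601 local timestamps.
#'
#' @param signal A [ts_signal()].
#' @param path Output path.
#' @export
write_signal <- function(signal, path) {
  p <- present_samples(signal)
  ts <- vapply(p$timestamps, function(t) format_iso_local(signal$day, t), "")
  utils::write.csv(data.frame(timestamp = ts, value = p$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a feature record
#'
#' One record holds the named feature map for one signal on one day, plus
#' provenance metadata (raw/filled sample counts, unfilled gap seconds).
#' Undefined features are `NULL` and serialize as JSON null / empty CSV cell,
#' never as 0.
#'
#' @param kind Signal kind name.
#' @param day Day identifier.
#' @param features Named list; elements numeric scalars or `NULL`.
#' @param metadata Named list of provenance counts.
#' @return An object of class `feature_record`.
#' @export
feature_record <- function(kind, day, features, metadata = list()) {
  stopifnot(is.list(features))
  structure(list(kind = kind, day = day, features = features,
                 metadata = metadata),
            class = "feature_record")
}

#' @export
print.feature_record <- function(x, ...) {
  cat("<feature_record>", x$kind, "day", x$day, "-",
      length(x$features), "features\n")
  vals <- vapply(x$features, function(v)
    if (is.null(v) || is.na(v)) "null" else format(v, digits = 6), "")
  print(vals, quote = FALSE)
  invisible(x)
}

#' Write feature records to CSV or JSON
#'
#' CSV output has one row per (day, signal) and one column per feature; JSON
#' mirrors the record structure (kind, day, features, metadata). Null features
#' become empty CSV cells / JSON nulls.
#'
#' @param records A list of [feature_record()] objects (or a single one).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_features <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(records, "feature_record")) records <- list(records)
  if (length(records) == 0) stop("records must be non-empty", call. = FALSE)
  if (format == "json") {
    payload <- lapply(records, function(r) {
      feats <- lapply(r$features, function(v)
        if (is.null(v) || is.na(v)) NULL else v)
      list(kind = r$kind, day = r$day, features = feats,
           metadata = r$metadata)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    all_names <- unique(unlist(lapply(records, function(r) names(r$features))))
    rows <- lapply(records, function(r) {
      vals <- vapply(all_names, function(nm) {
        v <- r$features[[nm]]
        if (is.null(v) || is.na(v)) "" else format(v, digits = 15)
      }, "")
      c(day = r$day, signal = r$kind, vals)
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' Read feature records back from JSON
#'
#' Inverse of [write_features()] with `format = "json"`.
#' @param path Path to a JSON feature file.
#' @return List of [feature_record()] objects.
#' @export
read_features <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    feats <- lapply(r$features, function(v) if (is.null(v)) NULL else as.numeric(v))
    feature_record(r$kind, r$day, feats, lapply(r$metadata, unlist))
  })
}

#' Write a gap report to CSV
#'
#' @param gaps List of gap segments from [detect_gaps()].
#' @param path Output path.
#' @export
write_gap_report <- function(gaps, path) {
  df <- gaps_as_data_frame(gaps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

gaps_as_data_frame <- function(gaps) {
  if (length(gaps) == 0) {
    return(data.frame(start = numeric(), end = numeric(),
                      duration_s = numeric(), n_missing = integer(),
                      filled = logical()))
  }
  data.frame(
    start = vapply(gaps, `[[`, 0, "start"),
    end = vapply(gaps, `[[`, 0, "end"),
    duration_s = vapply(gaps, `[[`, 0, "duration"),
    n_missing = vapply(gaps, `[[`, 0L, "n_missing"),
    filled = vapply(gaps, `[[`, TRUE, "fillable")
  )
}
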