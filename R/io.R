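#' Event annotation table
#'
#' Annotations are the segmentation boundaries: a UTC timestamp for every
#' scenario node transition (web-based virtual-patient session) or
#' coordinator gesture (mixed-reality session), plus session start/end marks.
#'
#' @param time_utc Numeric vector, UTC epoch seconds.
#' @param label Character vector of free-text labels.
#' @param kind Character vector; each element one of `"node_transition"`,
#'   `"gesture"`, `"session_start"`, `"session_end"`.
#' @return Tibble with columns `time_utc`, `label`, `kind`, sorted by time.
#'   Unsorted input is sorted with a warning; duplicate timestamps are an
#'   integrity error (segments would degenerate).
#' @export
event_annotations <- function(time_utc, label, kind) {
  kinds <- c("node_transition", "gesture", "session_start", "session_end")
  if (!all(kind %in% kinds)) {
    abort_format(paste0("annotation kind must be one of: ", paste(kinds, collapse = ", ")))
  }
  if (anyDuplicated(time_utc)) abort_integrity("duplicate annotation timestamps")
  if (is.unsorted(time_utc)) {
    warning("annotations not sorted by time_utc; sorting", call. = FALSE)
    o <- order(time_utc)
    time_utc <- time_utc[o]; label <- label[o]; kind <- kind[o]
  }
  tibble::tibble(time_utc = as.numeric(time_utc),
                 label = as.character(label),
                 kind = as.character(kind))
}

# stream CSV dialect: '#key=value' metadata header then one sample per line.
# Kept deliberately plain so fixtures stay human-auditable.

#' Write a biosignal stream to CSV
#'
#' The on-disk dialect is a `#key=value` metadata header (modality, channel,
#' rate, start_utc, units) followed by one sample per line under a `value`
#' column.
#'
#' @param stream A [biosignal_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  header <- c(
    sprintf("#modality=%s", stream$modality),
    sprintf("#channel=%s", stream$channel),
    sprintf("#rate=%.17g", stream$rate),
    sprintf("#start_utc=%.17g", stream$start_utc),
    sprintf("#units=%s", stream_units[[stream$modality]]),
    "value"
  )
  # %.17g round-trips IEEE doubles exactly
  writeLines(c(header, sprintf("%.17g", stream$samples)), path)
  invisible(path)
}

#' Read a biosignal stream from CSV
#'
#' @param path File in the stream CSV dialect (see [write_stream()]).
#' @param modality Expected modality; a mismatch with the header is an
#'   integrity error.
#' @param expected_rate Optional rate override. By default HR must be 1 Hz,
#'   EDA 4 Hz and EEG 256 Hz (the acquisition rates of the wearable rig);
#'   pass a different value when a session manifest overrides them.
#' @return A [biosignal_stream()].
#' @export
read_stream <- function(path, modality, expected_rate = NULL) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  kv <- strsplit(sub("^#", "", meta), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  names(vals) <- keys
  need <- c("modality", "channel", "rate", "start_utc")
  if (!all(need %in% keys)) {
    abort_format(paste0("stream header missing field(s): ",
                        paste(setdiff(need, keys), collapse = ", ")))
  }
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) > 0 && body[1] == "value") body <- body[-1]
  if (length(body) == 0L) abort_format("stream file has an empty samples section")
  if (!is.null(modality) && vals[["modality"]] != modality) {
    abort_integrity(sprintf("expected modality %s, file says %s", modality, vals[["modality"]]))
  }
  rate <- as.numeric(vals[["rate"]])
  default_rates <- c(EEG = 256, HR = 1, EDA = 4)
  check_rate <- if (is.null(expected_rate)) default_rates[[vals[["modality"]]]] else expected_rate
  if (!isTRUE(all.equal(rate, check_rate))) {
    abort_integrity(sprintf("%s stream rate %g does not match expected %g (override via expected_rate)",
                            vals[["modality"]], rate, check_rate))
  }
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) abort_format("non-numeric sample values in stream file")
  biosignal_stream(vals[["modality"]], samples, rate,
                   as.numeric(vals[["start_utc"]]), vals[["channel"]])
}

#' Read a wristband-style stream CSV
#'
#' Dialect used by common wearable exports: first row is the UTC epoch start
#' time, second row the sampling rate, remaining rows the samples.
#'
#' @inheritParams read_stream
#' @param channel Channel label to attach.
#' @return A [biosignal_stream()].
#' @export
read_stream_wristband <- function(path, modality, channel = NULL) {
  vals <- suppressWarnings(as.numeric(readLines(path)))
  if (length(vals) < 3L || anyNA(vals[1:2])) {
    abort_format("wristband CSV needs start row, rate row, then samples")
  }
  biosignal_stream(modality, vals[-(1:2)], rate = vals[2],
                   start_utc = vals[1], channel = channel)
}

#' Write / read event annotations
#'
#' Plain CSV with columns `time_utc,label,kind`.
#'
#' @param annotations Tibble from [event_annotations()].
#' @param path File path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns the annotation tibble (sorted, validated).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_utc", "label", "kind")
  if (!all(need %in% names(df))) {
    abort_format("annotation CSV must have columns time_utc,label,kind")
  }
  event_annotations(df$time_utc, df$label, df$kind)
}

#' Write / read a session to a directory
#'
#' Serializes each stream and the annotations as CSV next to a YAML manifest
#' (`manifest.yaml`: participant_id, group, session_kind, file names).
#'
#' @param recording A [session_recording()].
#' @param dir Session directory (created if missing).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns the [session_recording()].
#' @export
write_session <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (s in recording$streams) {
    fn <- sprintf("%s_%s.csv", tolower(s$modality), s$channel)
    write_stream(s, file.path(dir, fn))
    files[[length(files) + 1L]] <- list(file = fn, modality = s$modality, rate = s$rate)
  }
  write_annotations(recording$annotations, file.path(dir, "annotations.csv"))
  manifest <- list(
    participant_id = recording$participant_id,
    group = recording$group,
    session_kind = recording$session_kind,
    streams = files,
    annotations = "annotations.csv"
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) abort_format(paste0("no manifest.yaml in ", dir))
  manifest <- yaml::read_yaml(mf)
  streams <- lapply(manifest$streams, function(e) {
    read_stream(file.path(dir, e$file), e$modality, expected_rate = e$rate)
  })
  annotations <- read_annotations(file.path(dir, manifest$annotations))
  session_recording(manifest$participant_id, manifest$group,
                    manifest$session_kind, streams, annotations)
}
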