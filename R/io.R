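#' Multichannel EEG recording container
#'
#' @param data channels-by-samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channel_labels unique channel names (10-10 convention for scalp
#'   EEG).
#' @param meta free-form provenance list.
#' @return object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, meta = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(fs), fs > 0)
  if (any(!is.finite(data)))
    stop("recording contains non-finite samples")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (length(channel_labels) != nrow(data))
    stop("one label per channel required")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz (", round(ncol(x$data) / x$fs, 2), "s )\n")
  cat("  channels:", paste(head(x$channel_labels, 8), collapse = " "),
      if (length(x$channel_labels) > 8) "...\n" else "\n")
  invisible(x)
}

#' Read / write recordings as CSV with a JSON sidecar
#'
#' The on-disk form is a plain CSV matrix (one column per channel, header =
#' channel labels) plus a `<path>.json` sidecar holding the sampling rate
#' and metadata.  A recording without a sidecar can be read by passing `fs`
#' explicitly.
#'
#' @param path CSV file path.
#' @param format currently `"csv"`; requesting an unknown format is an
#'   error.
#' @param fs sampling rate override (required when no sidecar exists).
#' @return `read_recording`: an `eeg_recording`.  `write_recording`: the
#'   path, invisibly.
#' @export
read_recording <- function(path, format = "csv", fs = NULL) {
  if (!identical(format, "csv"))
    stop("unsupported recording format: '", format,
         "' (only 'csv' is available)")
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(sidecar)
    if (is.null(fs)) fs <- side$fs
    meta <- if (!is.null(side$meta)) as.list(side$meta) else list()
  }
  if (is.null(fs))
    stop("sampling rate `fs` is missing: supply it or provide the ",
         "sidecar ", sidecar)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- t(as.matrix(df))
  if (any(!is.finite(m)))
    stop("recording contains non-finite samples")
  recording(m, fs = fs, channel_labels = colnames(df), meta = meta)
}

#' @rdname read_recording
#' @param rec an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_labels = rec$channel_labels,
                            meta = rec$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write event interval lists as TSV
#'
#' Columns: `onset_s`, `offset_s`, `duration_s`, `source`.
#'
#' @param events an [event_list()].
#' @param path TSV file path.
#' @return `read_events`: an [event_list()]. `write_events`: the path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  df <- data.frame(onset_s = events$onset, offset_s = events$offset,
                   duration_s = events$offset - events$onset,
                   source = attr(events, "source"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("onset_s", "offset_s") %in% names(df)))
    stop("event file must have onset_s and offset_s columns")
  src <- if ("source" %in% names(df) && nrow(df) > 0L) df$source[1L]
         else "file"
  event_list(df$onset_s, df$offset_s, source = src)
}

#' Serialize a comparison summary as JSON
#'
#' @param cmp a `comparison_summary` from [compare_labels()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_summary_json <- function(cmp, path) {
  stopifnot(inherits(cmp, "comparison_summary"))
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
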