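#' Multichannel EEG recording
#'
#' Lightweight container for a labeled channels-by-samples matrix at a known
#' sampling rate. This is the raw unit of input for the preprocessing
#' pipeline.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channel_labels Character vector, one unique label per row.
#' @param fs Sampling rate in Hz.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, fs) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (nrow(data) < 1L) stop("recording needs at least one channel")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("need one channel label per data row (got ", length(channel_labels),
         " labels for ", nrow(data), " rows)")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel label: ",
         channel_labels[duplicated(channel_labels)][1L])
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels, fs = fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Five-second EEG segment
#'
#' One classification sample: a 19 x 640 matrix (19 canonical channels, 5 s
#' at 128 Hz), optionally carrying its class label and provenance.
#'
#' @param data 19 x 640 numeric matrix in canonical channel order.
#' @param fs Sampling rate (must be 128).
#' @param label Optional class label, 0 (control) or 1 (case).
#' @param subject_id Optional subject identifier.
#' @param segment_index Optional 0-based index within the subject.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs = 128, label = NA_integer_,
                        subject_id = NA_character_, segment_index = NA_integer_) {
  data <- as.matrix(data)
  if (nrow(data) != 19L)
    stop("segment must have exactly 19 channels, got ", nrow(data))
  if (ncol(data) != 640L)
    stop("segment must have exactly 640 samples per channel, got ", ncol(data))
  if (!all(is.finite(data))) stop("segment contains non-finite samples")
  if (fs != 128) stop("segments are defined at 128 Hz")
  if (!is.na(label) && !label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(data = data, fs = 128, label = as.integer(label),
                 subject_id = subject_id,
                 segment_index = as.integer(segment_index)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> 19 x 640 @ 128 Hz (subject %s, index %s, label %s)\n",
              x$subject_id, x$segment_index, x$label))
  invisible(x)
}
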