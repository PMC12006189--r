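# Preprocessing: montage harmonization, zero-phase bandpass, resampling to
# 128 Hz, and non-overlapping 5-s segmentation.

#' Harmonize channel names to the canonical 19-channel montage
#'
#' Renames the modern temporo-parietal labels T7/P7/P8/T8 to their older
#' equivalents T3/T5/T6/T4 and reorders the rows into the canonical order
#' of [canonical_montage()].
#'
#' @param rec An [eeg_recording()] whose labels are drawn from either
#'   naming convention.
#' @return An [eeg_recording()] with canonical labels and ordering.
#' @export
harmonize_montage <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  labs <- rec$channel_labels
  renamed <- ifelse(labs %in% names(.montage_synonyms),
                    .montage_synonyms[labs], labs)
  if (anyDuplicated(renamed))
    stop("duplicate channel after renaming: ",
         renamed[duplicated(renamed)][1L])
  canon <- canonical_montage()
  unknown <- setdiff(renamed, canon)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(canon, renamed)
  if (length(missing))
    stop("missing canonical channel(s): ", paste(missing, collapse = ", "))
  ord <- match(canon, renamed)
  eeg_recording(rec$data[ord, , drop = FALSE], canon, rec$fs)
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the filter has zero phase: inter-channel
#' phase relations -- the quantity the phase lag index measures -- are not
#' distorted.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @return Filtered [eeg_recording()] of the same shape.
#' @export
bandpass <- function(rec, low = 0.5, high = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= rec$fs / 2)
    stop("high edge ", high, " Hz is at or above Nyquist (fs = ", rec$fs,
         " Hz)")
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  eeg_recording(out, rec$channel_labels, rec$fs)
}

# Fourier-domain resampling: truncates the spectrum at the new Nyquist
# frequency (ideal anti-aliasing) and inverts at the new length. Exact for
# band-limited signals, which is what the bandpass stage guarantees.
fft_resample <- function(x, fs, target_fs) {
  n <- length(x)
  m <- round(n * target_fs / fs)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  Y[1] <- X[1]
  kpos <- seq_len(min(ceiling(m / 2) - 1L, n %/% 2))
  Y[1 + kpos] <- X[1 + kpos]
  Y[m + 1 - kpos] <- X[n + 1 - kpos]
  if (m %% 2 == 0 && m / 2 + 1 <= n - n %/% 2) Y[m / 2 + 1] <- Re(X[m / 2 + 1])
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording to a lower rate
#'
#' Fourier-domain resampling with ideal anti-aliasing. Only downsampling
#' (or the identity) is supported; the pipeline never upsamples.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target rate in Hz (default 128).
#' @return An [eeg_recording()] at `target_fs`, duration preserved to
#'   within one sample.
#' @export
resample_recording <- function(rec, target_fs = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("upsampling from ", rec$fs, " to ", target_fs,
         " Hz is not supported")
  if (target_fs == rec$fs) return(rec)
  out <- t(apply(rec$data, 1L, fft_resample, fs = rec$fs,
                 target_fs = target_fs))
  eeg_recording(out, rec$channel_labels, target_fs)
}

#' Split a recording into non-overlapping 5-s segments
#'
#' Requires a harmonized 19-channel recording at 128 Hz. Produces
#' `floor(duration / window_s)` segments of exactly 640 samples; a trailing
#' partial window is discarded.
#'
#' @param rec An [eeg_recording()] at 128 Hz with canonical channels.
#' @param window_s Window length in seconds (default 5).
#' @param label,subject_id Carried into each [eeg_segment()].
#' @return List of [eeg_segment()]s (possibly empty), `segment_index`
#'   sequential from 0.
#' @export
segment_recording <- function(rec, window_s = 5, label = NA_integer_,
                              subject_id = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs != 128) stop("segmentation expects a 128 Hz recording")
  if (!identical(rec$channel_labels, canonical_montage()))
    stop("segmentation expects the harmonized canonical montage")
  win <- as.integer(round(window_s * rec$fs))
  nseg <- ncol(rec$data) %/% win
  if (nseg == 0L) {
    message("recording shorter than one window; no segments produced")
    return(list())
  }
  lapply(seq_len(nseg) - 1L, function(i) {
    eeg_segment(rec$data[, (i * win + 1):((i + 1) * win), drop = FALSE],
                fs = 128, label = label, subject_id = subject_id,
                segment_index = i)
  })
}

#' Full preprocessing pipeline for one recording
#'
#' Fixed order: harmonize montage, bandpass, resample to 128 Hz, segment.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Bandpass edges in Hz.
#' @param target_fs Target rate (128).
#' @param window_s Segment length in seconds.
#' @param label,subject_id Carried into the segments.
#' @return List of [eeg_segment()]s.
#' @export
preprocess_recording <- function(rec, low = 0.5, high = 60, target_fs = 128,
                                 window_s = 5, label = NA_integer_,
                                 subject_id = NA_character_) {
  rec <- harmonize_montage(rec)
  rec <- bandpass(rec, low, high)
  rec <- resample_recording(rec, target_fs)
  segment_recording(rec, window_s, label = label, subject_id = subject_id)
}
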