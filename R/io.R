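# Readers and writers: delimited-text recordings, cohort manifests,
# connectivity TSVs, brain-network viewer exports, and flat key=value
# configuration files.

#' Write a recording as delimited text
#'
#' Tab-separated, channels as columns with a header row of channel labels,
#' preceded by a `# fs <Hz>` comment line recording the sampling rate.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs %.10g", rec$fs), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = rec$channel_labels, quote = FALSE)
}

#' Read a recording from delimited text
#'
#' Expects the format of [write_recording()]: an optional `# fs <Hz>`
#' comment, a header row of unique channel labels, then one numeric row
#' per sample.
#'
#' @param path Input file path.
#' @param fs Sampling rate in Hz; required when the file carries no
#'   `# fs` comment.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("cannot read recording: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*fs\\s", first)) {
    fs_file <- as.numeric(sub("^#\\s*fs\\s+", "", first))
    if (is.null(fs)) fs <- fs_file
  }
  if (is.null(fs))
    stop("no sampling rate: file ", path,
         " has no '# fs' line and none was supplied")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop("no data in ", path)
  labs <- colnames(df)
  if (anyDuplicated(labs))
    stop("duplicate channel label '", labs[duplicated(labs)][1L],
         "' in ", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric data in ", path)
  eeg_recording(t(m), labs, fs)
}

#' Write a cohort to a directory
#'
#' One delimited-text file per recording plus a `manifest.tsv` with
#' columns `subject_id`, `label`, `file`, `fs`.
#'
#' @param cohort List as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    fn <- paste0(s$subject_id, ".tsv")
    write_recording(s$recording, file.path(dir, fn))
    data.frame(subject_id = s$subject_id, label = s$label, file = fn,
               fs = s$recording$fs)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv`.
#' @return List of elements with `recording`, `label`, `subject_id`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t")
  lapply(seq_len(nrow(manifest)), function(i) {
    list(recording = read_recording(file.path(dir, manifest$file[i]),
                                    fs = manifest$fs[i]),
         label = as.integer(manifest$label[i]),
         subject_id = as.character(manifest$subject_id[i]))
  })
}

#' Write a connectivity matrix as TSV with channel-label headers
#'
#' @param cm A [connectivity_matrix()] (or plain matrix).
#' @param path Output path.
#' @param labels Channel labels (default canonical montage).
#' @export
write_connectivity_tsv <- function(cm, path, labels = canonical_montage()) {
  v <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  dimnames(v) <- list(labels, labels)
  utils::write.table(v, path, sep = "\t", quote = FALSE)
}

#' Export a connectivity matrix for brain-network viewers
#'
#' Writes `<stem>.node` (label, schematic 2-D position, degree as node
#' size) and `<stem>.edge` (the weight or adjacency matrix) in the
#' plain-text format brain-network renderers consume.
#'
#' @param cm A [connectivity_matrix()] or adjacency matrix.
#' @param stem Output path without extension.
#' @param threshold Edges with weight below this are zeroed in the degree
#'   computation (default 0).
#' @export
export_brainnet <- function(cm, stem, threshold = 0) {
  v <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  pos <- electrode_positions()
  deg <- rowSums(v >= pmax(threshold, 1e-12))
  node <- data.frame(x = pos$x, y = pos$y, z = 0, color = 1,
                     size = deg, label = pos$label)
  utils::write.table(node, paste0(stem, ".node"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(v, paste0(stem, ".edge"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Write a pipeline configuration as a flat key=value file
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(keys, "=", vals), path)
}

#' Read a pipeline configuration from a key=value file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Input path.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  defaults <- pipeline_config()
  out <- defaults
  for (p in kv) {
    key <- trimws(p[1])
    if (!key %in% names(defaults)) stop("unknown configuration key: ", key)
    val <- trimws(paste(p[-1], collapse = "="))
    proto <- defaults[[key]]
    out[[key]] <- if (is.numeric(proto)) {
      as.numeric(strsplit(val, ",")[[1]])
    } else val
  }
  out$seed <- as.integer(out$seed)
  do.call(pipeline_config, out)
}
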