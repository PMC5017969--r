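# Recording / annotation / trial containers and their on-disk formats.
#
# Recordings are plain delimited text (CSV/TSV autodetected by extension,
# one numeric value per row, column selectable) rather than a vendor
# acquisition format.  Annotation indices are 0-based half-open [start, end)
# sample intervals so that interval length is simply end - start.

#' Minimum analyzable trial length (samples)
#'
#' Trials shorter than this are rejected: a 3-level discrete wavelet
#' transform and spectral framing are not well-defined below it.
#' @export
MIN_TRIAL_LEN <- 64L

#' Number of vowel classes
#'
#' The Bangla script has 11 vowel letters, numbered 1..11.
#' @export
N_VOWEL_CLASSES <- 11L

#' Construct a single-channel sEMG recording
#'
#' @param samples numeric vector of samples (millivolts).
#' @param fs sampling rate in Hz (default 1000).
#' @param subject_id subject identifier.
#' @param channel_label channel label.
#' @return An object of class `semg_recording`.
#' @export
semg_recording <- function(samples, fs = 1000, subject_id = "S1",
                           channel_label = "ch1") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id),
                 channel_label = as.character(channel_label)),
            class = "semg_recording")
}

#' Construct an annotation track
#'
#' Intervals are 0-based, half-open `[start, end)` sample indices with a
#' vowel class label in `1..n_classes`.
#'
#' @param start,end integer vectors of interval bounds.
#' @param class_id integer vector of class labels.
#' @param n_classes number of permitted classes (default 11).
#' @return A `semg_annotations` data frame with columns start, end, class_id.
#' @export
semg_annotations <- function(start, end, class_id,
                             n_classes = N_VOWEL_CLASSES) {
  start <- as.integer(start); end <- as.integer(end)
  class_id <- as.integer(class_id)
  n <- length(start)
  if (length(end) != n || length(class_id) != n)
    stop("start, end and class_id must have equal length")
  if (n > 0L) {
    if (any(start < 0L) || any(end <= start))
      stop("annotation intervals must satisfy 0 <= start < end")
    if (any(class_id < 1L | class_id > n_classes))
      stop("class_id out of range 1..", n_classes)
    o <- order(start)
    start <- start[o]; end <- end[o]; class_id <- class_id[o]
    if (n > 1L && any(start[-1L] < end[-n]))
      stop("annotation intervals overlap")
  }
  structure(data.frame(start = start, end = end, class_id = class_id),
            class = c("semg_annotations", "data.frame"))
}

#' Construct a trial (one isolated utterance)
#'
#' @param samples numeric sample vector (millivolts).
#' @param fs sampling rate in Hz.
#' @param class_id vowel class label in 1..11.
#' @param subject_id subject identifier.
#' @return An object of class `semg_trial`.
#' @export
semg_trial <- function(samples, fs = 1000, class_id = 1L, subject_id = "S1") {
  samples <- as.numeric(samples)
  if (length(samples) < MIN_TRIAL_LEN)
    stop("trial shorter than minimum analyzable length (",
         MIN_TRIAL_LEN, " samples)")
  class_id <- as.integer(class_id)
  if (class_id < 1L || class_id > N_VOWEL_CLASSES)
    stop("class_id out of range 1..", N_VOWEL_CLASSES)
  structure(list(samples = samples, fs = fs, class_id = class_id,
                 subject_id = as.character(subject_id)),
            class = "semg_trial")
}

.delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a recording from delimited text
#'
#' One numeric value per row (or a configured column of a multi-column
#' export).  Delimiter is autodetected from the extension (`.tsv` means
#' tab, anything else comma).
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param column 1-based column index holding the samples.
#' @param subject_id,channel_label metadata carried onto the recording.
#' @return A `semg_recording`.
#' @export
read_recording <- function(path, fs = 1000, column = 1L,
                           subject_id = "S1", channel_label = "ch1") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty recording file: ", path)
  sep <- .delim_for(path)
  vals <- vapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], sep, fixed = TRUE)[[1L]]
    if (length(fields) < column)
      stop("line ", i, ": fewer than ", column, " columns")
    v <- suppressWarnings(as.numeric(fields[[column]]))
    if (is.na(v)) stop("line ", i, ": non-numeric value '",
                       fields[[column]], "'")
    v
  }, numeric(1))
  semg_recording(vals, fs = fs, subject_id = subject_id,
                 channel_label = channel_label)
}

#' Write a recording as delimited text
#'
#' @param rec a `semg_recording`.
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  writeLines(format(rec$samples, digits = 17, trim = TRUE,
                    scientific = FALSE), path)
  invisible(path)
}

#' Read an annotation sidecar
#'
#' CSV with header `start,end,class_id`; intervals are validated (sorted,
#' non-overlapping, class in range).
#'
#' @param path file path.
#' @param n_classes permitted class range upper bound.
#' @return A `semg_annotations` data frame.
#' @export
read_annotations <- function(path, n_classes = N_VOWEL_CLASSES) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("start", "end", "class_id")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns start,end,class_id")
  semg_annotations(df$start, df$end, df$class_id, n_classes = n_classes)
}

#' Write an annotation sidecar
#' @param ann a `semg_annotations` data frame.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[c("start", "end", "class_id")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Cut a recording into labeled trials
#'
#' One trial per annotated interval; the trial carries exactly the samples
#' in `[start, end)` plus the class label and the recording's subject id.
#'
#' @param rec a `semg_recording`.
#' @param ann a `semg_annotations` track.
#' @return A list of `semg_trial` objects (empty list for an empty track).
#' @export
segment_trials <- function(rec, ann) {
  stopifnot(inherits(rec, "semg_recording"))
  n <- length(rec$samples)
  if (nrow(ann) == 0L) return(list())
  if (any(ann$end > n))
    stop("annotation interval exceeds recording length (", n, " samples)")
  lapply(seq_len(nrow(ann)), function(i) {
    idx <- (ann$start[i] + 1L):ann$end[i]   # 0-based half-open -> R 1-based
    semg_trial(rec$samples[idx], fs = rec$fs, class_id = ann$class_id[i],
               subject_id = rec$subject_id)
  })
}

#' Write a feature table
#'
#' Delimited CSV whose header is the 57 canonical feature names followed by
#' `class_id` and `subject_id`.
#'
#' @param features numeric matrix (trials x 57) with canonical column names.
#' @param class_id integer labels, one per row.
#' @param subject_id character subject ids, one per row.
#' @param path output path.
#' @export
write_feature_table <- function(features, class_id, subject_id, path) {
  features <- as.matrix(features)
  if (is.null(colnames(features)) ||
      !identical(colnames(features), feature_names()))
    stop("feature table columns must be the canonical 57 feature names")
  n <- nrow(features)
  if (length(class_id) != n || length(subject_id) != n)
    stop("class_id/subject_id length must match feature rows")
  df <- as.data.frame(features)
  df$class_id <- as.integer(class_id)
  df$subject_id <- as.character(subject_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path input path.
#' @return list with `features` (matrix), `class_id`, `subject_id`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("class_id", "subject_id")
  if (!all(meta %in% names(df)))
    stop("feature table lacks class_id/subject_id columns")
  feat <- as.matrix(df[setdiff(names(df), meta)])
  list(features = feat, class_id = as.integer(df$class_id),
       subject_id = as.character(df$subject_id))
}
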