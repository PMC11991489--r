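#' Multichannel biosignal recording
#'
#' The pipeline's raw currency: a channels-by-samples matrix of EEG and/or EMG
#' in microvolts with a sampling rate, unique channel labels, per-channel kind
#' tags and free-form study metadata (subject id, sleep condition, motor
#' state).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names (10-10 names for
#'   EEG, `"EMG_L"`/`"EMG_R"` for muscle, `"M1"`/`"M2"` for mastoids).
#' @param kinds per-channel tag, one of `"EEG"`, `"EMG"`, `"REF"`. Defaults to
#'   a guess from the labels (EMG_* -> EMG, M1/M2 -> REF, else EEG).
#' @param meta named list of study metadata; recognised fields are `subject`,
#'   `condition` (`"good"`/`"poor"`) and `state` (`"rest"`,
#'   `"left_contraction"`, `"right_contraction"`).
#' @return An object of class `mb_recording`.
#' @export
recording <- function(data, rate, labels, kinds = NULL, meta = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  storage.mode(data) <- "double"
  if (is.null(kinds)) kinds <- guess_kinds(labels)
  rec <- structure(
    list(data = data, rate = as.numeric(rate), labels = as.character(labels),
         kinds = as.character(kinds), meta = meta),
    class = "mb_recording")
  validate_recording(rec)
  rec
}

guess_kinds <- function(labels) {
  ifelse(grepl("^EMG", labels), "EMG",
         ifelse(labels %in% c("M1", "M2"), "REF", "EEG"))
}

#' Validate a recording's invariants
#'
#' Checks rate > 0, unique labels, finite data and consistent dimensions;
#' stops with an informative error on the first violation.
#'
#' @param rec an `mb_recording`.
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "mb_recording"))
  if (!is.matrix(rec$data)) stop("recording data must be a matrix")
  if (length(rec$rate) != 1 || !is.finite(rec$rate) || rec$rate <= 0)
    stop("sampling rate must be a single positive number")
  n_ch <- nrow(rec$data)
  if (length(rec$labels) != n_ch || length(rec$kinds) != n_ch)
    stop("labels/kinds length must equal the number of channels")
  if (anyDuplicated(rec$labels))
    stop("duplicate channel labels: ",
         paste(unique(rec$labels[duplicated(rec$labels)]), collapse = ", "))
  if (!all(rec$kinds %in% c("EEG", "EMG", "REF")))
    stop("channel kinds must be EEG, EMG or REF")
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite samples")
  invisible(rec)
}

#' @export
print.mb_recording <- function(x, ...) {
  cat(sprintf("<mb_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  kinds:", paste(sprintf("%s=%d", names(table(x$kinds)),
                                table(x$kinds)), collapse = " "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `mb_recording`.
#' @return length in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$rate

#' Extract channels by label
#' @param rec an `mb_recording`.
#' @param labels channel labels to keep, in the requested order.
#' @return a new `mb_recording` with only those channels.
#' @export
pick_channels <- function(rec, labels) {
  idx <- match(labels, rec$labels)
  if (anyNA(idx))
    stop("channels not present: ", paste(labels[is.na(idx)], collapse = ", "))
  recording(rec$data[idx, , drop = FALSE], rec$rate, rec$labels[idx],
            rec$kinds[idx], rec$meta)
}

#' Epoched data block
#'
#' @param data numeric array, epochs x channels x samples.
#' @param rate sampling rate in Hz.
#' @param epoch_length epoch length in seconds.
#' @param labels,kinds channel labels and kinds (as in [recording()]).
#' @param kept_indices original epoch ids surviving rejection (1-based,
#'   strictly increasing).
#' @param meta study metadata carried over from the source recording.
#' @return An object of class `mb_epochs`.
#' @export
epochs_block <- function(data, rate, epoch_length, labels, kinds,
                         kept_indices = seq_len(dim(data)[1]), meta = list()) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != round(rate * epoch_length))
    stop("samples per epoch must equal round(rate * epoch_length)")
  if (is.unsorted(kept_indices, strictly = TRUE))
    stop("kept_indices must be strictly increasing")
  structure(list(data = data, rate = rate, epoch_length = epoch_length,
                 labels = labels, kinds = kinds,
                 kept_indices = as.integer(kept_indices), meta = meta),
            class = "mb_epochs")
}

#' @export
print.mb_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mb_epochs> %d epochs x %d channels x %d samples @ %g Hz (%g s epochs)\n",
              d[1], d[2], d[3], x$rate, x$epoch_length))
  invisible(x)
}

# derive a reproducible 31-bit substream seed from a master seed and a stage tag
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}
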