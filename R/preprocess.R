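# Signal cleaning chain. All filters are 4th-order Butterworth applied
# forward-backward (signal::filtfilt), i.e. zero-phase: PLV phase estimates
# downstream must not inherit filter phase delays.

apply_filter <- function(rec, flt, channels = NULL) {
  out <- rec$data
  idx <- if (is.null(channels)) seq_len(nrow(out)) else channels
  for (i in idx) out[i, ] <- signal::filtfilt(flt, out[i, ])
  recording(out, rec$rate, rec$labels, rec$kinds, rec$meta)
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param rec an `mb_recording`.
#' @param lo,hi band edges in Hz, `0 < lo < hi < rate/2`.
#' @param order filter order (default 4); the effective magnitude response is
#'   squared by the forward-backward pass.
#' @param channels optional integer channel indices; default all.
#' @return filtered `mb_recording`.
#' @export
filter_bandpass <- function(rec, lo, hi, order = 4, channels = NULL) {
  validate_recording(rec)
  nyq <- rec$rate / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop(sprintf("band (%g, %g) must satisfy 0 < lo < hi < Nyquist (%g)",
                 lo, hi, nyq))
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  apply_filter(rec, flt, channels)
}

#' Zero-phase Butterworth band-stop (notch) filter
#'
#' Specified as a stop band (e.g. 48-52 Hz), matching printed notch bounds.
#'
#' @inheritParams filter_bandpass
#' @return filtered `mb_recording`.
#' @export
filter_notch <- function(rec, lo, hi, order = 4, channels = NULL) {
  validate_recording(rec)
  nyq <- rec$rate / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop(sprintf("notch (%g, %g) must lie inside (0, Nyquist = %g)",
                 lo, hi, nyq))
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "stop")
  apply_filter(rec, flt, channels)
}

#' Downsample a recording
#'
#' Integer decimation with a zero-phase anti-alias low-pass (8th-order
#' Butterworth at 80% of the new Nyquist); non-integer ratios use polyphase
#' resampling (`signal::resample`). Upsampling is refused (the pipeline never
#' needs it).
#'
#' @param rec an `mb_recording`.
#' @param new_rate target rate in Hz, `<= rec$rate`.
#' @return resampled `mb_recording`.
#' @export
resample_recording <- function(rec, new_rate = 500) {
  validate_recording(rec)
  if (new_rate > rec$rate) stop("upsampling is not supported")
  if (abs(new_rate - rec$rate) < 1e-9) return(rec)
  ratio <- rec$rate / new_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- round(ratio)
    flt <- signal::butter(8, 0.8 * (new_rate / 2) / (rec$rate / 2),
                          type = "low")
    out <- rec$data
    for (i in seq_len(nrow(out))) out[i, ] <- signal::filtfilt(flt, out[i, ])
    out <- out[, seq(1, ncol(out), by = k), drop = FALSE]
  } else {
    frac <- .ratio_as_integers(new_rate, rec$rate)
    n_new <- floor(ncol(rec$data) * new_rate / rec$rate)
    out <- t(apply(rec$data, 1, function(x)
      signal::resample(x, frac[1], frac[2])[seq_len(n_new)]))
  }
  recording(out, new_rate, rec$labels, rec$kinds, rec$meta)
}

.ratio_as_integers <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(p * 1000), round(q * 1000))
  c(round(p * 1000) / d, round(q * 1000) / d)
}

#' Re-reference EEG channels to the bilateral mastoids
#'
#' Subtracts the mean of the two reference channels from every EEG channel;
#' EMG channels and the references themselves are left untouched.
#'
#' @param rec an `mb_recording`.
#' @param ref_labels the two mastoid labels (default `c("M1", "M2")`).
#' @return re-referenced `mb_recording`.
#' @export
rereference <- function(rec, ref_labels = c("M1", "M2")) {
  validate_recording(rec)
  idx <- match(ref_labels, rec$labels)
  if (anyNA(idx))
    stop("reference channels missing: ",
         paste(ref_labels[is.na(idx)], collapse = ", "))
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  out <- rec$data
  eeg <- which(rec$kinds == "EEG" & !(seq_along(rec$labels) %in% idx))
  for (i in eeg) out[i, ] <- out[i, ] - ref
  recording(out, rec$rate, rec$labels, rec$kinds, rec$meta)
}

#' Segment a recording into fixed-length epochs
#'
#' Non-overlapping epochs from the start of the recording; any trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param rec an `mb_recording`.
#' @param length epoch length in seconds (default 2).
#' @return an `mb_epochs` block.
#' @export
epoch_recording <- function(rec, length = 2.0) {
  validate_recording(rec)
  if (length <= 0) stop("epoch length must be positive")
  spe <- round(rec$rate * length)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1)
    stop(sprintf("recording (%.2f s) shorter than one epoch (%g s)",
                 rec_duration(rec), length))
  arr <- array(0, dim = c(n_ep, nrow(rec$data), spe))
  for (e in seq_len(n_ep))
    arr[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  epochs_block(arr, rec$rate, length, rec$labels, rec$kinds,
               meta = rec$meta)
}

#' Reject artifact epochs
#'
#' Deterministic stand-in for manual epoch screening: an epoch is dropped if
#' any channel's peak absolute amplitude exceeds `abs_uV`, or if any
#' channel's RMS, z-scored across epochs, exceeds `z_max`.
#'
#' @param ep an `mb_epochs` block.
#' @param abs_uV absolute amplitude threshold in microvolts (default 150).
#' @param z_max RMS z-score threshold (default 5). Use `Inf` to disable
#'   either rule.
#' @return `mb_epochs` with rejected epochs removed and `kept_indices`
#'   updated; errors if nothing survives.
#' @export
reject_epochs <- function(ep, abs_uV = 150, z_max = 5) {
  stopifnot(inherits(ep, "mb_epochs"))
  n_ep <- dim(ep$data)[1]
  peak <- apply(abs(ep$data), 1, max)
  rms_ec <- sqrt(apply(ep$data^2, c(1, 2), mean))   # epochs x channels
  zbad <- rep(FALSE, n_ep)
  if (is.finite(z_max) && n_ep >= 3) {
    mu <- colMeans(rms_ec)
    sd_ <- apply(rms_ec, 2, stats::sd)
    sd_[sd_ == 0] <- Inf
    z <- sweep(sweep(rms_ec, 2, mu), 2, sd_, "/")
    zbad <- apply(abs(z) > z_max, 1, any)
  }
  keep <- !(peak > abs_uV | zbad)
  if (!any(keep))
    stop(sprintf("all %d epochs rejected (abs_uV=%g, z_max=%g)",
                 n_ep, abs_uV, z_max))
  epochs_block(ep$data[keep, , , drop = FALSE], ep$rate, ep$epoch_length,
               ep$labels, ep$kinds,
               kept_indices = ep$kept_indices[keep], meta = ep$meta)
}

#' Run the full EEG cleaning chain
#'
#' Fixed order: band-pass 1-100 Hz, notch 48-52 and 98-102 Hz, resample to
#' 500 Hz, re-reference to M1/M2, epoch (2 s), reject. Only EEG/REF channels
#' are kept. The applied chain is recorded in `meta$provenance`.
#'
#' @param rec an `mb_recording` containing EEG (and reference) channels.
#' @param config configuration list, see [default_config()].
#' @param reject apply epoch rejection (default TRUE).
#' @return list with `epochs` (`mb_epochs`) and `continuous` (the cleaned
#'   continuous `mb_recording` before epoching, used by the MVAR/PDC stage).
#' @export
preprocess_eeg <- function(rec, config = default_config(), reject = TRUE) {
  keep <- which(rec$kinds %in% c("EEG", "REF"))
  r <- recording(rec$data[keep, , drop = FALSE], rec$rate, rec$labels[keep],
                 rec$kinds[keep], rec$meta)
  prov <- list()
  r <- filter_bandpass(r, config$eeg_band[1], config$eeg_band[2],
                       order = config$filter_order)
  prov <- c(prov, list(list(op = "bandpass", band = config$eeg_band)))
  for (nb in config$notches) {
    r <- filter_notch(r, nb[1], nb[2], order = config$filter_order)
    prov <- c(prov, list(list(op = "notch", band = nb)))
  }
  r <- resample_recording(r, config$target_rate)
  prov <- c(prov, list(list(op = "resample", rate = config$target_rate)))
  r <- rereference(r, config$ref_labels)
  prov <- c(prov, list(list(op = "rereference", ref = config$ref_labels)))
  r$meta$provenance <- prov
  ep <- epoch_recording(r, config$epoch_length)
  if (reject)
    ep <- reject_epochs(ep, config$reject_abs_uV, config$reject_z_max)
  list(epochs = ep, continuous = r)
}

#' Run the EMG cleaning chain
#'
#' Fixed order: band-pass 20-150 Hz applied as a cascade of two identical
#' passes (squared magnitude response), resample, epoch. No re-referencing
#' and no amplitude rejection (EMG amplitudes are task-dependent).
#'
#' @inheritParams preprocess_eeg
#' @return list with `epochs` and `continuous` as in [preprocess_eeg()].
#' @export
preprocess_emg <- function(rec, config = default_config()) {
  keep <- which(rec$kinds == "EMG")
  if (!length(keep)) stop("no EMG channel present")
  r <- recording(rec$data[keep, , drop = FALSE], rec$rate, rec$labels[keep],
                 rec$kinds[keep], rec$meta)
  for (pass in 1:2)
    r <- filter_bandpass(r, config$emg_band[1], config$emg_band[2],
                         order = config$filter_order)
  r <- resample_recording(r, config$target_rate)
  r$meta$provenance <- list(
    list(op = "bandpass_x2", band = config$emg_band),
    list(op = "resample", rate = config$target_rate))
  list(epochs = epoch_recording(r, config$epoch_length), continuous = r)
}
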