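# Surface-EMG fatigue indices. Spectral fatigue shows as a downshift of the
# power spectrum: MPF (power-weighted mean frequency) and MF (frequency
# splitting band power in half) both decrease.

#' Root mean square of a signal
#' @param x numeric vector (non-empty).
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty input")
  sqrt(mean(x^2))
}

#' Welch power spectral density
#'
#' Hann-windowed overlapping segments, averaged one-sided periodograms,
#' density scaling (integral over frequency approximates the signal
#' variance).
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param win segment length in seconds (default 1, i.e. 1 Hz resolution).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list of class `mb_spectrum` with `freqs` (Hz) and `power`
#'   (uV^2/Hz).
#' @export
welch_psd <- function(x, rate, win = 1.0, overlap = 0.5) {
  nper <- round(win * rate)
  if (nper > length(x)) stop("window longer than signal")
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)  # periodic Hann
  u <- sum(w^2)
  nfreq <- floor(nper / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / (rate * u)
    half <- p[seq_len(nfreq)]
    # one-sided: double all bins except DC (and Nyquist when nper is even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nper %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + half * dbl
  }
  structure(list(freqs = seq(0, nfreq - 1) * rate / nper,
                 power = acc / length(starts)),
            class = "mb_spectrum")
}

band_bins <- function(spec, band) {
  which(spec$freqs >= band[1] & spec$freqs <= band[2])
}

#' Mean power frequency of a spectrum within a band
#'
#' The power-weighted mean frequency: `sum(f * P) / sum(P)` over in-band
#' bins.
#'
#' @param spec an `mb_spectrum` from [welch_psd()].
#' @param band numeric `(lo, hi)` in Hz.
#' @return MPF in Hz.
#' @export
mpf <- function(spec, band) {
  i <- band_bins(spec, band)
  if (!length(i)) stop("band outside spectrum support")
  tot <- sum(spec$power[i])
  if (tot <= 0) stop("zero power in band; MPF undefined")
  sum(spec$freqs[i] * spec$power[i]) / tot
}

#' Median frequency of a spectrum within a band
#'
#' Smallest in-band frequency at which the cumulative band power reaches at
#' least half of the total band power (deterministic on discrete grids).
#'
#' @inheritParams mpf
#' @return MF in Hz.
#' @export
mf <- function(spec, band) {
  i <- band_bins(spec, band)
  if (!length(i)) stop("band outside spectrum support")
  p <- spec$power[i]
  tot <- sum(p)
  if (tot <= 0) stop("zero power in band; MF undefined")
  spec$freqs[i][which(cumsum(p) >= tot / 2)[1]]
}

#' Per-epoch EMG feature table
#'
#' One row per kept epoch x analysis band. RMS is computed on the
#' band-filtered time signal; MPF and MF on its Welch spectrum restricted to
#' the band.
#'
#' @param ep an `mb_epochs` block containing an EMG channel.
#' @param bands named list of `(lo, hi)` sub-bands (default 20-100 and
#'   100-150 Hz).
#' @param config configuration list (Welch window/overlap, filter order).
#' @return data.frame with columns subject, condition, state, epoch, band,
#'   rms, mpf, mf.
#' @export
emg_feature_table <- function(ep,
                              bands = list(low = c(20, 100),
                                           high = c(100, 150)),
                              config = default_config()) {
  stopifnot(inherits(ep, "mb_epochs"))
  ich <- which(ep$kinds == "EMG")
  if (!length(ich)) stop("no EMG channel in epochs")
  ich <- ich[1]
  meta <- ep$meta
  getm <- function(k) if (is.null(meta[[k]])) NA_character_ else meta[[k]]
  rows <- list()
  nyq <- ep$rate / 2
  for (bn in names(bands)) {
    b <- bands[[bn]]
    hi <- min(b[2], nyq * 0.99)
    flt <- signal::butter(config$filter_order, c(b[1], hi) / nyq,
                          type = "pass")
    for (e in seq_len(dim(ep$data)[1])) {
      x <- ep$data[e, ich, ]
      xb <- signal::filtfilt(flt, x)
      spec <- welch_psd(x, ep$rate, config$welch_win, config$welch_overlap)
      rows[[length(rows) + 1]] <- data.frame(
        subject = getm("subject"), condition = getm("condition"),
        state = getm("state"), epoch = ep$kept_indices[e], band = bn,
        rms = rms(xb), mpf = mpf(spec, c(b[1], hi)),
        mf = mf(spec, c(b[1], hi)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
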