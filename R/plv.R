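# Phase-locking-value functional connectivity between sensorimotor ROIs.
# Sensor-space proxy: each Brodmann area is represented by its nearest 10-10
# channels; source modelling is deliberately out of scope.

#' Default sensorimotor ROI-to-channel map
#'
#' 13 regions: Brodmann areas 1-6 and 8 on the left, 1, 2, 4-6 and 8 on the
#' right (right BA3 is absent from the scout template the study design
#' follows). Each ROI maps to nearby 10-10 channels; the map is a proxy and
#' can be replaced wholesale.
#'
#' @return named list: ROI name -> character vector of channel labels.
#' @export
default_roi_map <- function() {
  list(
    BA1_L = c("C3", "CP3"), BA2_L = c("C3", "CP3"), BA3_L = c("C3", "CP3"),
    BA4_L = c("C3", "C1"), BA5_L = c("CP1", "CPz"),
    BA6_L = c("FC3", "FCz"), BA8_L = c("F3", "AF3"),
    BA1_R = c("C4", "CP4"), BA2_R = c("C4", "CP4"),
    BA4_R = c("C4", "C2"), BA5_R = c("CP2", "CPz"),
    BA6_R = c("FC4", "FCz"), BA8_R = c("F4", "AF4")
  )
}

#' Frequency band definitions
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma1 30-60, gamma2
#' 60-100 Hz.
#'
#' @return named list of `(lo, hi)` pairs in Hz.
#' @export
default_bands <- function() default_config()$bands

#' Instantaneous phase via the analytic signal
#'
#' FFT-based Hilbert transform; the input is assumed band-limited already.
#'
#' @param x numeric vector (non-constant).
#' @return phase series in radians, in `(-pi, pi]`.
#' @export
analytic_phase <- function(x) {
  if (stats::sd(x) == 0) stop("constant signal: phase undefined")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  Arg(z)
}

#' Phase locking value between two phase series
#'
#' Modulus of the time-averaged unit phasor of the phase difference:
#' `|mean(exp(1i * (px - py)))|`. 0 = no phase coupling, 1 = perfect
#' locking.
#'
#' @param phase_x,phase_y phase series in radians, equal length >= 2.
#' @return PLV in `[0, 1]`.
#' @export
plv_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 2) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Band-limited ROI-level PLV matrix from epoched EEG
#'
#' Each mapped channel is band-pass filtered per epoch, its phase extracted
#' (edges trimmed to discard filter/Hilbert transients), channel-pair PLV is
#' computed over samples within each epoch and averaged across epochs; the
#' ROI-pair value is the mean over all cross-ROI channel pairs (identical
#' channels shared by two ROIs are excluded, as a self-pair would contribute
#' a hard 1).
#'
#' @param ep an `mb_epochs` block with the mapped EEG channels.
#' @param roi_map named list ROI -> channels, see [default_roi_map()].
#' @param band `(lo, hi)` in Hz.
#' @param order band-pass filter order (default 4).
#' @param edge_trim fraction of samples discarded at each epoch edge before
#'   the PLV average (default 0.1).
#' @return list of class `mb_plv` with `band`, `rois` and `plv` (symmetric
#'   matrix with unit diagonal).
#' @export
plv_matrix <- function(ep, roi_map = default_roi_map(), band,
                       order = 4, edge_trim = 0.1) {
  stopifnot(inherits(ep, "mb_epochs"))
  n_ep <- dim(ep$data)[1]
  if (n_ep < 1) stop("no epochs")
  chans <- unique(unlist(roi_map))
  idx <- match(chans, ep$labels)
  if (anyNA(idx))
    stop("ROI channels missing from epochs: ",
         paste(chans[is.na(idx)], collapse = ", "))
  nyq <- ep$rate / 2
  if (band[2] >= nyq) stop("band above Nyquist")
  flt <- signal::butter(order, pmax(band, 1e-3) / nyq, type = "pass")
  spe <- dim(ep$data)[3]
  trim <- floor(spe * edge_trim)
  keep <- (trim + 1):(spe - trim)
  nch <- length(chans)
  # channel-pair PLV averaged over epochs
  acc <- matrix(0, nch, nch)
  for (e in seq_len(n_ep)) {
    ph <- matrix(0, nch, length(keep))
    for (i in seq_len(nch)) {
      xf <- signal::filtfilt(flt, ep$data[e, idx[i], ])
      ph[i, ] <- analytic_phase(xf)[keep]
    }
    z <- exp(1i * ph)
    # PLV_ij = |mean_t z_i conj(z_j)|
    acc <- acc + Mod(z %*% Conj(t(z))) / ncol(ph)
  }
  chan_plv <- acc / n_ep
  dimnames(chan_plv) <- list(chans, chans)
  rois <- names(roi_map)
  n <- length(rois)
  M <- diag(1, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ca <- roi_map[[a]]
    cb <- roi_map[[b]]
    vals <- c()
    for (x in ca) for (y in cb) if (x != y) vals <- c(vals, chan_plv[x, y])
    M[a, b] <- M[b, a] <- if (length(vals)) mean(vals) else 1
  }
  dimnames(M) <- list(rois, rois)
  structure(list(band = band, rois = rois, plv = M), class = "mb_plv")
}

#' @export
print.mb_plv <- function(x, ...) {
  cat(sprintf("<mb_plv> %d ROIs, band %g-%g Hz, mean off-diagonal %.3f\n",
              length(x$rois), x$band[1], x$band[2],
              mean(x$plv[upper.tri(x$plv)])))
  invisible(x)
}
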