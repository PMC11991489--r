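# Synthetic study generator: coupled oscillatory EEG, spectrally shaped EMG
# surrogates, MVAR-driven cortex-muscle coupling, and a full mock study with
# injected condition effects and recorded ground truth. Gives every pipeline
# stage a reproducible test bed with analytic oracles (Bessel-ratio PLV,
# closed-form AR moments, known spectral centroids).

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` falls back to the
#' uniform circular distribution.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      take <- min(sum(ok), n - got)
      out[(got + 1):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  ang <- out + mu
  ((ang + pi) %% (2 * pi)) - pi
}

#' Expected PLV of a von Mises phase difference
#'
#' The Bessel ratio `I1(kappa) / I0(kappa)`: the modulus of the mean phasor
#' of a von Mises distributed angle.
#'
#' @param kappa concentration, >= 0.
#' @return expected PLV in `[0, 1)`.
#' @export
vonmises_plv <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ifelse(kappa == 0, 0, besselI(kappa, 1) / besselI(kappa, 0))
}

# 1/f-amplitude ("pink") background noise via FFT shaping, unit variance
pink_noise <- function(n, rate) {
  f <- seq(0, rate / 2, length.out = floor(n / 2) + 1)
  amp <- 1 / sqrt(pmax(f, 1))
  re <- stats::rnorm(length(f))
  im <- stats::rnorm(length(f))
  spec <- complex(real = re, imaginary = im) * amp
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n - length(spec) + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# piecewise-constant angle series held over blocks, linearly interpolated
held_angles <- function(n, rate, block_s, kappa) {
  nb <- max(2, ceiling(n / (block_s * rate)) + 1)
  vals <- rvonmises(nb, 0, kappa)
  centers <- seq(1, n, length.out = nb)
  # interpolate the unit phasor, not the angle, to avoid wrap glitches
  zr <- stats::approx(centers, cos(vals), xout = seq_len(n))$y
  zi <- stats::approx(centers, sin(vals), xout = seq_len(n))$y
  atan2(zi, zr)
}

#' Generate a phase-coupled narrow-band signal pair
#'
#' Two cosine carriers whose per-sample phase difference is i.i.d. von
#' Mises(const, kappa), so the expected PLV equals the Bessel ratio
#' `I1(kappa)/I0(kappa)`. The true phase series are attached as attributes
#' `phase_x` / `phase_y` for oracle checks.
#'
#' @param n_samples number of samples.
#' @param rate sampling rate in Hz.
#' @param carrier_f carrier frequency (< rate/2).
#' @param kappa von Mises concentration of the phase difference (>= 0).
#' @param seed RNG seed.
#' @param amp carrier amplitude in microvolts (default 10).
#' @return 2-channel `mb_recording` (labels `X`, `Y`) with phase attributes.
#' @export
gen_phase_coupled_pair <- function(n_samples, rate, carrier_f, kappa,
                                   seed = NULL, amp = 10) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (carrier_f >= rate / 2) stop("carrier above Nyquist")
  if (!is.null(seed)) set.seed(seed)
  t_ <- seq_len(n_samples) / rate
  drift <- cumsum(stats::rnorm(n_samples, 0, 0.01))
  phase_x <- 2 * pi * carrier_f * t_ + drift
  dphi <- rvonmises(n_samples, 0, kappa)
  phase_y <- phase_x - dphi
  rec <- recording(rbind(amp * cos(phase_x), amp * cos(phase_y)),
                   rate, c("X", "Y"), kinds = c("EEG", "EEG"))
  attr(rec, "phase_x") <- phase_x
  attr(rec, "phase_y") <- phase_y
  rec
}

#' Simulate a stable MVAR process
#'
#' `x_t = sum_k A_k x_{t-k} + e_t` with Gaussian innovations; unstable
#' models (companion spectral radius >= 1) are refused.
#'
#' @param A coefficient array N x N x p (or an N x N matrix for p = 1).
#' @param noise_cov innovation covariance (default identity).
#' @param n_samples samples returned after burn-in.
#' @param rate nominal sampling rate for the returned recording (default
#'   500).
#' @param seed RNG seed.
#' @param burnin samples discarded (default 500).
#' @return N-channel `mb_recording` (labels `ch1..chN`).
#' @export
gen_mvar_data <- function(A, noise_cov = NULL, n_samples = 1000, rate = 500,
                          seed = NULL, burnin = 500) {
  if (is.matrix(A)) A <- array(A, dim = c(nrow(A), ncol(A), 1))
  N <- dim(A)[1]
  p <- dim(A)[3]
  rho <- companion_spectral_radius(A)
  if (rho >= 1)
    stop(sprintf("unstable MVAR: companion spectral radius %.3f >= 1", rho))
  if (is.null(noise_cov)) noise_cov <- diag(N)
  if (!is.null(seed)) set.seed(seed)
  Lc <- chol(noise_cov)
  ntot <- n_samples + burnin
  E <- matrix(stats::rnorm(ntot * N), ntot, N) %*% Lc
  X <- matrix(0, ntot, N)
  for (t_ in seq_len(ntot)) {
    acc <- E[t_, ]
    for (k in seq_len(min(p, t_ - 1)))
      acc <- acc + A[, , k] %*% X[t_ - k, ]
    X[t_, ] <- acc
  }
  recording(t(X[(burnin + 1):ntot, , drop = FALSE]), rate,
            paste0("ch", seq_len(N)), kinds = rep("EEG", N))
}

# Gaussian-bump band-limited power shape whose in-band centroid is
# centroid_f; the bump center is solved numerically (the centroid of a
# truncated Gaussian is monotone in its center).
emg_shape <- function(freqs, band, centroid_f, width = 25) {
  inb <- freqs >= band[1] & freqs <= band[2]
  centroid_of <- function(center) {
    s <- exp(-(freqs[inb] - center)^2 / (2 * width^2))
    sum(freqs[inb] * s) / sum(s)
  }
  lohi <- c(band[1] - 3 * width, band[2] + 3 * width)
  center <- stats::uniroot(function(c0) centroid_of(c0) - centroid_f,
                           lohi, tol = 1e-6)$root
  s <- numeric(length(freqs))
  s[inb] <- exp(-(freqs[inb] - center)^2 / (2 * width^2))
  s
}

#' Generate a spectrally shaped EMG surrogate
#'
#' Gaussian noise shaped in the frequency domain so that its power-spectrum
#' centroid inside `band` equals `centroid_f` (Gaussian-bump shape,
#' band-limited to 20-150 Hz by construction).
#'
#' @param rate sampling rate in Hz.
#' @param duration length in seconds.
#' @param band `(lo, hi)` support in Hz (default 20-150).
#' @param centroid_f target in-band spectral centroid in Hz.
#' @param seed RNG seed.
#' @param rms_uV target RMS amplitude in microvolts (default 50).
#' @return 1-channel `mb_recording` (label `EMG_L`).
#' @export
gen_emg_surrogate <- function(rate, duration, band = c(20, 150), centroid_f,
                              seed = NULL, rms_uV = 50) {
  if (centroid_f < band[1] || centroid_f > band[2])
    stop("centroid outside band")
  if (!is.null(seed)) set.seed(seed)
  n <- round(rate * duration)
  x <- shaped_noise(n, rate, band, centroid_f)
  recording(matrix(x * rms_uV / rms(x), 1), rate, "EMG_L", kinds = "EMG")
}

shaped_noise <- function(n, rate, band, centroid_f, width = 25) {
  nf <- floor(n / 2) + 1
  freqs <- seq(0, rate / 2, length.out = nf)
  shape <- emg_shape(freqs, band, centroid_f, width)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) *
    sqrt(shape)
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# zero-phase narrowband unit-variance noise component
narrowband_noise <- function(n, rate, lo, hi) {
  flt <- signal::butter(4, c(lo, hi) / (rate / 2), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n))
  x / stats::sd(x)
}

#' Default ground-truth effect specification for the mock study
#'
#' Injected effects mirror the study's reported contrasts:
#' \itemize{
#'   \item reduced interhemispheric alpha phase coupling at rest after sleep
#'     deprivation (von Mises concentration of the inter-source phase
#'     difference drops from `kappa_inter_rest_good` to
#'     `kappa_inter_rest_poor`);
#'   \item lowered EMG spectral centroid for the left-biceps contraction
#'     after deprivation (`emg_centroid_shift` Hz);
#'   \item during left-biceps contraction, stronger right-cortex (C4) ->
#'     left-EMG drive and weaker left-EMG -> right-cortex feedback after
#'     deprivation (amplitude gains in microvolts).
#' }
#'
#' @return named list of generator parameters (the study conditions).
#' @export
default_ground_truth <- function() {
  list(
    carrier_f = 10,
    kappa_channel = 10,
    kappa_inter_rest_good = 6,
    kappa_inter_rest_poor = 1,
    kappa_inter_contraction = 4,
    alpha_amp = 8, osc_amp = 5, noise_sd = 6,
    left_locked = c("C3", "CP3", "C1"),
    right_locked = c("C4", "CP4", "C2"),
    plv_affected = list(left = c("BA1_L", "BA2_L", "BA3_L", "BA4_L"),
                        right = c("BA1_R", "BA2_R", "BA4_R", "BA5_R")),
    emg_centroid_good = 95,
    emg_centroid_shift = 10,        # poor-sleep left contraction: 95 -> 85
    emg_rms_contraction = 50,
    emg_rms_rest = 5,
    gamma_band = c(35, 55),
    cortex_gamma_amp = 4,
    emg_gamma_amp = 6,
    coupling_lag = 2,               # samples at the native rate
    cm_gain_good = 8, cm_gain_poor = 16,   # cortex -> EMG (uV)
    mc_gain_good = 3, mc_gain_poor = 0.8   # EMG -> cortex (uV)
  )
}

#' Default synthetic montage (30 EEG incl. mastoids + 1 EMG)
#' @return character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
    "FC3", "FCz", "FC4", "T7", "C3", "C1", "C2", "C4", "T8",
    "CP3", "CP1", "CPz", "CP2", "CP4", "P7", "P3", "Pz", "P4", "P8",
    "M1", "M2")
}

# one synthetic recording for (subject, condition, state)
gen_recording <- function(subject, condition, state, gt, rate, duration,
                          seed, subject_fx) {
  set.seed(seed)
  n <- round(rate * duration)
  labels <- default_montage()
  n_eeg <- length(labels)
  data <- matrix(0, n_eeg + 1, n)
  t_ <- seq_len(n) / rate
  for (i in seq_len(n_eeg)) data[i, ] <- gt$noise_sd * pink_noise(n, rate)
  # hemisphere alpha sources with inter-source von Mises phase difference
  kappa_inter <- if (state == "rest") {
    if (condition == "good") gt$kappa_inter_rest_good else
      gt$kappa_inter_rest_poor
  } else gt$kappa_inter_contraction
  kappa_inter <- kappa_inter * subject_fx$kappa_mult
  theta_L <- 2 * pi * gt$carrier_f * t_ + cumsum(stats::rnorm(n, 0, 0.02))
  theta_R <- theta_L + held_angles(n, rate, 0.25, kappa_inter)
  lockin <- function(label, theta) {
    i <- match(label, labels)
    jitter <- held_angles(n, rate, 0.25, gt$kappa_channel)
    data[i, ] <<- data[i, ] + gt$alpha_amp * cos(theta + jitter)
  }
  for (ch in gt$left_locked) lockin(ch, theta_L)
  for (ch in gt$right_locked) lockin(ch, theta_R)
  # remaining scalp channels get independent alpha oscillations
  others <- setdiff(labels, c(gt$left_locked, gt$right_locked, "M1", "M2"))
  for (ch in others) {
    i <- match(ch, labels)
    ph <- 2 * pi * gt$carrier_f * t_ + stats::runif(1, -pi, pi) +
      cumsum(stats::rnorm(n, 0, 0.05))
    data[i, ] <- data[i, ] + gt$osc_amp * cos(ph)
  }
  # EMG channel + gamma-band cortex-muscle coupling during contraction
  emg_label <- if (state == "right_contraction") "EMG_R" else "EMG_L"
  contract <- state != "rest"
  centroid <- subject_fx$centroid_base
  if (contract && state == "left_contraction" && condition == "poor")
    centroid <- centroid - gt$emg_centroid_shift
  emg_rms <- if (contract) gt$emg_rms_contraction else gt$emg_rms_rest
  emg <- shaped_noise(n, rate, c(20, 150), centroid) * emg_rms
  if (contract) {
    lag <- gt$coupling_lag
    shift <- function(x, l) c(rep(0, l), x[seq_len(length(x) - l)])
    cortex <- if (state == "left_contraction") "C4" else "C3"
    ic <- match(cortex, labels)
    g <- narrowband_noise(n, rate, gt$gamma_band[1], gt$gamma_band[2])
    m <- narrowband_noise(n, rate, gt$gamma_band[1], gt$gamma_band[2])
    if (state == "left_contraction") {
      cm <- if (condition == "poor") gt$cm_gain_poor else gt$cm_gain_good
      mc <- if (condition == "poor") gt$mc_gain_poor else gt$mc_gain_good
    } else {
      cm <- gt$cm_gain_good
      mc <- gt$mc_gain_good
    }
    cm <- cm * subject_fx$gain_mult
    mc <- mc * subject_fx$gain_mult
    data[ic, ] <- data[ic, ] + gt$cortex_gamma_amp * g + mc * shift(m, lag)
    emg <- emg + gt$emg_gamma_amp * m + cm * shift(g, lag)
  }
  data[n_eeg + 1, ] <- emg
  recording(data, rate, c(labels, emg_label),
            meta = list(subject = subject, condition = condition,
                        state = state))
}

#' Generate a full mock study on disk
#'
#' `n_subjects` x 2 sleep conditions (good/poor) x 3 motor states (rest,
#' left and right biceps contraction), written as EDF + JSON sidecars in a
#' `subject/condition/state.edf` tree, with the injected effect parameters
#' serialized as `ground_truth.json`. Fully reproducible from `(seed,
#' effects)`.
#'
#' @param out_dir output directory (created; refuses to reuse a non-empty
#'   one unless `overwrite = TRUE`).
#' @param n_subjects number of subjects (default 35, the study size).
#' @param seed master seed; every recording uses a derived substream.
#' @param effects ground-truth effect list, see [default_ground_truth()].
#' @param rate native sampling rate in Hz (default 1000).
#' @param rest_duration,contraction_duration recording lengths in seconds
#'   (defaults 40 and 60).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a list with `index` (data.frame of paths) and
#'   `ground_truth`.
#' @export
gen_study <- function(out_dir, n_subjects = 35, seed = 1,
                      effects = default_ground_truth(), rate = 1000,
                      rest_duration = 40, contraction_duration = 60,
                      overwrite = FALSE) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subject <- sprintf("S%02d", s)
    sfx_seed <- substream_seed(seed, paste0("subject", s))
    set.seed(sfx_seed)
    subject_fx <- list(
      centroid_base = effects$emg_centroid_good + stats::rnorm(1, 0, 2),
      kappa_mult = exp(stats::rnorm(1, 0, 0.15)),
      gain_mult = exp(stats::rnorm(1, 0, 0.1)))
    for (condition in c("good", "poor")) {
      for (state in c("rest", "left_contraction", "right_contraction")) {
        duration <- if (state == "rest") rest_duration else
          contraction_duration
        rseed <- substream_seed(seed, paste(s, condition, state))
        rec <- gen_recording(subject, condition, state, effects, rate,
                             duration, rseed, subject_fx)
        d <- file.path(out_dir, subject, condition)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        path <- file.path(d, paste0(state, ".edf"))
        write_edf(rec, path)
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject, condition = condition, state = state,
          path = path, stringsAsFactors = FALSE)
      }
    }
  }
  index <- do.call(rbind, rows)
  # paths are written relative so a dataset tree is location-independent
  utils::write.csv(index[, c("subject", "condition", "state")],
                   file.path(out_dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(effects, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(index = index, ground_truth = effects))
}
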