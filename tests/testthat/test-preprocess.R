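trimmed_rms <- function(x) rms(x[round(length(x) * 0.2):round(length(x) * 0.8)])

test_that("band-pass keeps in-band tones and kills drift", {
  s10 <- sine_rec(10)
  expect_gt(trimmed_rms(filter_bandpass(s10, 1, 100)$data[1, ]) /
              trimmed_rms(s10$data[1, ]), 0.95)
  drift <- sine_rec(0.1)
  expect_lt(trimmed_rms(filter_bandpass(drift, 1, 100)$data[1, ]) /
              trimmed_rms(drift$data[1, ]), 0.1)
  zero <- recording(matrix(0, 1, 1000) + 0, 500, "C3")
  expect_equal(filter_bandpass(zero, 1, 100)$data, zero$data)
  expect_error(filter_bandpass(s10, 1, 300), "Nyquist")
})

test_that("notch attenuates in-notch tones >= 20 dB and spares neighbours", {
  s50 <- sine_rec(50)
  db <- 20 * log10(trimmed_rms(filter_notch(s50, 48, 52)$data[1, ]) /
                     trimmed_rms(s50$data[1, ]))
  expect_lt(db, -20)
  s30 <- sine_rec(30)
  db30 <- 20 * log10(trimmed_rms(filter_notch(s30, 48, 52)$data[1, ]) /
                       trimmed_rms(s30$data[1, ]))
  expect_gt(db30, -1)
  zero <- recording(matrix(0, 1, 1000) + 0, 500, "C3")
  expect_equal(filter_notch(zero, 48, 52)$data, zero$data)
})

test_that("filters are zero-phase: a symmetric pulse keeps its peak location", {
  x <- exp(-((1:2000) - 1000)^2 / (2 * 15^2))
  rec <- recording(matrix(x, 1), 500, "C3")
  for (f in list(filter_bandpass(rec, 1, 100), filter_notch(rec, 48, 52)))
    expect_equal(which.max(f$data[1, ]), 1000)
})

test_that("resampling halves counts, preserves spectra, refuses upsampling", {
  rec <- recording(matrix(rnorm(1000), 1), 1000, "C3")
  out <- resample_recording(rec, 500)
  expect_equal(ncol(out$data), 500)
  expect_equal(out$rate, 500)
  t_ <- seq_len(10000) / 1000
  s40 <- recording(matrix(sin(2 * pi * 40 * t_), 1), 1000, "C3")
  r40 <- resample_recording(s40, 500)
  expect_lt(abs(mpf(welch_psd(r40$data[1, ], 500), c(1, 249)) - 40), 1)
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(rec, 2000), "upsampling")
})

test_that("mastoid re-referencing subtracts the reference mean from EEG only", {
  n <- 1000
  x <- rnorm(n)
  dat <- rbind(x, rnorm(n), rep(2, n), rep(4, n))
  rec <- recording(dat, 500, c("C3", "EMG_L", "M1", "M2"))
  out <- rereference(rec)
  expect_equal(out$data[1, ], x - 3)
  expect_equal(out$data[2, ], dat[2, ])           # EMG untouched
  expect_equal(out$data[3, ], dat[3, ])           # references untouched
  # channel equal to both references becomes identically zero
  rec2 <- recording(rbind(x, x, x), 500, c("C3", "M1", "M2"))
  expect_equal(max(abs(rereference(rec2)$data[1, ])), 0)
  expect_error(rereference(rec, c("M1", "M9")), "M9")
})

test_that("epoching counts and errors follow the duration arithmetic", {
  rec <- recording(matrix(rnorm(5000), 1), 500, "C3")
  ep <- epoch_recording(rec, 2)
  expect_identical(dim(ep$data), c(5L, 1L, 1000L))
  rec11 <- recording(matrix(rnorm(5500), 1), 500, "C3")
  expect_equal(dim(epoch_recording(rec11, 2)$data)[1], 5)
  short <- recording(matrix(rnorm(750), 1), 500, "C3")
  expect_error(epoch_recording(short, 2), "shorter")
})

test_that("epoch rejection drops exactly the constructed artifact", {
  set.seed(2)
  rec <- recording(matrix(rnorm(10000, sd = 10), 2), 500, c("C3", "C4"))
  ep <- epoch_recording(rec, 2)
  clean <- reject_epochs(ep)
  expect_equal(clean$kept_indices, 1:5)
  spiked <- ep
  spiked$data[3, 1, 100] <- 500
  out <- reject_epochs(spiked)
  expect_equal(out$kept_indices, c(1, 2, 4, 5))
  # kept + rejected = total
  expect_equal(length(out$kept_indices) + 1, dim(ep$data)[1])
  expect_equal(reject_epochs(spiked, abs_uV = Inf, z_max = Inf)$kept_indices,
               1:5)
  allbad <- ep
  allbad$data[] <- 1000
  expect_error(reject_epochs(allbad), "rejected")
})

test_that("EEG and EMG chains keep their paths separate and record provenance", {
  set.seed(3)
  n <- 8000
  dat <- rbind(matrix(rnorm(3 * n, sd = 10), 3), rnorm(n, sd = 40))
  rec <- recording(dat, 1000, c("C3", "M1", "M2", "EMG_L"),
                   meta = list(subject = "S01"))
  eeg <- preprocess_eeg(rec, reject = FALSE)
  expect_setequal(eeg$epochs$labels, c("C3", "M1", "M2"))
  expect_equal(eeg$epochs$rate, 500)
  ops <- vapply(eeg$continuous$meta$provenance, `[[`, "", "op")
  expect_equal(ops, c("bandpass", "notch", "notch", "resample", "rereference"))
  emg <- preprocess_emg(rec)
  expect_equal(emg$epochs$labels, "EMG_L")
  expect_equal(dim(emg$epochs$data)[3], 1000)
})
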