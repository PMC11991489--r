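true_model <- function(A, rate = 500) {
  structure(list(A = A, Sigma = diag(dim(A)[1]), order = dim(A)[3],
                 rate = rate, stable = TRUE, spectral_radius = NA,
                 labels = NULL), class = "mb_mvar")
}

test_that("MVAR fits recover known coefficients and reject bad input", {
  bat <- mvar_battery()
  for (nm in names(bat)) {
    A <- bat[[nm]]
    sim <- gen_mvar_data(A, n_samples = 20000, seed = 40)
    fit <- fit_mvar(sim, order = dim(A)[3])
    expect_lt(max(abs(fit$A - A)), 0.05, label = nm)
    expect_true(fit$stable)
  }
  # white noise at a forced order: all coefficients near zero
  wn <- recording(matrix(rnorm(3 * 10000), 3), 500,
                  c("a", "b", "c"))
  fit0 <- fit_mvar(wn, order = 3)
  expect_lt(max(abs(fit0$A)), 0.05)
  expect_error(fit_mvar(matrix(rnorm(20), 2), order = 4), "rate")
  short <- recording(matrix(rnorm(2 * 30), 2), 500, c("a", "b"))
  expect_error(fit_mvar(short, order = 20), "too few")
})

test_that("BIC selects the generating order for strongly autoregressive data", {
  A <- array(0, c(1, 1, 2))
  A[, , 1] <- 1.2
  A[, , 2] <- -0.8
  hits <- 0
  for (s in 1:10) {
    sim <- gen_mvar_data(A, n_samples = 3000, seed = 40 + s)
    fit <- fit_mvar(sim, max_order = 8)
    if (fit$order == 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("transfer function matches closed forms", {
  m0 <- true_model(array(0, c(3, 3, 1)))
  H <- transfer_function(m0, c(1, 10, 40))
  for (fi in 1:3) expect_equal(H[, , fi], diag(1 + 0i, 3))
  m1 <- true_model(array(0.5, c(1, 1, 1)))
  expect_equal(Re(transfer_function(m1, 0)[1, 1, 1]), 2)
  # lower-triangular coefficients force a lower-triangular H at every f
  A <- mvar_battery()$trivariate
  Hf <- transfer_function(true_model(A), seq(1, 100, by = 7))
  expect_lt(max(abs(Hf[upper.tri(matrix(0, 3, 3))])), 1e-12)
})

test_that("PDC is bounded, column-normalized, and zero without coupling", {
  diagA <- array(0, c(2, 2, 1))
  diagA[1, 1, 1] <- 0.6
  diagA[2, 2, 1] <- 0.4
  for (variant in c("paper_H", "standard_Abar")) {
    spec <- pdc(true_model(diagA), variant = variant)
    expect_true(all(spec$pdc >= 0 & spec$pdc <= 1))
    expect_equal(max(abs(spec$pdc[1, 2, ])), 0)
    expect_equal(max(abs(spec$pdc[2, 1, ])), 0)
  }
  A <- mvar_battery()$bivariate
  spec <- pdc(true_model(A), variant = "paper_H")
  cs <- apply(spec$pdc, c(2, 3), sum)
  expect_lt(max(abs(cs - 1)), 1e-10)
  # 1 -> 2 coupling flows, 2 -> 1 does not; value matches the closed form
  # |H21|^2/(|H11|^2+|H21|^2) with H = (I - A z)^{-1}, z = exp(-2i pi f/fs)
  f <- 10
  z <- exp(-2i * pi * f / 500)
  Ab <- diag(2) - A[, , 1] * z
  Hm <- solve(Ab)
  want <- Mod(Hm[2, 1])^2 / (Mod(Hm[1, 1])^2 + Mod(Hm[2, 1])^2)
  fi <- which(spec$freqs == f)
  expect_equal(spec$pdc[2, 1, fi], want, tolerance = 1e-12)
  expect_equal(spec$pdc[1, 2, fi], 0)
})

test_that("estimated PDC matches the ground-truth PDC across the grid", {
  for (nm in names(mvar_battery())) {
    A <- mvar_battery()[[nm]]
    sim <- gen_mvar_data(A, n_samples = 10000, seed = 43)
    fit <- fit_mvar(sim, order = dim(A)[3])
    est <- pdc(fit)
    truth <- pdc(true_model(A))
    expect_lt(max(abs(est$pdc - truth$pdc)), 0.05, label = nm)
  }
})

test_that("band PDC averages correctly and localizes narrowband coupling", {
  A <- mvar_battery()$bivariate
  spec <- pdc(true_model(A))
  bp <- band_pdc(spec, c(13, 30))
  sel <- spec$freqs >= 13 & spec$freqs <= 30
  expect_equal(bp$value[bp$source == "ch1" & bp$target == "ch2"],
               mean(spec$pdc[2, 1, sel]))
  # split-band linearity (equal-width halves of an even bin count)
  lohalf <- band_pdc(spec, c(13, 21))
  hihalf <- band_pdc(spec, c(21.5, 29.5))
  whole <- band_pdc(spec, c(13, 29.5))
  n1 <- sum(spec$freqs >= 13 & spec$freqs <= 21)
  n2 <- sum(spec$freqs >= 21.5 & spec$freqs <= 29.5)
  expect_equal(whole$value, (lohalf$value * n1 + hihalf$value * n2) / (n1 + n2))
  # oscillatory coupling around 45 Hz: gamma1 mean exceeds gamma2 mean
  Ao <- array(0, c(2, 2, 2))
  r <- 0.9
  th <- 2 * pi * 45 / 500
  Ao[1, 1, 1] <- 2 * r * cos(th)
  Ao[1, 1, 2] <- -r^2
  Ao[2, 2, 1] <- 0.3
  Ao[2, 1, 1] <- 0.5
  so <- pdc(true_model(Ao))
  g1 <- band_pdc(so, c(30, 60))
  g2 <- band_pdc(so, c(60, 100))
  expect_gt(g1$value[g1$source == "ch1" & g1$target == "ch2"],
            g2$value[g2$source == "ch1" & g2$target == "ch2"])
  expect_error(band_pdc(spec, c(300, 400)), "grid")
})

test_that("pdc_contrast flags injected directional effects under FDR", {
  set.seed(44)
  pairs_ <- expand.grid(source = c("C3", "C4", "EMG"),
                        target = c("C3", "C4", "EMG"),
                        stringsAsFactors = FALSE)
  pairs_ <- pairs_[pairs_$source != pairs_$target, ]
  mk <- function(n_sub, bump_pair = NULL, bump = 0) {
    do.call(rbind, lapply(seq_len(n_sub), function(s) {
      tb <- merge(pairs_, data.frame(band = c("beta", "gamma1", "gamma2")))
      tb$subject <- sprintf("S%02d", s)
      tb$value <- runif(nrow(tb), 0.1, 0.3)
      if (!is.null(bump_pair)) {
        hit <- tb$source == bump_pair[1] & tb$target == bump_pair[2] &
          tb$band == bump_pair[3]
        tb$value[hit] <- tb$value[hit] + bump
      }
      tb
    }))
  }
  a <- mk(12, c("C4", "EMG", "gamma1"), 0.4)
  b <- mk(12)
  con <- pdc_contrast(a, b)
  hit <- con[con$source == "C4" & con$target == "EMG" & con$band == "gamma1", ]
  expect_true(hit$q_significant)
  expect_equal(hit$direction, "increase")
  expect_lte(sum(con$q_significant), 3)    # essentially only the injected cell
  # null case: false positives bounded
  con0 <- pdc_contrast(mk(12), mk(12))
  expect_lte(mean(con0$q_significant), 0.05 + 1e-9)
  # constant large shift everywhere: everything flagged
  aa <- mk(12)
  bb <- aa
  bb$value <- bb$value - 0.5 + rnorm(nrow(bb), 0, 0.01)
  conA <- pdc_contrast(aa, bb)
  expect_true(all(conA$q_significant))
  expect_true(all(conA$direction == "increase"))
  # an exactly constant difference is a degenerate paired t-test
  cc <- aa
  cc$value <- cc$value - 0.5
  expect_error(pdc_contrast(aa, cc), "degenerate")
})
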