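test_that("analytic phase advances at the carrier rate and ignores amplitude", {
  rate <- 500
  t_ <- seq_len(5000) / rate
  ph <- analytic_phase(sin(2 * pi * 10 * t_))
  slope <- stats::coef(stats::lm(unwrap_phase(ph) ~ t_))[[2]] / (2 * pi)
  expect_lt(abs(slope - 10) / 10, 0.01)
  # quadrature offset between cos and sin
  pc <- analytic_phase(cos(2 * pi * 10 * t_))
  ps <- analytic_phase(sin(2 * pi * 10 * t_))
  d <- Arg(exp(1i * (pc - ps)))
  inner <- d[500:4500]
  expect_lt(max(abs(inner - pi / 2)), 0.01)
  expect_equal(analytic_phase(3.7 * sin(2 * pi * 10 * t_)), ps)
  expect_error(analytic_phase(rep(1, 100)), "constant")
})

test_that("plv_pair obeys its algebraic identities and the Bessel oracle", {
  ph <- runif(1000, -pi, pi)
  expect_equal(plv_pair(ph, ph), 1)
  px <- rep(0, 1000)
  py <- rep(c(0, pi), 500)
  expect_equal(plv_pair(px, py), 0, tolerance = 1e-12)
  set.seed(12)
  n <- 1e5
  dphi <- rvonmises(n, 0, 2)
  base <- runif(n, -pi, pi)
  expect_lt(abs(plv_pair(base, base - dphi) - vonmises_plv(2)), 3 / sqrt(n))
  expect_error(plv_pair(1:10, 1:9), "mismatch")
})

make_roi_epochs <- function(n_ep = 6, rate = 250, kappa_inter = 5,
                            seed = 1) {
  # two 3-channel groups locked to two alpha sources
  set.seed(seed)
  n <- n_ep * 2 * rate
  t_ <- seq_len(n) / rate
  thL <- 2 * pi * 10 * t_ + cumsum(rnorm(n, 0, 0.02))
  dphi <- mbconn::rvonmises(max(2, ceiling(n / (0.25 * rate)) + 1), 0,
                            kappa_inter)
  centers <- seq(1, n, length.out = length(dphi))
  delta <- atan2(approx(centers, sin(dphi), xout = 1:n)$y,
                 approx(centers, cos(dphi), xout = 1:n)$y)
  thR <- thL + delta
  labs <- c("L1", "L2", "L3", "R1", "R2", "R3")
  dat <- rbind(cos(thL), cos(thL + 0.3), cos(thL - 0.2),
               cos(thR), cos(thR + 0.1), cos(thR - 0.3)) +
    matrix(rnorm(6 * n, sd = 0.3), 6)
  rec <- recording(dat * 10, rate, labs)
  epoch_recording(rec, 2)
}

test_that("PLV matrices are symmetric, unit-diagonal, bounded and equivariant", {
  ep <- make_roi_epochs()
  map <- list(A = c("L1", "L2"), B = c("L3"), C = c("R1", "R2"), D = c("R3"))
  pm <- plv_matrix(ep, map, band = c(8, 13))
  M <- pm$plv
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 4))
  # same-source ROIs nearly locked
  expect_gt(M["A", "B"], 0.9)
  # permuting the ROI map permutes the matrix identically
  pm2 <- plv_matrix(ep, map[c(3, 1, 4, 2)], band = c(8, 13))
  expect_equal(pm2$plv[names(map), names(map)], M, tolerance = 1e-12)
  # amplitude scaling of channels leaves PLV untouched
  ep_scaled <- ep
  ep_scaled$data <- ep$data * 7
  pm3 <- plv_matrix(ep_scaled, map, band = c(8, 13))
  expect_equal(pm3$plv, M, tolerance = 1e-10)
  expect_error(plv_matrix(ep, list(A = "nope", B = "L1"), c(8, 13)), "missing")
})

test_that("inter-group PLV tracks the injected coupling strength", {
  map <- list(L = c("L1", "L2", "L3"), R = c("R1", "R2", "R3"))
  weak <- plv_matrix(make_roi_epochs(kappa_inter = 0.5, seed = 3), map,
                     c(8, 13))
  strong <- plv_matrix(make_roi_epochs(kappa_inter = 8, seed = 3), map,
                       c(8, 13))
  expect_gt(strong$plv["L", "R"], weak$plv["L", "R"] + 0.15)
})

test_that("independent noise channels sit near the finite-sample PLV floor", {
  set.seed(4)
  rec <- recording(matrix(rnorm(2 * 6000), 2) * 10, 250, c("a", "b"))
  ep <- epoch_recording(rec, 2)
  map <- list(A = "a", B = "b")
  pm <- plv_matrix(ep, map, band = c(8, 13))
  # narrow-band filtering leaves few independent phase samples per epoch;
  # the empirical null floor is well below the locked regime
  expect_lt(pm$plv["A", "B"], 0.6)
  expect_gt(pm$plv["A", "B"], 0)
})
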