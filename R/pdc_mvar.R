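# MVAR-based directed coherence between motor-cortex channels and muscle.
# Estimation is ordinary least squares on the stacked lag regression with
# BIC order selection; stability is checked on the companion matrix.

companion_spectral_radius <- function(A) {
  p <- dim(A)[3]
  N <- dim(A)[1]
  C <- matrix(0, N * p, N * p)
  for (k in seq_len(p)) C[1:N, ((k - 1) * N + 1):(k * N)] <- A[, , k]
  if (p > 1)
    C[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(N * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

mvar_ols <- function(X, p) {
  # X: samples x channels, demeaned
  n <- nrow(X)
  N <- ncol(X)
  Y <- X[(p + 1):n, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(k)
    X[(p + 1 - k):(n - k), , drop = FALSE]))
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop("rank-deficient lag regression")
  B <- qr.coef(qrZ, Y)                      # (N*p) x N
  E <- Y - Z %*% B
  Sigma <- crossprod(E) / (nrow(Y) - ncol(Z))
  A <- array(0, dim = c(N, N, p))
  for (k in seq_len(p))
    A[, , k] <- t(B[((k - 1) * N + 1):(k * N), , drop = FALSE])
  list(A = A, Sigma = Sigma, E = E, n_eff = nrow(Y))
}

#' Fit a multivariate autoregressive model
#'
#' OLS estimates of the coefficient matrices `A_1..A_p` in
#' `x_t = sum_k A_k x_{t-k} + e_t`. When `order` is `NULL` the order is
#' chosen by minimum BIC over `1..max_order`. Data are demeaned internally.
#'
#' @param data channels x samples matrix, or an `mb_recording`.
#' @param order model order, or `NULL` for BIC selection.
#' @param max_order largest order tried under BIC selection (default 20).
#' @param rate sampling rate in Hz (taken from the recording if given).
#' @return object of class `mb_mvar`: `A` (N x N x p array), `Sigma`
#'   (residual covariance), `order`, `rate`, `stable`, `bic` (per tried
#'   order), `labels`.
#' @export
fit_mvar <- function(data, order = NULL, max_order = 20, rate = NULL) {
  labels <- NULL
  if (inherits(data, "mb_recording")) {
    rate <- data$rate
    labels <- data$labels
    data <- data$data
  }
  if (is.null(rate)) stop("sampling rate required")
  X <- t(data)                               # samples x channels
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(X)
  N <- ncol(X)
  bic <- NULL
  if (is.null(order)) {
    orders <- seq_len(max_order)
    bic <- vapply(orders, function(p) {
      if (n - p <= N * p + 1) return(Inf)
      fit <- mvar_ols(X, p)
      ne <- fit$n_eff
      ne * determinant(fit$Sigma, logarithm = TRUE)$modulus +
        log(ne) * p * N^2
    }, 1.0)
    order <- orders[which.min(bic)]
  }
  if (n - order <= N * order + 1) stop("too few samples for this order")
  fit <- mvar_ols(X, order)
  rho <- companion_spectral_radius(fit$A)
  model <- structure(list(A = fit$A, Sigma = fit$Sigma, order = order,
                          rate = rate, stable = rho < 1,
                          spectral_radius = rho, bic = bic, labels = labels),
                     class = "mb_mvar")
  if (!model$stable)
    warning(sprintf("fitted MVAR is unstable (spectral radius %.3f)", rho))
  model
}

#' @export
print.mb_mvar <- function(x, ...) {
  cat(sprintf("<mb_mvar> %d channels, order %d, spectral radius %.3f%s\n",
              dim(x$A)[1], x$order, x$spectral_radius,
              if (x$stable) "" else " (UNSTABLE)"))
  invisible(x)
}

# Abar(f) = I - sum_k A_k exp(-i 2 pi f k / rate)
abar_at <- function(A, f, rate) {
  N <- dim(A)[1]
  p <- dim(A)[3]
  Ab <- diag(1 + 0i, N)
  for (k in seq_len(p))
    Ab <- Ab - A[, , k] * exp(-2i * pi * f * k / rate)
  Ab
}

#' MVAR transfer function on a frequency grid
#'
#' `H(f) = [I - sum_k A_k exp(-i 2 pi f k / rate)]^{-1}`.
#'
#' @param model an `mb_mvar`.
#' @param freqs frequency grid in Hz.
#' @return complex array N x N x length(freqs).
#' @export
transfer_function <- function(model, freqs) {
  N <- dim(model$A)[1]
  H <- array(0i, dim = c(N, N, length(freqs)))
  for (fi in seq_along(freqs)) {
    Ab <- abar_at(model$A, freqs[fi], model$rate)
    Hf <- tryCatch(solve(Ab), error = function(e)
      stop(sprintf("singular A(f) at %g Hz", freqs[fi])))
    H[, , fi] <- Hf
  }
  H
}

#' Partial directed coherence spectrum
#'
#' Directed influence from channel j (source) to channel i (target) per
#' frequency. Two variants:
#' \describe{
#'   \item{`paper_H`}{`|H_ij(f)|^2 / sum_k |H_kj(f)|^2`, a transfer-function
#'     based normalization whose per-source column sums are exactly 1 at
#'     every frequency (the study's printed formula).}
#'   \item{`standard_Abar`}{conventional PDC,
#'     `|Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)`.}
#' }
#' Both lie in `[0, 1]`.
#'
#' @param model an `mb_mvar`.
#' @param freqs frequency grid in Hz (default 1-100 Hz, step 0.5).
#' @param variant `"paper_H"` (default) or `"standard_Abar"`.
#' @return object of class `mb_pdc`: `freqs`, `pdc` (N x N x F array,
#'   target x source), `variant`, `labels`.
#' @export
pdc <- function(model, freqs = seq(1, 100, by = 0.5),
                variant = c("paper_H", "standard_Abar")) {
  variant <- match.arg(variant)
  N <- dim(model$A)[1]
  out <- array(0, dim = c(N, N, length(freqs)))
  for (fi in seq_along(freqs)) {
    Ab <- abar_at(model$A, freqs[fi], model$rate)
    if (variant == "paper_H") {
      M <- Mod(solve(Ab))^2
      cs <- colSums(M)
      if (any(cs == 0)) stop("zero denominator column in PDC")
      out[, , fi] <- sweep(M, 2, cs, "/")
    } else {
      M <- Mod(Ab)
      cs <- sqrt(colSums(M^2))
      if (any(cs == 0)) stop("zero denominator column in PDC")
      out[, , fi] <- sweep(M, 2, cs, "/")
    }
  }
  if (!is.null(model$labels))
    dimnames(out) <- list(model$labels, model$labels, NULL)
  structure(list(freqs = freqs, pdc = out, variant = variant,
                 labels = model$labels), class = "mb_pdc")
}

#' Band-averaged PDC
#'
#' Arithmetic mean of the PDC over in-band frequency bins, for every
#' directed (source -> target) pair.
#'
#' @param spec an `mb_pdc`.
#' @param band `(lo, hi)` in Hz.
#' @return data.frame with columns source, target, value.
#' @export
band_pdc <- function(spec, band) {
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (!length(sel)) stop("band outside frequency grid")
  N <- dim(spec$pdc)[1]
  labs <- if (is.null(spec$labels)) paste0("ch", seq_len(N)) else spec$labels
  M <- apply(spec$pdc[, , sel, drop = FALSE], c(1, 2), mean)
  idx <- which(row(M) != col(M), arr.ind = TRUE)
  data.frame(source = labs[idx[, 2]], target = labs[idx[, 1]],
             value = M[idx], stringsAsFactors = FALSE)
}

#' Paired condition contrast of band PDC values
#'
#' One paired test per (directed pair, band), BH-FDR across the whole
#' family, with the direction of the mean difference reported.
#'
#' @param tab_a,tab_b data.frames with columns subject, source, target,
#'   band, value — subject-matched between conditions.
#' @param q FDR level (default 0.05).
#' @param test `"t"` (paired t) or `"wilcoxon"`.
#' @return data.frame: source, target, band, statistic, p, q_significant,
#'   direction (`"increase"` means condition A > condition B).
#' @export
pdc_contrast <- function(tab_a, tab_b, q = 0.05, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  key <- function(tb) interaction(tb$source, tb$target, tb$band, drop = TRUE)
  cells <- sort(unique(as.character(key(tab_a))))
  if (!setequal(cells, unique(as.character(key(tab_b)))))
    stop("conditions cover different (pair, band) cells")
  rows <- list()
  for (cl in cells) {
    a <- tab_a[as.character(key(tab_a)) == cl, ]
    b <- tab_b[as.character(key(tab_b)) == cl, ]
    a <- a[order(a$subject), ]
    b <- b[order(b$subject), ]
    if (!identical(a$subject, b$subject))
      stop("subjects not matched for cell ", cl)
    res <- if (test == "t") paired_t(a$value, b$value)
           else wilcoxon_signed(a$value, b$value)
    rows[[length(rows) + 1]] <- data.frame(
      source = a$source[1], target = a$target[1], band = a$band[1],
      statistic = res$statistic, p = res$p,
      direction = if (mean(a$value - b$value) >= 0) "increase" else "decrease",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_significant <- fdr_bh(out$p, q)
  out
}
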