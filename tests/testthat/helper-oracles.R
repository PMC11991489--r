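# Independent brute-force oracles and small fixture builders, kept free of
# any package internals they are used to check.

# all-pairs shortest paths by exhaustive BFS
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + A[nb[a], nb[b]]
    vals[i] <- 2 * tri / (k * (k - 1))
  }
  mean(vals)
}

oracle_path_length <- function(A) {
  D <- bfs_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  D <- bfs_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    vals[i] <- oracle_global_eff(A[nb, nb, drop = FALSE]) # same normalization
  }
  mean(vals)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k <- i
  mask <- rep(FALSE, m)
  if (k > 0) mask[ord[seq_len(k)]] <- TRUE
  mask
}

random_sym_adj <- function(n, p_edge = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p_edge)
  A + t(A)
}

# symmetric unit-diagonal random "connectivity" stack for NBS tests
random_plv_stack <- function(n_roi, n_sub, shift = NULL) {
  arr <- array(0, c(n_roi, n_roi, n_sub))
  for (s in seq_len(n_sub)) {
    M <- matrix(stats::rnorm(n_roi^2), n_roi)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- 1
    if (!is.null(shift))
      for (e in seq_len(nrow(shift))) {
        M[shift[e, 1], shift[e, 2]] <- M[shift[e, 1], shift[e, 2]] + shift[e, 3]
        M[shift[e, 2], shift[e, 1]] <- M[shift[e, 1], shift[e, 2]]
      }
    arr[, , s] <- M
  }
  arr
}

sine_rec <- function(f, rate = 500, dur = 10, amp = 1, label = "C3") {
  t_ <- seq_len(round(rate * dur)) / rate
  recording(matrix(amp * sin(2 * pi * f * t_), 1), rate, label)
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  cumsum(c(ph[1], atan2(sin(d), cos(d))))
}

# tiny stable ground-truth MVAR battery used in recovery tests
mvar_battery <- function() {
  A2 <- array(0, c(2, 2, 1))
  A2[, , 1] <- matrix(c(0.5, 0, 0.4, 0.5), 2, byrow = TRUE)
  A3 <- array(0, c(3, 3, 2))
  A3[, , 1] <- matrix(c(0.5, 0, 0, 0.3, 0.4, 0, 0, 0.3, 0.5), 3, byrow = TRUE)
  A3[, , 2] <- matrix(c(-0.2, 0, 0, 0, -0.1, 0, 0, 0, -0.2), 3, byrow = TRUE)
  list(bivariate = A2, trivariate = A3)
}
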