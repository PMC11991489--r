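# Binary graph metrics on sparsity-thresholded connectivity matrices, with
# degree-preserving random-network nulls (Maslov-Sneppen double-edge swaps).

#' Threshold a weighted connectivity matrix by sparsity
#'
#' Keeps the `round(s * N(N-1)/2)` strongest off-diagonal weights as binary
#' undirected edges. Ties are broken deterministically by (weight
#' descending, row index, column index).
#'
#' @param W symmetric numeric matrix (weights), or an `mb_plv`.
#' @param s sparsity in (0, 1): fraction of possible edges retained.
#' @return binary symmetric adjacency matrix with zero diagonal and
#'   attribute `"sparsity"`.
#' @export
threshold_by_sparsity <- function(W, s) {
  if (inherits(W, "mb_plv")) W <- W$plv
  if (!(s > 0 && s < 1)) stop("sparsity must lie in (0, 1)")
  n <- nrow(W)
  m_possible <- n * (n - 1) / 2
  m <- round(s * m_possible)
  if (m < 1) stop("sparsity yields zero edges")
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(0L, n, n)
  A[cbind(ut[keep, 1], ut[keep, 2])] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(W)
  attr(A, "sparsity") <- s
  A
}

as_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Binary clustering coefficient (Watts-Strogatz)
#'
#' Mean over nodes of the local triangle density; nodes with degree < 2
#' contribute 0.
#'
#' @param A binary symmetric adjacency matrix.
#' @return clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(A) {
  g <- as_graph(A)
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered node pairs; disconnected
#' pairs are excluded (a `disconnected` attribute flags their presence).
#'
#' @param A binary symmetric adjacency matrix with at least one edge.
#' @return characteristic path length (with attribute `disconnected`).
#' @export
char_path_length <- function(A) {
  if (sum(A) == 0) stop("graph has no edges: path length undefined")
  d <- igraph::distances(as_graph(A))
  off <- d[row(d) != col(d)]
  conn <- is.finite(off)
  L <- mean(off[conn])
  attr(L, "disconnected") <- any(!conn)
  L
}

#' Global efficiency
#'
#' `E_g = 1/(N(N-1)) * sum_{i != j} 1/d_ij`, with zero contribution from
#' disconnected pairs.
#'
#' @param A binary symmetric adjacency matrix.
#' @return global efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  d <- igraph::distances(as_graph(A))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the efficiency of each node's neighbour subgraph with
#' the `1/(k_i (k_i - 1))` normalization; nodes with degree < 2 contribute 0.
#' Path lengths are computed within the neighbour subgraph.
#'
#' @param A binary symmetric adjacency matrix.
#' @return local efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- A[nb, nb, drop = FALSE]
    d <- igraph::distances(as_graph(sub))
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    vals[i] <- sum(inv) / (k * (k - 1))
  }
  mean(vals)
}

#' Degree-preserving random-network null
#'
#' Ensemble of Maslov-Sneppen double-edge-swap rewirings (100 x E attempted
#' swaps each) of the input graph; returns ensemble means of the clustering
#' coefficient and characteristic path length.
#'
#' @param A binary symmetric adjacency matrix with >= 2 edges.
#' @param n_random ensemble size (default 1000).
#' @param seed RNG seed (default NULL: leave RNG state alone).
#' @return list `C_random`, `L_random`, `n_random`, plus the per-network
#'   values.
#' @export
random_null <- function(A, n_random = 1000, seed = NULL) {
  if (sum(A) / 2 < 2) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  g <- as_graph(A)
  m <- igraph::ecount(g)
  Cs <- numeric(n_random)
  Ls <- numeric(n_random)
  for (r in seq_len(n_random)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 100 * m))
    Cs[r] <- mean(igraph::transitivity(gr, type = "localundirected",
                                       isolates = "zero"))
    d <- igraph::distances(gr)
    off <- d[row(d) != col(d)]
    Ls[r] <- mean(off[is.finite(off)])
  }
  list(C_random = mean(Cs), L_random = mean(Ls), n_random = n_random,
       C_each = Cs, L_each = Ls)
}

#' Small-world index and efficiencies at one sparsity level
#'
#' sigma = gamma / lambda with gamma = C_actual / C_random and lambda =
#' L_actual / L_random; sigma > 1 indicates small-world organization.
#'
#' @param A binary symmetric adjacency matrix.
#' @param n_random null-ensemble size.
#' @param seed RNG seed.
#' @return one-row data.frame with C_actual, L_actual, C_random, L_random,
#'   gamma, lambda, sigma, E_g, E_loc.
#' @export
smallworld_metrics <- function(A, n_random = 1000, seed = NULL) {
  C <- clustering_coefficient(A)
  L <- char_path_length(A)
  null <- random_null(A, n_random, seed)
  gamma <- C / null$C_random
  lambda <- as.numeric(L) / null$L_random
  data.frame(C_actual = C, L_actual = as.numeric(L),
             C_random = null$C_random, L_random = null$L_random,
             gamma = gamma, lambda = lambda, sigma = gamma / lambda,
             E_g = global_efficiency(A), E_loc = local_efficiency(A))
}

#' Graph metrics across a sparsity range
#'
#' Thresholds a weighted matrix at each sparsity level, computes
#' small-world and efficiency metrics against degree-preserving nulls, and
#' appends the across-level arithmetic mean (AUC-style aggregate) as a row
#' with `sparsity = NA`.
#'
#' @param W weighted symmetric matrix or `mb_plv`.
#' @param s_range sparsity levels (default 0.22-0.29 step 0.01).
#' @param n_random null-ensemble size per level (default 1000).
#' @param seed master seed; each level gets a derived substream.
#' @return data.frame, one row per level plus the aggregate row.
#' @export
metrics_over_sparsity <- function(W, s_range = seq(0.22, 0.29, by = 0.01),
                                  n_random = 1000, seed = NULL) {
  rows <- list()
  for (k in seq_along(s_range)) {
    s <- s_range[k]
    row <- tryCatch({
      A <- threshold_by_sparsity(W, s)
      sk <- if (is.null(seed)) NULL else substream_seed(seed, paste0("sp", k))
      cbind(data.frame(sparsity = s), smallworld_metrics(A, n_random, sk))
    }, error = function(e) {
      warning(sprintf("sparsity %g failed: %s", s, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  agg <- out[1, , drop = FALSE]
  agg$sparsity <- NA
  for (cn in setdiff(names(out), "sparsity")) agg[[cn]] <- mean(out[[cn]])
  rbind(out, agg)
}
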