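# Group-level statistics: outlier replacement, paired tests, BH-FDR, and
# the network-based statistic (NBS) for paired connectivity designs.

#' Replace extreme values by the mean of the remaining values
#'
#' Values whose z-score (against the sample mean/SD) exceeds `z_limit` in
#' magnitude are replaced by the mean of the non-flagged values; all other
#' values are untouched. A second pass changes nothing.
#'
#' @param x numeric vector, length >= 3.
#' @param z_limit z-score threshold (default 3).
#' @return corrected vector.
#' @export
replace_outliers <- function(x, z_limit = 3) {
  if (length(x) < 3) stop("need at least 3 values")
  s <- stats::sd(x)
  if (s == 0) return(x)
  z <- (x - mean(x)) / s
  bad <- abs(z) > z_limit
  if (all(bad)) stop("all values flagged as outliers")
  if (any(bad)) x[bad] <- mean(x[!bad])
  x
}

#' Paired-sample tests
#'
#' Thin wrappers around the classical tests, returning `(statistic, p)` with
#' two-sided p-values.
#'
#' @param a,b matched numeric vectors (one value per subject).
#' @return named list with `statistic` and `p`.
#' @export
paired_t <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(statistic = 0, p = 1))
    stop("zero variance of differences: t-test degenerate")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname paired_t
#' @export
wilcoxon_signed <- function(a, b) {
  if (all(a == b)) return(list(statistic = 0, p = 1))
  ht <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Friedman test for k matched samples
#' @param mat numeric matrix, subjects x conditions (k >= 2 columns).
#' @return named list with `statistic` (chi-squared) and `p`.
#' @export
friedman <- function(mat) {
  mat <- as.matrix(mat)
  if (all(apply(mat, 1, function(r) length(unique(r))) == 1))
    return(list(statistic = 0, p = 1))   # every subject ties all conditions
  ht <- stats::friedman.test(mat)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q` (via `stats::p.adjust`).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical rejection mask of the same length.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

# vectorised paired t statistics over columns of D (subjects x edges),
# optionally under a matrix of sign flips S (n_perm x subjects)
edgewise_t <- function(D, S = NULL) {
  n <- nrow(D)
  msq <- colMeans(D^2)
  tfun <- function(m) {
    v <- (msq - m^2) * n / (n - 1)
    v[v <= 0] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  if (is.null(S)) return(tfun(colMeans(D)))
  M <- (S %*% D) / n
  t(apply(M, 1, tfun))
}

max_component_extent <- function(mask_vec, pairs, n_nodes) {
  on <- which(mask_vec)
  if (!length(on)) return(0L)
  g <- igraph::graph_from_edgelist(pairs[on, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # component extent = number of suprathreshold edges inside the component
  max(tabulate(comp[pairs[on, 1]]))
}

#' Network-based statistic for a paired design
#'
#' Edge-wise paired t-tests on subject-matched connectivity matrices; edges
#' with `p < edge_alpha` form a suprathreshold mask whose connected
#' components are scored by extent (edge count). Family-wise significance is
#' assessed against the permutation null distribution of the maximum
#' component extent under random per-subject sign flips of the difference
#' matrices, with the +1 small-sample correction (smallest attainable p is
#' `1/(n_perm+1)`).
#'
#' @param stack_a,stack_b arrays `n_roi x n_roi x n_subjects` of symmetric
#'   connectivity matrices, subject-matched.
#' @param edge_alpha edge-level p threshold (default 0.05).
#' @param comp_alpha component-level alpha (default 0.05).
#' @param n_perm permutations (default 2000).
#' @param seed RNG seed.
#' @return list of class `mb_nbs`: `t` and `p` edge matrices, `components`
#'   (list of edge data.frames with p-values), `null_max` distribution,
#'   `significant` (any component p < comp_alpha).
#' @export
nbs_paired <- function(stack_a, stack_b, edge_alpha = 0.05,
                       comp_alpha = 0.05, n_perm = 2000, seed = NULL) {
  da <- dim(stack_a)
  if (!identical(da, dim(stack_b))) stop("stacks differ in shape")
  n_sub <- da[3]
  if (n_sub < 2) stop("need at least 2 subjects")
  n <- da[1]
  rois <- dimnames(stack_a)[[1]]
  if (is.null(rois)) rois <- paste0("R", seq_len(n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  D <- t(apply(stack_a - stack_b, 3, function(m) m[upper.tri(m)]))
  if (n_sub == 1) D <- matrix(D, nrow = 1)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- edgewise_t(D)
  p_obs <- 2 * stats::pt(-abs(t_obs), df = n_sub - 1)
  tcrit <- stats::qt(1 - edge_alpha / 2, df = n_sub - 1)
  mask <- abs(t_obs) > tcrit

  # observed components
  comps <- list()
  if (any(mask)) {
    on <- which(mask)
    g <- igraph::graph_from_edgelist(ut[on, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    for (cid in unique(memb[ut[on, 1]])) {
      sel <- on[memb[ut[on, 1]] == cid]
      comps[[length(comps) + 1]] <- data.frame(
        from = rois[ut[sel, 1]], to = rois[ut[sel, 2]],
        t = t_obs[sel], p_edge = p_obs[sel], stringsAsFactors = FALSE)
    }
  }
  # permutation null of the maximum component extent
  S <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
              n_perm, n_sub)
  Tm <- edgewise_t(D, S)
  null_max <- integer(n_perm)
  for (r in seq_len(n_perm))
    null_max[r] <- max_component_extent(abs(Tm[r, ]) > tcrit, ut, n)
  for (i in seq_along(comps)) {
    ext <- nrow(comps[[i]])
    attr(comps[[i]], "extent") <- ext
    attr(comps[[i]], "p") <- (1 + sum(null_max >= ext)) / (n_perm + 1)
  }
  tmat <- matrix(0, n, n, dimnames = list(rois, rois))
  pmat <- matrix(1, n, n, dimnames = list(rois, rois))
  tmat[upper.tri(tmat)] <- t_obs
  pmat[upper.tri(pmat)] <- p_obs
  tmat <- tmat + t(tmat)
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  comp_p <- vapply(comps, function(cp) attr(cp, "p"), 1.0)
  structure(list(t = tmat, p = pmat, components = comps,
                 component_p = comp_p, null_max = null_max,
                 edge_alpha = edge_alpha, comp_alpha = comp_alpha,
                 n_perm = n_perm,
                 significant = length(comp_p) > 0 && any(comp_p < comp_alpha)),
            class = "mb_nbs")
}

#' @export
print.mb_nbs <- function(x, ...) {
  cat(sprintf("<mb_nbs> %d suprathreshold component(s), %d permutations\n",
              length(x$components), x$n_perm))
  for (i in seq_along(x$components))
    cat(sprintf("  component %d: %d edges, p = %.4f\n", i,
                nrow(x$components[[i]]), x$component_p[i]))
  invisible(x)
}
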