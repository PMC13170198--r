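# Shared inference machinery: cluster-mass permutation tests for 1-D time
# series and 2-D temporal-generalization maps, Benjamini-Hochberg FDR, and
# Welch's two-sample t (the generic routine used for amplitude comparisons).

#' Benjamini-Hochberg false discovery rate correction
#'
#' @param pvalues vector of p-values (NA allowed, passed through).
#' @param alpha FDR level.
#' @return list: `p_adjusted`, `significant` (adjusted p <= alpha).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0)
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  adj <- p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= alpha)
}

#' Welch's two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] with unequal variances, returned as a
#' flat record.
#'
#' @param x,y samples.
#' @return list: `t`, `df`, `p`, `mean_diff`.
#' @export
welch_t <- function(x, y) {
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(x) - mean(y))
}

# one-sample t statistics per column, vectorized over sign-flip permutations:
# for flips s (n_perm x S) the per-column sum of squares is invariant, so
# t = m / sqrt((ssq/S - m^2) / (S - 1) / S) with m = (s %*% x) / S.
flip_t_matrix <- function(x, flips) {
  S <- nrow(x)
  ssq <- colSums(x^2)
  m <- (flips %*% x) / S
  v <- (rep(ssq, each = nrow(flips)) / S - m^2) * S / (S - 1)
  t <- m / sqrt(v / S)
  t[!is.finite(t)] <- 0
  t
}

one_sample_t <- function(x) {
  S <- nrow(x)
  m <- colMeans(x)
  v <- apply(x, 2, var)
  t <- m / sqrt(v / S)
  t[!is.finite(t)] <- 0   # zero-variance bins carry no evidence
  t
}

# contiguous clusters of a supra-threshold sign pattern in 1-D; returns list
# of (indices, mass)
clusters_1d <- function(tvals, thresh) {
  lab <- ifelse(tvals > thresh, 1L, ifelse(tvals < -thresh, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    list(indices = idx, mass = sum(tvals[idx]))
  })
}

# 4-connected clusters on a 2-D grid; mask is a logical matrix
clusters_2d_mask <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  out <- list()
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i, j), 1)
    cells <- NULL
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
      if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask))
        next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      cells <- rbind(cells, p)
      stack <- rbind(stack, c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                     c(p[1], p[2] - 1), c(p[1], p[2] + 1))
    }
    out[[cur]] <- cells
  }
  out
}

max_cluster_mass_1d <- function(tvals, thresh) {
  cl <- clusters_1d(tvals, thresh)
  if (length(cl) == 0) return(0)
  max(vapply(cl, function(c) abs(c$mass), numeric(1)))
}

#' Cluster-mass permutation test for time series
#'
#' Bin-wise one-sample (or paired-difference) t-tests at a two-tailed
#' cluster-forming threshold define contiguous clusters; each cluster's mass
#' (sum of t within it) is compared against the maximum cluster mass under
#' sign-flipping permutations of the subject data. Positive and negative
#' clusters are handled separately; the null uses the maximum absolute mass,
#' and the p-value includes the observed permutation (add-one rule).
#'
#' @param data subjects x bins matrix. For a paired test pass the per-subject
#'   condition difference; for one-sample, the series itself.
#' @param mu0 null value subtracted before testing.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param alpha cluster-level significance (FWER).
#' @param cluster_alpha two-tailed cluster-forming threshold on the bin-wise
#'   t-tests.
#' @return list of class `cluster_test`: `clusters` (data.frame: start, end,
#'   extent, mass, p, significant), `significant_mask` (per bin), `t`
#'   (observed bin-wise t), `n_perm`, `alpha`.
#' @export
cluster_perm_1d <- function(data, mu0 = 0, n_perm = 5000, alpha = 0.05,
                            cluster_alpha = 0.05) {
  data <- as.matrix(data)
  S <- nrow(data)
  if (S < 3) stop("need at least 3 subjects")
  if (n_perm < 100) stop("n_perm must be at least 100")
  x <- sweep(data, 2, rep(mu0, ncol(data)), `-`)
  thresh <- stats::qt(1 - cluster_alpha / 2, df = S - 1)
  tobs <- one_sample_t(x)
  cl <- clusters_1d(tobs, thresh)
  flips <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  tnull <- flip_t_matrix(x, flips)
  null_max <- vapply(seq_len(n_perm), function(p)
    max_cluster_mass_1d(tnull[p, ], thresh), numeric(1))
  mask <- rep(FALSE, ncol(data))
  rows <- lapply(cl, function(c) {
    p <- (1 + sum(null_max >= abs(c$mass))) / (1 + n_perm)
    sig <- p <= alpha
    if (sig) mask[c$indices] <<- TRUE
    data.frame(start = min(c$indices), end = max(c$indices),
               extent = length(c$indices), mass = c$mass, p = p,
               significant = sig)
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), extent = integer(0),
               mass = numeric(0), p = numeric(0), significant = logical(0))
  structure(list(clusters = clusters, significant_mask = mask, t = tobs,
                 n_perm = n_perm, alpha = alpha,
                 cluster_alpha = cluster_alpha),
            class = "cluster_test")
}

#' Cluster-mass permutation test on a 2-D train x test map
#'
#' Identical machinery to [cluster_perm_1d()] with 4-connectivity clustering
#' on the 2-D grid of train x test bins.
#'
#' @param data subjects x train-bins x test-bins array.
#' @inheritParams cluster_perm_1d
#' @return list of class `cluster_test_2d`: `clusters` (data.frame: extent,
#'   mass, p, significant), `significant_mask` (train x test logical),
#'   `t` (train x test), `n_perm`, `alpha`.
#' @export
cluster_perm_2d <- function(data, mu0 = 0, n_perm = 5000, alpha = 0.05,
                            cluster_alpha = 0.05) {
  stopifnot(length(dim(data)) == 3)
  S <- dim(data)[1]
  if (S < 3) stop("need at least 3 subjects")
  if (n_perm < 100) stop("n_perm must be at least 100")
  d1 <- dim(data)[2]; d2 <- dim(data)[3]
  flat <- matrix(data, S, d1 * d2) - mu0
  thresh <- stats::qt(1 - cluster_alpha / 2, df = S - 1)
  tobs <- matrix(one_sample_t(flat), d1, d2)
  flips <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  tnull <- flip_t_matrix(flat, flips)
  null_max <- vapply(seq_len(n_perm), function(p) {
    tm <- matrix(tnull[p, ], d1, d2)
    cls <- c(clusters_2d_mask(tm > thresh), clusters_2d_mask(tm < -thresh))
    if (length(cls) == 0) return(0)
    max(vapply(cls, function(cells)
      abs(sum(tm[cells])), numeric(1)))
  }, numeric(1))
  pos <- clusters_2d_mask(tobs > thresh)
  neg <- clusters_2d_mask(tobs < -thresh)
  mask <- matrix(FALSE, d1, d2)
  rows <- lapply(c(pos, neg), function(cells) {
    mass <- sum(tobs[cells])
    p <- (1 + sum(null_max >= abs(mass))) / (1 + n_perm)
    sig <- p <= alpha
    if (sig) mask[cells] <<- TRUE
    data.frame(extent = nrow(cells), mass = mass, p = p, significant = sig)
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(extent = integer(0), mass = numeric(0), p = numeric(0),
               significant = logical(0))
  structure(list(clusters = clusters, significant_mask = mask, t = tobs,
                 n_perm = n_perm, alpha = alpha,
                 cluster_alpha = cluster_alpha),
            class = "cluster_test_2d")
}
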