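# Regression-based representational similarity analysis: time-resolved
# pairwise-decoding neural RDMs (shrinkage LDA on pseudo-trials) regressed
# on mean-direction, variance and category model RDMs.

# binary linear discriminant with pooled covariance; shrinks the covariance
# toward a scaled identity when the feature count approaches the per-fold
# sample count (flagged via attribute).
lda_fit <- function(x, y, shrink_if = nrow(x) <= 2 * ncol(x), gamma = 0.2) {
  lev <- sort(unique(as.character(y)))
  stopifnot(length(lev) == 2)
  x0 <- x[y == lev[1], , drop = FALSE]
  x1 <- x[y == lev[2], , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  S <- (crossprod(sweep(x0, 2, m0)) + crossprod(sweep(x1, 2, m1))) /
    (nrow(x) - 2)
  shrunk <- FALSE
  if (shrink_if) {
    S <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(ncol(x))
    shrunk <- TRUE
  }
  S <- S + 1e-8 * mean(diag(S)) * diag(ncol(x))
  w <- solve(S, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2
  structure(list(w = w, b = b, levels = lev, shrunk = shrunk),
            class = "lda_binary")
}

#' @export
predict.lda_binary <- function(object, newdata, ...) {
  object$levels[(drop(as.matrix(newdata) %*% object$w) + object$b > 0) + 1]
}

#' Build chunked pseudo-trials
#'
#' Trials of each of the 16 stimulus conditions (8 directions x hom/het) are
#' split into `n_chunks` independent chunks (stratified by trial order, to
#' balance slow drift); within each chunk, `n_synth` pseudo-trials are
#' created, each the average of a random `frac` subset (at least one trial).
#'
#' @inheritParams iem_timecourse
#' @param n_chunks number of chunks (cross-validation folds downstream).
#' @param frac fraction of a chunk's trials averaged into one pseudo-trial.
#' @param n_synth pseudo-trials per condition and chunk (500 in the
#'   reference protocol; reduce for desk-scale runs).
#' @return list of class `pseudo_trials`: `conditions` (data.frame:
#'   direction, variance), `bin_times`, and `data[[cond]][[chunk]]` =
#'   pseudo-trials x neurons x bins array.
#' @export
pseudo_trials <- function(traces, trials, n_chunks = 4, frac = 0.25,
                          n_synth = 500, correct_only = TRUE,
                          epoch = c(-0.5, 4), bin_width = NULL) {
  tr <- filter_trials(trials, NULL, correct_only)
  conds <- expand.grid(direction = direction_set(),
                       variance = c("hom", "het"),
                       stringsAsFactors = FALSE)
  conds <- conds[conds$variance %in% unique(tr$variance_condition), ]
  arr <- binned_epoch_array(traces, tr, epoch, bin_width)
  n_bins <- dim(arr)[3]
  data <- vector("list", nrow(conds))
  for (ci in seq_len(nrow(conds))) {
    idx <- which(tr$mean_direction == conds$direction[ci] &
                   tr$variance_condition == conds$variance[ci])
    if (length(idx) < n_chunks)
      stop("condition ", conds$direction[ci], "/", conds$variance[ci],
           " has ", length(idx), " trials; need >= ", n_chunks)
    chunk_of <- rep_len(seq_len(n_chunks), length(idx))  # order-stratified
    data[[ci]] <- lapply(seq_len(n_chunks), function(ch) {
      members <- idx[chunk_of == ch]
      k <- max(1L, round(frac * length(members)))
      out <- array(NA_real_, c(n_synth, dim(arr)[2], n_bins))
      for (s in seq_len(n_synth)) {
        pick <- if (length(members) == 1) members else sample(members, k)
        out[s, , ] <- if (length(pick) == 1) arr[pick, , ] else
          colMeans(arr[pick, , , drop = FALSE], dims = 1)
      }
      out
    })
  }
  structure(list(conditions = conds, bin_times = attr(arr, "bin_times"),
                 n_chunks = n_chunks, data = data),
            class = "pseudo_trials")
}

#' Pairwise-decoding neural RDM at one time bin
#'
#' For every unordered pair of stimulus conditions, a shrinkage-LDA
#' classifier is trained and tested with chunk-wise cross-validation
#' (`n_chunks`-fold, folds = chunks) on the pseudo-trials; the mean decoding
#' accuracy fills the symmetric RDM (higher accuracy = greater neural
#' dissimilarity).
#'
#' @param pseudo a [pseudo_trials()] object.
#' @param time_bin bin index into `pseudo$bin_times`.
#' @return n_cond x n_cond symmetric matrix, NA diagonal; attribute
#'   `shrunk` reports whether covariance shrinkage was engaged.
#' @export
pairwise_rdm <- function(pseudo, time_bin) {
  nc <- nrow(pseudo$conditions)
  n_chunks <- pseudo$n_chunks
  rdm <- matrix(NA_real_, nc, nc)
  shrunk <- FALSE
  slice <- function(ci, ch) pseudo$data[[ci]][[ch]][, , time_bin,
                                                    drop = FALSE][, , 1]
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    acc <- 0
    for (f in seq_len(n_chunks)) {
      tri <- do.call(rbind, lapply(setdiff(seq_len(n_chunks), f),
                                   function(ch) slice(i, ch)))
      trj <- do.call(rbind, lapply(setdiff(seq_len(n_chunks), f),
                                   function(ch) slice(j, ch)))
      fit <- lda_fit(rbind(tri, trj),
                     rep(c("a", "b"), c(nrow(tri), nrow(trj))))
      shrunk <- shrunk || fit$shrunk
      tei <- slice(i, f); tej <- slice(j, f)
      acc <- acc + (mean(predict(fit, tei) == "a") +
                      mean(predict(fit, tej) == "b")) / 2
    }
    rdm[i, j] <- rdm[j, i] <- acc / n_chunks
  }
  attr(rdm, "shrunk") <- shrunk
  rdm
}

#' Model RDMs for mean direction, variance and category
#'
#' The mean-direction model is one minus the cosine similarity of the
#' channel-basis response vectors of the two directions (identical across
#' variance pairings); the variance and category models are binary
#' same/different matrices.
#'
#' @param conditions data.frame with `direction` and `variance` columns (the
#'   ordering of the RDM rows); defaults to the canonical 16 conditions.
#' @return list of class `model_rdms`: `mean_rdm`, `variance_rdm`,
#'   `category_rdm` and `conditions`.
#' @export
build_model_rdms <- function(conditions = NULL) {
  if (is.null(conditions))
    conditions <- expand.grid(direction = direction_set(),
                              variance = c("hom", "het"),
                              stringsAsFactors = FALSE)
  B <- make_basis(conditions$direction)      # channels x conditions
  nb <- sqrt(colSums(B^2))
  cossim <- crossprod(B) / outer(nb, nb)
  mean_rdm <- 1 - cossim
  mean_rdm <- (mean_rdm + t(mean_rdm)) / 2
  mean_rdm <- mean_rdm / max(mean_rdm)       # scale to [0, 1]
  variance_rdm <- outer(conditions$variance, conditions$variance, `!=`) * 1
  cat <- direction_category(conditions$direction)
  category_rdm <- outer(cat, cat, `!=`) * 1
  structure(list(mean_rdm = mean_rdm, variance_rdm = variance_rdm,
                 category_rdm = category_rdm, conditions = conditions),
            class = "model_rdms")
}

#' Regress a neural RDM on the model RDMs
#'
#' Vectorizes the off-diagonal upper triangles, z-scores each model vector
#' and fits `neural ~ mean + variance + category` by OLS.
#'
#' @param neural symmetric neural RDM (one time bin).
#' @param models a [build_model_rdms()] object.
#' @return named numeric: `beta0`, `beta_mean`, `beta_variance`,
#'   `beta_category`.
#' @export
regress_rdm <- function(neural, models) {
  ut <- upper.tri(neural)
  zs <- function(m) {
    v <- m[ut]
    (v - mean(v)) / sd(v)
  }
  df <- data.frame(y = neural[ut], mean = zs(models$mean_rdm),
                   variance = zs(models$variance_rdm),
                   category = zs(models$category_rdm))
  beta <- coef(lm(y ~ mean + variance + category, data = df))
  c(beta0 = unname(beta[1]), beta_mean = unname(beta[2]),
    beta_variance = unname(beta[3]), beta_category = unname(beta[4]))
}

#' Time-resolved RSA of one session
#'
#' Convenience wrapper: builds pseudo-trials, computes the pairwise-decoding
#' RDM at every bin and regresses each on the model RDMs.
#'
#' @inheritParams pseudo_trials
#' @return list of class `rsa_result`: `betas` (bins x 4), `bin_times`,
#'   `rdms` (list of per-bin matrices), `models`.
#' @export
rsa_timecourse <- function(traces, trials, n_chunks = 4, frac = 0.25,
                           n_synth = 500, correct_only = TRUE,
                           epoch = c(-0.5, 4), bin_width = NULL) {
  pseudo <- pseudo_trials(traces, trials, n_chunks, frac, n_synth,
                          correct_only, epoch, bin_width)
  models <- build_model_rdms(pseudo$conditions)
  n_bins <- length(pseudo$bin_times)
  rdms <- vector("list", n_bins)
  betas <- matrix(NA_real_, n_bins, 4,
                  dimnames = list(NULL, c("beta0", "beta_mean",
                                          "beta_variance", "beta_category")))
  for (b in seq_len(n_bins)) {
    rdms[[b]] <- pairwise_rdm(pseudo, b)
    betas[b, ] <- regress_rdm(rdms[[b]], models)
  }
  structure(list(betas = betas, bin_times = pseudo$bin_times, rdms = rdms,
                 models = models), class = "rsa_result")
}
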