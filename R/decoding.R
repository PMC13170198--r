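# Trial-resolved decoding: the inverted encoding model (IEM) for mean
# direction, linear SVM classifiers for variance and category (including
# within- vs between-category discrimination), and temporal generalization.

#' Channel basis of half-sinusoids raised to the sixth power
#'
#' Eight hypothetical channel tuning functions centered at the canonical
#' directions; channel j responds `cos(delta/2)^6` where delta is the
#' wrapped difference between the stimulus direction and the channel center.
#' Each basis function is 1 at its center, 0 at the opposite direction, and
#' the set tiles the circle (their sum is constant).
#'
#' @param directions stimulus directions (degrees), one per trial/column.
#' @param centers channel centers (degrees).
#' @return channels x length(directions) basis matrix of class
#'   `channel_basis` with attribute `centers`.
#' @export
make_basis <- function(directions, centers = direction_set()) {
  C <- outer(centers, directions, function(cc, th)
    cos(deg2rad(wrap180(th - cc)) / 2)^6)
  rownames(C) <- centers
  structure(C, centers = centers, class = c("channel_basis", "matrix"))
}

# Moore-Penrose pseudoinverse via SVD. The cos^6 basis is band-limited to
# circular harmonics 0..3, so the 8 channel profiles span only a 7-dim
# space and C1 C1' (and W'W) are exactly rank deficient; the normal
# equations are therefore solved with pseudoinverses throughout.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Estimate IEM channel weights
#'
#' Solves the forward model `B1 = W C1` for the neurons x channels weight
#' matrix via the normal equation `W = B1 C1' (C1 C1')^+` (pseudoinverse,
#' since the channel basis is band-limited and `C1 C1'` is rank 7).
#'
#' @param B1 neurons x trials training activity.
#' @param C1 channels x trials basis matrix from [make_basis()].
#' @return list of class `iem_model`: `W` (neurons x channels), `centers`.
#' @export
iem_fit <- function(B1, C1) {
  B1 <- as.matrix(B1); C1 <- as.matrix(C1)
  stopifnot(ncol(B1) == ncol(C1))
  n_distinct <- nrow(unique(round(t(C1), 10)))
  if (n_distinct < nrow(C1))
    stop("the training set needs at least ", nrow(C1),
         " distinct directions, got ", n_distinct)
  G <- tcrossprod(C1)
  W <- B1 %*% t(C1) %*% pinv(G)
  structure(list(W = W, centers = attr(C1, "centers")), class = "iem_model")
}

#' Invert an IEM on test activity
#'
#' `C2 = (W'W)^+ W' B2`, the minimum-norm least-squares channel-response
#' estimate for each test trial.
#'
#' @param model an [iem_fit()] result.
#' @param B2 neurons x test-trials activity.
#' @return channels x test-trials matrix of channel responses.
#' @export
iem_invert <- function(model, B2) {
  W <- model$W
  if (nrow(W) < ncol(W) - 1)
    stop("too few neurons to span the channel space; more (linearly ",
         "independent) neurons are needed")
  # W'W is rank deficient by construction (band-limited basis) and may be
  # further degenerate for structureless data; the pseudoinverse returns the
  # minimum-norm channel estimate in every case
  out <- pinv(crossprod(W)) %*% crossprod(W, as.matrix(B2))
  rownames(out) <- model$centers
  out
}

# zero-center channel responses on each trial's labeled direction and
# average: returns the 8-offset channel tuning function (CTF)
align_ctf <- function(C2, labels, centers = direction_set()) {
  offs <- prc_offsets()
  acc <- matrix(0, length(offs), ncol(C2))
  for (j in seq_len(ncol(C2))) {
    o <- wrap180(centers - labels[j])
    acc[, j] <- C2[match(offs, o), j]
  }
  ctf <- rowMeans(acc)
  names(ctf) <- offs
  ctf
}

#' Slope of a channel tuning function
#'
#' The offsets +45, +90 and +135 are sign-reversed and an OLS line with
#' intercept is fitted across the resulting eight points
#' (-180, -135, -135, -90, -90, -45, -45, 0); the slope summarizes how
#' sharply the reconstruction peaks at the true direction.
#'
#' @param ctf named 8-vector of channel responses at offsets -135..180 (as
#'   returned by [align_ctf()] / [iem_timecourse()]).
#' @return the regression slope (response units per degree).
#' @export
ctf_slope <- function(ctf) {
  offs <- as.numeric(names(ctf))
  if (is.null(offs) || anyNA(offs)) offs <- prc_offsets()
  x <- -abs(offs)
  unname(stats::cov(x, ctf) / stats::var(x))
}

#' Time-resolved IEM decoding
#'
#' Homogeneous trials are decoded with leave-one-trial-out cross-validation
#' at every time bin (training and testing at the same bin); heterogeneous
#' trials are decoded with the weight matrix trained on all homogeneous
#' trials of that bin. Reports the CTF slope per bin and condition.
#'
#' @inheritParams compute_tuning
#' @param epoch,bin_width epoch definition as in [binned_epoch_array()].
#' @return list of class `decoding_series`: `bin_times`, `slope_hom`,
#'   `slope_het`, `ctf_hom`, `ctf_het` (offsets x bins).
#' @export
iem_timecourse <- function(traces, trials, correct_only = TRUE,
                           epoch = c(-0.5, 4), bin_width = NULL) {
  tr_h <- filter_trials(trials, "hom", correct_only)
  tr_e <- filter_trials(trials, "het", correct_only)
  arr_h <- binned_epoch_array(traces, tr_h, epoch, bin_width)
  arr_e <- if (nrow(tr_e)) binned_epoch_array(traces, tr_e, epoch, bin_width)
  bin_times <- attr(arr_h, "bin_times")
  n_bins <- dim(arr_h)[3]
  C1_all <- make_basis(tr_h$mean_direction)
  offs <- prc_offsets()
  ctf_hom <- ctf_het <- matrix(NA_real_, 8, n_bins, dimnames = list(offs))
  for (b in seq_len(n_bins)) {
    Bh <- t(arr_h[, , b])                        # neurons x trials
    # hom: leave-one-trial-out
    acc <- matrix(0, 8, ncol(Bh))
    for (i in seq_len(ncol(Bh))) {
      m <- iem_fit(Bh[, -i, drop = FALSE], C1_all[, -i, drop = FALSE])
      acc[, i] <- iem_invert(m, Bh[, i, drop = FALSE])
    }
    ctf_hom[, b] <- align_ctf(acc, tr_h$mean_direction)
    if (!is.null(arr_e)) {
      m <- iem_fit(Bh, C1_all)
      C2 <- iem_invert(m, t(arr_e[, , b]))
      ctf_het[, b] <- align_ctf(C2, tr_e$mean_direction)
    }
  }
  slope_of <- function(M) apply(M, 2, function(col) {
    names(col) <- offs; ctf_slope(col)
  })
  structure(list(bin_times = bin_times, slope_hom = slope_of(ctf_hom),
                 slope_het = if (!is.null(arr_e)) slope_of(ctf_het),
                 ctf_hom = ctf_hom,
                 ctf_het = if (!is.null(arr_e)) ctf_het),
            class = "decoding_series")
}

#' Time-resolved SVM decoding of variance or category
#'
#' `labels = "variance"` discriminates homogeneous vs heterogeneous trials
#' with leave-one-trial-out cross-validation at each bin. `labels =
#' "category"` discriminates left vs right; homogeneous trials are decoded
#' by LOO cross-validation and heterogeneous trials with the
#' homogeneous-trained decoder.
#'
#' @inheritParams iem_timecourse
#' @param labels "variance" or "category".
#' @param C SVM cost parameter.
#' @return list of class `decoding_series`: `bin_times`, `accuracy` (per
#'   bin; for category also `accuracy_het`).
#' @export
svm_condition_timecourse <- function(traces, trials, labels = c("variance",
                                                                "category"),
                                     correct_only = TRUE, epoch = c(-0.5, 4),
                                     bin_width = NULL, C = 1) {
  labels <- match.arg(labels)
  if (labels == "variance") {
    tr <- filter_trials(trials, NULL, correct_only)
    y <- tr$variance_condition
    if (length(unique(y)) < 2) stop("variance decoding needs both conditions")
    arr <- binned_epoch_array(traces, tr, epoch, bin_width)
    acc <- vapply(seq_len(dim(arr)[3]), function(b)
      svm_loo_accuracy(arr[, , b], y, C), numeric(1))
    structure(list(bin_times = attr(arr, "bin_times"), accuracy = acc,
                   labels = labels), class = "decoding_series")
  } else {
    tr_h <- filter_trials(trials, "hom", correct_only)
    tr_e <- filter_trials(trials, "het", correct_only)
    if (length(unique(tr_h$category)) < 2)
      stop("category decoding needs both categories")
    arr_h <- binned_epoch_array(traces, tr_h, epoch, bin_width)
    arr_e <- if (nrow(tr_e)) binned_epoch_array(traces, tr_e, epoch,
                                                bin_width)
    n_bins <- dim(arr_h)[3]
    acc_h <- acc_e <- rep(NA_real_, n_bins)
    for (b in seq_len(n_bins)) {
      acc_h[b] <- svm_loo_accuracy(arr_h[, , b], tr_h$category, C)
      if (!is.null(arr_e)) {
        fit <- svm_fit(arr_h[, , b], tr_h$category, C)
        acc_e[b] <- mean(predict(fit, arr_e[, , b]) == tr_e$category)
      }
    }
    structure(list(bin_times = attr(arr_h, "bin_times"), accuracy = acc_h,
                   accuracy_het = if (!is.null(arr_e)) acc_e,
                   labels = labels), class = "decoding_series")
  }
}

# direction-pair indices (1..8 from 22.5 deg) for within- and
# between-category discrimination: pairs 90 deg apart
# as absolute directions (degrees); within-category pairs stay on one side
# of the vertical boundary, between-category pairs cross it
wcd_pairs <- function() list(c(112.5, 202.5), c(157.5, 247.5),
                             c(292.5, 22.5), c(337.5, 67.5))
bcd_pairs <- function() list(c(22.5, 112.5), c(67.5, 157.5),
                             c(202.5, 292.5), c(247.5, 337.5))

#' Within- vs between-category discrimination (WCD/BCD)
#'
#' For each direction pair 90 degrees apart, a linear SVM discriminates the
#' two directions with repeated stratified 5-fold cross-validation on
#' homogeneous trials (`n_repeats` random partitions); the homogeneous-
#' trained decoders are also applied to the heterogeneous trials of the same
#' pair. Accuracies are averaged over the four within-category pairs (WCD)
#' and the four between-category pairs (BCD).
#'
#' @inheritParams iem_timecourse
#' @param n_repeats repetitions of the 5-fold partition (100 in the
#'   reference protocol).
#' @param n_folds folds.
#' @param C SVM cost.
#' @return list of class `wcd_bcd_series`: `bin_times`, and per condition
#'   (`hom`, `het`) `wcd`, `bcd` and `bcd_minus_wcd` accuracy series.
#' @export
wcd_bcd <- function(traces, trials, correct_only = TRUE, epoch = c(-0.5, 4),
                    bin_width = NULL, n_repeats = 100, n_folds = 5, C = 1) {
  tr_h <- filter_trials(trials, "hom", correct_only)
  tr_e <- filter_trials(trials, "het", correct_only)
  arr_h <- binned_epoch_array(traces, tr_h, epoch, bin_width)
  arr_e <- if (nrow(tr_e)) binned_epoch_array(traces, tr_e, epoch, bin_width)
  n_bins <- dim(arr_h)[3]
  pair_acc <- function(pair) {
    d <- pair
    sel_h <- tr_h$mean_direction %in% d
    if (sum(sel_h) < n_folds) stop("not enough homogeneous trials for pair ",
                                   paste(d, collapse = "/"))
    y_h <- tr_h$mean_direction[sel_h]
    sel_e <- if (!is.null(arr_e)) tr_e$mean_direction %in% d
    acc_h <- acc_e <- matrix(0, n_repeats, n_bins)
    for (b in seq_len(n_bins)) {
      Xh <- arr_h[sel_h, , b, drop = FALSE][, , 1]
      Xe <- if (!is.null(arr_e)) arr_e[sel_e, , b, drop = FALSE][, , 1]
      for (r in seq_len(n_repeats)) {
        folds <- stratified_folds(y_h, n_folds)
        corr_h <- 0; pe <- 0
        for (f in folds) {
          fit <- svm_fit(Xh[-f, , drop = FALSE], y_h[-f], C)
          corr_h <- corr_h + sum(predict(fit, Xh[f, , drop = FALSE]) ==
                                   as.character(y_h[f]))
          if (!is.null(arr_e))
            pe <- pe + mean(predict(fit, Xe) ==
                              as.character(tr_e$mean_direction[sel_e]))
        }
        acc_h[r, b] <- corr_h / length(y_h)
        if (!is.null(arr_e)) acc_e[r, b] <- pe / n_folds
      }
    }
    list(hom = colMeans(acc_h),
         het = if (!is.null(arr_e)) colMeans(acc_e))
  }
  avg_pairs <- function(pairs) {
    res <- lapply(pairs, pair_acc)
    list(hom = Reduce(`+`, lapply(res, `[[`, "hom")) / length(pairs),
         het = if (!is.null(arr_e))
           Reduce(`+`, lapply(res, `[[`, "het")) / length(pairs))
  }
  w <- avg_pairs(wcd_pairs())
  b <- avg_pairs(bcd_pairs())
  structure(list(bin_times = attr(arr_h, "bin_times"),
                 wcd_hom = w$hom, bcd_hom = b$hom,
                 bcd_minus_wcd_hom = b$hom - w$hom,
                 wcd_het = w$het, bcd_het = b$het,
                 bcd_minus_wcd_het = if (!is.null(arr_e)) b$het - w$het),
            class = "wcd_bcd_series")
}

#' Temporal generalization matrix
#'
#' Trains the decoder at each time bin on homogeneous trials and tests it at
#' every bin: IEM weights are applied to heterogeneous trials (CTF slope),
#' the category SVM to heterogeneous trials, and the variance SVM to
#' held-out trials of both conditions (50/50 split by trial parity).
#'
#' @inheritParams iem_timecourse
#' @param decoder "iem", "svm_category" or "svm_variance".
#' @param C SVM cost.
#' @return list of class `tg_matrix`: `values` (train x test bins),
#'   `bin_times`, `decoder`.
#' @export
temporal_generalization <- function(traces, trials,
                                    decoder = c("iem", "svm_category",
                                                "svm_variance"),
                                    correct_only = TRUE, epoch = c(-0.5, 4),
                                    bin_width = NULL, C = 1) {
  decoder <- match.arg(decoder)
  offs <- prc_offsets()
  if (decoder == "svm_variance") {
    tr <- filter_trials(trials, NULL, correct_only)
    arr <- binned_epoch_array(traces, tr, epoch, bin_width)
    n_bins <- dim(arr)[3]
    train_idx <- which(seq_len(nrow(tr)) %% 2 == 1)
    test_idx <- setdiff(seq_len(nrow(tr)), train_idx)
    y <- tr$variance_condition
    vals <- matrix(NA_real_, n_bins, n_bins)
    for (tb in seq_len(n_bins)) {
      fit <- svm_fit(arr[train_idx, , tb], y[train_idx], C)
      for (sb in seq_len(n_bins))
        vals[tb, sb] <- mean(predict(fit, arr[test_idx, , sb]) == y[test_idx])
    }
  } else {
    tr_h <- filter_trials(trials, "hom", correct_only)
    tr_e <- filter_trials(trials, "het", correct_only)
    if (nrow(tr_e) == 0) stop("temporal generalization tests heterogeneous ",
                              "trials; the session has none")
    arr_h <- binned_epoch_array(traces, tr_h, epoch, bin_width)
    arr_e <- binned_epoch_array(traces, tr_e, epoch, bin_width)
    n_bins <- dim(arr_h)[3]
    vals <- matrix(NA_real_, n_bins, n_bins)
    if (decoder == "iem") {
      C1 <- make_basis(tr_h$mean_direction)
      for (tb in seq_len(n_bins)) {
        m <- iem_fit(t(arr_h[, , tb]), C1)
        for (sb in seq_len(n_bins)) {
          ctf <- align_ctf(iem_invert(m, t(arr_e[, , sb])),
                           tr_e$mean_direction)
          vals[tb, sb] <- ctf_slope(ctf)
        }
      }
    } else {
      for (tb in seq_len(n_bins)) {
        fit <- svm_fit(arr_h[, , tb], tr_h$category, C)
        for (sb in seq_len(n_bins))
          vals[tb, sb] <- mean(predict(fit, arr_e[, , sb]) == tr_e$category)
      }
    }
  }
  structure(list(values = vals,
                 bin_times = attr(if (decoder == "svm_variance") arr else
                   arr_h, "bin_times"),
                 decoder = decoder),
            class = "tg_matrix")
}
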