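# Single-neuron analyses: direction tuning curves (stimulus-window AUC),
# direction selectivity index, slope-based permutation selectivity, the
# linear-summation simulation of heterogeneous tuning, cross-condition
# response correlation and the peak-direction confusion matrix.

# 8 x T aggregation matrix mapping trials to direction-cell means
direction_aggregator <- function(labels, dirs = direction_set()) {
  M <- outer(dirs, labels, `==`) * 1
  cnt <- rowSums(M)
  if (any(cnt == 0))
    stop("empty direction cell(s): ", paste(dirs[cnt == 0], collapse = ", "))
  M / cnt
}

# vectorized tuning-curve slope: average +/-45, +/-90, +/-135 offset pairs,
# OLS line over the 5 points at offsets (-180, -135, -90, -45, 0).
# responses: neurons x 8 (columns in direction_set order); preferred: index 1..8
slope_from_curve <- function(responses, preferred) {
  idx <- function(shift) cbind(seq_len(nrow(responses)),
                               ((preferred - 1 + shift) %% 8) + 1)
  y0 <- responses[idx(0)]
  y45 <- (responses[idx(1)] + responses[idx(-1)]) / 2
  y90 <- (responses[idx(2)] + responses[idx(-2)]) / 2
  y135 <- (responses[idx(3)] + responses[idx(-3)]) / 2
  y180 <- responses[idx(4)]
  # closed-form OLS over x = (-180,-135,-90,-45,0): sum((x - xbar)^2) = 20250
  (90 * (y0 - y180) + 45 * (y45 - y135)) / 20250
}

#' Direction selectivity index
#'
#' `DSI = (R_pref - R_antipref) / R_pref`, the contrast of the preferred
#' response against the response 180 degrees away.
#'
#' @param responses 8-vector (or neurons x 8 matrix) of direction responses
#'   in [direction_set()] order.
#' @return DSI value(s); NA when the preferred response is 0.
#' @export
#' @examples
#' dsi(c(2, 1, 1, 1, 1, 1, 1, 1))  # 0.5
dsi <- function(responses) {
  if (is.null(dim(responses))) responses <- matrix(responses, 1)
  pref <- max.col(responses, ties.method = "first")
  anti <- ((pref - 1 + 4) %% 8) + 1
  rp <- responses[cbind(seq_len(nrow(responses)), pref)]
  ra <- responses[cbind(seq_len(nrow(responses)), anti)]
  out <- (rp - ra) / rp
  out[rp == 0] <- NA_real_
  out
}

#' Single-neuron direction tuning curves
#'
#' For each neuron and mean direction, the trials of the requested condition
#' (correct trials only, by default) are averaged over the 4-s stimulus
#' window; the response is the area under that trial-averaged signal
#' (window mean times window duration).
#'
#' @param traces neurons x frames dF/F matrix with `frame_rate` attribute.
#' @param trials trial table.
#' @param condition "hom" or "het".
#' @param correct_only restrict to correct trials (ignored when choices are
#'   absent, e.g. passive sessions).
#' @param window stimulus window in seconds.
#' @return object of class `tuning_set`: list with `responses` (neurons x 8
#'   AUC matrix, columns named by direction), `preferred_direction`, `dsi`,
#'   `slope`, `tie` (argmax tie flag), `condition`, `n_trials`.
#' @export
compute_tuning <- function(traces, trials, condition = "hom",
                           correct_only = TRUE, window = c(0, 4)) {
  tr <- filter_trials(trials, condition, correct_only)
  if (nrow(tr) == 0) stop("no usable trials for condition ", condition)
  auc <- trial_response_matrix(traces, tr, window) * diff(window)
  M <- direction_aggregator(tr$mean_direction)
  responses <- t(M %*% auc)                       # neurons x 8
  colnames(responses) <- direction_set()
  pref <- max.col(responses, ties.method = "first")
  tie <- apply(responses, 1, function(r) sum(r == max(r)) > 1)
  structure(list(responses = responses,
                 preferred_direction = direction_set()[pref],
                 dsi = dsi(responses),
                 slope = slope_from_curve(responses, pref),
                 tie = tie, condition = condition, n_trials = nrow(tr)),
            class = "tuning_set")
}

#' Permutation-based direction-selectivity classification
#'
#' A neuron is direction-selective when its DSI exceeds `dsi_thresh` and its
#' tuning-curve slope exceeds the `pct`-th percentile of slopes recomputed
#' from datasets in which direction labels are shuffled across trials
#' (within the condition, preserving per-direction trial counts).
#'
#' @inheritParams compute_tuning
#' @param dsi_thresh DSI threshold (strict inequality).
#' @param n_perm number of label shuffles (>= 100).
#' @param pct null-slope percentile.
#' @return the `tuning_set` with added fields `selective` (logical),
#'   `null_slope_q` (per-neuron null percentile), `slope_rank` (fraction of
#'   null slopes below the observed slope; used for subset ranking).
#' @export
classify_selective <- function(traces, trials, condition = "hom",
                               dsi_thresh = 0.4, n_perm = 5000, pct = 95,
                               correct_only = TRUE, window = c(0, 4)) {
  if (n_perm < 100) stop("n_perm must be at least 100 for a stable percentile")
  tun <- compute_tuning(traces, trials, condition, correct_only, window)
  tr <- filter_trials(trials, condition, correct_only)
  auc <- trial_response_matrix(traces, tr, window) * diff(window)
  labels <- tr$mean_direction
  n_neurons <- ncol(auc)
  null_slopes <- matrix(NA_real_, n_perm, n_neurons)
  for (p in seq_len(n_perm)) {
    M <- direction_aggregator(sample(labels))
    resp <- t(M %*% auc)
    null_slopes[p, ] <- slope_from_curve(resp, max.col(resp, ties.method = "first"))
  }
  q <- apply(null_slopes, 2, quantile, probs = pct / 100, names = FALSE)
  tun$null_slope_q <- q
  tun$slope_rank <- colMeans(sweep(null_slopes, 2, tun$slope, `<`))
  tun$selective <- !is.na(tun$dsi) & tun$dsi > dsi_thresh & tun$slope > q
  tun
}

# attenuate the circular harmonics of 8-point tuning curves for averaging
# over a uniform direction window of width `range` degrees: harmonic n is
# multiplied by sinc(n * range/2). Exact for band-limited curves.
window_average_curves <- function(responses, range) {
  if (range == 0) return(responses)
  z <- (1:4) * deg2rad(range) / 2
  att <- c(1, ifelse(z == 0, 1, sin(z) / z))        # harmonics 0..4
  t(apply(responses, 1, function(y) {
    f <- stats::fft(y)
    f <- f * att[c(1, 2, 3, 4, 5, 4, 3, 2)]
    Re(stats::fft(f, inverse = TRUE)) / 8
  }))
}

#' Linear-summation simulation of heterogeneous tuning
#'
#' Predicts the population-averaged tuning curve expected under pure linear
#' summation of local motion directions: each direction-selective neuron's
#' homogeneous tuning curve is averaged over a uniform direction window of
#' width `range` (via exact attenuation of its circular harmonics), a
#' bootstrap sample of `n_match` transformed curves is aligned on its peak
#' and averaged, and the procedure is repeated `n_resample` times.
#'
#' @param hom_responses neurons x 8 response matrix of the direction-selective
#'   neurons identified in the homogeneous condition.
#' @param range heterogeneity range in degrees.
#' @param n_match neurons drawn per resample (match to the heterogeneous
#'   selective count).
#' @param n_resample bootstrap repetitions (1000 in the reference analysis).
#' @return list: `mean_curve` (8 aligned offsets, -135..180, averaged over
#'   resamples), `offsets`, `peak_amplitudes` (per resample: aligned value at
#'   offset 0 minus the curve mean).
#' @export
simulate_het_tuning <- function(hom_responses, range, n_match,
                                n_resample = 1000) {
  stopifnot(nrow(hom_responses) >= 1, n_match >= 1)
  transformed <- window_average_curves(as.matrix(hom_responses), range)
  offsets <- c(-135, -90, -45, 0, 45, 90, 135, 180)
  curves <- matrix(0, n_resample, 8)
  peaks <- numeric(n_resample)
  for (r in seq_len(n_resample)) {
    rows <- sample(nrow(transformed), n_match, replace = TRUE)
    sub <- transformed[rows, , drop = FALSE]
    pref <- max.col(sub, ties.method = "first")
    aligned <- t(vapply(seq_len(nrow(sub)), function(i)
      sub[i, ((pref[i] - 1 + c(5:7, 0:4)) %% 8) + 1], numeric(8)))
    avg <- colMeans(aligned)
    curves[r, ] <- avg
    peaks[r] <- avg[4] - mean(avg)
  }
  list(mean_curve = colMeans(curves), offsets = offsets,
       peak_amplitudes = peaks)
}

#' Cross-condition correlation of direction-selective responses
#'
#' Pearson correlation between the concatenated 8-direction response vectors
#' of the same neurons measured in two conditions, with a permutation p-value
#' obtained by shuffling neuron identity in the second array.
#'
#' @param responses_a,responses_b neurons x 8 response matrices (same
#'   neurons, same order).
#' @param n_perm permutations for the null.
#' @return list: `r`, `p`, `n_perm`.
#' @export
cross_condition_correlation <- function(responses_a, responses_b,
                                        n_perm = 5000) {
  responses_a <- as.matrix(responses_a); responses_b <- as.matrix(responses_b)
  stopifnot(nrow(responses_a) == nrow(responses_b))
  if (nrow(responses_a) < 2) stop("need at least 2 neurons")
  a <- as.vector(t(responses_a)); b <- as.vector(t(responses_b))
  r <- stats::cor(a, b)
  null <- vapply(seq_len(n_perm), function(i) {
    stats::cor(a, as.vector(t(responses_b[sample(nrow(responses_b)), ,
                                          drop = FALSE])))
  }, numeric(1))
  list(r = r, p = (1 + sum(abs(null) >= abs(r))) / (1 + n_perm),
       n_perm = n_perm)
}

#' Peak-direction confusion matrix across conditions
#'
#' Cell (i, j) holds the proportion of all neurons whose heterogeneous-trial
#' peak direction is i and homogeneous-trial peak is j. Per-cell significance
#' is assessed against surrogate matrices from direction-label shuffles
#' (within each condition) and corrected with Benjamini-Hochberg FDR over the
#' 64 cells.
#'
#' @inheritParams compute_tuning
#' @param n_perm surrogate datasets.
#' @param alpha FDR level.
#' @return list of class `peak_confusion`: `proportions` (8 x 8, rows =
#'   heterogeneous peak, cols = homogeneous peak), `p`, `p_adjusted`,
#'   `significant`, `n_neurons`.
#' @export
peak_confusion <- function(traces, trials, n_perm = 5000, alpha = 0.05,
                           correct_only = TRUE, window = c(0, 4)) {
  tr_h <- filter_trials(trials, "hom", correct_only)
  tr_e <- filter_trials(trials, "het", correct_only)
  auc_h <- trial_response_matrix(traces, tr_h, window) * diff(window)
  auc_e <- trial_response_matrix(traces, tr_e, window) * diff(window)
  peaks <- function(auc, labels) {
    resp <- t(direction_aggregator(labels) %*% auc)
    max.col(resp, ties.method = "first")
  }
  confusion <- function(ph, pe) {
    m <- matrix(0, 8, 8, dimnames = list(het = direction_set(),
                                         hom = direction_set()))
    for (k in seq_along(ph)) m[pe[k], ph[k]] <- m[pe[k], ph[k]] + 1
    m / length(ph)
  }
  obs <- confusion(peaks(auc_h, tr_h$mean_direction),
                   peaks(auc_e, tr_e$mean_direction))
  exceed <- matrix(0, 8, 8)
  for (p in seq_len(n_perm)) {
    surr <- confusion(peaks(auc_h, sample(tr_h$mean_direction)),
                      peaks(auc_e, sample(tr_e$mean_direction)))
    exceed <- exceed + (surr >= obs)
  }
  pv <- (1 + exceed) / (1 + n_perm)
  fdr <- bh_fdr(as.vector(pv), alpha)
  structure(list(proportions = obs,
                 p = pv,
                 p_adjusted = matrix(fdr$p_adjusted, 8, 8,
                                     dimnames = dimnames(obs)),
                 significant = matrix(fdr$significant, 8, 8,
                                      dimnames = dimnames(obs)),
                 n_neurons = ncol(auc_h),
                 n_perm = n_perm, alpha = alpha),
            class = "peak_confusion")
}
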