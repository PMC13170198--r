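# Trace conditioning downstream of source extraction: sliding-percentile
# baseline removal, Savitzky-Golay smoothing, IQR-based event thresholding
# and neuron-level quality control.

# Savitzky-Golay smoothing by local polynomial least squares. Interior frames
# use the precomputed centered projection row; edge frames refit the
# polynomial on the truncated window so that polynomials up to `order` pass
# through unchanged everywhere.
savitzky_golay <- function(x, order = 3, length = 11) {
  n <- length(x)
  if (n < length) stop("trace shorter than the smoothing window (", length,
                       " frames)")
  half <- (length - 1) %/% 2
  k <- -half:half
  A <- outer(k, 0:order, `^`)
  # center row of the hat matrix: evaluates the fit at the window center
  h <- (A %*% solve(crossprod(A), t(A)))[half + 1, ]
  sm <- stats::filter(x, rev(h), sides = 2)
  out <- as.numeric(sm)
  for (i in c(seq_len(half), n - half + seq_len(half))) {
    w <- max(1, i - half):min(n, i + half)
    kk <- w - i
    Aw <- outer(kk, 0:order, `^`)
    out[i] <- (solve(crossprod(Aw), crossprod(Aw, x[w])))[1]
  }
  out
}

#' Remove slow baseline drift and smooth traces
#'
#' Per neuron, subtracts the running 8th-percentile baseline within a
#' centered sliding window (truncated at the trace edges) and then applies a
#' Savitzky-Golay polynomial smoother.
#'
#' @param raw neurons x frames dF/F matrix (an attribute `frame_rate` is
#'   carried through if present).
#' @param window_frames sliding-window length in frames (900 = 30 s at 30 Hz).
#' @param percentile baseline percentile (0-100).
#' @param sg_order polynomial order of the smoother.
#' @param sg_len smoother window length in frames (odd).
#' @return matrix of the same shape with attribute
#'   `preprocess_steps` recording the applied parameters.
#' @export
clean_traces <- function(raw, window_frames = 900, percentile = 8,
                         sg_order = 3, sg_len = 11) {
  raw <- as.matrix(raw)
  if (ncol(raw) < sg_len)
    stop("traces have ", ncol(raw), " frames; smoothing needs >= ", sg_len)
  out <- raw
  for (i in seq_len(nrow(raw))) {
    base <- running_percentile(raw[i, ], as.integer(window_frames),
                               percentile / 100)
    out[i, ] <- savitzky_golay(raw[i, ] - base, sg_order, sg_len)
  }
  attr(out, "frame_rate") <- attr(raw, "frame_rate")
  attr(out, "preprocess_steps") <- list(window_frames = window_frames,
                                        percentile = percentile,
                                        sg_order = sg_order, sg_len = sg_len)
  out
}

# maximal runs of consecutive TRUE; returns number of runs
count_runs <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  sum(r$values)
}

#' Detect calcium events and apply neuron-level QC
#'
#' Per neuron, the noise level is estimated from the negative dF/F
#' excursions: all negative values and their absolute values are pooled and
#' the threshold set at `k` times the interquartile range of that pool.
#' Samples above threshold are retained, the rest zeroed. A neuron fails QC
#' when its count of negative events (maximal supra-threshold runs of the
#' sign-flipped trace) exceeds `qc_ratio` times its count of positive events.
#'
#' @param clean neurons x frames matrix from [clean_traces()].
#' @param k threshold multiplier on the IQR (3 in the reference protocol).
#' @param qc_ratio maximum tolerated negative/positive event ratio (0.05).
#' @return list of class `event_traces`: `events` (matrix, thresholded
#'   dF/F), and `qc` data.frame with `neuron_id`, `threshold`, `n_pos`,
#'   `n_neg`, `qc_pass`, `no_negative_values` (TRUE when the threshold was
#'   undefined and set to 0).
#' @export
detect_events_and_qc <- function(clean, k = 3, qc_ratio = 0.05) {
  clean <- as.matrix(clean)
  n <- nrow(clean)
  events <- matrix(0, n, ncol(clean), dimnames = dimnames(clean))
  qc <- data.frame(neuron_id = seq_len(n), threshold = NA_real_,
                   n_pos = NA_integer_, n_neg = NA_integer_, qc_pass = NA,
                   no_negative_values = FALSE)
  for (i in seq_len(n)) {
    x <- clean[i, ]
    neg <- x[x < 0]
    if (length(neg) == 0) {
      thr <- 0
      qc$no_negative_values[i] <- TRUE
    } else {
      pool <- c(neg, abs(neg))
      thr <- k * stats::IQR(pool, type = 7)
    }
    keep <- x > thr
    events[i, keep] <- x[keep]
    n_pos <- count_runs(keep)
    n_neg <- count_runs(-x > thr)
    qc$threshold[i] <- thr
    qc$n_pos[i] <- n_pos
    qc$n_neg[i] <- n_neg
    qc$qc_pass[i] <- n_neg <= qc_ratio * n_pos
  }
  attr(events, "frame_rate") <- attr(clean, "frame_rate")
  structure(list(events = events, qc = qc), class = "event_traces")
}
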