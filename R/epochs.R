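# Shared epoch extraction: per-trial stimulus-window responses and
# time-binned trial x neuron x bin arrays aligned to stimulus onset.

#' Per-trial stimulus-window response matrix
#'
#' Averages each neuron's signal over a window relative to stimulus onset,
#' for every trial. The default window is the 4-s stimulus period.
#'
#' @param traces neurons x frames matrix with attribute `frame_rate` (or pass
#'   `frame_rate`).
#' @param trials trial table with `onset_frame`.
#' @param window c(start, end) in seconds relative to onset.
#' @param frame_rate frames per second; defaults to the trace attribute.
#' @return trials x neurons matrix of window-mean dF/F.
#' @export
trial_response_matrix <- function(traces, trials, window = c(0, 4),
                                  frame_rate = attr(traces, "frame_rate")) {
  stopifnot(!is.null(frame_rate))
  f0 <- round(window[1] * frame_rate)
  f1 <- round(window[2] * frame_rate) - 1L
  n_frames <- ncol(traces)
  out <- matrix(NA_real_, nrow(trials), nrow(traces))
  for (i in seq_len(nrow(trials))) {
    fr <- trials$onset_frame[i] + (f0:f1)
    fr <- fr[fr >= 1 & fr <= n_frames]
    if (length(fr) == 0) stop("trial ", trials$trial_id[i],
                              " window falls outside the trace")
    out[i, ] <- rowMeans(traces[, fr, drop = FALSE])
  }
  out
}

#' Time-binned epoch array
#'
#' Carves the epoch from `epoch[1]` to `epoch[2]` seconds around each
#' stimulus onset into bins of `bin_width` seconds and averages frames
#' within each bin.
#'
#' @inheritParams trial_response_matrix
#' @param epoch c(start, end) seconds relative to onset (default -0.5 to 4,
#'   the analysis epoch).
#' @param bin_width bin width in seconds (defaults to one frame).
#' @return 3-d array trials x neurons x bins with attribute `bin_times`
#'   (bin centers, seconds).
#' @export
binned_epoch_array <- function(traces, trials, epoch = c(-0.5, 4),
                               bin_width = NULL,
                               frame_rate = attr(traces, "frame_rate")) {
  stopifnot(!is.null(frame_rate))
  if (is.null(bin_width)) bin_width <- 1 / frame_rate
  bpf <- max(1L, round(bin_width * frame_rate))
  f0 <- round(epoch[1] * frame_rate)
  f1 <- round(epoch[2] * frame_rate) - 1L
  starts <- seq(f0, f1 - bpf + 1L, by = bpf)
  n_bins <- length(starts)
  out <- array(NA_real_, c(nrow(trials), nrow(traces), n_bins))
  for (i in seq_len(nrow(trials))) {
    for (b in seq_len(n_bins)) {
      fr <- trials$onset_frame[i] + starts[b] + seq_len(bpf) - 1L
      fr <- fr[fr >= 1 & fr <= ncol(traces)]
      if (length(fr))
        out[i, , b] <- rowMeans(traces[, fr, drop = FALSE])
    }
  }
  attr(out, "bin_times") <- (starts + (bpf - 1) / 2) / frame_rate
  out
}

# trials restricted to a condition and (optionally) correct choices
filter_trials <- function(trials, condition = NULL, correct_only = TRUE) {
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(condition)) keep <- keep & trials$variance_condition == condition
  if (correct_only && !all(is.na(trials$correct)))
    keep <- keep & !is.na(trials$correct) & trials$correct
  trials[keep, , drop = FALSE]
}
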