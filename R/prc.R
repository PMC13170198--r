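# Population response curves: the transpose view of tuning -- fix the
# presented direction and read activity across neurons grouped by their
# preferred direction -- and the dynamics of the PRC slope over time.

prc_offsets <- function() c(-135, -90, -45, 0, 45, 90, 135, 180)

#' Preferred-direction map
#'
#' Assigns every neuron the direction maximizing its 4-s stimulus-window
#' tuning curve in the given condition.
#'
#' @inheritParams compute_tuning
#' @return list: `preferred` (degrees per neuron), `tie` (argmax tie flag,
#'   ties resolved toward the lowest direction).
#' @export
preferred_direction_map <- function(traces, trials, condition = "hom",
                                    correct_only = TRUE, window = c(0, 4)) {
  tun <- compute_tuning(traces, trials, condition, correct_only, window)
  list(preferred = tun$preferred_direction, tie = tun$tie)
}

#' Build the population response curve tensor
#'
#' For each trial and time bin, neurons are grouped by preferred direction
#' and averaged within group; group responses are then re-indexed by the
#' wrapped offset (preferred minus presented direction) and averaged over
#' trials and presented directions.
#'
#' @inheritParams compute_tuning
#' @param pref_map preferred directions per neuron (vector of degrees or the
#'   list from [preferred_direction_map()]).
#' @param epoch,bin_width epoch and bin width passed to
#'   [binned_epoch_array()].
#' @return object of class `prc_tensor`: `values` (8 offsets x bins;
#'   offsets -135..180), `offsets`, `bin_times`, `n_trials`,
#'   `n_per_offset_bin` (neurons per preferred-direction bin), `condition`.
#'   Offset cells with no neurons are NA.
#' @export
build_prc <- function(traces, trials, pref_map, condition = "hom",
                      correct_only = TRUE, epoch = c(-0.5, 4),
                      bin_width = NULL) {
  if (is.list(pref_map)) pref_map <- pref_map$preferred
  stopifnot(length(pref_map) == nrow(traces))
  tr <- filter_trials(trials, condition, correct_only)
  arr <- binned_epoch_array(traces, tr, epoch, bin_width)
  bin_times <- attr(arr, "bin_times")
  n_bins <- dim(arr)[3]
  dirs <- direction_set()
  offs <- prc_offsets()
  # group neurons by preferred direction once
  groups <- lapply(dirs, function(d) which(pref_map == d))
  n_group <- lengths(groups)
  acc <- matrix(0, 8, n_bins)
  cnt <- matrix(0, 8, n_bins)
  for (i in seq_len(nrow(tr))) {
    pres <- tr$mean_direction[i]
    for (g in seq_along(dirs)) {
      if (n_group[g] == 0) next
      o <- match(wrap180(dirs[g] - pres), offs)
      v <- colMeans(matrix(arr[i, groups[[g]], , drop = FALSE],
                           n_group[g], n_bins))
      acc[o, ] <- acc[o, ] + v
      cnt[o, ] <- cnt[o, ] + 1
    }
  }
  values <- acc / cnt
  values[cnt == 0] <- NA_real_
  rownames(values) <- offs
  structure(list(values = values, offsets = offs, bin_times = bin_times,
                 n_trials = nrow(tr), n_per_offset_bin = n_group,
                 condition = condition),
            class = "prc_tensor")
}

#' PRC slope time series
#'
#' Per time bin, PRC values equidistant from offset 0 are averaged
#' (+/-45, +/-90, +/-135) and an ordinary least-squares line is fitted over
#' the offsets -180, -135, -90, -45, 0. A positive slope means the
#' population peaks at the presented direction.
#'
#' @param prc a `prc_tensor` from [build_prc()].
#' @return list of class `prc_slope_series`: `slope` (per bin; NA where an
#'   offset cell is missing), `bin_times`, `condition`.
#' @export
prc_slope <- function(prc) {
  v <- prc$values
  o <- prc$offsets
  at <- function(x) v[match(x, o), , drop = FALSE]
  y0 <- at(0)
  y45 <- (at(45) + at(-45)) / 2
  y135 <- (at(135) + at(-135)) / 2
  y90 <- (at(90) + at(-90)) / 2
  y180 <- at(180)
  slope <- as.numeric((90 * (y0 - y180) + 45 * (y45 - y135)) / 20250)
  structure(list(slope = slope, bin_times = prc$bin_times,
                 condition = prc$condition),
            class = "prc_slope_series")
}

#' PRC slope from rank-ordered neuron subsets
#'
#' Recomputes the full PRC analysis (preferred-direction map, PRC, slope)
#' within the bottom `percent`% of neurons ranked by how their tuning-curve
#' slope compares to its own trial-shuffled null (`slope_rank` from
#' [classify_selective()]), and summarizes the mean slope over the 4-s
#' stimulus window.
#'
#' @inheritParams build_prc
#' @param slope_rank per-neuron rank statistic in [0, 1] (fraction of null
#'   slopes below the observed slope).
#' @param percents subset sizes in percent.
#' @return data.frame: `percent`, `n_neurons`, `mean_slope` (mean over
#'   stimulus-window bins).
#' @export
subset_prc <- function(traces, trials, slope_rank,
                       percents = c(10, 50, 95, 100), condition = "hom",
                       correct_only = TRUE, epoch = c(-0.5, 4),
                       bin_width = NULL) {
  stopifnot(length(slope_rank) == nrow(traces))
  ord <- order(slope_rank)          # weakest tuning first
  out <- lapply(percents, function(pc) {
    n_sub <- max(1L, floor(length(ord) * pc / 100))
    sub <- sort(ord[seq_len(n_sub)])
    if (length(sub) < 8)
      stop("subset of ", length(sub), " neurons cannot tile the 8 offsets")
    tr_sub <- traces[sub, , drop = FALSE]
    attr(tr_sub, "frame_rate") <- attr(traces, "frame_rate")
    pm <- preferred_direction_map(tr_sub, trials, condition, correct_only)
    prc <- build_prc(tr_sub, trials, pm, condition, correct_only, epoch,
                     bin_width)
    sl <- prc_slope(prc)
    stim <- sl$bin_times >= 0 & sl$bin_times < 4
    data.frame(percent = pc, n_neurons = length(sub),
               mean_slope = mean(sl$slope[stim], na.rm = TRUE))
  })
  do.call(rbind, out)
}
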