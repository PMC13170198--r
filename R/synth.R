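# Synthetic session generator: stimulus schedules, dot-direction sampling,
# ground-truth population rates, GCaMP-like calcium dynamics and psychometric
# choice behavior. Every downstream analysis in the package can be validated
# against the ground truth planted here.

#' Session configuration
#'
#' Describes one recording session of the motion categorization experiment:
#' eight global mean directions crossed with a homogeneous condition and one
#' heterogeneous dot-direction range.
#'
#' @param het_range width (degrees) of the uniform dot-direction distribution
#'   of the heterogeneous condition; one of 0, 90, 180, 270. 0 means the
#'   session contains homogeneous trials only.
#' @param trials_per_direction trials per (direction, condition) cell;
#'   the experimental sessions used 20.
#' @param n_dots dots per random-dot kinematogram (500 in the experiment).
#' @param frame_rate imaging frame rate in Hz.
#' @param stim_duration stimulus duration in seconds.
#' @param pre_window pre-stimulus epoch per trial in seconds.
#' @param seed optional integer seed recorded in the config.
#' @return object of class `session_config`.
#' @export
#' @examples
#' session_config(het_range = 90)
session_config <- function(het_range = 90, trials_per_direction = 20,
                           n_dots = 500, frame_rate = 30,
                           stim_duration = 4, pre_window = 2, seed = NULL) {
  stopifnot(het_range %in% c(0, 90, 180, 270),
            trials_per_direction >= 1, n_dots >= 1,
            frame_rate > 0, stim_duration > 0, pre_window >= 0)
  structure(list(direction_set = direction_set(), het_range = het_range,
                 trials_per_direction = trials_per_direction, n_dots = n_dots,
                 frame_rate = frame_rate, stim_duration = stim_duration,
                 pre_window = pre_window, seed = seed),
            class = "session_config")
}

#' Design a pseudo-randomized trial schedule
#'
#' Produces a balanced trial table: every (direction, condition) cell appears
#' exactly `trials_per_direction` times, and no two consecutive trials share
#' both the mean direction and the variance condition. The schedule is drawn
#' by constrained sequential sampling with restarts.
#'
#' @param config a [session_config()].
#' @param max_restarts restart cap before the constraint is declared
#'   unsatisfiable.
#' @return data.frame with columns `trial_id`, `variance_condition`
#'   ("hom"/"het"), `het_range`, `mean_direction`, `category`, `onset_frame`,
#'   `choice` (NA until simulated), `correct`.
#' @export
design_session <- function(config, max_restarts = 200) {
  stopifnot(inherits(config, "session_config"))
  dirs <- config$direction_set
  conds <- if (config$het_range > 0) c("hom", "het") else "hom"
  cells <- expand.grid(mean_direction = dirs, variance_condition = conds,
                       stringsAsFactors = FALSE)
  n_cell <- nrow(cells)
  n <- n_cell * config$trials_per_direction
  counts0 <- rep(config$trials_per_direction, n_cell)
  if (max(counts0) > ceiling(n / 2))
    stop("adjacency constraint unsatisfiable: one trial type exceeds half the session")

  order_idx <- NULL
  for (restart in seq_len(max_restarts)) {
    counts <- counts0
    idx <- integer(n)
    prev <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- which(counts > 0L)
      avail <- setdiff(avail, prev)
      if (length(avail) == 0L) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = counts[avail])
      idx[i] <- pick
      counts[pick] <- counts[pick] - 1L
      prev <- pick
    }
    if (ok) { order_idx <- idx; break }
  }
  if (is.null(order_idx))
    stop("could not satisfy the adjacency constraint after ", max_restarts,
         " restarts")

  trials <- cells[order_idx, , drop = FALSE]
  rownames(trials) <- NULL
  trials$trial_id <- seq_len(n)
  trials$het_range <- ifelse(trials$variance_condition == "het",
                             config$het_range, 0)
  trials$category <- direction_category(trials$mean_direction)
  frames_per_trial <- round((config$pre_window + config$stim_duration) *
                              config$frame_rate)
  trials$onset_frame <- (trials$trial_id - 1L) * frames_per_trial +
    round(config$pre_window * config$frame_rate) + 1L
  trials$choice <- NA_character_
  trials$correct <- NA
  trials[, c("trial_id", "variance_condition", "het_range", "mean_direction",
             "category", "onset_frame", "choice", "correct")]
}

#' Sample dot directions for one kinematogram
#'
#' Dot directions are i.i.d. uniform on `mean +/- range/2`, wrapped to
#' `[0, 360)`. Draws exactly equal to the mean are rejected and resampled,
#' mirroring the stimulus design in which no dot carries the global mean
#' direction itself. `range = 0` returns the degenerate homogeneous stimulus.
#'
#' @param mean global mean direction (degrees).
#' @param range width of the uniform distribution (degrees, in `[0, 360)`).
#' @param n number of dots.
#' @return numeric vector of `n` directions in `[0, 360)`.
#' @export
sample_dot_directions <- function(mean, range, n) {
  stopifnot(range >= 0, range < 360, n >= 1)
  if (range == 0) return(rep(wrap360(mean), n))
  x <- wrap360(runif(n, mean - range / 2, mean + range / 2))
  bad <- x == wrap360(mean)
  while (any(bad)) {
    x[bad] <- wrap360(runif(sum(bad), mean - range / 2, mean + range / 2))
    bad <- x == wrap360(mean)
  }
  x
}

# von-Mises-shaped tuning bump: peak `amplitude` at delta = 0, width set by
# the concentration kappa; delta in degrees.
tuning_bump <- function(delta, amplitude, kappa) {
  amplitude * exp(kappa * (cos(deg2rad(delta)) - 1))
}

#' Generative population model
#'
#' One row per neuron. `coding_mode` selects the generative rule used by
#' [simulate_trial_rates()]:
#' \describe{
#'   \item{linear_sum}{stimulus response is the mean of the tuning function
#'     over the individual dot directions (the local-motion null model).}
#'   \item{sharpened_mean}{tuning evaluated at the dots' circular mean and
#'     scaled by a per-range gain (global-mean coding).}
#'   \item{untuned}{baseline only.}
#'   \item{category}{two response levels keyed to the trial's category.}
#' }
#'
#' @param n_neurons number of neurons.
#' @param coding_mode one of "linear_sum", "sharpened_mean", "untuned",
#'   "category"; recycled per neuron.
#' @param amplitude peak dF/F modulation above baseline. The default, with
#'   the default frame noise of [calcium_params()], puts single-neuron
#'   single-frame discriminability of neighboring directions near d' = 0.2:
#'   weak single-neuron coding that becomes reliable only at the population
#'   level, as observed in mouse V1 population imaging.
#' @param kappa tuning concentration (dimensionless); 2 gives a half-width
#'   near 60 degrees, typical of direction-tuned V1 neurons.
#' @param baseline baseline dF/F.
#' @param gain_by_range named multiplicative gain per heterogeneity range;
#'   must map range 0 to 1.
#' @param bias_toward_center degrees by which the effective stimulus direction
#'   is displaced toward the nearest horizontal category center before tuning
#'   is evaluated (models a learned categorical bias; 0 = none).
#' @param preferred_directions optional vector of preferred directions; by
#'   default neurons tile the circle uniformly.
#' @return data.frame of class `population_model` with attributes
#'   `gain_by_range` and `bias_toward_center`.
#' @export
population_model <- function(n_neurons, coding_mode = "sharpened_mean",
                             amplitude = 0.15, kappa = 2, baseline = 0.05,
                             gain_by_range = c("0" = 1, "90" = 1,
                                               "180" = 0.95, "270" = 0.6),
                             bias_toward_center = 0,
                             preferred_directions = NULL) {
  stopifnot(n_neurons >= 1, all(amplitude >= 0),
            gain_by_range[["0"]] == 1)
  if (is.null(preferred_directions))
    preferred_directions <- wrap360(seq(0, 360, length.out = n_neurons + 1)[-1])
  pop <- data.frame(
    neuron_id = seq_len(n_neurons),
    preferred_direction = rep_len(preferred_directions, n_neurons),
    amplitude = rep_len(amplitude, n_neurons),
    kappa = rep_len(kappa, n_neurons),
    baseline = rep_len(baseline, n_neurons),
    coding_mode = rep_len(coding_mode, n_neurons),
    stringsAsFactors = FALSE)
  bad <- setdiff(unique(pop$coding_mode),
                 c("linear_sum", "sharpened_mean", "untuned", "category"))
  if (length(bad)) stop("unknown coding_mode: ", paste(bad, collapse = ", "))
  structure(pop, gain_by_range = gain_by_range,
            bias_toward_center = bias_toward_center,
            class = c("population_model", "data.frame"))
}

# displace a direction by `delta` degrees toward its nearest horizontal
# category center (0 or 180), never overshooting the center.
shift_toward_center <- function(direction, delta) {
  if (delta == 0) return(direction)
  center <- category_center(direction)
  off <- wrap180(direction - center)
  step <- sign(off) * pmin(abs(off), delta)
  wrap360(direction - step)
}

#' Ground-truth firing rates for one trial
#'
#' @param trial one row of a trial table from [design_session()].
#' @param dots dot directions from [sample_dot_directions()].
#' @param pop a [population_model()].
#' @param config the [session_config()].
#' @return neurons x frames matrix of nonnegative rates (dF/F drive units);
#'   pre-stimulus frames sit at baseline.
#' @export
simulate_trial_rates <- function(trial, dots, pop, config) {
  n_pre <- round(config$pre_window * config$frame_rate)
  n_stim <- round(config$stim_duration * config$frame_rate)
  n_neurons <- nrow(pop)
  gains <- attr(pop, "gain_by_range")
  bias <- attr(pop, "bias_toward_center")
  rng_key <- as.character(trial$het_range)
  if (!rng_key %in% names(gains))
    stop("gain_by_range has no entry for range ", rng_key)

  stim_rate <- numeric(n_neurons)
  for (mode in unique(pop$coding_mode)) {
    sel <- pop$coding_mode == mode
    p <- pop[sel, , drop = FALSE]
    stim_rate[sel] <- switch(
      mode,
      linear_sum = {
        # mean over dots of the tuning function at each dot direction
        d <- outer(p$preferred_direction, dots, function(pref, th)
          wrap180(th - pref))
        rowMeans(tuning_bump(d, p$amplitude, p$kappa)) + p$baseline
      },
      sharpened_mean = {
        th <- shift_toward_center(circ_mean(dots), bias)
        gains[[rng_key]] *
          tuning_bump(wrap180(th - p$preferred_direction),
                      p$amplitude, p$kappa) + p$baseline
      },
      untuned = p$baseline,
      category = p$baseline + p$amplitude *
        (direction_category(p$preferred_direction) == trial$category),
      stop("unknown coding_mode: ", mode))
  }
  cbind(matrix(rep(pop$baseline, n_pre), n_neurons, n_pre),
        matrix(rep(stim_rate, n_stim), n_neurons, n_stim))
}

#' Calcium dynamics parameters
#'
#' Defaults emulate GCaMP6f at 30 Hz: ~0.5 s decay, modest shot noise and a
#' slow sinusoidal baseline drift such as photobleaching/arousal would cause.
#'
#' @param decay_tau exponential decay constant, seconds.
#' @param noise_sd i.i.d. Gaussian noise SD, dF/F units.
#' @param drift_amplitude slow drift amplitude, dF/F units.
#' @param drift_period drift period, seconds.
#' @return list of class `calcium_params`.
#' @export
calcium_params <- function(decay_tau = 0.5, noise_sd = 0.5,
                           drift_amplitude = 0.05, drift_period = 300) {
  stopifnot(decay_tau > 0, noise_sd >= 0, drift_amplitude >= 0,
            drift_period > 0)
  structure(list(decay_tau = decay_tau, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period), class = "calcium_params")
}

#' Convolve rates with calcium dynamics
#'
#' Each neuron's rate series is filtered with a causal exponential kernel
#' (unit response at the impulse frame, decay `exp(-t/decay_tau)`), then a
#' per-neuron random-phase sinusoidal drift and i.i.d. Gaussian noise are
#' added.
#'
#' @param rates neurons x frames nonnegative rate matrix.
#' @param params a [calcium_params()].
#' @param frame_rate frames per second.
#' @return neurons x frames dF/F matrix with attribute `frame_rate`.
#' @export
simulate_calcium <- function(rates, params, frame_rate = 30) {
  stopifnot(all(rates >= 0))
  n_neurons <- nrow(rates); n_frames <- ncol(rates)
  a <- exp(-1 / (params$decay_tau * frame_rate))
  traces <- t(apply(rates, 1, function(x)
    as.numeric(stats::filter(x, a, method = "recursive"))))
  if (n_frames == 1) traces <- matrix(traces, n_neurons, n_frames)
  if (params$drift_amplitude > 0) {
    tsec <- (seq_len(n_frames) - 1) / frame_rate
    phase <- runif(n_neurons, 0, 2 * pi)
    drift <- params$drift_amplitude *
      sin(outer(phase, 2 * pi * tsec / params$drift_period, `+`))
    traces <- traces + drift
  }
  if (params$noise_sd > 0)
    traces <- traces + matrix(rnorm(n_neurons * n_frames, 0, params$noise_sd),
                              n_neurons, n_frames)
  attr(traces, "frame_rate") <- frame_rate
  traces
}

#' Psychometric behavior parameters
#'
#' @param sigma SD (degrees) of the cumulative-normal psychometric function;
#'   its slope is 1/sigma.
#' @param lapse lapse probability in `[0, 1]`.
#' @return list of class `psych_params`. The category boundary is the
#'   vertical axis (90/270 degrees).
#' @export
psych_params <- function(sigma = 30, lapse = 0.1) {
  stopifnot(sigma > 0, lapse >= 0, lapse <= 1)
  structure(list(sigma = sigma, lapse = lapse, boundary = "vertical"),
            class = "psych_params")
}

#' Simulate categorical choices
#'
#' P(choose right) follows a cumulative normal in the signed horizontal
#' distance of the mean direction from the vertical boundary, with a lapse
#' term: `(1 - lapse) * pnorm(d / sigma) + lapse / 2`.
#'
#' @param trials trial table from [design_session()].
#' @param psych a [psych_params()].
#' @return the trial table with `choice` and `correct` filled.
#' @export
simulate_choices <- function(trials, psych) {
  d <- boundary_distance(trials$mean_direction)
  p_right <- (1 - psych$lapse) * pnorm(d / psych$sigma) + psych$lapse / 2
  right <- runif(nrow(trials)) < p_right
  trials$choice <- ifelse(right, "right", "left")
  trials$correct <- trials$choice == trials$category
  trials
}

#' Generate a complete synthetic session
#'
#' Chains [design_session()], [sample_dot_directions()],
#' [simulate_trial_rates()], [simulate_calcium()] and [simulate_choices()]
#' into a session object with full ground truth attached.
#'
#' @param config a [session_config()].
#' @param pop a [population_model()].
#' @param calcium a [calcium_params()].
#' @param psych a [psych_params()].
#' @param seed integer seed; the session is fully reproducible given the seed.
#' @return object of class `rdk_session`: list with `trials` (data.frame),
#'   `traces` (neurons x frames dF/F), `frame_rate`, `config`, and
#'   `ground_truth` (population model, dot draws, parameters).
#' @export
#' @examples
#' s <- simulate_session(session_config(trials_per_direction = 2, n_dots = 50),
#'                       population_model(16), seed = 1)
#' dim(s$traces)
simulate_session <- function(config = session_config(),
                             pop = population_model(100),
                             calcium = calcium_params(),
                             psych = psych_params(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- design_session(config)
  dots <- lapply(seq_len(nrow(trials)), function(i)
    sample_dot_directions(trials$mean_direction[i], trials$het_range[i],
                          config$n_dots))
  frames_per_trial <- round((config$pre_window + config$stim_duration) *
                              config$frame_rate)
  rates <- matrix(0, nrow(pop), nrow(trials) * frames_per_trial)
  for (i in seq_len(nrow(trials))) {
    cols <- (i - 1L) * frames_per_trial + seq_len(frames_per_trial)
    rates[, cols] <- simulate_trial_rates(trials[i, ], dots[[i]], pop, config)
  }
  traces <- simulate_calcium(rates, calcium, config$frame_rate)
  trials <- simulate_choices(trials, psych)
  structure(list(trials = trials, traces = traces,
                 frame_rate = config$frame_rate, config = config,
                 ground_truth = list(population = pop, dots = dots,
                                     calcium = calcium, psych = psych,
                                     seed = seed)),
            class = "rdk_session")
}

#' @export
print.rdk_session <- function(x, ...) {
  cat("<rdk_session> ", nrow(x$traces), " neurons x ", ncol(x$traces),
      " frames @ ", x$frame_rate, " Hz; ", nrow(x$trials), " trials (",
      sum(x$trials$variance_condition == "hom"), " hom / ",
      sum(x$trials$variance_condition == "het"), " het, range ",
      x$config$het_range, " deg)\n", sep = "")
  invisible(x)
}
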