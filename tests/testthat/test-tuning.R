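test_that("tuning curves are stimulus-window AUCs of trial averages", {
  trials <- manual_trials(2, 90)
  # constant response c for every direction: all 8 responses equal c * 4 s
  traces <- manual_session_traces(trials, prefs = c(0, 0),
                                  function(pref, dir) 0.6)
  tun <- compute_tuning(traces, trials, "hom", correct_only = FALSE)
  expect_equal(unname(tun$responses), matrix(0.6 * 4, 2, 8))
  expect_true(all(tun$tie))
  # enumeration oracle on a 2-trial-per-direction toy with direction-indexed
  # responses
  resp_fn <- function(pref, dir) 0.1 + 0.002 * dir
  traces2 <- manual_session_traces(trials, prefs = c(22.5, 112.5), resp_fn)
  tun2 <- compute_tuning(traces2, trials, "het", correct_only = FALSE)
  expect_equal(unname(tun2$responses[1, ]),
               (0.1 + 0.002 * direction_set()) * 4)
  expect_equal(tun2$preferred_direction, c(337.5, 337.5))
})

test_that("correct-only filtering only touches the affected cells", {
  trials <- manual_trials(2, 90)
  trials$choice <- trials$category
  trials$correct <- TRUE
  withr::with_seed(41, traces <- matrix(rnorm(6 * (max(trials$onset_frame) +
                                                     200), 1, 0.1),
                                        nrow = 6))
  attr(traces, "frame_rate") <- 5
  before <- compute_tuning(traces, trials, "hom")
  # flip one homogeneous 67.5-degree trial to incorrect
  i <- which(trials$variance_condition == "hom" &
               trials$mean_direction == 67.5)[1]
  trials$correct[i] <- FALSE
  after <- compute_tuning(traces, trials, "hom")
  changed <- before$responses != after$responses
  expect_true(all(changed[, colnames(before$responses) != "67.5"] == FALSE))
  expect_true(any(changed[, colnames(before$responses) == "67.5"]))
})

test_that("DSI matches its definition and is scale invariant", {
  expect_equal(dsi(c(2, 0, 0, 0, 1, 0, 0, 0)), 0.5)
  expect_equal(dsi(rep(1, 8)), 0)
  expect_equal(dsi(c(1, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_true(is.na(dsi(rep(0, 8))))
  withr::with_seed(42, r <- matrix(runif(40, 0.1, 2), 5, 8))
  expect_equal(dsi(3.3 * r), dsi(r))
})

test_that("tuning slope equals the least-squares oracle", {
  flat <- matrix(1, 1, 8)
  expect_equal(popsumstats:::slope_from_curve(flat, 1), 0)
  # responses linear in |offset| with coefficient -a: slope = a
  a <- 0.004
  offs <- wrap180(direction_set() - 67.5)
  lin <- matrix(1 - a * abs(offs), 1, 8)
  expect_equal(popsumstats:::slope_from_curve(lin, 2), a)
  # cosine curve: slope equals lm() on the 5 averaged points
  cosine <- matrix(1 + cos(deg2rad(offs)), 1, 8)
  got <- popsumstats:::slope_from_curve(cosine, 2)
  y5 <- c(cosine[1 + (2 + 4 - 1) %% 8],
          (cosine[1 + (2 + 3 - 1) %% 8] + cosine[1 + (2 - 3 - 1) %% 8]) / 2,
          (cosine[1 + (2 + 2 - 1) %% 8] + cosine[1 + (2 - 2 - 1) %% 8]) / 2,
          (cosine[1 + (2 + 1 - 1) %% 8] + cosine[1 + (2 - 1 - 1) %% 8]) / 2,
          cosine[2])
  oracle <- unname(coef(lm(y5 ~ x, data.frame(x = c(-180, -135, -90, -45, 0),
                                              y5 = y5)))[2])
  expect_equal(got, oracle)
})

test_that("selectivity classification separates tuned from untuned neurons", {
  s <- small_direction_session()
  withr::with_seed(54,
    cs <- classify_selective(s$traces, s$trials, "hom", n_perm = 150))
  expect_gt(mean(cs$selective), 0.8)      # strongly tuned generator
  # a sharp curve with DSI exactly 0.39 is rejected (strict threshold)
  trials <- manual_trials(2, 90)
  resp_fn <- function(pref, dir) {
    off <- abs(wrap180(dir - pref))
    1 - 0.39 * (off == 180) - 0.2 * (off %in% c(45, 90, 135))
  }
  traces <- manual_session_traces(trials, prefs = rep(22.5, 9), resp_fn)
  withr::with_seed(55,
    cs39 <- classify_selective(traces, trials, "hom", n_perm = 150,
                               correct_only = FALSE))
  expect_equal(cs39$dsi, rep(0.39, 9), tolerance = 1e-10)
  expect_false(any(cs39$selective))
  # untuned noise: false-positive rate stays near the nominal joint level
  su <- small_untuned_session()
  withr::with_seed(56,
    csu <- classify_selective(su$traces, su$trials, "hom", n_perm = 150,
                              correct_only = FALSE))
  expect_lte(mean(csu$selective), 0.10)
  expect_error(classify_selective(s$traces, s$trials, "hom", n_perm = 50),
               "n_perm")
})

test_that("heterogeneous-tuning simulation reproduces analytic attenuation", {
  cosine <- matrix(1 + cos(deg2rad(direction_set() - 67.5)), 1)
  # identity window
  same <- simulate_het_tuning(cosine, 0, 1, n_resample = 3)
  expect_equal(mean(same$peak_amplitudes), 1, tolerance = 1e-9)
  # full-circle average of a cosine is flat
  flat <- simulate_het_tuning(cosine, 359.999, 1, n_resample = 3)
  expect_lt(abs(mean(flat$peak_amplitudes)), 1e-3)
  # range 180: peak shrinks to 2/pi, against the numeric-integration oracle
  half <- simulate_het_tuning(cosine, 180, 1, n_resample = 3)
  oracle <- stats::integrate(function(x) cos(deg2rad(x)) / 180, -90,
                             90)$value
  expect_equal(mean(half$peak_amplitudes), oracle, tolerance = 1e-3)
  expect_equal(oracle, 2 / pi, tolerance = 1e-8)
  # peak amplitude non-increasing in range for a unimodal von Mises curve
  vm <- matrix(exp(2 * (cos(deg2rad(direction_set() - 112.5)) - 1)), 1)
  withr::with_seed(43, peaks <- vapply(c(0, 90, 180, 270), function(rg)
    mean(simulate_het_tuning(vm, rg, 1, n_resample = 3)$peak_amplitudes),
    numeric(1)))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("cross-condition correlation behaves at its fixed points", {
  withr::with_seed(44, r <- matrix(runif(50 * 8), 50, 8))
  same <- cross_condition_correlation(r, r, n_perm = 200)
  expect_equal(same$r, 1)
  flipped <- cross_condition_correlation(r, -r + 2 * mean(r), n_perm = 200)
  expect_equal(flipped$r, -1)
  withr::with_seed(45, shuf <- matrix(sample(r), 50, 8))
  indep <- cross_condition_correlation(r, shuf, n_perm = 200)
  expect_lt(abs(indep$r), 0.1)
  expect_gt(indep$p, 0.05)
  expect_error(cross_condition_correlation(r[1, , drop = FALSE],
                                           r[1, , drop = FALSE]), "neurons")
})

test_that("peak confusion matrix concentrates on the diagonal when tuning
           is stable", {
  # heterogeneous tuned population whose single-trial noise exceeds the
  # tuning modulation: trial-averaged peaks stay put, while label shuffles
  # give each neuron an independent surrogate peak (a correlated,
  # structure-dominated population would lump whole preference groups into
  # one surrogate cell and make the null overdispersed)
  withr::with_seed(51, trials <- manual_trials(20, 90))
  n_neurons <- 160
  withr::with_seed(49, {
    prefs <- runif(n_neurons, 0, 360)
    kappas <- runif(n_neurons, 1.5, 3)
  })
  frames_per_trial <- 25
  traces <- matrix(0, n_neurons, nrow(trials) * frames_per_trial)
  n_stim <- 20
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_frame[i]
    traces[, on:(on + n_stim - 1)] <-
      0.2 * exp(kappas * (cos(deg2rad(trials$mean_direction[i] - prefs)) -
                            1))
  }
  withr::with_seed(50, traces <- traces +
                     matrix(rnorm(length(traces), 0, 0.5), n_neurons))
  attr(traces, "frame_rate") <- 5
  withr::with_seed(46,
    pc <- peak_confusion(traces, trials, n_perm = 600,
                         correct_only = FALSE))
  expect_equal(sum(pc$proportions), 1)
  expect_gte(sum(diag(pc$proportions)), 0.7)    # diagonal-heavy
  expect_true(all(diag(pc$significant)))
  expect_false(any(pc$significant[upper.tri(pc$significant)] |
                     pc$significant[lower.tri(pc$significant)]))
  # independent random peaks: mass spreads, nothing survives FDR
  su <- small_untuned_session()
  withr::with_seed(47,
    pcn <- peak_confusion(su$traces, su$trials, n_perm = 300,
                          correct_only = FALSE))
  expect_equal(sum(pcn$proportions), 1)
  expect_lte(sum(pcn$significant), 2)
})
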