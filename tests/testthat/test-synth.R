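test_that("session design is balanced, pseudo-randomized and deterministic", {
  cfg <- session_config()
  withr::with_seed(1, tr <- design_session(cfg))
  expect_equal(nrow(tr), 320)
  expect_equal(sum(tr$variance_condition == "hom"), 160)
  expect_equal(sum(tr$variance_condition == "het"), 160)
  # every (direction, condition) cell exactly trials_per_direction times
  counts <- table(tr$mean_direction, tr$variance_condition)
  expect_true(all(counts == 20))
  # no consecutive trials share both direction and condition
  same_dir <- diff(tr$mean_direction) == 0
  same_cond <- tr$variance_condition[-1] == tr$variance_condition[-320]
  expect_false(any(same_dir & same_cond))
  # sixteen trial types with one trial each
  one <- design_session(session_config(trials_per_direction = 1))
  expect_equal(nrow(one), 16)
  expect_equal(nrow(unique(one[, c("mean_direction", "variance_condition")])),
               16)
  # determinism under a fixed seed
  withr::with_seed(7, a <- design_session(cfg))
  withr::with_seed(7, b <- design_session(cfg))
  expect_identical(a, b)
  # category labels: the four directions nearest 0 degrees are "right"
  expect_setequal(unique(tr$category[tr$mean_direction %in%
                                       c(22.5, 67.5, 292.5, 337.5)]), "right")
  expect_setequal(unique(tr$category[tr$mean_direction %in%
                                       c(112.5, 157.5, 202.5, 247.5)]), "left")
})

test_that("degenerate one-cell schedules are rejected", {
  cfg <- session_config(het_range = 0, trials_per_direction = 3)
  cfg$direction_set <- 22.5          # a single trial type, three repeats
  expect_error(design_session(cfg), "unsatisfiable")
})

test_that("dot directions follow the wrapped uniform with mean excluded", {
  expect_equal(sample_dot_directions(67.5, 0, 500), rep(67.5, 500))
  withr::with_seed(11, x <- sample_dot_directions(90, 180, 1e5))
  expect_true(all(x >= 0 & x < 360))
  expect_false(any(x == 90))
  # circular mean converges to the nominal mean
  expect_lt(abs(wrap180(circ_mean(x) - 90)), 0.5)
  # empirical range converges to the nominal range
  off <- wrap180(x - 90)
  expect_lt(abs((max(off) - min(off)) - 180), 2)
  # wrap-through-zero case
  withr::with_seed(12, y <- sample_dot_directions(10, 90, 1e5))
  expect_lt(abs(wrap180(circ_mean(y) - 10)), 0.5)
  expect_true(all(abs(wrap180(y - 10)) <= 45))
})

test_that("trial rates implement the four coding modes", {
  cfg <- session_config(het_range = 90, trials_per_direction = 1,
                        frame_rate = 5, pre_window = 1)
  trials <- manual_trials(1, 90)
  hom <- trials[trials$variance_condition == "hom", ][1, ]
  pop <- population_model(3, coding_mode = "linear_sum", amplitude = 2,
                          baseline = 0.1,
                          preferred_directions = c(hom$mean_direction,
                                                   hom$mean_direction + 90,
                                                   hom$mean_direction + 180))
  dots <- rep(hom$mean_direction, 50)
  r <- simulate_trial_rates(hom, dots, pop, cfg)
  n_pre <- 5
  # pre-stimulus frames at baseline; peak response = baseline + amplitude
  expect_equal(unname(r[, 1:n_pre]), matrix(0.1, 3, n_pre))
  expect_equal(r[1, n_pre + 1], 2 + 0.1)
  # linear_sum with full-circle dots equals the tuning curve's circular
  # average (numeric-integration oracle), identical for all neurons
  withr::with_seed(3, dots360 <- sample_dot_directions(90, 359.999, 2e5))
  r360 <- simulate_trial_rates(hom, dots360, pop, cfg)
  oracle <- stats::integrate(function(d)
    popsumstats:::tuning_bump(d, 2, 2) / 360, -180, 180)$value + 0.1
  expect_equal(r360[, n_pre + 1], rep(oracle, 3), tolerance = 0.01)
  # sharpened_mean with unit gains equals linear_sum on a homogeneous trial
  pop_sm <- population_model(3, coding_mode = "sharpened_mean", amplitude = 2,
                             baseline = 0.1,
                             gain_by_range = c("0" = 1, "90" = 1),
                             preferred_directions = pop$preferred_direction)
  expect_equal(simulate_trial_rates(hom, dots, pop_sm, cfg), r)
  # untuned: baseline only
  pop_u <- population_model(2, coding_mode = "untuned", baseline = 0.3)
  expect_true(all(simulate_trial_rates(hom, dots, pop_u, cfg) == 0.3))
  # category: two levels keyed to the trial's category
  pop_c <- population_model(2, coding_mode = "category", amplitude = 1,
                            baseline = 0.1,
                            preferred_directions = c(0, 180))
  rc <- simulate_trial_rates(hom, dots, pop_c, cfg)
  stim_col <- n_pre + 1
  if (hom$category == "right") {
    expect_equal(rc[, stim_col], c(1.1, 0.1))
  } else {
    expect_equal(rc[, stim_col], c(0.1, 1.1))
  }
  # unknown mode fails loudly
  pop_bad <- pop
  pop_bad$coding_mode <- "quadratic"
  expect_error(simulate_trial_rates(hom, dots, pop_bad, cfg), "coding_mode")
})

test_that("linear_sum amplitude shrinks by the analytic attenuation factor", {
  # for near-cosine tuning (small kappa), averaging over a uniform window of
  # width R multiplies the modulated part by sin(R/2)/(R/2)
  cfg <- session_config(het_range = 180, trials_per_direction = 1,
                        frame_rate = 5, pre_window = 1)
  trials <- manual_trials(1, 180)
  het <- trials[trials$variance_condition == "het", ][1, ]
  pop <- population_model(1, coding_mode = "linear_sum", amplitude = 1,
                          kappa = 2, baseline = 0,
                          preferred_directions = het$mean_direction)
  withr::with_seed(4, dots <- sample_dot_directions(het$mean_direction, 180,
                                                    2e5))
  r <- simulate_trial_rates(het, dots, pop, cfg)
  oracle <- stats::integrate(function(d)
    popsumstats:::tuning_bump(d, 1, 2) / 180, -90, 90)$value
  expect_equal(r[1, 6], oracle, tolerance = 0.01)
})

test_that("calcium dynamics follow the causal exponential kernel", {
  p0 <- calcium_params(noise_sd = 0, drift_amplitude = 0)
  zero <- simulate_calcium(matrix(0, 2, 50), p0, frame_rate = 10)
  expect_true(all(zero == 0))
  # unit impulse: exp(-t/tau) from the impulse frame, peak at that frame
  imp <- matrix(0, 1, 40); imp[1, 10] <- 1
  tr <- simulate_calcium(imp, calcium_params(decay_tau = 0.5, noise_sd = 0,
                                             drift_amplitude = 0),
                         frame_rate = 10)
  expect_equal(which.max(tr[1, ]), 10)
  k <- 0:20
  expect_equal(tr[1, 10 + k], exp(-k / (0.5 * 10)), tolerance = 1e-10)
  expect_true(all(tr[1, 1:9] == 0))
  # seeded reproducibility with noise and drift
  pn <- calcium_params()
  withr::with_seed(5, a <- simulate_calcium(imp, pn, 10))
  withr::with_seed(5, b <- simulate_calcium(imp, pn, 10))
  expect_identical(a, b)
})

test_that("choices follow the cumulative-normal psychometric rule", {
  trials <- manual_trials(20, 90)
  # sigma -> 0, no lapse: all choices correct
  withr::with_seed(6, done <- simulate_choices(trials,
                                               psych_params(sigma = 1e-6,
                                                            lapse = 0)))
  expect_true(all(done$correct))
  # direction 67.5, sigma 22.5: P(right) = pnorm(1)
  t67 <- trials[rep(which(trials$mean_direction == 67.5)[1], 4000), ]
  withr::with_seed(7, c67 <- simulate_choices(t67, psych_params(22.5, 0)))
  p_hat <- mean(c67$choice == "right")
  expect_equal(p_hat, pnorm(1), tolerance = 3 * sqrt(pnorm(1) * 0.16 / 4000))
  # full lapse: accuracy near one half
  withr::with_seed(8, lapsed <- simulate_choices(trials,
                                                 psych_params(20, 1)))
  expect_lt(abs(mean(lapsed$correct) - 0.5), 0.09)  # 3 binomial SE at n=320
})

test_that("simulated sessions are reproducible end to end", {
  cfg <- session_config(trials_per_direction = 1, n_dots = 20,
                        frame_rate = 5, pre_window = 1)
  a <- simulate_session(cfg, population_model(4), seed = 9)
  b <- simulate_session(cfg, population_model(4), seed = 9)
  expect_identical(a$trials, b$trials)
  expect_identical(a$traces, b$traces)
  expect_equal(dim(a$traces), c(4, 16 * 25))
})
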