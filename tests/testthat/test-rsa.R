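test_that("pseudo-trials average within chunks and reduce variance", {
  s <- small_direction_session()
  withr::with_seed(81, ps <- pseudo_trials(s$traces, s$trials, n_chunks = 2,
                                           frac = 0.5, n_synth = 20,
                                           correct_only = FALSE,
                                           epoch = c(0, 4), bin_width = 2))
  expect_equal(nrow(ps$conditions), 16)
  expect_equal(dim(ps$data[[1]][[1]]), c(20, 24, 2))
  # seeded reproducibility
  withr::with_seed(81, ps2 <- pseudo_trials(s$traces, s$trials, n_chunks = 2,
                                            frac = 0.5, n_synth = 20,
                                            correct_only = FALSE,
                                            epoch = c(0, 4), bin_width = 2))
  expect_identical(ps$data, ps2$data)
  # identical trials produce identical pseudo-trials
  trials <- manual_trials(4, 90)
  traces <- manual_session_traces(trials, prefs = c(0, 90),
                                  function(pref, dir) 0.7)
  psc <- pseudo_trials(traces, trials, n_chunks = 2, n_synth = 5,
                       correct_only = FALSE, epoch = c(1, 3), bin_width = 2)
  expect_true(all(psc$data[[1]][[1]] == 0.7))
  # averaging shrinks trial-to-trial variance below the raw variance
  arr <- binned_epoch_array(s$traces,
                            s$trials[s$trials$mean_direction == 22.5 &
                                       s$trials$variance_condition == "hom", ],
                            epoch = c(0, 4), bin_width = 2)
  raw_var <- mean(apply(arr[, , 1], 2, var))
  ps_var <- mean(apply(ps$data[[1]][[1]][, , 1], 2, var))
  expect_lt(ps_var, raw_var)
  expect_error(pseudo_trials(s$traces, s$trials[1:20, ], n_chunks = 4,
                             correct_only = FALSE), "trials")
})

test_that("the internal shrinkage LDA matches MASS::lda without shrinkage", {
  withr::with_seed(82, {
    x <- rbind(matrix(rnorm(60 * 4, 0), 60, 4),
               matrix(rnorm(60 * 4, 1.2), 60, 4))
    y <- rep(c("a", "b"), each = 60)
    xt <- matrix(rnorm(40 * 4, 0.6), 40, 4)
  })
  ours <- popsumstats:::lda_fit(x, y, shrink_if = FALSE)
  ref <- MASS::lda(x, grouping = y)
  expect_equal(predict(ours, xt),
               as.character(predict(ref, xt)$class))
})

test_that("pairwise decoding reflects condition separation", {
  mk <- function(sep, seed) {
    withr::with_seed(seed, list(
      a = matrix(rnorm(40 * 6, 0), 40, 6),
      b = matrix(rnorm(40 * 6, sep), 40, 6)))
  }
  acc_at <- vapply(c(0, 0.8, 3), function(sep) {
    d <- mk(sep, 83 + round(sep * 10))
    pseudo <- structure(list(
      conditions = data.frame(direction = c(22.5, 67.5),
                              variance = "hom"),
      bin_times = 0, n_chunks = 2,
      data = list(list(array(d$a[1:20, ], c(20, 6, 1)),
                       array(d$a[21:40, ], c(20, 6, 1))),
                  list(array(d$b[1:20, ], c(20, 6, 1)),
                       array(d$b[21:40, ], c(20, 6, 1))))),
      class = "pseudo_trials")
    pairwise_rdm(pseudo, 1)[1, 2]
  }, numeric(1))
  expect_lt(abs(acc_at[1] - 0.5), 0.15)      # identical generators
  expect_true(all(diff(acc_at) > 0))         # monotone in separation
  expect_gt(acc_at[3], 0.99)                 # far-separated: perfect
})

test_that("model RDMs encode mean, variance and category structure", {
  m <- build_model_rdms()
  conds <- m$conditions
  at <- function(rdm, d1, v1, d2, v2) {
    i <- which(conds$direction == d1 & conds$variance == v1)
    j <- which(conds$direction == d2 & conds$variance == v2)
    rdm[i, j]
  }
  # same direction, same variance: zero mean dissimilarity
  expect_equal(at(m$mean_rdm, 22.5, "hom", 22.5, "hom"), 0)
  # the mean model ignores the variance pairing
  expect_equal(at(m$mean_rdm, 22.5, "hom", 67.5, "het"),
               at(m$mean_rdm, 22.5, "hom", 67.5, "hom"))
  # opposite directions maximal
  expect_equal(at(m$mean_rdm, 22.5, "hom", 202.5, "hom"), max(m$mean_rdm))
  # variance model is binary same/different
  expect_equal(at(m$variance_rdm, 22.5, "hom", 67.5, "hom"), 0)
  expect_equal(at(m$variance_rdm, 22.5, "hom", 22.5, "het"), 1)
  # category model follows the vertical boundary
  expect_equal(at(m$category_rdm, 22.5, "hom", 157.5, "hom"), 1)
  expect_equal(at(m$category_rdm, 112.5, "hom", 157.5, "hom"), 0)
  expect_equal(at(m$category_rdm, 67.5, "hom", 112.5, "hom"), 1)
  expect_true(isSymmetric(m$mean_rdm))
})

test_that("RDM regression recovers planted model combinations exactly", {
  m <- build_model_rdms()
  ut <- upper.tri(m$mean_rdm)
  zs <- function(r) (r[ut] - mean(r[ut])) / sd(r[ut])
  embed <- function(v) {
    out <- matrix(0, 16, 16)
    out[ut] <- v
    out + t(out)
  }
  b <- regress_rdm(embed(zs(m$mean_rdm)), m)
  expect_equal(unname(b[2:4]), c(1, 0, 0), tolerance = 1e-10)
  b2 <- regress_rdm(embed(zs(m$category_rdm)), m)
  expect_equal(unname(b2[2:4]), c(0, 0, 1), tolerance = 1e-10)
  b3 <- regress_rdm(embed(0.5 * zs(m$mean_rdm) + 0.5 * zs(m$variance_rdm)),
                    m)
  expect_equal(unname(b3[2:4]), c(0.5, 0.5, 0), tolerance = 1e-10)
})

test_that("session-level RSA separates direction from category coders", {
  # package-default SNR: pairwise accuracies stay off the ceiling so the
  # regression has graded structure to work with
  mk <- function(mode, seed) simulate_session(
    session_config(het_range = 90, trials_per_direction = 5, n_dots = 50,
                   frame_rate = 5, pre_window = 1),
    population_model(24, coding_mode = mode),
    calcium_params(drift_amplitude = 0.02), psych_params(5, 0), seed = seed)
  run_rsa <- function(s) rsa_timecourse(s$traces, s$trials, n_synth = 25,
                                        correct_only = FALSE,
                                        epoch = c(0.5, 4), bin_width = 3.5)
  withr::with_seed(84, r_dir <- run_rsa(mk("sharpened_mean", 86)))
  withr::with_seed(85, r_cat <- run_rsa(mk("category", 87)))
  # bounds and symmetry of the neural RDM
  rdm <- r_dir$rdms[[1]]
  expect_true(isSymmetric(unname(rdm)))
  expect_true(all(rdm[upper.tri(rdm)] >= 0 & rdm[upper.tri(rdm)] <= 1))
  # off the ceiling: mean pairwise accuracy clearly below 1
  expect_lt(mean(rdm[upper.tri(rdm)]), 0.97)
  # direction coder: mean beta dominates category beta
  expect_gt(r_dir$betas[1, "beta_mean"], 0.05)
  expect_gt(r_dir$betas[1, "beta_mean"], 3 * abs(r_dir$betas[1,
                                                             "beta_category"]))
  # category coder: the reverse
  expect_gt(r_cat$betas[1, "beta_category"], 0.1)
  expect_gt(r_cat$betas[1, "beta_category"], 3 * abs(r_cat$betas[1,
                                                                 "beta_mean"]))
})
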