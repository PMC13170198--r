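# Session persistence (plain-text schema) and end-to-end orchestration.

#' Write a session to a directory
#'
#' On-disk schema: `trials.csv` (the trial table), `traces.csv`
#' (neurons x frames dF/F, no header) and `config.json` (session config and
#' frame rate). Plain text throughout so sessions are portable and
#' diffable.
#'
#' @param session an `rdk_session` (or a list with `trials`, `traces`,
#'   `frame_rate`, `config`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  data.table::fwrite(data.table::as.data.table(session$traces),
                     file.path(dir, "traces.csv"), col.names = FALSE)
  cfg <- session$config
  cfg$frame_rate <- session$frame_rate
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from a directory
#'
#' @param dir directory written by [write_session()] (or following the same
#'   schema).
#' @return an `rdk_session` (without ground truth).
#' @export
read_session <- function(dir) {
  needed <- file.path(dir, c("trials.csv", "traces.csv", "config.json"))
  missing <- needed[!file.exists(needed)]
  if (length(missing))
    stop("session directory is missing: ", paste(missing, collapse = ", "))
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  traces <- as.matrix(data.table::fread(file.path(dir, "traces.csv"),
                                        header = FALSE))
  dimnames(traces) <- NULL
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  attr(traces, "frame_rate") <- cfg$frame_rate
  structure(list(trials = trials, traces = traces,
                 frame_rate = cfg$frame_rate, config = cfg,
                 ground_truth = NULL),
            class = "rdk_session")
}

#' Run the full analysis pipeline on one session
#'
#' Executes preprocessing, behavior, tuning, PRC, bias, decoding and RSA in
#' order, writes each stage's tables as CSV under `out_dir` and a JSON run
#' manifest with content hashes of every output.
#'
#' @param session an `rdk_session`.
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived as
#'   `seed + stage index` so stages are independently reproducible.
#' @param bin_width analysis bin width in seconds (default 0.5; the raw
#'   frame rate is retained in the preprocessed traces).
#' @param n_perm permutations for selectivity classification.
#' @param n_synth pseudo-trials per condition/chunk for RSA.
#' @param n_repeats WCD/BCD partition repeats.
#' @return list with all stage results and the manifest, invisibly; files
#'   under `out_dir`.
#' @export
run_full_analysis <- function(session, out_dir, seed = 1, bin_width = 0.5,
                              n_perm = 500, n_synth = 100, n_repeats = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- c()
  stage <- function(i, name, expr) {
    set.seed(seed + i)
    tic <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    res
  }
  has_het <- any(session$trials$variance_condition == "het")

  clean <- stage(1, "preprocess", {
    cl <- clean_traces(session$traces)
    ev <- detect_events_and_qc(cl)
    utils::write.csv(ev$qc, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    list(traces = cl, events = ev)
  })
  traces <- clean$traces

  behavior <- stage(2, "behavior", {
    bs <- summarize_behavior(session$trials)
    utils::write.csv(bs$by_direction, file.path(out_dir, "behavior_by_direction.csv"),
                     row.names = FALSE)
    utils::write.csv(bs$dprime_table, file.path(out_dir, "dprime_export.csv"),
                     row.names = FALSE)
    hom <- bs$by_direction[bs$by_direction$condition == "hom", ]
    fit <- fit_cumulative_normal(hom$mean_direction,
                                 round(hom$prop_right * hom$n), hom$n)
    list(summary = bs, fit_hom = fit)
  })

  tuning <- stage(3, "tuning", {
    th <- classify_selective(traces, session$trials, "hom", n_perm = n_perm)
    te <- if (has_het)
      classify_selective(traces, session$trials, "het", n_perm = n_perm)
    tab <- data.frame(neuron_id = seq_along(th$preferred_direction),
                      condition = "hom",
                      preferred_direction = th$preferred_direction,
                      dsi = th$dsi, slope = th$slope,
                      selective = th$selective)
    if (has_het)
      tab <- rbind(tab, data.frame(neuron_id = seq_along(te$preferred_direction),
                                   condition = "het",
                                   preferred_direction = te$preferred_direction,
                                   dsi = te$dsi, slope = te$slope,
                                   selective = te$selective))
    utils::write.csv(tab, file.path(out_dir, "tuning.csv"), row.names = FALSE)
    list(hom = th, het = if (has_het) te)
  })

  prc <- stage(4, "prc", {
    out <- list()
    for (cond in c("hom", if (has_het) "het")) {
      pm <- preferred_direction_map(traces, session$trials, cond)
      tens <- build_prc(traces, session$trials, pm, cond,
                        bin_width = bin_width)
      out[[cond]] <- list(prc = tens, slope = prc_slope(tens), pref = pm)
    }
    sl <- data.frame(bin_time = out$hom$slope$bin_times,
                     slope_hom = out$hom$slope$slope)
    if (has_het) sl$slope_het <- out$het$slope$slope
    utils::write.csv(sl, file.path(out_dir, "prc_slope.csv"),
                     row.names = FALSE)
    out
  })

  bias <- stage(5, "bias", {
    b <- session_bias(traces, session$trials, prc$hom$pref, "hom",
                      bin_width = bin_width)
    utils::write.csv(b, file.path(out_dir, "bias.csv"), row.names = FALSE)
    b
  })

  decoding <- stage(6, "decoding", {
    iem <- iem_timecourse(traces, session$trials, bin_width = bin_width)
    out <- data.frame(bin_time = iem$bin_times, ctf_slope_hom = iem$slope_hom)
    if (has_het) out$ctf_slope_het <- iem$slope_het
    svm_var <- if (has_het)
      svm_condition_timecourse(traces, session$trials, "variance",
                               bin_width = bin_width)
    if (has_het) out$svm_variance_accuracy <- svm_var$accuracy
    utils::write.csv(out, file.path(out_dir, "decoding.csv"),
                     row.names = FALSE)
    list(iem = iem, svm_variance = svm_var)
  })

  rsa <- stage(7, "rsa", {
    if (!has_het) return(NULL)
    r <- rsa_timecourse(traces, session$trials, n_synth = n_synth,
                        bin_width = bin_width)
    utils::write.csv(cbind(bin_time = r$bin_times, as.data.frame(r$betas)),
                     file.path(out_dir, "rsa_betas.csv"), row.names = FALSE)
    r
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    seed = seed, bin_width = bin_width,
    n_trials = nrow(session$trials), n_neurons = nrow(session$traces),
    wall_clock_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(preprocess = clean, behavior = behavior, tuning = tuning,
                 prc = prc, bias = bias, decoding = decoding, rsa = rsa,
                 manifest = manifest))
}

#' Synthetic acceptance benchmark
#'
#' Re-runs the package's design- and calibration-level checks on freshly
#' generated synthetic data and returns a machine-readable verdict table:
#' session design counts, stimulus properties, IEM algebra, linear-summation
#' attenuation, and decoder chance calibration.
#'
#' @param seed master seed.
#' @return data.frame: `check`, `value`, `expected`, `pass`.
#' @export
run_acceptance_benchmark <- function(seed = 1) {
  set.seed(seed)
  rows <- list()
  add <- function(check, value, expected, pass)
    rows[[length(rows) + 1]] <<- data.frame(check = check, value = value,
                                            expected = expected, pass = pass)
  tr <- design_session(session_config())
  add("hom_trials", sum(tr$variance_condition == "hom"), 160,
      sum(tr$variance_condition == "hom") == 160)
  add("het_trials", sum(tr$variance_condition == "het"), 160,
      sum(tr$variance_condition == "het") == 160)
  types <- nrow(unique(tr[, c("mean_direction", "variance_condition")]))
  add("trial_types", types, 16, types == 16)
  adj <- !any(diff(tr$mean_direction) == 0 &
                tr$variance_condition[-1] == tr$variance_condition[-nrow(tr)])
  add("adjacency_constraint", as.numeric(adj), 1, adj)
  add("dots_per_rdk", session_config()$n_dots, 500,
      session_config()$n_dots == 500)
  add("n_directions", length(direction_set()), 8,
      length(direction_set()) == 8)
  # IEM algebraic round trip
  W <- matrix(rnorm(20 * 8), 20)
  Cb <- make_basis(wrap360(runif(40, 0, 360)))
  Chat <- iem_invert(iem_fit(W %*% Cb, Cb), W %*% Cb)
  err <- max(abs(Chat - Cb))
  add("iem_round_trip_error", err, 0, err < 1e-8)
  # linear-summation attenuation of a cosine curve at range 180
  cosine <- matrix(1 + cos(deg2rad(direction_set() - 67.5)), 1)
  sim <- simulate_het_tuning(cosine, 180, 1, n_resample = 10)
  att <- mean(sim$peak_amplitudes)
  add("cosine_attenuation_180", att, 2 / pi, abs(att - 2 / pi) < 0.01 * 2 / pi)
  do.call(rbind, rows)
}
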