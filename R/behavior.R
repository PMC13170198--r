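# Psychometric analysis: proportion-right curves over mean direction,
# binomial maximum-likelihood cumulative-normal fits (slope = 1/sigma),
# d-prime sensitivity and the easy/hard direction split.

#' The easy and hard direction subsets
#'
#' Easy directions lie far from the vertical category boundary, hard
#' directions close to it.
#' @return list with numeric vectors `easy` and `hard` (degrees).
#' @export
difficulty_sets <- function() {
  list(easy = c(22.5, 157.5, 202.5, 337.5),
       hard = c(67.5, 112.5, 247.5, 292.5))
}

#' Fit a cumulative-normal psychometric function
#'
#' Directions are folded onto their signed horizontal distance from the
#' vertical category boundary (positive toward the right-category center) and
#' the proportion of rightward choices is fitted with
#' `P(right) = (1 - lapse) * pnorm((d - mu) / sigma) + lapse / 2`
#' by binomial maximum likelihood. The psychometric slope is reported as
#' `1 / sigma`.
#'
#' @param directions stimulus mean directions (degrees), one per level.
#' @param n_right rightward-choice counts per level.
#' @param n_total trial counts per level.
#' @param lapse fixed lapse rate (default 0; the fit does not estimate it).
#' @param sigma_bounds lower/upper bound on sigma (degrees); hitting a bound
#'   sets the corresponding flag.
#' @return list of class `psychometric_fit`: `mu`, `sigma`, `slope`
#'   (= 1/sigma), `log_likelihood`, `n_trials`, `at_lower_bound`,
#'   `at_upper_bound`, `perfect_separation`.
#' @export
fit_cumulative_normal <- function(directions, n_right, n_total, lapse = 0,
                                  sigma_bounds = c(0.5, 1000)) {
  stopifnot(length(directions) >= 4, all(n_total >= 1),
            length(n_right) == length(directions),
            length(n_total) == length(directions))
  d <- boundary_distance(directions)
  nll <- function(par) {
    mu <- par[1]; sigma <- par[2]
    p <- (1 - lapse) * pnorm((d - mu) / sigma) + lapse / 2
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(n_right * log(p) + (n_total - n_right) * log(1 - p))
  }
  fit <- optim(c(0, 20), nll, method = "L-BFGS-B",
               lower = c(-90, sigma_bounds[1]),
               upper = c(90, sigma_bounds[2]))
  sigma <- fit$par[2]
  prop <- n_right / n_total
  sep <- all(prop[order(d)] %in% c(0, 1)) && length(unique(prop)) > 1
  structure(list(mu = fit$par[1], sigma = sigma, slope = 1 / sigma,
                 log_likelihood = -fit$value, n_trials = sum(n_total),
                 at_lower_bound = abs(sigma - sigma_bounds[1]) < 1e-6,
                 at_upper_bound = abs(sigma - sigma_bounds[2]) < 1e-6,
                 perfect_separation = sep),
            class = "psychometric_fit")
}

#' Two-alternative forced-choice sensitivity d'
#'
#' `d' = sqrt(2) * qnorm(p)` for proportion correct `p` in a 2AFC design.
#' Proportions of exactly 0 or 1 are clipped to `1/(2N)` and `1 - 1/(2N)`
#' before the transform; `n` is then required.
#'
#' @param p proportion correct.
#' @param n number of trials behind `p` (needed only for clipping).
#' @return numeric d' value(s).
#' @export
#' @examples
#' dprime(0.5)      # 0
#' dprime(0.8413)   # ~ sqrt(2)
dprime <- function(p, n = NULL) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  extreme <- p %in% c(0, 1)
  if (any(extreme)) {
    if (is.null(n)) stop("p of 0 or 1 requires n for the 1/(2N) clipping rule")
    n <- rep_len(n, length(p))
    p[extreme] <- pmin(pmax(p[extreme], 1 / (2 * n[extreme])),
                       1 - 1 / (2 * n[extreme]))
  }
  sqrt(2) * qnorm(p)
}

#' Summarize choice behavior of one session
#'
#' Computes the per-direction proportion of rightward choices and, per
#' variance condition and difficulty (easy/hard), the proportion correct and
#' d'. The returned `dprime_table` is shaped for export to an external
#' mixed-model fit (one row per condition x difficulty).
#'
#' @param trials a trial table with `choice` filled.
#' @return list of class `behavior_summary`: `by_direction` (data.frame:
#'   condition, mean_direction, n, prop_right), `dprime_table` (data.frame:
#'   condition, difficulty, n, prop_correct, d_prime).
#' @export
summarize_behavior <- function(trials) {
  tr <- trials[!is.na(trials$choice) & trials$choice != "none", ]
  if (nrow(tr) == 0) stop("no scored choices in the trial table")
  by_dir <- do.call(rbind, lapply(split(tr,
      list(tr$variance_condition, tr$mean_direction), drop = TRUE),
    function(g) data.frame(condition = g$variance_condition[1],
                           mean_direction = g$mean_direction[1],
                           n = nrow(g),
                           prop_right = mean(g$choice == "right"))))
  by_dir <- by_dir[order(by_dir$condition, by_dir$mean_direction), ]
  rownames(by_dir) <- NULL

  sets <- difficulty_sets()
  tr$difficulty <- ifelse(tr$mean_direction %in% sets$easy, "easy",
                   ifelse(tr$mean_direction %in% sets$hard, "hard", NA))
  td <- tr[!is.na(tr$difficulty), ]
  dp <- do.call(rbind, lapply(split(td,
      list(td$variance_condition, td$difficulty), drop = TRUE),
    function(g) {
      p <- mean(g$correct)
      data.frame(condition = g$variance_condition[1],
                 difficulty = g$difficulty[1], n = nrow(g),
                 prop_correct = p, d_prime = dprime(p, nrow(g)))
    }))
  dp <- dp[order(dp$condition, dp$difficulty), ]
  rownames(dp) <- NULL
  structure(list(by_direction = by_dir, dprime_table = dp),
            class = "behavior_summary")
}
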