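# Categorical bias of the population representation: wrapped-normal fits of
# the time-averaged PRC, re-anchored to absolute direction, and the signed
# displacement of the fitted peak toward the category center.

#' Wrapped-normal density (truncated sum)
#'
#' `f(theta) = sum_k exp(-(theta - mu + 360 k)^2 / (2 sigma^2))`, with the
#' wrapped sum truncated to `|k| <= K`. Angles in degrees.
#'
#' @param theta evaluation angles (degrees).
#' @param mu peak location (degrees).
#' @param sigma width (degrees).
#' @param K truncation order (terms beyond |k| = 3 are negligible for
#'   sigma <= 90 degrees).
#' @return density values (unnormalized, peak value ~1 for small sigma).
#' @export
wrapped_normal <- function(theta, mu, sigma, K = 3) {
  out <- 0
  for (k in -K:K) out <- out + exp(-((theta - mu + 360 * k)^2) / (2 * sigma^2))
  out
}

#' Fit a wrapped normal to an 8-point response curve
#'
#' Least-squares fit of `amplitude * wrapped_normal(theta; mu, sigma) +
#' offset` to direction-indexed responses (typically a PRC averaged over the
#' stimulus window and re-anchored to absolute direction). `mu` is
#' initialized at the empirical argmax and optimized on the circle, so
#' wrap-adjacent peaks are recovered without aliasing.
#'
#' @param theta sample directions (degrees), at least 5 distinct values.
#' @param values responses at `theta`.
#' @param K wrapped-sum truncation.
#' @return list of class `wrapped_normal_fit`: `mu` (in [0, 360)),
#'   `sigma_w`, `amplitude`, `offset`, `converged`, `rss`.
#' @export
fit_wrapped_normal <- function(theta, values, K = 3) {
  stopifnot(length(theta) == length(values))
  if (length(unique(wrap360(theta))) < 5)
    stop("need at least 5 distinct direction samples")
  if (stats::sd(values) == 0 || anyNA(values))
    return(structure(list(mu = NA_real_, sigma_w = NA_real_,
                          amplitude = NA_real_, offset = NA_real_,
                          converged = FALSE, rss = NA_real_),
                     class = "wrapped_normal_fit"))
  mu0 <- theta[which.max(values)]
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    f <- wrapped_normal(theta, mu, sigma, K)
    # profile amplitude and offset by linear least squares
    X <- cbind(1, f)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, values)),
                     error = function(e) NULL)
    if (is.null(beta)) return(sum((values - mean(values))^2) * 2)
    sum((values - X %*% beta)^2)
  }
  best <- NULL
  for (s0 in c(25, 45, 70)) {
    fit <- tryCatch(optim(c(mu0, log(s0)), obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(structure(list(mu = NA_real_, sigma_w = NA_real_,
                          amplitude = NA_real_, offset = NA_real_,
                          converged = FALSE, rss = NA_real_),
                     class = "wrapped_normal_fit"))
  mu <- wrap360(best$par[1]); sigma <- exp(best$par[2])
  f <- wrapped_normal(theta, mu, sigma, K)
  X <- cbind(1, f)
  beta <- solve(crossprod(X), crossprod(X, values))
  converged <- best$convergence == 0 && sigma > 1 && sigma < 360 &&
    beta[2] > 0
  structure(list(mu = mu, sigma_w = sigma, amplitude = beta[2],
                 offset = beta[1], converged = converged, rss = best$value),
            class = "wrapped_normal_fit")
}

#' Signed categorical bias of a fitted peak
#'
#' The wrapped difference between the fitted peak and the presented
#' direction, signed so that displacement toward the nearest horizontal
#' category center (0 degrees for the right category, 180 for the left) is
#' positive and displacement toward the vertical boundary is negative.
#'
#' @param fit a converged [fit_wrapped_normal()] result (or a numeric mu).
#' @param theta_sample presented direction (degrees); must not lie on the
#'   boundary.
#' @return list of class `bias_estimate`: `theta_sample`, `mu`,
#'   `raw_difference` (wrapped, degrees), `signed_bias`.
#' @export
signed_bias <- function(fit, theta_sample) {
  mu <- if (is.numeric(fit)) fit else {
    if (!isTRUE(fit$converged)) stop("fit did not converge")
    fit$mu
  }
  if (abs(boundary_distance(theta_sample)) < 1e-9)
    stop("theta_sample lies on the category boundary; sign undefined")
  center <- category_center(theta_sample)
  raw <- wrap180(mu - theta_sample)
  towards <- abs(wrap180(mu - center)) < abs(wrap180(theta_sample - center))
  structure(list(theta_sample = theta_sample, mu = mu, raw_difference = raw,
                 signed_bias = ifelse(towards, 1, -1) * abs(raw)),
            class = "bias_estimate")
}

#' Session-level categorical bias from a time-averaged PRC
#'
#' For each presented direction, re-anchors the stimulus-window-averaged PRC
#' offsets to absolute direction, fits the wrapped normal and returns the
#' signed bias.
#'
#' @inheritParams build_prc
#' @param window stimulus window (seconds) over which the PRC is averaged.
#' @return data.frame: `theta_sample`, `mu`, `signed_bias`, `converged`.
#' @export
session_bias <- function(traces, trials, pref_map, condition = "hom",
                         correct_only = TRUE, window = c(0, 4),
                         bin_width = NULL) {
  if (is.list(pref_map)) pref_map <- pref_map$preferred
  dirs <- direction_set()
  out <- lapply(dirs, function(ds) {
    tr <- trials[trials$mean_direction == ds, , drop = FALSE]
    prc <- build_prc(traces, tr, pref_map, condition, correct_only,
                     epoch = window, bin_width = bin_width)
    stim <- prc$bin_times >= window[1] & prc$bin_times < window[2]
    avg <- rowMeans(prc$values[, stim, drop = FALSE])
    theta <- wrap360(prc$offsets + ds)
    fit <- fit_wrapped_normal(theta, avg)
    if (isTRUE(fit$converged)) {
      b <- signed_bias(fit, ds)
      data.frame(theta_sample = ds, mu = fit$mu,
                 signed_bias = b$signed_bias, converged = TRUE)
    } else {
      data.frame(theta_sample = ds, mu = NA_real_, signed_bias = NA_real_,
                 converged = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Group-level bias summary with outlier exclusion
#'
#' Applies Tukey-fence outlier exclusion (beyond `iqr_k` times the IQR from
#' the quartiles) per condition, then a one-sample t-test of the mean bias
#' against zero per condition and, when a paired column is present, a paired
#' test between conditions; p-values are Benjamini-Hochberg corrected across
#' conditions.
#'
#' @param biases data.frame with columns `subject`, `condition`, `bias`
#'   (one value per subject x condition, e.g. subject-mean signed bias).
#' @param iqr_k Tukey fence multiplier.
#' @param alpha FDR level.
#' @return data.frame per condition: `condition`, `n`, `n_excluded`,
#'   `mean_bias`, `t`, `p`, `p_adjusted`, `significant`.
#' @export
bias_summary <- function(biases, iqr_k = 1.5, alpha = 0.05) {
  stopifnot(all(c("subject", "condition", "bias") %in% names(biases)))
  conds <- unique(biases$condition)
  rows <- lapply(conds, function(cc) {
    x <- biases$bias[biases$condition == cc]
    x <- x[!is.na(x)]
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    fence <- c(q[1] - iqr_k * diff(q), q[2] + iqr_k * diff(q))
    keep <- x >= fence[1] & x <= fence[2]
    xk <- x[keep]
    if (length(xk) < 3 || stats::sd(xk) == 0)
      return(data.frame(condition = cc, n = length(xk),
                        n_excluded = sum(!keep), mean_bias = mean(xk),
                        t = NA_real_, p = NA_real_))
    tt <- t.test(xk, mu = 0)
    data.frame(condition = cc, n = length(xk), n_excluded = sum(!keep),
               mean_bias = mean(xk), t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  out
}
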