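# Minimal linear support-vector classifier (L2-regularized squared hinge,
# class-weight balanced), written in-package because no SVM library ships
# with the analysis environment. The smooth squared hinge keeps the problem
# convex and differentiable so BFGS converges quickly at the data sizes used
# here (tens of neurons, hundreds of trials).

#' Fit a linear SVM
#'
#' Minimizes `0.5 * ||w||^2 + C * sum_i u_i * max(0, 1 - y_i f(x_i))^2`
#' with `f(x) = w'x + b`, where `u_i` balances the classes (inverse class
#' frequency). Features are standardized internally using training
#' statistics.
#'
#' @param x trials x features matrix.
#' @param y labels; any two-level factor/character/numeric vector.
#' @param C cost parameter.
#' @return list of class `linear_svm`: `w`, `b`, `levels`, scaling.
#' @export
svm_fit <- function(x, y, C = 1) {
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("svm_fit needs exactly two classes, got ",
                             length(lev))
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  n <- nrow(xs); p <- ncol(xs)
  wts <- ifelse(yy > 0, n / (2 * sum(yy > 0)), n / (2 * sum(yy < 0)))
  obj <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- pmax(0, 1 - yy * (xs %*% w + b))
    0.5 * sum(w^2) + C * sum(wts * m^2)
  }
  grad <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- pmax(0, 1 - yy * (drop(xs %*% w) + b))
    g <- -2 * C * wts * m * yy
    c(w + drop(crossprod(xs, g)), sum(g))
  }
  fit <- optim(numeric(p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  structure(list(w = fit$par[1:p], b = fit$par[p + 1], levels = lev,
                 center = mu, scale = sdv, C = C),
            class = "linear_svm")
}

#' Predict with a linear SVM
#' @param object a `linear_svm` fit.
#' @param newdata trials x features matrix.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale,
              `/`)
  object$levels[(drop(xs %*% object$w) + object$b > 0) + 1]
}

# leave-one-trial-out CV accuracy of the linear SVM
svm_loo_accuracy <- function(x, y, C = 1) {
  n <- nrow(x)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- svm_fit(x[-i, , drop = FALSE], y[-i], C)
    correct[i] <- predict(fit, x[i, , drop = FALSE]) == as.character(y[i])
  }
  mean(correct)
}

# stratified k-fold partition: list of test-index vectors
stratified_folds <- function(y, k) {
  idx <- split(seq_along(y), y)
  folds <- vector("list", k)
  for (cls in idx) {
    cls <- sample(cls)
    asg <- rep_len(seq_len(k), length(cls))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], cls[asg == f])
  }
  folds
}
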