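#' @export
print.recoil_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kelvin-Voigt recoil fit (order %d, %d points)\n",
              x$model_order, x$n_points))
  print(coef(x), digits = digits)
  cat(sprintf("residual RMS: %.*g um%s\n", digits, x$residual_rms,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.recoil_fit <- function(object, ...) {
  if (object$model_order == 2)
    with(object$params, c(X_f = X_f, X_s = X_s, tau_f = tau_f, tau_s = tau_s))
  else c(X = object$params$X, tau = object$params$tau)
}

#' @export
summary.recoil_fit <- function(object, ...) {
  est <- coef(object)
  # asymptotic standard errors from the LM Jacobian
  se <- rep(NA_real_, length(est))
  hess <- try(object$optim$hessian, silent = TRUE)
  if (!inherits(hess, "try-error") && !is.null(hess)) {
    dof <- max(object$n_points - length(est), 1L)
    s2 <- object$rss / dof
    cv <- try(solve(hess) * 2 * s2, silent = TRUE)  # hessian of SSR ~ 2 J'J
    if (!inherits(cv, "try-error")) {
      d <- diag(cv)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  tab <- cbind(Estimate = est, `Std. Error` = se)
  out <- list(coefficients = tab, residual_rms = object$residual_rms,
              n_points = object$n_points, model_order = object$model_order,
              converged = object$converged, flags = object$flags)
  class(out) <- "summary.recoil_fit"
  out
}

#' @export
print.summary.recoil_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kelvin-Voigt recoil fit, model order %d\n", x$model_order))
  printCoefmat(x$coefficients, digits = digits, na.print = "NA")
  cat(sprintf("residual RMS %.*g um on %d points%s\n", digits, x$residual_rms,
              x$n_points, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted displacement from a fitted recoil model
#'
#' @param object a `recoil_fit`.
#' @param times observation times (s since first post-gap frame); defaults to
#'   the fitted trace's times. The stored ablation-gap `delta_t` is added
#'   before evaluating the model.
#' @param ... unused.
#' @return Predicted displacement (um) at `times`.
#' @export
predict.recoil_fit <- function(object, times = object$trace$times, ...) {
  teff <- times + object$trace$delta_t
  if (object$model_order == 2) displacement(teff, object$params)
  else object$params$X * (1 - exp(-teff / object$params$tau))
}

#' @export
fitted.recoil_fit <- function(object, ...) object$fitted

#' @export
residuals.recoil_fit <- function(object, ...) {
  object$trace$displacements - object$fitted
}

#' @export
logLik.recoil_fit <- function(object, ...) {
  n <- object$n_points
  s2 <- object$rss / n
  val <- -n / 2 * (log(2 * pi * s2) + 1)
  structure(val, df = length(coef(object)) + 1, nobs = n, class = "logLik")
}

#' Plot a fitted recoil trace
#'
#' Data points with the fitted relaxation curve overlaid on a fine time
#' grid.
#'
#' @param x a `recoil_fit`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.recoil_fit <- function(x, ...) {
  tr <- x$trace
  plot(tr$times, tr$displacements, xlab = "time since first frame (s)",
       ylab = "displacement (um)", pch = 16, cex = 0.6,
       main = sprintf("Kelvin-Voigt recoil fit (order %d)", x$model_order), ...)
  tt <- seq(min(tr$times), max(tr$times), length.out = 400)
  lines(tt, predict(x, tt), col = "red", lwd = 2)
  invisible(x)
}

#' Simulate displacement traces from a fitted recoil model
#'
#' Draws `nsim` new traces at the fitted time points: the fitted curve plus
#' i.i.d. Gaussian noise with standard deviation equal to the residual RMS.
#'
#' @param object a `recoil_fit`.
#' @param nsim number of traces.
#' @param seed RNG seed (required for reproducibility).
#' @param ... unused.
#' @return A list of [displacement_trace()] objects of length `nsim`.
#' @export
simulate.recoil_fit <- function(object, nsim = 1, seed = 1, ...) {
  mu <- object$fitted
  tr <- object$trace
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    displacement_trace(tr$times, mu + rnorm(length(mu), 0, object$residual_rms),
                       delta_t = tr$delta_t, orientation = tr$orientation,
                       genotype = tr$genotype, specimen_id = tr$specimen_id)
  }))
}

#' @importFrom stats printCoefmat logLik cor
NULL
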