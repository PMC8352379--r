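#' Fit the first-order step-response model to a heating trace
#'
#' Estimates `(T0, Tinf, tau)` of the first-order heating model
#' `T(t) = (T0 - Tinf) exp(-t/tau) + Tinf` by least squares on the exposure
#' window (`t` in `[0, exposure_s]`; pre-exposure baseline points are
#' excluded). The fit is unweighted by default: the per-frame SD channel of
#' an ROI trace describes spatial spread across pixels, not measurement
#' error of the mean.
#'
#' Estimation uses Levenberg-Marquardt least squares with the analytic
#' Jacobian. Starting values are data-driven: `T0` from the first sample,
#' `Tinf` from the mean of the final 5% of samples, and `tau` from the time
#' at which the trace first crosses `T0 + (1 - e^-1)(Tinf - T0)` (linear
#' interpolation; fallback `exposure / 3`). On non-convergence the fit is
#' deterministically restarted from 0.5x and 2x the initial `tau`.
#'
#' 95% confidence intervals come from the linearized covariance
#' `sigma^2 (J'J)^-1` with `sigma^2 = SSE / (n - 3)` and a Student-t
#' quantile on `n - 3` degrees of freedom. `r_squared = 1 - SSE/SStot`;
#' `rmse = sqrt(SSE / n)` (denominator `n`, a descriptive residual scale).
#'
#' @param trace a [temperature_trace()] (or data frame with `time_s` and
#'   `temp_mean_C` columns).
#' @param exposure_s end of the fitted window, s; default the last observed
#'   time.
#' @param weighted if `TRUE`, weight points by `1 / temp_sd^2` (points with
#'   zero SD are given the median weight).
#' @param span_floor minimum temperature span, degrees C, below which the
#'   trace is declared degenerate (default 1).
#' @return An object of class `first_order_fit` with fields `t0_hat`,
#'   `tinf_hat`, `tau_hat`, `ci95` (3 x 2 matrix), `se`, `r_squared`,
#'   `rmse`, `sse`, `n_points`, `converged`, `reason`, plus the fitted
#'   window (`times`, `observed`) and trace metadata.
#' @examples
#' p <- default_group_params()[1, ]
#' tr <- simulate_trace(p, camera_model(noise_sd = 0), seed = 7)
#' fit <- fit_first_order(tr)
#' fit$tau_hat
#' @export
fit_first_order <- function(trace, exposure_s = NULL, weighted = FALSE,
                            span_floor = 1) {
  if (is.data.frame(trace)) {
    trace <- temperature_trace(trace$time_s, trace$temp_mean_C,
                               if ("temp_sd_C" %in% names(trace))
                                 trace$temp_sd_C else rep(0, nrow(trace)))
  }
  stopifnot(inherits(trace, "temperature_trace"))
  if (is.null(exposure_s)) exposure_s <- max(trace$times)
  keep <- trace$times >= 0 & trace$times <= exposure_s
  t <- trace$times[keep]
  y <- trace$temp_mean[keep]
  n <- length(t)
  if (n < 5) stop("need at least 5 points with t >= 0 to fit")

  failed <- function(reason) {
    structure(
      list(t0_hat = NA_real_, tinf_hat = NA_real_, tau_hat = NA_real_,
           ci95 = matrix(NA_real_, 3, 2,
                         dimnames = list(c("t0", "tinf", "tau"), c("low", "high"))),
           se = rep(NA_real_, 3), r_squared = NA_real_, rmse = NA_real_,
           sse = NA_real_, n_points = n, converged = FALSE, reason = reason,
           times = t, observed = y, animal_id = trace$animal_id,
           wavelength = trace$wavelength, injection = trace$injection),
      class = "first_order_fit")
  }
  span <- diff(range(y))
  if (span < span_floor) return(failed("degenerate span"))

  w <- if (weighted) {
    sd <- trace$temp_sd[keep]
    wts <- 1 / sd^2
    wts[!is.finite(wts)] <- stats::median(wts[is.finite(wts)], na.rm = TRUE)
    if (all(!is.finite(wts))) rep(1, n) else wts
  } else rep(1, n)
  sw <- sqrt(w)

  # data-driven initialization
  t0_0 <- y[1]
  tail_n <- max(1L, ceiling(0.05 * n))
  tinf_0 <- mean(y[(n - tail_n + 1):n])
  target <- t0_0 + (1 - exp(-1)) * (tinf_0 - t0_0)
  tau_0 <- {
    above <- if (tinf_0 >= t0_0) y >= target else y <= target
    i <- which(above)[1]
    if (!is.na(i) && i > 1) {
      t[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
    } else exposure_s / 3
  }
  if (!is.finite(tau_0) || tau_0 <= 0) tau_0 <- exposure_s / 3

  resid_fn <- function(par) {
    sw * (y - ((par[1] - par[2]) * exp(-t / par[3]) + par[2]))
  }
  jac_fn <- function(par) {
    e <- exp(-t / par[3])
    -sw * cbind(e, 1 - e, (par[1] - par[2]) * e * t / par[3]^2)
  }
  lower <- c(-Inf, -Inf, 1e-6)
  upper <- c(Inf, Inf, 10 * exposure_s)

  best <- NULL
  for (mult in c(1, 0.5, 2)) {
    start <- c(t0_0, tinf_0, min(max(tau_0 * mult, lower[3]), upper[3]))
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper,
        fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(res) && res$info %in% 1:4) {
      if (is.null(best) || res$deviance < best$deviance) best <- res
    }
  }
  if (is.null(best)) return(failed("optimizer did not converge"))

  par <- best$par
  sse <- best$deviance
  sstot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- 1 - sse / sstot
  rmse <- sqrt(sum((y - ((par[1] - par[2]) * exp(-t / par[3]) + par[2]))^2) / n)

  J <- jac_fn(par)
  se <- rep(NA_real_, 3)
  ok <- tryCatch({
    covm <- solve(crossprod(J)) * sse / (n - 3)
    se <- sqrt(diag(covm))
    TRUE
  }, error = function(e) FALSE)
  tq <- stats::qt(0.975, df = n - 3)
  ci <- cbind(low = par - tq * se, high = par + tq * se)
  rownames(ci) <- c("t0", "tinf", "tau")

  structure(
    list(t0_hat = par[1], tinf_hat = par[2], tau_hat = par[3],
         ci95 = ci, se = se, r_squared = r2, rmse = rmse, sse = sse,
         n_points = n, converged = TRUE, reason = "ok",
         times = t, observed = y, animal_id = trace$animal_id,
         wavelength = trace$wavelength, injection = trace$injection),
    class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<first_order_fit> NOT converged (%s), n = %d\n",
                x$reason, x$n_points))
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<first_order_fit> T0 = %.2f C, Tinf = %.2f C, ",
           "tau = %.2f s [%.2f, %.2f]\n  R^2 = %.4f, RMSE = %.3f C, n = %d\n"),
    x$t0_hat, x$tinf_hat, x$tau_hat, x$ci95["tau", 1], x$ci95["tau", 2],
    x$r_squared, x$rmse, x$n_points))
  invisible(x)
}

#' Predict temperatures from a fitted first-order model
#'
#' @param object a converged [fit_first_order()] result.
#' @param times times in seconds at which to evaluate the model; default the
#'   fitted time points.
#' @param ... unused.
#' @return Predicted temperatures, degrees C.
#' @export
predict.first_order_fit <- function(object, times = object$times, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  first_order_temperature(times, object$t0_hat, object$tinf_hat, object$tau_hat)
}

#' Normalized heating curve
#'
#' Rescales a temperature trace to the unit interval,
#' `T_tilde(t) = (T(t) - Tmin) / (Tmax - Tmin)`, where `Tmin` and `Tmax` are
#' the observed extrema over the exposure window — the normalized heating
#' curve used to compare heating kinetics across groups irrespective of the
#' absolute temperatures reached. A robust variant takes the 1st/99th
#' percentiles as the extrema (values are then clipped to `[0, 1]`).
#'
#' @param trace a [temperature_trace()].
#' @param exposure_s end of the window, s; default the last observed time.
#' @param robust use 1st/99th percentiles instead of min/max.
#' @return An object of class `normalized_trace` with fields `times`,
#'   `t_tilde`, `tmin`, `tmax`.
#' @export
normalized_temperature <- function(trace, exposure_s = NULL, robust = FALSE) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (is.null(exposure_s)) exposure_s <- max(trace$times)
  keep <- trace$times >= 0 & trace$times <= exposure_s
  t <- trace$times[keep]
  y <- trace$temp_mean[keep]
  if (length(y) < 2) stop("need at least 2 points in the exposure window")
  ex <- if (robust) stats::quantile(y, c(0.01, 0.99), names = FALSE) else range(y)
  if (diff(ex) <= 0) stop("zero temperature span; normalized curve undefined")
  tt <- (y - ex[1]) / (ex[2] - ex[1])
  if (robust) tt <- pmin(pmax(tt, 0), 1)
  structure(list(times = t, t_tilde = tt, tmin = ex[1], tmax = ex[2]),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> %d points, Tmin = %.2f C, Tmax = %.2f C\n",
              length(x$times), x$tmin, x$tmax))
  invisible(x)
}
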