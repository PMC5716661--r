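#' Normalized autocovariance of a fluorescence trace
#'
#' Stationary noise analysis: estimates
#' `C(dt) = <(x_t - xbar)(x_{t+dt} - xbar)>` for lags up to `max_lag` and
#' normalises so that `C(0) = 1`. The biased (1/N) estimator is used, which
#' keeps the implied spectrum positive semi-definite; the convention is
#' recorded in the result.
#'
#' @param trace A [fluor_trace()].
#' @param max_lag Maximum lag in seconds, < trace duration.
#' @return List of class `autocovariance` with `lags` (s, starting at 0),
#'   `c` (normalized autocovariance), `c0` (the raw lag-0 autocovariance,
#'   i.e. the biased variance) and `estimator = "biased"`.
#' @export
autocovariance <- function(trace, max_lag) {
  stopifnot(inherits(trace, "fluor_trace"))
  n <- length(trace$values)
  if (max_lag >= trace_duration(trace))
    stop("'max_lag' must be smaller than the trace duration")
  n_lag <- floor(max_lag / trace$dt + 1e-9)
  v <- stats::var(trace$values)
  if (!is.finite(v) || v == 0) stop("no fluctuations: trace variance is zero")
  a <- stats::acf(trace$values, lag.max = n_lag, type = "covariance",
                  demean = TRUE, plot = FALSE)  # divisor N (biased)
  cc <- as.numeric(a$acf)
  structure(list(lags = (0:n_lag) * trace$dt, c = cc / cc[1L], c0 = cc[1L],
                 estimator = "biased"),
            class = "autocovariance")
}

#' Fit a one- or two-exponential decay to an autocovariance
#'
#' Least-squares fit of `sum_i a_i exp(-lag / tau_i) + c0` with non-negative
#' amplitudes and, by default, a free constant offset. The time constants of
#' such a fit report on the relaxation rates of the underlying two-state
#' kinetics (for a single telegraph with rate sum `r`, `tau = 1/r`).
#' Initialisation is a log-spaced grid search over tau (amplitudes and
#' offset solved linearly at each grid point) followed by Levenberg-Marquardt
#' refinement under positivity bounds.
#'
#' @param lags Numeric vector of lags (s), >= 10 points.
#' @param c Autocovariance values at `lags`.
#' @param n_components 1 or 2.
#' @param offset Include a constant offset term (default `TRUE`).
#' @param tau_grid Log-spaced tau grid (s) for initialisation; default 40
#'   points between 1 ms and 1 s.
#' @return An object of class `autocorr_decay`: list with `lags`, `c`,
#'   `n_components`, `taus` (s, ascending), `amplitudes` (matched to
#'   `taus`), `offset`, `fit_residual` (sum of squared residuals) and
#'   `fitted`.
#' @examples
#' lg <- seq(0, 0.1, by = 0.002)
#' fit <- fit_exp_decay(lg, exp(-lg / 0.010), n_components = 1)
#' fit$taus  # ~0.010
#' @export
fit_exp_decay <- function(lags, c, n_components = 1L, offset = TRUE,
                          tau_grid = NULL) {
  if (!n_components %in% c(1L, 2L)) stop("'n_components' must be 1 or 2")
  if (length(lags) < 10L) stop("need at least 10 lag points")
  if (length(lags) != length(c) || !all(is.finite(c)) || !all(is.finite(lags)))
    stop("'lags' and 'c' must be equal-length finite vectors")
  if (is.null(tau_grid))
    tau_grid <- exp(seq(log(0.001), log(1), length.out = 40L))

  ## linear LS for amplitudes (+offset) at fixed taus
  lin_fit <- function(taus) {
    X <- vapply(taus, function(tau) exp(-lags / tau), numeric(length(lags)))
    if (offset) X <- cbind(X, 1)
    cf <- tryCatch(stats::lm.fit(X, c)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    resid <- c - X %*% cf
    list(coef = cf, rss = sum(resid^2))
  }

  best <- NULL
  if (n_components == 1L) {
    for (tau in tau_grid) {
      f <- lin_fit(tau)
      if (!is.null(f) && (is.null(best) || f$rss < best$rss))
        best <- c(f, list(taus = tau))
    }
  } else {
    ng <- length(tau_grid)
    for (i in seq_len(ng - 1L)) for (j in seq((i + 1L), ng)) {
      f <- lin_fit(tau_grid[c(i, j)])
      if (!is.null(f) && (is.null(best) || f$rss < best$rss))
        best <- c(f, list(taus = tau_grid[c(i, j)]))
    }
  }
  if (is.null(best)) stop("exponential fit failed: grid search degenerate")

  k <- n_components
  a0 <- pmax(best$coef[seq_len(k)], 1e-8)
  c0_0 <- if (offset) best$coef[k + 1L] else 0
  start <- c(a0, best$taus, if (offset) c0_0)
  names(start) <- c(paste0("a", seq_len(k)), paste0("tau", seq_len(k)),
                    if (offset) "c0")
  lower <- c(rep(0, k), rep(min(diff(sort(unique(lags))), na.rm = TRUE) / 20,
                            k), if (offset) -Inf)
  fml <- if (k == 1L) {
    if (offset) c ~ a1 * exp(-lags / tau1) + c0 else c ~ a1 * exp(-lags / tau1)
  } else {
    if (offset) c ~ a1 * exp(-lags / tau1) + a2 * exp(-lags / tau2) + c0
    else c ~ a1 * exp(-lags / tau1) + a2 * exp(-lags / tau2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = list(lags = lags, c = c),
                      start = as.list(start), lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (!inherits(fit, "error")) {
    cf <- stats::coef(fit)
    taus <- unname(cf[paste0("tau", seq_len(k))])
    amps <- unname(cf[paste0("a", seq_len(k))])
    off <- if (offset) unname(cf["c0"]) else 0
    rss <- sum(stats::residuals(fit)^2)
  } else {
    ## variable-projection refinement: optimise log(tau), solve amplitudes
    ## and offset linearly (Levenberg-Marquardt can stall when the grid
    ## solution is already an exact interpolant)
    vp <- function(logtau) {
      f <- lin_fit(exp(logtau))
      if (is.null(f)) Inf else f$rss
    }
    taus <- if (k == 1L) {
      exp(stats::optimize(vp, log(best$taus) + c(-1, 1), tol = 1e-12)$minimum)
    } else {
      op <- stats::optim(log(best$taus), vp, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 2000))
      exp(op$par)
    }
    sol <- lin_fit(taus)
    if (is.null(sol))
      stop(sprintf("exponential fit did not converge (best grid residual %.4g)",
                   best$rss))
    amps <- pmax(sol$coef[seq_len(k)], 0)
    off <- if (offset) sol$coef[k + 1L] else 0
    rss <- sol$rss
  }
  ord <- order(taus)
  taus <- taus[ord]; amps <- amps[ord]
  fitted_vals <- rep(off, length(lags))
  for (i in seq_len(k)) fitted_vals <- fitted_vals + amps[i] *
      exp(-lags / taus[i])
  structure(list(lags = lags, c = c, n_components = k, taus = taus,
                 amplitudes = amps, offset = off,
                 fit_residual = rss,
                 fitted = as.numeric(fitted_vals)),
            class = "autocorr_decay")
}

#' @export
print.autocorr_decay <- function(x, ...) {
  cat(sprintf("<autocorr_decay> %d component(s): tau = %s ms; amplitudes %s; offset %.4g; RSS %.4g\n",
              x$n_components,
              paste(signif(1000 * x$taus, 4), collapse = ", "),
              paste(signif(x$amplitudes, 4), collapse = ", "),
              x$offset, x$fit_residual))
  invisible(x)
}

#' Choose between one- and two-component decay fits
#'
#' Fits both models and accepts the second component only when it is a
#' genuine, resolvable process: the residual sum of squares must drop by at
#' least `min_improvement`, the two time constants must be separated by at
#' least `min_tau_ratio`, and each amplitude must carry at least
#' `min_amp_fraction` of the total. On single-exponential data the
#' two-component fit typically collapses (near-equal taus or a vanishing
#' amplitude) and is rejected.
#'
#' @param lags,c As in [fit_exp_decay()].
#' @param min_improvement Minimum fractional RSS reduction (default 0.5).
#' @param min_tau_ratio Minimum slow/fast tau ratio (default 3).
#' @param min_amp_fraction Minimum share of the summed amplitudes per
#'   component (default 0.05).
#' @param offset Passed to [fit_exp_decay()].
#' @return The selected `autocorr_decay` fit, with attribute `rss_ratio`
#'   (two-component RSS / one-component RSS).
#' @export
select_exp_components <- function(lags, c, min_improvement = 0.5,
                                  min_tau_ratio = 3, min_amp_fraction = 0.05,
                                  offset = TRUE) {
  f1 <- fit_exp_decay(lags, c, 1L, offset = offset)
  f2 <- tryCatch(fit_exp_decay(lags, c, 2L, offset = offset),
                 error = function(e) NULL)
  ratio <- if (is.null(f2)) 1 else f2$fit_residual / f1$fit_residual
  accept2 <- !is.null(f2) &&
    ratio < (1 - min_improvement) &&
    f2$taus[2L] / f2$taus[1L] >= min_tau_ratio &&
    min(f2$amplitudes) >= min_amp_fraction * sum(f2$amplitudes)
  out <- if (accept2) f2 else f1
  attr(out, "rss_ratio") <- ratio
  out
}
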