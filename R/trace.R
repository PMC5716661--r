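#' Uniformly sampled fluorescence trace
#'
#' Container for a single intensity time series recorded at a fixed sampling
#' interval, e.g. a 500 Hz EM-CCD recording of one diffraction-limited spot
#' (`dt = 0.002`).
#'
#' @param values Numeric vector of intensities (arbitrary units), length >= 2.
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Start time in seconds of the first sample.
#' @return An object of class `fluor_trace`: a list with elements `values`,
#'   `dt` and `t0`.
#' @examples
#' tr <- fluor_trace(rnorm(100), dt = 0.002)
#' trace_times(tr)[1:3]
#' @export
fluor_trace <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a trace needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("trace values must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  structure(list(values = values, dt = dt, t0 = t0),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples @ %.6g s (%.4g s total)\n",
              length(x$values), x$dt, length(x$values) * x$dt))
  cat(sprintf("  mean %.4g, sd %.4g\n", mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [fluor_trace()].
#' @return Numeric vector of times (s), one per sample (left edge of each bin).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  trace$t0 + (seq_along(trace$values) - 1L) * trace$dt
}

#' Trace duration in seconds
#' @param trace A [fluor_trace()].
#' @return Total duration (s) covered by the samples.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  length(trace$values) * trace$dt
}

#' Ensemble average of aligned traces
#'
#' Pointwise mean and standard deviation across a set of traces recorded with
#' the same sampling interval, as used to visualise the agonist-induced change
#' in both the mean and the spread of the spot fluorescence.
#'
#' The SD is the population convention (divisor `n`), so that two traces at
#' exactly `+a` and `-a` around zero give SD identically `a`.
#'
#' @param traces List of [fluor_trace()] objects of identical length and `dt`.
#' @return A list with `mean` (a `fluor_trace`), `sd` (numeric vector) and
#'   `n` (number of traces).
#' @export
ensemble_average <- function(traces) {
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "fluor_trace")))
    stop("'traces' must be a non-empty list of fluor_trace objects")
  n_samp <- vapply(traces, function(t) length(t$values), 1L)
  dts <- vapply(traces, function(t) t$dt, 1.0)
  if (length(unique(n_samp)) != 1L)
    stop("traces have mismatched lengths")
  if (diff(range(dts)) > 1e-12)
    stop("traces have mismatched sampling intervals")
  m <- do.call(rbind, lapply(traces, `[[`, "values"))
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  list(mean = fluor_trace(mu, dt = dts[1L], t0 = traces[[1L]]$t0),
       sd = sdv, n = length(traces))
}
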