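#' Zero-phase Gaussian digital filter
#'
#' Smooths a trace with a symmetric Gaussian kernel whose -3 dB cutoff
#' frequency is `cutoff_fraction` times the sampling frequency (default one
#' fourth, the post-acquisition filter applied to 500 Hz recordings before
#' noise analysis). A symmetric FIR kernel introduces no phase shift. Edges
#' are handled by renormalising the truncated kernel, so a constant trace is
#' returned unchanged.
#'
#' The kernel standard deviation in samples follows from the Gaussian
#' transfer function `H(f) = exp(-f^2 / (2 sigma_f^2))` with
#' `|H(fc)|^2 = 1/2`: `sigma = sqrt(ln 2) / (2 pi * cutoff_fraction)`.
#'
#' @param trace A [fluor_trace()].
#' @param cutoff_fraction Cutoff as a fraction of the sampling frequency,
#'   in (0, 0.5].
#' @return A filtered [fluor_trace()] of the same length; the kernel is
#'   attached as attribute `kernel`.
#' @export
gaussian_filter <- function(trace, cutoff_fraction = 0.25) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (cutoff_fraction <= 0 || cutoff_fraction > 0.5)
    stop("'cutoff_fraction' must be in (0, 0.5]")
  sigma <- sqrt(log(2)) / (2 * pi * cutoff_fraction)
  radius <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  x <- trace$values
  n <- length(x)
  ## numerator: convolution with zero padding; denominator: kernel mass that
  ## actually overlapped the signal -> renormalised truncated kernel at edges
  xp <- c(rep(0, radius), x, rep(0, radius))
  wp <- c(rep(0, radius), rep(1, n), rep(0, radius))
  num <- stats::filter(xp, k, method = "convolution", sides = 2)
  den <- stats::filter(wp, k, method = "convolution", sides = 2)
  y <- (num / den)[(radius + 1L):(radius + n)]
  out <- fluor_trace(as.numeric(y), dt = trace$dt, t0 = trace$t0)
  attr(out, "kernel") <- k
  out
}
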