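#' Generative model of a single fluorescent emitter
#'
#' Parameter container for the spot-fluorescence generator: a slow
#' channel-gating telegraph (dark/bright), an independent fast dye-blinking
#' telegraph per fluorophore, one-step irreversible photobleaching per
#' fluorophore, and additive Gaussian camera noise. Agonist concentration
#' enters only through the opening rate via a Hill relation (see
#' [hill_open_rate()]); the closing rate is concentration-independent, which
#' reproduces the observed agonist effect of longer bright bursts through
#' shortened dark periods.
#'
#' @param k_open_max Dark -> bright gating rate (s^-1) at saturating agonist.
#' @param k_close Bright -> dark gating rate (s^-1).
#' @param ec50 Agonist concentration (uM) at half-maximal opening rate, > 0.
#' @param hill_n Hill coefficient (> 0) of the agonist dependence.
#' @param k_blink_off,k_blink_on Dye blinking rates (s^-1), bright -> dark and
#'   dark -> bright. Setting both to zero disables blinking (fluorophore
#'   always emissive).
#' @param k_bleach Irreversible photobleaching rate (s^-1) per fluorophore.
#' @param brightness Mean intensity (arbitrary units) of one emitting
#'   fluorophore above background.
#' @param bg_mean,bg_sd Background mean intensity and noise SD (`bg_sd > 0`).
#' @param n_fluors Integer number of fluorophores per spot, >= 1.
#' @return An object of class `emitter_model`.
#' @export
emitter_model <- function(k_open_max = 4, k_close = 6.41, ec50 = 0.33,
                          hill_n = 2, k_blink_off = 0, k_blink_on = 0,
                          k_bleach = 0, brightness = 10, bg_mean = 0,
                          bg_sd = 1, n_fluors = 1L) {
  rates <- c(k_open_max = k_open_max, k_close = k_close,
             k_blink_off = k_blink_off, k_blink_on = k_blink_on,
             k_bleach = k_bleach)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (ec50 <= 0) stop("'ec50' must be positive")
  if (hill_n <= 0) stop("'hill_n' must be positive")
  if (bg_sd <= 0) stop("'bg_sd' must be positive")
  n_fluors <- as.integer(n_fluors)
  if (is.na(n_fluors) || n_fluors < 1L) stop("'n_fluors' must be >= 1")
  structure(list(k_open_max = k_open_max, k_close = k_close, ec50 = ec50,
                 hill_n = hill_n, k_blink_off = k_blink_off,
                 k_blink_on = k_blink_on, k_bleach = k_bleach,
                 brightness = brightness, bg_mean = bg_mean, bg_sd = bg_sd,
                 n_fluors = n_fluors),
            class = "emitter_model")
}

#' @export
print.emitter_model <- function(x, ...) {
  cat(sprintf(paste0("<emitter_model> gating %0.4g/%0.4g s^-1 (EC50 %.3g uM,",
                     " n_H %.3g), blink %.3g/%.3g, bleach %.3g, %d fluor(s)\n"),
              x$k_open_max, x$k_close, x$ec50, x$hill_n, x$k_blink_off,
              x$k_blink_on, x$k_bleach, x$n_fluors))
  invisible(x)
}

#' Agonist-dependent opening rate (Hill relation)
#'
#' `k_open(c) = k_open_max * c^n / (c^n + ec50^n)`: zero without agonist,
#' half-maximal at `c = ec50`, saturating at `k_open_max`.
#'
#' @param concentration Agonist concentration (uM), >= 0. `Inf` is allowed
#'   and returns `k_open_max`.
#' @param model An [emitter_model()].
#' @return Opening rate in s^-1.
#' @examples
#' m <- emitter_model(k_open_max = 10, ec50 = 0.33, hill_n = 2)
#' hill_open_rate(0.33, m)  # 5
#' @export
hill_open_rate <- function(concentration, model) {
  stopifnot(inherits(model, "emitter_model"))
  if (any(concentration < 0)) stop("'concentration' must be non-negative")
  cn <- concentration^model$hill_n
  out <- ifelse(is.infinite(concentration), model$k_open_max,
                model$k_open_max * cn / (cn + model$ec50^model$hill_n))
  ## c = 0 with hill_n > 0 gives 0/ec50^n = 0 exactly
  out
}

#' Simulate a single-spot fluorescence trace
#'
#' Per fluorophore, the instantaneous emission is
#' `brightness * gate(t) * blink(t) * 1(t < t_bleach)`; the gating telegraph
#' is shared by all fluorophores of the spot (they sit on one channel) while
#' blinking and bleaching are independent per fluorophore. Each sample is the
#' time-average of the continuous path over its `dt` window (camera
#' integration), after which Gaussian background noise
#' `N(bg_mean, bg_sd)` is added per sample.
#'
#' @param model An [emitter_model()].
#' @param concentration Agonist concentration (uM) controlling the opening
#'   rate through [hill_open_rate()]; use `Inf` for saturation.
#' @param duration Trace duration (s), >= 10 * dt.
#' @param dt Sampling interval (s), e.g. 0.002 for 500 Hz.
#' @param seed Optional integer seed.
#' @param noiseless If `TRUE`, omit the Gaussian noise (useful for
#'   ground-truth tests of bleach steps).
#' @return A [fluor_trace()]; attributes `gate_path` (the gating
#'   `telegraph_path`, `NULL` when gating is disabled) and `n_bleached`
#'   (fluorophores bleached within the trace) are attached for ground-truth
#'   checks.
#' @export
simulate_emitter_trace <- function(model, concentration, duration, dt = 0.002,
                                   seed = NULL, noiseless = FALSE) {
  stopifnot(inherits(model, "emitter_model"))
  if (dt <= 0) stop("'dt' must be positive")
  if (duration < 10 * dt) stop("'duration' must be at least 10 * dt")
  if (!is.null(seed)) set.seed(seed)

  k_open <- hill_open_rate(concentration, model)
  n_bins <- floor(duration / dt + 1e-9)
  dur <- n_bins * dt

  ## gating path, shared across fluorophores
  gate_path <- NULL
  if (k_open == 0 && model$k_close == 0) {
    gate_seg <- list(start = 0, end = dur, state = 1)   # gate pinned bright
  } else if (k_open == 0) {
    ## opening impossible: channel dark after at most one closure
    gate_path <- simulate_telegraph(0, model$k_close, dur)
    gate_seg <- telegraph_segments(gate_path)
  } else {
    gate_path <- simulate_telegraph(k_open, model$k_close, dur)
    gate_seg <- telegraph_segments(gate_path)
  }

  total <- numeric(n_bins)
  n_bleached <- 0L
  for (f in seq_len(model$n_fluors)) {
    segs <- list(gate_seg)
    if (model$k_blink_off > 0 || model$k_blink_on > 0) {
      blink <- simulate_telegraph(model$k_blink_on, model$k_blink_off, dur)
      segs <- c(segs, list(telegraph_segments(blink)))
    }
    if (model$k_bleach > 0) {
      t_bleach <- stats::rexp(1L, model$k_bleach)
      if (t_bleach < dur) {
        n_bleached <- n_bleached + 1L
        segs <- c(segs, list(list(start = c(0, t_bleach),
                                  end = c(t_bleach, dur),
                                  state = c(1, 0))))
      }
    }
    prod_seg <- combine_piecewise(segs, dur)
    total <- total + model$brightness * piecewise_bin_average(prod_seg, dt, dur)
  }

  vals <- total + model$bg_mean
  if (!noiseless) vals <- vals + stats::rnorm(n_bins, 0, model$bg_sd)
  out <- fluor_trace(vals, dt = dt)
  attr(out, "gate_path") <- gate_path
  attr(out, "n_bleached") <- n_bleached
  out
}

#' Distribution of labeled subunits per tetramer
#'
#' With wild-type and labeled subunit cDNA mixed so that a fraction
#' `labeled_fraction` of expressed subunits carries the fluorophore (1/8 for
#' the 7:1 co-transfection used to favour single-emitter tetramers), the
#' number of labeled subunits in a random tetramer is binomial(4, p).
#'
#' @param labeled_fraction Probability in \[0, 1\] that a subunit is labeled.
#' @return Named numeric vector `P(0)..P(4)`, summing to 1.
#' @examples
#' subunit_stoichiometry(1 / 8)[["1"]]  # ~0.3348: one emitter per tetramer
#' @export
subunit_stoichiometry <- function(labeled_fraction) {
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop("'labeled_fraction' must be in [0, 1]")
  p <- stats::dbinom(0:4, size = 4L, prob = labeled_fraction)
  names(p) <- as.character(0:4)
  p
}
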