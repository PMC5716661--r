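#' Simulate a two-state telegraph (continuous-time Markov) process
#'
#' Generates one realisation of a two-state continuous-time Markov chain with
#' exponential holding times: state 0 -> 1 at rate `k01`, state 1 -> 0 at rate
#' `k10`. This is the generative model used for both channel gating
#' (closed/open) and dye blinking (dark/bright).
#'
#' The initial state is drawn from the stationary distribution,
#' `P(state 1) = k01 / (k01 + k10)`. If one rate is zero the chain is
#' absorbed in (or never leaves) the corresponding state; if both are zero
#' the chain is degenerate and an error is raised.
#'
#' @param k01 Rate (s^-1) of 0 -> 1 switching, >= 0.
#' @param k10 Rate (s^-1) of 1 -> 0 switching, >= 0.
#' @param duration Total simulated time (s), > 0.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `telegraph_path`: list with `switch_times`
#'   (strictly increasing event times in (0, duration)), `states` (state
#'   after each switch; `initial_state` before the first), `initial_state`,
#'   and `duration`. The path is right-continuous piecewise constant.
#' @examples
#' p <- simulate_telegraph(10, 30, 100, seed = 1)
#' telegraph_occupancy(p)  # ~ 10 / (10 + 30)
#' @export
simulate_telegraph <- function(k01, k10, duration, seed = NULL) {
  if (k01 < 0 || k10 < 0) stop("rates must be non-negative")
  if (duration <= 0) stop("'duration' must be positive")
  if (k01 == 0 && k10 == 0) stop("degenerate chain: both rates are zero")
  if (!is.null(seed)) set.seed(seed)

  p1 <- k01 / (k01 + k10)
  state0 <- as.integer(stats::runif(1L) < p1)

  ## absorbing cases: at most one switch ever happens
  exit_rate <- function(s) if (s == 1L) k10 else k01
  times <- numeric(0)
  states <- integer(0)
  t_cur <- 0
  s_cur <- state0
  ## draw holding times in blocks for speed
  repeat {
    r <- exit_rate(s_cur)
    if (r == 0) break  # absorbed
    ## expected number of remaining events from this state pair
    k_mean <- 2 / (1 / max(k01, 1e-300) + 1 / max(k10, 1e-300))
    block <- max(16L, ceiling(1.2 * (duration - t_cur) * k_mean) + 10L)
    ## alternate exit rates starting from current state
    rates <- rep(c(exit_rate(s_cur), exit_rate(1L - s_cur)),
                 length.out = block)
    if (any(rates == 0)) {
      ## one direction is absorbing: only the first holding time matters
      dt1 <- stats::rexp(1L, rates[1L])
      t_new <- t_cur + dt1
      if (t_new < duration) {
        times <- c(times, t_new)
        s_cur <- 1L - s_cur
        states <- c(states, s_cur)
        t_cur <- t_new
      } else t_cur <- duration
      if (t_cur >= duration) break
      next
    }
    hold <- stats::rexp(block, rates)
    tt <- t_cur + cumsum(hold)
    keep <- tt < duration
    if (!all(keep)) {
      nkeep <- sum(keep)
      if (nkeep > 0L) {
        times <- c(times, tt[keep])
        new_states <- rep(c(1L - s_cur, s_cur), length.out = block)[keep]
        states <- c(states, new_states)
        s_cur <- new_states[nkeep]
      }
      t_cur <- duration
      break
    }
    times <- c(times, tt)
    new_states <- rep(c(1L - s_cur, s_cur), length.out = block)
    states <- c(states, new_states)
    s_cur <- new_states[block]
    t_cur <- tt[block]
  }

  structure(list(switch_times = times, states = states,
                 initial_state = state0, duration = duration),
            class = "telegraph_path")
}

#' @export
print.telegraph_path <- function(x, ...) {
  cat(sprintf("<telegraph_path> %d switches over %.4g s, occupancy(1) = %.3f\n",
              length(x$switch_times), x$duration, telegraph_occupancy(x)))
  invisible(x)
}

## Breakpoints and levels of the piecewise-constant path, including endpoints.
telegraph_segments <- function(path) {
  t <- c(0, path$switch_times, path$duration)
  s <- c(path$initial_state, path$states)
  list(start = t[-length(t)], end = t[-1L], state = s)
}

#' Fraction of time a telegraph path spends in state 1
#' @param path A `telegraph_path`.
#' @return Scalar in \[0, 1\].
#' @export
telegraph_occupancy <- function(path) {
  seg <- telegraph_segments(path)
  sum((seg$end - seg$start) * seg$state) / path$duration
}

#' Complete dwell times of a telegraph path
#'
#' Dwells truncated by the start or end of the simulation are censored and
#' excluded.
#'
#' @param path A `telegraph_path`.
#' @param state Which state's dwells to return (0 or 1).
#' @return Numeric vector of complete dwell durations (s).
#' @export
telegraph_dwells <- function(path, state = 1L) {
  seg <- telegraph_segments(path)
  n <- length(seg$state)
  if (n <= 2L) return(numeric(0))
  keep <- seq_len(n)[-c(1L, n)]
  keep <- keep[seg$state[keep] == state]
  seg$end[keep] - seg$start[keep]
}

#' Evaluate the time-average of a telegraph path over sampling bins
#'
#' Models camera integration: each sample is the average of the continuous
#' 0/1 path over its `dt` window, not a point sample.
#'
#' @param path A `telegraph_path`.
#' @param dt Bin width (s).
#' @return A [fluor_trace()] whose values lie in \[0, 1\].
#' @export
telegraph_trace <- function(path, dt) {
  stopifnot(dt > 0)
  n_bins <- floor(path$duration / dt + 1e-9)
  if (n_bins < 2L) stop("duration too short for the requested dt")
  edges <- (0:n_bins) * dt
  ## cumulative time spent in state 1, piecewise linear in t
  knots <- c(0, path$switch_times, path$duration)
  s <- c(path$initial_state, path$states)
  seg_int <- s * diff(knots)
  cum <- c(0, cumsum(seg_int))
  f <- stats::approx(knots, cum, xout = edges, rule = 2)$y
  ## clamp float round-off: bin averages of a 0/1 path live in [0, 1]
  fluor_trace(pmin(pmax(diff(f) / dt, 0), 1), dt = dt)
}

## Multiply several telegraph-like paths (piecewise-constant, shared time
## origin) into one piecewise-constant path; used for gate x blink products.
## Each element of `paths` is a list(start, end, state) from
## telegraph_segments() or compatible (states need not be 0/1).
combine_piecewise <- function(segs_list, duration) {
  brk <- sort(unique(c(0, duration,
                       unlist(lapply(segs_list, function(s) s$start)))))
  brk <- brk[brk < duration + 1e-12]
  if (abs(brk[length(brk)] - duration) > 1e-12) brk <- c(brk, duration)
  mid <- (brk[-length(brk)] + brk[-1L]) / 2
  val <- rep(1, length(mid))
  for (s in segs_list) {
    idx <- findInterval(mid, s$start)
    idx[idx < 1L] <- 1L
    val <- val * s$state[idx]
  }
  list(start = brk[-length(brk)], end = brk[-1L], state = val)
}

## Bin-average an arbitrary piecewise-constant path over dt windows.
piecewise_bin_average <- function(seg, dt, duration) {
  n_bins <- floor(duration / dt + 1e-9)
  edges <- (0:n_bins) * dt
  knots <- c(seg$start, duration)
  cum <- c(0, cumsum(seg$state * (seg$end - seg$start)))
  f <- stats::approx(knots, cum, xout = edges, rule = 2)$y
  diff(f) / dt
}
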