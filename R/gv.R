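## Physical constants for the Boltzmann activation curve
FARADAY <- 96485      # C mol^-1
GAS_CONSTANT <- 8.314 # J mol^-1 K^-1

## Boltzmann activation: rises with V for z > 0 and passes through
## i_max / 2 at v_half. Voltages in mV.
boltzmann_current <- function(v_mV, v_half, z_valence, i_max,
                              temperature = 293.15) {
  x <- -z_valence * FARADAY * (v_mV - v_half) * 1e-3 /
    (GAS_CONSTANT * temperature)
  i_max / (1 + exp(x))
}

#' Simulate a conductance-voltage (G-V) current table
#'
#' Noiseless means follow a Boltzmann activation curve
#' `I = I_max / (1 + exp(-zF(V - V_0.5)/RT))` — increasing with voltage for
#' positive valence and half-maximal at `V_0.5` — with Gaussian measurement
#' noise added. The default midpoint of +100 mV matches the activation range
#' of the channel studied; recordings at 20 C motivate the default
#' temperature.
#'
#' @param voltages Test potentials (mV).
#' @param v_half Half-activation voltage (mV).
#' @param z_valence Effective gating valence (dimensionless).
#' @param i_max Maximal current (pA or any current unit).
#' @param temperature Absolute temperature (K), > 0; default 293.15.
#' @param noise_sd Gaussian noise SD in current units.
#' @param seed Optional integer seed.
#' @return Data frame with columns `voltage_mV` and `current`.
#' @export
simulate_gv_currents <- function(voltages, v_half = 100, z_valence = 1,
                                 i_max = 100, temperature = 293.15,
                                 noise_sd = 0, seed = NULL) {
  if (temperature <= 0) stop("'temperature' must be positive")
  if (!is.null(seed)) set.seed(seed)
  mu <- boltzmann_current(voltages, v_half, z_valence, i_max, temperature)
  data.frame(voltage_mV = voltages,
             current = mu + stats::rnorm(length(voltages), 0, noise_sd))
}

#' Fit a Boltzmann activation curve to voltage-current data
#'
#' Least-squares fit of `I = I_max / (1 + exp(-zF(V - V_0.5)/RT))`,
#' returning the midpoint voltage, effective valence and maximal current
#' with their standard errors. The fitted midpoint and valence are invariant
#' to rescaling of the current units.
#'
#' @param voltages Test potentials (mV), >= 5 values bracketing the midpoint.
#' @param currents Currents (or conductances) at those potentials.
#' @param temperature Absolute temperature (K), default 293.15 (20 C).
#' @return An object of class `gv_fit`: list with `v_half` (mV),
#'   `z_valence`, `i_max`, `temperature`, `se` (named), `fitted`,
#'   `residuals` and `data`.
#' @export
fit_boltzmann <- function(voltages, currents, temperature = 293.15) {
  if (length(voltages) != length(currents))
    stop("'voltages' and 'currents' must have equal length")
  if (length(unique(voltages)) < 5L)
    stop("need at least 5 distinct voltages bracketing the midpoint")
  if (temperature <= 0) stop("'temperature' must be positive")
  if (stats::sd(currents) < 1e-12 * max(abs(currents), 1))
    stop("flat current-voltage data: activation curve unidentifiable")
  imax0 <- max(currents)
  vh0 <- voltages[which.min(abs(currents - imax0 / 2))]
  dat <- list(v = voltages, i = currents, FF = FARADAY,
              RR = GAS_CONSTANT, TT = temperature)
  fit <- minpack.lm::nlsLM(
    i ~ imax / (1 + exp(-z * FF * (v - vhalf) * 1e-3 / (RR * TT))),
    data = dat, start = list(imax = imax0, vhalf = vh0, z = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(Inf, length(cf)),
                                                     names(cf)))
  structure(list(v_half = unname(cf["vhalf"]), z_valence = unname(cf["z"]),
                 i_max = unname(cf["imax"]), temperature = temperature,
                 se = se, fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(stats::residuals(fit)),
                 data = data.frame(voltage_mV = voltages, current = currents)),
            class = "gv_fit")
}

#' @export
print.gv_fit <- function(x, ...) {
  cat(sprintf("<gv_fit> V_0.5 = %.4g mV (SE %.3g), z = %.3g, I_max = %.4g at %g K\n",
              x$v_half, unname(x$se["vhalf"]), x$z_valence, x$i_max,
              x$temperature))
  invisible(x)
}
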