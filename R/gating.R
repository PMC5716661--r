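## Fraction of positive transitions shown by the free dye on glass; this is
## the blinking background linearly subtracted from raw P_L1 values.
BLINK_FRACTION_DEFAULT <- 0.12

#' Correct a bright-state probability for dye blinking
#'
#' Linearly subtracts the blinking background measured from the free dye
#' (default 0.12) from a raw bright-state probability (or transition
#' fraction), flooring at zero.
#'
#' @param p_l1_raw Raw probability/fraction values in \[0, 1\].
#' @param blink_fraction Blinking background to subtract, in \[0, 1\]
#'   (default 0.12).
#' @return List with `corrected` (floored at 0) and `floored` (logical, per
#'   value, `TRUE` where the floor was applied).
#' @examples
#' correct_blinking(0.50)$corrected  # 0.38
#' @export
correct_blinking <- function(p_l1_raw, blink_fraction = BLINK_FRACTION_DEFAULT) {
  if (any(p_l1_raw < 0 | p_l1_raw > 1)) stop("'p_l1_raw' must be in [0, 1]")
  if (blink_fraction < 0 || blink_fraction > 1)
    stop("'blink_fraction' must be in [0, 1]")
  raw <- p_l1_raw - blink_fraction
  list(corrected = pmax(raw, 0), floored = raw < 0)
}

#' Normalize responses to a reference maximum
#'
#' `F / F_max` scaling of signal amplitudes.
#'
#' @param values Numeric responses.
#' @param reference_max Positive reference (e.g. the maximal signal).
#' @return `values / reference_max`.
#' @export
normalize_response <- function(values, reference_max) {
  if (length(reference_max) != 1L || !is.finite(reference_max) ||
      reference_max <= 0)
    stop("'reference_max' must be a single positive number")
  values / reference_max
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `R = R_max * c^n / (c^n + EC50^n)` to
#' concentration-response data, optionally with the Hill coefficient fixed
#' and per-point weights (e.g. 1/SEM^2).
#'
#' @param concentrations Agonist concentrations (uM), >= 4 distinct values
#'   spanning the inflection.
#' @param responses Responses (same length).
#' @param fix_hill_n Optional fixed Hill coefficient; fitted when `NULL`.
#' @param weights Optional non-negative fitting weights.
#' @return An object of class `dose_response`: list with `ec50`, `hill_n`,
#'   `response_max`, `se` (named vector of fitted-parameter SEs),
#'   `fitted`, `residuals`, `r_squared`, `data` and `fixed_n` flag.
#' @export
fit_hill <- function(concentrations, responses, fix_hill_n = NULL,
                     weights = NULL) {
  if (length(concentrations) != length(responses))
    stop("'concentrations' and 'responses' must have equal length")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (length(unique(concentrations)) < 4L)
    stop("need at least 4 distinct concentrations")
  if (max(responses) - min(responses) <= 0 ||
      stats::sd(responses) < 1e-12 * max(abs(responses), 1))
    stop("responses carry no dose dependence to fit")
  dat <- data.frame(conc = concentrations, resp = responses)
  rmax0 <- max(responses)
  pos <- concentrations > 0
  half <- rmax0 / 2
  ec0 <- concentrations[pos][which.min(abs(responses[pos] - half))]
  if (!length(ec0) || ec0 <= 0) ec0 <- stats::median(concentrations[pos])
  fixed <- !is.null(fix_hill_n)
  if (fixed && fix_hill_n <= 0) stop("'fix_hill_n' must be positive")
  fml <- if (fixed)
    resp ~ rmax * conc^nfix / (conc^nfix + ec50^nfix)
  else
    resp ~ rmax * conc^n / (conc^n + ec50^n)
  start <- if (fixed) list(rmax = rmax0, ec50 = ec0)
           else list(rmax = rmax0, ec50 = ec0, n = 1.5)
  lower <- if (fixed) c(rmax = 0, ec50 = 1e-12)
           else c(rmax = 0, ec50 = 1e-12, n = 0.05)
  env_dat <- c(as.list(dat), if (fixed) list(nfix = fix_hill_n))
  args <- list(fml, data = env_dat, start = start, lower = lower,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- do.call(minpack.lm::nlsLM, args)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(Inf, length(cf)),
                                                     names(cf)))
  resid <- stats::residuals(fit)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(list(ec50 = unname(cf["ec50"]),
                 hill_n = if (fixed) fix_hill_n else unname(cf["n"]),
                 response_max = unname(cf["rmax"]),
                 se = se,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(resid),
                 r_squared = 1 - sum(resid^2) / ss_tot,
                 data = dat, fixed_n = fixed),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> EC50 = %.4g uM (SE %.3g), n_H = %.3g%s, R_max = %.4g, R^2 = %.4f\n",
              x$ec50, unname(x$se["ec50"]), x$hill_n,
              if (x$fixed_n) " [fixed]" else "", x$response_max, x$r_squared))
  invisible(x)
}

#' Predict from a fitted Hill curve
#' @param object A `dose_response` fit.
#' @param newdata Optional data frame with column `conc` (uM).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.dose_response <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  cn <- conc^object$hill_n
  object$response_max * cn / (cn + object$ec50^object$hill_n)
}

#' Compare optical and electrophysiological dose-response fits
#'
#' Reports the EC50 ratio (optical/electrical), absolute difference, a
#' normal-approximation overlap test based on the fitted standard errors,
#' and an overlay table of both normalized curves on a shared logarithmic
#' concentration grid.
#'
#' @param optical,electrical `dose_response` fits.
#' @param n_grid Number of grid points for the overlay table.
#' @return List with `ec50_optical`, `ec50_electrical`, `ratio`,
#'   `difference`, `z`, `p_value`, `ci_overlap` (do the 95% CIs overlap?),
#'   `mismatch` flag (disjoint CIs) and `overlay` (data frame: conc,
#'   optical, electrical — responses normalized to each fitted maximum).
#' @export
compare_optical_electrical <- function(optical, electrical, n_grid = 50L) {
  stopifnot(inherits(optical, "dose_response"),
            inherits(electrical, "dose_response"))
  e_o <- optical$ec50; e_e <- electrical$ec50
  se_o <- unname(optical$se["ec50"]); se_e <- unname(electrical$se["ec50"])
  z <- abs(e_o - e_e) / sqrt(se_o^2 + se_e^2)
  ci_o <- e_o + c(-1.96, 1.96) * se_o
  ci_e <- e_e + c(-1.96, 1.96) * se_e
  overlap <- ci_o[1L] <= ci_e[2L] && ci_e[1L] <= ci_o[2L]
  rng <- range(c(optical$data$conc, electrical$data$conc))
  rng[1L] <- max(rng[1L], 1e-4 * rng[2L])
  grid <- exp(seq(log(rng[1L]), log(rng[2L]), length.out = n_grid))
  overlay <- data.frame(
    conc = grid,
    optical = predict(optical, data.frame(conc = grid)) / optical$response_max,
    electrical = predict(electrical,
                         data.frame(conc = grid)) / electrical$response_max)
  list(ec50_optical = e_o, ec50_electrical = e_e,
       ratio = e_o / e_e, difference = abs(e_o - e_e),
       z = z, p_value = 2 * stats::pnorm(-z),
       ci_overlap = overlap, mismatch = !overlap,
       overlay = overlay)
}
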