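test_that("blinking correction subtracts linearly and floors at zero", {
  expect_equal(correct_blinking(0.50, 0.12)$corrected, 0.38)
  low <- correct_blinking(0.05, 0.12)
  expect_equal(low$corrected, 0)
  expect_true(low$floored)
  expect_equal(correct_blinking(0.3, 0)$corrected, 0.3)
  expect_error(correct_blinking(1.2), "p_l1_raw")
})

test_that("normalization divides by a positive reference", {
  expect_equal(normalize_response(c(1, 2, 4), 4), c(0.25, 0.5, 1))
  v <- c(0.2, 0.9, 0.4)
  expect_equal(max(normalize_response(v, max(v))), 1)
  expect_error(normalize_response(v, 0), "positive")
})

test_that("correct-then-normalize commutes with normalize-then-rescale off the floor", {
  p <- c(0.3, 0.5, 0.8)
  blink <- 0.12
  a <- normalize_response(correct_blinking(p, blink)$corrected,
                          max(p) - blink)
  b <- normalize_response(p - blink, max(p) - blink)  # no floor hit
  expect_equal(a, b)
  ## with a floored point the two routes differ
  p2 <- c(0.05, 0.5, 0.8)
  a2 <- normalize_response(correct_blinking(p2, blink)$corrected,
                           max(p2) - blink)
  b2 <- (p2 - blink) / (max(p2) - blink)
  expect_false(isTRUE(all.equal(a2, b2)))
})

test_that("noiseless Hill data recover EC50 to 1e-6 relative", {
  conc <- c(0.01, 0.03, 0.1, 0.33, 1, 3, 10)
  resp <- 0.8 * conc^2 / (conc^2 + 0.33^2)
  fit <- fit_hill(conc, resp)
  expect_equal(fit$ec50, 0.33, tolerance = 1e-6)
  expect_equal(fit$hill_n, 2, tolerance = 1e-5)
  expect_equal(fit$response_max, 0.8, tolerance = 1e-6)
  fitf <- fit_hill(conc, resp, fix_hill_n = 2)
  expect_equal(fitf$ec50, 0.33, tolerance = 1e-8)
})

test_that("degenerate dose-response inputs are rejected or flagged", {
  expect_error(fit_hill(c(1, 2, 3), c(0.1, 0.2, 0.3)), "4 distinct")
  expect_error(fit_hill(c(0.1, 1, 3, 10), rep(0.8, 4)), "no dose dependence")
  ## saturating range only: fit is unidentifiable -> error or huge EC50 SE
  conc <- c(30, 60, 100, 300)
  resp <- 0.8 * conc^2 / (conc^2 + 0.33^2) + c(1, -1, 1, -1) * 1e-5
  res <- tryCatch(fit_hill(conc, resp), error = function(e) e)
  if (!inherits(res, "error")) {
    expect_gt(unname(res$se["ec50"]) / res$ec50, 1)
  } else succeed()
})

test_that("noisy dose series recover EC50 within 15% in the median", {
  conc <- c(0.03, 0.1, 0.3, 1, 3, 10)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    resp <- 0.7 * conc^2 / (conc^2 + 0.33^2) + rnorm(6, 0, 0.05)
    fit <- tryCatch(fit_hill(conc, pmax(resp, 0), fix_hill_n = 2),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$ec50 - 0.33) / 0.33
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("noiseless Boltzmann activation recovers its parameters", {
  v <- seq(-40, 200, by = 20)
  gv <- simulate_gv_currents(v, v_half = 100, z_valence = 0.8, i_max = 250)
  fit <- fit_boltzmann(gv$voltage_mV, gv$current)
  expect_equal(fit$v_half, 100, tolerance = 1e-6)
  expect_equal(fit$z_valence, 0.8, tolerance = 1e-6)
  expect_equal(fit$i_max, 250, tolerance = 1e-6)
  ## midpoint property of the fitted curve
  mid <- fit$i_max / (1 + exp(0))
  expect_equal(mid, fit$i_max / 2)
})

test_that("Boltzmann fit is invariant to current-unit rescaling", {
  v <- seq(-40, 200, by = 20)
  set.seed(51)
  gv <- simulate_gv_currents(v, 100, 1, 100, noise_sd = 2)
  f1 <- fit_boltzmann(gv$voltage_mV, gv$current)
  f2 <- fit_boltzmann(gv$voltage_mV, gv$current * 1e3)
  expect_equal(f1$v_half, f2$v_half, tolerance = 1e-8)
  expect_equal(f1$z_valence, f2$z_valence, tolerance = 1e-8)
  expect_equal(f2$i_max, f1$i_max * 1e3, tolerance = 1e-8)
})

test_that("flat G-V data are rejected as unidentifiable", {
  v <- seq(-40, 200, by = 40)
  expect_error(fit_boltzmann(v, rep(5, length(v))), "unidentifiable")
  expect_error(fit_boltzmann(c(0, 20, 40), c(1, 2, 3)), "5 distinct")
})

test_that("a large valence approaches a step around the midpoint", {
  v <- seq(60, 140, by = 10)
  gv <- simulate_gv_currents(v, 100, z_valence = 50, i_max = 1)
  expect_true(all(gv$current[gv$voltage_mV < 95] < 0.01))
  expect_true(all(gv$current[gv$voltage_mV > 105] > 0.99))
})

test_that("optical/electrical comparison reports ratio, difference and overlap", {
  conc <- c(0.01, 0.03, 0.1, 0.33, 1, 3, 10)
  fit_o <- fit_hill(conc, conc^2 / (conc^2 + 0.33^2))
  fit_e <- fit_hill(conc, conc^2 / (conc^2 + 0.43^2))
  same <- compare_optical_electrical(fit_o, fit_o)
  expect_equal(same$ratio, 1)
  expect_equal(same$difference, 0)
  cmp <- compare_optical_electrical(fit_o, fit_e)
  expect_equal(cmp$ratio, 0.33 / 0.43, tolerance = 1e-4)
  expect_equal(cmp$difference, 0.10, tolerance = 1e-3)
  expect_true(all(c("conc", "optical", "electrical") %in% names(cmp$overlay)))
  expect_true(all(cmp$overlay$optical >= 0 & cmp$overlay$optical <= 1))
})

test_that("end-to-end optical dose-response pipeline is monotone with high R2", {
  ## simulate traces across doses -> idealize -> P_L1 -> correct -> fit
  m <- emitter_model(k_open_max = 8, k_close = 4, ec50 = 0.33, hill_n = 2,
                     brightness = 10, bg_sd = 1)
  conc <- c(0.05, 0.15, 0.33, 1, 3, 10)
  p_raw <- vapply(seq_along(conc), function(i) {
    tr <- simulate_emitter_trace(m, conc[i], 60, 0.002, seed = 60 + i)
    idealize(tr, 0, 1)$p_l1 + 0.12   # add the blinking background
  }, numeric(1))
  corr <- correct_blinking(pmin(p_raw, 1))$corrected
  normed <- normalize_response(corr, max(corr))
  fit <- fit_hill(conc, normed, fix_hill_n = 2)
  expect_gt(fit$r_squared, 0.95)
  expect_true(all(diff(predict(fit)) >= 0))
  expect_equal(fit$ec50, 0.33, tolerance = 0.5)
})
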