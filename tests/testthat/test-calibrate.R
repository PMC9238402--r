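# Boltzmann fitting, inversion with clamping, pH estimation, CTAB
# recalibration.

test_that("inversion is the exact inverse of the response inside the dynamic range", {
  for (p in list(sensor_params_invitro(), sensor_params_imager())) {
    grid <- seq(p$pH_lo + 1e-6, p$pH_hi - 1e-6, length.out = 41)
    back <- invert_ratio(boltzmann_ratio(grid, p), p)
    expect_lt(max(abs(back$pH - grid)), 1e-9)
    expect_true(all(back$clamped == "none"))
  }
})

test_that("inversion is strictly increasing in ratio over the unclamped domain", {
  p <- sensor_params_imager()
  rs <- seq(boltzmann_ratio(p$pH_lo, p) + 1e-6,
            boltzmann_ratio(p$pH_hi, p) - 1e-6, length.out = 100)
  est <- invert_ratio(rs, p)
  expect_true(all(diff(est$pH) > 0))
})

test_that("ratios beyond the detection limits clamp with the correct flag", {
  p <- sensor_params_invitro()
  lo <- invert_ratio(boltzmann_ratio(p$pH_lo, p) / 2, p)
  expect_equal(lo$pH, p$pH_lo)
  expect_equal(as.character(lo$clamped), "low")
  hi <- invert_ratio(boltzmann_ratio(p$pH_hi, p) * 1.2, p)
  expect_equal(hi$pH, p$pH_hi)
  expect_equal(as.character(hi$clamped), "high")
  mid <- invert_ratio((p$A1 + p$A2) / 2, p)
  expect_equal(mid$pH, p$x0)
  expect_equal(as.character(mid$clamped), "none")
  expect_error(invert_ratio(-0.1, p), "> 0")
})

test_that("propagated pH uncertainty scales with ratio SD and vanishes with it", {
  p <- sensor_params_imager()
  r <- boltzmann_ratio(7.5, p)
  e1 <- invert_ratio(r, p, sd = 0.02)
  e2 <- invert_ratio(r, p, sd = 0.002)
  expect_gt(e1$sd, 0)
  expect_equal(e1$sd / e2$sd, 10, tolerance = 1e-9)
  expect_equal(invert_ratio(r, p, sd = 0)$sd, 0)
  # delta method agrees with a finite-difference slope
  h <- 1e-7
  slope <- (invert_ratio(r + h, p)$pH - invert_ratio(r - h, p)$pH) / (2 * h)
  expect_equal(e1$sd, abs(slope) * 0.02, tolerance = 1e-4)
})

test_that("noise-free calibration series recover the generating parameters", {
  truth <- sensor_params(0.48, 1.31, 7.9, 0.55, 6.5, 8.75)
  ph <- seq(6.4, 9.0, length.out = 8)
  ser <- calibration_series(ph, boltzmann_ratio(ph, truth))
  fit <- fit_boltzmann(ser)
  for (f in c("A1", "A2", "x0", "dx"))
    expect_lt(abs(fit[[f]] / truth[[f]] - 1), 1e-6)
  d <- attr(fit, "diagnostics")
  expect_lt(d$residual_norm, 1e-6)
})

test_that("anchored two-point refit of A2 matches an independent least-squares solve", {
  truth <- sensor_params_imager()
  ph <- c(7.0, 8.4)
  ratios <- boltzmann_ratio(ph, truth) * 1.07  # perturbed session
  ser <- calibration_series(ph, ratios)
  fit <- fit_boltzmann(ser, fixed = c(A1 = truth$A1, x0 = truth$x0,
                                      dx = truth$dx))
  # oracle: brute-force 1-D least squares over A2
  sse <- function(A2) sum((ratios - (A2 + (truth$A1 - A2) /
    (1 + exp((ph - truth$x0) / truth$dx))))^2)
  oracle <- stats::optimize(sse, c(0.5, 3))$minimum
  expect_equal(fit$A2, oracle, tolerance = 1e-4)
})

test_that("under-determined and degenerate fits fail loudly", {
  ser <- calibration_series(c(6.5, 7.5, 8.5), c(0.6, 0.8, 1.1))
  expect_error(fit_boltzmann(ser), "under-determined")
  expect_error(calibration_series(c(4, 7), c(0.5, 1)), "within")
  expect_error(calibration_series(c(6, 7), c(-0.5, 1)), "> 0")
  nonmono <- calibration_series(seq(6.5, 8.6, length.out = 8),
                                c(0.55, 0.6, 0.58, 0.7, 0.8, 0.95, 1.05,
                                  1.1))
  expect_warning(fit_boltzmann(nonmono), "not monotone")
})

test_that("replicate SDs act as inverse-variance weights in the fit", {
  truth <- sensor_params_imager()
  ph <- seq(6.5, 8.75, length.out = 8)
  ratios <- boltzmann_ratio(ph, truth)
  ratios[4] <- ratios[4] + 0.3          # one corrupted point...
  sds <- rep(0.01, 8); sds[4] <- 10     # ...with huge uncertainty
  # the corrupted point breaks monotonicity, which is warned about
  expect_warning(fit <- fit_boltzmann(calibration_series(ph, ratios, sds)),
                 "not monotone")
  expect_lt(abs(fit$x0 - truth$x0), 0.01)
})

test_that("weak-signal colonies come out as n.d. while the rest get estimates", {
  lay <- small_layout()
  p <- sensor_params_imager()
  colonies <- colony_grid(lay, pH_i = 7.53)
  colonies$L[3] <- 40                   # near-silent mutant
  img <- render_plate(lay, colonies, p, instrument_imager(),
                      noise = FALSE)
  meas <- measure_plate(img, detect_grid(img))
  est <- estimate_internal_ph(meas, p)
  expect_true(est$nd[3])
  expect_true(is.na(est$pH[3]))
  expect_false(any(est$nd[-3]))
  expect_equal(mean(est$pH[-3]), 7.53, tolerance = 0.02)
})

test_that("full render-quantify-calibrate path recovers colony internal pH", {
  lay <- small_layout()
  p <- sensor_params_imager(); ins <- instrument_imager()
  phs <- seq(6.5, 8.75, length.out = 10)
  cal_img <- render_plate(lay, colony_grid(lay, pH_i = phs,
                                           permeabilized = TRUE),
                          p, ins, noise = FALSE)
  cal_meas <- measure_plate(cal_img, detect_grid(cal_img))
  fit <- fit_boltzmann(calibration_series(phs, cal_meas$ratio))
  for (truth_ph in c(7.53, 7.39)) {
    img <- render_plate(lay, colony_grid(lay, pH_i = truth_ph), p, ins,
                        noise = FALSE)
    meas <- measure_plate(img, detect_grid(img))
    est <- estimate_internal_ph(meas, fit)
    expect_lt(abs(mean(est$pH, na.rm = TRUE) - truth_ph), 0.1)
  }
})

test_that("CTAB recalibration recovers multiplicative scale drift exactly", {
  p <- sensor_params_invitro()
  t <- seq(0, 60, 5)
  ratio <- c(boltzmann_ratio(rep(7.4, 11), p),
             boltzmann_ratio(rep(7.0, 2), p))
  df <- data.frame(time_min = t, ratio = ratio)
  same <- recalibrate_ctab(df, ctab_time = 55, pH_ex = 7.0, p)
  expect_equal(attr(same, "rescale_factor"), 1, tolerance = 1e-12)
  drift <- df; drift$ratio <- df$ratio * 0.9
  re <- recalibrate_ctab(drift, ctab_time = 55, pH_ex = 7.0, p)
  expect_equal(attr(re, "rescale_factor"), 0.9, tolerance = 1e-12)
  post <- mean(drift$ratio[drift$time_min >= 55])
  expect_equal(invert_ratio(post, re)$pH, 7.0, tolerance = 1e-9)
  expect_error(recalibrate_ctab(df[df$time_min < 55, ], 55, 7.0, p),
               "no post-CTAB")
})
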