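# Boltzmann calibration fitting, ratio-to-pH inversion with detection-limit
# clamping, and per-session CTAB recalibration.

#' Calibration series of (set pH, ratio) standards
#'
#' Measurements of CTAB-permeabilized standards whose internal pH is pinned
#' to the external buffer pH.
#'
#' @param pH_set Buffer pH values (strictly within `[5, 10]`).
#' @param ratio Measured ratios (> 0).
#' @param replicate_sd Optional per-point replicate standard deviations.
#' @param instrument_tag Free-text tag identifying the instrument/session;
#'   calibrations from different sessions must never be mixed (their ratio
#'   scales differ).
#' @return A data frame of class `calibration_series`.
#' @export
calibration_series <- function(pH_set, ratio, replicate_sd = NA_real_,
                               instrument_tag = "") {
  if (any(pH_set <= 5 | pH_set >= 10))
    stop("calibration_series: pH_set must lie strictly within [5, 10]")
  if (any(ratio <= 0)) stop("calibration_series: ratios must be > 0")
  out <- data.frame(pH_set = pH_set, ratio = ratio,
                    replicate_sd = rep_len(replicate_sd, length(pH_set)))
  attr(out, "instrument_tag") <- instrument_tag
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Write / read a calibration series CSV (`pH_set,ratio,sd`)
#'
#' @param series A `calibration_series`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `calibration_series` (read).
#' @export
write_calibration_csv <- function(series, path) {
  out <- data.frame(pH_set = series$pH_set, ratio = series$ratio,
                    sd = series$replicate_sd)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("pH_set", "ratio") %in% names(x)))
    stop("read_calibration_csv: need columns pH_set, ratio")
  calibration_series(x$pH_set, x$ratio,
                     if ("sd" %in% names(x)) x$sd else NA_real_)
}

# closed-form weighted LS for A2 with A1, x0, dx fixed (used for anchored
# refits and as the analytic backbone of the fixed-parameter path)
solve_A2_fixed <- function(series, A1, x0, dx, weights) {
  w <- 1 - 1 / (1 + exp((series$pH_set - x0) / dx))  # coefficient of A2
  sum(weights * w * (series$ratio - A1 * (1 - w))) / sum(weights * w^2)
}

#' Fit the Boltzmann calibration curve
#'
#' Weighted least squares (weights `1/sd^2` when replicate SDs are present)
#' of the four-parameter sigmoid to a calibration series, by
#' Levenberg-Marquardt. Any subset of parameters can be held fixed via
#' `fixed`. Initialization: asymptotes from the series range (+/- 5%),
#' midpoint from the half-range crossing, width = span/8; up to three
#' jittered restarts before declaring non-convergence.
#'
#' @param series A `calibration_series` (or data frame with `pH_set`,
#'   `ratio`, optionally `replicate_sd`).
#' @param fixed Named numeric vector of parameters to hold fixed, e.g.
#'   `c(A1 = 0.5, dx = 0.5)`.
#' @param pH_lo,pH_hi Detection limits attached to the fitted parameters;
#'   default to the span of the calibration series.
#' @return A `sensor_params` object with attribute `diagnostics` (list:
#'   `residual_norm`, `std_errors`, `n_points`, `restarts_used`).
#' @export
fit_boltzmann <- function(series, fixed = NULL,
                          pH_lo = min(series$pH_set),
                          pH_hi = max(series$pH_set)) {
  par_names <- c("A1", "A2", "x0", "dx")
  if (!is.null(fixed) && !all(names(fixed) %in% par_names))
    stop("fit_boltzmann: unknown fixed parameter(s)")
  free <- setdiff(par_names, names(fixed))
  npts <- length(unique(series$pH_set))
  if (npts < length(free) || (length(free) == 4 && npts < 4))
    stop("fit_boltzmann: under-determined (", npts,
         " distinct pH values for ", length(free), " free parameters)")
  if (any(series$ratio <= 0))
    stop("fit_boltzmann: ratios must be > 0")
  if (is.unsorted(series$ratio[order(series$pH_set)]))
    warning("fit_boltzmann: calibration series is not monotone in pH")
  sds <- series$replicate_sd
  wts <- if (!is.null(sds) && all(is.finite(sds)) && all(sds > 0))
    1 / sds^2 else rep(1, nrow(series))

  rng <- range(series$ratio)
  half <- mean(rng)
  ord <- order(series$pH_set)
  x0_init <- stats::approx(series$ratio[ord], series$pH_set[ord],
                           xout = half, ties = mean, rule = 2)$y
  start_all <- c(A1 = rng[1] * 0.95, A2 = rng[2] * 1.05, x0 = x0_init,
                 dx = diff(range(series$pH_set)) / 8)
  start_all[names(fixed)] <- fixed

  # fully anchored refit: A2 has a closed form, no iteration needed
  if (identical(sort(free), "A2")) {
    A2 <- solve_A2_fixed(series, fixed[["A1"]], fixed[["x0"]],
                         fixed[["dx"]], wts)
    out <- sensor_params(fixed[["A1"]], A2, fixed[["x0"]], fixed[["dx"]],
                         pH_lo, pH_hi)
    pred <- boltzmann_ratio(series$pH_set, out)
    attr(out, "diagnostics") <- list(
      residual_norm = sqrt(sum(wts * (series$ratio - pred)^2)),
      std_errors = c(A2 = NA_real_), n_points = nrow(series),
      restarts_used = 0L)
    return(out)
  }

  form_terms <- vapply(par_names, function(p)
    if (p %in% free) p else format(fixed[[p]], digits = 17), character(1))
  form <- stats::as.formula(sprintf(
    "ratio ~ %s + (%s - %s) / (1 + exp((pH_set - %s) / %s))",
    form_terms["A2"], form_terms["A1"], form_terms["A2"],
    form_terms["x0"], form_terms["dx"]))
  dat <- data.frame(pH_set = series$pH_set, ratio = series$ratio)

  fit <- NULL; restarts <- 0L
  for (attempt in 0:3) {
    st <- start_all[free]
    if (attempt > 0)
      st <- st * (1 + stats::runif(length(st), -0.15, 0.15))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(st),
                        weights = wts,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convInfo$isConv) { restarts <- attempt; break }
    fit <- NULL
  }
  if (is.null(fit))
    stop("fit_boltzmann: non-convergence after 3 jittered restarts ",
         "(n = ", nrow(series), " points, start: ",
         paste(sprintf("%s=%.3g", free, start_all[free]), collapse = ", "),
         ")")
  est <- start_all
  est[free] <- stats::coef(fit)[free]
  out <- sensor_params(est[["A1"]], est[["A2"]], est[["x0"]], est[["dx"]],
                       pH_lo, pH_hi)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(free)))
  attr(out, "diagnostics") <- list(
    residual_norm = sqrt(sum(wts * stats::residuals(fit)^2)),
    std_errors = se, n_points = nrow(series), restarts_used = restarts)
  out
}

#' Write fitted parameters with diagnostics to YAML
#'
#' @param params A `sensor_params`, possibly carrying a `diagnostics`
#'   attribute from [fit_boltzmann()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_yaml <- function(params, path) {
  lst <- unclass(params)
  d <- attr(params, "diagnostics")
  if (!is.null(d))
    lst$diagnostics <- list(residual_norm = d$residual_norm,
                            std_errors = as.list(d$std_errors),
                            n_points = d$n_points,
                            restarts_used = d$restarts_used)
  lst$.class <- "sensor_params"
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Invert a ratio to internal pH
#'
#' Analytic inverse of the Boltzmann curve,
#' `pH = x0 + dx * log((A1 - A2)/(ratio - A2) - 1)`, applied inside the
#' sensor's dynamic range. Ratios at or beyond the ratio values of the
#' detection limits are clamped to the corresponding limit and flagged --
#' the sensor genuinely reads its limit value there, so a clamped reading
#' is a value, not a missing one. Uncertainty is propagated from the ratio
#' SD by the first-order delta method (zero at the clamps).
#'
#' @param ratio Numeric vector of measured ratios (> 0).
#' @param params A `sensor_params`.
#' @param sd Ratio standard deviation(s), recycled.
#' @return A data frame of class `ph_estimate`: `pH`, `clamped` (factor
#'   `none`/`low`/`high`), `sd`.
#' @export
invert_ratio <- function(ratio, params, sd = 0) {
  stopifnot(inherits(params, "sensor_params"))
  if (any(!is.na(ratio) & ratio <= 0))
    stop("invert_ratio: ratios must be > 0")
  sd <- rep_len(sd, length(ratio))
  r_lo <- boltzmann_ratio(params$pH_lo, params)
  r_hi <- boltzmann_ratio(params$pH_hi, params)
  pH <- rep(NA_real_, length(ratio))
  clamped <- rep(NA_character_, length(ratio))
  out_sd <- rep(NA_real_, length(ratio))
  for (i in seq_along(ratio)) {
    r <- ratio[i]
    if (is.na(r)) next
    if (r <= r_lo) {
      pH[i] <- params$pH_lo; clamped[i] <- "low"; out_sd[i] <- 0
    } else if (r >= r_hi) {
      pH[i] <- params$pH_hi; clamped[i] <- "high"; out_sd[i] <- 0
    } else {
      q <- (params$A1 - params$A2) / (r - params$A2)
      pH[i] <- params$x0 + params$dx * log(q - 1)
      clamped[i] <- "none"
      # d(pH)/d(r) via q: dq/dr = -(A1-A2)/(r-A2)^2
      dq <- -(params$A1 - params$A2) / (r - params$A2)^2
      out_sd[i] <- abs(params$dx * dq / (q - 1)) * sd[i]
    }
  }
  out <- data.frame(pH = pH,
                    clamped = factor(clamped,
                                     levels = c("none", "low", "high")),
                    sd = out_sd)
  class(out) <- c("ph_estimate", "data.frame")
  out
}

#' Estimate internal pH for measured colonies
#'
#' Applies [invert_ratio()] to each colony measurement. Colonies flagged
#' `low_signal` or `missing` get no estimate ("n.d.": weak sensor
#' expression does not permit a reliable ratio); edge-excluded colonies are
#' skipped unless `include_flagged`.
#'
#' @param meas A `colony_measurements` table.
#' @param params A `sensor_params` (same instrument/session as the
#'   measurements).
#' @param ratio_sd Optional measurement SD on ratios for uncertainty
#'   propagation.
#' @param include_flagged Include edge-excluded colonies?
#' @return `meas` with columns `pH`, `clamped`, `pH_sd` and `nd` (logical)
#'   appended.
#' @export
estimate_internal_ph <- function(meas, params, ratio_sd = 0,
                                 include_flagged = FALSE) {
  est <- invert_ratio(ifelse(meas$low_signal | meas$missing,
                             NA_real_, meas$ratio),
                      params, sd = ratio_sd)
  meas$pH <- est$pH
  meas$clamped <- est$clamped
  meas$pH_sd <- est$sd
  meas$nd <- meas$low_signal | meas$missing
  if (!include_flagged) {
    meas$pH[meas$edge_excluded] <- NA_real_
  }
  meas
}

#' Recalibrate a session from its CTAB end point
#'
#' After CTAB permeabilization the internal pH equals the external buffer
#' pH, so the mean post-CTAB ratio must invert exactly to `pH_ex`. The
#' asymptotes are rescaled multiplicatively to enforce this (midpoint and
#' width are sensor chemistry and stay untouched).
#'
#' @param ratios Data frame with columns `time_min` and `ratio` for one
#'   well.
#' @param ctab_time CTAB addition time; rows at `time_min >= ctab_time`
#'   form the post-CTAB segment.
#' @param pH_ex External pH during the post-CTAB segment. When it lies
#'   beyond a detection limit the anchor uses the extrapolated sigmoid (the
#'   curve extends smoothly; only reported pH values are clamped), so the
#'   subsequent inversion of the post-CTAB ratio lands on the corresponding
#'   limit.
#' @param params A `sensor_params`.
#' @return A rescaled `sensor_params`, with attribute `rescale_factor`.
#' @export
recalibrate_ctab <- function(ratios, ctab_time, pH_ex, params) {
  post <- ratios$ratio[ratios$time_min >= ctab_time]
  post <- post[is.finite(post)]
  if (length(post) == 0)
    stop("recalibrate_ctab: no post-CTAB points at or after ctab_time")
  anchor <- mean(post)
  factor <- anchor / boltzmann_ratio(pH_ex, params)
  if (!is.finite(factor) || factor <= 0)
    stop("recalibrate_ctab: post-CTAB ratio ", signif(anchor, 4),
         " not representable by rescaled sensor parameters")
  out <- scale_sensor_params(params, factor)
  attr(out, "rescale_factor") <- factor
  out
}
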