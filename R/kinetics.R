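# Kinetic plate-reader analysis: per-well ratio trajectories, inversion to
# internal pH, CTAB end-point validation and recalibration.

#' Per-well ratio time series from a kinetic export
#'
#' Pairs the two excitation channels at each (well, time) and divides the
#' shorter-wavelength emission intensity by the longer-wavelength one.
#' Timepoints with a missing channel are dropped with a warning; zero
#' denominators yield `NA` ratios (flagged, not fatal).
#'
#' @param series A `kinetic_series` (see [synthesize_kinetic_export()],
#'   [read_kinetic_csv()]).
#' @param instrument Optional `instrument_profile`; when given, the
#'   excitation/emission wavelengths in the table are validated against it
#'   (catches channel-swapped exports).
#' @return Data frame `well`, `time_min`, `I_A`, `I_B`, `ratio`, carrying
#'   forward the `ctab_time` / `pH_ex` annotations.
#' @export
ratios_from_series <- function(series, instrument = NULL) {
  stopifnot(all(c("well", "time_min", "ex_nm", "em_nm",
                  "intensity_FLU") %in% names(series)))
  exs <- sort(unique(series$ex_nm))
  if (length(exs) != 2)
    stop("ratios_from_series: expected exactly 2 excitation wavelengths, ",
         "found ", length(exs))
  if (!is.null(instrument)) {
    if (!identical(exs, sort(c(instrument$ex_A, instrument$ex_B))) ||
        !all(series$em_nm == instrument$em))
      stop("ratios_from_series: wavelengths in export do not match the ",
           "instrument profile (ex ", instrument$ex_A, "/",
           instrument$ex_B, " nm, em ", instrument$em, " nm)")
  }
  a <- series[series$ex_nm == exs[1], c("well", "time_min", "intensity_FLU")]
  b <- series[series$ex_nm == exs[2], c("well", "time_min", "intensity_FLU")]
  names(a)[3] <- "I_A"; names(b)[3] <- "I_B"
  m <- merge(a, b, by = c("well", "time_min"))
  dropped <- nrow(a) + nrow(b) - 2 * nrow(m)
  if (dropped > 0)
    warning("ratios_from_series: dropped ", dropped,
            " unpaired channel reading(s)")
  m <- m[order(m$well, m$time_min), ]
  m$ratio <- ifelse(m$I_B > 0, m$I_A / m$I_B, NA_real_)
  rownames(m) <- NULL
  attr(m, "ctab_time") <- attr(series, "ctab_time")
  attr(m, "pH_ex") <- attr(series, "pH_ex")
  m
}

#' Analyze one well's ratio trajectory
#'
#' Optionally recalibrates the sensor from the post-CTAB segment
#' ([recalibrate_ctab()]), inverts the ratio series to internal pH, takes
#' the plateau as the mean of the last three pre-CTAB points, and
#' validates sensor function at the CTAB step: the mean post-CTAB pH must
#' match the external pH (clamped into the sensor's observable range) to
#' within `ctab_tol`.
#'
#' @param ratios Data frame with `time_min` and `ratio` for one well.
#' @param params A `sensor_params` (plate-reader session).
#' @param ctab_time CTAB addition time in minutes, or `NULL` if none.
#' @param pH_ex External pH of the well (needed for recalibration and
#'   validation).
#' @param recalibrate Recalibrate from the CTAB end point first?
#' @param ctab_tol Validation tolerance in pH units.
#' @return An object of class `trajectory_result`: list with `series`
#'   (time, ratio, pH, clamped), `plateau_pH`, `ctab_valid` (`NA` when no
#'   CTAB annotation), `params` (possibly recalibrated).
#' @export
analyze_trajectory <- function(ratios, params, ctab_time = NULL,
                               pH_ex = NULL, recalibrate = TRUE,
                               ctab_tol = 0.2) {
  ratios <- ratios[order(ratios$time_min), ]
  pre <- if (is.null(ctab_time)) ratios else
    ratios[ratios$time_min < ctab_time, ]
  if (nrow(pre) < 3)
    stop("analyze_trajectory: need at least 3 pre-CTAB points")
  if (!is.null(ctab_time)) {
    post <- ratios[ratios$time_min >= ctab_time, ]
    if (nrow(post) == 0)
      stop("analyze_trajectory: ctab_time set but no post-CTAB points")
    if (recalibrate) {
      if (is.null(pH_ex))
        stop("analyze_trajectory: recalibration needs pH_ex")
      params <- recalibrate_ctab(ratios, ctab_time, pH_ex, params)
    }
  }
  est <- invert_ratio(ratios$ratio, params)
  series <- data.frame(time_min = ratios$time_min, ratio = ratios$ratio,
                       pH = est$pH, clamped = est$clamped)
  pre_pH <- series$pH[if (is.null(ctab_time)) TRUE else
                        series$time_min < ctab_time]
  plateau <- mean(utils::tail(pre_pH[is.finite(pre_pH)], 3))
  ctab_valid <- NA
  if (!is.null(ctab_time) && !is.null(pH_ex)) {
    post_pH <- series$pH[series$time_min >= ctab_time]
    expect <- min(max(pH_ex, params$pH_lo), params$pH_hi)
    ctab_valid <- abs(mean(post_pH, na.rm = TRUE) - expect) <= ctab_tol
  }
  structure(list(series = series, plateau_pH = plateau,
                 ctab_valid = ctab_valid, params = params),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %d points, plateau pH %.3f, ctab_valid: %s\n",
              nrow(x$series), x$plateau_pH, format(x$ctab_valid)))
  invisible(x)
}

#' Analyze all wells of a kinetic series
#'
#' @param series A `kinetic_series`.
#' @param params A `sensor_params`.
#' @param instrument Optional `instrument_profile` for wavelength
#'   validation.
#' @param recalibrate Per-well CTAB recalibration (the default; each well's
#'   own end point anchors its session scale).
#' @return List with `wells` (named list of `trajectory_result`) and
#'   `summary` (data frame `well`, `plateau_pH`, `ctab_valid`).
#' @export
analyze_kinetics <- function(series, params, instrument = NULL,
                             recalibrate = TRUE) {
  rt <- ratios_from_series(series, instrument)
  ctab_time <- attr(rt, "ctab_time")
  pH_ex <- attr(rt, "pH_ex")
  wells <- unique(rt$well)
  res <- lapply(wells, function(wl) {
    analyze_trajectory(rt[rt$well == wl, ], params,
                       ctab_time = ctab_time,
                       pH_ex = if (!is.null(pH_ex)) pH_ex[[wl]] else NULL,
                       recalibrate = recalibrate)
  })
  names(res) <- wells
  list(wells = res,
       summary = data.frame(
         well = wells,
         plateau_pH = vapply(res, function(r) r$plateau_pH, numeric(1)),
         ctab_valid = vapply(res, function(r) r$ctab_valid, logical(1))))
}

#' Write per-well trajectory CSV (`time_min,ratio,pH,clamped`)
#'
#' @param result A `trajectory_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  utils::write.csv(result$series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
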