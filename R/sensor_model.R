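# Forward model of the ratiometric pH sensor and of cell physiology
# (homeostasis, CTAB permeabilization). Everything downstream -- plate
# rendering, quantification, calibration, screening -- is tested against the
# ground truth this module produces.

#' Sensor response parameters
#'
#' Bundles the four Boltzmann sigmoid parameters of a ratiometric pH sensor
#' together with its pH detection limits. The ratio-versus-pH calibration
#' curve is \deqn{R(pH) = A_2 + (A_1 - A_2) / (1 + e^{(pH - x_0)/dx})}
#' with low-pH asymptote `A1`, high-pH asymptote `A2`, midpoint `x0`
#' (the apparent pKa) and width `dx`. Outside `[pH_lo, pH_hi]` the ratio
#' saturates and readings are clamped rather than extrapolated.
#'
#' @param A1 Low-pH ratio asymptote (dimensionless, > 0).
#' @param A2 High-pH ratio asymptote (> `A1`).
#' @param x0 Sigmoid midpoint in pH units (apparent pKa).
#' @param dx Sigmoid width in pH units (> 0).
#' @param pH_lo,pH_hi Lower/upper pH detection limits; must bracket `x0`.
#' @return An object of class `sensor_params`.
#' @seealso [sensor_params_invitro()], [sensor_params_imager()],
#'   [boltzmann_ratio()], [invert_ratio()]
#' @export
sensor_params <- function(A1, A2, x0, dx, pH_lo, pH_hi) {
  stopifnot(is.numeric(A1), is.numeric(A2), is.numeric(x0), is.numeric(dx),
            is.numeric(pH_lo), is.numeric(pH_hi))
  if (!(A2 > A1 && A1 > 0))
    stop("sensor_params: require A2 > A1 > 0")
  if (dx <= 0)
    stop("sensor_params: require dx > 0")
  if (!(pH_lo < x0 && x0 < pH_hi))
    stop("sensor_params: require pH_lo < x0 < pH_hi")
  structure(list(A1 = A1, A2 = A2, x0 = x0, dx = dx,
                 pH_lo = pH_lo, pH_hi = pH_hi),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat("<sensor_params>\n")
  cat(sprintf("  A1 = %.4f  A2 = %.4f  x0 = %.3f  dx = %.3f\n",
              x$A1, x$A2, x$x0, x$dx))
  cat(sprintf("  detection limits: pH %.2f - %.2f  (ratio %.3f - %.3f)\n",
              x$pH_lo, x$pH_hi,
              boltzmann_ratio(x$pH_lo, x), boltzmann_ratio(x$pH_hi, x)))
  invisible(x)
}

#' Default in-vitro (cell extract, plate reader) sensor parameters
#'
#' Midpoint fixed at the sensor's apparent pKa of 7.3; asymptotes and width
#' chosen so the ratio rises approximately 8-fold between pH 6.5 and 9.0,
#' matching the in-vitro characterization of the sensor in cell extracts.
#' Detection limits 6.5 and 8.75.
#'
#' @return A `sensor_params` object.
#' @export
sensor_params_invitro <- function() {
  sensor_params(A1 = 0.1, A2 = 3.0, x0 = 7.3, dx = 0.35,
                pH_lo = 6.5, pH_hi = 8.75)
}

#' Default imager (arrayed colonies) sensor parameters
#'
#' The colony-imaging instrument reports ratios on a compressed scale
#' relative to the plate reader (0.5-1.2 rather than ~8-fold). These
#' defaults are the Boltzmann curve through the three in-situ calibration
#' anchors -- ratio 0.55 at pH 6.5, 0.73 at pH 7.53 and 1.15 at pH 8.75 --
#' with the width held at 0.5 pH units and the midpoint solved freely
#' (the two instruments' ratio scales are never assumed to share a
#' midpoint).
#'
#' @return A `sensor_params` object.
#' @export
sensor_params_imager <- function() {
  # anchor solve with dx = 0.5: residuals < 1e-7 at the three anchors
  sensor_params(A1 = 0.51363462, A2 = 1.29478504, x0 = 8.00973854,
                dx = 0.5, pH_lo = 6.5, pH_hi = 8.75)
}

#' Rescale the ratio axis of a sensor calibration
#'
#' Multiplies both asymptotes by `factor`, leaving midpoint and width
#' untouched. This is the transformation used for per-session recalibration
#' (instrument gain drift rescales measured ratios multiplicatively while
#' the chemistry of the sensor, hence `x0` and `dx`, is unchanged).
#'
#' @param params A `sensor_params` object.
#' @param factor Positive multiplicative factor.
#' @return A rescaled `sensor_params` object.
#' @export
scale_sensor_params <- function(params, factor) {
  stopifnot(inherits(params, "sensor_params"), is.numeric(factor),
            factor > 0)
  sensor_params(params$A1 * factor, params$A2 * factor,
                params$x0, params$dx, params$pH_lo, params$pH_hi)
}

#' Instrument acquisition profile
#'
#' Describes one dual-excitation fluorescence instrument: the two excitation
#' wavelengths (channel A is always the shorter one and forms the ratio
#' numerator), the emission filter, exposure times, gain, additive
#' background and the two noise terms of the acquisition model. Noise per
#' measured value is Gaussian with standard deviation
#' `sqrt(noise_read_sd^2 + noise_shot_scale^2 * signal)`, i.e. a constant
#' read-noise floor plus a shot-noise-like term growing with the signal.
#'
#' @param ex_A,ex_B Excitation wavelengths in nm, `ex_A < ex_B`.
#' @param em Emission wavelength in nm.
#' @param exposure_A,exposure_B Exposure times in ms (> 0). Reported FLU are
#'   treated as already instrument-scaled, so exposures are carried as
#'   metadata and not multiplied into intensities.
#' @param gain FLU per unit signal (> 0).
#' @param background Additive background level in FLU (>= 0).
#' @param noise_read_sd Read-noise standard deviation in FLU (>= 0).
#' @param noise_shot_scale Dimensionless shot-noise scale (>= 0).
#' @return An object of class `instrument_profile`.
#' @export
instrument_profile <- function(ex_A, ex_B, em, exposure_A = 100,
                               exposure_B = 100, gain = 1,
                               background = 0, noise_read_sd = 0,
                               noise_shot_scale = 0) {
  if (!(ex_A < ex_B))
    stop("instrument_profile: require ex_A < ex_B")
  if (exposure_A <= 0 || exposure_B <= 0 || gain <= 0)
    stop("instrument_profile: exposures and gain must be > 0")
  if (background < 0 || noise_read_sd < 0 || noise_shot_scale < 0)
    stop("instrument_profile: background and noise terms must be >= 0")
  structure(list(ex_A = ex_A, ex_B = ex_B, em = em,
                 exposure_A = exposure_A, exposure_B = exposure_B,
                 gain = gain, background = background,
                 noise_read_sd = noise_read_sd,
                 noise_shot_scale = noise_shot_scale),
            class = "instrument_profile")
}

#' Default colony-imaging instrument (gel documentation system)
#'
#' Excitation capsules at 440 and 530 nm, emission filter at 595 nm,
#' exposures 40 and 1560 ms. The background default of 2500 FLU represents
#' the residual plate/colony autofluorescence on dye-darkened agar; the
#' noise defaults give per-pixel SDs of a few hundred FLU on bright
#' colonies, comparable to the replicate scatter seen in colony imaging.
#'
#' @return An `instrument_profile`.
#' @export
instrument_imager <- function() {
  instrument_profile(ex_A = 440, ex_B = 530, em = 595,
                     exposure_A = 40, exposure_B = 1560, gain = 1,
                     background = 2500, noise_read_sd = 30,
                     noise_shot_scale = 1)
}

#' Default kinetic plate-reader instrument
#'
#' Excitation 454 and 580 nm, emission 630 nm, black 96-well plates (low
#' background).
#'
#' @return An `instrument_profile`.
#' @export
instrument_plate_reader <- function() {
  instrument_profile(ex_A = 454, ex_B = 580, em = 630,
                     exposure_A = 100, exposure_B = 100, gain = 1,
                     background = 200, noise_read_sd = 30,
                     noise_shot_scale = 1)
}

#' Strain pH-homeostasis profile
#'
#' Phenomenological description of one strain: after resuspension at an
#' external pH, the internal pH relaxes toward the homeostatic set point
#' `pH_set` with first-order rate `k_relax`. The initial internal pH is
#' given by `pH_init_rule(pH_ex)`; the default (identity) reflects the
#' observation that internal pH initially follows the externally set pH.
#'
#' @param label Strain label.
#' @param pH_set Homeostatic set point, in `[6, 9]`.
#' @param k_relax First-order relaxation rate (1/min, >= 0).
#' @param pH_init_rule Function mapping external pH to initial internal pH.
#' @param expression_mean Mean sensor expression level (relative units,
#'   >= 0); at the default instrument gain this is the above-background
#'   channel-B signal of a colony at the low-pH end.
#' @param expression_cv Coefficient of variation of expression across
#'   colonies/wells.
#' @return An object of class `strain_profile`.
#' @export
strain_profile <- function(label, pH_set, k_relax,
                           pH_init_rule = identity,
                           expression_mean = 38000,
                           expression_cv = 0.15) {
  if (k_relax < 0) stop("strain_profile: k_relax must be >= 0")
  if (expression_mean < 0) stop("strain_profile: expression_mean must be >= 0")
  if (pH_set < 6 || pH_set > 9)
    stop("strain_profile: pH_set must lie in [6, 9]")
  stopifnot(is.function(pH_init_rule))
  structure(list(label = label, pH_set = pH_set, k_relax = k_relax,
                 pH_init_rule = pH_init_rule,
                 expression_mean = expression_mean,
                 expression_cv = expression_cv),
            class = "strain_profile")
}

#' Built-in strain profiles
#'
#' Presets encoding the homeostasis phenotypes of the characterized strains:
#' wild-type sensor strain (`WT_S`) and the potassium-uptake triple mutant
#' (`TK2309_S`), each under potassium-replete (`K120`, 120 mM) and
#' potassium-starved (`K0.1`, 0.1 mM) conditions, plus the RpoS-stabilized
#' regulator mutant `TP1` which pins its internal pH near 7.15 regardless
#' of the external pH.
#'
#' Set points: WT_S reaches ~7.7 (K120) or ~7.0 (K0.1) within 15 min;
#' TK2309_S reaches ~7.3 within 20 min at K120 but stays acidic (~6.3,
#' below the sensor floor of 6.5) at K0.1; TP1 holds 7.1-7.2 at any
#' external pH.
#'
#' @param name One of `"WT_S_K120"`, `"WT_S_K0.1"`, `"TK2309_S_K120"`,
#'   `"TK2309_S_K0.1"`, `"TP1"`.
#' @return A `strain_profile`.
#' @export
strain_preset <- function(name = c("WT_S_K120", "WT_S_K0.1",
                                   "TK2309_S_K120", "TK2309_S_K0.1",
                                   "TP1")) {
  name <- match.arg(name)
  switch(name,
    "WT_S_K120"      = strain_profile("WT_S_K120", pH_set = 7.7,
                                      k_relax = 0.2),
    "WT_S_K0.1"      = strain_profile("WT_S_K0.1", pH_set = 7.0,
                                      k_relax = 0.2),
    "TK2309_S_K120"  = strain_profile("TK2309_S_K120", pH_set = 7.3,
                                      k_relax = 0.15),
    "TK2309_S_K0.1"  = strain_profile("TK2309_S_K0.1", pH_set = 6.3,
                                      k_relax = 0.15,
                                      pH_init_rule = function(pH_ex) 6.3),
    "TP1"            = strain_profile("TP1", pH_set = 7.15, k_relax = 0.3,
                                      pH_init_rule = function(pH_ex) 7.15)
  )
}

#' Physiological state of one sensor-bearing cell population
#'
#' @param pH_i Internal pH.
#' @param pH_ex External pH.
#' @param permeabilized Logical; if `TRUE`, `pH_i` must equal `pH_ex`
#'   (surfactant-permeabilized membranes equilibrate the two).
#' @param L Sensor expression level (relative units, >= 0).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(pH_i, pH_ex = pH_i, permeabilized = FALSE, L = 1) {
  if (L < 0) stop("cell_state: expression level L must be >= 0")
  if (permeabilized && !isTRUE(all.equal(pH_i, pH_ex)))
    stop("cell_state: permeabilized cells must have pH_i == pH_ex")
  structure(list(pH_i = pH_i, pH_ex = pH_ex,
                 permeabilized = permeabilized, L = L),
            class = "cell_state")
}

#' Boltzmann ratio response of the sensor
#'
#' Evaluates the sigmoid calibration curve `R(pH)`; strictly increasing in
#' pH and bounded in `(A1, A2)`.
#'
#' @param pH Numeric vector of pH values (finite).
#' @param params A `sensor_params` object.
#' @return Numeric vector of ratios.
#' @export
boltzmann_ratio <- function(pH, params) {
  stopifnot(inherits(params, "sensor_params"))
  if (!is.numeric(pH) || any(!is.finite(pH)))
    stop("boltzmann_ratio: pH must be finite numeric")
  params$A2 + (params$A1 - params$A2) /
    (1 + exp((pH - params$x0) / params$dx))
}

# Decreasing channel-B response: fraction of the protonated chromophore
# population driving the long-wavelength excitation channel. Shares the
# sensor's midpoint and width; g2 -> g1 as pH rises. g1 is kept large
# enough that the product g(pH) * R(pH) (channel A) remains increasing.
channel_b_profile <- function(pH, params, g1 = 0.7, g2 = 1.0) {
  g1 + (g2 - g1) / (1 + exp((pH - params$x0) / params$dx))
}

#' Noise-free channel intensities of a cell population
#'
#' Forward acquisition model. The long-wavelength channel is
#' `I_B = background + gain * L * g(pH)` with `g` a decreasing sigmoid, and
#' the short-wavelength channel is `I_A = background + R(pH) * (I_B -
#' background)`, so the background-subtracted channel ratio equals the
#' Boltzmann ratio exactly by construction. Raw (unsubtracted) intensities
#' are returned, mirroring how instruments report FLU; with the default low
#' backgrounds the raw ratio is close to, but not identical with, `R(pH)`.
#'
#' @param state A `cell_state`.
#' @param params A `sensor_params`.
#' @param instrument An `instrument_profile`.
#' @return Named numeric vector `c(I_A=, I_B=)` in FLU.
#' @export
channel_intensities <- function(state, params, instrument) {
  stopifnot(inherits(state, "cell_state"),
            inherits(params, "sensor_params"),
            inherits(instrument, "instrument_profile"))
  if (state$L < 0) stop("channel_intensities: negative expression level")
  sig_B <- instrument$gain * state$L *
    channel_b_profile(state$pH_i, params)
  I_B <- instrument$background + sig_B
  I_A <- instrument$background + boltzmann_ratio(state$pH_i, params) * sig_B
  c(I_A = I_A, I_B = I_B)
}

#' Permeabilize a cell population with CTAB
#'
#' The surfactant collapses the transmembrane proton gradient so the
#' internal pH equilibrates with the external buffer. Idempotent.
#'
#' @param state A `cell_state`.
#' @return The permeabilized `cell_state` (with `pH_i == pH_ex`).
#' @export
apply_ctab <- function(state) {
  stopifnot(inherits(state, "cell_state"))
  cell_state(pH_i = state$pH_ex, pH_ex = state$pH_ex,
             permeabilized = TRUE, L = state$L)
}

#' Simulate first-order pH homeostasis
#'
#' Closed-form relaxation of the internal pH toward the strain's set point:
#' `pH_i(t) = pH_set - (pH_set - pH_init) * exp(-k_relax * t)`, with
#' `pH_init = pH_init_rule(pH_ex)`. The trajectory is the physiological
#' truth; clamping to the sensor-observable range happens downstream in the
#' inversion, not here.
#'
#' @param profile A `strain_profile`.
#' @param pH_ex External pH.
#' @param duration Total time in minutes (> 0).
#' @param dt Time step in minutes (> 0, <= duration).
#' @return A data frame with columns `time_min` and `pH_i`.
#' @export
simulate_homeostasis <- function(profile, pH_ex, duration, dt) {
  stopifnot(inherits(profile, "strain_profile"))
  if (duration <= 0 || dt <= 0)
    stop("simulate_homeostasis: duration and dt must be > 0")
  if (dt > duration)
    stop("simulate_homeostasis: dt must not exceed duration")
  t <- seq(0, duration, by = dt)
  pH_init <- profile$pH_init_rule(pH_ex)
  pH_i <- profile$pH_set - (profile$pH_set - pH_init) *
    exp(-profile$k_relax * t)
  data.frame(time_min = t, pH_i = pH_i)
}

# ---- serialization -------------------------------------------------------

#' Write sensor/instrument/strain configuration to YAML
#'
#' @param x A `sensor_params`, `instrument_profile` or `strain_profile`.
#'   For strain profiles the initial-pH rule is stored by name
#'   (`"identity"` or `"constant"` with its value); arbitrary functions are
#'   not serializable.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(x, path) {
  lst <- unclass(x)
  lst$.class <- class(x)[1]
  if (inherits(x, "strain_profile")) {
    init0 <- x$pH_init_rule(0)
    if (isTRUE(all.equal(init0, 0))) {
      lst$pH_init_rule <- list(rule = "identity")
    } else {
      lst$pH_init_rule <- list(rule = "constant", value = init0)
    }
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a configuration object written by [write_params_yaml()]
#'
#' @param path File path.
#' @return The reconstructed object.
#' @export
read_params_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  switch(cls,
    sensor_params = do.call(sensor_params, lst),
    instrument_profile = do.call(instrument_profile, lst),
    strain_profile = {
      rule <- lst$pH_init_rule
      lst$pH_init_rule <- if (identical(rule$rule, "constant")) {
        v <- rule$value
        function(pH_ex) v
      } else identity
      do.call(strain_profile, lst)
    },
    stop("read_params_yaml: unknown class ", cls)
  )
}
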