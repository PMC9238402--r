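# Synthetic two-channel plate images of arrayed colonies, plus the image
# and tabular formats consumed by the rest of the pipeline.

#' Arrayed-plate layout
#'
#' Geometry of a robot-spotted colony grid on a rectangular plate, plus the
#' camera scale. Rows run down the image (y), columns across (x); indices
#' are 1-based internally and reported with A1-style labels.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param pitch_mm Center-to-center spacing in mm.
#' @param colony_radius_mm Nominal colony radius in mm.
#' @param origin_mm Numeric length 2, (x, y) of the first (top-left) colony
#'   center in mm from the image origin.
#' @param px_per_mm Camera scale (> 0).
#' @param edge_margin Number of outermost rows/columns excluded from
#'   analysis (reflections and border effects at the plate edge).
#' @param width_px,height_px Raster dimensions in pixels.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(n_rows, n_cols, pitch_mm = 4.5,
                         colony_radius_mm = 1.5, origin_mm = c(20, 20),
                         px_per_mm = 7.5, edge_margin = 1,
                         width_px = 968, height_px = 648) {
  if (n_rows < 1 || n_cols < 1)
    stop("plate_layout: n_rows and n_cols must be >= 1")
  if (px_per_mm <= 0) stop("plate_layout: px_per_mm must be > 0")
  if (pitch_mm <= 2 * colony_radius_mm)
    warning("plate_layout: pitch does not exceed the colony diameter; ",
            "neighboring colonies may overlap")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm,
                 colony_radius_mm = colony_radius_mm,
                 origin_mm = origin_mm, px_per_mm = px_per_mm,
                 edge_margin = edge_margin,
                 width_px = width_px, height_px = height_px),
            class = "plate_layout")
}

#' Default screening-plate layout
#'
#' An 18 x 10 spotted grid at 384-format spacing (4.5 mm pitch); with the
#' default edge margin of 1 this leaves a 16 x 8 analyzed array of 128
#' colonies, the configuration of one screening agar plate. The raster is
#' kept at quarter linear scale of the physical camera (968 x 648 px,
#' 7.5 px/mm) so simulated plates stay light; full camera scale is a
#' layout parameter away.
#'
#' @return A `plate_layout`.
#' @export
layout_screen <- function() plate_layout(n_rows = 10, n_cols = 18)

#' A1-style well/colony labels
#'
#' @param row,col 1-based indices.
#' @return Character vector like `"B07"`.
#' @export
grid_label <- function(row, col) {
  rl <- c(LETTERS, paste0("A", LETTERS))[row]
  sprintf("%s%02d", rl, col)
}

# pixel coordinates of nominal colony centers; returns data.frame
grid_centers <- function(layout) {
  g <- expand.grid(row = seq_len(layout$n_rows),
                   col = seq_len(layout$n_cols))
  g <- g[order(g$row, g$col), , drop = FALSE]
  g$x_px <- (layout$origin_mm[1] + (g$col - 1) * layout$pitch_mm) *
    layout$px_per_mm
  g$y_px <- (layout$origin_mm[2] + (g$row - 1) * layout$pitch_mm) *
    layout$px_per_mm
  rownames(g) <- NULL
  g
}

# rows/cols excluded by the edge margin
is_edge <- function(row, col, layout) {
  m <- layout$edge_margin
  row <= m | row > layout$n_rows - m | col <= m | col > layout$n_cols - m
}

#' Build a colony table for a plate
#'
#' One row per grid position carrying the ground-truth cell state. This is
#' the `colonies` input of [render_plate()] and the truth table against
#' which recovery is tested.
#'
#' @param layout A `plate_layout`.
#' @param pH_i Internal pH, recycled over positions.
#' @param pH_ex External pH (defaults to `pH_i`).
#' @param permeabilized Logical, recycled.
#' @param L Expression level, recycled.
#' @param present Logical, recycled; absent positions render as background.
#' @param size_jitter Multiplicative radius jitter (> 0), recycled.
#' @return A data frame of class `colony_states` with columns `row`, `col`,
#'   `label`, `pH_i`, `pH_ex`, `permeabilized`, `L`, `present`,
#'   `size_jitter`.
#' @export
colony_grid <- function(layout, pH_i, pH_ex = pH_i, permeabilized = FALSE,
                        L = 38000, present = TRUE, size_jitter = 1) {
  g <- grid_centers(layout)
  n <- nrow(g)
  out <- data.frame(row = g$row, col = g$col,
                    label = grid_label(g$row, g$col),
                    pH_i = rep_len(pH_i, n), pH_ex = rep_len(pH_ex, n),
                    permeabilized = rep_len(permeabilized, n),
                    L = rep_len(L, n), present = rep_len(present, n),
                    size_jitter = rep_len(size_jitter, n))
  if (any(out$size_jitter <= 0))
    stop("colony_grid: size_jitter must be > 0")
  class(out) <- c("colony_states", "data.frame")
  out
}

# smoothed-disk stamp with peak ~1: flat disk convolved with a Gaussian
disk_stamp <- function(radius_px, sigma_px) {
  half <- ceiling(radius_px + 3 * sigma_px + 1)
  n <- 2 * half + 1
  d <- (seq_len(n) - half - 1)
  dist2 <- outer(d^2, d^2, `+`)
  disk <- (dist2 <= radius_px^2) * 1
  if (sigma_px > 0) {
    bw <- 2 * ceiling(3 * sigma_px) + 1
    disk <- EBImage::filter2(disk,
      EBImage::makeBrush(bw, shape = "gaussian", sigma = sigma_px))
  }
  disk
}

#' Render a synthetic two-channel plate image
#'
#' Each present colony is drawn as a blurred disk whose per-channel peak
#' amplitude equals the noise-free [channel_intensities()] of its cell
#' state; everywhere else the raster sits at the instrument background
#' (low, emulating dye-darkened agar). Optional seeded noise (read +
#' shot-like, per the instrument profile) is added per pixel, then rasters
#' are quantized to 16-bit integers.
#'
#' @param layout A `plate_layout`.
#' @param colonies A `colony_states` table consistent with the layout.
#' @param params A `sensor_params`.
#' @param instrument An `instrument_profile`.
#' @param seed Integer seed; required when `noise = TRUE`.
#' @param noise Logical; add acquisition noise?
#' @return An object of class `plate_image`: list with integer matrices
#'   `channel_A`, `channel_B` (`[y, x]`, 16-bit range), `instrument`,
#'   `layout`.
#' @export
render_plate <- function(layout, colonies, params, instrument,
                         seed = NULL, noise = TRUE) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(params, "sensor_params"),
            inherits(instrument, "instrument_profile"))
  if (anyDuplicated(colonies[, c("row", "col")]))
    stop("render_plate: duplicate (row, col) positions")
  if (any(colonies$row < 1 | colonies$row > layout$n_rows |
          colonies$col < 1 | colonies$col > layout$n_cols))
    stop("render_plate: colony indices outside layout")
  h <- layout$height_px; w <- layout$width_px
  A <- matrix(instrument$background, h, w)
  B <- matrix(instrument$background, h, w)
  g <- grid_centers(layout)
  key <- paste(g$row, g$col)
  ck <- paste(colonies$row, colonies$col)
  cx <- g$x_px[match(ck, key)]
  cy <- g$y_px[match(ck, key)]
  for (i in seq_len(nrow(colonies))) {
    if (!colonies$present[i]) next
    st <- cell_state(pH_i = colonies$pH_i[i], pH_ex = colonies$pH_ex[i],
                     permeabilized = colonies$permeabilized[i],
                     L = colonies$L[i])
    I <- channel_intensities(st, params, instrument)
    r_px <- layout$colony_radius_mm * colonies$size_jitter[i] *
      layout$px_per_mm
    stamp <- disk_stamp(r_px, 0.15 * r_px)
    half <- (nrow(stamp) - 1) / 2
    x0 <- round(cx[i]); y0 <- round(cy[i])
    ys <- max(1, y0 - half):min(h, y0 + half)
    xs <- max(1, x0 - half):min(w, x0 + half)
    sy <- ys - (y0 - half) + 1
    sx <- xs - (x0 - half) + 1
    A[ys, xs] <- A[ys, xs] +
      (I[["I_A"]] - instrument$background) * stamp[sy, sx]
    B[ys, xs] <- B[ys, xs] +
      (I[["I_B"]] - instrument$background) * stamp[sy, sx]
  }
  if (noise) {
    if (is.null(seed))
      stop("render_plate: seed required when noise = TRUE")
    withr::with_seed(seed, {
      A <- A + stats::rnorm(length(A),
        sd = sqrt(instrument$noise_read_sd^2 +
                  instrument$noise_shot_scale^2 * pmax(A, 0)))
      B <- B + stats::rnorm(length(B),
        sd = sqrt(instrument$noise_read_sd^2 +
                  instrument$noise_shot_scale^2 * pmax(B, 0)))
    })
  }
  A <- matrix(as.integer(pmin(pmax(round(A), 0), 65535)), h, w)
  B <- matrix(as.integer(pmin(pmax(round(B), 0), 65535)), h, w)
  structure(list(channel_A = A, channel_B = B,
                 instrument = instrument, layout = layout),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, grid %d x %d, ex %g/%g nm em %g nm\n",
              ncol(x$channel_A), nrow(x$channel_A),
              x$layout$n_rows, x$layout$n_cols,
              x$instrument$ex_A, x$instrument$ex_B, x$instrument$em))
  invisible(x)
}

#' Write a plate image to disk
#'
#' Two 16-bit grayscale TIFFs (one per excitation channel) plus a YAML
#' sidecar holding the instrument profile, layout and channel roles, so the
#' image is self-describing on re-read.
#'
#' @param img A `plate_image`.
#' @param path Base path without extension; writes `<path>_exA.tif`,
#'   `<path>_exB.tif`, `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(img, path) {
  stopifnot(inherits(img, "plate_image"))
  fa <- paste0(path, "_exA.tif"); fb <- paste0(path, "_exB.tif")
  tiff::writeTIFF(img$channel_A / 65535, fa, bits.per.sample = 16)
  tiff::writeTIFF(img$channel_B / 65535, fb, bits.per.sample = 16)
  side <- list(
    format = "phscreen_plate_image/1",
    channel_A = basename(fa), channel_B = basename(fb),
    instrument = unclass(img$instrument),
    layout = unclass(img$layout))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

read_channel_tiff <- function(path) {
  meta <- tiff::readTIFF(path, payload = FALSE)
  if (!identical(as.integer(meta$bits.per.sample), 16L))
    stop("read_plate_image: ", basename(path), " is ",
         meta$bits.per.sample, "-bit; 16-bit grayscale TIFF required")
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2)
    stop("read_plate_image: ", basename(path),
         " is not single-channel grayscale")
  m
}

#' Read a plate image written by [write_plate_image()]
#'
#' Refuses to guess: a missing sidecar, non-16-bit channel files or a
#' shape/metadata mismatch are errors.
#'
#' @param path Base path as passed to [write_plate_image()].
#' @return A `plate_image`.
#' @export
read_plate_image <- function(path) {
  sidefile <- paste0(path, ".yaml")
  if (!file.exists(sidefile))
    stop("read_plate_image: metadata sidecar not found: ", sidefile)
  side <- yaml::read_yaml(sidefile)
  if (!identical(side$format, "phscreen_plate_image/1"))
    stop("read_plate_image: unrecognized sidecar format")
  dirn <- dirname(path)
  A <- read_channel_tiff(file.path(dirn, side$channel_A))
  B <- read_channel_tiff(file.path(dirn, side$channel_B))
  if (!identical(dim(A), dim(B)))
    stop("read_plate_image: channel shapes differ")
  layout <- do.call(plate_layout, side$layout)
  if (!all(dim(A) == c(layout$height_px, layout$width_px)))
    stop("read_plate_image: raster shape does not match layout metadata")
  instrument <- do.call(instrument_profile, side$instrument)
  structure(list(channel_A = A, channel_B = B,
                 instrument = instrument, layout = layout),
            class = "plate_image")
}

#' Internal pH giving a target raw channel ratio
#'
#' Inverts the full forward acquisition model (sensor sigmoid, decreasing
#' channel-B response and additive instrument background) to find the
#' internal pH at which a colony of expression level `L` reads the raw
#' ratio `r`. Used to plant ground-truth ratios on synthetic plates: the
#' printed screening statistics are raw measured ratios, so targets are
#' planted on the raw scale.
#'
#' @param r Target raw ratio(s).
#' @param params A `sensor_params`.
#' @param instrument An `instrument_profile`.
#' @param L Expression level.
#' @return pH value(s); errors if a target is not representable within the
#'   sensor's detection limits.
#' @export
ph_for_raw_ratio <- function(r, params, instrument, L = 38000) {
  raw <- function(pH) {
    st <- cell_state(pH_i = pH, L = L)
    I <- channel_intensities(st, params, instrument)
    I[["I_A"]] / I[["I_B"]]
  }
  lo <- params$pH_lo; hi <- params$pH_hi
  vapply(r, function(ri) {
    if (ri <= raw(lo) || ri >= raw(hi))
      stop(sprintf(
        "ph_for_raw_ratio: ratio %.3f outside the representable range (%.3f, %.3f)",
        ri, raw(lo), raw(hi)))
    stats::uniroot(function(p) raw(p) - ri, c(lo, hi),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Screening-session sensor parameters
#'
#' Screening plates are imaged in their own session, whose ratio scale is
#' calibrated independently of the in-situ anchor session. This helper
#' rescales the default imager curve so that a colony at the reference
#' internal pH (default 7.3, the sensor midpoint and a typical library
#' colony pH) reads the raw ratio observed as the screening-plate average
#' (default 0.50) at the reference expression level. With this pinning the
#' session's representable raw-ratio band (about 0.42-0.82) comfortably
#' brackets both the low- and high-ratio hits seen in screens.
#'
#' @param mean_ratio Raw ratio to pin at `at_pH`.
#' @param at_pH Reference internal pH.
#' @param instrument An `instrument_profile`.
#' @param L Reference expression level.
#' @return A `sensor_params`.
#' @export
sensor_params_screen <- function(mean_ratio = 0.50, at_pH = 7.3,
                                 instrument = instrument_imager(),
                                 L = 38000) {
  base <- sensor_params_imager()
  X <- instrument$gain * L * channel_b_profile(at_pH, base)
  target_R <- (mean_ratio * (instrument$background + X) -
               instrument$background) / X
  scale_sensor_params(base, target_R / boltzmann_ratio(at_pH, base))
}

#' Simulate a screening plate with known ground truth
#'
#' Draws per-colony raw ratios from a normal distribution (truncated to the
#' representable range), optionally replaces chosen positions with spiked
#' ratios (screen hits) or near-silent expression (weak-sensor mutants),
#' converts ratios to internal pH under the session calibration, applies
#' expression-level variation, and renders the plate.
#'
#' @param layout A `plate_layout`.
#' @param mean_ratio,sd_ratio Ratio distribution across colonies.
#' @param spikes Optional data frame with columns `row`, `col`, `ratio`
#'   (and optionally `label`): positions whose ground-truth ratio is fixed.
#' @param silent Optional data frame with columns `row`, `col`: positions
#'   rendered with near-silent sensor expression (weak-expression mutants
#'   that must come out as "n.d.").
#' @param params Session `sensor_params`.
#' @param instrument An `instrument_profile`.
#' @param seed Integer seed.
#' @param noise Logical; passed to [render_plate()].
#' @param expression_mean,expression_cv Log-normal expression variation.
#' @return List with `img` (a `plate_image`) and `truth` (the colony table
#'   with planted `ratio_true` and `pH_i`).
#' @export
simulate_screening_plate <- function(layout = layout_screen(),
                                     mean_ratio = 0.50, sd_ratio = 0.04,
                                     spikes = NULL, silent = NULL,
                                     params = sensor_params_screen(),
                                     instrument = instrument_imager(),
                                     seed = 1, noise = TRUE,
                                     expression_mean = 38000,
                                     expression_cv = 0.15) {
  n <- layout$n_rows * layout$n_cols
  ref_L <- expression_mean
  raw_lo <- {
    I <- channel_intensities(cell_state(params$pH_lo, L = ref_L),
                             params, instrument); I[["I_A"]] / I[["I_B"]]
  }
  raw_hi <- {
    I <- channel_intensities(cell_state(params$pH_hi, L = ref_L),
                             params, instrument); I[["I_A"]] / I[["I_B"]]
  }
  eps <- 1e-4
  draw <- withr::with_seed(seed, {
    r <- stats::rnorm(n, mean_ratio, sd_ratio)
    list(r = pmin(pmax(r, raw_lo + eps), raw_hi - eps),
         L = expression_mean *
           exp(stats::rnorm(n, 0, sqrt(log(1 + expression_cv^2)))))
  })
  colonies <- colony_grid(layout, pH_i = 7)
  colonies$ratio_true <- draw$r
  key <- paste(colonies$row, colonies$col)
  if (!is.null(spikes)) {
    idx <- match(paste(spikes$row, spikes$col), key)
    if (anyNA(idx)) stop("simulate_screening_plate: spike outside layout")
    colonies$ratio_true[idx] <- spikes$ratio
  }
  # pH consistent with the planted raw ratio at the reference expression
  colonies$pH_i <- ph_for_raw_ratio(colonies$ratio_true, params,
                                    instrument, L = ref_L)
  colonies$pH_ex <- colonies$pH_i
  colonies$L <- draw$L
  if (!is.null(silent)) {
    idx <- match(paste(silent$row, silent$col), key)
    if (anyNA(idx)) stop("simulate_screening_plate: silent outside layout")
    colonies$L[idx] <- expression_mean * 0.001
  }
  # planting is exact at the reference expression; with expression variation
  # the raw ratio shifts slightly through the background term, so re-render
  # hits the target best when L is held at the reference for spiked wells
  if (!is.null(spikes)) {
    idx <- match(paste(spikes$row, spikes$col), key)
    colonies$L[idx] <- ref_L
  }
  img <- render_plate(layout, colonies, params, instrument,
                      seed = seed + 1L, noise = noise)
  list(img = img, truth = colonies)
}

#' Synthesize a kinetic plate-reader export
#'
#' Tidy table of dual-excitation intensities over time for a set of wells,
#' each following its strain profile's homeostasis relaxation, with CTAB
#' added at `ctab_time` (from then on the internal pH equals the external).
#' Matches the export schema read back by [read_kinetic_csv()] /
#' [ratios_from_series()].
#'
#' @param strains Data frame with columns `well`, `preset` (a
#'   [strain_preset()] name) and `pH_ex`; alternatively a list of lists
#'   with elements `well`, `profile` (a `strain_profile`) and `pH_ex`.
#' @param params A `sensor_params` (plate-reader scale).
#' @param instrument An `instrument_profile`.
#' @param duration,interval Acquisition window and spacing in minutes.
#' @param ctab_time Time of CTAB addition (<= duration); measurements at
#'   `time >= ctab_time` are post-permeabilization.
#' @param seed Integer seed.
#' @param noise Logical; add acquisition noise to intensities?
#' @return A data frame of class `kinetic_series` with columns `well`,
#'   `time_min`, `ex_nm`, `em_nm`, `intensity_FLU` and attributes
#'   `ctab_time` and `pH_ex` (named per well).
#' @export
synthesize_kinetic_export <- function(strains,
                                      params = sensor_params_invitro(),
                                      instrument = instrument_plate_reader(),
                                      duration = 60, interval = 5,
                                      ctab_time = 55, seed = 1,
                                      noise = TRUE) {
  if (interval <= 0)
    stop("synthesize_kinetic_export: interval must be > 0")
  if (ctab_time > duration)
    stop("synthesize_kinetic_export: ctab_time must not exceed duration")
  if (is.data.frame(strains)) {
    strains <- lapply(seq_len(nrow(strains)), function(i)
      list(well = strains$well[i],
           profile = strain_preset(strains$preset[i]),
           pH_ex = strains$pH_ex[i]))
  }
  rows <- list()
  pH_ex_map <- numeric(0)
  for (s in strains) {
    prof <- s$profile; well <- s$well; pH_ex <- s$pH_ex
    pH_ex_map[well] <- pH_ex
    traj <- simulate_homeostasis(prof, pH_ex, duration, interval)
    post <- traj$time_min >= ctab_time
    traj$pH_i[post] <- pH_ex
    for (i in seq_len(nrow(traj))) {
      st <- cell_state(pH_i = traj$pH_i[i], pH_ex = pH_ex,
                       permeabilized = post[i], L = prof$expression_mean)
      I <- channel_intensities(st, params, instrument)
      rows[[length(rows) + 1]] <- data.frame(
        well = well, time_min = traj$time_min[i],
        ex_nm = c(instrument$ex_A, instrument$ex_B),
        em_nm = instrument$em,
        intensity_FLU = c(I[["I_A"]], I[["I_B"]]))
    }
  }
  out <- do.call(rbind, rows)
  if (noise) {
    out$intensity_FLU <- withr::with_seed(seed,
      out$intensity_FLU + stats::rnorm(nrow(out),
        sd = sqrt(instrument$noise_read_sd^2 +
                  instrument$noise_shot_scale^2 *
                    pmax(out$intensity_FLU, 0))))
  }
  out$intensity_FLU <- pmax(out$intensity_FLU, 0)
  attr(out, "ctab_time") <- ctab_time
  attr(out, "pH_ex") <- pH_ex_map
  class(out) <- c("kinetic_series", "data.frame")
  out
}

#' Write / read a kinetic export CSV
#'
#' Header is exactly `well,time_min,ex_nm,em_nm,intensity_FLU`; the CTAB
#' time and per-well external pH annotations travel in a YAML sidecar
#' `<path>.yaml`.
#'
#' @param series A `kinetic_series`.
#' @param path CSV file path.
#' @return `path` invisibly (write); a `kinetic_series` (read).
#' @export
write_kinetic_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("well", "time_min", "ex_nm",
                                             "em_nm", "intensity_FLU")],
                   path, row.names = FALSE, quote = FALSE)
  ann <- list(ctab_time = attr(series, "ctab_time"),
              pH_ex = as.list(attr(series, "pH_ex")))
  yaml::write_yaml(ann, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @export
read_kinetic_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_min", "ex_nm", "em_nm", "intensity_FLU")
  if (!identical(names(out), need))
    stop("read_kinetic_csv: expected header ", paste(need, collapse = ","))
  annfile <- paste0(path, ".yaml")
  if (file.exists(annfile)) {
    ann <- yaml::read_yaml(annfile)
    attr(out, "ctab_time") <- ann$ctab_time
    attr(out, "pH_ex") <- unlist(ann$pH_ex)
  }
  class(out) <- c("kinetic_series", "data.frame")
  out
}
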