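# Locating arrayed colonies in two-channel plate images and extracting
# per-colony intensities, ratios and QC flags.

# 3x3 (size = smooth_px) median smoothing on a 16-bit integer raster.
# EBImage's constant-time median filter operates on [0,1] grayscale.
med_smooth <- function(m, smooth_px = 1) {
  if (smooth_px < 1) return(m)
  mx <- max(m, 65535)  # keep out-of-range rasters from clipping
  EBImage::medianFilter(m / mx, smooth_px) * mx
}

#' Fit the expected colony grid to a plate image
#'
#' Maximizes the mean summed-channel intensity sampled at the layout's
#' nominal centers over integer global translations within half a pitch,
#' then refines each center by intensity centroid in its local window
#' (ties and empty windows resolve toward the nominal grid point). Errors
#' when the image carries no detectable array (best alignment contrast not
#' above the image noise floor).
#'
#' @param img A `plate_image`.
#' @param refine Logical; per-position centroid refinement.
#' @return An object of class `grid_fit`: list with `centers` (data frame
#'   `row`, `col`, `x_px`, `y_px`), `global_offset` (length-2 integer) and
#'   `score`.
#' @export
detect_grid <- function(img, refine = TRUE) {
  stopifnot(inherits(img, "plate_image"))
  layout <- img$layout
  S <- img$channel_A + img$channel_B
  Ssm <- med_smooth(matrix(pmin(S, 65535), nrow(S), ncol(S)))
  g <- grid_centers(layout)
  h <- nrow(S); w <- ncol(S)
  half <- floor(layout$pitch_mm * layout$px_per_mm / 2)
  # correlate with the colony footprint: convolving with a disk kernel
  # makes the alignment score strictly peaked at the true offset (point
  # sampling would be flat across the colony plateau)
  r_px <- max(1, round(layout$colony_radius_mm * layout$px_per_mm))
  ksize <- 2 * r_px + 1
  kern <- EBImage::makeBrush(ksize, shape = "disc")
  kern <- kern / sum(kern)
  Sc <- EBImage::filter2(Ssm, kern)
  offs <- expand.grid(dx = -half:half, dy = -half:half)
  # visit near-zero offsets first so exact ties resolve to the nominal grid
  offs <- offs[order(offs$dx^2 + offs$dy^2), ]
  best <- -Inf; best_off <- c(0L, 0L)
  x0 <- round(g$x_px); y0 <- round(g$y_px)
  for (i in seq_len(nrow(offs))) {
    xs <- x0 + offs$dx[i]; ys <- y0 + offs$dy[i]
    ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
    if (!any(ok)) next
    sc <- mean(Sc[cbind(ys[ok], xs[ok])])
    if (sc > best + 1e-9) { best <- sc; best_off <- c(offs$dx[i], offs$dy[i]) }
  }
  floor_level <- stats::median(Ssm)
  noise_level <- stats::mad(Ssm)
  if (!is.finite(best) ||
      best - floor_level <= max(3 * noise_level, 1e-9 * max(floor_level, 1)))
    stop("detect_grid: no colony array detected ",
         "(alignment contrast not above image noise)")
  cx <- g$x_px + best_off[1]; cy <- g$y_px + best_off[2]
  if (refine) {
    win <- max(half - 1, 1)
    for (i in seq_along(cx)) {
      xs <- max(1, round(cx[i]) - win):min(w, round(cx[i]) + win)
      ys <- max(1, round(cy[i]) - win):min(h, round(cy[i]) + win)
      patch <- Ssm[ys, xs, drop = FALSE] - floor_level
      patch[patch < 0] <- 0
      tot <- sum(patch)
      if (tot > 0) {
        cx[i] <- sum(rep(xs, each = length(ys)) * patch) / tot
        cy[i] <- sum(rep(ys, times = length(xs)) * patch) / tot
      }
    }
  }
  centers <- data.frame(row = g$row, col = g$col, x_px = cx, y_px = cy)
  structure(list(centers = centers,
                 global_offset = as.integer(best_off), score = best),
            class = "grid_fit")
}

#' Peak intensity of one colony
#'
#' The reported colony intensity is the maximum of the median-smoothed
#' pixels within the colony disk -- the operational reading of "highest
#' measured fluorescence" that is robust to single hot pixels. Background
#' is not subtracted.
#'
#' @param raster Intensity matrix `[y, x]`.
#' @param x_px,y_px Colony center in pixels.
#' @param radius_px Disk radius in pixels.
#' @param smooth_px Median-filter radius (default 1, i.e. a 3x3 kernel);
#'   0 disables smoothing.
#' @return Peak intensity in FLU.
#' @export
colony_intensity <- function(raster, x_px, y_px, radius_px,
                             smooth_px = 1) {
  h <- nrow(raster); w <- ncol(raster)
  if (x_px - radius_px < 1 || x_px + radius_px > w ||
      y_px - radius_px < 1 || y_px + radius_px > h)
    stop("colony_intensity: colony disk extends outside the raster")
  pad <- ceiling(radius_px) + smooth_px
  xs <- max(1, round(x_px) - pad):min(w, round(x_px) + pad)
  ys <- max(1, round(y_px) - pad):min(h, round(y_px) + pad)
  patch <- med_smooth(raster[ys, xs, drop = FALSE], smooth_px)
  dist2 <- outer((ys - y_px)^2, (xs - x_px)^2, `+`)
  max(patch[dist2 <= radius_px^2])
}

#' Measure every colony on a plate
#'
#' For each fitted grid position, extracts the two channel peak intensities
#' and their ratio (shorter-wavelength excitation in the numerator), and
#' attaches QC flags: `edge_excluded` from the layout's edge margin,
#' `missing` when both channels sit at the background level, and
#' `low_signal` from [qc_low_signal()] (applied with defaults when
#' `qc = TRUE`). A non-positive denominator leaves the ratio `NA` and the
#' colony flagged rather than erroring.
#'
#' @param img A `plate_image`.
#' @param grid A `grid_fit` for the same layout (default: detect).
#' @param smooth_px Median-filter radius for [colony_intensity()].
#' @param qc Apply the default low-signal QC?
#' @param k_missing Factor over instrument background below which both
#'   channels count as colony-absent.
#' @return A data frame of class `colony_measurements`: `row`, `col`,
#'   `label`, `I_A`, `I_B`, `ratio`, `edge_excluded`, `missing`,
#'   `low_signal`.
#' @export
measure_plate <- function(img, grid = detect_grid(img), smooth_px = 1,
                          qc = TRUE, k_missing = 1.2) {
  stopifnot(inherits(img, "plate_image"), inherits(grid, "grid_fit"))
  layout <- img$layout
  r_px <- layout$colony_radius_mm * layout$px_per_mm
  cen <- grid$centers
  n <- nrow(cen)
  I_A <- I_B <- numeric(n)
  for (i in seq_len(n)) {
    I_A[i] <- colony_intensity(img$channel_A, cen$x_px[i], cen$y_px[i],
                               r_px, smooth_px)
    I_B[i] <- colony_intensity(img$channel_B, cen$x_px[i], cen$y_px[i],
                               r_px, smooth_px)
  }
  ratio <- ifelse(I_B > 0, I_A / I_B, NA_real_)
  bg <- img$instrument$background
  out <- data.frame(row = cen$row, col = cen$col,
                    label = grid_label(cen$row, cen$col),
                    I_A = I_A, I_B = I_B, ratio = ratio,
                    edge_excluded = is_edge(cen$row, cen$col, layout),
                    missing = (I_A < k_missing * bg & I_B < k_missing * bg) |
                              I_B <= 0,
                    low_signal = FALSE)
  class(out) <- c("colony_measurements", "data.frame")
  if (qc) out <- qc_low_signal(out, background_ref = bg)
  out
}

#' Write colony measurements to CSV
#'
#' Header: `plate,row,col,label,I_ex440,I_ex530,ratio,flags` (excitation
#' columns named after the instrument's wavelengths); flags joined with
#' `;`.
#'
#' @param meas A `colony_measurements` table.
#' @param path CSV path.
#' @param plate Plate identifier written in the first column.
#' @param instrument Optional `instrument_profile` used to name the
#'   intensity columns.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(meas, path, plate = "plate1",
                                   instrument = NULL) {
  exA <- if (is.null(instrument)) 440 else instrument$ex_A
  exB <- if (is.null(instrument)) 530 else instrument$ex_B
  flags <- apply(meas[, c("edge_excluded", "missing", "low_signal")], 1,
                 function(f) paste(c("edge_excluded", "missing",
                                     "low_signal")[as.logical(f)],
                                   collapse = ";"))
  out <- data.frame(plate = plate, row = meas$row, col = meas$col,
                    label = meas$label, I_A = meas$I_A, I_B = meas$I_B,
                    ratio = meas$ratio, flags = flags)
  names(out)[5:6] <- c(paste0("I_ex", exA), paste0("I_ex", exB))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' False-color two-channel composite
#'
#' Short-wavelength excitation maps to blue, long-wavelength to red, green
#' stays zero -- so alkaline (high-ratio) colonies appear blue and acidic
#' ones red. Each channel is normalized to its own upper percentile
#' (default 99.5th) before display.
#'
#' @param img A `plate_image`.
#' @param percentile Normalization percentile per channel.
#' @return An `height x width x 3` array in `[0, 1]` (R, G, B planes).
#' @export
false_color_composite <- function(img, percentile = 0.995) {
  stopifnot(inherits(img, "plate_image"))
  norm <- function(m) {
    hi <- stats::quantile(m, percentile)
    if (hi <= 0) return(m * 0)
    pmin(m / hi, 1)
  }
  h <- nrow(img$channel_A); w <- ncol(img$channel_A)
  out <- array(0, dim = c(h, w, 3))
  out[, , 1] <- norm(img$channel_B)  # red <- long-wavelength excitation
  out[, , 3] <- norm(img$channel_A)  # blue <- short-wavelength excitation
  out
}

#' Write a composite as 8-bit RGB PNG
#'
#' @param composite Array from [false_color_composite()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_composite_png <- function(composite, path) {
  png::writePNG(composite, path)
  invisible(path)
}
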