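# Plate-level ratio statistics, low-signal QC and hit calling for arrayed
# mutant libraries.

#' Plate-level ratio statistics
#'
#' Classical (mean/SD) and robust (median/MAD, MAD scaled to be
#' SD-consistent under normality) location and scale of the per-colony
#' ratios, computed over unflagged colonies only. The robust pair is what
#' hit calling uses; the classical pair is reported for comparability with
#' mean +/- SD summaries.
#'
#' @param meas A `colony_measurements` table.
#' @return An object of class `plate_stats`: list with `n`, `mean`, `sd`,
#'   `median`, `mad`.
#' @export
plate_stats <- function(meas) {
  r <- meas$ratio[unflagged(meas)]
  r <- r[is.finite(r)]
  if (length(r) < 2)
    stop("plate_stats: fewer than 2 unflagged colonies")
  structure(list(n = length(r), mean = mean(r), sd = stats::sd(r),
                 median = stats::median(r), mad = stats::mad(r)),
            class = "plate_stats")
}

#' @export
print.plate_stats <- function(x, ...) {
  cat(sprintf(
    "<plate_stats> n = %d  mean = %.3f  sd = %.3f  median = %.3f  mad = %.3f\n",
    x$n, x$mean, x$sd, x$median, x$mad))
  invisible(x)
}

# colonies that enter statistics and hit calling
unflagged <- function(meas) {
  !meas$edge_excluded & !meas$missing & !meas$low_signal
}

#' Flag weak-expression colonies
#'
#' A colony whose intensities in both channels fall below `k` times the
#' background reference carries too little sensor protein for a reliable
#' ratio. The default `k = 2` sits around the empty-vector fluorescence
#' level, which is 4- to 6-fold below properly expressing sensor colonies,
#' so genuine sensor colonies clear the threshold comfortably.
#'
#' @param meas A `colony_measurements` table.
#' @param background_ref Background reference level in FLU.
#' @param k Multiplier (> 1).
#' @return `meas` with the `low_signal` column updated.
#' @export
qc_low_signal <- function(meas, background_ref, k = 2) {
  if (k <= 1) stop("qc_low_signal: k must be > 1")
  meas$low_signal <- meas$I_A < k * background_ref &
                     meas$I_B < k * background_ref
  meas
}

#' Call screening hits by robust z-score
#'
#' Robust z = (ratio - median) / MAD over the plate; colonies with
#' `|z| >= z_threshold` are called, labelled `low` or `high` by the sign.
#' All unflagged colonies are returned ranked by `|z|` so sub-threshold
#' tails remain inspectable (screens often pursue borderline colonies by
#' eye). If the MAD is zero on non-constant data the SD is substituted
#' with a warning.
#'
#' @param meas A `colony_measurements` table.
#' @param stats A `plate_stats` from the same plate (default: computed).
#' @param z_threshold Calling threshold (> 0), default 3.
#' @return A data frame of class `hit_calls`: `row`, `col`, `label`,
#'   `ratio`, `z`, `direction`, `called`, ordered by decreasing `|z|`.
#' @export
call_hits <- function(meas, stats = plate_stats(meas), z_threshold = 3) {
  stopifnot(inherits(stats, "plate_stats"))
  if (z_threshold <= 0) stop("call_hits: z_threshold must be > 0")
  keep <- unflagged(meas) & is.finite(meas$ratio)
  m <- meas[keep, , drop = FALSE]
  scale <- stats$mad
  if (scale == 0) {
    if (stats$sd > 0) {
      warning("call_hits: MAD is zero on non-constant data; using SD")
      scale <- stats$sd
    } else {
      scale <- NA_real_  # constant plate: all z = 0
    }
  }
  z <- if (is.na(scale)) rep(0, nrow(m)) else (m$ratio - stats$median) / scale
  out <- data.frame(row = m$row, col = m$col, label = m$label,
                    ratio = m$ratio, z = z,
                    direction = ifelse(z < 0, "low", "high"),
                    called = abs(z) >= z_threshold)
  out <- out[order(-abs(out$z)), ]
  rownames(out) <- NULL
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' Write hit calls to CSV (`plate,label,ratio,z,direction,called`)
#'
#' @param hits A `hit_calls` table.
#' @param path CSV path.
#' @param plate Plate identifier.
#' @return `path`, invisibly.
#' @export
write_hits_csv <- function(hits, path, plate = "plate1") {
  out <- data.frame(plate = plate, label = hits$label, ratio = hits$ratio,
                    z = hits$z, direction = hits$direction,
                    called = hits$called)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plain-text screening report
#'
#' @param meas A `colony_measurements` table.
#' @param stats A `plate_stats`.
#' @param hits A `hit_calls` table.
#' @param plate Plate identifier.
#' @return Character vector of report lines.
#' @export
screen_report <- function(meas, stats, hits, plate = "plate1") {
  nd <- sum((meas$low_signal | meas$missing) & !meas$edge_excluded)
  c(sprintf("screen report: %s", plate),
    sprintf("analyzed colonies (n): %d", stats$n),
    sprintf("mean ratio: %.4f", stats$mean),
    sprintf("sd: %.4f", stats$sd),
    sprintf("median: %.4f", stats$median),
    sprintf("mad: %.4f", stats$mad),
    sprintf("n.d. colonies (weak signal/missing): %d", nd),
    sprintf("hits called: %d", sum(hits$called)),
    if (any(hits$called))
      sprintf("  %s ratio %.3f z %+.2f (%s)",
              hits$label[hits$called], hits$ratio[hits$called],
              hits$z[hits$called], hits$direction[hits$called]))
}
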