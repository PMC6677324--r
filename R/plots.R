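# Minimal base-graphics views of the two headline outputs.

#' Phase histogram of rhythmic genes (1-h bins)
#'
#' @param rhythm_table output of [call_rhythmic()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot_phase_histogram <- function(rhythm_table, ...) {
  h <- attr(rhythm_table, "phase_hist")
  if (is.null(h)) {
    ph <- floor(rhythm_table$phase_h[rhythm_table$is_rhythmic]) %% 24
    h <- table(factor(ph, levels = 0:23))
  }
  graphics::barplot(h, xlab = "Phase (ZT, h)", ylab = "Rhythmic genes", ...)
  invisible(h)
}

#' Average Tn5 cut profile around footprint centers
#'
#' Column means of a profile matrix, smoothed by a 3-bp rolling average.
#'
#' @param profiles matrix from [extract_profiles()].
#' @param smooth_w rolling-average window (odd; 1 = none).
#' @param ... passed to [graphics::plot()].
#' @export
plot_footprint_profile <- function(profiles, smooth_w = 3L, ...) {
  avg <- colMeans(profiles)
  if (smooth_w > 1L) avg <- rolling_average(avg, smooth_w)
  x <- as.integer(colnames(profiles))
  graphics::plot(x, avg, type = "l",
                 xlab = "Distance from footprint center (bp)",
                 ylab = "Mean Tn5 cuts", ...)
  invisible(avg)
}
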