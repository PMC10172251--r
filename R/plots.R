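## Rose diagrams (circular histograms) for angle families.

#' Rose plot of an angular sample
#'
#' Circular histogram with 18 sectors of 20 degrees, a mean-direction
#' arrow scaled by the resultant length, and an R annotation. Sector area
#' is proportional to the bin count. Rendering is deterministic given the
#' data. Angles follow the package's image-frame convention; the plot
#' places 0 degrees to the right and positive angles clockwise on screen,
#' matching how the underlying y-down image data would look.
#'
#' @param angles_deg numeric vector of angles in degrees (non-empty).
#' @param path optional PNG output path; when given, the plot is written
#'   there instead of the active device.
#' @param main plot title.
#' @param col sector fill colour.
#' @param ... ignored.
#' @return invisibly, the 18 sector counts (named by bin centre).
#' @export
rose_plot <- function(angles_deg, path = NULL, main = "", col = "steelblue",
                      ...) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (!length(angles_deg)) stop("empty angular sample", call. = FALSE)
  a <- wrap_angle(angles_deg)
  breaks <- seq(-180, 180, by = 20)
  idx <- findInterval(a, breaks, rightmost.closed = TRUE)
  idx[idx > 18] <- 18
  counts <- tabulate(idx, nbins = 18)
  names(counts) <- breaks[-19] + 10
  cs <- circular_summary(a)

  draw <- function() {
    op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
    on.exit(graphics::par(op))
    graphics::plot.new()
    graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
    rmax <- max(sqrt(counts), 1)
    for (k in seq_len(18)) {
      if (counts[k] == 0) next
      th <- seq(breaks[k], breaks[k + 1], length.out = 12) * pi / 180
      rr <- sqrt(counts[k]) / rmax   # equal-area sectors
      graphics::polygon(c(0, rr * cos(th), 0), c(0, rr * sin(th), 0),
                        col = col, border = "white")
    }
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(cos(th), sin(th), col = "grey40")
    for (ang in seq(-180, 150, by = 30)) {
      r <- ang * pi / 180
      graphics::segments(0, 0, cos(r), sin(r), col = "grey85")
      graphics::text(1.1 * cos(r), 1.1 * sin(r), sprintf("%d", ang),
                     cex = 0.6, col = "grey30")
    }
    if (!is.na(cs$mean_deg)) {
      r <- cs$mean_deg * pi / 180
      graphics::arrows(0, 0, cs$resultant_length * cos(r),
                       cs$resultant_length * sin(r),
                       length = 0.1, lwd = 2, col = "black")
    }
    graphics::title(main = main, cex.main = 0.9)
    graphics::mtext(sprintf("n = %d, R = %.3f", cs$n, cs$resultant_length),
                    side = 1, line = 0, cex = 0.8)
  }

  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else draw()
  invisible(counts)
}
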