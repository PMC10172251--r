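## Ciliary beat frequency: time-lapse preprocessing, kymogram extraction
## along polylines, reduction to intensity traces, and dominant-peak FFT
## frequency estimation.

#' Construct an image stack
#'
#' @param frames numeric array T x H x W (frame, row = y, column = x),
#'   T >= 2.
#' @param fs_hz sampling rate in frames per second (default 21, the
#'   acquisition rate the defaults emulate).
#' @param integration_ms exposure per frame in milliseconds (default 10);
#'   metadata only.
#' @return object of class `"image_stack"`.
#' @export
image_stack <- function(frames, fs_hz = 21, integration_ms = 10) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[1] < 2) stop("stack needs at least 2 frames", call. = FALSE)
  stopifnot(is.numeric(fs_hz), fs_hz > 0)
  structure(list(frames = frames, fs_hz = fs_hz,
                 integration_ms = integration_ms),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d frames of %d x %d px at %g frames/s\n",
              d[1], d[2], d[3], x$fs_hz))
  invisible(x)
}

#' Construct an intensity trace
#'
#' @param values numeric vector of per-frame intensities (finite).
#' @param fs_hz sampling rate in Hz.
#' @return object of class `"cbf_trace"`.
#' @export
cbf_trace <- function(values, fs_hz = 21) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("trace values must be finite", call. = FALSE)
  stopifnot(fs_hz > 0)
  structure(list(values = values, fs_hz = fs_hz), class = "cbf_trace")
}

## 3x3 spatial box mean of one frame, edge-normalised (each pixel averages
## its available neighbours)
.box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  cnt <- matrix(0, h + 2, w + 2)
  cnt[2:(h + 1), 2:(w + 1)] <- 1
  acc <- matrix(0, h, w); den <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + pad[di + 1:h, dj + 1:w]
    den <- den + cnt[di + 1:h, dj + 1:w]
  }
  acc / den
}

#' Preprocess a fluorescence time-lapse
#'
#' Applies, in order: per-pixel temporal-minimum background subtraction,
#' photobleaching correction by dividing each frame by a mono-exponential
#' fit to the frame-mean intensity (renormalised to the first frame), and
#' 3 x 3 spatial mean smoothing per frame. Each step can be switched off.
#' The bleach fit is skipped with a warning when the frame means do not
#' decrease (nothing to correct) or the fit fails.
#'
#' @param stack an `image_stack` with at least 16 frames when bleach
#'   correction is on.
#' @param background `"temporal_min"` or `"none"`.
#' @param bleach `"exponential"` or `"none"`.
#' @param smooth `"box3"` or `"none"`.
#' @return the preprocessed `image_stack`.
#' @export
preprocess_stack <- function(stack,
                             background = c("temporal_min", "none"),
                             bleach = c("exponential", "none"),
                             smooth = c("box3", "none")) {
  stopifnot(inherits(stack, "image_stack"))
  background <- match.arg(background)
  bleach <- match.arg(bleach)
  smooth <- match.arg(smooth)
  fr <- stack$frames
  d <- dim(fr)
  if (bleach == "exponential" && d[1] < 16)
    stop("bleach fitting needs at least 16 frames", call. = FALSE)

  if (background == "temporal_min") {
    mn <- apply(fr, c(2, 3), min)
    fr <- sweep(fr, c(2, 3), mn, "-")
  }

  if (bleach == "exponential") {
    means <- apply(fr, 1, mean)
    tt <- (seq_len(d[1]) - 1) / stack$fs_hz
    corrected <- FALSE
    if (all(means > 0) && means[length(means)] < means[1]) {
      fit <- tryCatch({
        lf <- stats::lm(log(means) ~ tt)
        a <- exp(coef(lf)[1]); rate <- -coef(lf)[2]
        if (rate > 0) a * exp(-rate * tt) else NULL
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        scale <- fit / fit[1]
        fr <- fr / array(rep(scale, d[2] * d[3]), d)
        corrected <- TRUE
      }
    }
    if (!corrected)
      warning("bleach correction skipped: frame means not decaying or fit failed",
              call. = FALSE)
  }

  if (smooth == "box3") {
    for (t in seq_len(d[1])) fr[t, , ] <- .box3(fr[t, , ])
  }

  image_stack(fr, fs_hz = stack$fs_hz, integration_ms = stack$integration_ms)
}

## unit-spaced sample positions along a polyline (0-based pixel coords)
.polyline_positions <- function(polyline) {
  pl <- as_polyline(polyline)
  segs <- diff(pl)
  lens <- sqrt(rowSums(segs^2))
  total <- sum(lens)
  if (total <= 0) stop("polyline has zero length", call. = FALSE)
  s <- seq(0, total, by = 1)
  cum <- c(0, cumsum(lens))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(pl)] <- nrow(pl) - 1
  frac <- (s - cum[idx]) / lens[idx]
  cbind(x = pl[idx, 1] + frac * segs[idx, 1],
        y = pl[idx, 2] + frac * segs[idx, 2])
}

as_polyline <- function(p) {
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, lapply(p, as.numeric))
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2 || nrow(p) < 2)
    stop("polyline must be >= 2 points of (x, y)", call. = FALSE)
  if (!all(is.finite(p))) stop("polyline coordinates must be finite", call. = FALSE)
  unname(p)
}

#' Extract a kymogram along a polyline
#'
#' Samples the stack by bilinear interpolation at unit-spaced positions
#' along the polyline, for every frame, producing a position x time image
#' (the classic kymograph of intensity along a line). With
#' `linewidth_px > 1` (odd), intensities are averaged over integer pixel
#' offsets perpendicular to the local line direction.
#'
#' @param stack an `image_stack`.
#' @param polyline k x 2 matrix or list of c(x, y) points, 0-based pixel
#'   coordinates, within image bounds.
#' @param linewidth_px odd integer line width (default 1).
#' @return object of class `"kymogram"`: list with `values` (P x T matrix),
#'   `polyline`, `fs_hz`.
#' @export
extract_kymogram <- function(stack, polyline, linewidth_px = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (linewidth_px < 1 || linewidth_px %% 2 != 1)
    stop("linewidth_px must be a positive odd integer", call. = FALSE)
  pos <- .polyline_positions(polyline)
  d <- dim(stack$frames)  # T, H, W
  offs <- if (linewidth_px == 1) 0 else
    seq(-(linewidth_px - 1) / 2, (linewidth_px - 1) / 2)

  ## perpendicular unit direction per sample (from local tangent)
  tang <- rbind(pos[2, ] - pos[1, ],
                (pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]))
  tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
  perp <- cbind(-tang[, 2] / tl, tang[, 1] / tl)

  fmat <- matrix(stack$frames, nrow = d[1])  # T x (H*W), column (x)*H + y + 1
  sample_at <- function(xy) {
    x <- xy[, 1]; y <- xy[, 2]
    if (any(x < 0 | y < 0 | x > d[3] - 1 | y > d[2] - 1))
      stop("polyline samples outside image bounds", call. = FALSE)
    x0 <- pmin(floor(x), d[3] - 2); y0 <- pmin(floor(y), d[2] - 2)
    fx <- x - x0; fy <- y - y0
    colidx <- function(xx, yy) xx * d[2] + yy + 1
    w <- rbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
    cols <- rbind(colidx(x0, y0), colidx(x0 + 1, y0),
                  colidx(x0, y0 + 1), colidx(x0 + 1, y0 + 1))
    out <- matrix(0, length(x), d[1])
    for (k in 1:4)
      out <- out + t(fmat[, cols[k, ], drop = FALSE]) * w[k, ]
    out  # P x T
  }

  vals <- 0
  for (o in offs) vals <- vals + sample_at(pos + o * perp)
  vals <- vals / length(offs)
  structure(list(values = vals, polyline = as_polyline(polyline),
                 fs_hz = stack$fs_hz),
            class = "kymogram")
}

#' Reduce a kymogram to an intensity-versus-time trace
#'
#' @param k a `kymogram`.
#' @param method `"mean"` (default; per-frame mean over positions along the
#'   line) or `"row"` (a single kymogram row).
#' @param row row index when `method = "row"`.
#' @return a `cbf_trace`.
#' @export
trace_from_kymogram <- function(k, method = c("mean", "row"), row = 1) {
  stopifnot(inherits(k, "kymogram"))
  method <- match.arg(method)
  v <- switch(method,
              mean = colMeans(k$values),
              row = k$values[row, ])
  cbf_trace(v, fs_hz = k$fs_hz)
}

#' Estimate beat frequency from a trace by thresholded FFT peak
#'
#' Mean-subtracts the trace, takes the FFT magnitude spectrum (rectangular
#' window by default), restricts the search to frequencies in
#' (`f_min_hz`, fs/2\], and takes the in-band global maximum as the
#' candidate beat frequency. The candidate is accepted only when its
#' magnitude exceeds median + `threshold_k` * MAD of the in-band
#' magnitudes (MAD with the usual 1.4826 consistency scaling); otherwise
#' the estimate is flagged invalid. Frequency resolution is fs/T.
#'
#' @param trace a `cbf_trace` (or numeric vector with `fs_hz` supplied),
#'   length >= 64.
#' @param fs_hz sampling rate, required when `trace` is a bare vector.
#' @param f_min_hz lower edge of the search band, excluding residual
#'   bleach/drift power (default 0.5 Hz).
#' @param threshold_k robust peak threshold multiplier (default 4).
#' @param window `"none"` (default) or `"hann"`.
#' @return object of class `"cbf_estimate"`: list with `freq_hz`,
#'   `peak_magnitude`, `threshold_used`, `valid`, `spectrum`
#'   (data.frame freq_hz, magnitude), `fs_hz`, `n`.
#' @examples
#' tr <- generate_trace(video_params(true_freqs_hz = 5, noise_sd = 0, seed = 3))
#' estimate_cbf(tr$trace)$freq_hz
#' @export
estimate_cbf <- function(trace, fs_hz = NULL, f_min_hz = 0.5,
                         threshold_k = 4, window = c("none", "hann")) {
  window <- match.arg(window)
  if (inherits(trace, "cbf_trace")) {
    v <- trace$values; fs <- trace$fs_hz
  } else {
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric trace", call. = FALSE)
    v <- as.numeric(trace); fs <- fs_hz
  }
  n <- length(v)
  if (n < 64) stop("trace too short for frequency estimation (need >= 64)",
                   call. = FALSE)
  x <- v - mean(v)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  mag <- Mod(stats::fft(x))
  freqs <- (seq_len(n) - 1) * fs / n
  band <- freqs > f_min_hz & freqs <= fs / 2
  bm <- mag[band]; bf <- freqs[band]
  thr <- stats::median(bm) + threshold_k * stats::mad(bm)
  i <- which.max(bm)
  valid <- bm[i] > thr && bm[i] > 0
  structure(list(freq_hz = if (valid) bf[i] else NA_real_,
                 peak_magnitude = bm[i],
                 threshold_used = thr,
                 valid = valid,
                 spectrum = data.frame(freq_hz = bf, magnitude = bm),
                 fs_hz = fs, n = n),
            class = "cbf_estimate")
}

#' @export
print.cbf_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("CBF estimate: %.3f Hz (peak %.3g > threshold %.3g; resolution %.4f Hz)\n",
                x$freq_hz, x$peak_magnitude, x$threshold_used, x$fs_hz / x$n))
  else
    cat(sprintf("CBF estimate: invalid (peak %.3g <= threshold %.3g)\n",
                x$peak_magnitude, x$threshold_used))
  invisible(x)
}

#' @export
plot.cbf_estimate <- function(x, ...) {
  plot(x$spectrum$freq_hz, x$spectrum$magnitude, type = "l",
       xlab = "frequency (Hz)", ylab = "|FFT|", ...)
  graphics::abline(h = x$threshold_used, lty = 2)
  if (x$valid) graphics::abline(v = x$freq_hz, col = 2, lty = 3)
  invisible(x)
}

#' Summarise beat-frequency estimates, optionally comparing two groups
#'
#' Excludes invalid estimates (counting them), reports per-group linear
#' mean, SD and n, and, when two groups are given, the pooled-variance
#' two-sample t test between them.
#'
#' @param group_a,group_b lists of `cbf_estimate` objects (or numeric
#'   vectors of frequencies); `group_b` optional.
#' @return list with per-group `mean`, `sd`, `n`, `n_invalid`, and `t`,
#'   `p_value` when both groups have >= 2 valid estimates (class
#'   `"cbf_summary"`).
#' @export
summarize_cbf <- function(group_a, group_b = NULL) {
  pull <- function(g) {
    if (is.numeric(g)) return(list(f = g[!is.na(g)], inv = sum(is.na(g))))
    f <- vapply(g, function(e) if (isTRUE(e$valid)) e$freq_hz else NA_real_,
                numeric(1))
    list(f = f[!is.na(f)], inv = sum(is.na(f)))
  }
  a <- pull(group_a)
  out <- list(a = list(mean = mean(a$f), sd = stats::sd(a$f),
                       n = length(a$f), n_invalid = a$inv))
  if (!is.null(group_b)) {
    b <- pull(group_b)
    out$b <- list(mean = mean(b$f), sd = stats::sd(b$f),
                  n = length(b$f), n_invalid = b$inv)
    out$test <- if (length(a$f) >= 2 && length(b$f) >= 2)
      tryCatch(two_sample_t(a$f, b$f), error = function(e) NULL) else NULL
  }
  class(out) <- "cbf_summary"
  out
}

#' @export
print.cbf_summary <- function(x, ...) {
  fmt <- function(g, lab)
    cat(sprintf("  %s: mean %.3f Hz, SD %.3f, n = %d (%d invalid excluded)\n",
                lab, g$mean, g$sd, g$n, g$n_invalid))
  cat("CBF summary\n"); fmt(x$a, "group A")
  if (!is.null(x$b)) {
    fmt(x$b, "group B")
    if (is.null(x$test)) cat("  t test: not testable\n")
    else cat(sprintf("  t = %.3f, p = %.4g\n", x$test$t, x$test$p_value))
  }
  invisible(x)
}
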