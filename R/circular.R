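## Circular descriptive statistics. Angles are degrees in [-180, 180)
## throughout; the wrap convention maps both -180 and +180 to -180.

#' Wrap an angle into \[-180, 180) degrees
#'
#' @param deg numeric vector of angles in degrees (finite).
#' @return angles congruent mod 360, in \[-180, 180).
#' @examples
#' wrap_angle(340)   # -20
#' wrap_angle(180)   # -180
#' @export
wrap_angle <- function(deg) {
  if (!is.numeric(deg) || any(!is.finite(deg)))
    stop("angles must be finite numeric", call. = FALSE)
  ((deg + 180) %% 360) - 180
}

#' Signed angular difference a - b
#'
#' Shortest signed arc from `b` to `a`, in degrees in \[-180, 180).
#'
#' @param a,b angles in degrees.
#' @export
angular_difference <- function(a, b) wrap_angle(a - b)

#' Circular mean, resultant length and circular standard deviation
#'
#' Summarises an angular sample by its circular mean direction
#' \eqn{\bar\theta = \mathrm{atan2}(\sum\sin\theta_i, \sum\cos\theta_i)},
#' mean resultant length \eqn{R \in [0,1]} and circular standard deviation
#' \eqn{\mathrm{CSD} = (180/\pi)\sqrt{-2\ln R}} degrees. A perfectly
#' balanced sample (R = 0) has no mean direction: `mean_deg` is NA and
#' `csd_deg` is `Inf` (the dispersion sentinel used by downstream filters).
#'
#' @param angles_deg numeric vector of angles in degrees, n >= 1.
#' @return object of class `"circular_summary"`: list with `mean_deg`,
#'   `resultant_length`, `csd_deg`, `n`.
#' @examples
#' circular_summary(c(0, 90))   # mean 45, R = sqrt(2)/2
#' @export
circular_summary <- function(angles_deg) {
  if (length(angles_deg) < 1) stop("empty angular sample", call. = FALSE)
  a <- wrap_angle(angles_deg)
  th <- a * pi / 180
  s <- sum(sin(th)); co <- sum(cos(th)); n <- length(th)
  r <- sqrt(s^2 + co^2) / n
  r <- min(r, 1)  # guard rounding above 1
  if (r <= .Machine$double.eps * n) {
    out <- list(mean_deg = NA_real_, resultant_length = 0,
                csd_deg = Inf, n = n)
  } else {
    ## clamp: R within double rounding of 1 means an identical-angle sample
    csd <- if (1 - r < 1e-13) 0 else (180 / pi) * sqrt(max(0, -2 * log(r)))
    out <- list(mean_deg = wrap_angle(atan2(s, co) * 180 / pi),
                resultant_length = r,
                csd_deg = csd,
                n = n)
  }
  class(out) <- "circular_summary"
  out
}

#' @export
print.circular_summary <- function(x, ...) {
  cat("Circular summary (n = ", x$n, ")\n", sep = "")
  cat("  mean direction: ",
      if (is.na(x$mean_deg)) "undefined (R = 0)" else sprintf("%.2f deg", x$mean_deg),
      "\n", sep = "")
  cat(sprintf("  resultant length R: %.4f\n", x$resultant_length))
  cat("  circular SD: ",
      if (is.infinite(x$csd_deg)) "Inf" else sprintf("%.2f deg", x$csd_deg),
      "\n", sep = "")
  invisible(x)
}

#' Closed-form circular SD of a von Mises distribution
#'
#' Population value \eqn{(180/\pi)\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}}
#' degrees, the large-sample limit of the sample CSD for von Mises data.
#' Used as the analytic oracle in parameter-recovery checks.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return circular SD in degrees (`Inf` at kappa = 0).
#' @export
von_mises_csd <- function(kappa) {
  stopifnot(all(kappa >= 0))
  r <- ifelse(kappa == 0, 0, besselI(kappa, 1) / besselI(kappa, 0))
  ifelse(r == 0, Inf, (180 / pi) * sqrt(-2 * log(r)))
}

#' Histogram of circular SD values in 10-degree intervals
#'
#' Counts per half-open bin \[0,10), \[10,20), ..., \[90,100), plus an 11th
#' overflow bin collecting values >= 100 including the `Inf` sentinel of
#' direction-free cells.
#'
#' @param values numeric vector of CSD values in degrees, >= 0 (may contain
#'   `Inf`); NA values are dropped.
#' @return named integer vector of 11 counts summing to the number of
#'   non-NA values.
#' @export
csd_histogram <- function(values) {
  values <- values[!is.na(values)]
  if (any(values < 0)) stop("CSD values must be non-negative", call. = FALSE)
  breaks <- seq(0, 100, by = 10)
  counts <- integer(11)
  names(counts) <- c(paste0("[", breaks[-11], ",", breaks[-1], ")"), ">=100")
  if (length(values)) {
    over <- values >= 100
    counts[11] <- sum(over)
    if (any(!over)) {
      idx <- findInterval(values[!over], breaks, rightmost.closed = FALSE)
      tab <- tabulate(idx, nbins = 10)
      counts[1:10] <- tab
    }
  }
  counts
}

#' Classical pooled-variance two-sample t test
#'
#' Two-tailed Student t test with pooled variance and n1 + n2 - 2 degrees of
#' freedom, the routine comparison for linear quantities (CSD, strength,
#' areas, cilia counts, beat frequencies).
#'
#' @param v1,v2 numeric vectors, each of length >= 2; NA dropped.
#' @return list with `t`, `p_value`, `df`, `n1`, `n2`.
#' @export
two_sample_t <- function(v1, v2) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 2 || length(v2) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  pooled_ss <- sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)
  if (pooled_ss <= 0 && mean(v1) == mean(v2)) {
    ## identical constants: difference 0 with no variance; report t = 0, p = 1
    return(list(t = 0, p_value = 1, df = length(v1) + length(v2) - 2,
                n1 = length(v1), n2 = length(v2)))
  }
  if (pooled_ss <= 0)
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(v1, v2, var.equal = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n1 = length(v1), n2 = length(v2))
}
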