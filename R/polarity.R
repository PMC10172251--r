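## Per-cell and per-field planar-polarity quantification.
##
## A field record is a list:
##   field_id, pixel_size_um, group_label,
##   cells = list of cell records: cell_id, contour (n x 2 matrix),
##     patch_contour (matrix or NULL), cilia = list of list(fop=, gtub=).
##
## Derived per-cell quantities:
##   disp_angle  - direction of cell centre -> patch centre (translational
##                 polarity raw vector)
##   mean_orient - circular mean of the per-cilium basal-body -> basal-foot
##                 (beating) vectors; csd its circular SD
##   vpatchD     - disp_angle relative to the field mean displacement
##   vpatchO     - mean_orient relative to the field mean orientation,
##                 defined only for cells whose CSD passes the threshold
##   vpatchDO    - disp_angle minus mean_orient within the cell
##   strength    - |displacement| / equivalent cell radius sqrt(area/pi)

#' Beating angle of a single cilium
#'
#' Direction of the vector from the basal-body marker point (`fop`) to the
#' basal-foot marker point (`gtub`); the basal foot points in the cilium's
#' effective-stroke direction, so this angle encodes beating direction.
#'
#' @param fop,gtub numeric length-2 points c(x, y) in pixels.
#' @return angle in degrees in \[-180, 180), or NA with a warning when the
#'   two points coincide (the cilium is skipped by consumers).
#' @export
cilium_angle <- function(fop, gtub) {
  v <- vector_between(fop, gtub)
  if (v$length == 0) {
    warning("coincident basal-body/basal-foot points: cilium skipped",
            call. = FALSE)
    return(NA_real_)
  }
  v$angle_deg
}

#' Construct a field record
#'
#' Validating constructor for the container consumed by [field_polarity()].
#'
#' @param field_id identifier string.
#' @param cells list of cell records; each a list with `cell_id`,
#'   `contour` (n x 2 matrix, n >= 3), optional `patch_contour`
#'   (matrix or NULL), and `cilia` (possibly empty list of
#'   `list(fop = c(x, y), gtub = c(x, y))`).
#' @param pixel_size_um physical pixel size in micrometres (> 0);
#'   default 0.09 (90 nm pixels).
#' @param group_label free-text group tag, e.g. "control" or "mutant".
#' @return object of class `"field_record"`.
#' @export
field_record <- function(field_id, cells, pixel_size_um = 0.09,
                         group_label = "unlabeled") {
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  if (length(cells) < 1) stop("a field needs at least one cell", call. = FALSE)
  cells <- lapply(cells, function(cl) {
    if (is.null(cl$cell_id)) stop("cell without cell_id", call. = FALSE)
    cl$contour <- tryCatch(as_polygon(cl$contour), error = function(e)
      stop(sprintf("cell %s: %s", cl$cell_id, conditionMessage(e)), call. = FALSE))
    if (!is.null(cl$patch_contour))
      cl$patch_contour <- tryCatch(as_polygon(cl$patch_contour), error = function(e)
        stop(sprintf("cell %s patch: %s", cl$cell_id, conditionMessage(e)), call. = FALSE))
    if (is.null(cl$cilia)) cl$cilia <- list()
    cl
  })
  structure(list(field_id = as.character(field_id),
                 pixel_size_um = pixel_size_um,
                 group_label = as.character(group_label),
                 cells = cells),
            class = "field_record")
}

#' @export
print.field_record <- function(x, ...) {
  cat(sprintf("Field record '%s' (%s): %d cells, pixel size %.3f um\n",
              x$field_id, x$group_label, length(x$cells), x$pixel_size_um))
  invisible(x)
}

#' Per-cell polarity metrics
#'
#' Computes one cell's translational and rotational polarity quantities:
#' the displacement vector from the cell centroid to the ciliary-patch
#' centroid, the circular mean and circular SD of the per-cilium beating
#' angles, the displacement strength (displacement length over the
#' equivalent cell radius \eqn{\sqrt{A/\pi}}), areas in square
#' micrometres and the usable cilia count. A cell with no patch contour
#' and exactly one cilium runs in primary-cilium mode: the single
#' basal-body point stands in for the patch centre and rotational metrics
#' stay undefined.
#'
#' @param cell a cell record (see [field_record()]).
#' @param csd_threshold_deg validity threshold on the cell's circular SD;
#'   cells above it carry no defined beating orientation (default 45).
#' @param min_cilia minimum usable cilia for rotational metrics (default 3).
#' @param pixel_size_um pixel size for area/length conversion.
#' @return one-row data.frame with columns cell_id, disp_angle_deg,
#'   disp_len_px, mean_orient_deg, csd_deg, orient_valid, strength,
#'   cell_area_um2, patch_area_um2, n_cilia. Undefined metrics are NA.
#' @export
cell_polarity <- function(cell, csd_threshold_deg = 45, min_cilia = 3,
                          pixel_size_um = 0.09) {
  contour <- as_polygon(cell$contour)
  area_px <- polygon_area(contour)
  centroid <- polygon_centroid(contour)

  cil_angles <- vapply(cell$cilia, function(c.) {
    suppressWarnings(cilium_angle(c.$fop, c.$gtub))
  }, numeric(1))
  n_skip <- sum(is.na(cil_angles))
  if (n_skip > 0)
    warning(sprintf("cell %s: %d degenerate cilium vector(s) skipped",
                    cell$cell_id, n_skip), call. = FALSE)
  cil_angles <- cil_angles[!is.na(cil_angles)]
  n_cilia <- length(cil_angles)

  ## patch centre: traced patch contour, or the lone cilium's basal body
  ## point in primary-cilium mode
  patch_area_um2 <- NA_real_
  target <- NULL
  if (!is.null(cell$patch_contour)) {
    patch <- as_polygon(cell$patch_contour)
    patch_area_um2 <- polygon_area(patch) * pixel_size_um^2
    target <- polygon_centroid(patch)
  } else if (length(cell$cilia) == 1) {
    target <- as.numeric(cell$cilia[[1]]$fop)
  }

  disp_angle <- NA_real_; disp_len <- NA_real_; strength <- NA_real_
  if (!is.null(target)) {
    v <- vector_between(centroid, target)
    disp_len <- v$length
    disp_angle <- v$angle_deg        # NA when patch centre == cell centre
    strength <- disp_len / sqrt(area_px / pi)
  }

  mean_orient <- NA_real_; csd <- NA_real_
  if (n_cilia >= min_cilia) {
    cs <- circular_summary(cil_angles)
    csd <- cs$csd_deg
    mean_orient <- cs$mean_deg       # NA when R = 0 (csd Inf)
  }
  orient_valid <- !is.na(mean_orient) && is.finite(csd) && csd <= csd_threshold_deg
  if (!orient_valid) mean_orient <- NA_real_

  data.frame(cell_id = as.character(cell$cell_id),
             disp_angle_deg = disp_angle,
             disp_len_px = disp_len,
             mean_orient_deg = mean_orient,
             csd_deg = csd,
             orient_valid = orient_valid,
             strength = strength,
             cell_area_um2 = area_px * pixel_size_um^2,
             patch_area_um2 = patch_area_um2,
             n_cilia = n_cilia,
             stringsAsFactors = FALSE)
}

#' Field-level polarity quantification
#'
#' The central fit: from a traced field it derives every per-cell metric,
#' the field mean displacement and orientation directions (unit-weighted
#' circular means over cells), and the three field-referenced angle
#' families:
#' \describe{
#'   \item{vpatchD}{per-cell patch-displacement angle relative to the field
#'     mean displacement direction (translational polarity).}
#'   \item{vpatchO}{per-cell mean beating angle relative to the field mean
#'     orientation; defined only for cells whose circular SD is at most
#'     `csd_threshold_deg` (rotational polarity across cells).}
#'   \item{vpatchDO}{per-cell angle between displacement direction and mean
#'     beating orientation (their alignment).}
#' }
#' Undefined metrics propagate as NA; cells are never imputed, so each
#' metric carries its own n.
#'
#' @param field a `field_record` (or a plain list with the same fields).
#' @inheritParams cell_polarity
#' @return object of class `"field_polarity"`: list with `field_id`,
#'   `group_label`, `field_disp_mean_deg`, `field_orient_mean_deg`,
#'   `cells` (per-cell data.frame including vpatchD_deg, vpatchO_deg,
#'   vpatchDO_deg), and the effective `config`.
#' @examples
#' f <- generate_tissue(tissue_params(n_cells = 12, seed = 7))$field
#' fp <- field_polarity(f)
#' summary(fp)
#' @export
field_polarity <- function(field, csd_threshold_deg = 45, min_cilia = 3) {
  if (!inherits(field, "field_record"))
    field <- field_record(field$field_id, field$cells,
                          pixel_size_um = field$pixel_size_um,
                          group_label = field$group_label)
  rows <- lapply(field$cells, function(cl)
    tryCatch(cell_polarity(cl, csd_threshold_deg, min_cilia,
                           field$pixel_size_um),
             error = function(e) {
               warning(sprintf("cell %s excluded: %s", cl$cell_id,
                               conditionMessage(e)), call. = FALSE)
               NULL
             }))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no valid cells in field", call. = FALSE)
  cells <- do.call(rbind, rows)

  disp <- cells$disp_angle_deg[!is.na(cells$disp_angle_deg)]
  if (length(disp) < 2)
    stop("need at least 2 cells with defined displacement", call. = FALSE)
  dsum <- circular_summary(disp)
  field_disp_mean <- dsum$mean_deg   # NA if R = 0: field flagged
  orient <- cells$mean_orient_deg[!is.na(cells$mean_orient_deg)]
  field_orient_mean <- if (length(orient) >= 1)
    circular_summary(orient)$mean_deg else NA_real_

  ## NA-preserving angular difference for per-cell columns
  adiff <- function(a, b) {
    out <- rep(NA_real_, length(a))
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) out[ok] <- angular_difference(a[ok], if (length(b) == 1) b else b[ok])
    out
  }
  cells$vpatchD_deg <- if (is.na(field_disp_mean)) NA_real_ else
    adiff(cells$disp_angle_deg, field_disp_mean)
  cells$vpatchO_deg <- if (is.na(field_orient_mean)) NA_real_ else
    adiff(cells$mean_orient_deg, field_orient_mean)
  cells$vpatchDO_deg <- adiff(cells$disp_angle_deg, cells$mean_orient_deg)

  structure(list(field_id = field$field_id,
                 group_label = field$group_label,
                 field_disp_mean_deg = field_disp_mean,
                 field_orient_mean_deg = field_orient_mean,
                 cells = cells,
                 config = list(csd_threshold_deg = csd_threshold_deg,
                               min_cilia = min_cilia,
                               pixel_size_um = field$pixel_size_um)),
            class = "field_polarity")
}

#' @export
print.field_polarity <- function(x, ...) {
  cat(sprintf("Field polarity '%s' (%s): %d cells\n",
              x$field_id, x$group_label, nrow(x$cells)))
  cat(sprintf("  field mean displacement: %s\n",
              if (is.na(x$field_disp_mean_deg)) "undefined"
              else sprintf("%.1f deg", x$field_disp_mean_deg)))
  cat(sprintf("  field mean orientation:  %s\n",
              if (is.na(x$field_orient_mean_deg)) "undefined"
              else sprintf("%.1f deg", x$field_orient_mean_deg)))
  cat(sprintf("  cells with valid orientation (CSD <= %g): %d\n",
              x$config$csd_threshold_deg, sum(x$cells$orient_valid)))
  invisible(x)
}

#' @export
summary.field_polarity <- function(object, ...) {
  cells <- object$cells
  metr <- function(v) c(n = sum(!is.na(v)),
                        mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v, na.rm = TRUE))
  ang <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 1) return(c(n = 0, mean = NA, csd = NA))
    cs <- circular_summary(v)
    c(n = cs$n, mean = cs$mean_deg, csd = cs$csd_deg)
  }
  out <- list(field_id = object$field_id,
              group_label = object$group_label,
              n_cells = nrow(cells),
              vpatchD = ang(cells$vpatchD_deg),
              vpatchO = ang(cells$vpatchO_deg),
              vpatchDO = ang(cells$vpatchDO_deg),
              csd = metr(cells$csd_deg[is.finite(cells$csd_deg)]),
              strength = metr(cells$strength),
              cell_area_um2 = metr(cells$cell_area_um2),
              patch_area_um2 = metr(cells$patch_area_um2),
              n_cilia = metr(cells$n_cilia))
  class(out) <- "summary.field_polarity"
  out
}

#' @export
print.summary.field_polarity <- function(x, ...) {
  cat(sprintf("Polarity summary for field '%s' (%s), %d cells\n",
              x$field_id, x$group_label, x$n_cells))
  for (m in c("vpatchD", "vpatchO", "vpatchDO")) {
    v <- x[[m]]
    cat(sprintf("  %-9s n = %3d  circ. mean %7.2f deg  CSD %6.2f deg\n",
                m, v["n"], v["mean"], v["csd"]))
  }
  for (m in c("csd", "strength", "cell_area_um2", "patch_area_um2", "n_cilia")) {
    v <- x[[m]]
    cat(sprintf("  %-14s n = %3d  mean %9.3f  sd %8.3f\n",
                m, v["n"], v["mean"], v["sd"]))
  }
  invisible(x)
}

#' Per-cell metrics table of a fitted field
#'
#' @param x a `field_polarity` object.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame, one row per cell, in the canonical column order
#'   used by [write_metrics_csv()].
#' @export
as.data.frame.field_polarity <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  cells <- x$cells
  out <- data.frame(field_id = x$field_id,
                    group_label = x$group_label,
                    cell_id = cells$cell_id,
                    vpatchD_deg = cells$vpatchD_deg,
                    vpatchO_deg = cells$vpatchO_deg,
                    vpatchDO_deg = cells$vpatchDO_deg,
                    csd_deg = cells$csd_deg,
                    orient_valid = cells$orient_valid,
                    strength = cells$strength,
                    cell_area_um2 = cells$cell_area_um2,
                    patch_area_um2 = cells$patch_area_um2,
                    n_cilia = cells$n_cilia,
                    disp_angle_deg = cells$disp_angle_deg,
                    mean_orient_deg = cells$mean_orient_deg,
                    stringsAsFactors = FALSE)
  rownames(out) <- row.names
  out
}

#' Rose plot of a field's displacement angles
#'
#' @param x a `field_polarity` object.
#' @param which metric to plot: "vpatchD", "vpatchO" or "vpatchDO".
#' @param ... passed to [rose_plot()].
#' @export
plot.field_polarity <- function(x, which = "vpatchD", ...) {
  col <- paste0(which, "_deg")
  v <- x$cells[[col]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no defined ", which, " angles to plot", call. = FALSE)
  rose_plot(v, main = sprintf("%s - %s (%s)", x$field_id, which,
                              x$group_label), ...)
}
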