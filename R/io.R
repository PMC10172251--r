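## File formats: field-record JSON, metrics CSV, TIFF stacks, polyline
## JSON, statistics report JSON, and the effective run configuration that
## is echoed alongside every output artifact.

.known_field_keys <- c("field_id", "pixel_size_um", "group_label", "cells")
.known_cell_keys <- c("cell_id", "contour", "patch_contour", "cilia")

#' Read a field record from JSON
#'
#' Schema: `{"field_id", "pixel_size_um", "group_label", "cells":
#' [{"cell_id", "contour": [[x,y],...], "patch_contour": [[x,y],...]|null,
#' "cilia": [{"fop": [x,y], "gtub": [x,y]}, ...]}]}` with 0-based pixel
#' coordinates. Unknown keys are preserved and re-emitted by
#' [write_field_json()]. Validation failures name the offending cell and
#' the file path.
#'
#' @param path path to a JSON file.
#' @return a `field_record`.
#' @export
read_field_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("%s: malformed JSON (%s)", path,
                                 conditionMessage(e)), call. = FALSE))
  for (k in c("field_id", "pixel_size_um", "cells"))
    if (is.null(raw[[k]]))
      stop(sprintf("%s: missing required key '%s'", path, k), call. = FALSE)
  num2 <- function(x, what, cid) {
    x <- unlist(x)
    if (length(x) != 2 || !is.numeric(x) || any(!is.finite(x)))
      stop(sprintf("%s: cell %s: %s must be a finite [x, y] pair",
                   path, cid, what), call. = FALSE)
    as.numeric(x)
  }
  cells <- lapply(raw$cells, function(cl) {
    cid <- if (is.null(cl$cell_id)) "<missing cell_id>" else cl$cell_id
    if (is.null(cl$cell_id))
      stop(sprintf("%s: cell without cell_id", path), call. = FALSE)
    mat <- function(x, what, min_n) {
      m <- tryCatch(do.call(rbind, lapply(x, function(r) num2(r, what, cid))),
                    error = function(e) stop(conditionMessage(e), call. = FALSE))
      if (is.null(m) || nrow(m) < min_n)
        stop(sprintf("%s: cell %s: %s needs at least %d vertices",
                     path, cid, what, min_n), call. = FALSE)
      m
    }
    out <- list(cell_id = cid,
                contour = mat(cl$contour, "contour", 3),
                patch_contour = if (is.null(cl$patch_contour)) NULL
                else mat(cl$patch_contour, "patch_contour", 3),
                cilia = lapply(if (is.null(cl$cilia)) list() else cl$cilia,
                               function(c.) list(fop = num2(c.$fop, "fop", cid),
                                                 gtub = num2(c.$gtub, "gtub", cid))))
    extra <- cl[setdiff(names(cl), .known_cell_keys)]
    if (length(extra)) out$extra <- extra
    out
  })
  field <- tryCatch(
    field_record(raw$field_id, cells,
                 pixel_size_um = raw$pixel_size_um,
                 group_label = if (is.null(raw$group_label)) "unlabeled"
                 else raw$group_label),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  extra <- raw[setdiff(names(raw), .known_field_keys)]
  if (length(extra)) attr(field, "extra") <- extra
  field
}

#' Write a field record to JSON
#'
#' Inverse of [read_field_json()]; write-then-read round-trips losslessly
#' (full floating-point precision, unknown keys preserved).
#'
#' @param field a `field_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_json <- function(field, path) {
  stopifnot(inherits(field, "field_record"))
  enc_pts <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  obj <- list(field_id = field$field_id,
              pixel_size_um = field$pixel_size_um,
              group_label = field$group_label,
              cells = lapply(field$cells, function(cl) {
                o <- list(cell_id = cl$cell_id,
                          contour = enc_pts(cl$contour),
                          patch_contour = if (is.null(cl$patch_contour)) NULL
                          else enc_pts(cl$patch_contour),
                          cilia = lapply(cl$cilia, function(c.)
                            list(fop = unname(as.numeric(c.$fop)),
                                 gtub = unname(as.numeric(c.$gtub)))))
                if (!is.null(cl$extra)) o <- c(o, cl$extra)
                o
              }))
  if (!is.null(attr(field, "extra"))) obj <- c(obj, attr(field, "extra"))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

.metrics_columns <- c("field_id", "group_label", "cell_id", "vpatchD_deg",
                      "vpatchO_deg", "vpatchDO_deg", "csd_deg", "orient_valid",
                      "strength", "cell_area_um2", "patch_area_um2", "n_cilia",
                      "disp_angle_deg", "mean_orient_deg")

#' Write a per-cell metrics table to CSV
#'
#' One row per cell in the canonical column order; undefined metrics are
#' written as empty cells (never 0), UTF-8, '.' decimal.
#'
#' @param table data.frame as returned by [as.data.frame.field_polarity()]
#'   (or an rbind of several), or a list of `field_polarity` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  if (!is.data.frame(table)) table <- .pool_metrics(table)
  missing_cols <- setdiff(.metrics_columns, names(table))
  if (length(missing_cols))
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(table[, .metrics_columns], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-cell metrics table from CSV
#'
#' @param path path to a CSV written by [write_metrics_csv()].
#' @return data.frame with the canonical metric columns; empty cells
#'   become NA.
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.metrics_columns, names(tab))
  if (length(missing_cols))
    stop(path, ": not a metrics CSV (missing ",
         paste(missing_cols, collapse = ", "), ")", call. = FALSE)
  num_cols <- setdiff(.metrics_columns,
                      c("field_id", "group_label", "cell_id", "orient_valid"))
  for (cc in num_cols) tab[[cc]] <- as.numeric(tab[[cc]])
  tab$orient_valid <- as.logical(tab$orient_valid)
  tab
}

#' Read / write a multi-page TIFF stack
#'
#' 16-bit grayscale multi-page TIFF; intensities are rescaled to the unit
#' interval on write (a global affine rescaling, which the frequency
#' analysis is invariant to).
#'
#' @param path TIFF file path.
#' @param fs_hz sampling rate to stamp on the stack on read.
#' @return `read_tiff_stack`: an `image_stack`.
#' @export
read_tiff_stack <- function(path, fs_hz = 21) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  fr <- array(0, c(length(pages), h, w))
  for (t in seq_along(pages)) fr[t, , ] <- pages[[t]]
  image_stack(fr, fs_hz = fs_hz)
}

#' @rdname read_tiff_stack
#' @param stack an `image_stack` to write.
#' @export
write_tiff_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  rng <- range(fr)
  fr <- if (diff(rng) > 0) (fr - rng[1]) / diff(rng) else fr * 0
  pages <- lapply(seq_len(dim(fr)[1]), function(t) fr[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read / write polylines as JSON
#'
#' A polyline file is a JSON array of polylines, each an array of
#' `[x, y]` points in 0-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return `read_polylines_json`: list of k x 2 matrices.
#' @export
read_polylines_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(pl) as_polyline(lapply(pl, unlist)))
}

#' @rdname read_polylines_json
#' @param polylines list of k x 2 matrices (or lists of points).
#' @export
write_polylines_json <- function(polylines, path) {
  obj <- lapply(polylines, function(pl) {
    pl <- as_polyline(pl)
    lapply(seq_len(nrow(pl)), function(i) unname(pl[i, ]))
  })
  writeLines(jsonlite::toJSON(obj, digits = NA), path)
  invisible(path)
}

#' Effective run configuration
#'
#' Collects the tunable analysis parameters with their defaults; written
#' as a JSON sidecar next to every output artifact so any result can be
#' reproduced bit for bit.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(csd_threshold_deg = 45, min_cilia = 3, n_permutations = 999,
              seed = 1, pixel_size_um = 0.09, fs_hz = 21, f_min_hz = 0.5,
              threshold_k = 4, window = "none", log_level = "info")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "run_config"
  cfg
}

write_config_sidecar <- function(cfg, out_path) {
  side <- paste0(out_path, ".config.json")
  obj <- c(unclass(cfg),
           list(package = "ciliapol",
                version = as.character(utils::packageVersion("ciliapol"))))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             side)
  invisible(side)
}
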