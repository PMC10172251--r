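## Group comparison: pooled per-cell angles per group tested by Watson U2,
## linear per-cell quantities by the pooled-variance t test.

.pool_metrics <- function(group) {
  ## accepts a list of field_polarity objects, a list of metric
  ## data.frames, or one data.frame (e.g. read back from a metrics CSV)
  if (is.data.frame(group)) return(group)
  tabs <- lapply(group, function(g) {
    if (inherits(g, "field_polarity")) as.data.frame(g)
    else if (is.data.frame(g)) g
    else stop("group elements must be field_polarity objects or data.frames",
              call. = FALSE)
  })
  do.call(rbind, tabs)
}

#' Compare two groups of quantified fields
#'
#' Pools per-cell metrics across the fields of each group and tests:
#' the circular metrics vpatchD, vpatchO and vpatchDO with the permutation
#' Watson U2 test (rotation-invariant, so pooling field-referenced angles
#' across fields is legitimate), and the linear metrics csd, strength,
#' cell_area, patch_area and n_cilia with the classical two-tailed
#' pooled-variance t test. Cells with an undefined value of a metric are
#' excluded from that metric only; infinite circular SD values
#' (direction-free cells) are excluded from the CSD t test and their count
#' reported.
#'
#' @param group_a,group_b lists of `field_polarity` objects (or metric
#'   data.frames as produced by [as.data.frame.field_polarity()] /
#'   [read_metrics_csv()]).
#' @param n_permutations permutations for each Watson test (default 999).
#' @param seed integer seed; each metric uses an offset of it, so the whole
#'   comparison is reproducible.
#' @return object of class `"group_comparison"`: list with `circular`
#'   (named list of `watson_test` objects or NULL when untestable),
#'   `linear` (named list of t-test results), `excluded_inf_csd` counts and
#'   `config`.
#' @export
compare_groups <- function(group_a, group_b, n_permutations = 999, seed = 1) {
  ta <- .pool_metrics(group_a); tb <- .pool_metrics(group_b)

  circ_metrics <- c(vpatchD = "vpatchD_deg", vpatchO = "vpatchO_deg",
                    vpatchDO = "vpatchDO_deg")
  lin_metrics <- c(csd = "csd_deg", strength = "strength",
                   cell_area = "cell_area_um2", patch_area = "patch_area_um2",
                   n_cilia = "n_cilia")

  circular <- list(); i <- 0L
  for (m in names(circ_metrics)) {
    i <- i + 1L
    va <- ta[[circ_metrics[m]]]; vb <- tb[[circ_metrics[m]]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    circular[[m]] <- if (length(va) >= 2 && length(vb) >= 2)
      watson_u2_test(va, vb, n_permutations = n_permutations,
                     seed = seed + i) else NULL
  }

  excl <- c(a = 0L, b = 0L)
  linear <- list()
  for (m in names(lin_metrics)) {
    va <- ta[[lin_metrics[m]]]; vb <- tb[[lin_metrics[m]]]
    if (m == "csd") {
      excl <- c(a = sum(is.infinite(va)), b = sum(is.infinite(vb)))
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    } else {
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    }
    linear[[m]] <- if (length(va) >= 2 && length(vb) >= 2)
      tryCatch(two_sample_t(va, vb), error = function(e) NULL) else NULL
  }

  structure(list(circular = circular, linear = linear,
                 excluded_inf_csd = excl,
                 n_cells = c(a = nrow(ta), b = nrow(tb)),
                 config = list(n_permutations = n_permutations, seed = seed)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%d vs %d cells pooled)\n",
              x$n_cells["a"], x$n_cells["b"]))
  cat("Circular metrics (Watson U2, permutation p):\n")
  for (m in names(x$circular)) {
    w <- x$circular[[m]]
    if (is.null(w)) cat(sprintf("  %-9s not testable\n", m))
    else cat(sprintf("  %-9s U2 = %8.5f  p = %.4g  (n = %d vs %d)\n",
                     m, w$u2, w$p_value, w$n1, w$n2))
  }
  cat("Linear metrics (pooled-variance t, two-tailed p):\n")
  for (m in names(x$linear)) {
    l <- x$linear[[m]]
    if (is.null(l)) cat(sprintf("  %-10s not testable\n", m))
    else cat(sprintf("  %-10s t = %8.3f  p = %.4g  (n = %d vs %d)\n",
                     m, l$t, l$p_value, l$n1, l$n2))
  }
  if (any(x$excluded_inf_csd > 0))
    cat(sprintf("  (%d + %d direction-free cells excluded from the CSD test)\n",
                x$excluded_inf_csd["a"], x$excluded_inf_csd["b"]))
  invisible(x)
}
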