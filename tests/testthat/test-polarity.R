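test_that("cilium_angle follows the basal-body to basal-foot vector", {
  expect_equal(cilium_angle(c(0, 0), c(1, 0)), 0)
  expect_equal(cilium_angle(c(0, 0), c(0, -2)), -90)
  expect_warning(a <- cilium_angle(c(1, 1), c(1, 1)), "coincident")
  expect_true(is.na(a))
})

test_that("cell_polarity reproduces the constructed reference cell", {
  # circular cell radius 10, patch centre 3 px along +x, 10 aligned cilia
  cell <- make_cell(centre = c(50, 50), radius = 10, patch_offset = c(3, 0),
                    cilium_angles = rep(0, 10))
  cp <- cell_polarity(cell, pixel_size_um = 0.09)
  expect_equal(cp$disp_angle_deg, 0, tolerance = 1e-9)
  expect_equal(cp$csd_deg, 0)
  expect_true(cp$orient_valid)
  expect_equal(cp$mean_orient_deg, 0, tolerance = 1e-9)
  # strength = |disp| / sqrt(area/pi); the 64-gon radius is slightly below
  # the circumscribed 10 px, so compare against its own equivalent radius
  r_eq <- sqrt(polygon_area(cell$contour) / pi)
  expect_equal(cp$strength, 3 / r_eq, tolerance = 1e-12)
  expect_equal(cp$strength, 0.3, tolerance = 0.01)
  expect_equal(cp$n_cilia, 10)
  expect_equal(cp$cell_area_um2, polygon_area(cell$contour) * 0.09^2)
})

test_that("evenly spread cilia leave orientation undefined", {
  cell <- make_cell(cilium_angles = seq(-180, 179, by = 36))
  cp <- cell_polarity(cell)
  expect_true(is.infinite(cp$csd_deg))
  expect_false(cp$orient_valid)
  expect_true(is.na(cp$mean_orient_deg))
})

test_that("rotational metrics need min_cilia usable cilia", {
  cell <- make_cell(cilium_angles = c(10, 20))
  cp <- cell_polarity(cell, min_cilia = 3)
  expect_true(is.na(cp$csd_deg))
  expect_false(cp$orient_valid)
  expect_equal(cp$n_cilia, 2)
  # degenerate cilium pairs are skipped, not fatal
  cell$cilia <- c(cell$cilia, list(list(fop = c(1, 1), gtub = c(1, 1))))
  expect_warning(cp2 <- cell_polarity(cell, min_cilia = 3), "skipped")
  expect_equal(cp2$n_cilia, 2)
})

test_that("primary-cilium mode uses the basal-body point as patch centre", {
  cell <- list(cell_id = "p1",
               contour = regular_polygon(20, 20, 8),
               patch_contour = NULL,
               cilia = list(list(fop = c(24, 20), gtub = c(25, 20))))
  cp <- cell_polarity(cell)
  expect_equal(cp$disp_angle_deg, 0, tolerance = 1e-9)
  expect_true(is.na(cp$patch_area_um2))
  expect_true(is.na(cp$csd_deg))      # rotational metrics undefined
  expect_false(cp$orient_valid)
})

test_that("CSD of generated cells tracks the von Mises closed form", {
  sim <- generate_tissue(tissue_params(n_cells = 60, kappa_cil = 4,
                                       n_cilia_range = c(30, 30), seed = 21))
  fp <- field_polarity(sim$field)
  csd <- fp$cells$csd_deg[is.finite(fp$cells$csd_deg)]
  expect_equal(mean(csd), von_mises_csd(4), tolerance = 0.08)
})

test_that("aligned displacement collapses vpatchD to zero", {
  field <- make_disp_field(rep(0, 8))
  fp <- field_polarity(field)
  expect_equal(fp$field_disp_mean_deg, 0, tolerance = 1e-9)
  expect_equal(fp$cells$vpatchD_deg, rep(0, 8), tolerance = 1e-9)
})

test_that("vpatchD matches a direct circular-mean recomputation", {
  angles <- c(rep(0, 9), 90)
  fp <- field_polarity(make_disp_field(angles))
  # independent recomputation of the ten-unit-vector mean
  mean_ref <- atan2(sum(sin(angles * pi / 180)),
                    sum(cos(angles * pi / 180))) * 180 / pi
  expect_equal(fp$field_disp_mean_deg, mean_ref, tolerance = 1e-6)
  expect_equal(fp$cells$vpatchD_deg[10], 90 - mean_ref, tolerance = 1e-6)
  expect_equal(fp$cells$vpatchD_deg[1], -mean_ref, tolerance = 1e-6)
})

test_that("aligned displacement and orientation give vpatchDO = 0", {
  cell <- make_cell(patch_offset = 3 * c(cos(pi / 6), sin(pi / 6)),
                    cilium_angles = rep(30, 6))
  field <- field_record("f", list(cell, make_cell(id = "c2")))
  fp <- field_polarity(field)
  expect_equal(fp$cells$vpatchDO_deg[1], 0, tolerance = 1e-6)
})

test_that("polarity metrics are invariant under rigid motions of the field", {
  sim <- generate_tissue(tissue_params(n_cells = 25, seed = 31))
  f0 <- field_polarity(sim$field)
  f1 <- field_polarity(transform_field(sim$field, rot_deg = 37,
                                       dx = 120, dy = -60))
  for (col in c("vpatchD_deg", "vpatchO_deg", "vpatchDO_deg", "csd_deg",
                "strength", "cell_area_um2", "patch_area_um2", "n_cilia"))
    expect_equal(f1$cells[[col]], f0$cells[[col]], tolerance = 1e-6,
                 label = col)
  expect_equal(wrap_angle(f1$field_disp_mean_deg - f0$field_disp_mean_deg),
               37, tolerance = 1e-6)
})

test_that("vpatchD is centred on zero by construction", {
  sim <- generate_tissue(tissue_params(n_cells = 40, seed = 41))
  fp <- field_polarity(sim$field)
  v <- fp$cells$vpatchD_deg[!is.na(fp$cells$vpatchD_deg)]
  expect_lt(abs(circular_summary(v)$mean_deg), 1e-6)
})

test_that("the CSD threshold rule and vpatchO exclusion coincide", {
  sim <- generate_tissue(tissue_params(n_cells = 50, preset = "mutant",
                                       seed = 51))
  fp <- field_polarity(sim$field)
  cells <- fp$cells
  expect_identical(is.na(cells$vpatchO_deg), !cells$orient_valid)
  expect_identical(cells$orient_valid,
                   !is.na(cells$csd_deg) & is.finite(cells$csd_deg) &
                     cells$csd_deg <= 45)
})

test_that("vpatchD dispersion decreases monotonically with kappa_D", {
  kappas <- c(8, 4, 2, 1, 0.5)
  ordered <- sapply(1:8, function(s) {
    csd <- sapply(kappas, function(k) {
      sim <- generate_tissue(tissue_params(n_cells = 80, kappa_D = k,
                                           seed = 1000 * s + round(10 * k)))
      fp <- field_polarity(sim$field)
      v <- fp$cells$vpatchD_deg[!is.na(fp$cells$vpatchD_deg)]
      circular_summary(v)$csd_deg
    })
    all(diff(csd) > 0)
  })
  expect_gte(sum(ordered), 7)
})

test_that("comparing a group with itself is null everywhere", {
  st <- generate_study(n_fields = 2, seed = 61)
  fa <- lapply(st$control, function(s) field_polarity(s$field))
  cmp <- compare_groups(fa, fa, n_permutations = 199, seed = 3)
  for (m in names(cmp$circular)) {
    expect_equal(cmp$circular[[m]]$u2, 0, label = m)
    expect_equal(cmp$circular[[m]]$p_value, 1, label = m)
  }
  for (m in names(cmp$linear))
    expect_equal(cmp$linear[[m]]$t, 0, label = m, tolerance = 1e-12)
})

test_that("groups differing only in intra-cell concentration separate on CSD, not vpatchD", {
  base <- function(k_cil, seed) tissue_params(n_cells = 40, kappa_D = 4,
                                              kappa_O = 4, kappa_cil = k_cil,
                                              seed = seed)
  res <- sapply(1:12, function(s) {
    fa <- lapply(1:2, function(i)
      field_polarity(generate_tissue(base(8, 300 + 10 * s + i))$field))
    fb <- lapply(1:2, function(i)
      field_polarity(generate_tissue(base(2, 600 + 10 * s + i))$field))
    cmp <- compare_groups(fa, fb, n_permutations = 199, seed = s)
    c(csd_sig = cmp$linear$csd$p_value < 0.05,
      vd_sig = cmp$circular$vpatchD$p_value < 0.05)
  })
  expect_gte(sum(res["csd_sig", ]), 11)   # rotational defect detected
  expect_lte(sum(res["vd_sig", ]), 2)     # translational polarity untouched
})
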