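# Independent oracles and small fixture builders used across test files.

# Brute-force Watson U2: evaluates the defining sum directly from the two
# ECDFs at every pooled observation (F(v) counts all values <= v, so tied
# observations automatically share their post-tie ECDF difference).
# Deliberately unrelated to the package's sorted-run implementation.
watson_u2_bruteforce <- function(s1, s2) {
  n1 <- length(s1); n2 <- length(s2); N <- n1 + n2
  pooled <- c(s1, s2)
  d <- vapply(pooled, function(v) mean(s1 <= v) - mean(s2 <= v), numeric(1))
  (n1 * n2 / N^2) * (sum(d^2) - sum(d)^2 / N)
}

# Method-of-moments inversion of the von Mises mean resultant length:
# solves I1(k)/I0(k) = R for k.
kappa_from_R <- function(R) {
  if (R <= 0) return(0)
  stats::uniroot(function(k) besselI(k, 1) / besselI(k, 0) - R,
                 c(1e-6, 500), tol = 1e-9)$root
}

# regular polygon (approximate circle) as an n x 2 matrix
regular_polygon <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# build a cell record with a circular contour, a small square patch at a
# given offset from the centre, and cilia all beating at given angles
make_cell <- function(id = "c1", centre = c(50, 50), radius = 10,
                      patch_offset = c(3, 0), cilium_angles = rep(0, 10),
                      sep = 2) {
  pc <- centre + patch_offset
  patch <- rbind(pc + c(-1, -1), pc + c(1, -1), pc + c(1, 1), pc + c(-1, 1))
  cilia <- lapply(cilium_angles, function(a) {
    r <- a * pi / 180
    list(fop = pc, gtub = pc + sep * c(cos(r), sin(r)))
  })
  list(cell_id = id, contour = regular_polygon(centre[1], centre[2], radius),
       patch_contour = patch, cilia = cilia)
}

# field of unit-variance square cells with prescribed displacement angles
make_disp_field <- function(disp_angles_deg, spacing = 40, radius = 10,
                            disp_len = 3) {
  cells <- lapply(seq_along(disp_angles_deg), function(i) {
    th <- disp_angles_deg[i] * pi / 180
    make_cell(id = sprintf("c%02d", i),
              centre = c(spacing * i, 100), radius = radius,
              patch_offset = disp_len * c(cos(th), sin(th)),
              cilium_angles = rep(disp_angles_deg[i], 5))
  })
  field_record("fixture", cells, pixel_size_um = 0.09, group_label = "fixture")
}

# apply a rigid motion (rotation by deg about the origin, then translation)
# to every coordinate of a field record
transform_field <- function(field, rot_deg = 0, dx = 0, dy = 0) {
  r <- rot_deg * pi / 180
  Rm <- rbind(c(cos(r), -sin(r)), c(sin(r), cos(r)))
  tp <- function(m) sweep(m %*% t(Rm), 2, c(dx, dy), "+")
  field$cells <- lapply(field$cells, function(cl) {
    cl$contour <- tp(cl$contour)
    if (!is.null(cl$patch_contour)) cl$patch_contour <- tp(cl$patch_contour)
    cl$cilia <- lapply(cl$cilia, function(c.) {
      list(fop = as.numeric(tp(matrix(c.$fop, 1))),
           gtub = as.numeric(tp(matrix(c.$gtub, 1))))
    })
    cl
  })
  field
}
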