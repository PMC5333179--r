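# Shared fixtures: all constructed in code at test time.

# homogeneous cubic grid of one material
homog_grid <- function(n = 8, spacing_um = 1250, sigma_s = 1,
                       sigma_a = 1, g = 0, dye = NULL) {
  mat <- optical_material(sigma_s, sigma_a, g = g, dye = dye)
  voxel_grid(array(1L, dim = rep(n, 3)), spacing = spacing_um,
             materials = list("1" = mat))
}

# two-slab grid along z: material 1 for the lower half, 2 for the upper
two_slab_grid <- function(n = 8, spacing_um = 1250, st1 = 0.5, st2 = 2) {
  labs <- array(1L, dim = c(n, n, n))
  labs[, , (n / 2 + 1):n] <- 2L
  voxel_grid(labs, spacing = spacing_um,
             materials = list("1" = optical_material(0, st1, g = 0),
                              "2" = optical_material(0, st2, g = 0)))
}

# small absorbing scene with a dilute dye, used by the quadrature-oracle
# and estimator-consistency tests
oracle_scene <- function(g = 0.6, c_molar = 1e-4, width = 1, height = 1) {
  dye <- dye_solution(alexa_fluor("AF488"), c_molar)
  mat <- optical_material(0.5, 0.2, g = g, dye = dye)
  vg <- voxel_grid(array(1L, dim = c(8, 8, 8)), spacing = 100,
                   materials = list("1" = mat))
  li <- rect_light(corner = c(-1100, -1100, -300),
                   edge1 = c(3000, 0, 0), edge2 = c(0, 3000, 0),
                   emission = monochromatic_emission(495))
  cam <- camera(position = c(400, 400, -1200), lookat = c(400, 400, 400),
                vfov = 30, width = width, height = height)
  scene(vg, cam, li)
}

# unit cube as 12 outward-oriented triangles (vertices in um)
cube_mesh <- function(lo = c(0, 0, 0), hi = c(10, 10, 10)) {
  v <- rbind(c(lo[1], lo[2], lo[3]), c(hi[1], lo[2], lo[3]),
             c(hi[1], hi[2], lo[3]), c(lo[1], hi[2], lo[3]),
             c(lo[1], lo[2], hi[3]), c(hi[1], lo[2], hi[3]),
             c(hi[1], hi[2], hi[3]), c(lo[1], hi[2], hi[3]))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),    # z = lo
             c(5, 6, 7), c(5, 7, 8),    # z = hi
             c(1, 2, 6), c(1, 6, 5),    # y = lo
             c(3, 4, 8), c(3, 8, 7),    # y = hi
             c(2, 3, 7), c(2, 7, 6),    # x = hi
             c(4, 1, 5), c(4, 5, 8))    # x = lo
  tri_mesh(v, f)
}

# ---------------------------------------------------------------------------
# Independent quadrature oracle for the single-scatter (one-vertex)
# fluorescence integral along the center camera ray:
#   I = phi p_m(lm) L_e mu_a^f(lx) *
#       int_t0^t1 exp(-sigma_t(lm) (s - t0)) *
#         int_A f_p G tau_x dA  ds
# Everything here is computed from the S3 scene objects with plain
# midpoint quadrature; none of the tracer code paths are used.

seg_box_exit_len <- function(p, q, lo, hi) {
  # length of segment p -> q inside the box [lo, hi] (p inside)
  d <- q - p
  tmax <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-15) next
    t1 <- (lo[ax] - p[ax]) / d[ax]
    t2 <- (hi[ax] - p[ax]) / d[ax]
    tpos <- max(t1, t2)
    tmax <- min(tmax, tpos)
  }
  sqrt(sum(d^2)) * max(tmax, 0)
}

oracle_single_scatter <- function(sc, lambda_m, ns = 400, nl = 40) {
  vg <- sc$grid
  mat <- fluortrace:::grid_material(vg, 1L)
  fl <- mat$dye$fluorophore
  wg <- fl$grid
  im <- grid_bin(wg, lambda_m)
  st <- material_sigma_t(mat)
  maf <- fluortrace:::material_mu_af(mat)
  pm <- emission_pdf(fl)$values
  li <- sc$light
  ix <- which(li$emission$values > 0)
  stopifnot(length(ix) == 1)
  le <- li$emission$values[ix]

  # geometry in mm
  cam_p <- sc$camera$position / 1000
  fwd <- (sc$camera$lookat - sc$camera$position)
  fwd <- fwd / sqrt(sum(fwd^2))
  lo <- vg$origin / 1000
  hi <- lo + vg$dims * vg$spacing / 1000
  # ray-box overlap
  t0 <- 0; t1 <- Inf
  for (ax in 1:3) {
    if (abs(fwd[ax]) < 1e-15) next
    ta <- (lo[ax] - cam_p[ax]) / fwd[ax]
    tb <- (hi[ax] - cam_p[ax]) / fwd[ax]
    t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
  }
  stopifnot(t1 > t0)
  corner <- li$corner / 1000
  e1 <- li$edge1 / 1000
  e2 <- li$edge2 / 1000
  nrm <- li$normal
  area <- li$area_um2 / 1e6
  st_m <- st[im]
  st_x <- st[ix]

  smid <- t0 + (t1 - t0) * (seq_len(ns) - 0.5) / ns
  ds <- (t1 - t0) / ns
  u1 <- (seq_len(nl) - 0.5) / nl
  total <- 0
  for (s in smid) {
    x <- cam_p + s * fwd
    acc <- 0
    for (a in u1) for (b in u1) {
      xl <- corner + a * e1 + b * e2
      dv <- xl - x
      r2 <- sum(dv^2)
      r <- sqrt(r2)
      wl <- dv / r
      cosl <- -sum(nrm * wl)
      if (cosl <= 0) next
      fp <- phase_eval(mat$g, sum(fwd * wl))
      tau <- exp(-st_x * seg_box_exit_len(x, xl, lo, hi))
      acc <- acc + fp * (cosl / r2) * tau
    }
    inner <- acc * area / (nl * nl)
    total <- total + exp(-st_m * (s - t0)) * inner * ds
  }
  fl$phi * pm[im] * le * maf[ix] * total
}
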