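test_that("total absorption and extinction compose base and dye terms", {
  vac <- homog_grid(sigma_s = 0, sigma_a = 0)
  expect_equal(total_extinction(vac, c(0, 0, 0), 500), 0)
  s0 <- dye_solution(alexa_fluor("AF488"), 0)
  g0 <- homog_grid(sigma_s = 0.5, sigma_a = 0.01, dye = s0)
  expect_equal(total_absorption(g0, c(1, 1, 1), 495), 0.01)
  s <- dye_solution(alexa_fluor("AF488"), 0.4)
  g1 <- homog_grid(sigma_s = 0.5, sigma_a = 0.01, dye = s)
  expect_equal(total_absorption(g1, c(1, 1, 1), 495),
               0.01 + fluorescence_absorption_coefficient(s, 495))
  expect_equal(total_extinction(g1, c(1, 1, 1), 495),
               0.51 + fluorescence_absorption_coefficient(s, 495))
  expect_error(total_absorption(g1, c(8, 0, 0), 495), "out of range")
})

test_that("mu_a dominates mu_a^f for every material", {
  s <- dye_solution(alexa_fluor("AF633"), 0.4)
  m <- optical_material(1, 0.05, dye = s)
  expect_true(all(material_mu_a(m) >= fluortrace:::material_mu_af(m)))
})

test_that("majorant dominates a random labeled grid (exhaustive check)", {
  set.seed(7)
  mats <- list(
    "1" = optical_material(0.3, 0.1, g = 0),
    "2" = optical_material(2, 0.5, g = 0,
                           dye = dye_solution(alexa_fluor("AF488"), 0.01)),
    "3" = optical_material(0, 5, g = 0))
  labs <- array(sample(0:3, 8^3, replace = TRUE), dim = c(8, 8, 8))
  vg <- voxel_grid(labs, spacing = 10, materials = mats)
  mj <- build_majorant(vg)
  wl <- mj$grid$wavelengths
  for (lam in wl[seq(1, 501, by = 25)]) {
    bin <- grid_bin(mj$grid, lam)
    mx <- 0
    for (l in 1:3) {
      if (!any(labs == l)) next
      mx <- max(mx, material_sigma_t(mats[[as.character(l)]])[bin])
    }
    expect_equal(mj$mu_bar[bin], mx)
    # dominate every voxel
    expect_true(all(vapply(0:3, function(l) {
      st <- if (l == 0) 0 else material_sigma_t(mats[[as.character(l)]])[bin]
      st <= mj$mu_bar[bin] + 1e-12
    }, logical(1))))
  }
  # homogeneous grid: majorant equals sigma_t exactly
  hg <- homog_grid(sigma_s = 0.7, sigma_a = 0.3)
  expect_equal(build_majorant(hg)$mu_bar,
               material_sigma_t(fluortrace:::grid_material(hg, 1L)))
})

test_that("water-baseline materials scale linearly and order transmittance", {
  m1 <- water_baseline_material(1)
  m1000 <- water_baseline_material(1000)
  expect_equal(material_sigma_t(m1), rep(0.001, 501))
  expect_equal(material_sigma_t(m1000), 1000 * material_sigma_t(m1))
  expect_error(water_baseline_material(0), "positive")
  # Beer-Lambert through a fixed 1 mm slab: strictly ordered transmittance
  taus <- vapply(c(10, 100, 1000), function(mult) {
    vg <- voxel_grid(array(1L, dim = c(4, 4, 4)), spacing = 250,
                     materials = list("1" = water_baseline_material(mult)))
    transmittance(vg, c(500, 500, -10), c(500, 500, 1010), 500,
                  method = "exact")
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_equal(taus, exp(-c(10, 100, 1000) * 0.001), tolerance = 1e-6)
})

test_that("volume IO round-trips and checks sizes", {
  labs <- array(0L, dim = c(16, 16, 16))
  labs[4:8, 5:9, 6:10] <- 1L
  vg <- voxel_grid(labs, spacing = 2.5, origin = c(-1, 0, 3),
                   materials = list("1" = optical_material(1, 0.1)))
  stem <- file.path(withr::local_tempdir(), "vol")
  write_volume(vg, stem, format = "nrrd")
  expect_equal(file.size(paste0(stem, ".raw")), 4096)
  expect_true(file.exists(paste0(stem, ".nhdr")))
  back <- read_volume(stem, materials = vg$materials)
  expect_identical(back$labels, vg$labels)
  expect_equal(back$spacing, 2.5)
  expect_equal(back$origin, c(-1, 0, 3))
  # truncated raw file is rejected
  writeBin(as.raw(rep(0, 100)), paste0(stem, ".raw"))
  expect_error(read_volume(stem), "promises")
})

test_that("annotation is order-independent", {
  labs <- array(1L, dim = c(2, 2, 2))
  base <- voxel_grid(labs, spacing = 1,
                     materials = list("1" = optical_material(0, 0)))
  dye <- dye_solution(alexa_fluor("AF568"), 0.2)
  a <- set_material_dye(set_material_optics(base, 1, 2, 0.3, g = 0.5), 1, dye)
  b <- set_material_optics(set_material_dye(base, 1, dye), 1, 2, 0.3,
                           g = 0.5)
  ma <- fluortrace:::grid_material(a, 1L)
  mb <- fluortrace:::grid_material(b, 1L)
  expect_equal(material_sigma_t(ma), material_sigma_t(mb))
  expect_equal(ma$g, mb$g)
  expect_equal(ma$dye$concentration, mb$dye$concentration)
})

test_that("labels without material entries are rejected", {
  expect_error(voxel_grid(array(2L, dim = c(2, 2, 2)), spacing = 1,
                          materials = list("1" = optical_material(0, 0))),
               "no material")
})
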