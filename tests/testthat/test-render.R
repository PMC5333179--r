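test_that("Henyey-Greenstein phase function normalizes and samples correctly", {
  # integral over the sphere is 1: 2 pi int f(cos) dcos
  for (g in c(0, -0.3, 0.5, 0.9)) {
    q <- stats::integrate(function(ct) 2 * pi * phase_eval(g, ct), -1, 1,
                          rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  expect_equal(phase_eval(0, c(-1, 0, 1)), rep(1 / (4 * pi), 3))
  expect_error(phase_eval(1, 0), "g")
  # sampled mean cosine equals g within 3 standard errors
  for (g in c(0, 0.9)) {
    d <- phase_sample(g, n = 1e5, seed = 2)
    expect_equal(sqrt(rowSums(d^2) |> mean()), 1, tolerance = 1e-9)
    ct <- d[, 3]
    se <- stats::sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se + 1e-12)
  }
})

test_that("woodcock tracking reproduces exponential free paths", {
  # vacuum: always escape
  vac <- homog_grid(sigma_s = 0, sigma_a = 0)
  d <- sample_free_path_woodcock(vac, c(5000, 5000, -1), c(0, 0, 1), 500,
                                 n = 100, seed = 1)
  expect_true(all(is.infinite(d)))
  # homogeneous medium: KS test against Exponential(sigma_t)
  hg <- homog_grid(n = 8, spacing_um = 1250, sigma_s = 1, sigma_a = 1)
  d <- sample_free_path_woodcock(hg, c(5000, 5000, 0), c(0, 0, 1), 500,
                                 n = 1e5, seed = 7)
  d_mm <- d[is.finite(d)] / 1000
  expect_gt(length(d_mm) / length(d), 0.999)
  expect_gt(stats::ks.test(d_mm, "pexp", 2)$p.value, 0.01)
})

test_that("two-slab collision depths follow the piecewise-exponential law", {
  vg <- two_slab_grid(n = 8, spacing_um = 1250, st1 = 0.5, st2 = 2)
  d <- sample_free_path_woodcock(vg, c(5000, 5000, 0), c(0, 0, 1), 500,
                                 n = 1e5, seed = 11)
  d_mm <- d[is.finite(d)] / 1000
  cdf <- function(q) {
    ifelse(q <= 5, 1 - exp(-0.5 * q),
           1 - exp(-2.5 - 2 * (q - 5)))
  }
  expect_gt(stats::ks.test(d_mm, cdf)$p.value, 0.01)
})

test_that("transmittance estimates are unbiased and match Beer-Lambert", {
  vac <- homog_grid(sigma_s = 0, sigma_a = 0)
  expect_equal(transmittance(vac, c(0, 0, -10), c(0, 0, 10010), 500), 1)
  hg <- homog_grid(n = 8, spacing_um = 1250, sigma_s = 0.4, sigma_a = 0.6)
  a <- c(5000, 5000, -1)
  b <- c(5000, 5000, 1000)  # 1 mm of medium, sigma_t = 1
  expect_equal(transmittance(hg, a, b, 500, method = "exact"), exp(-1),
               tolerance = 1e-4)
  est <- transmittance(hg, a, b, 500, n = 5e5, seed = 3)
  expect_lt(abs(mean(est) - exp(-1)) / exp(-1), 0.005)
  # opaque occluder drives transmittance to zero
  thick <- homog_grid(n = 8, spacing_um = 1250, sigma_s = 0, sigma_a = 5000)
  expect_lt(transmittance(thick, a, b, 500, method = "exact"), 1e-300)
})

test_that("event classification follows the Fig-3 taxonomy probabilities", {
  # dye-free material never fluoresces
  m0 <- optical_material(0.7, 0.3, g = 0)
  set.seed(1)
  ev <- classify_event(m0, 500, n = 2000)
  expect_false(any(ev == "fluorescence"))
  # pure fluorescent absorber: every collision takes the inelastic branch
  af <- alexa_fluor("AF488")
  pure <- optical_material(0, 0, g = 0, dye = dye_solution(af, 0.1))
  ev <- classify_event(pure, 495, n = 500)
  expect_true(all(ev == "fluorescence"))
  # branch frequencies (0.7, 0.15, 0.15) within 3 binomial sigmas
  muaf495 <- fluorescence_absorption_coefficient(dye_solution(af, 0.1), 495)
  mat <- optical_material(sigma_s = 7 / 3 * muaf495 * 2,
                          sigma_a_base = muaf495, g = 0,
                          dye = dye_solution(af, 0.1))
  st <- material_sigma_t(mat)[grid_bin(mat$grid, 495)]
  expect_equal(mat$sigma_s$values[grid_bin(mat$grid, 495)] / st, 0.7)
  set.seed(99)
  n <- 1e5
  ev <- classify_event(mat, 495, n = n)
  freq <- table(factor(ev, levels = c("elastic_scatter", "fluorescence",
                                      "absorb_terminate"))) / n
  for (i in seq_along(freq)) {
    p <- c(0.7, 0.15, 0.15)[i]
    expect_lt(abs(freq[[i]] - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_error(classify_event(optical_material(0, 0, g = 0), 500),
               "sigma_t = 0")
})

test_that("direct light connections obey inverse-square and attenuation", {
  sc <- oracle_scene(g = 0)
  # event in vacuum (outside the block, on the light's side), tiny light:
  # ~ Le * cos * A / d^2 * f_p
  ev <- c(400, 400, -100)
  tiny <- rect_light(corner = c(395, 395, -600), edge1 = c(10, 0, 0),
                     edge2 = c(0, 10, 0),
                     emission = monochromatic_emission(495))
  sc$light <- tiny
  got <- mean(direct_light_at_emission(sc, ev, 495, incoming = c(0, 0, 1),
                                       g = 0, n = 64, seed = 1))
  d_mm <- 0.5
  want <- 1 * (100 / 1e6) / d_mm^2 * (1 / (4 * pi))
  expect_equal(got, want, tolerance = 0.01)
  # fully occluded by an opaque wall
  sc2 <- oracle_scene()
  wall <- optical_material(0, 1e9, g = 0)
  sc2$grid$materials[["1"]] <- wall
  got <- direct_light_at_emission(sc2, c(400, 400, 900), 495, n = 16,
                                  seed = 2)
  expect_true(all(got == 0))
})

test_that("dye-free and out-of-band scenes render identically zero", {
  # no dye anywhere: the fluorescence visibility never gets set
  vg <- homog_grid(n = 4, spacing_um = 10, sigma_s = 5, sigma_a = 1)
  cam <- camera(c(20, 20, -60), c(20, 20, 20), vfov = 40, width = 4,
                height = 4)
  li <- rect_light(c(-20, -20, -30), c(80, 0, 0), c(0, 80, 0),
                   monochromatic_emission(495))
  img <- render(scene(vg, cam, li),
                render_config(spp = 8, spectral_samples = 8, seed = 1))
  expect_true(all(img$values == 0))
  # dye present but illuminated outside its excitation band
  sc <- dye_block_scene("AF488", illumination = 700, width = 8, height = 8)
  img <- render(sc, render_config(spp = 8, spectral_samples = 8, seed = 1))
  expect_true(all(img$values == 0))
})

test_that("rendering is bit-identical for a fixed seed", {
  sc <- dye_block_scene("AF488", width = 8, height = 8)
  cfg <- render_config(spp = 8, spectral_samples = 8, seed = 5)
  a <- render(sc, cfg)
  b <- render(sc, cfg)
  expect_identical(a$values, b$values)
  c2 <- render(sc, render_config(spp = 8, spectral_samples = 8, seed = 6))
  expect_false(identical(a$values, c2$values))
})

test_that("single-scatter radiance matches the quadrature oracle", {
  sc <- oracle_scene(g = 0.6)
  lam <- 519
  want <- oracle_single_scatter(sc, lam)
  for (est in c("collision", "event")) {
    cfg <- render_config(spp = 1, spectral_samples = 1, max_bounces = 1,
                         seed = 21, estimator = est)
    x <- trace_path(sc, cfg, pixel = c(0, 0), lambda = lam, n = 1e4,
                    seed = 21, jitter = FALSE)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(se / want, 0.2)  # the comparison has teeth
    expect_lt(abs(mean(x) - want), 3 * se)
  }
})

test_that("wavelengths below a non-overlapping source line stay dark", {
  # custom dye with disjoint, band-limited excitation and emission
  g <- default_grid()
  fl <- fluorophore("stokes",
                    gaussian_spectrum(420, 30, g),
                    gaussian_spectrum(560, 30, g),
                    phi = 0.8, epsilon = 5e4, mw = 1)
  sc <- dye_block_scene(fl, width = 8, height = 8, illumination = 420)
  img <- render(sc, render_config(spp = 16, spectral_samples = 16,
                                  seed = 1))
  wl <- img$grid$wavelengths
  expect_true(all(img$values[, , wl <= 420] == 0))
  expect_gt(sum(img$values), 0)
})

test_that("instrumented paths carry at most one wavelength change", {
  # at max_bounces = 1 the single vertex is the inelastic one; radiance
  # from a 2-vertex-only configuration must come from elastic + inelastic,
  # never two inelastic: with sigma_s = 0 every deeper bounce budget
  # changes nothing because the walk terminates at the first absorption
  sc <- oracle_scene(g = 0)
  m <- fluortrace:::grid_material(sc$grid, 1L)
  m$sigma_s <- spectrum_fl(rep(0, 501), m$grid)
  sc$grid$materials[["1"]] <- m
  a <- trace_path(sc, render_config(max_bounces = 1, seed = 3),
                  lambda = 519, n = 4000, seed = 3)
  b <- trace_path(sc, render_config(max_bounces = 32, seed = 3),
                  lambda = 519, n = 4000, seed = 3)
  expect_identical(a, b)
})

test_that("spectral images convert to plausible RGB and round-trip on disk", {
  sc <- dye_block_scene("AF488", width = 4, height = 4)
  img <- render(sc, render_config(spp = 4, spectral_samples = 8, seed = 2))
  # all-zero image is black
  zero <- img
  zero$values[] <- 0
  expect_true(all(spectral_to_rgb(zero) == 0))
  # monochromatic 550 nm is green-dominant
  mono <- img
  mono$values[] <- 0
  mono$values[, , grid_bin(img$grid, 550)] <- 1
  rgb <- spectral_to_rgb(mono, gamma = FALSE)
  expect_gt(rgb[1, 1, 2], rgb[1, 1, 1])
  expect_gt(rgb[1, 1, 2], rgb[1, 1, 3])
  # float32 round trip
  stem <- file.path(withr::local_tempdir(), "img")
  write_spectral_image(img, stem)
  back <- read_spectral_image(stem)
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$grid$n, img$grid$n)
})
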