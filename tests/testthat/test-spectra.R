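test_that("wavelength grids enforce their invariants", {
  g <- default_grid()
  expect_equal(g$n, 501L)
  expect_equal(g$wavelengths[1], 300)
  expect_equal(g$wavelengths[501], 800)
  expect_error(wavelength_grid(800, 300), "smaller")
  expect_error(wavelength_grid(300, 800, 0), "positive")
})

test_that("spectra are nonnegative, interpolate linearly and vanish off-grid", {
  g <- wavelength_grid(400, 410, 1)
  expect_error(spectrum_fl(c(rep(1, 10), -0.1), g), "nonnegative")
  s <- spectrum_fl(seq(0, 10), g)
  expect_equal(eval_spectrum(s, 404.5), 4.5)
  expect_equal(eval_spectrum(s, c(399, 411)), c(0, 0))
})

test_that("gaussian spectra honor FWHM and band-limiting", {
  s <- gaussian_spectrum(519, 60)
  expect_equal(eval_spectrum(s, 519), 1)
  expect_equal(eval_spectrum(s, 519 + 30), 0.5, tolerance = 1e-3)
  expect_equal(eval_spectrum(s, 519 - 30), 0.5, tolerance = 1e-3)
  expect_identical(eval_spectrum(s, 519 + 121), 0)  # beyond 2 FWHM
  expect_error(gaussian_spectrum(200, 60), "outside")
  expect_error(gaussian_spectrum(500, -1), "positive")
})

test_that("Alexa presets carry the published dye constants", {
  af <- alexa_fluor("AF488")
  expect_equal(af$phi, 0.92)
  expect_equal(af$epsilon, 73000)
  expect_equal(af$lambda_x_peak, 495)
  expect_equal(af$lambda_m_peak, 519)
  expect_equal(af$mw, 0.643)
  expect_equal(max(af$f_x$values), 1)
  # Stokes shift holds for all four packaged dyes
  for (nm in alexa_names()) {
    d <- alexa_fluor(nm)
    expect_gt(d$lambda_m_peak, d$lambda_x_peak)
    expect_equal(eval_spectrum(d$f_x, d$lambda_x_peak), 1)
  }
  expect_equal(alexa_fluor("AF350")$phi, 0.02)
  expect_equal(alexa_fluor("AF633")$epsilon, 159000)
  expect_error(alexa_fluor("AF999"), "unknown")
})

test_that("emission pdf normalizes exactly and peaks with f_m", {
  for (nm in alexa_names()) {
    p <- emission_pdf(alexa_fluor(nm))
    expect_lt(abs(sum(p$values) - 1), 1e-9)
  }
  expect_equal(peak_wavelength(emission_pdf(alexa_fluor("AF488"))), 519)
  # uniform emission band -> uniform masses
  g <- default_grid()
  fm <- rep(0, g$n)
  fm[grid_bin(g, 500):grid_bin(g, 509)] <- 0.7
  fl <- fluorophore("uni", gaussian_spectrum(450, 40, g),
                    spectrum_fl(fm, g), phi = 0.5, epsilon = 1e4, mw = 1)
  p <- emission_pdf(fl)
  expect_equal(p$values[grid_bin(g, 500):grid_bin(g, 509)], rep(0.1, 10))
  expect_equal(sum(p$values), 1)
})

test_that("emission sampling inverts the discrete CDF", {
  g <- default_grid()
  point <- rep(0, g$n)
  point[grid_bin(g, 519)] <- 1
  pm <- spectrum_fl(point, g)
  expect_equal(sample_emission_wavelength(pm, u = c(0, 0.4, 0.999)),
               c(519, 519, 519))
  unif <- rep(0, g$n)
  unif[grid_bin(g, 500):grid_bin(g, 509)] <- 0.1
  expect_equal(sample_emission_wavelength(spectrum_fl(unif, g), u = 0), 500)
  expect_error(sample_emission_wavelength(pm, u = 1.2), "\\[0, 1\\)")
})

test_that("emission sampling histogram matches the pdf (chi-square)", {
  pm <- emission_pdf(alexa_fluor("AF488"))
  set.seed(42)
  draws <- sample_emission_wavelength(pm, n = 1e5)
  wl <- pm$grid$wavelengths
  counts <- tabulate(match(draws, wl), nbins = length(wl))
  expected <- 1e5 * pm$values
  keep <- expected >= 5
  chi <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  # pool the tail mass into one cell
  chi <- chi + (sum(counts[!keep]) - sum(expected[!keep]))^2 /
    max(sum(expected[!keep]), 1e-12)
  df <- sum(keep)  # cells - 1 + pooled cell
  expect_gt(stats::pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("fluorescence absorption follows Beer-Lambert in 1/mm", {
  af <- alexa_fluor("AF488")
  s0 <- dye_solution(af, 0)
  expect_equal(fluorescence_absorption_coefficient(s0, c(400, 495, 600)),
               c(0, 0, 0))
  s <- dye_solution(af, 0.4)
  expect_equal(fluorescence_absorption_coefficient(s, 495),
               log(10) * 73000 * 0.4 / 10, tolerance = 1e-12)
  expect_identical(fluorescence_absorption_coefficient(s, 700), 0)
  # linear in concentration at every wavelength
  s2 <- dye_solution(af, 0.8)
  wl <- seq(380, 610, by = 10)
  expect_equal(fluorescence_absorption_coefficient(s2, wl),
               2 * fluorescence_absorption_coefficient(s, wl))
  expect_error(dye_solution(af, -1), "nonnegative")
})

test_that("excitation probability is phi times the absorption ratio", {
  af <- alexa_fluor("AF488")
  s <- dye_solution(af, 0.4)
  muaf <- fluorescence_absorption_coefficient(s, 495)
  expect_equal(excitation_probability(s, muaf, 495), 0.92)
  s633 <- dye_solution(alexa_fluor("AF633"), 0.4)
  muaf633 <- fluorescence_absorption_coefficient(s633, 632)
  expect_equal(excitation_probability(s633, muaf633, 632), 0.90)
  # perfect absorber/emitter and product-of-factors cases
  g <- default_grid()
  ideal <- fluorophore("ideal", gaussian_spectrum(495, 60, g),
                       gaussian_spectrum(519, 60, g), phi = 1,
                       epsilon = 1e4, mw = 1)
  si <- dye_solution(ideal, 0.1)
  mui <- fluorescence_absorption_coefficient(si, 495)
  expect_equal(excitation_probability(si, mui, 495), 1)
  half <- fluorophore("half", gaussian_spectrum(495, 60, g),
                      gaussian_spectrum(519, 60, g), phi = 0.5,
                      epsilon = 1e4, mw = 1)
  sh <- dye_solution(half, 0.1)
  muh <- fluorescence_absorption_coefficient(sh, 495)
  expect_equal(excitation_probability(sh, 2 * muh, 495), 0.25)
  # monotone non-decreasing in mu_a^f at fixed mu_a and phi
  ratios <- vapply(seq(0.1, 1, by = 0.1), function(r) {
    excitation_probability(s, muaf / r, 495)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_error(excitation_probability(s, 0, 495), "positive")
  expect_error(excitation_probability(s, muaf / 2, 495), "inconsistent")
})

test_that("joint fluorescence probability composes p_x and p_m", {
  af <- alexa_fluor("AF488")
  s <- dye_solution(af, 0.4)
  muaf <- fluorescence_absorption_coefficient(s, 495)
  pm <- emission_pdf(af)
  expect_equal(fluorescence_probability(s, muaf, 495, 519),
               0.92 * pm$values[grid_bin(af$grid, 519)])
  # p_x = 0 outside the excitation band
  expect_equal(fluorescence_probability(s, 1, 700, 519), 0)
})

test_that("spectrum CSV IO round-trips and rejects bad input", {
  s <- gaussian_spectrum(519, 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$values, s$values)
  # 5 nm tabulation resamples linearly with knots preserved
  wl5 <- seq(300, 800, by = 5)
  df <- data.frame(wavelength_nm = wl5,
                   value = eval_spectrum(s, wl5))
  utils::write.csv(df, path, row.names = FALSE)
  r5 <- read_spectrum(path)
  expect_equal(eval_spectrum(r5, wl5), df$value)
  utils::write.csv(data.frame(w = c(400, 410), v = c(1, -2)), path,
                   row.names = FALSE)
  expect_error(read_spectrum(path), "negative")
  utils::write.csv(data.frame(w = c(410, 400), v = c(1, 2)), path,
                   row.names = FALSE)
  expect_error(read_spectrum(path), "increasing")
})
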