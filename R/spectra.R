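#' Uniform wavelength grid
#'
#' All spectral quantities in the package live on a uniform wavelength grid.
#' The default grid spans 300--800 nm in 1 nm steps (501 samples), which
#' covers the excitation and emission bands of the common visible-range
#' fluorophores.
#'
#' @param lambda_min,lambda_max Grid range in nm (`lambda_min < lambda_max`).
#' @param delta_lambda Grid step in nm (positive).
#' @return An object of class `wavelength_grid` with fields `lambda_min`,
#'   `lambda_max`, `delta_lambda`, `n` and the vector of grid `wavelengths`.
#' @examples
#' g <- wavelength_grid()
#' g$n  # 501
#' @export
wavelength_grid <- function(lambda_min = 300, lambda_max = 800,
                            delta_lambda = 1) {
  stopifnot(is.numeric(lambda_min), is.numeric(lambda_max),
            is.numeric(delta_lambda), length(delta_lambda) == 1L)
  if (!(lambda_min < lambda_max)) {
    stop("`lambda_min` must be smaller than `lambda_max`", call. = FALSE)
  }
  if (delta_lambda <= 0) {
    stop("`delta_lambda` must be positive", call. = FALSE)
  }
  wl <- seq(lambda_min, lambda_max, by = delta_lambda)
  if (abs(wl[length(wl)] - lambda_max) > 1e-9) {
    stop("grid range must be an integer multiple of `delta_lambda`",
         call. = FALSE)
  }
  structure(
    list(lambda_min = lambda_min, lambda_max = lambda_max,
         delta_lambda = delta_lambda, n = length(wl), wavelengths = wl),
    class = "wavelength_grid")
}

#' Default 300--800 nm, 1 nm wavelength grid
#' @return A `wavelength_grid`.
#' @export
default_grid <- function() wavelength_grid(300, 800, 1)

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lambda_min, b$lambda_min)) &&
    isTRUE(all.equal(a$lambda_max, b$lambda_max)) &&
    isTRUE(all.equal(a$delta_lambda, b$delta_lambda))
}

#' Tabulated spectral distribution
#'
#' A nonnegative function of wavelength tabulated on a [wavelength_grid()].
#' Depending on its role the values are dimensionless (excitation/emission
#' shapes), radiance (source emission, measured SPDs) or attenuation
#' coefficients in 1/mm.
#'
#' @param values Nonnegative numeric vector, one value per grid point.
#' @param grid A `wavelength_grid` (default [default_grid()]).
#' @return An object of class `spectrum_fl`.
#' @export
spectrum_fl <- function(values, grid = default_grid()) {
  stopifnot(inherits(grid, "wavelength_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n) {
    stop(sprintf("`values` must have length %d (one per grid point)", grid$n),
         call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("spectrum values must be nonnegative and non-missing", call. = FALSE)
  }
  structure(list(grid = grid, values = values), class = "spectrum_fl")
}

#' @export
print.spectrum_fl <- function(x, ...) {
  cat(sprintf("<spectrum_fl> %g-%g nm by %g nm; max %.4g at %g nm\n",
              x$grid$lambda_min, x$grid$lambda_max, x$grid$delta_lambda,
              max(x$values), peak_of(x)))
  invisible(x)
}

peak_of <- function(spec) {
  spec$grid$wavelengths[which.max(spec$values)]
}

#' Evaluate a spectrum at arbitrary wavelengths
#'
#' Linear interpolation between grid points; zero outside the grid range.
#'
#' @param spec A [spectrum_fl()].
#' @param lambda Numeric vector of wavelengths in nm.
#' @return Numeric vector of the same length as `lambda`.
#' @export
eval_spectrum <- function(spec, lambda) {
  stopifnot(inherits(spec, "spectrum_fl"))
  out <- stats::approx(spec$grid$wavelengths, spec$values, xout = lambda,
                       method = "linear", yleft = 0, yright = 0,
                       rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Index of the nearest grid bin for a wavelength
#' @param grid A `wavelength_grid`.
#' @param lambda Wavelength(s) in nm; must lie inside the grid range.
#' @return 1-based bin index (integer vector).
#' @export
grid_bin <- function(grid, lambda) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (any(lambda < grid$lambda_min - 1e-9) ||
      any(lambda > grid$lambda_max + 1e-9)) {
    stop("wavelength outside grid range", call. = FALSE)
  }
  idx <- as.integer(round((lambda - grid$lambda_min) / grid$delta_lambda)) + 1L
  pmin(pmax(idx, 1L), grid$n)
}

#' Band-limited Gaussian spectral shape
#'
#' A Gaussian of the given full width at half maximum, peak-normalized to 1,
#' truncated to zero beyond `truncate` FWHMs from the peak. The truncation
#' makes the shape genuinely band-limited so that, e.g., illumination far
#' outside an excitation band excites exactly nothing.
#'
#' @param peak Peak wavelength in nm (must lie inside the grid).
#' @param fwhm Full width at half maximum in nm (positive).
#' @param grid A `wavelength_grid`.
#' @param truncate Support half-width in FWHM units (default 2).
#' @return A [spectrum_fl()] with maximum value 1 at `peak`.
#' @export
gaussian_spectrum <- function(peak, fwhm, grid = default_grid(),
                              truncate = 2) {
  stopifnot(is.numeric(peak), is.numeric(fwhm))
  if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  if (peak < grid$lambda_min || peak > grid$lambda_max) {
    stop("`peak` lies outside the wavelength grid", call. = FALSE)
  }
  wl <- grid$wavelengths
  v <- exp(-4 * log(2) * ((wl - peak) / fwhm)^2)
  v[abs(wl - peak) > truncate * fwhm] <- 0
  spectrum_fl(v, grid)
}

#' Fluorophore model
#'
#' Bundles the peak-normalized excitation spectrum `f_x`, the emission
#' spectrum `f_m`, the quantum yield `phi` (probability that an absorbed
#' photon is re-emitted), the molar absorptivity `epsilon` at the excitation
#' maximum (1/cm/M) and the molecular weight (kDa).
#'
#' @param name Identifier.
#' @param f_x,f_m Excitation and emission spectra ([spectrum_fl()]); `f_x`
#'   must be peak-normalized to 1.
#' @param phi Quantum yield in `[0, 1]`.
#' @param epsilon Molar absorptivity at the excitation maximum (1/cm/M, > 0).
#' @param mw Molecular weight in kDa.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, f_x, f_m, phi, epsilon, mw) {
  stopifnot(inherits(f_x, "spectrum_fl"), inherits(f_m, "spectrum_fl"))
  if (!grids_identical(f_x$grid, f_m$grid)) {
    stop("`f_x` and `f_m` must share one wavelength grid", call. = FALSE)
  }
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  if (abs(max(f_x$values) - 1) > 1e-9) {
    stop("`f_x` must be peak-normalized to 1", call. = FALSE)
  }
  if (max(f_m$values) <= 0) {
    stop("`f_m` must not be identically zero", call. = FALSE)
  }
  lx <- peak_of(f_x)
  lm <- peak_of(f_m)
  if (lm < lx) {
    stop("Stokes shift violated: emission peak below excitation peak",
         call. = FALSE)
  }
  structure(
    list(name = name, f_x = f_x, f_m = f_m, phi = phi, epsilon = epsilon,
         mw = mw, lambda_x_peak = lx, lambda_m_peak = lm,
         grid = f_x$grid),
    class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf(
    "<fluorophore> %s: ex %g nm / em %g nm, phi = %.3g, eps = %g /cm/M\n",
    x$name, x$lambda_x_peak, x$lambda_m_peak, x$phi, x$epsilon))
  invisible(x)
}

#' Fluorophore with Gaussian excitation and emission bands
#'
#' Synthetic stand-in for measured dye spectra: both bands are band-limited
#' Gaussians ([gaussian_spectrum()]), the excitation band peak-normalized
#' to 1. Measured two-column CSV spectra can be substituted via
#' [fluorophore()] + [read_spectrum()].
#'
#' @param name Identifier.
#' @param lambda_x_peak,lambda_m_peak Excitation/emission maxima in nm
#'   (inside the grid; `lambda_m_peak >= lambda_x_peak`).
#' @param fwhm_x,fwhm_m Band widths (FWHM) in nm.
#' @param phi Quantum yield.
#' @param epsilon Molar absorptivity at `lambda_x_peak` (1/cm/M).
#' @param mw Molecular weight (kDa).
#' @param grid Wavelength grid.
#' @return A [fluorophore()].
#' @examples
#' af488 <- make_gaussian_fluorophore("AF488", 495, 519, 60, 60,
#'                                    0.92, 73000, 0.643)
#' @export
make_gaussian_fluorophore <- function(name, lambda_x_peak, lambda_m_peak,
                                      fwhm_x = 60, fwhm_m = 60,
                                      phi, epsilon, mw,
                                      grid = default_grid()) {
  f_x <- gaussian_spectrum(lambda_x_peak, fwhm_x, grid)
  f_m <- gaussian_spectrum(lambda_m_peak, fwhm_m, grid)
  fluorophore(name, f_x, f_m, phi, epsilon, mw)
}

# Alexa Fluor family constants (max excitation/emission nm, quantum yield,
# molar absorptivity 1/cm/M, molecular weight kDa).
.alexa_table <- list(
  AF350 = list(lx = 346, lm = 442, phi = 0.02, eps = 19000,  mw = 0.410),
  AF488 = list(lx = 495, lm = 519, phi = 0.92, eps = 73000,  mw = 0.643),
  AF568 = list(lx = 578, lm = 603, phi = 0.69, eps = 88000,  mw = 0.792),
  AF633 = list(lx = 632, lm = 647, phi = 0.90, eps = 159000, mw = 1.200))

#' Packaged Alexa Fluor dye presets
#'
#' Four Alexa Fluor dyes (350, 488, 568, 633) with their published maximum
#' excitation/emission wavelengths, quantum yields, molar absorptivities and
#' molecular weights. The spectral *shapes* are synthetic 60 nm FWHM
#' Gaussians standing in for the measured curves (which are proprietary);
#' peak positions and scalar photophysics are the published values.
#'
#' @param name One of `"AF350"`, `"AF488"`, `"AF568"`, `"AF633"` (aliases
#'   `"AlexaFluor488"` etc. and bare numbers are accepted).
#' @param fwhm Gaussian FWHM used for both bands, in nm (default 60).
#' @param grid Wavelength grid.
#' @return A [fluorophore()].
#' @examples
#' alexa_fluor("AF488")$phi  # 0.92
#' @export
alexa_fluor <- function(name, fwhm = 60, grid = default_grid()) {
  key <- toupper(gsub("(ALEXA\\s*FLUOR\\s*|ALEXA|AF|\\s)", "",
                      toupper(as.character(name))))
  key <- paste0("AF", key)
  if (!key %in% names(.alexa_table)) {
    stop(sprintf("unknown dye preset '%s' (have: %s)", name,
                 paste(names(.alexa_table), collapse = ", ")), call. = FALSE)
  }
  p <- .alexa_table[[key]]
  make_gaussian_fluorophore(key, p$lx, p$lm, fwhm, fwhm, p$phi, p$eps, p$mw,
                            grid)
}

#' Names of the packaged dye presets
#' @return Character vector.
#' @export
alexa_names <- function() names(.alexa_table)

#' Fluorophore at a given concentration
#'
#' @param fluorophore A [fluorophore()].
#' @param concentration Molar concentration of the dye (mol/L, >= 0).
#' @return An object of class `dye_solution`.
#' @export
dye_solution <- function(fluorophore, concentration) {
  stopifnot(inherits(fluorophore, "fluorophore"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("`concentration` must be a single nonnegative number (mol/L)",
         call. = FALSE)
  }
  structure(list(fluorophore = fluorophore, concentration = concentration),
            class = "dye_solution")
}

#' Photon emission probability per wavelength bin
#'
#' The discrete emission pdf `p_m(lambda) = f_m(lambda) * dlambda /
#' integral(f_m)`, evaluated per grid bin; the bin masses sum to exactly 1.
#'
#' @param fluor A [fluorophore()].
#' @param grid Optional grid; must equal the fluorophore's grid.
#' @return A [spectrum_fl()] of per-bin probability masses.
#' @export
emission_pdf <- function(fluor, grid = NULL) {
  stopifnot(inherits(fluor, "fluorophore"))
  if (!is.null(grid) && !grids_identical(grid, fluor$grid)) {
    stop("`grid` does not match the fluorophore's grid", call. = FALSE)
  }
  v <- fluor$f_m$values
  s <- sum(v)
  if (s <= 0) stop("emission spectrum is identically zero", call. = FALSE)
  spectrum_fl(v / s, fluor$grid)
}

#' Sample emission wavelengths by inverse-CDF on the grid
#'
#' @param pdf A per-bin probability-mass [spectrum_fl()] (e.g. from
#'   [emission_pdf()]).
#' @param n Number of draws (ignored when `u` is supplied).
#' @param u Optional uniform variates in `[0, 1)`; supplying them makes the
#'   draw deterministic.
#' @return Numeric vector of grid wavelengths in nm.
#' @export
sample_emission_wavelength <- function(pdf, n = 1, u = NULL) {
  stopifnot(inherits(pdf, "spectrum_fl"))
  if (is.null(u)) u <- stats::runif(n)
  if (any(u < 0 | u >= 1)) stop("`u` must lie in [0, 1)", call. = FALSE)
  cdf <- cumsum(pdf$values)
  tot <- cdf[length(cdf)]
  if (tot <= 0) stop("pdf has zero total mass", call. = FALSE)
  idx <- findInterval(u * tot, cdf, left.open = FALSE) + 1L
  idx <- pmin(idx, pdf$grid$n)
  pdf$grid$wavelengths[idx]
}

#' Fluorescence absorption coefficient of a dye solution
#'
#' Beer--Lambert form `mu_a^f(lambda) = ln(10) * epsilon * C *
#' f_x(lambda)`, with the excitation spectrum peak-normalized (epsilon is
#' defined at the excitation maximum). `epsilon` is given per cm; the
#' result is returned per mm.
#'
#' @param solution A [dye_solution()].
#' @param lambda Wavelength(s) in nm; must lie inside the grid.
#' @return Coefficient(s) in 1/mm.
#' @examples
#' s <- dye_solution(alexa_fluor("AF488"), 0.4)
#' fluorescence_absorption_coefficient(s, 495)  # ~6723.4 /mm
#' @export
fluorescence_absorption_coefficient <- function(solution, lambda) {
  stopifnot(inherits(solution, "dye_solution"))
  fl <- solution$fluorophore
  if (any(lambda < fl$grid$lambda_min | lambda > fl$grid$lambda_max)) {
    stop("wavelength outside grid range", call. = FALSE)
  }
  fx <- eval_spectrum(fl$f_x, lambda)
  log(10) * fl$epsilon * solution$concentration * fx / 10  # 1/cm -> 1/mm
}

#' Photon excitation (absorption) probability
#'
#' `p_x(lambda_x) = phi * mu_a^f(lambda_x) / mu_a(lambda_x)`: the
#' probability that a photon absorbed at `lambda_x` was absorbed by the
#' fluorophore and re-emitted.
#'
#' @param solution A [dye_solution()].
#' @param medium_total_absorption Total absorption coefficient
#'   `mu_a(lambda_x)` of the medium (1/mm); must be at least `mu_a^f`.
#' @param lambda_x Excitation wavelength in nm.
#' @return Probability in `[0, 1]`.
#' @export
excitation_probability <- function(solution, medium_total_absorption,
                                   lambda_x) {
  muaf <- fluorescence_absorption_coefficient(solution, lambda_x)
  mua <- medium_total_absorption
  if (any(mua <= 0)) {
    stop("total absorption must be positive at `lambda_x`", call. = FALSE)
  }
  if (any(muaf > mua * (1 + 1e-12))) {
    stop("inconsistent medium: mu_a^f exceeds total mu_a", call. = FALSE)
  }
  solution$fluorophore$phi * muaf / mua
}

#' Joint fluorescence probability p_x(lambda_x) * p_m(lambda_m)
#'
#' @inheritParams excitation_probability
#' @param lambda_m Emission wavelength in nm (snapped to the nearest bin).
#' @return Probability mass.
#' @export
fluorescence_probability <- function(solution, medium_total_absorption,
                                     lambda_x, lambda_m) {
  px <- excitation_probability(solution, medium_total_absorption, lambda_x)
  pm <- emission_pdf(solution$fluorophore)
  bin <- grid_bin(solution$fluorophore$grid, lambda_m)
  px * pm$values[bin]
}

#' Read / write a spectrum as two-column CSV
#'
#' The interchange format is a CSV with header `wavelength_nm,value` and
#' ascending wavelengths. On read, values are linearly interpolated onto
#' the target grid (zero outside the tabulated range); a file sampled on
#' the grid itself round-trips exactly.
#'
#' @param path File path.
#' @param grid Target grid for [read_spectrum()].
#' @return [read_spectrum()] returns a [spectrum_fl()];
#'   [write_spectrum()] returns `path` invisibly.
#' @export
read_spectrum <- function(path, grid = default_grid()) {
  df <- utils::read.csv(path, header = TRUE)
  if (ncol(df) < 2) stop("spectrum CSV needs two columns", call. = FALSE)
  wl <- as.numeric(df[[1]])
  v <- as.numeric(df[[2]])
  if (anyNA(wl) || anyNA(v)) stop("non-numeric entries in spectrum CSV",
                                  call. = FALSE)
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(v < 0)) stop("negative spectrum values are not allowed",
                       call. = FALSE)
  out <- stats::approx(wl, v, xout = grid$wavelengths, method = "linear",
                       yleft = 0, yright = 0)$y
  out[is.na(out)] <- 0
  spectrum_fl(out, grid)
}

#' @rdname read_spectrum
#' @param spec A [spectrum_fl()] to write.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_fl"))
  utils::write.csv(
    data.frame(wavelength_nm = spec$grid$wavelengths, value = spec$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
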