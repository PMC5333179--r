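#' Measure the spectral power distribution of an image region
#'
#' Per-wavelength mean radiance over the pixels of a rectangular region,
#' taken from the raw spectral accumulators (never from RGB).
#'
#' @param img A [render()] result.
#' @param region Integer vector `c(x0, y0, x1, y1)` (1-based, inclusive
#'   pixel rectangle); `NULL` = full image.
#' @return An object of class `measured_spd` wrapping a [spectrum_fl()].
#' @export
measure_spd <- function(img, region = NULL) {
  stopifnot(inherits(img, "spectral_image"))
  if (is.null(region)) region <- c(1L, 1L, img$width, img$height)
  region <- as.integer(region)
  if (length(region) != 4L || region[1] > region[3] ||
      region[2] > region[4] || region[1] < 1L || region[2] < 1L ||
      region[3] > img$width || region[4] > img$height) {
    stop("empty or out-of-bounds region", call. = FALSE)
  }
  sub <- img$values[region[1]:region[3], region[2]:region[4], ,
                    drop = FALSE]
  v <- apply(sub, 3, mean)
  structure(list(spectrum = spectrum_fl(v, img$grid), region = region,
                 normalization = "none"),
            class = "measured_spd")
}

#' @export
print.measured_spd <- function(x, ...) {
  cat(sprintf("<measured_spd> region [%d,%d]-[%d,%d], total %.4g\n",
              x$region[1], x$region[2], x$region[3], x$region[4],
              sum(x$spectrum$values)))
  invisible(x)
}

as_spectrum <- function(x) {
  if (inherits(x, "measured_spd")) return(x$spectrum)
  if (inherits(x, "spectrum_fl")) return(x)
  stop("expected a spectrum_fl or measured_spd", call. = FALSE)
}

#' Wavelength of the SPD maximum
#'
#' Ties are broken toward the smaller wavelength.
#'
#' @param spd A [spectrum_fl()] or [measure_spd()] result.
#' @return Wavelength in nm.
#' @export
peak_wavelength <- function(spd) {
  s <- as_spectrum(spd)
  if (max(s$values) <= 0) stop("SPD is identically zero", call. = FALSE)
  s$grid$wavelengths[which.max(s$values)]
}

#' Pearson similarity of peak-normalized spectral profiles
#'
#' Both inputs are divided by their maxima and correlated over the union
#' of their supports (bins where either profile is positive).
#'
#' @param spd,reference [spectrum_fl()]s or [measure_spd()] results on
#'   the same grid.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
profile_similarity <- function(spd, reference) {
  a <- as_spectrum(spd)
  b <- as_spectrum(reference)
  if (!grids_identical(a$grid, b$grid)) {
    stop("profiles must share one wavelength grid", call. = FALSE)
  }
  if (max(a$values) <= 0 || max(b$values) <= 0) {
    stop("zero profile has no shape to compare", call. = FALSE)
  }
  av <- a$values / max(a$values)
  bv <- b$values / max(b$values)
  keep <- av > 0 | bv > 0
  if (stats::sd(av[keep]) == 0 || stats::sd(bv[keep]) == 0) {
    stop("zero-variance profile over the union support", call. = FALSE)
  }
  stats::cor(av[keep], bv[keep])
}

#' Homogeneous dye-block validation scene
#'
#' The standard emission-validation scene: a cubic block of `n_vox^3`
#' voxels filled with one dye solution, illuminated head-on by a
#' monochromatic rectangular source and viewed by a pinhole camera on the
#' same side. The voxel spacing is chosen so that the block's optical
#' depth at the dye's emission maximum equals `target_optical_depth`
#' (default 0.25): an optically thin sample, the rendering analogue of
#' the short cuvette path length spectroscopists use so that
#' inner-filter reabsorption does not distort the recorded emission
#' profile.
#'
#' @param fluor A [fluorophore()] or a preset name for [alexa_fluor()].
#' @param concentration Dye concentration in mol/L (default 0.4).
#' @param illumination Source line in nm (default: the dye's excitation
#'   maximum).
#' @param n_vox Voxels per cube edge (default 16).
#' @param target_optical_depth `sigma_t(lambda_m_peak) * extent` of the
#'   block.
#' @param sigma_s,sigma_a_base Background scattering / absorption of the
#'   solution (1/mm); the default scattering level is cortex-like.
#' @param g Phase anisotropy; a stirred dye solution scatters nearly
#'   isotropically, hence `g = 0` here (tissue-like forward scattering
#'   remains the default of [optical_material()]).
#' @param width,height Film resolution in pixels.
#' @return A [scene()].
#' @export
dye_block_scene <- function(fluor, concentration = 0.4,
                            illumination = NULL, n_vox = 16,
                            target_optical_depth = 0.25,
                            sigma_s = 40, sigma_a_base = 0.1, g = 0,
                            width = 32, height = 32) {
  if (is.character(fluor)) fluor <- alexa_fluor(fluor)
  stopifnot(inherits(fluor, "fluorophore"))
  sol <- dye_solution(fluor, concentration)
  mu_em <- log(10) * fluor$epsilon * concentration / 10 *
    eval_spectrum(fluor$f_x, fluor$lambda_m_peak)  # mu_a^f at emission max
  sigma_peak <- mu_em + sigma_s + sigma_a_base
  extent_um <- target_optical_depth / sigma_peak * 1000
  spacing <- extent_um / n_vox
  mat <- optical_material(sigma_s, sigma_a_base, g = g, dye = sol,
                          grid = fluor$grid)
  vg <- voxel_grid(array(1L, dim = rep(n_vox, 3)), spacing = spacing,
                   origin = c(0, 0, 0), materials = list("1" = mat))
  E <- extent_um
  if (is.null(illumination)) illumination <- fluor$lambda_x_peak
  li <- rect_light(corner = c(-E, -E, -0.5 * E),
                   edge1 = c(3 * E, 0, 0), edge2 = c(0, 3 * E, 0),
                   emission = monochromatic_emission(illumination, 1,
                                                     fluor$grid))
  cam <- camera(position = c(E / 2, E / 2, -1.5 * E),
                lookat = c(E / 2, E / 2, E / 2), up = c(0, 1, 0),
                vfov = 32, width = width, height = height)
  scene(vg, cam, li)
}

scene_primary_dye <- function(sc) {
  for (l in used_material_labels(sc$grid)) {
    m <- grid_material(sc$grid, l)
    if (!is.null(m$dye)) return(m$dye$fluorophore)
  }
  NULL
}

#' Excitation-wavelength scan
#'
#' Renders the same scene once per illumination line and reports, for each
#' line, the maximum and the integral of the measured SPD relative to the
#' reference run (by default the run at the dye's excitation maximum,
#' whose relative amplitude is 1 by construction). The rank order of the
#' amplitudes follows the rank order of the excitation spectrum at the
#' illumination lines, up to Monte Carlo noise.
#'
#' @param sc A [scene()] (e.g. [dye_block_scene()]).
#' @param wavelengths Illumination lines in nm.
#' @param config A [render_config()]; run `i` uses `seed + i`.
#' @param reference_wavelength Line defining amplitude 1 (default: the
#'   scene dye's excitation maximum if scanned, otherwise the strongest
#'   run).
#' @param region SPD measurement region (see [measure_spd()]).
#' @return An object of class `excitation_scan`: a data frame with
#'   columns `wavelength`, `spd_max`, `spd_integral`, `rel_amplitude`,
#'   `rel_integral`, `excitation_value`, plus the per-run SPDs in
#'   `attr(, "spds")`.
#' @export
excitation_scan <- function(sc, wavelengths, config = render_config(),
                            reference_wavelength = NULL, region = NULL) {
  stopifnot(inherits(sc, "scene_fl"), length(wavelengths) >= 1)
  fl <- scene_primary_dye(sc)
  spds <- vector("list", length(wavelengths))
  mx <- integ <- numeric(length(wavelengths))
  for (i in seq_along(wavelengths)) {
    sci <- set_light_wavelength(sc, wavelengths[i])
    cfg <- config
    cfg$seed <- config$seed + i
    img <- render(sci, cfg)
    spd <- measure_spd(img, region)
    spds[[i]] <- spd
    mx[i] <- max(spd$spectrum$values)
    integ[i] <- sum(spd$spectrum$values) * spd$spectrum$grid$delta_lambda
  }
  if (is.null(reference_wavelength) && !is.null(fl) &&
      any(wavelengths == fl$lambda_x_peak)) {
    reference_wavelength <- fl$lambda_x_peak
  }
  ref <- if (!is.null(reference_wavelength)) {
    which(wavelengths == reference_wavelength)[1]
  } else which.max(mx)
  if (is.na(ref)) ref <- which.max(mx)
  fx <- if (!is.null(fl)) eval_spectrum(fl$f_x, wavelengths)
        else rep(NA_real_, length(wavelengths))
  out <- data.frame(wavelength = wavelengths, spd_max = mx,
                    spd_integral = integ,
                    rel_amplitude = if (mx[ref] > 0) mx / mx[ref] else mx,
                    rel_integral = if (integ[ref] > 0) integ / integ[ref]
                                   else integ,
                    excitation_value = fx)
  attr(out, "spds") <- spds
  class(out) <- c("excitation_scan", "data.frame")
  out
}

#' Write a validation report (CSVs + plots)
#'
#' Writes `spds.csv` (one wavelength column plus one column per named
#' SPD), `scan.csv` (the [excitation_scan()] table, if any) and PNG plots
#' of the normalized emission profiles and of the scan amplitudes.
#' Content is deterministic given the rendering seeds.
#'
#' @param results List with optional elements `spds` (named list of
#'   [measure_spd()] results or [spectrum_fl()]s) and `scan` (an
#'   [excitation_scan()] result).
#' @param out_dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
validation_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  written <- character(0)
  spds <- results$spds
  spd_path <- file.path(out_dir, "spds.csv")
  if (is.null(spds) || length(spds) == 0) {
    writeLines("wavelength_nm", spd_path)
  } else {
    wg <- as_spectrum(spds[[1]])$grid
    df <- data.frame(wavelength_nm = wg$wavelengths)
    nms <- names(spds)
    if (is.null(nms)) nms <- paste0("spd", seq_along(spds))
    for (i in seq_along(spds)) df[[nms[i]]] <- as_spectrum(spds[[i]])$values
    utils::write.csv(df, spd_path, row.names = FALSE, quote = FALSE)
    png_path <- file.path(out_dir, "emission_profiles.png")
    grDevices::png(png_path, width = 800, height = 500)
    graphics::matplot(df$wavelength_nm,
                      apply(as.matrix(df[, -1, drop = FALSE]), 2,
                            function(v) if (max(v) > 0) v / max(v) else v),
                      type = "l", lty = 1, lwd = 2,
                      xlab = "wavelength (nm)",
                      ylab = "normalized SPD", main = "Emission profiles")
    graphics::legend("topright", legend = nms, lty = 1,
                     col = seq_along(nms), lwd = 2)
    grDevices::dev.off()
    written <- c(written, png_path)
  }
  written <- c(written, spd_path)
  if (!is.null(results$scan)) {
    scan_path <- file.path(out_dir, "scan.csv")
    utils::write.csv(as.data.frame(results$scan), scan_path,
                     row.names = FALSE, quote = FALSE)
    png_path <- file.path(out_dir, "excitation_scan.png")
    grDevices::png(png_path, width = 800, height = 500)
    graphics::plot(results$scan$wavelength, results$scan$rel_amplitude,
                   type = "b", pch = 19, xlab = "illumination (nm)",
                   ylab = "relative SPD amplitude",
                   main = "Excitation scan")
    grDevices::dev.off()
    written <- c(written, scan_path, png_path)
  }
  invisible(written)
}
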