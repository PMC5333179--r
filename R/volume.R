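#' Optical material of a labeled voxel region
#'
#' Per-label optical description: elastic scattering coefficient `sigma_s`,
#' non-fluorescent absorption `sigma_a_base` (both 1/mm, flat scalars or
#' tabulated [spectrum_fl()]s), Henyey--Greenstein anisotropy `g`, and an
#' optional [dye_solution()]. Total absorption is
#' `mu_a(lambda) = sigma_a_base(lambda) + mu_a^f(lambda)`.
#'
#' @param sigma_s,sigma_a_base Scalars (flat spectra) or [spectrum_fl()]s,
#'   1/mm, nonnegative.
#' @param g Phase-function anisotropy, `-1 < g < 1` (default 0.9,
#'   brain-tissue-typical forward scattering).
#' @param dye Optional [dye_solution()].
#' @param grid Wavelength grid used to tabulate flat scalars.
#' @return An object of class `optical_material`.
#' @export
optical_material <- function(sigma_s = 0, sigma_a_base = 0, g = 0.9,
                             dye = NULL, grid = default_grid()) {
  as_spec <- function(x, what) {
    if (inherits(x, "spectrum_fl")) return(x)
    if (is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0) {
      return(spectrum_fl(rep(x, grid$n), grid))
    }
    stop(sprintf("`%s` must be a nonnegative scalar or a spectrum_fl", what),
         call. = FALSE)
  }
  sigma_s <- as_spec(sigma_s, "sigma_s")
  sigma_a_base <- as_spec(sigma_a_base, "sigma_a_base")
  if (!grids_identical(sigma_s$grid, sigma_a_base$grid)) {
    stop("`sigma_s` and `sigma_a_base` must share one grid", call. = FALSE)
  }
  if (!is.null(dye)) {
    stopifnot(inherits(dye, "dye_solution"))
    if (!grids_identical(dye$fluorophore$grid, sigma_s$grid)) {
      stop("dye grid does not match material grid", call. = FALSE)
    }
  }
  if (abs(g) >= 1) stop("`g` must satisfy -1 < g < 1", call. = FALSE)
  structure(list(sigma_s = sigma_s, sigma_a_base = sigma_a_base, g = g,
                 dye = dye, grid = sigma_s$grid),
            class = "optical_material")
}

#' Vacuum material (no interaction)
#' @param grid Wavelength grid.
#' @return An [optical_material()] with `sigma_t = 0` everywhere.
#' @export
vacuum_material <- function(grid = default_grid()) {
  optical_material(0, 0, g = 0, dye = NULL, grid = grid)
}

#' Water-referenced background material
#'
#' A flat material whose total extinction is `multiplier` times a pure-water
#' extinction baseline. The baseline defaults to a flat 0.001/mm constant
#' and can be overridden with a tabulated spectrum; the extinction is split
#' between scattering and absorption by the single-scattering `albedo`.
#'
#' @param multiplier Positive scale factor (e.g. 10, 100, 1000).
#' @param baseline Scalar (1/mm) or [spectrum_fl()] pure-water extinction.
#' @param albedo Fraction of extinction that is scattering (default 0.9).
#' @param g Anisotropy of the scattering part.
#' @param grid Wavelength grid.
#' @return An [optical_material()].
#' @export
water_baseline_material <- function(multiplier, baseline = 0.001,
                                    albedo = 0.9, g = 0.9,
                                    grid = default_grid()) {
  if (!is.numeric(multiplier) || multiplier <= 0) {
    stop("`multiplier` must be positive", call. = FALSE)
  }
  base <- if (inherits(baseline, "spectrum_fl")) baseline$values
          else rep(baseline, grid$n)
  st <- multiplier * base
  optical_material(spectrum_fl(albedo * st, grid),
                   spectrum_fl((1 - albedo) * st, grid),
                   g = g, grid = grid)
}

#' Per-bin coefficients of a material
#'
#' `material_mu_a()` returns the total absorption `sigma_a_base + mu_a^f`,
#' `material_sigma_t()` the total extinction `sigma_s + mu_a`, as vectors
#' over the whole grid (1/mm).
#'
#' @param mat An [optical_material()].
#' @return Numeric vector of length `grid$n`.
#' @export
material_mu_a <- function(mat) {
  stopifnot(inherits(mat, "optical_material"))
  mat$sigma_a_base$values + material_mu_af(mat)
}

#' @rdname material_mu_a
#' @export
material_sigma_t <- function(mat) {
  mat$sigma_s$values + material_mu_a(mat)
}

#' @rdname material_mu_a
#' @export
material_mu_af <- function(mat) {
  stopifnot(inherits(mat, "optical_material"))
  if (is.null(mat$dye)) return(rep(0, mat$grid$n))
  fl <- mat$dye$fluorophore
  log(10) * fl$epsilon * mat$dye$concentration * fl$f_x$values / 10
}

#' Labeled voxel volume
#'
#' A 3-D grid of material labels with a material table. Label 0 is
#' background (vacuum unless a material is explicitly assigned to it):
#' rays traverse unlabeled space unattenuated. Voxel `(i, j, k)` (0-based)
#' occupies the half-open box `[origin + (i,j,k)*spacing,
#' origin + (i+1,j+1,k+1)*spacing)` in world coordinates (micrometers).
#'
#' @param labels Integer 3-D array (or vector with `dims`) of material
#'   indices; 0 = background.
#' @param spacing Voxel edge length in micrometers.
#' @param origin World position of the (0,0,0) voxel corner (um).
#' @param materials Named or indexed list mapping label -> \
#'   [optical_material()]; entry `"0"` optionally assigns a background
#'   material.
#' @param dims Dimensions when `labels` is given as a plain vector.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(labels, spacing, origin = c(0, 0, 0),
                       materials = list(), dims = NULL) {
  if (is.null(dim(labels))) {
    if (is.null(dims)) stop("need `dims` for non-array labels", call. = FALSE)
    labels <- array(as.integer(labels), dim = dims)
  }
  if (length(dim(labels)) != 3L) stop("`labels` must be 3-D", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0)) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  if (!is.numeric(spacing) || spacing <= 0) {
    stop("`spacing` must be positive (um)", call. = FALSE)
  }
  used <- setdiff(sort(unique(as.vector(labels))), 0L)
  matkey <- function(l) as.character(l)
  for (l in used) {
    m <- materials[[matkey(l)]]
    if (is.null(m) && l <= length(materials)) m <- materials[[l]]
    if (is.null(m) || !inherits(m, "optical_material")) {
      stop(sprintf("label %d has no material entry", l), call. = FALSE)
    }
  }
  structure(list(labels = labels, dims = dim(labels), spacing = spacing,
                 origin = as.numeric(origin), materials = materials),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %dx%dx%d voxels, %g um spacing, %d material(s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              length(x$materials)))
  invisible(x)
}

grid_material <- function(vg, label) {
  if (label == 0L) {
    m <- vg$materials[["0"]]
    if (is.null(m)) return(NULL)  # background vacuum
    return(m)
  }
  m <- vg$materials[[as.character(label)]]
  if (is.null(m) && label <= length(vg$materials)) m <- vg$materials[[label]]
  m
}

check_voxel <- function(vg, voxel) {
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L ||
      any(voxel < 0L) || any(voxel >= vg$dims)) {
    stop("voxel index out of range (0-based)", call. = FALSE)
  }
  voxel
}

#' Total absorption / extinction at a voxel and wavelength
#'
#' `mu_a = sigma_a_base + mu_a^f` (zero-dye materials contribute no
#' fluorescence absorption); `sigma_t = sigma_s + mu_a`. Background voxels
#' without an assigned material are vacuum (`0`).
#'
#' @param vg A [voxel_grid()].
#' @param voxel Integer triple, 0-based voxel index.
#' @param lambda Wavelength in nm (snapped to the nearest grid bin).
#' @return Coefficient in 1/mm.
#' @export
total_absorption <- function(vg, voxel, lambda) {
  stopifnot(inherits(vg, "voxel_grid"))
  voxel <- check_voxel(vg, voxel)
  mat <- grid_material(vg, vg$labels[voxel[1] + 1L, voxel[2] + 1L,
                                     voxel[3] + 1L])
  if (is.null(mat)) return(0)
  material_mu_a(mat)[grid_bin(mat$grid, lambda)]
}

#' @rdname total_absorption
#' @export
total_extinction <- function(vg, voxel, lambda) {
  stopifnot(inherits(vg, "voxel_grid"))
  voxel <- check_voxel(vg, voxel)
  mat <- grid_material(vg, vg$labels[voxel[1] + 1L, voxel[2] + 1L,
                                     voxel[3] + 1L])
  if (is.null(mat)) return(0)
  material_sigma_t(mat)[grid_bin(mat$grid, lambda)]
}

#' Per-wavelength majorant extinction for woodcock tracking
#'
#' The pointwise maximum of `sigma_t(lambda)` over all materials present in
#' the grid; it dominates the extinction of every voxel at every grid
#' wavelength, as null-collision tracking requires.
#'
#' @param vg A [voxel_grid()].
#' @return An object of class `majorant_table`: list with `mu_bar`
#'   (numeric vector over the grid) and `grid`.
#' @export
build_majorant <- function(vg) {
  stopifnot(inherits(vg, "voxel_grid"))
  used <- sort(unique(as.vector(vg$labels)))
  wg <- NULL
  mu <- NULL
  for (l in used) {
    mat <- grid_material(vg, l)
    if (is.null(mat)) next
    st <- material_sigma_t(mat)
    if (is.null(mu)) { mu <- st; wg <- mat$grid } else mu <- pmax(mu, st)
  }
  if (is.null(mu)) { wg <- default_grid(); mu <- rep(0, wg$n) }
  structure(list(mu_bar = mu, grid = wg), class = "majorant_table")
}

#' Write / read a labeled volume as raw bytes + JSON sidecar
#'
#' Labels are stored as a little-endian 8-bit array (x fastest) in
#' `<path>.raw`; dims, spacing, origin and the number of materials go to a
#' `<path>.json` sidecar. With `format = "nrrd"` an additional detached
#' NRRD header `<path>.nhdr` referencing the raw file is written. The
#' material table itself is runtime state and is not serialized.
#'
#' @param vg A [voxel_grid()] (labels must fit in a byte).
#' @param path Path stem (without extension).
#' @param format `"raw"` or `"nrrd"` (raw + detached NRRD header).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vg, path, format = c("raw", "nrrd")) {
  stopifnot(inherits(vg, "voxel_grid"))
  format <- match.arg(format)
  if (max(vg$labels) > 255L) stop("labels exceed 8-bit range", call. = FALSE)
  raw_path <- paste0(path, ".raw")
  writeBin(as.raw(as.vector(vg$labels)), raw_path)
  meta <- list(dims = vg$dims, spacing_um = vg$spacing,
               origin_um = vg$origin, dtype = "uint8", order = "x-fastest",
               n_materials = length(vg$materials))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (format == "nrrd") {
    hdr <- c("NRRD0004", "type: uint8", "dimension: 3",
             sprintf("sizes: %d %d %d", vg$dims[1], vg$dims[2], vg$dims[3]),
             sprintf("spacings: %g %g %g", vg$spacing, vg$spacing,
                     vg$spacing),
             "encoding: raw", "endian: little",
             sprintf("data file: %s", basename(raw_path)))
    writeLines(hdr, paste0(path, ".nhdr"))
  }
  invisible(path)
}

#' @rdname write_volume
#' @param materials Material table to attach on read.
#' @export
read_volume <- function(path, materials = list()) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw_path <- paste0(path, ".raw")
  n <- prod(meta$dims)
  bytes <- readBin(raw_path, what = "raw", n = n + 1L)
  if (length(bytes) != n) {
    stop(sprintf("raw file has %d voxels, sidecar promises %d",
                 length(bytes), n), call. = FALSE)
  }
  voxel_grid(array(as.integer(bytes), dim = meta$dims),
             spacing = meta$spacing_um, origin = meta$origin_um,
             materials = materials)
}
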