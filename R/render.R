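#' Pinhole camera
#'
#' @param position,lookat,up World-space vectors in micrometers.
#' @param vfov Vertical field of view in degrees.
#' @param width,height Film resolution in pixels.
#' @return An object of class `camera_fl`.
#' @export
camera <- function(position, lookat, up = c(0, 1, 0), vfov = 40,
                   width = 32, height = 32) {
  stopifnot(length(position) == 3, length(lookat) == 3, length(up) == 3)
  if (vfov <= 0 || vfov >= 180) stop("`vfov` must be in (0, 180) degrees",
                                     call. = FALSE)
  if (width < 1 || height < 1) stop("film resolution must be positive",
                                    call. = FALSE)
  fwd <- lookat - position
  if (sum(fwd^2) == 0) stop("camera position equals look-at point",
                            call. = FALSE)
  structure(list(position = as.numeric(position),
                 lookat = as.numeric(lookat), up = as.numeric(up),
                 vfov = vfov, width = as.integer(width),
                 height = as.integer(height)),
            class = "camera_fl")
}

#' Rectangular (one-sided diffuse) area light
#'
#' The light emits from the face whose normal is `cross(edge1, edge2)`.
#'
#' @param corner Corner position (um).
#' @param edge1,edge2 Edge vectors spanning the rectangle (um).
#' @param emission A [spectrum_fl()] of emitted radiance per wavelength
#'   bin.
#' @return An object of class `light_fl`.
#' @export
rect_light <- function(corner, edge1, edge2, emission) {
  stopifnot(inherits(emission, "spectrum_fl"))
  n <- c(edge1[2] * edge2[3] - edge1[3] * edge2[2],
         edge1[3] * edge2[1] - edge1[1] * edge2[3],
         edge1[1] * edge2[2] - edge1[2] * edge2[1])
  area <- sqrt(sum(n^2))
  if (area <= 0) stop("degenerate light rectangle", call. = FALSE)
  structure(list(corner = as.numeric(corner), edge1 = as.numeric(edge1),
                 edge2 = as.numeric(edge2), normal = n / area,
                 area_um2 = area, emission = emission),
            class = "light_fl")
}

#' Monochromatic emission spectrum (single grid line)
#'
#' @param wavelength Line wavelength in nm (snapped to the nearest bin).
#' @param radiance Emitted radiance at the line (default 1).
#' @param grid Wavelength grid.
#' @return A [spectrum_fl()] with a single nonzero bin.
#' @export
monochromatic_emission <- function(wavelength, radiance = 1,
                                   grid = default_grid()) {
  v <- rep(0, grid$n)
  v[grid_bin(grid, wavelength)] <- radiance
  spectrum_fl(v, grid)
}

#' Sampling configuration of the renderer
#'
#' @param spp Paths per pixel and spectral sample (`N` in the estimator).
#' @param spectral_samples Emission wavelengths drawn per pixel sample
#'   (`N_lambda`), stratified over the scene's emission distribution.
#' @param max_bounces Maximum number of interaction vertices per path
#'   (the single fluorescence vertex counts as one).
#' @param seed Integer seed of the deterministic per-(pixel, sample)
#'   counter-based random streams.
#' @param rr_depth Vertex count at which Russian roulette starts.
#' @param rr_floor Roulette survival probability (unbiased reweighting).
#' @param estimator `"collision"` (default): next-event estimation at
#'   every real collision, with the fluorescence-branch probability
#'   marginalized analytically; `"event"`: the light is sampled only when
#'   the classified event is a fluorescence emission, with the
#'   vertex-selection probability divided out. Both are unbiased
#'   estimators of the same path integral; `"collision"` has far lower
#'   variance for dyes with a large Stokes shift.
#' @return An object of class `render_config`.
#' @export
render_config <- function(spp = 64, spectral_samples = 64, max_bounces = 32,
                          seed = 1, rr_depth = 16, rr_floor = 0.5,
                          estimator = c("collision", "event")) {
  estimator <- match.arg(estimator)
  if (spp < 1) stop("`spp` must be positive", call. = FALSE)
  if (spectral_samples < 1) stop("`spectral_samples` must be positive",
                                 call. = FALSE)
  if (max_bounces < 1) stop("`max_bounces` must be positive", call. = FALSE)
  if (rr_floor <= 0 || rr_floor > 1) stop("`rr_floor` must be in (0, 1]",
                                          call. = FALSE)
  structure(list(spp = as.integer(spp),
                 spectral_samples = as.integer(spectral_samples),
                 max_bounces = as.integer(max_bounces),
                 seed = as.integer(seed), rr_depth = as.integer(rr_depth),
                 rr_floor = rr_floor, estimator = estimator),
            class = "render_config")
}

#' Renderable scene
#'
#' @param grid A [voxel_grid()] (the participating medium).
#' @param camera A [camera()].
#' @param light A [rect_light()].
#' @return An object of class `scene_fl`.
#' @export
scene <- function(grid, camera, light) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(camera, "camera_fl"),
            inherits(light, "light_fl"))
  structure(list(grid = grid, camera = camera, light = light),
            class = "scene_fl")
}

#' Swap the light of a scene for a monochromatic line
#' @param sc A [scene()].
#' @param wavelength Line wavelength (nm).
#' @param radiance Line radiance.
#' @return The modified scene.
#' @export
set_light_wavelength <- function(sc, wavelength, radiance = 1) {
  stopifnot(inherits(sc, "scene_fl"))
  em <- monochromatic_emission(wavelength, radiance,
                               sc$light$emission$grid)
  sc$light <- rect_light(sc$light$corner, sc$light$edge1, sc$light$edge2, em)
  sc
}

# --------------------------------------------------------------------------
# Scene packing: flatten the S3 scene into the plain-vector structure the
# C++ core consumes. Lengths are converted um -> mm here, once.

used_material_labels <- function(vg) {
  used <- sort(unique(as.vector(vg$labels)))
  keep <- integer(0)
  for (l in used) if (!is.null(grid_material(vg, l))) keep <- c(keep, l)
  keep
}

pack_scene <- function(sc, config = render_config()) {
  vg <- sc$grid
  labs <- used_material_labels(vg)
  K <- length(labs)
  mats <- lapply(labs, function(l) grid_material(vg, l))
  wg <- if (K > 0) mats[[1]]$grid else default_grid()
  nb <- wg$n
  zero <- matrix(0, nb, max(K, 1))
  st <- ss <- ma <- maf <- pmm <- zero[, seq_len(max(K, 1)), drop = FALSE]
  gvec <- numeric(max(K, 1)); phiv <- numeric(max(K, 1))
  for (i in seq_len(K)) {
    m <- mats[[i]]
    ss[, i] <- m$sigma_s$values
    ma[, i] <- material_mu_a(m)
    maf[, i] <- material_mu_af(m)
    st[, i] <- ss[, i] + ma[, i]
    gvec[i] <- m$g
    phiv[i] <- if (!is.null(m$dye)) m$dye$fluorophore$phi else 0
    if (!is.null(m$dye)) {
      pmm[, i] <- emission_pdf(m$dye$fluorophore)$values
    }
  }
  relab <- array(0L, dim = vg$dims)
  for (i in seq_len(K)) relab[vg$labels == labs[i]] <- i
  maj <- if (K > 0) apply(st, 1, max) else rep(0, nb)

  # spectral sampling distribution: mixture of the emission pdfs of the
  # dyes present (uniform over the grid when the scene holds no dye)
  dyecols <- which(vapply(mats, function(m) !is.null(m$dye), logical(1)))
  spdf <- if (length(dyecols) > 0) {
    rowMeans(pmm[, dyecols, drop = FALSE])
  } else rep(1 / nb, nb)
  spdf <- spdf / sum(spdf)
  scdf <- cumsum(spdf)
  scdf[nb] <- 1

  cam <- sc$camera
  fwd <- cam$lookat - cam$position
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * cam$up[3] - fwd[3] * cam$up[2],
             fwd[3] * cam$up[1] - fwd[1] * cam$up[3],
             fwd[1] * cam$up[2] - fwd[2] * cam$up[1])
  rn <- sqrt(sum(right^2))
  if (rn == 0) stop("camera `up` is parallel to the view direction",
                    call. = FALSE)
  right <- right / rn
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])

  li <- sc$light
  list(dims = as.integer(vg$dims), origin = vg$origin / 1000,
       spacing = vg$spacing / 1000, labels = as.integer(relab),
       nb = as.integer(nb), K = as.integer(K),
       st = st, ss = ss, ma = ma, maf = maf, pm = pmm,
       g = gvec, phi = phiv, maj = maj,
       cam = list(pos = cam$position / 1000, right = right, up = upv,
                  fwd = fwd, tanhalf = tan(cam$vfov * pi / 360),
                  width = cam$width, height = cam$height),
       light = list(corner = li$corner / 1000, e1 = li$edge1 / 1000,
                    e2 = li$edge2 / 1000, normal = li$normal,
                    area = li$area_um2 / 1e6, Le = li$emission$values),
       spdf = spdf, scdf = scdf,
       max_bounces = config$max_bounces, rr_depth = config$rr_depth,
       rr_floor = config$rr_floor,
       nee_mode = if (identical(config$estimator, "event")) 1L else 0L,
       grid = wg)
}

# a pack for medium-only queries (free paths, transmittance)
pack_volume <- function(vg, max_bounces = 32L) {
  cam0 <- camera(c(0, 0, -1), c(0, 0, 0), width = 1, height = 1)
  li0 <- rect_light(c(0, 0, -1), c(1, 0, 0), c(0, 1, 0),
                    monochromatic_emission(500))
  grid0 <- vg
  pack_scene(structure(list(grid = grid0, camera = cam0, light = li0),
                       class = "scene_fl"),
             render_config(max_bounces = max_bounces))
}

# --------------------------------------------------------------------------

#' Henyey--Greenstein phase function
#'
#' `phase_eval()` returns the density per steradian at scattering cosine
#' `cos_theta`; it integrates to 1 over the sphere. `phase_sample()` draws
#' unit directions relative to an incoming direction `(0, 0, 1)` with
#' exactly that density, so sample/eval importance weights are 1.
#'
#' @param g Anisotropy, `-1 < g < 1` (`g = 0` is isotropic; the mean
#'   scattering cosine equals `g`).
#' @param cos_theta Scattering cosine(s).
#' @return `phase_eval()`: densities; `phase_sample()`: an `n x 3` matrix
#'   of unit directions.
#' @export
phase_eval <- function(g, cos_theta) {
  if (abs(g) >= 1) stop("`g` must satisfy -1 < g < 1", call. = FALSE)
  if (abs(g) < 1e-9) return(rep(1 / (4 * pi), length(cos_theta)))
  den <- 1 + g^2 - 2 * g * cos_theta
  (1 - g^2) / (4 * pi * den^1.5)
}

#' @rdname phase_eval
#' @param n Number of draws.
#' @param seed Integer seed (deterministic stream).
#' @export
phase_sample <- function(g, n = 1, seed = 1) {
  if (abs(g) >= 1) stop("`g` must satisfy -1 < g < 1", call. = FALSE)
  cpp_hg_sample(g, as.integer(n), as.integer(seed))
}

#' Woodcock (delta-tracking) free-path sampling
#'
#' Tentative collisions are generated at exponential spacing with the
#' majorant rate and accepted as real with probability
#' `sigma_t(x, lambda) / mu_bar(lambda)`; the first real collision distance
#' is returned, `Inf` when the ray escapes the volume.
#'
#' @param vg A [voxel_grid()].
#' @param origin,direction Ray origin (um) and direction.
#' @param lambda Wavelength in nm.
#' @param n Number of independent samples.
#' @param seed Integer seed.
#' @return Distances in micrometers (`Inf` = escape).
#' @export
sample_free_path_woodcock <- function(vg, origin, direction, lambda,
                                      n = 1, seed = 1) {
  pk <- pack_volume(vg)
  bin <- grid_bin(pk$grid, lambda)
  if (pk$maj[bin] <= 0 && any(pk$st[bin, ] > 0)) {
    stop("invalid majorant: zero bound over a non-vacuum medium",
         call. = FALSE)
  }
  d <- cpp_free_path(pk, as.numeric(origin) / 1000, as.numeric(direction),
                     bin - 1L, as.integer(n), as.integer(seed))
  d * 1000
}

#' Classify an interaction event at a real collision
#'
#' An accepted collision scatters elastically with probability
#' `sigma_s / sigma_t`; otherwise it is an absorption, which is a
#' fluorescence event with probability `mu_a^f(lambda) / mu_a(lambda)`
#' (possible only at dye-bearing materials) and terminal otherwise.
#'
#' @param mat An [optical_material()] with `sigma_t > 0` at `lambda`.
#' @param lambda Current (emission-side) wavelength in nm.
#' @param n Number of events to draw.
#' @param u Optional uniform variates (`n x 2` matrix) for deterministic
#'   classification.
#' @return Character vector with levels `"elastic_scatter"`,
#'   `"fluorescence"`, `"absorb_terminate"`.
#' @export
classify_event <- function(mat, lambda, n = 1, u = NULL) {
  stopifnot(inherits(mat, "optical_material"))
  bin <- grid_bin(mat$grid, lambda)
  ss <- mat$sigma_s$values[bin]
  mua <- material_mu_a(mat)[bin]
  muaf <- material_mu_af(mat)[bin]
  st <- ss + mua
  if (st <= 0) stop("no real collision possible: sigma_t = 0", call. = FALSE)
  p_scat <- ss / st
  p_fl <- if (mua > 0) muaf / mua else 0
  if (p_scat < 0 || p_scat > 1 || p_fl < 0 || p_fl > 1) {
    stop("event probabilities outside [0, 1]", call. = FALSE)
  }
  if (is.null(u)) u <- matrix(stats::runif(2 * n), ncol = 2)
  out <- ifelse(u[, 1] < p_scat, "elastic_scatter",
                ifelse(u[, 2] < p_fl, "fluorescence", "absorb_terminate"))
  out
}

#' Transmittance along a segment through the volume
#'
#' `method = "track"` gives the unbiased ratio-tracking estimate of
#' `exp(-integral of sigma_t)`; `method = "exact"` evaluates the
#' attenuation line integral exactly (the medium is piecewise constant
#' per voxel, so DDA marching gives the closed form; for a homogeneous
#' segment this is Beer--Lambert exactly).
#'
#' @param vg A [voxel_grid()].
#' @param a,b Segment endpoints (um).
#' @param lambda Wavelength (nm).
#' @param n Number of tracking replicates (`"track"` only).
#' @param seed Integer seed.
#' @param method `"track"` or `"exact"`.
#' @return Transmittance estimate(s) in `[0, 1]`.
#' @export
transmittance <- function(vg, a, b, lambda, n = 1, seed = 1,
                          method = c("track", "exact")) {
  method <- match.arg(method)
  pk <- pack_volume(vg)
  bin <- grid_bin(pk$grid, lambda)
  if (method == "track") {
    return(cpp_transmittance(pk, as.numeric(a) / 1000,
                             as.numeric(b) / 1000, bin - 1L,
                             as.integer(n), as.integer(seed)))
  }
  # exact piecewise-constant line integral (DDA voxel marching)
  cpp_exact_tau(pk, as.numeric(a) / 1000, as.numeric(b) / 1000, bin - 1L)
}

#' Direct-light contribution at a fluorescence emission vertex
#'
#' Samples a point on the light (uniform area pdf), and returns
#' `L_e(lambda_x) * G * tau(lambda_x) * f_p / p(x_n)` where `G` is the
#' light-side cosine over squared distance and `tau` the transmittance of
#' the connecting segment.
#'
#' @param sc A [scene()].
#' @param event_position Fluorescence vertex position (um).
#' @param lambda_x Excitation wavelength (nm).
#' @param incoming Unit direction of the camera-side walk at the vertex.
#' @param g Phase anisotropy at the vertex.
#' @param n Number of light samples.
#' @param seed Integer seed.
#' @return Numeric vector of `n` single-sample estimates.
#' @export
direct_light_at_emission <- function(sc, event_position, lambda_x,
                                     incoming = c(0, 0, 1), g = 0,
                                     n = 1, seed = 1) {
  stopifnot(inherits(sc, "scene_fl"))
  li <- sc$light
  bin <- grid_bin(li$emission$grid, lambda_x)
  le <- li$emission$values[bin]
  if (le == 0) return(rep(0, n))
  pk <- pack_scene(sc)
  rng <- local_rng_state(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    uv <- rng(2)
    xl <- li$corner + uv[1] * li$edge1 + uv[2] * li$edge2
    d <- xl - event_position
    r2 <- sum(d^2)
    wl <- d / sqrt(r2)
    cosl <- sum(li$normal * (-wl))
    if (cosl <= 0) { out[i] <- 0; next }
    tau <- cpp_transmittance(pk, event_position / 1000, xl / 1000,
                             bin - 1L, 1L, as.integer(seed) + i)
    fp <- phase_eval(g, sum(incoming * wl))
    # um -> mm conversion of the geometry term (r2 in um^2, area in um^2)
    out[i] <- le * (cosl / (r2 / 1e6)) * tau * fp * (li$area_um2 / 1e6)
  }
  out
}

# small deterministic uniform stream helper (keeps the global RNG intact)
local_rng_state <- function(seed) {
  env <- new.env()
  env$state <- as.numeric(seed)
  function(k) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      env$state <- (1103515245 * env$state + 12345) %% 2147483648
      out[i] <- env$state / 2147483648
    }
    out
  }
}

#' Trace camera paths at a fixed emission wavelength
#'
#' Runs the full path loop (woodcock free flight, event classification,
#' elastic Henyey--Greenstein bounces, single fluorescence vertex with
#' next-event light sampling) for one pixel, returning one radiance sample
#' per path. Paths that never encounter a fluorescence emission contribute
#' exactly zero.
#'
#' @param sc A [scene()].
#' @param config A [render_config()].
#' @param pixel Integer pair (0-based pixel column, row).
#' @param lambda Emission wavelength (nm).
#' @param n Number of paths.
#' @param seed Integer seed.
#' @param jitter Jitter ray positions inside the pixel (disable for
#'   quadrature comparisons against the exact center ray).
#' @return Numeric vector of `n` radiance samples.
#' @export
trace_path <- function(sc, config, pixel = c(0L, 0L), lambda, n = 1,
                       seed = config$seed, jitter = FALSE) {
  stopifnot(inherits(sc, "scene_fl"), inherits(config, "render_config"))
  pk <- pack_scene(sc, config)
  bin <- grid_bin(pk$grid, lambda)
  out <- cpp_trace(pk, as.integer(pixel[1]), as.integer(pixel[2]),
                   bin - 1L, as.integer(n), as.integer(seed), jitter)
  if (any(!is.finite(out)) || any(out < 0)) {
    stop("tracer produced non-finite or negative radiance", call. = FALSE)
  }
  out
}

#' Render a spectral image
#'
#' For every pixel, `spectral_samples` emission wavelengths are drawn
#' stratified from the scene's combined emission distribution (the mixture
#' of the emission pdfs of the dyes present), `spp` paths are traced for
#' each, and contributions are accumulated into per-wavelength radiance
#' bins with the sampling pdf divided out. Rendering is deterministic per
#' seed: identical configurations give bit-identical accumulators.
#'
#' @param sc A [scene()].
#' @param config A [render_config()].
#' @return An object of class `spectral_image`: `values` is a
#'   `width x height x n_bins` array of spectral radiance.
#' @export
render <- function(sc, config = render_config()) {
  stopifnot(inherits(sc, "scene_fl"), inherits(config, "render_config"))
  pk <- pack_scene(sc, config)
  v <- cpp_render(pk, config$spp, config$spectral_samples, config$seed)
  img <- array(v, dim = c(pk$cam$width, pk$cam$height, pk$nb))
  structure(list(values = img, grid = pk$grid,
                 width = pk$cam$width, height = pk$cam$height,
                 spp = config$spp,
                 spectral_samples = config$spectral_samples,
                 seed = config$seed),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("<spectral_image> %dx%d px, %d bins, %d spp x %d spectral\n",
              x$width, x$height, x$grid$n, x$spp, x$spectral_samples))
  invisible(x)
}

# --------------------------------------------------------------------------
# CIE 1931 2-degree observer (analytic multi-lobe Gaussian fit) and sRGB.

cie_lobe <- function(wl, peak, s1, s2) {
  t <- (wl - peak) * ifelse(wl < peak, 1 / s1, 1 / s2)
  exp(-0.5 * t^2)
}

cie_xyz_bar <- function(wl) {
  xb <- 1.056 * cie_lobe(wl, 599.8, 37.9, 31.0) +
    0.362 * cie_lobe(wl, 442.0, 16.0, 26.7) -
    0.065 * cie_lobe(wl, 501.1, 20.4, 26.2)
  yb <- 0.821 * cie_lobe(wl, 568.8, 46.9, 40.5) +
    0.286 * cie_lobe(wl, 530.9, 16.3, 31.1)
  zb <- 1.217 * cie_lobe(wl, 437.0, 11.8, 36.0) +
    0.681 * cie_lobe(wl, 459.0, 26.0, 13.8)
  cbind(x = pmax(xb, 0), y = pmax(yb, 0), z = pmax(zb, 0))
}

#' Convert a spectral image to display RGB
#'
#' Integrates the per-pixel SPD against the CIE 1931 2-degree matching
#' functions (analytic fit), converts XYZ to linear sRGB, normalizes to
#' the image maximum and applies the sRGB transfer curve. Display
#' plumbing only: quantitative analysis uses the raw spectral values.
#'
#' @param img A [render()] result.
#' @param gamma Apply the sRGB transfer curve (default `TRUE`).
#' @return A `width x height x 3` array in `[0, 1]`.
#' @export
spectral_to_rgb <- function(img, gamma = TRUE) {
  stopifnot(inherits(img, "spectral_image"))
  cmf <- cie_xyz_bar(img$grid$wavelengths)
  flat <- matrix(img$values, nrow = img$width * img$height)
  xyz <- flat %*% cmf * img$grid$delta_lambda
  m <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  rgb <- xyz %*% t(m)
  rgb[rgb < 0] <- 0
  mx <- max(rgb)
  if (mx > 0) rgb <- rgb / mx
  if (gamma) {
    rgb <- ifelse(rgb <= 0.0031308, 12.92 * rgb,
                  1.055 * rgb^(1 / 2.4) - 0.055)
  }
  array(rgb, dim = c(img$width, img$height, 3))
}

#' Write / read a spectral image (raw float32 + JSON sidecar)
#'
#' @param img A `spectral_image`.
#' @param path Path stem (writes `<path>.f32` and `<path>.json`).
#' @return `path` (write) or a `spectral_image` (read).
#' @export
write_spectral_image <- function(img, path) {
  stopifnot(inherits(img, "spectral_image"))
  writeBin(as.numeric(img$values), paste0(path, ".f32"), size = 4,
           endian = "little")
  meta <- list(width = img$width, height = img$height, n_bins = img$grid$n,
               lambda_min = img$grid$lambda_min,
               lambda_max = img$grid$lambda_max,
               delta_lambda = img$grid$delta_lambda,
               spp = img$spp, spectral_samples = img$spectral_samples,
               seed = img$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectral_image
#' @export
read_spectral_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wg <- wavelength_grid(meta$lambda_min, meta$lambda_max,
                        meta$delta_lambda)
  n <- meta$width * meta$height * meta$n_bins
  v <- readBin(paste0(path, ".f32"), what = "numeric", n = n, size = 4,
               endian = "little")
  structure(list(values = array(v, dim = c(meta$width, meta$height,
                                           meta$n_bins)),
                 grid = wg, width = meta$width, height = meta$height,
                 spp = meta$spp, spectral_samples = meta$spectral_samples,
                 seed = meta$seed),
            class = "spectral_image")
}
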