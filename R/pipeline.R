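# End-to-end driver: generate -> voxelize -> annotate -> render -> measure.

#' Assign or modify the material of a label
#'
#' `set_material()` replaces the whole entry; `set_material_optics()` and
#' `set_material_dye()` update the optical and fluorescent parts
#' independently (annotation is order-independent).
#'
#' @param vg A [voxel_grid()].
#' @param label Label value (0 = background).
#' @param material An [optical_material()].
#' @return The modified grid.
#' @export
set_material <- function(vg, label, material) {
  stopifnot(inherits(vg, "voxel_grid"),
            inherits(material, "optical_material"))
  vg$materials[[as.character(label)]] <- material
  vg
}

#' @rdname set_material
#' @param sigma_s,sigma_a_base,g Optical parameters (see
#'   [optical_material()]).
#' @export
set_material_optics <- function(vg, label, sigma_s, sigma_a_base, g = 0.9) {
  old <- grid_material(vg, label)
  dye <- if (!is.null(old)) old$dye else NULL
  grid <- if (!is.null(old)) old$grid
          else if (!is.null(dye)) dye$fluorophore$grid else default_grid()
  set_material(vg, label,
               optical_material(sigma_s, sigma_a_base, g = g, dye = dye,
                                grid = grid))
}

#' @rdname set_material
#' @param dye A [dye_solution()].
#' @export
set_material_dye <- function(vg, label, dye) {
  old <- grid_material(vg, label)
  if (is.null(old)) old <- vacuum_material(dye$fluorophore$grid)
  set_material(vg, label,
               optical_material(old$sigma_s, old$sigma_a_base, g = old$g,
                                dye = dye, grid = old$grid))
}

#' Read a pipeline configuration file (YAML)
#' @param path Path to a YAML file; see [run_pipeline()] for the schema.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("pipeline_config", "list"))
}

validate_pipeline_config <- function(cfg) {
  need <- function(x, what) if (is.null(x)) stop(
    sprintf("pipeline config: missing `%s`", what), call. = FALSE) else x
  tis <- need(cfg$tissue, "tissue")
  need(tis$block, "tissue.block")
  need(tis$spacing, "tissue.spacing")
  mat <- need(cfg$materials, "materials")
  for (nm in names(mat)) {
    d <- mat[[nm]]$dye
    if (!is.null(d)) {
      need(d$preset, paste0("materials.", nm, ".dye.preset"))
      alexa_fluor(d$preset)  # unknown dye aborts here, before any stage
      need(d$concentration, paste0("materials.", nm, ".dye.concentration"))
    }
  }
  need(cfg$camera, "camera")
  need(cfg$light, "light")
  need(cfg$sampling, "sampling")
  invisible(cfg)
}

config_material <- function(mc) {
  dye <- NULL
  if (!is.null(mc$dye)) {
    dye <- dye_solution(alexa_fluor(mc$dye$preset), mc$dye$concentration)
  }
  optical_material(sigma_s = mc$sigma_s %||% 0,
                   sigma_a_base = mc$sigma_a_base %||% 0,
                   g = mc$g %||% 0.9, dye = dye)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full virtual-fluorescence pipeline
#'
#' Stages, in order: generate morphologies ([place_population()]),
#' voxelize them into a labeled block ([rasterize_morphology()] or
#' meshing + [voxelize_solid()]), annotate labels with optical materials
#' and dyes, render ([render()]), and measure the image SPD
#' ([measure_spd()]). Every artifact is written under `out_dir` together
#' with a manifest (config checksum, seeds, package version). Re-running
#' an identical configuration reproduces identical artifacts. A stage
#' failure aborts with the stage name; non-watertight meshes abort with
#' the morphology identifier.
#'
#' Config schema (YAML or list): `tissue` (n, seed, block {min, max},
#' spacing, mode "rasterize" | "mesh", plus optional
#' [generate_morphology()] parameters under `morphology`), `materials`
#' (label -> {sigma_s, sigma_a_base, g, dye {preset, concentration}}),
#' `camera` (position, lookat, up, vfov, width, height), `light`
#' (corner, edge1, edge2, wavelength, radiance), `sampling` (spp,
#' spectral_samples, max_bounces, seed).
#'
#' @param cfg A [pipeline_config()] or equivalent named list.
#' @param out_dir Output directory.
#' @return List with `volume`, `image`, `spd` and the written `files`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tis <- cfg$tissue
  blk <- block3(unlist(tis$block$min), unlist(tis$block$max))
  n <- tis$n %||% 1
  seed <- tis$seed %||% 1
  mode <- tis$mode %||% "rasterize"
  mp <- tis$morphology %||% list()

  gen <- function(s) do.call(generate_morphology,
                             c(list(seed = s), mp))
  cells <- stage("generate", place_population(n, blk, seed,
                                              morph_generator = gen))

  occ <- stage("voxelize", {
    dims <- block_dims(blk, tis$spacing)
    acc <- array(0L, dim = dims)
    for (i in seq_along(cells)) {
      m <- cells[[i]]$morphology
      vgi <- if (identical(mode, "mesh")) {
        mesh <- morphology_to_mesh(m)
        wt <- check_watertight(mesh)
        if (!wt$watertight) {
          stop(sprintf("morphology %d produced a non-watertight mesh", i),
               call. = FALSE)
        }
        voxelize_solid(mesh, tis$spacing, blk)
      } else {
        rasterize_morphology(m, tis$spacing, blk)
      }
      acc[vgi$labels > 0L] <- 1L  # later cells win on overlap
    }
    acc
  })

  vg <- stage("annotate", {
    mats <- lapply(cfg$materials, config_material)
    names(mats) <- names(cfg$materials)
    voxel_grid(occ, spacing = tis$spacing, origin = blk$min,
               materials = mats)
  })
  vol_path <- file.path(out_dir, "volume")
  write_volume(vg, vol_path)

  img <- stage("render", {
    cam <- do.call(camera, lapply(cfg$camera, unlist))
    li <- rect_light(unlist(cfg$light$corner), unlist(cfg$light$edge1),
                     unlist(cfg$light$edge2),
                     monochromatic_emission(cfg$light$wavelength,
                                            cfg$light$radiance %||% 1))
    sp <- cfg$sampling
    render(scene(vg, cam, li),
           render_config(spp = sp$spp %||% 16,
                         spectral_samples = sp$spectral_samples %||% 16,
                         max_bounces = sp$max_bounces %||% 16,
                         seed = sp$seed %||% 1))
  })
  img_path <- file.path(out_dir, "image")
  write_spectral_image(img, img_path)

  spd <- stage("measure", measure_spd(img))
  spd_path <- file.path(out_dir, "spd.csv")
  write_spectrum(spd$spectrum, spd_path)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    tissue_seed = seed, sampling_seed = cfg$sampling$seed %||% 1,
    package = "fluortrace",
    version = as.character(utils::packageVersion("fluortrace")),
    files = c(volume = paste0("volume", c(".raw", ".json")),
              image = paste0("image", c(".f32", ".json")),
              spd = "spd.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(volume = vg, image = img, spd = spd,
       files = c(vol_path, img_path, spd_path, cfg_path,
                 file.path(out_dir, "manifest.json")))
}
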