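test_that("morphology generation is deterministic and tree-connected", {
  m1 <- generate_morphology(seed = 11)
  m2 <- generate_morphology(seed = 11)
  expect_identical(m1, m2)
  m3 <- generate_morphology(seed = 12)
  expect_false(identical(m1$segments, m3$segments))
  # soma only at depth zero
  m0 <- generate_morphology(seed = 1, max_depth = 0)
  expect_equal(nrow(m0$segments), 0)
  # structural invariants: stems start on the soma surface, children start
  # at their parent's tip, radii at or above the configured minimum
  s <- m1$segments
  expect_gt(nrow(s), 0)
  for (i in seq_len(nrow(s))) {
    p0 <- c(s$x0[i], s$y0[i], s$z0[i])
    if (s$parent[i] == 0L) {
      expect_equal(sqrt(sum(p0^2)), m1$soma$radius, tolerance = 1e-9)
    } else {
      j <- s$parent[i]
      expect_equal(p0, c(s$x1[j], s$y1[j], s$z1[j]))
      expect_equal(s$r0[i], s$r1[j])
    }
    expect_gte(s$r1[i], 0.3)
    expect_lte(s$r1[i], s$r0[i])
  }
})

test_that("population placement is uniform in the block and deterministic", {
  blk <- block3(c(0, 0, 0), c(100, 120, 80))
  pop <- place_population(5, blk, seed = 3,
                          morph_generator = function(s)
                            generate_morphology(s, max_depth = 1))
  expect_length(pop, 5)
  for (p in pop) {
    ctr <- p$morphology$soma$center
    expect_true(all(ctr >= blk$min & ctr <= blk$max))
    expect_equal(det(p$rotation), 1, tolerance = 1e-9)
  }
  expect_identical(place_population(5, blk, seed = 3,
                                    morph_generator = function(s)
                                      generate_morphology(s, max_depth = 1)),
                   pop)
  # per-axis KS test for uniformity of soma centers
  big <- place_population(1000, blk, seed = 9,
                          morph_generator = function(s)
                            generate_morphology(s, max_depth = 0))
  ctrs <- t(vapply(big, function(p) p$morphology$soma$center, numeric(3)))
  for (ax in 1:3) {
    p <- stats::ks.test(ctrs[, ax], "punif", blk$min[ax],
                        blk$max[ax])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("meshing produces watertight closed surfaces", {
  soma_only <- generate_morphology(seed = 1, max_depth = 0)
  ms <- morphology_to_mesh(soma_only)
  expect_true(check_watertight(ms)$watertight)
  expect_equal(mesh_euler(ms), 2L)
  # a single capsule is a closed genus-0 surface
  cap <- fluortrace:::make_capsule(c(0, 0, 0), 2, c(0, 0, 15), 1.5,
                                   nseg = 16)
  expect_true(check_watertight(cap)$watertight)
  expect_equal(mesh_euler(cap), 2L)
  # every generator output is watertight
  for (seed in 1:3) {
    m <- generate_morphology(seed = seed, max_depth = 3)
    expect_true(check_watertight(morphology_to_mesh(m))$watertight)
  }
})

test_that("watertight check reports the boundary of a removed face", {
  cb <- cube_mesh()
  expect_true(check_watertight(cb)$watertight)
  broken <- tri_mesh(cb$vertices, cb$faces[-1, ])
  res <- check_watertight(broken)
  expect_false(res$watertight)
  expect_equal(nrow(res$report), 3)  # boundary loop of the removed face
  removed_edges <- t(apply(cbind(cb$faces[1, ],
                                 cb$faces[1, c(2, 3, 1)]), 1, sort))
  got <- res$report[order(res$report$v1, res$report$v2), c("v1", "v2")]
  want <- removed_edges[order(removed_edges[, 1], removed_edges[, 2]), ]
  expect_equal(unname(as.matrix(got)), unname(want))
})

test_that("voxelization is exact for aligned boxes and accurate for spheres", {
  blk <- block3(c(0, 0, 0), c(20, 20, 20))
  # box aligned to voxel boundaries: exact voxel count
  bx <- cube_mesh(c(2, 4, 6), c(12, 14, 18))
  vg <- voxelize_solid(bx, spacing = 1, block = blk)
  expect_equal(sum(vg$labels), 10 * 10 * 12)
  # empty mesh -> all zeros
  empty <- tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  expect_equal(sum(voxelize_solid(empty, 1, blk)$labels), 0)
  # sphere volume within 2% of (4/3) pi r^3
  sph <- make_icosphere(c(0, 0, 0), 10, subdiv = 3)
  sblk <- block3(c(-12, -12, -12), c(12, 12, 12))
  sv <- voxelize_solid(sph, spacing = 0.5, block = sblk)
  vol <- sum(sv$labels) * 0.5^3
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  # parity is axis-invariant
  vx <- voxelize_solid(sph, 0.5, sblk, axis = "x")$labels
  vy <- voxelize_solid(sph, 0.5, sblk, axis = "y")$labels
  vz <- voxelize_solid(sph, 0.5, sblk, axis = "z")$labels
  expect_identical(vx, vy)
  expect_identical(vx, vz)
  # conservative mode marks at least the plain-parity voxels
  cons <- voxelize_solid(sph, 0.5, sblk, conservative = TRUE)$labels
  expect_true(all(cons[sv$labels > 0] > 0))
  expect_gt(sum(cons), sum(sv$labels))
  # non-watertight input is rejected with a report
  expect_error(voxelize_solid(tri_mesh(sph$vertices, sph$faces[-1, ]),
                              0.5, sblk), "watertight")
})

test_that("clipping keeps solids watertight and halves a centered sphere", {
  blk_big <- block3(c(-30, -30, -30), c(30, 30, 30))
  sph <- make_icosphere(c(0, 0, 0), 10, subdiv = 3)
  expect_identical(clip_to_block(sph, blk_big)$vertices, sph$vertices)
  # half-space through the center: hemisphere with a cap
  half <- block3(c(-30, -30, -30), c(30, 30, 0))
  hemi <- clip_to_block(sph, half)
  expect_true(check_watertight(hemi)$watertight)
  sph_vol <- mesh_volume(sph)
  expect_lt(abs(mesh_volume(hemi) - sph_vol / 2) / (sph_vol / 2), 0.02)
  # fully outside -> empty mesh
  far <- block3(c(100, 100, 100), c(120, 120, 120))
  expect_equal(nrow(clip_to_block(sph, far)$faces), 0)
  expect_error(clip_to_block(tri_mesh(sph$vertices, sph$faces[-1, ]),
                             half), "watertight")
})

test_that("clip-then-voxelize equals voxelize-then-crop on aligned bounds", {
  sph <- make_icosphere(c(10, 10, 10), 8, subdiv = 3)
  full <- block3(c(0, 0, 0), c(20, 20, 20))
  sub <- block3(c(0, 0, 0), c(20, 20, 10))
  a <- voxelize_solid(clip_to_block(sph, sub), 1, sub)$labels
  b <- voxelize_solid(sph, 1, full)$labels[, , 1:10]
  expect_gt(sum(b), 0)
  expect_equal(mean(a == b), 1, tolerance = 0.001)
})

test_that("voxelized morphology volume matches the analytic solid", {
  # straight untapered stem: sphere + cylinder + tip hemisphere
  m <- structure(list(
    soma = list(center = c(0, 0, 0), radius = 5),
    segments = data.frame(x0 = 5, y0 = 0, z0 = 0, r0 = 1.5,
                          x1 = 20, y1 = 0, z1 = 0, r1 = 1.5,
                          parent = 0L, depth = 1L)),
    class = "morphology")
  mesh <- morphology_to_mesh(m, segments_per_circle = 16)
  blk <- block3(c(-8, -8, -8), c(24, 8, 8))
  vg <- voxelize_solid(mesh, spacing = 0.5, block = blk)
  vol <- sum(vg$labels) * 0.5^3
  analytic <- 4 / 3 * pi * 125 + pi * 1.5^2 * 15 + 2 / 3 * pi * 1.5^3
  expect_lt(abs(vol - analytic) / analytic, 0.05)
})

test_that("rasterization agrees with mesh voxelization and converges", {
  m <- generate_morphology(seed = 5, max_depth = 2, n_stems = 2)
  blk <- block3(c(-20, -20, -20), c(20, 20, 20))
  a <- voxelize_solid(morphology_to_mesh(m), 0.5, blk)$labels
  b <- rasterize_morphology(m, 0.5, blk)$labels
  expect_gt(sum(b), 0)
  expect_gte(mean((a > 0) == (b > 0)), 0.99)
  # soma-only morphology gives a digital ball
  m0 <- generate_morphology(seed = 1, max_depth = 0)
  ball <- rasterize_morphology(m0, 0.5, blk)
  vol <- sum(ball$labels) * 0.125
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.02)
  # occupied volume converges under refinement
  sblk <- block3(c(-8, -8, -8), c(8, 8, 8))
  v1 <- sum(rasterize_morphology(m0, 0.5, sblk)$labels) * 0.5^3
  v2 <- sum(rasterize_morphology(m0, 0.25, sblk)$labels) * 0.25^3
  expect_lt(abs(v1 - v2) / v2, 0.01)
})

test_that("OBJ and SWC interchange round-trip", {
  mesh <- make_icosphere(c(1, 2, 3), 4, subdiv = 1)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, path)
  back <- read_obj(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-7)
  expect_identical(back$faces, mesh$faces)
  m <- generate_morphology(seed = 4, max_depth = 3)
  swc <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, swc)
  back <- read_swc(swc)
  expect_equal(back$soma$center, m$soma$center)
  expect_equal(back$soma$radius, m$soma$radius)
  cols <- c("x0", "y0", "z0", "r0", "x1", "y1", "z1", "r1", "parent")
  expect_equal(back$segments[, cols], m$segments[, cols],
               tolerance = 1e-7, ignore_attr = TRUE)
})
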