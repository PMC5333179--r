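# Procedural neuron-like morphologies, watertight capsule meshes, block
# clipping and solid voxelization.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Axis-aligned block (bounding box)
#' @param min,max Corner coordinates in micrometers (`min < max` per axis).
#' @return An object of class `block3`.
#' @export
block3 <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  stopifnot(length(min) == 3, length(max) == 3)
  if (any(min >= max)) stop("block must satisfy min < max per axis",
                            call. = FALSE)
  structure(list(min = min, max = max), class = "block3")
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Procedural neuron-like morphology
#'
#' Grows a tree of tapered capsule segments from a spherical soma.
#' Growth is breadth-first: `n_stems` stems leave the soma surface in
#' random directions; each segment extends its parent direction with a
#' random angular perturbation, a length drawn around
#' `mean_segment_len`, and a radius shrunk by `taper`; a branch point
#' (two children) occurs with probability `branch_prob` until
#' `max_depth` levels or the minimum radius is reached. Deterministic
#' given `seed`; with `max_depth = 0` only the soma is produced.
#'
#' @param seed Integer seed.
#' @param n_stems Number of stems leaving the soma.
#' @param branch_prob Probability that a segment forks into two children.
#' @param mean_segment_len Mean segment length (um).
#' @param taper Child/parent radius ratio (0--1].
#' @param max_depth Maximum tree depth (segments per stem path).
#' @param extent Half-size of the allowed growth cube around the soma
#'   (um); growth stops at the boundary.
#' @param soma_radius,stem_radius,min_radius Radii in um.
#' @return An object of class `morphology`: `soma` (center, radius) and a
#'   data frame `segments` with columns `x0..z1`, `r0`, `r1`, `parent`
#'   (0 = soma) and `depth`.
#' @export
generate_morphology <- function(seed = 1, n_stems = 3, branch_prob = 0.3,
                                mean_segment_len = 8, taper = 0.85,
                                max_depth = 4, extent = 40,
                                soma_radius = 5, stem_radius = 1.5,
                                min_radius = 0.3) {
  stopifnot(n_stems >= 1, branch_prob >= 0, branch_prob <= 1,
            mean_segment_len > 0, taper > 0, taper <= 1, max_depth >= 0,
            extent > 0, soma_radius > 0, stem_radius > 0, min_radius > 0)
  seg <- list()
  with_local_seed(seed, {
    queue <- list()
    if (max_depth >= 1) {
      for (s in seq_len(n_stems)) {
        d <- random_unit()
        queue[[length(queue) + 1L]] <-
          list(p = soma_radius * d, dir = d, r = stem_radius, depth = 1L,
               parent = 0L)
      }
    }
    while (length(queue) > 0) {
      nd <- queue[[1]]
      queue <- queue[-1]
      len <- mean_segment_len * stats::runif(1, 0.7, 1.3)
      dir <- nd$dir + 0.4 * random_unit()
      dir <- dir / sqrt(sum(dir^2))
      p1 <- nd$p + len * dir
      if (any(abs(p1) > extent)) next
      r1 <- max(nd$r * taper, min_radius)
      seg[[length(seg) + 1L]] <-
        c(nd$p, nd$r, p1, r1, nd$parent, nd$depth)
      idx <- length(seg)
      if (nd$depth < max_depth && r1 > min_radius) {
        nchild <- if (stats::runif(1) < branch_prob) 2L else 1L
        for (ch in seq_len(nchild)) {
          queue[[length(queue) + 1L]] <-
            list(p = p1, dir = dir, r = r1, depth = nd$depth + 1L,
                 parent = idx)
        }
      }
    }
  })
  segments <- if (length(seg) == 0) {
    data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
               r0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
               z1 = numeric(0), r1 = numeric(0), parent = integer(0),
               depth = integer(0))
  } else {
    m <- do.call(rbind, seg)
    data.frame(x0 = m[, 1], y0 = m[, 2], z0 = m[, 3], r0 = m[, 4],
               x1 = m[, 5], y1 = m[, 6], z1 = m[, 7], r1 = m[, 8],
               parent = as.integer(m[, 9]), depth = as.integer(m[, 10]))
  }
  structure(list(soma = list(center = c(0, 0, 0), radius = soma_radius),
                 segments = segments),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> soma r = %g um at (%g, %g, %g), %d segment(s)\n",
              x$soma$radius, x$soma$center[1], x$soma$center[2],
              x$soma$center[3], nrow(x$segments)))
  invisible(x)
}

#' Rigidly transform a morphology
#' @param morph A [generate_morphology()] result.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (um).
#' @return The transformed `morphology`.
#' @export
transform_morphology <- function(morph, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  stopifnot(inherits(morph, "morphology"))
  rot <- function(p) as.numeric(rotation %*% p) + translation
  morph$soma$center <- rot(morph$soma$center)
  s <- morph$segments
  if (nrow(s) > 0) {
    a <- t(apply(as.matrix(s[, c("x0", "y0", "z0")]), 1, rot))
    b <- t(apply(as.matrix(s[, c("x1", "y1", "z1")]), 1, rot))
    s[, c("x0", "y0", "z0")] <- a
    s[, c("x1", "y1", "z1")] <- b
    morph$segments <- s
  }
  morph
}

# uniform random rotation (Shoemake quaternion method)
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Statistically place a population of morphologies in a block
#'
#' Soma centers are uniform in the block; orientations are uniform over
#' rotations; deterministic per seed.
#'
#' @param n Number of cells (>= 1).
#' @param block A [block3()].
#' @param seed Integer seed.
#' @param morph_generator Function `(seed) -> morphology` for the
#'   per-cell morphology (defaults to [generate_morphology()]).
#' @return List of entries `list(morphology, rotation, translation)`,
#'   where `morphology` is already transformed into place.
#' @export
place_population <- function(n, block, seed = 1,
                             morph_generator = generate_morphology) {
  stopifnot(n >= 1, inherits(block, "block3"))
  out <- vector("list", n)
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      ctr <- block$min + stats::runif(3) * (block$max - block$min)
      rotm <- random_rotation()
      m <- morph_generator(seed + i * 7919L)
      out[[i]] <- list(
        morphology = transform_morphology(m, rotm, ctr),
        rotation = rotm, translation = ctr)
    }
  })
  out
}

# --------------------------------------------------------------------------
# Triangle meshes

#' Triangle mesh
#' @param vertices `n x 3` numeric matrix (um).
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n", nrow(x$vertices),
              nrow(x$faces)))
  invisible(x)
}

#' Merge meshes into one (disjoint components)
#' @param meshes List of [tri_mesh()]s.
#' @return A single `tri_mesh`.
#' @export
merge_meshes <- function(meshes) {
  meshes <- Filter(function(m) nrow(m$faces) > 0, meshes)
  if (length(meshes) == 0) {
    return(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  }
  vs <- list(); fs <- list(); off <- 0L
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Connected components of a mesh
#' @param mesh A [tri_mesh()].
#' @return Integer vector: component id per face.
#' @export
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nrow(mesh$faces) == 0) return(integer(0))
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  roots <- vapply(f[, 1], find, integer(1))
  as.integer(factor(roots))
}

#' Signed volume enclosed by a mesh (divergence theorem)
#' @param mesh A [tri_mesh()] with outward-oriented faces.
#' @return Volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(a * cr) / 6
}

#' Euler characteristic V - E + F
#' @param mesh A [tri_mesh()].
#' @return Integer.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0L)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nrow(unique(mesh$vertices)) * 0L +  # vertices counted as referenced ids
    length(unique(as.vector(f))) - nrow(e) + nrow(f)
}

#' Check that a mesh is watertight
#'
#' Watertight = every undirected edge is shared by exactly two faces with
#' opposite directed orientation (a closed, consistently wound 2-manifold,
#' possibly with several closed components).
#'
#' @param mesh A [tri_mesh()].
#' @return List with `watertight` (logical) and `report`: a data frame of
#'   offending edges (`v1`, `v2`, `count`).
#' @export
check_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) {
    return(list(watertight = TRUE,
                report = data.frame(v1 = integer(0), v2 = integer(0),
                                    count = integer(0))))
  }
  dir_e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  undir <- t(apply(dir_e, 1, sort))
  key <- paste(undir[, 1], undir[, 2])
  cnt <- table(key)
  dirkey <- paste(dir_e[, 1], dir_e[, 2])
  dircnt <- table(dirkey)
  bad_count <- names(cnt)[cnt != 2]
  bad_orient <- character(0)
  ok2 <- names(cnt)[cnt == 2]
  if (length(ok2) > 0) {
    # for consistent orientation each directed edge appears exactly once
    dup_dir <- names(dircnt)[dircnt > 1]
    if (length(dup_dir) > 0) {
      du <- do.call(rbind, strsplit(dup_dir, " "))
      dk <- paste(pmin(as.integer(du[, 1]), as.integer(du[, 2])),
                  pmax(as.integer(du[, 1]), as.integer(du[, 2])))
      bad_orient <- intersect(dk, ok2)
    }
  }
  bad <- union(bad_count, bad_orient)
  report <- if (length(bad) == 0) {
    data.frame(v1 = integer(0), v2 = integer(0), count = integer(0))
  } else {
    m <- do.call(rbind, strsplit(bad, " "))
    data.frame(v1 = as.integer(m[, 1]), v2 = as.integer(m[, 2]),
               count = as.integer(cnt[bad]))
  }
  list(watertight = length(bad) == 0, report = report)
}

# --------------------------------------------------------------------------
# Primitive tessellations

#' Icosphere (subdivided icosahedron projected to a sphere)
#' @param center,radius Sphere parameters (um).
#' @param subdiv Subdivision level (0 = icosahedron, each level quadruples
#'   the face count).
#' @return A watertight [tri_mesh()].
#' @export
make_icosphere <- function(center = c(0, 0, 0), radius = 1, subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    mid_env <- new.env()
    vlist <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mid_env[[key]]
      if (!is.null(got)) return(got)
      p <- (vlist[a, ] + vlist[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      vlist <<- rbind(vlist, p)
      id <- nrow(vlist)
      mid_env[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
    }
    v <- vlist
    f <- nf
  }
  tri_mesh(sweep(v * radius, 2, center, "+"), f)
}

# closed capsule: cone frustum between p0 (r0) and p1 (r1) plus
# axis-aligned hemispherical caps
make_capsule <- function(p0, r0, p1, r1, nseg = 16, ncap = NULL) {
  axis <- p1 - p0
  h <- sqrt(sum(axis^2))
  if (h < 1e-9) return(NULL)
  w <- axis / h
  if (is.null(ncap)) ncap <- max(3L, as.integer(nseg / 4))
  u <- if (abs(w[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  u <- u - sum(u * w) * w
  u <- u / sqrt(sum(u^2))
  vv <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
          w[1] * u[2] - w[2] * u[1])
  ang <- 2 * pi * (seq_len(nseg) - 1) / nseg
  circle <- function(ctr, r, off_w = 0) {
    t(vapply(ang, function(a) {
      ctr + r * (cos(a) * u + sin(a) * vv) + off_w * w
    }, numeric(3)))
  }
  verts <- matrix(0, 0, 3)
  rings <- list()  # vertex index rows, bottom to top
  add_ring <- function(pts) {
    verts <<- rbind(verts, pts)
    seq(nrow(verts) - nseg + 1L, nrow(verts))
  }
  # bottom pole + bottom hemisphere rings (from pole up to equator at p0)
  verts <- rbind(verts, p0 - r0 * w)
  bottom_pole <- 1L
  for (k in seq_len(ncap - 1L)) {
    th <- pi / 2 * k / ncap  # angle from pole
    rings[[length(rings) + 1L]] <-
      add_ring(circle(p0, r0 * sin(th), -r0 * cos(th)))
  }
  rings[[length(rings) + 1L]] <- add_ring(circle(p0, r0))      # equator p0
  rings[[length(rings) + 1L]] <- add_ring(circle(p1, r1))      # equator p1
  for (k in seq_len(ncap - 1L)) {
    th <- pi / 2 * (ncap - k) / ncap
    rings[[length(rings) + 1L]] <-
      add_ring(circle(p1, r1 * sin(th), r1 * cos(th)))
  }
  verts <- rbind(verts, p1 + r1 * w)
  top_pole <- nrow(verts)

  faces <- matrix(0L, 0, 3)
  first <- rings[[1]]
  for (i in seq_len(nseg)) {
    j <- i %% nseg + 1L
    faces <- rbind(faces, c(bottom_pole, first[j], first[i]))
  }
  for (q in seq_len(length(rings) - 1L)) {
    lo <- rings[[q]]; hi <- rings[[q + 1L]]
    for (i in seq_len(nseg)) {
      j <- i %% nseg + 1L
      faces <- rbind(faces, c(lo[i], lo[j], hi[j]), c(lo[i], hi[j], hi[i]))
    }
  }
  last <- rings[[length(rings)]]
  for (i in seq_len(nseg)) {
    j <- i %% nseg + 1L
    faces <- rbind(faces, c(top_pole, last[i], last[j]))
  }
  tri_mesh(verts, faces)
}

#' Tessellate a morphology into a watertight surface mesh
#'
#' The soma becomes an icosphere; every segment becomes a closed capsule
#' (cone frustum plus hemispherical end caps). Components overlap at the
#' joints; each component is itself watertight, which is what the
#' per-component solid voxelizer requires. Zero-length segments are
#' skipped with a warning.
#'
#' @param morph A [generate_morphology()] result.
#' @param segments_per_circle Tessellation resolution around each capsule.
#' @param soma_subdiv Icosphere subdivision of the soma.
#' @return A [tri_mesh()].
#' @export
morphology_to_mesh <- function(morph, segments_per_circle = 16,
                               soma_subdiv = 2) {
  stopifnot(inherits(morph, "morphology"))
  parts <- list(make_icosphere(morph$soma$center, morph$soma$radius,
                               soma_subdiv))
  s <- morph$segments
  for (i in seq_len(nrow(s))) {
    cap <- make_capsule(c(s$x0[i], s$y0[i], s$z0[i]), s$r0[i],
                        c(s$x1[i], s$y1[i], s$z1[i]), s$r1[i],
                        nseg = segments_per_circle)
    if (is.null(cap)) {
      warning(sprintf("segment %d has zero length; skipped", i))
      next
    }
    parts[[length(parts) + 1L]] <- cap
  }
  merge_meshes(parts)
}

# --------------------------------------------------------------------------
# Clipping a watertight mesh to a box (plane-by-plane, caps re-closed)

# clip solid to half-space dot(v, n) <= d; returns closed mesh
clip_halfspace <- function(mesh, n, d) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(mesh)
  s <- as.numeric(v %*% n) - d
  scale <- max(abs(v)) + 1
  eps <- 1e-9 * scale
  if (any(abs(s) < eps)) {
    # tie: nudge the plane outward slightly (documented deterministic rule)
    d <- d + 7.3 * eps
    s <- as.numeric(v %*% n) - d
  }
  keep <- s <= 0
  if (all(keep)) return(mesh)
  if (!any(keep)) return(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))

  new_v <- list()
  nv0 <- nrow(v)
  cut_env <- new.env()  # undirected original edge -> new vertex id
  cut_point <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    got <- cut_env[[key]]
    if (!is.null(got)) return(got)
    t <- s[a] / (s[a] - s[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    new_v[[length(new_v) + 1L]] <<- p
    id <- nv0 + length(new_v)
    cut_env[[key]] <- id
    id
  }
  out_f <- list()
  cut_seg <- list()  # directed boundary segments (a_id, b_id)
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    inside <- keep[tri]
    ni <- sum(inside)
    if (ni == 3L) { out_f[[length(out_f) + 1L]] <- tri; next }
    if (ni == 0L) next
    # rotate so pattern starts with the unique in/out vertex
    ord <- tri
    ins <- inside
    while (!((ni == 1L && ins[1] && !ins[2]) ||
             (ni == 2L && !ins[1] && ins[2]))) {
      ord <- ord[c(2, 3, 1)]
      ins <- ins[c(2, 3, 1)]
    }
    if (ni == 1L) {
      a <- ord[1]; b <- ord[2]; c <- ord[3]
      pab <- cut_point(a, b)
      pca <- cut_point(c, a)
      out_f[[length(out_f) + 1L]] <- c(a, pab, pca)
      cut_seg[[length(cut_seg) + 1L]] <- c(pab, pca)
    } else {
      a <- ord[1]; b <- ord[2]; c <- ord[3]  # a out, b c in
      pab <- cut_point(a, b)
      pca <- cut_point(c, a)
      out_f[[length(out_f) + 1L]] <- c(pab, b, c)
      out_f[[length(out_f) + 1L]] <- c(pab, c, pca)
      cut_seg[[length(cut_seg) + 1L]] <- c(pca, pab)
    }
  }
  verts <- rbind(v, do.call(rbind, new_v))
  faces <- do.call(rbind, out_f)

  # chain directed cut segments into loops, triangulate caps (reversed)
  if (length(cut_seg) > 0) {
    segm <- do.call(rbind, cut_seg)
    nxt <- new.env()
    for (r in seq_len(nrow(segm))) nxt[[as.character(segm[r, 1])]] <- segm[r, 2]
    visited <- new.env()
    # 2-D basis in the plane
    bu <- if (abs(n[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    bu <- bu - sum(bu * n) * n
    bu <- bu / sqrt(sum(bu^2))
    bv <- c(n[2] * bu[3] - n[3] * bu[2], n[3] * bu[1] - n[1] * bu[3],
            n[1] * bu[2] - n[2] * bu[1])
    for (r in seq_len(nrow(segm))) {
      start <- segm[r, 1]
      if (!is.null(visited[[as.character(start)]])) next
      loop <- integer(0)
      cur <- start
      ok <- TRUE
      repeat {
        if (!is.null(visited[[as.character(cur)]])) { ok <- FALSE; break }
        visited[[as.character(cur)]] <- TRUE
        loop <- c(loop, cur)
        nx <- nxt[[as.character(cur)]]
        if (is.null(nx)) { ok <- FALSE; break }
        cur <- nx
        if (cur == start) break
      }
      if (!ok || length(loop) < 3) next
      # cap with reversed orientation so shared edges oppose
      loop <- rev(loop)
      p2 <- cbind(as.numeric(verts[loop, ] %*% bu),
                  as.numeric(verts[loop, ] %*% bv))
      tris <- earclip(p2)
      if (nrow(tris) > 0) {
        faces <- rbind(faces, matrix(loop[tris], ncol = 3))
      }
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  tri_mesh(verts[used, , drop = FALSE],
           matrix(remap[faces], ncol = 3))
}

# 2-D ear clipping; returns index triples into the polygon
earclip <- function(p) {
  n <- nrow(p)
  if (n < 3) return(matrix(0L, 0, 3))
  area2 <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
  idx <- if (area2 < 0) rev(seq_len(n)) else seq_len(n)
  tris <- matrix(0L, 0, 3)
  guard <- 0L
  while (length(idx) > 3 && guard < 10000L) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      a <- idx[(i - 2) %% m + 1]; b <- idx[(i - 1) %% m + 1]
      c <- idx[i %% m + 1]
      cr <- (p[b, 1] - p[a, 1]) * (p[c, 2] - p[a, 2]) -
        (p[b, 2] - p[a, 2]) * (p[c, 1] - p[a, 1])
      if (cr <= 1e-14) next  # reflex or degenerate
      others <- setdiff(idx, c(a, b, c))
      if (length(others) > 0 && any(point_in_tri(p[others, , drop = FALSE],
                                                 p[a, ], p[b, ], p[c, ]))) {
        next
      }
      tris <- rbind(tris, c(a, b, c))
      idx <- idx[idx != b]
      clipped <- TRUE
      break
    }
    if (!clipped) break  # give up on pathological remainder
  }
  if (length(idx) == 3) tris <- rbind(tris, idx)
  tris
}

point_in_tri <- function(q, a, b, c) {
  s1 <- (b[1] - a[1]) * (q[, 2] - a[2]) - (b[2] - a[2]) * (q[, 1] - a[1])
  s2 <- (c[1] - b[1]) * (q[, 2] - b[2]) - (c[2] - b[2]) * (q[, 1] - b[1])
  s3 <- (a[1] - c[1]) * (q[, 2] - c[2]) - (a[2] - c[2]) * (q[, 1] - c[1])
  (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
}

#' Clip a watertight mesh to a block, re-closing the cuts
#'
#' Sequentially clips against the six box planes; each cut cross-section
#' is re-capped so the output is again watertight. An empty intersection
#' yields an empty (valid) mesh.
#'
#' @param mesh A watertight [tri_mesh()].
#' @param block A [block3()].
#' @return A [tri_mesh()].
#' @export
clip_to_block <- function(mesh, block) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(block, "block3"))
  if (nrow(mesh$faces) > 0 && !check_watertight(mesh)$watertight) {
    stop("clip_to_block requires a watertight input mesh", call. = FALSE)
  }
  out <- mesh
  for (axis in 1:3) {
    n <- c(0, 0, 0)
    n[axis] <- 1
    out <- clip_halfspace(out, n, block$max[axis])
    out <- clip_halfspace(out, -n, -block$min[axis])
    if (nrow(out$faces) == 0) return(out)
  }
  out
}

# --------------------------------------------------------------------------
# Solid voxelization

block_dims <- function(block, spacing) {
  d <- as.integer(round((block$max - block$min) / spacing))
  if (any(d < 1L)) stop("block smaller than one voxel", call. = FALSE)
  d
}

#' Solid-voxelize a watertight mesh
#'
#' A voxel is occupied iff its center lies inside the solid, decided by
#' ray-crossing parity along the scan axis. Parity is evaluated per
#' connected mesh component and OR-ed, so unions of overlapping closed
#' components (e.g. capsule morphologies) fill correctly. Scan rays that
#' meet an edge or vertex exactly are retried from a deterministically
#' jittered origin. With `conservative = TRUE`, voxels overlapped by any
#' triangle's bounding box are additionally marked.
#'
#' @param mesh A watertight [tri_mesh()] (enforced; offending edges are
#'   reported).
#' @param spacing Voxel edge length (um).
#' @param block A [block3()] defining the grid extent.
#' @param axis Scan axis, `"x"`, `"y"` or `"z"`.
#' @param conservative Also mark boundary-intersecting voxels.
#' @param label Label value for occupied voxels.
#' @param material Optional [optical_material()] attached to `label`.
#' @return A [voxel_grid()] with binary occupancy.
#' @export
voxelize_solid <- function(mesh, spacing, block, axis = "x",
                           conservative = FALSE, label = 1L,
                           material = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(block, "block3"))
  dims <- block_dims(block, spacing)
  if (nrow(mesh$faces) == 0) {
    occ <- array(0L, dim = dims)
  } else {
    wt <- check_watertight(mesh)
    if (!wt$watertight) {
      stop(paste0("mesh is not watertight; offending edges: ",
                  paste(utils::head(paste0("(", wt$report$v1, ",",
                                           wt$report$v2, ")"), 10),
                        collapse = " ")), call. = FALSE)
    }
    ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z")) - 1L
    comp <- mesh_components(mesh)
    occ <- array(cpp_voxelize(mesh$vertices, mesh$faces, comp,
                              as.integer(dims), block$min, spacing, ax),
                 dim = dims)
    if (conservative) {
      v <- mesh$vertices
      f <- mesh$faces
      for (r in seq_len(nrow(f))) {
        tv <- v[f[r, ], , drop = FALSE]
        lo <- pmax(floor((apply(tv, 2, min) - block$min) / spacing), 0)
        hi <- pmin(floor((apply(tv, 2, max) - block$min) / spacing),
                   dims - 1)
        if (any(hi < lo)) next
        occ[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L,
            (lo[3]:hi[3]) + 1L] <- 1L
      }
    }
  }
  mats <- list()
  if (!is.null(material)) mats[[as.character(label)]] <- material
  else mats[[as.character(label)]] <- optical_material(0, 0, g = 0)
  voxel_grid(occ * as.integer(label), spacing = spacing,
             origin = block$min, materials = mats)
}

#' Rasterize a morphology directly into a voxel grid
#'
#' Distance-based alternative to meshing + [voxelize_solid()]: a voxel is
#' occupied iff its center lies within the soma sphere or within any
#' tapered capsule (closest axis point with linearly interpolated
#' radius).
#'
#' @param morph A [generate_morphology()] result.
#' @param spacing Voxel edge length (um).
#' @param block A [block3()].
#' @param label,material As in [voxelize_solid()].
#' @return A [voxel_grid()].
#' @export
rasterize_morphology <- function(morph, spacing, block, label = 1L,
                                 material = NULL) {
  stopifnot(inherits(morph, "morphology"), inherits(block, "block3"))
  dims <- block_dims(block, spacing)
  cx <- block$min[1] + (seq_len(dims[1]) - 0.5) * spacing
  cy <- block$min[2] + (seq_len(dims[2]) - 0.5) * spacing
  cz <- block$min[3] + (seq_len(dims[3]) - 0.5) * spacing
  pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  ctr <- morph$soma$center
  occ <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
    (pts[, 3] - ctr[3])^2 <= morph$soma$radius^2
  s <- morph$segments
  for (i in seq_len(nrow(s))) {
    p0 <- c(s$x0[i], s$y0[i], s$z0[i])
    p1 <- c(s$x1[i], s$y1[i], s$z1[i])
    d <- p1 - p0
    len2 <- sum(d^2)
    if (len2 < 1e-18) next
    rel <- sweep(pts, 2, p0)
    t <- pmin(pmax(as.numeric(rel %*% d) / len2, 0), 1)
    rad <- s$r0[i] + (s$r1[i] - s$r0[i]) * t
    dist2 <- (rel[, 1] - t * d[1])^2 + (rel[, 2] - t * d[2])^2 +
      (rel[, 3] - t * d[3])^2
    occ <- occ | (dist2 <= rad^2)
  }
  mats <- list()
  if (!is.null(material)) mats[[as.character(label)]] <- material
  else mats[[as.character(label)]] <- optical_material(0, 0, g = 0)
  voxel_grid(array(as.integer(occ) * as.integer(label), dim = dims),
             spacing = spacing, origin = block$min, materials = mats)
}

# --------------------------------------------------------------------------
# Interchange formats

#' Write / read Wavefront OBJ
#' @param mesh A [tri_mesh()].
#' @param path File path.
#' @return `path` (write) or a `tri_mesh` (read).
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fluortrace mesh", con)
  if (nrow(mesh$vertices) > 0) {
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  }
  if (nrow(mesh$faces) > 0) {
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  parse3 <- function(lines, prefix) {
    if (length(lines) == 0) return(matrix(0, 0, 3))
    m <- do.call(rbind, strsplit(trimws(sub(prefix, "", lines)), "\\s+"))
    # tolerate v/vt/vn face syntax
    m <- apply(m, 2, function(col) as.numeric(sub("/.*", "", col)))
    matrix(m, ncol = 3)
  }
  tri_mesh(parse3(vs, "^v "), parse3(fs, "^f "))
}

#' Write / read a morphology as SWC-style text
#'
#' Columns: id, type, x, y, z, radius, parent. The soma is sample 1
#' (type 1); each stem writes its start point as a junction sample
#' attached to the soma, and every segment endpoint becomes a sample
#' whose parent is its segment's start sample. Round-trips exactly.
#'
#' @param morph A [generate_morphology()] result.
#' @param path File path.
#' @return `path` (write) or a `morphology` (read).
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "morphology"))
  rows <- list()
  ctr <- morph$soma$center
  rows[[1]] <- c(1, 1, ctr, morph$soma$radius, -1)
  s <- morph$segments
  end_sample <- integer(nrow(s))  # sample id of each segment's p1
  nid <- 1L
  for (i in seq_len(nrow(s))) {
    if (s$parent[i] == 0L) {
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <- c(nid, 3, s$x0[i], s$y0[i], s$z0[i],
                                     s$r0[i], 1)
      start_id <- nid
    } else {
      start_id <- end_sample[s$parent[i]]
    }
    nid <- nid + 1L
    rows[[length(rows) + 1L]] <- c(nid, 3, s$x1[i], s$y1[i], s$z1[i],
                                   s$r1[i], start_id)
    end_sample[i] <- nid
  }
  m <- do.call(rbind, rows)
  writeLines(c("# id type x y z radius parent",
               sprintf("%d %d %.9g %.9g %.9g %.9g %d", m[, 1], m[, 2],
                       m[, 3], m[, 4], m[, 5], m[, 6], m[, 7])), path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(trimws(ln), "#") & nzchar(trimws(ln))]
  m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  soma_row <- m[m[, 7] == -1, , drop = FALSE][1, ]
  ids <- m[, 1]
  seg_rows <- which(m[, 7] > 1)  # samples attached to non-soma parents
  segments <- data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                         r0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                         z1 = numeric(0), r1 = numeric(0),
                         parent = integer(0), depth = integer(0))
  sample_of_segment <- integer(0)  # end-sample id -> segment index
  for (r in seg_rows) {
    pid <- m[r, 7]
    prow <- m[match(pid, ids), ]
    parent_seg <- if (pid %in% names(sample_of_segment)) {
      sample_of_segment[[as.character(pid)]]
    } else 0L
    segments <- rbind(segments, data.frame(
      x0 = prow[3], y0 = prow[4], z0 = prow[5], r0 = prow[6],
      x1 = m[r, 3], y1 = m[r, 4], z1 = m[r, 5], r1 = m[r, 6],
      parent = as.integer(parent_seg), depth = NA_integer_))
    sample_of_segment[[as.character(m[r, 1])]] <- nrow(segments)
  }
  rownames(segments) <- NULL
  structure(list(soma = list(center = soma_row[3:5],
                             radius = soma_row[6]),
                 segments = segments),
            class = "morphology")
}
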