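# Triangulated pocket-imprint surfaces.
#
# The solvent-excluded surface of the sphere cluster is extracted as an
# iso-surface of a signed distance field: the union of probe-inflated
# spheres is voxelized, interior depth is measured with an exact Euclidean
# distance transform, and the field is contoured at depth = probe radius
# (morphological dilate-erode by the probe). Contouring uses marching
# tetrahedra on a 6-tetrahedron cube decomposition, which yields a closed
# manifold triangulation without ambiguous cases.

#' Surface mesh constructor
#'
#' @param vertices n x 3 coordinate matrix.
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return Object of class `surface_mesh` with unit `face_normals` and
#'   area-weighted `vertex_normals` (orientation as given by face winding).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- rbind(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
  m$face_normals <- mesh_face_normals(m)
  m$vertex_normals <- mesh_vertex_normals(m)
  m
}

mesh_face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-300)
}

mesh_vertex_normals <- function(mesh) {
  f <- mesh$faces
  fn <- mesh_face_normals(mesh)
  a2 <- mesh_face_areas(mesh)           # area weighting
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    for (d in 1:3) {
      vn[, d] <- vn[, d] + unname(tapply_sum(fn[, d] * a2, f[, c],
        nrow(mesh$vertices)))
    }
  }
  len <- sqrt(rowSums(vn^2))
  vn / pmax(len, 1e-300)
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Face areas of a mesh
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of triangle areas.
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Total surface area
#' @param mesh A `surface_mesh`.
#' @return Scalar area.
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' Euler characteristic V - E + F
#' @param mesh A `surface_mesh`.
#' @return Integer Euler characteristic (2 for a closed genus-0 surface).
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

# connected components over shared vertices; returns face component labels
mesh_face_components <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  vc <- igraph::components(g)$membership
  vc[f[, 1]]
}

keep_largest_component <- function(mesh) {
  comp <- mesh_face_components(mesh)
  tab <- table(comp)
  if (length(tab) > 1) {
    warning("mesh has ", length(tab),
      " disconnected components; keeping the largest")
    mesh <- surface_mesh(mesh$vertices,
      mesh$faces[comp == as.integer(names(which.max(tab))), , drop = FALSE])
    mesh <- clean_mesh(mesh)
  }
  mesh
}

# ---- exact squared Euclidean distance transform (separable lower envelope)

BIGF <- 1e20

edt_1d <- function(f) {
  n <- length(f)
  if (all(f >= BIGF) || all(f == 0)) return(f)
  d <- numeric(n)
  v <- integer(n)
  zz <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  zz[1] <- -BIGF
  zz[2] <- BIGF
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= zz[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    zz[k] <- s
    zz[k + 1] <- BIGF
  }
  k <- 1L
  for (q in 1:n) {
    while (zz[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# squared distance (in voxel units) from each voxel to the nearest FALSE
# voxel of `inside` (3D logical array)
edt3 <- function(inside) {
  dims <- dim(inside)
  f <- array(ifelse(inside, BIGF, 0), dims)
  for (k in seq_len(dims[3])) {
    sl <- f[, , k]
    sl <- apply(sl, 2, edt_1d)
    sl <- t(apply(sl, 1, edt_1d))
    f[, , k] <- sl
  }
  # third axis
  nxy <- dims[1] * dims[2]
  f <- matrix(f, nrow = nxy, ncol = dims[3])
  f <- t(apply(f, 1, edt_1d))
  array(f, dims)
}

# ---- marching tetrahedra

MT_OFF <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
MT_TETS <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                 c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

# iso-surface of a 3D scalar field sampled at xs x ys x zs; returns an
# unwelded triangle soup (each face has its own 3 vertices)
marching_tetrahedra <- function(field, xs, ys, zs, iso = 0) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  stopifnot(all(dim(field) == c(nx, ny, nz)))
  ci <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  cj <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  ck <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  lin <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny

  corn <- vapply(1:8, function(c) {
    field[lin(ci + MT_OFF[c, 1], cj + MT_OFF[c, 2], ck + MT_OFF[c, 3])]
  }, numeric(length(ci)))
  act <- which(matrixStats_rowMins(corn) < iso & matrixStats_rowMaxs(corn) >= iso)
  if (!length(act)) stop("iso-surface is empty on this grid")
  ci <- ci[act]; cj <- cj[act]; ck <- ck[act]
  corn <- corn[act, , drop = FALSE]

  corner_pos <- function(c) {
    cbind(xs[ci + MT_OFF[c, 1]], ys[cj + MT_OFF[c, 2]], zs[ck + MT_OFF[c, 3]])
  }
  pos <- lapply(1:8, corner_pos)

  tris <- vector("list", 64)
  nt <- 0L
  emit <- function(p1, p2, p3) {
    nt <<- nt + 1L
    tris[[nt]] <<- cbind(p1, p2, p3)  # ncell x 9
  }
  interp <- function(pa, va, pb, vb) {
    t <- (iso - va) / (vb - va)
    pa + t * (pb - pa)
  }

  for (tt in seq_len(nrow(MT_TETS))) {
    tc <- MT_TETS[tt, ]
    v <- corn[, tc, drop = FALSE]
    p <- pos[tc]
    inside <- v < iso
    case <- inside %*% c(1, 2, 4, 8)
    for (a in 1:4) {
      others <- setdiff(1:4, a)
      sel <- which(case == 2^(a - 1) | case == 15 - 2^(a - 1))
      if (length(sel)) {
        pa <- p[[a]][sel, , drop = FALSE]; va <- v[sel, a]
        q <- lapply(others, function(b) {
          interp(pa, va, p[[b]][sel, , drop = FALSE], v[sel, b])
        })
        emit(q[[1]], q[[2]], q[[3]])
      }
    }
    prs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pi in seq_len(nrow(prs))) {
      a <- prs[pi, 1]; b <- prs[pi, 2]
      cd <- setdiff(1:4, c(a, b))
      sel <- which(case == 2^(a - 1) + 2^(b - 1))
      if (length(sel)) {
        pa <- p[[a]][sel, , drop = FALSE]; va <- v[sel, a]
        pb <- p[[b]][sel, , drop = FALSE]; vb <- v[sel, b]
        e_ac <- interp(pa, va, p[[cd[1]]][sel, , drop = FALSE], v[sel, cd[1]])
        e_ad <- interp(pa, va, p[[cd[2]]][sel, , drop = FALSE], v[sel, cd[2]])
        e_bd <- interp(pb, vb, p[[cd[2]]][sel, , drop = FALSE], v[sel, cd[2]])
        e_bc <- interp(pb, vb, p[[cd[1]]][sel, , drop = FALSE], v[sel, cd[1]])
        emit(e_ac, e_ad, e_bd)
        emit(e_ac, e_bd, e_bc)
      }
    }
  }
  soup <- do.call(rbind, tris[seq_len(nt)])
  verts <- rbind(soup[, 1:3], soup[, 4:6], soup[, 7:9])
  nf <- nrow(soup)
  faces <- cbind(seq_len(nf), seq_len(nf) + nf, seq_len(nf) + 2L * nf)
  weld_mesh(verts, faces)
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

# merge coincident vertices (exact arithmetic duplicates up to 1e-9)
weld_mesh <- function(verts, faces) {
  key <- paste(round(verts[, 1], 9), round(verts[, 2], 9),
               round(verts[, 3], 9))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- verts[first, , drop = FALSE]
  newf <- matrix(map[faces], ncol = 3)
  surface_mesh(newv, newf)
}

#' Triangulate the solvent-excluded surface of a sphere cluster
#'
#' Extracts the closed, outward-oriented surface of the union of pocket
#' spheres traced by a probe of the given radius. Disconnected clusters
#' emit the surface of the largest one with a warning.
#'
#' @param spheres A `pocket_spheres` object.
#' @param probe Probe radius in Å (default 1.5).
#' @param density Target vertex density in vertices/Å^2 (default 3); sets
#'   the contouring grid spacing unless `spacing` is given.
#' @param spacing Optional grid spacing override (Å).
#' @return A cleaned `surface_mesh`.
#' @export
triangulate_surface <- function(spheres, probe = 1.5, density = 3.0,
                                spacing = NULL) {
  if (!length(spheres$radius)) stop("empty sphere set")
  stopifnot(probe >= 0)
  keep <- spheres$cluster == 1L
  if (!all(keep)) {
    warning("sphere set has ", max(spheres$cluster),
      " clusters; meshing the largest")
  }
  ctr <- spheres$center[keep, , drop = FALSE]
  rad <- spheres$radius[keep]
  # marching tetrahedra emit ~MT_VERTEX_FACTOR vertices per h^2 of surface
  if (is.null(spacing)) spacing <- sqrt(MT_VERTEX_FACTOR / density)
  h <- spacing

  lo <- apply(ctr - rad, 2, min) - probe - 2 * h
  hi <- apply(ctr + rad, 2, max) + probe + 2 * h
  xs <- seq(lo[1], hi[1], by = h)
  ys <- seq(lo[2], hi[2], by = h)
  zs <- seq(lo[3], hi[3], by = h)
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))

  # f1: min over spheres of distance to the probe-inflated sphere surface
  f1 <- rep(Inf, length(gx))
  for (s in seq_along(rad)) {
    d <- sqrt((gx - ctr[s, 1])^2 + (gy - ctr[s, 2])^2 +
              (gz - ctr[s, 3])^2) - (rad[s] + probe)
    f1 <- pmin(f1, d)
  }
  dims <- c(length(xs), length(ys), length(zs))
  f1 <- array(f1, dims)

  # interior depth: lower bound from f1 (exact where one sphere dominates),
  # improved in crevices by the distance transform to the exterior, with
  # the voxel-center excess subtracted so the estimate never overshoots
  depth_edt <- sqrt(edt3(f1 <= 0)) * h - (sqrt(3) / 2) * h
  depth <- pmax(-f1, depth_edt)
  field <- ifelse(f1 > 0, f1, -depth)

  mesh <- marching_tetrahedra(field, xs, ys, zs, iso = -probe)
  mesh <- orient_by_field(mesh, field, xs, ys, zs)
  mesh <- clean_mesh(mesh)
  mesh <- keep_largest_component(mesh)
  mesh
}

# empirical vertices-per-h^2 yield of the tetrahedral contouring
MT_VERTEX_FACTOR <- 4.7

# flip each face whose normal opposes the trilinear field gradient, so all
# normals point toward increasing field values (outward for signed distance)
orient_by_field <- function(mesh, field, xs, ys, zs) {
  f <- mesh$faces
  cen <- (mesh$vertices[f[, 1], , drop = FALSE] +
          mesh$vertices[f[, 2], , drop = FALSE] +
          mesh$vertices[f[, 3], , drop = FALSE]) / 3
  g <- field_gradient(field, xs, ys, zs, cen)
  fn <- mesh_face_normals(mesh)
  flip <- rowSums(g * fn) < 0
  f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
  surface_mesh(mesh$vertices, f)
}

# central-difference gradient of a gridded field at arbitrary points
field_gradient <- function(field, xs, ys, zs, pts) {
  h <- c(xs[2] - xs[1], ys[2] - ys[1], zs[2] - zs[1])
  interp <- function(p) trilinear(field, xs, ys, zs, p)
  g <- matrix(0, nrow(pts), 3)
  for (d in 1:3) {
    e <- matrix(0, 1, 3); e[d] <- h[d] / 2
    g[, d] <- (interp(sweep(pts, 2, -e[1, ])) -
               interp(sweep(pts, 2, e[1, ]))) / h[d]
  }
  g
}

trilinear <- function(field, xs, ys, zs, pts) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  ix <- pmin(pmax(findInterval(pts[, 1], xs), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(pts[, 2], ys), 1L), ny - 1L)
  iz <- pmin(pmax(findInterval(pts[, 3], zs), 1L), nz - 1L)
  tx <- (pts[, 1] - xs[ix]) / (xs[ix + 1] - xs[ix])
  ty <- (pts[, 2] - ys[iy]) / (ys[iy + 1] - ys[iy])
  tz <- (pts[, 3] - zs[iz]) / (zs[iz + 1] - zs[iz])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  tz <- pmin(pmax(tz, 0), 1)
  lin <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
         (if (dz) tz else 1 - tz)
    v <- v + w * field[lin(ix + dx, iy + dy, iz + dz)]
  }
  v
}

#' Clean a mesh
#'
#' Removes non-finite vertices, zero-area (degenerate) faces, duplicate
#' faces (same vertex triple in any winding; first kept) and unreferenced
#' vertices, remapping indices while preserving the order of surviving
#' vertices. Idempotent.
#'
#' @param mesh A `surface_mesh`.
#' @param area_tol Faces with area below this are degenerate.
#' @return A cleaned `surface_mesh`.
#' @export
clean_mesh <- function(mesh, area_tol = 1e-10) {
  v <- mesh$vertices
  f <- mesh$faces
  finite_v <- rowSums(is.finite(v)) == 3
  f <- f[finite_v[f[, 1]] & finite_v[f[, 2]] & finite_v[f[, 3]], , drop = FALSE]
  # degenerate: repeated index or zero area
  rep_idx <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!rep_idx, , drop = FALSE]
  if (nrow(f)) {
    areas <- mesh_face_areas(list(vertices = v, faces = f))
    f <- f[areas > area_tol, , drop = FALSE]
  }
  if (nrow(f)) {
    key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
    f <- f[!duplicated(key), , drop = FALSE]
  }
  if (!nrow(f)) stop("mesh empty after cleaning")
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(v))
  map[used] <- seq_along(used)
  surface_mesh(v[used, , drop = FALSE], matrix(map[f], ncol = 3))
}

#' Laplacian mesh smoothing
#'
#' Each iteration replaces every vertex by the arithmetic mean of its
#' 1-ring neighbours (uniform umbrella weights). Connectivity is unchanged;
#' normals are recomputed.
#'
#' @param mesh A clean `surface_mesh`.
#' @param iterations Number of smoothing passes (default 4); 0 is the
#'   identity.
#' @return The smoothed `surface_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations = 4L) {
  stopifnot(iterations >= 0)
  if (iterations == 0) return(mesh)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(rbind(e, e[, 2:1]))
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    v <- as.matrix(A %*% v) / deg
  }
  surface_mesh(v, f)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 offset applied after rotation.
#' @return The transformed `surface_mesh` (normals recomputed).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, -translation)
  surface_mesh(v, mesh$faces)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d faces, area %.1f\n",
    nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}
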