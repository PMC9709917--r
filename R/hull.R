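# 3D convex hull (quickhull) and point-in-hull tests.
#
# Only the facet planes are needed downstream: a point is inside the closed
# hull iff its signed distance to every outward facet plane is <= tol.

#' Convex hull of a 3D point cloud
#'
#' Quickhull in three dimensions. Returns the hull facets as vertex-index
#' triples with outward unit normals and plane offsets, so membership tests
#' reduce to signed plane distances.
#'
#' @param points n x 3 matrix, n >= 4, not all coplanar.
#' @param tol Degeneracy tolerance (Å).
#' @return List with `points`, `faces` (m x 3 indices), `normals` (m x 3
#'   outward units), `offsets` (m, so that a point p is on facet plane i when
#'   `normals[i,] . p == offsets[i]`).
#' @export
convex_hull <- function(points, tol = 1e-9) {
  pts <- rbind(points)
  n <- nrow(pts)
  if (n < 4) stop("convex hull needs at least 4 points")

  # initial simplex: extremes along x, farthest from segment, then plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (sqrt(sum((pts[i1, ] - pts[i2, ])^2)) < tol) {
    stop("degenerate point set (all points coincident along x)")
  }
  d <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossm <- cbind(
    rel[, 2] * d[3] - rel[, 3] * d[2],
    rel[, 3] * d[1] - rel[, 1] * d[3],
    rel[, 1] * d[2] - rel[, 2] * d[1]
  )
  i3 <- which.max(rowSums(crossm^2))
  if (sqrt(sum(crossm[i3, ]^2)) / sqrt(sum(d^2)) < tol) {
    stop("degenerate (collinear) point set")
  }
  nrm0 <- vcross(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- abs(rel %*% nrm0) / sqrt(sum(nrm0^2))
  i4 <- which.max(h)
  if (h[i4] < tol) stop("degenerate (coplanar) point set")

  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, function(f) orient_face(f, pts, centroid)))

  face_plane <- function(f) {
    nr <- vcross(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nr <- nr / sqrt(sum(nr^2))
    c(nr, sum(nr * pts[f[1], ]))
  }
  planes <- t(apply(faces, 1, face_plane))

  # outside sets: for each face, points strictly above its plane
  assign_outside <- function(face_rows, cand) {
    lapply(face_rows, function(i) {
      s <- pts[cand, , drop = FALSE] %*% planes[i, 1:3] - planes[i, 4]
      cand[s > tol]
    })
  }
  outside <- assign_outside(seq_len(nrow(faces)), seq_len(n))

  repeat {
    fi <- which(vapply(outside, length, integer(1)) > 0)[1]
    if (is.na(fi)) break
    cand <- outside[[fi]]
    s <- pts[cand, , drop = FALSE] %*% planes[fi, 1:3] - planes[fi, 4]
    apex <- cand[which.max(s)]

    # visible faces from apex
    vis <- which(planes[, 1:3, drop = FALSE] %*% pts[apex, ] - planes[, 4] > tol)
    if (!length(vis)) { # numerical guard: drop the point
      outside[[fi]] <- setdiff(outside[[fi]], apex)
      next
    }
    # horizon = edges of visible faces shared with exactly one visible face
    edges <- do.call(rbind, lapply(vis, function(i) {
      f <- faces[i, ]
      rbind(sort(c(f[1], f[2])), sort(c(f[2], f[3])), sort(c(f[1], f[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]

    pool <- unique(unlist(outside[vis]))
    pool <- setdiff(pool, apex)

    faces <- faces[-vis, , drop = FALSE]
    planes <- planes[-vis, , drop = FALSE]
    outside <- outside[-vis]

    newf <- t(apply(horizon, 1, function(e) {
      orient_face(c(e[1], e[2], apex), pts, centroid)
    }))
    newp <- t(apply(newf, 1, face_plane))
    faces <- rbind(faces, newf)
    planes <- rbind(planes, newp)
    newrows <- seq(nrow(faces) - nrow(newf) + 1, nrow(faces))
    outside <- c(outside, assign_outside(newrows, pool))
  }

  list(points = pts, faces = faces,
       normals = planes[, 1:3, drop = FALSE], offsets = planes[, 4])
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# order face vertices so the normal points away from an interior point
orient_face <- function(f, pts, interior) {
  nr <- vcross(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(nr * (pts[f[1], ] - interior)) < 0) f <- f[c(1, 3, 2)]
  f
}

#' Point-in-convex-hull test
#'
#' Closed-hull convention: points on the boundary count as inside.
#'
#' @param hull Result of [convex_hull()].
#' @param points m x 3 matrix of query points.
#' @param tol Boundary tolerance (Å).
#' @return Logical vector of length m.
#' @export
hull_contains <- function(hull, points, tol = 1e-9) {
  pts <- rbind(points)
  s <- pts %*% t(hull$normals) - rep(hull$offsets, each = nrow(pts))
  apply(s <= tol, 1, all)
}
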