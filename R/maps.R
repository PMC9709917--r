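# Spherical feature maps by ray casting.
#
# The attributed pocket surface is scaled into the unit sphere; a ray is
# cast from every HEALPix pixel center toward the origin and the first
# mesh intersection recorded. Nine channels result: depth (distance
# traveled from the sphere before hitting), cos/sin of the angle between
# the outward face normal and the hit-to-pixel direction, mean charge and
# hydrophobicity of the hit face's vertices, and OR-aggregated DON, ACC,
# ALI, ARO bits.

#' Channel names of the nine spherical feature maps
#' @export
MAP_CHANNELS <- c("depth", "cos_angle", "sin_angle", "charge",
                  "hydrophobicity", "DON", "ACC", "ALI", "ARO")

#' Scale a pocket mesh into the unit sphere
#'
#' Translates the vertex centroid to the origin and scales uniformly so the
#' farthest vertex sits at radius 0.99 (leaving a gap so rays never start
#' exactly on the surface). Idempotent; aspect ratios preserved.
#'
#' @param mesh A `surface_mesh`.
#' @return The normalized `surface_mesh`.
#' @export
normalize_pocket <- function(mesh) {
  if (!nrow(mesh$vertices)) stop("empty mesh")
  v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
  rmax <- sqrt(max(rowSums(v^2)))
  if (rmax < 1e-12) stop("zero-extent mesh")
  surface_mesh(v * (0.99 / rmax), mesh$faces)
}

#' Cast pixel rays at a normalized pocket mesh
#'
#' Rays start at each pixel's unit vector and travel toward the origin.
#' For each pixel the first intersected triangle is recorded along with the
#' travel distance, barycentric coordinates and theta, the angle between
#' the outward face normal and the direction from the hit point back to
#' the pixel (a concentric sphere gives theta = 0 everywhere).
#'
#' @param mesh A normalized `surface_mesh` (see [normalize_pocket()]).
#' @param grid A [healpix_grid()].
#' @return List of per-pixel records: `hit` (logical), `face`, `t` (depth
#'   from the sphere surface), `u`, `v` (barycentrics on vertices 2/3),
#'   `cos_theta`, `sin_theta`.
#' @export
raycast <- function(mesh, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  origins <- grid$vec
  dirs <- -origins
  res <- raycast_mesh(origins, dirs, mesh$vertices, mesh$faces)
  hit <- res$face > 0L
  cos_theta <- rep(NA_real_, grid$n_pix)
  if (any(hit)) {
    fn <- mesh$face_normals[res$face[hit], , drop = FALSE]
    # direction from hit point back to pixel = +pixel unit vector
    ct <- rowSums(fn * origins[hit, , drop = FALSE])
    cos_theta[hit] <- pmin(pmax(ct, -1), 1)
  }
  list(hit = hit, face = res$face, t = res$t, u = res$u, v = res$v,
       cos_theta = cos_theta,
       sin_theta = sqrt(pmax(0, 1 - cos_theta^2)))
}

#' Assemble the nine spherical feature maps
#'
#' Per hit pixel: depth and the two normal-angle maps from the ray record;
#' charge and hydrophobicity as the mean over the three vertices of the hit
#' face; pseudocenter bits as the logical OR over those vertices. Missed
#' pixels carry depth 0, angles 0 and all-zero properties, and are flagged
#' in `miss_mask` (an open pocket mouth reads as far and featureless).
#'
#' @param hits Result of [raycast()].
#' @param mesh The mesh the rays were cast at.
#' @param props A `vertex_properties` object for that mesh.
#' @param grid The [healpix_grid()] used.
#' @return Object of class `spherical_maps`: list with `channels`
#'   (9 x n_pix matrix, rows named by channel), `miss_mask`, `n_side`.
#' @export
build_feature_maps <- function(hits, mesh, props, grid) {
  n_pix <- grid$n_pix
  ch <- matrix(0, length(MAP_CHANNELS), n_pix,
               dimnames = list(MAP_CHANNELS, NULL))
  hit <- hits$hit
  if (any(hit)) {
    f <- mesh$faces[hits$face[hit], , drop = FALSE]
    ch["depth", hit] <- hits$t[hit]
    ch["cos_angle", hit] <- hits$cos_theta[hit]
    ch["sin_angle", hit] <- hits$sin_theta[hit]
    ch["charge", hit] <- (props$charge[f[, 1]] + props$charge[f[, 2]] +
      props$charge[f[, 3]]) / 3
    ch["hydrophobicity", hit] <- (props$hydrophobicity[f[, 1]] +
      props$hydrophobicity[f[, 2]] + props$hydrophobicity[f[, 3]]) / 3
    for (b in c("DON", "ACC", "ALI", "ARO")) {
      ch[b, hit] <- pmax(props$pseudo[f[, 1], b], props$pseudo[f[, 2], b],
        props$pseudo[f[, 3], b])
    }
  }
  structure(list(channels = ch, miss_mask = as.integer(!hit),
                 n_side = grid$n_side), class = "spherical_maps")
}

#' Project an attributed pocket to spherical maps
#'
#' Convenience wrapper: normalize, ray-cast and aggregate in one call.
#'
#' @param mesh A `surface_mesh` (normalized internally).
#' @param props Its `vertex_properties`.
#' @param n_side HEALPix resolution (default 16, 3072 pixels).
#' @param grid Optional prebuilt [healpix_grid()].
#' @return A `spherical_maps` object.
#' @export
featurize_pocket <- function(mesh, props, n_side = 16, grid = NULL) {
  if (is.null(grid)) grid <- healpix_grid(n_side)
  mesh <- normalize_pocket(mesh)
  build_feature_maps(raycast(mesh, grid), mesh, props, grid)
}

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) via uniform unit quaternions;
#' deterministic under the current RNG state (or `seed` when given).
#'
#' @param seed Optional integer seed applied locally.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation_matrix <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Randomly rotate a mesh
#'
#' @param mesh A `surface_mesh`.
#' @param seed Optional seed for reproducible rotations.
#' @return The rotated mesh (normals recomputed).
#' @export
random_rotation <- function(mesh, seed = NULL) {
  transform_mesh(mesh, rotation = random_rotation_matrix(seed))
}

#' Rotate spherical maps by nearest-pixel resampling
#'
#' Resamples every channel at the rotated pixel directions (value at pixel
#' u taken from the pixel containing R^T u). Used for map-level rotation
#' augmentation during training.
#'
#' @param maps A `spherical_maps` object.
#' @param rotation 3 x 3 rotation matrix.
#' @param grid Optional prebuilt grid matching `maps$n_side`.
#' @return The rotated `spherical_maps`.
#' @export
rotate_maps <- function(maps, rotation, grid = NULL) {
  if (is.null(grid)) grid <- healpix_grid(maps$n_side)
  src <- healpix_lookup(grid, grid$vec %*% rotation)
  structure(list(channels = maps$channels[, src, drop = FALSE],
                 miss_mask = maps$miss_mask[src], n_side = maps$n_side),
            class = "spherical_maps")
}

#' Write spherical maps to a JSON file
#'
#' Single-file format: a JSON object with a header (n_side, ordering,
#' channel names, miss count) and the flattened channel values.
#'
#' @param maps A `spherical_maps` object.
#' @param file Output path.
#' @export
write_maps <- function(maps, file) {
  obj <- list(
    n_side = maps$n_side, ordering = "nested",
    channels = rownames(maps$channels),
    n_miss = sum(maps$miss_mask),
    miss_mask = as.integer(maps$miss_mask),
    values = as.vector(t(maps$channels)))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read spherical maps written by [write_maps()]
#' @param file Path to the JSON file.
#' @return A `spherical_maps` object.
#' @export
read_maps <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  n_pix <- 12 * obj$n_side^2
  ch <- t(matrix(obj$values, nrow = n_pix, ncol = length(obj$channels)))
  rownames(ch) <- obj$channels
  structure(list(channels = ch, miss_mask = as.integer(obj$miss_mask),
                 n_side = obj$n_side), class = "spherical_maps")
}

#' @export
print.spherical_maps <- function(x, ...) {
  cat(sprintf("spherical maps: %d channels x %d pixels (n_side=%d), %d misses\n",
    nrow(x$channels), ncol(x$channels), x$n_side, sum(x$miss_mask)))
  invisible(x)
}
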