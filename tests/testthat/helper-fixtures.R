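# Shared fixtures, built in code.

# a sphere-cluster mesh cached per session (cheap, deterministic)
unit_sphere_mesh <- local({
  cache <- NULL
  function(radius = 3) {
    if (is.null(cache)) {
      sph <- structure(list(center = rbind(c(0, 0, 0)), radius = radius,
        cluster = 1L), class = "pocket_spheres")
      cache <<- triangulate_surface(sph)
    }
    cache
  }
})

toy_pocket_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- toy_pocket_spec(cavity_radius = 5, mouth_angle = 60, seed = 3)
      cache <<- pocket_pipeline(make_toy_protein(spec))
    }
    cache
  }
})

# LP feasibility oracle for point-in-convex-hull (boot::simplex);
# coordinates shifted positive because the solver needs nonnegative RHS
lp_in_hull <- function(X, p) {
  shift <- apply(rbind(X, p), 2, min) - 1
  Xs <- sweep(X, 2, shift)
  ps <- p - shift
  n <- nrow(X)
  r <- suppressWarnings(boot::simplex(a = rep(0, n),
    A3 = rbind(t(Xs), rep(1, n)), b3 = c(ps, 1)))
  r$solved == 1
}

# independent scalar ray-triangle intersection: solve the 3x3 system
# o + t d = v1 + u (v2 - v1) + v (v3 - v1) with base solve()
raycast_oracle <- function(mesh, origins, dirs) {
  nray <- nrow(origins)
  out <- data.frame(face = integer(nray), t = NA_real_)
  for (r in seq_len(nray)) {
    best_t <- Inf; best_f <- 0L
    for (f in seq_len(nrow(mesh$faces))) {
      v1 <- mesh$vertices[mesh$faces[f, 1], ]
      v2 <- mesh$vertices[mesh$faces[f, 2], ]
      v3 <- mesh$vertices[mesh$faces[f, 3], ]
      A <- cbind(-dirs[r, ], v2 - v1, v3 - v1)
      if (abs(det(A)) < 1e-14) next
      sol <- solve(A, origins[r, ] - v1)
      t <- sol[1]; u <- sol[2]; v <- sol[3]
      if (u >= -1e-9 && v >= -1e-9 && u + v <= 1 + 1e-9 && t > 1e-9 &&
          t < best_t) {
        best_t <- t; best_f <- f
      }
    }
    out$face[r] <- best_f
    out$t[r] <- if (best_f) best_t else NA_real_
  }
  out
}

# exhaustive O(n^2) AUC pair counting
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
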