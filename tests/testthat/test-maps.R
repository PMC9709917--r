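test_that("normalization centers the mesh and scales to radius 0.99", {
  m <- unit_sphere_mesh()
  shifted <- transform_mesh(m, diag(3), c(5, -2, 7))
  n1 <- normalize_pocket(shifted)
  expect_lt(max(abs(colMeans(n1$vertices))), 1e-9)
  expect_equal(max(sqrt(rowSums(n1$vertices^2))), 0.99, tolerance = 1e-9)
  # idempotent
  n2 <- normalize_pocket(n1)
  expect_equal(n2$vertices, n1$vertices, tolerance = 1e-12)
  # aspect ratio preserved: pairwise distance ratios unchanged
  i <- c(1, 5); j <- c(20, 40)
  r_before <- dist(shifted$vertices[c(i, j), ])
  r_after <- dist(n1$vertices[c(i, j), ])
  expect_equal(as.numeric(r_after / r_before),
    rep(as.numeric(r_after / r_before)[1], 6), tolerance = 1e-9)
})

test_that("rays at a concentric sphere give uniform depth and zero angle", {
  sph <- structure(list(center = rbind(c(0, 0, 0)), radius = 3,
    cluster = 1L), class = "pocket_spheres")
  fine <- normalize_pocket(triangulate_surface(sph, spacing = 0.35))
  half <- surface_mesh(fine$vertices * (0.5 / 0.99), fine$faces)
  grid <- healpix_grid(4)
  hits <- raycast(half, grid)
  expect_true(all(hits$hit))
  # depth ~ 0.5 up to the facet sag of the inscribed triangulation
  expect_equal(mean(hits$t), 0.5, tolerance = 0.01)
  expect_true(all(abs(hits$t - 0.5) < 0.02))
  # outward normals nearly radial: theta ~ 0
  expect_true(all(hits$cos_theta > 0.98))
  expect_true(all(hits$sin_theta < 0.2))
})

test_that("ray casting agrees with the all-triangle oracle", {
  pp <- toy_pocket_cached()
  mesh <- normalize_pocket(pp$mesh)
  grid <- healpix_grid(2)
  hits <- raycast(mesh, grid)
  oracle <- raycast_oracle(mesh, grid$vec, -grid$vec)
  expect_equal(hits$face, oracle$face)
  expect_equal(hits$t, oracle$t, tolerance = 1e-9)
})

test_that("feature maps aggregate face-vertex properties correctly", {
  # one triangle straddling the +x axis, inside the unit sphere
  mesh <- surface_mesh(
    rbind(c(0.5, 0.3, -0.2), c(0.5, -0.3, -0.2), c(0.5, 0, 0.4)),
    rbind(c(1, 2, 3)))
  grid <- healpix_grid(4)
  props <- structure(list(
    pseudo = rbind(c(1L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L),
                   c(0L, 1L, 0L, 0L)),
    hydrophobicity = c(-1, 0, 1),
    charge = c(0.6, 0.6, -0.6)), class = "vertex_properties")
  colnames(props$pseudo) <- c("DON", "ACC", "ALI", "ARO")
  hits <- raycast(mesh, grid)
  maps <- build_feature_maps(hits, mesh, props, grid)
  expect_equal(dim(maps$channels), c(9, grid$n_pix))
  hit <- hits$hit
  expect_true(any(hit))
  # mean aggregation for continuous channels, OR for binary
  expect_true(all(abs(maps$channels["hydrophobicity", hit] - 0) < 1e-9))
  expect_true(all(abs(maps$channels["charge", hit] - 0.2) < 1e-9))
  expect_true(all(maps$channels["DON", hit] == 1))
  expect_true(all(maps$channels["ACC", hit] == 1))
  expect_true(all(maps$channels["ALI", hit] == 0))
  # missed pixels carry zeros and the miss mask
  expect_true(all(maps$channels[, !hit] == 0))
  expect_equal(maps$miss_mask, as.integer(!hit))
})

test_that("map channels respect their documented ranges on real pockets", {
  pp <- toy_pocket_cached()
  ch <- pp$maps$channels
  expect_true(all(ch["depth", ] >= 0 & ch["depth", ] <= 1))
  expect_true(all(ch["cos_angle", ] >= -1 & ch["cos_angle", ] <= 1))
  expect_true(all(ch["sin_angle", ] >= 0 & ch["sin_angle", ] <= 1))
  expect_true(all(ch["charge", ] >= -1 & ch["charge", ] <= 1))
  expect_true(all(abs(ch["hydrophobicity", ]) <= 1))
  expect_true(all(ch[c("DON", "ACC", "ALI", "ARO"), ] %in% c(0, 1)))
  # star-shaped enclosed pocket: every pixel hits
  expect_true(all(pp$maps$miss_mask == 0))
})

test_that("random rotations are uniform-seeded isometries", {
  R1 <- random_rotation_matrix(seed = 11)
  R2 <- random_rotation_matrix(seed = 11)
  expect_identical(R1, R2)
  expect_equal(t(R1) %*% R1, diag(3), tolerance = 1e-12)
  expect_equal(det(R1), 1, tolerance = 1e-12)
  m <- unit_sphere_mesh()
  mr <- random_rotation(m, seed = 11)
  d0 <- dist(m$vertices[1:30, ])
  d1 <- dist(mr$vertices[1:30, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("rotating then projecting matches projecting then resampling", {
  # histogram-level equivariance on a smooth synthetic pocket
  spec <- toy_pocket_spec(cavity_radius = 5, mouth_angle = 40,
    lining = c(aliphatic = 1), noise_sd = 0.02, seed = 5)
  pp <- pocket_pipeline(make_toy_protein(spec))
  R <- random_rotation_matrix(seed = 3)
  maps_rot <- featurize_pocket(transform_mesh(pp$mesh, R), pp$props)
  br <- seq(0, 1, length.out = 33)
  h0 <- hist(pp$maps$channels["depth", ], breaks = br, plot = FALSE)$counts
  h1 <- hist(maps_rot$channels["depth", ], breaks = br, plot = FALSE)$counts
  l1 <- sum(abs(h0 / sum(h0) - h1 / sum(h1)))
  expect_lt(l1, 0.05)
})

test_that("maps serialize to JSON and back losslessly", {
  pp <- toy_pocket_cached()
  f <- tempfile(fileext = ".json")
  write_maps(pp$maps, f)
  back <- read_maps(f)
  expect_equal(back$channels, pp$maps$channels)
  expect_equal(back$miss_mask, pp$maps$miss_mask)
  expect_equal(back$n_side, pp$maps$n_side)
})
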