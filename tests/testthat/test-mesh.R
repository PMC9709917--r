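test_that("single-sphere SES area matches the analytic sphere", {
  m <- unit_sphere_mesh()        # radius 3, probe 1.5, density 3
  expect_equal(mesh_area(m), 4 * pi * 9, tolerance = 0.05)
  expect_equal(mesh_euler(m), 2)
  # density within x2 of the requested 3 vertices/A^2
  dens <- nrow(m$vertices) / mesh_area(m)
  expect_gt(dens, 1.5)
  expect_lt(dens, 6)
  # all faces oriented outward for a star-shaped surface
  ctr <- m$vertices[m$faces[, 1], ]
  ctr <- ctr / sqrt(rowSums(ctr^2))
  expect_true(all(rowSums(m$face_normals * ctr) > 0))
})

test_that("multi-sphere clusters give closed genus-0 surfaces", {
  set.seed(3)
  ctr <- matrix(rnorm(30, sd = 1.5), ncol = 3)
  sph <- structure(list(center = ctr, radius = runif(10, 1.5, 2.5),
    cluster = rep(1L, 10)), class = "pocket_spheres")
  m <- triangulate_surface(sph)
  expect_equal(mesh_euler(m), 2)
  expect_true(all(is.finite(m$vertices)))
  expect_lt(max(abs(sqrt(rowSums(m$face_normals^2)) - 1)), 1e-9)
})

test_that("disconnected sphere clusters emit only the largest surface", {
  sph <- structure(list(center = rbind(c(0, 0, 0), c(30, 0, 0)),
    radius = c(3, 2), cluster = c(1L, 2L)), class = "pocket_spheres")
  expect_warning(m <- triangulate_surface(sph), "clusters")
  # area close to the larger sphere only
  expect_equal(mesh_area(m), 4 * pi * 9, tolerance = 0.06)
})

test_that("clean_mesh removes degenerate/duplicate faces and orphans", {
  m <- unit_sphere_mesh()
  v <- m$vertices
  f <- m$faces
  bad <- rbind(
    c(f[1, 1], f[1, 1], f[1, 2]),      # repeated index (zero area)
    f[2, c(2, 1, 3)],                  # duplicate of face 2, other winding
    f[1, ])                            # exact duplicate
  v2 <- rbind(v, c(99, 99, 99))        # unreferenced vertex
  dirty <- surface_mesh(v2, rbind(f, bad))
  cleaned <- clean_mesh(dirty)
  expect_equal(nrow(cleaned$faces), nrow(f))
  expect_equal(nrow(cleaned$vertices), nrow(v))
  # face-vertex coordinates identical before/after remapping
  expect_equal(cleaned$vertices[cleaned$faces[3, ], ], v[f[3, ], ])
  # idempotent
  again <- clean_mesh(cleaned)
  expect_identical(again$vertices, cleaned$vertices)
  expect_identical(again$faces, cleaned$faces)
  expect_error(clean_mesh(surface_mesh(v[1:3, ], rbind(c(1, 1, 2)))),
    "empty")
})

test_that("smoothing is 1-ring averaging, identity at 0 iterations", {
  # regular octahedron: each vertex's 4 neighbours average to -v/2... the
  # mean of the four equatorial neighbours of the apex is the origin, and
  # for a generic vertex the mean of its neighbours is computable by hand
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  m <- surface_mesh(v, f)
  expect_identical(smooth_mesh(m, 0), m)
  sm <- smooth_mesh(m, 1)
  # neighbours of vertex 1 are 3, 4, 5, 6 whose mean is (0, 0, 0); all
  # vertices collapse to the origin in one step by symmetry
  expect_equal(sm$vertices, matrix(0, 6, 3))
  expect_identical(sm$faces, m$faces)
  # smoothing a noisy sphere never increases area
  set.seed(8)
  m2 <- unit_sphere_mesh()
  noisy <- surface_mesh(m2$vertices + matrix(rnorm(length(m2$vertices),
    sd = 0.05), ncol = 3), m2$faces)
  areas <- mesh_area(noisy)
  cur <- noisy
  for (i in 1:4) {
    cur <- smooth_mesh(cur, 1)
    areas <- c(areas, mesh_area(cur))
  }
  expect_true(all(diff(areas) < 0))
  # four one-step passes equal one four-step call
  expect_equal(smooth_mesh(noisy, 4)$vertices, cur$vertices)
})

test_that("smoothing commutes with rigid transforms", {
  m <- unit_sphere_mesh()
  R <- random_rotation_matrix(seed = 4)
  a <- smooth_mesh(transform_mesh(m, R, c(1, 2, 3)), 2)$vertices
  b <- transform_mesh(smooth_mesh(m, 2), R, c(1, 2, 3))$vertices
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("PLY and OFF round-trip the mesh", {
  m <- unit_sphere_mesh()
  f1 <- tempfile(fileext = ".ply")
  write_ply(m, f1)                       # binary little-endian
  r1 <- read_ply(f1)
  expect_equal(r1$vertices, m$vertices, tolerance = 1e-6)  # float32
  expect_identical(r1$faces, m$faces)
  f2 <- tempfile(fileext = ".ply")
  write_ply(m, f2, format = "ascii")
  r2 <- read_ply(f2)
  expect_equal(r2$vertices, m$vertices, tolerance = 1e-6)
  expect_identical(r2$faces, m$faces)
  f3 <- tempfile(fileext = ".off")
  write_off(m, f3)
  lines <- readLines(f3)
  expect_identical(lines[1], "OFF")
  expect_equal(scan(text = lines[2], quiet = TRUE),
    c(nrow(m$vertices), nrow(m$faces), 0))
})
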