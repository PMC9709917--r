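# Pseudocenter construction, exposure filtering and vertex attribution.

# a glycine-like dipeptide backbone in a plane, with a preceding carbonyl C
dipeptide_atoms <- function() {
  atom_set(
    coord = rbind(
      c(-1.2, 0.8, 0),    # C of residue 1 (peptide carbonyl)
      c(-2.0, 1.8, 0),    # O of residue 1
      c(-2.0, -0.3, 0),   # CA of residue 1
      c(0, 0, 0),         # N of residue 2
      c(1.4, 0.3, 0),     # CA of residue 2
      c(2.3, -0.8, 0),    # C of residue 2
      c(3.5, -0.6, 0)),   # O of residue 2
    element = c("C", "O", "C", "N", "C", "C", "O"),
    chain = "A", resnum = c(1, 1, 1, 2, 2, 2, 2),
    resname = "GLY",
    atom_name = c("C", "O", "CA", "N", "CA", "C", "O"))
}

test_that("backbone pseudocenters follow the bisector and carbonyl rules", {
  pc <- build_pseudocenters(dipeptide_atoms())
  don <- pc[pc$kind == "DON", ]
  expect_equal(nrow(don), 1)       # residue 2 N (residue 1 has no prev C)
  expect_equal(c(don$x, don$y, don$z), c(0, 0, 0))
  # v along the projected N-H: opposite the C-N-CA bisector
  uC <- c(-1.2, 0.8, 0) / sqrt(sum(c(-1.2, 0.8, 0)^2))
  uCA <- c(1.4, 0.3, 0) / sqrt(sum(c(1.4, 0.3, 0)^2))
  vexp <- -(uC + uCA) / sqrt(sum((uC + uCA)^2))
  expect_equal(c(don$vx, don$vy, don$vz), vexp, tolerance = 1e-9)
  acc <- pc[pc$kind == "ACC", ]
  expect_equal(nrow(acc), 2)       # both backbone O
  a1 <- acc[acc$resnum == 1, ]
  vexp <- (c(-2.0, 1.8, 0) - c(-1.2, 0.8, 0))
  vexp <- vexp / sqrt(sum(vexp^2))
  expect_equal(c(a1$vx, a1$vy, a1$vz), vexp, tolerance = 1e-9)
})

test_that("aromatic rings give centroid centers with plane-normal v", {
  th <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  # tilt the ring to a non-axis plane and shift it
  R <- random_rotation_matrix(seed = 6)
  shift <- c(3, -1, 2)
  ringr <- sweep(ring %*% t(R), 2, -shift)
  atoms <- atom_set(ringr, element = "C", resname = "PHE", resnum = 1,
    atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
  pc <- build_pseudocenters(atoms)
  aro <- pc[pc$kind == "ARO", ]
  expect_equal(nrow(aro), 1)
  expect_equal(c(aro$x, aro$y, aro$z), colMeans(ringr), tolerance = 1e-9)
  # v perpendicular to every ring edge
  v <- c(aro$vx, aro$vy, aro$vz)
  edges <- ringr[c(2:6, 1), ] - ringr
  expect_lt(max(abs(edges %*% v)), 1e-9)
})

test_that("histidine side-chain nitrogens become mixed donor/acceptor", {
  th <- seq(0, by = 2 * pi / 5, length.out = 5)
  penta <- cbind(1.37 * cos(th), 1.37 * sin(th), 0)
  atoms <- atom_set(penta, element = c("C", "N", "C", "N", "C"),
    resname = "HIS", resnum = 1,
    atom_name = c("CG", "ND1", "CE1", "NE2", "CD2"))
  pc <- build_pseudocenters(atoms)
  dac <- pc[pc$kind == "DAC", ]
  expect_setequal(dac$label, c("ND1", "NE2"))
  # v points away from the ring centroid (radially outward here)
  nd1 <- dac[dac$label == "ND1", ]
  expect_equal(c(nd1$vx, nd1$vy, nd1$vz),
    penta[2, ] / sqrt(sum(penta[2, ]^2)), tolerance = 1e-6)
})

test_that("exposure vectors are normalized sums over nearby vertices", {
  mesh <- surface_mesh(rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 9)),
    rbind(c(1, 2, 3)))
  ctr <- data.frame(kind = "DON", x = 0, y = 0, z = 0, vx = 1, vy = 0,
    vz = 0)
  ev <- exposure_vector(ctr, mesh, d_max = 3)
  expect_true(ev$defined)
  sexp <- c(2, 2, 0) / sqrt(8)
  expect_equal(unname(ev$r[1, ]), sexp)
  # two symmetric vertices cancel -> undefined
  mesh2 <- surface_mesh(rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 0, 9)),
    rbind(c(1, 2, 3)))
  ev2 <- exposure_vector(ctr, mesh2, d_max = 3)
  expect_false(ev2$defined)
  # random cloud equals the brute-force normalized sum
  set.seed(12)
  pts <- matrix(rnorm(60), ncol = 3)
  mesh3 <- surface_mesh(pts, rbind(c(1, 2, 3)))
  ev3 <- exposure_vector(ctr, mesh3, d_max = 2.5)
  inr <- sqrt(rowSums(pts^2)) <= 2.5
  sexp <- colSums(pts[inr, , drop = FALSE])
  sexp <- sexp / sqrt(sum(sexp^2))
  expect_equal(unname(ev3$r[1, ]), sexp)
})

test_that("exposure-angle filtering applies the per-kind cutoffs exactly", {
  # surface vertex sits along +x from each center, so r = (1, 0, 0);
  # choose v at controlled angles to r
  mesh <- surface_mesh(rbind(c(1, 0, 0), c(1, 0.01, 0), c(1, 0, 9)),
    rbind(c(1, 2, 3)))
  vat <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  mk <- function(kind, deg) {
    v <- vat(deg)
    data.frame(kind = kind, x = 0, y = 0, z = 0, vx = v[1], vy = v[2],
      vz = v[3], stringsAsFactors = FALSE)
  }
  centers <- rbind(
    mk("DON", 99), mk("DON", 101),
    mk("ACC", 99), mk("ACC", 101),
    mk("DAC", 110), mk("DAC", 121),
    mk("ARO", 99), mk("ARO", 101))
  kept <- filter_pseudocenters(centers, mesh)
  # ARO is axial: both 99 and 101 degree normals fold to ~81/79 and pass
  expect_equal(paste(kept$kind, round(kept$angle)),
    c("DON 99", "ACC 99", "DAC 110", "ARO 81", "ARO 79"))
  # ALI is never filtered, even with undefined v
  ali <- data.frame(kind = "ALI", x = 0, y = 0, z = 0, vx = NA_real_,
    vy = NA_real_, vz = NA_real_)
  expect_equal(nrow(filter_pseudocenters(ali, mesh)), 1)
  # a directional center with no surface in range is dropped
  far <- mk("DON", 0)
  far$x <- 100
  expect_equal(nrow(filter_pseudocenters(far, mesh)), 0)
  # raising every cutoff keeps a superset
  kept_hi <- filter_pseudocenters(centers, mesh,
    cutoffs = c(DON = 150, ACC = 150, DAC = 150, ARO = 150))
  expect_true(all(paste(kept$kind, round(kept$angle)) %in%
    paste(kept_hi$kind, round(kept_hi$angle))))
})

test_that("vertex channels take the single nearest center within 3 A", {
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 0, 9)),
    rbind(c(1, 2, 3)))
  centers <- data.frame(
    kind = c("ACC", "DON", "DAC"),
    x = c(2, 2.5, 10), y = 0, z = 0,
    vx = 1, vy = 0, vz = 0, stringsAsFactors = FALSE)
  ch <- assign_pseudo_channels(mesh, centers)
  expect_equal(unname(ch[1, ]), c(0L, 1L, 0L, 0L))  # nearest is ACC
  expect_equal(unname(ch[2, ]), c(1L, 1L, 0L, 0L))  # DAC sets DON and ACC
  expect_equal(unname(ch[3, ]), c(0L, 0L, 0L, 0L))  # nothing within 3 A
  # row sums in {0, 1, 2}, 2 only for the DON+ACC double set
  rs <- rowSums(ch)
  expect_true(all(rs %in% 0:2))
  expect_true(all(ch[rs == 2, "DON"] == 1 & ch[rs == 2, "ACC"] == 1))
})

test_that("hydrophobicity is a bounded distance-weighted polarity average", {
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 0, 99)),
    rbind(c(1, 2, 3)))
  one <- function(q, pos = c(2, 0, 0)) {
    atom_set(rbind(pos), element = "C", charge = q)
  }
  expect_equal(assign_hydrophobicity(mesh, one(0.1))[1], -1)  # nonpolar
  expect_equal(assign_hydrophobicity(mesh, one(0.5))[1], 1)   # polar
  expect_equal(assign_hydrophobicity(mesh, one(-0.3))[1], 1)  # |q| rule
  # two equidistant atoms of opposite polarity cancel
  two <- atom_set(rbind(c(2, 0, 0), c(-2, 0, 0)), element = "C",
    charge = c(0.5, 0.1))
  expect_equal(assign_hydrophobicity(mesh, two)[1], 0)
  # out-of-range vertex scores 0
  expect_equal(assign_hydrophobicity(mesh, one(0.5))[2], 0)
  # always bounded
  set.seed(3)
  cloud <- atom_set(matrix(rnorm(90), ncol = 3), element = "C",
    charge = rnorm(30))
  hv <- assign_hydrophobicity(mesh, cloud)
  expect_true(all(hv >= -1 & hv <= 1))
})

test_that("electrostatic capping maps 45 to 1.0 and -15 to -0.5", {
  # a grid whose interpolated values at the two vertices are 45 and -15
  g <- structure(list(xs = seq(-2, 2), ys = seq(-2, 2), zs = seq(-2, 2),
    values = array(45, c(5, 5, 5))), class = "dx_grid")
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    rbind(c(1, 2, 3)))
  expect_equal(assign_electrostatics(mesh, g), c(1, 1, 1))
  g$values[] <- -15
  expect_equal(assign_electrostatics(mesh, g), c(-0.5, -0.5, -0.5))
  # grid not covering the mesh is an error naming the axis
  mesh_out <- surface_mesh(rbind(c(9, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    rbind(c(1, 2, 3)))
  expect_error(assign_electrostatics(mesh_out, g), "axis x")
  # built-in backend with zero charges gives all zeros
  atoms <- atom_set(rbind(c(1, 1, 1)), element = "C", charge = 0)
  expect_equal(assign_electrostatics(mesh, atoms), c(0, 0, 0))
})

test_that("property assignment commutes with rigid transforms", {
  pp <- toy_pocket_cached()
  atoms <- make_toy_protein(toy_pocket_spec(cavity_radius = 5,
    mouth_angle = 60, seed = 3))
  R <- random_rotation_matrix(seed = 13)
  shift <- c(4, 5, -6)
  atoms_r <- atoms
  atoms_r[, c("x", "y", "z")] <-
    sweep(as.matrix(atoms[, c("x", "y", "z")]) %*% t(R), 2, -shift)
  mesh_r <- transform_mesh(pp$mesh, R, shift)
  p0 <- compute_vertex_properties(pp$mesh, atoms)
  p1 <- compute_vertex_properties(mesh_r, atoms_r)
  expect_equal(p1$pseudo, p0$pseudo)
  expect_equal(p1$hydrophobicity, p0$hydrophobicity, tolerance = 1e-6)
  expect_equal(p1$charge, p0$charge, tolerance = 1e-6)
})

test_that("OpenDX scalar grids round-trip through the reader", {
  f <- tempfile(fileext = ".dx")
  vals <- array(seq_len(24), c(2, 3, 4))  # x, y, z
  # dx order: z fastest
  flat <- as.vector(aperm(vals, c(3, 2, 1)))
  writeLines(c(
    "# test grid",
    "object 1 class gridpositions counts 2 3 4",
    "origin 0.0 1.0 2.0",
    "delta 0.5 0.0 0.0",
    "delta 0.0 0.5 0.0",
    "delta 0.0 0.0 0.5",
    "object 2 class gridconnections counts 2 3 4",
    "object 3 class array type double rank 0 items 24 data follows",
    paste(matrix(flat, ncol = 3, byrow = TRUE)[, 1],
          matrix(flat, ncol = 3, byrow = TRUE)[, 2],
          matrix(flat, ncol = 3, byrow = TRUE)[, 3]),
    'attribute "dep" string "positions"'), f)
  g <- read_opendx(f)
  expect_equal(g$xs, c(0, 0.5))
  expect_equal(g$ys, c(1, 1.5, 2))
  expect_equal(g$zs, c(2, 2.5, 3, 3.5))
  expect_equal(g$values, vals)
})
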