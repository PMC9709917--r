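# Desk-scale synthetic inputs with known structure: toy proteins whose
# concave pocket lining is controllable, directly generated labeled
# spherical map datasets, and labeled pair lists.

#' Toy pocket specification
#'
#' Describes a spherical-cap shell of pseudo-residues forming a concave,
#' ligand-occupied cavity. `lining` gives the composition of the wall:
#' named fractions over donor, acceptor, aromatic, aliphatic and charged
#' groups, realized as minimal Lys/Asp/Phe/Ala/Arg/Glu fragments whose
#' functional group points into the cavity.
#'
#' @param cavity_radius Cavity radius in Å (3-12).
#' @param mouth_angle Full opening angle of the pocket mouth in degrees
#'   (0 = fully enclosed shell).
#' @param lining Named fractions summing to 1; names from donor,
#'   acceptor, aromatic, aliphatic, charged_pos, charged_neg.
#' @param noise_sd Gaussian positional noise (Å).
#' @param seed Integer seed.
#' @return A `toy_pocket_spec` list.
#' @export
toy_pocket_spec <- function(cavity_radius = 5, mouth_angle = 60,
                            lining = c(donor = 0.25, acceptor = 0.25,
                                       aromatic = 0.2, aliphatic = 0.3),
                            noise_sd = 0.05, seed = 1L) {
  if (cavity_radius < 3 || cavity_radius > 12) {
    stop("cavity_radius must be in [3, 12] Å")
  }
  known <- c("donor", "acceptor", "aromatic", "aliphatic", "charged_pos",
             "charged_neg")
  if (!all(names(lining) %in% known)) {
    stop("unknown lining kinds: ",
      paste(setdiff(names(lining), known), collapse = ", "))
  }
  if (abs(sum(lining) - 1) > 1e-6) stop("lining fractions must sum to 1")
  if (any(lining < 0)) stop("lining fractions must be nonnegative")
  structure(list(cavity_radius = cavity_radius, mouth_angle = mouth_angle,
                 lining = lining, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "toy_pocket_spec")
}

# deterministic, roughly uniform directions on the sphere
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  st <- sqrt(pmax(0, 1 - z^2))
  cbind(st * cos(phi), st * sin(phi), z)
}

# orthonormal tangent basis for a unit direction
tangent_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- vcross(u, ref)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- vcross(u, t1)
  list(t1 = t1, t2 = t2)
}

#' Build a toy protein with a concave pocket
#'
#' Pseudo-residue fragments are placed on a spherical shell of the given
#' cavity radius, omitting directions inside the mouth cone (around +z),
#' each oriented with its functional group pointing into the cavity. A
#' small dummy ligand (LIG) sits at the cavity centre. Deterministic for a
#' given spec.
#'
#' @param spec A [toy_pocket_spec()].
#' @return An [atom_set()] (PDB-writable via [write_structure()]).
#' @export
make_toy_protein <- function(spec) {
  stopifnot(inherits(spec, "toy_pocket_spec"))
  set.seed(spec$seed)
  R <- spec$cavity_radius
  n_dirs <- max(12L, round(4 * pi * (R + 1)^2 / 3.8^2))
  dirs <- fibonacci_directions(n_dirs)
  mouth_cos <- cos(spec$mouth_angle / 2 * pi / 180)
  if (spec$mouth_angle > 0) {
    dirs <- dirs[dirs[, 3] < mouth_cos, , drop = FALSE]
  }
  n_res <- nrow(dirs)
  kinds <- rep(names(spec$lining),
    times = round(spec$lining * n_res))
  kinds <- c(kinds, rep(names(which.max(spec$lining)),
    max(0, n_res - length(kinds))))[seq_len(n_res)]
  kinds <- sample(kinds)

  rows <- list()
  add <- function(resname, resnum, names_, offsets, charges, elements) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resname = resname, resnum = resnum, atom_name = names_,
      x = offsets[, 1], y = offsets[, 2], z = offsets[, 3],
      charge = charges, element = elements, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    u <- dirs[i, ]
    tb <- tangent_basis(u)
    wall <- R * u          # functional-group position on the cavity wall
    out1 <- (R + 1.4) * u  # anchor one bond length outward
    switch(kinds[i],
      donor = add("LYS", i, c("CE", "NZ"), rbind(out1, wall),
        c(0.05, 0.4), c("C", "N")),
      acceptor = add("ASP", i, c("CG", "OD1", "OD2"),
        rbind(out1, wall + 1.1 * tb$t1, wall - 1.1 * tb$t1),
        c(0.05, -0.4, -0.4), c("C", "O", "O")),
      aromatic = {
        ring <- t(vapply(0:5, function(j) {
          th <- j * pi / 3
          wall + 1.39 * (cos(th) * tb$t1 + sin(th) * tb$t2)
        }, numeric(3)))
        add("PHE", i, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), ring,
          rep(0.02, 6), rep("C", 6))
      },
      aliphatic = add("ALA", i, "CB", rbind(wall), 0.05, "C"),
      charged_pos = add("ARG", i, c("CZ", "NH1", "NH2"),
        rbind(out1, wall + 1.1 * tb$t1, wall - 1.1 * tb$t1),
        c(0.2, 0.64, 0.64), c("C", "N", "N")),
      charged_neg = add("GLU", i, c("CD", "OE1", "OE2"),
        rbind(out1, wall + 1.1 * tb$t1, wall - 1.1 * tb$t1),
        c(0.2, -0.57, -0.57), c("C", "O", "O"))
    )
  }
  prot <- do.call(rbind, rows)
  # dummy ligand: small tetrahedron at the cavity centre
  lig <- data.frame(resname = "LIG", resnum = n_res + 1L,
    atom_name = c("C1", "C2", "C3", "C4"),
    x = c(0.8, -0.8, 0.8, -0.8), y = c(0.8, -0.8, -0.8, 0.8),
    z = c(0.8, 0.8, -0.8, -0.8), charge = 0, element = "C",
    stringsAsFactors = FALSE)
  all <- rbind(prot, lig)
  coord <- as.matrix(all[, c("x", "y", "z")])
  coord <- coord + matrix(stats::rnorm(length(coord), sd = spec$noise_sd),
    ncol = 3)
  atom_set(coord, element = all$element, chain = "A",
    resnum = all$resnum, resname = all$resname,
    atom_name = all$atom_name, charge = all$charge,
    is_ligand = all$resname == "LIG")
}

#' Run the full featurization pipeline on a toy protein
#'
#' Pocket spheres -> ligand-based atom selection -> hull filter -> SES
#' mesh -> clean -> smooth -> properties -> spherical maps.
#'
#' @param atoms An [atom_set()] with ligand rows (e.g. from
#'   [make_toy_protein()]).
#' @param n_side Map resolution (default 16).
#' @param r Ligand selection radius (default 6).
#' @param smooth_iterations Laplacian smoothing passes (default 4).
#' @param grid Optional prebuilt [healpix_grid()].
#' @return List with `spheres`, `mesh`, `props`, `maps`.
#' @export
pocket_pipeline <- function(atoms, n_side = 16, r = 6.0,
                            smooth_iterations = 4, grid = NULL) {
  spheres <- generate_pocket_spheres(atoms)
  lig <- atoms[atoms$is_ligand, , drop = FALSE]
  ligs <- if (nrow(lig)) list(lig) else list()
  sel <- select_binding_atoms(atoms, ligs, r = r, spheres = spheres)
  spheres <- filter_spheres_by_hull(spheres, sel, atoms)
  mesh <- suppressWarnings(triangulate_surface(spheres))
  mesh <- smooth_mesh(clean_mesh(mesh), smooth_iterations)
  props <- compute_vertex_properties(mesh, atoms)
  maps <- featurize_pocket(mesh, props, n_side = n_side, grid = grid)
  list(spheres = spheres, mesh = mesh, props = props, maps = maps)
}

#' Generate a labeled synthetic spherical-map dataset
#'
#' Each class is a characteristic combination of smooth spherical-cap
#' motifs on specific channels (depth, charge, hydrophobicity plus one
#' binary pseudocenter cap per class). Every sample applies a uniformly
#' random rotation to the motif directions, so class identity is
#' orientation-free, and adds Gaussian channel noise. All channels respect
#' their documented ranges.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Samples per class.
#' @param n_side Map resolution (default 16).
#' @param seed Integer seed.
#' @param noise_sd Channel noise (default 0.05).
#' @return List with `maps` (list of `spherical_maps`) and `labels`.
#' @export
make_map_dataset <- function(n_classes = 3, n_per_class = 20, n_side = 16,
                             seed = 1L, noise_sd = 0.05) {
  stopifnot(n_classes >= 2)
  set.seed(seed)
  grid <- healpix_grid(n_side)
  # class templates: motif directions and channel signatures
  templates <- lapply(seq_len(n_classes), function(cl) {
    n_motif <- 3L
    dirs <- matrix(stats::rnorm(3 * n_motif), n_motif, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(dirs = dirs,
         width = stats::runif(n_motif, 0.4, 0.8),
         depth_amp = stats::runif(n_motif, 0.3, 0.6),
         charge_amp = stats::runif(n_motif, -1, 1),
         hydro_amp = stats::runif(n_motif, -1, 1),
         pseudo_channel = 5L + ((cl - 1L) %% 4L))
  })
  cap <- function(u, dirs, width) {
    # n_pix x n_motif smooth bumps
    ang <- acos(pmin(pmax(u %*% t(dirs), -1), 1))
    exp(-(ang / matrix(width, nrow(u), length(width), byrow = TRUE))^2)
  }
  maps <- list()
  labels <- integer(0)
  for (cl in seq_len(n_classes)) {
    tp <- templates[[cl]]
    for (s in seq_len(n_per_class)) {
      Rm <- random_rotation_matrix()
      dirs <- tp$dirs %*% t(Rm)
      caps <- cap(grid$vec, dirs, tp$width)
      ch <- matrix(0, length(MAP_CHANNELS), grid$n_pix,
        dimnames = list(MAP_CHANNELS, NULL))
      nz <- function(x) x + stats::rnorm(length(x), sd = noise_sd)
      ch["depth", ] <- pmin(pmax(nz(0.35 + caps %*% tp$depth_amp), 0), 1)
      cosang <- pmin(pmax(nz(0.85 - 0.3 * rowMeans(caps)), -1), 1)
      ch["cos_angle", ] <- cosang
      ch["sin_angle", ] <- sqrt(1 - cosang^2)
      ch["charge", ] <- pmin(pmax(nz(caps %*% tp$charge_amp), -1), 1)
      ch["hydrophobicity", ] <- pmin(pmax(nz(caps %*% tp$hydro_amp), -1), 1)
      ch[tp$pseudo_channel, ] <- as.integer(nz(caps[, 1]) > 0.5)
      maps[[length(maps) + 1L]] <- structure(
        list(channels = ch, miss_mask = integer(grid$n_pix),
             n_side = n_side), class = "spherical_maps")
      labels <- c(labels, cl)
    }
  }
  list(maps = maps, labels = labels)
}

#' Generate a labeled pair dataset from class labels
#'
#' Positives are drawn within classes, negatives across classes, without
#' duplicates; deterministic for a given seed.
#'
#' @param labels Integer class labels (indexing the map list).
#' @param n_pos,n_neg Number of positive / negative pairs.
#' @param seed Integer seed.
#' @return Data frame with `id_a`, `id_b`, `label`.
#' @export
make_pair_dataset <- function(labels, n_pos, n_neg, seed = 1L) {
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  set.seed(seed)
  n <- length(labels)
  all_pairs <- t(utils::combn(n, 2))
  same <- labels[all_pairs[, 1]] == labels[all_pairs[, 2]]
  pos_pool <- which(same)
  neg_pool <- which(!same)
  if (n_pos > length(pos_pool) || n_neg > length(neg_pool)) {
    stop("requested pair counts exceed available combinations (",
      length(pos_pool), " positive, ", length(neg_pool), " negative)")
  }
  sel <- c(sample(pos_pool, n_pos), sample(neg_pool, n_neg))
  out <- data.frame(id_a = all_pairs[sel, 1], id_b = all_pairs[sel, 2],
    label = rep(c(1L, 0L), c(n_pos, n_neg)))
  out[sample(nrow(out)), , drop = FALSE]
}
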