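# Pocket location by gap-sphere placement (SURFNET-style).
#
# Candidate spheres are seeded at the midpoint of protein atom pairs with
# radius equal to half the inter-surface gap, then iteratively shrunk and
# recentred away from the nearest intruding atom until they clear every
# atom's van der Waals surface. Clusters of overlapping surviving spheres
# are the negative imprints of surface cavities.

#' Default gap-sphere parameters
#'
#' `r_min`/`r_max` bound the sphere radii (Å); `pair_cutoff` limits the
#' atom-pair centre distance considered (derived from the radius bounds when
#' `NULL`); `grid_spacing` deduplicates near-coincident candidate spheres
#' (the largest sphere per grid cell is kept); `max_iter` bounds the
#' shrink-and-recentre loop.
#'
#' @param r_min,r_max Sphere radius bounds (Å).
#' @param pair_cutoff Maximum atom-pair distance (Å) or `NULL` for auto.
#' @param grid_spacing Deduplication grid (Å).
#' @param max_iter Maximum shrink iterations per sphere.
#' @return A named list of parameters.
#' @export
sphere_params <- function(r_min = 1.0, r_max = 4.0, pair_cutoff = NULL,
                          grid_spacing = 0.5, max_iter = 10L) {
  list(r_min = r_min, r_max = r_max, pair_cutoff = pair_cutoff,
       grid_spacing = grid_spacing, max_iter = as.integer(max_iter))
}

#' Generate pocket gap spheres
#'
#' Places spheres in the gaps between pairs of protein atoms such that no
#' sphere penetrates the van der Waals surface of any atom, then groups the
#' survivors into overlap clusters.
#'
#' @param atoms An [atom_set()]; ligand atoms are ignored for placement.
#' @param params See [sphere_params()].
#' @return An object of class `pocket_spheres`: list with `center`
#'   (n x 3), `radius` (n), `cluster` (integer cluster id per sphere,
#'   1 = largest cluster).
#' @export
generate_pocket_spheres <- function(atoms, params = sphere_params()) {
  prot <- atoms[!atoms$is_ligand & atoms$is_heavy, , drop = FALSE]
  if (nrow(prot) < 2) stop("need at least 2 non-ligand heavy atoms")
  xyz <- atom_coords(prot)
  rad <- prot$vdw_radius
  n <- nrow(xyz)

  cutoff <- params$pair_cutoff
  if (is.null(cutoff)) cutoff <- 2 * params$r_max + 2 * max(rad)

  # candidate pairs within the cutoff whose inter-surface gap allows a
  # sphere of at least r_min
  d2 <- as.matrix(stats::dist(xyz))^2
  pair_idx <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(pair_idx)) {
    i <- pair_idx[, 1]; j <- pair_idx[, 2]
    gap <- sqrt(d2[pair_idx]) - rad[i] - rad[j]
    keep <- gap >= 2 * params$r_min
    i <- i[keep]; j <- j[keep]
  } else {
    i <- integer(0); j <- integer(0)
  }
  if (!length(i)) {
    return(empty_spheres(diagnostics = list(n_atoms = n, n_pairs = 0)))
  }

  centers <- (xyz[i, , drop = FALSE] + xyz[j, , drop = FALSE]) / 2
  radii <- pmin((sqrt(rowSums((xyz[i, , drop = FALSE] -
    xyz[j, , drop = FALSE])^2)) - rad[i] - rad[j]) / 2, params$r_max)

  # shrink-and-recentre against the nearest intruding atom; each step
  # makes the sphere tangent to that atom
  alive <- rep(TRUE, length(radii))
  for (iter in seq_len(params$max_iter)) {
    idx <- which(alive)
    if (!length(idx)) break
    cc <- centers[idx, , drop = FALSE]
    # clearance of each candidate against every atom (chunked)
    viol <- numeric(length(idx)); vat <- integer(length(idx))
    step <- max(1L, floor(2e6 / n))
    for (s in seq(1, length(idx), by = step)) {
      e <- min(s + step - 1, length(idx))
      block <- cc[s:e, , drop = FALSE]
      d2m <- outer(rowSums(block^2), rowSums(xyz^2), `+`) -
        2 * block %*% t(xyz)
      d2m[d2m < 0] <- 0
      dd <- sqrt(d2m)
      clr <- sweep(dd, 2, rad) - radii[idx][s:e]
      vat[s:e] <- apply(clr, 1, which.min)
      viol[s:e] <- clr[cbind(seq_len(e - s + 1), vat[s:e])]
    }
    bad <- viol < -1e-9
    if (!any(bad)) break
    bi <- idx[bad]
    delta <- viol[bad] / 2                      # negative
    away <- centers[bi, , drop = FALSE] - xyz[vat[bad], , drop = FALSE]
    away <- away / sqrt(rowSums(away^2))
    centers[bi, ] <- centers[bi, , drop = FALSE] - delta * away
    radii[bi] <- radii[bi] + delta
    alive[bi] <- radii[bi] >= params$r_min
    alive[idx[!bad]] <- TRUE
  }
  # final brute-force validity pass
  idx <- which(alive)
  if (length(idx)) {
    cc <- centers[idx, , drop = FALSE]
    ok <- logical(length(idx))
    step <- max(1L, floor(2e6 / n))
    for (s in seq(1, length(idx), by = step)) {
      e <- min(s + step - 1, length(idx))
      block <- cc[s:e, , drop = FALSE]
      d2m <- outer(rowSums(block^2), rowSums(xyz^2), `+`) -
        2 * block %*% t(xyz)
      d2m[d2m < 0] <- 0
      dd <- sqrt(d2m)
      clr <- sweep(dd, 2, rad) - radii[idx][s:e]
      ok[s:e] <- apply(clr, 1, min) >= -1e-6
    }
    alive[idx] <- ok & radii[idx] >= params$r_min
  }
  centers <- centers[alive, , drop = FALSE]
  radii <- radii[alive]
  if (!nrow(centers)) {
    return(empty_spheres(diagnostics = list(n_atoms = n,
      n_pairs = length(i), n_candidates = length(alive))))
  }

  # deduplicate on a grid, keeping the largest sphere per cell
  key <- paste(round(centers[, 1] / params$grid_spacing),
               round(centers[, 2] / params$grid_spacing),
               round(centers[, 3] / params$grid_spacing))
  ord <- order(-radii)
  keep <- ord[!duplicated(key[ord])]
  centers <- centers[keep, , drop = FALSE]
  radii <- radii[keep]

  dimnames(centers) <- NULL
  radii <- unname(radii)
  cl <- cluster_spheres(centers, radii)
  structure(list(center = centers, radius = radii, cluster = cl),
            class = "pocket_spheres")
}

empty_spheres <- function(diagnostics = NULL) {
  stop("no pocket sphere survives; diagnostics: ",
       paste(names(diagnostics), unlist(diagnostics),
             sep = "=", collapse = ", "))
}

# connected components under sphere overlap, labelled by decreasing size
cluster_spheres <- function(centers, radii) {
  n <- nrow(centers)
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(centers))
  overlap <- d < outer(radii, radii, `+`)
  diag(overlap) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(overlap, mode = "undirected")
  comp <- igraph::components(g)
  # relabel so cluster 1 is the largest
  sizes <- comp$csize
  rank <- match(comp$membership, order(-sizes))
  as.integer(rank)
}

#' Select binding-site atoms around ligands
#'
#' Returns the ids of protein atoms within `r` of any ligand heavy atom,
#' unioned over an ensemble of ligand poses. With no ligand, delegates to a
#' pluggable pocket predictor; the built-in default selects atoms within
#' `r` of the sphere centres of the largest gap-sphere cluster.
#'
#' @param atoms An [atom_set()] (its ligand rows are ignored here).
#' @param ligand_sets List of `atom_set`s holding ligand atoms, aligned to
#'   the frame of `atoms`. May be empty.
#' @param r Radial threshold in Å (default 6).
#' @param spheres Optional [generate_pocket_spheres()] result for the
#'   ligand-free fallback (computed when needed).
#' @param predictor Optional function `(atoms) -> n x 3 matrix` of probe
#'   points replacing the built-in largest-cluster heuristic (e.g. points
#'   read from an external pocket-prediction program).
#' @return Integer vector of selected protein atom ids.
#' @export
select_binding_atoms <- function(atoms, ligand_sets = list(), r = 6.0,
                                 spheres = NULL, predictor = NULL) {
  stopifnot(r > 0)
  prot <- atoms[!atoms$is_ligand, , drop = FALSE]
  pxyz <- atom_coords(prot)
  if (length(ligand_sets)) {
    probe <- do.call(rbind, lapply(ligand_sets, function(l) {
      lh <- l[l$is_heavy, , drop = FALSE]
      if (!nrow(lh)) stop("ligand with no heavy atoms")
      atom_coords(lh)
    }))
  } else if (!is.null(predictor)) {
    probe <- rbind(predictor(atoms))
  } else {
    if (is.null(spheres)) spheres <- generate_pocket_spheres(atoms)
    probe <- spheres$center[spheres$cluster == 1L, , drop = FALSE]
  }
  d2 <- outer(rowSums(pxyz^2), rowSums(probe^2), `+`) - 2 * pxyz %*% t(probe)
  sel <- prot$id[apply(d2 <= r^2 + 1e-12, 1, any)]
  if (!length(sel)) stop("empty binding-atom selection at r = ", r)
  sel
}

#' Filter spheres by the convex hull of selected atoms
#'
#' Keeps exactly the spheres whose centre lies inside or on the convex hull
#' of the selected atom coordinates (closed-hull convention), then
#' reclusters the survivors.
#'
#' @param spheres A `pocket_spheres` object.
#' @param selected Atom ids from [select_binding_atoms()].
#' @param atoms The `atom_set` the ids refer to.
#' @return A filtered `pocket_spheres` object.
#' @export
filter_spheres_by_hull <- function(spheres, selected, atoms) {
  sel <- atoms[atoms$id %in% selected, , drop = FALSE]
  if (nrow(sel) < 4) stop("hull construction needs >= 4 selected atoms")
  hull <- convex_hull(atom_coords(sel))
  inside <- hull_contains(hull, spheres$center)
  if (!any(inside)) stop("no sphere centre inside the selection hull")
  centers <- spheres$center[inside, , drop = FALSE]
  radii <- spheres$radius[inside]
  structure(list(center = centers, radius = radii,
                 cluster = cluster_spheres(centers, radii)),
            class = "pocket_spheres")
}

#' Write spheres as TSV (x y z r cluster)
#' @param spheres A `pocket_spheres` object.
#' @param file Output path.
#' @export
write_spheres <- function(spheres, file) {
  df <- data.frame(x = spheres$center[, 1], y = spheres$center[, 2],
                   z = spheres$center[, 3], r = spheres$radius,
                   cluster = spheres$cluster)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.pocket_spheres <- function(x, ...) {
  cat(sprintf("pocket spheres: %d spheres in %d cluster(s); radii %.2f-%.2f A\n",
    length(x$radius), max(x$cluster), min(x$radius), max(x$radius)))
  invisible(x)
}
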