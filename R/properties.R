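# Physicochemical attribution of pocket surface vertices.
#
# Pseudocenters summarize the interaction capability of binding-site
# residues: hydrogen-bond donor (DON), acceptor (ACC), mixed donor/acceptor
# (DAC), aliphatic (ALI) and aromatic/pi (ARO). Each directional center
# carries an interaction direction v; its surface exposure vector r (the
# normalized sum of vectors to nearby mesh vertices) decides by the angle
# between v and r whether the group points into the cavity.

PSEUDO_KINDS <- c("DON", "ACC", "DAC", "ALI", "ARO")

#' Default pseudocenter template table
#'
#' Reads the residue template table shipped with the package (editable TSV:
#' one row per pseudocenter with the defining atoms and the rule that
#' orients its interaction vector).
#'
#' @param file Optional path to an alternative template TSV.
#' @return A data frame of templates.
#' @export
pseudocenter_templates <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "pseudocenter_templates.tsv",
      package = "pocketsphere")
    if (file == "") file <- "inst/extdata/pseudocenter_templates.tsv"
  }
  utils::read.delim(file, stringsAsFactors = FALSE, na.strings = "")
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
  v / n
}

# best-fit plane normal of a ring (smallest principal component)
ring_normal <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  sv$v[, 3]
}

#' Build pseudocenters from a structure
#'
#' Emits pseudocenters for every protein residue according to the template
#' table: backbone N (donor, direction bisecting the C(-1)-N-CA angle,
#' pointing along the projected N-H), backbone O (acceptor, along C=O),
#' and side-chain donors/acceptors/mixed centers, aromatic ring centroids
#' (direction = ring plane normal, sign-ambiguous, treated as axial
#' downstream) and aliphatic carbon centroids (no direction).
#'
#' @param atoms An [atom_set()] (ligand rows ignored).
#' @param templates Template table from [pseudocenter_templates()].
#' @param verbose Warn about skipped centers (missing atoms, unknown
#'   residues).
#' @return A data frame of class `pseudocenters`: kind, position (x, y, z),
#'   direction (vx, vy, vz; NA for ALI), residue identity and label.
#' @export
build_pseudocenters <- function(atoms, templates = pseudocenter_templates(),
                                verbose = FALSE) {
  prot <- atoms[!atoms$is_ligand, , drop = FALSE]
  reskey <- paste(prot$chain, prot$resnum)
  residues <- unique(data.frame(chain = prot$chain, resnum = prot$resnum,
    resname = prot$resname, stringsAsFactors = FALSE))
  known <- unique(c(templates$resname, "GLY"))
  unknown <- setdiff(unique(residues$resname), c(known, "*"))
  if (length(unknown) && verbose) {
    warning("no pseudocenter templates for residue(s): ",
      paste(unknown, collapse = ", "))
  }

  out <- list()
  for (ri in seq_len(nrow(residues))) {
    res <- residues[ri, ]
    rows <- prot[reskey == paste(res$chain, res$resnum), , drop = FALSE]
    getpos <- function(name) {
      if (name == "C_prev") {
        prev <- prot[prot$chain == res$chain &
          prot$resnum == res$resnum - 1L & prot$atom_name == "C", ,
          drop = FALSE]
        if (!nrow(prev)) return(NULL)
        return(as.numeric(prev[1, c("x", "y", "z")]))
      }
      hit <- rows[rows$atom_name == name, , drop = FALSE]
      if (!nrow(hit)) return(NULL)
      as.numeric(hit[1, c("x", "y", "z")])
    }
    tmpl <- templates[templates$resname %in% c("*", res$resname), , drop = FALSE]
    for (ti in seq_len(nrow(tmpl))) {
      tr <- tmpl[ti, ]
      catoms <- strsplit(tr$center_atoms, ",")[[1]]
      cpos <- lapply(catoms, getpos)
      if (any(vapply(cpos, is.null, logical(1)))) {
        if (verbose) warning(sprintf("%s %s%d: missing atoms for %s center",
          res$resname, res$chain, res$resnum, tr$center))
        next
      }
      cpos <- do.call(rbind, cpos)
      pos <- colMeans(cpos)
      v <- c(NA_real_, NA_real_, NA_real_)
      rule <- tr$v_rule
      if (is.na(rule)) rule <- "none"
      if (rule == "along") {
        ref <- getpos(tr$v_atoms)
        if (is.null(ref)) next
        v <- unit3(pos - ref)
      } else if (rule == "bisector_opposite") {
        refs <- lapply(strsplit(tr$v_atoms, ",")[[1]], getpos)
        if (any(vapply(refs, is.null, logical(1)))) next
        v <- unit3(-(unit3(refs[[1]] - pos) + unit3(refs[[2]] - pos)))
      } else if (rule == "away_centroid") {
        refs <- lapply(strsplit(tr$v_atoms, ",")[[1]], getpos)
        if (any(vapply(refs, is.null, logical(1)))) next
        v <- unit3(pos - colMeans(do.call(rbind, refs)))
      } else if (rule == "ring_normal") {
        v <- ring_normal(cpos)
      }
      out[[length(out) + 1L]] <- data.frame(
        kind = tr$kind, x = pos[1], y = pos[2], z = pos[3],
        vx = v[1], vy = v[2], vz = v[3],
        chain = res$chain, resnum = res$resnum, resname = res$resname,
        label = tr$center, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    centers <- data.frame(kind = character(), x = numeric(), y = numeric(),
      z = numeric(), vx = numeric(), vy = numeric(), vz = numeric(),
      chain = character(), resnum = integer(), resname = character(),
      label = character(), stringsAsFactors = FALSE)
  } else {
    centers <- do.call(rbind, out)
  }
  class(centers) <- c("pseudocenters", "data.frame")
  centers
}

#' Surface-exposure vectors of pseudocenters
#'
#' For each center p, r = normalize(sum over mesh vertices s with
#' |s - p| <= d_max of (s - p)). Centers with no vertex in range, or whose
#' vector sum cancels, are flagged undefined.
#'
#' @param centers A `pseudocenters` data frame.
#' @param mesh A `surface_mesh`.
#' @param d_max Neighbourhood radius in Å (default 3).
#' @return List with `r` (n x 3, rows NA when undefined) and `defined`
#'   (logical).
#' @export
exposure_vector <- function(centers, mesh, d_max = 3.0) {
  if (!nrow(mesh$vertices)) stop("empty mesh")
  p <- as.matrix(centers[, c("x", "y", "z"), drop = FALSE])
  vtx <- mesh$vertices
  n <- nrow(p)
  r <- matrix(NA_real_, n, 3)
  defined <- logical(n)
  d2max <- d_max^2
  for (i in seq_len(n)) {
    dv <- sweep(vtx, 2, p[i, ])
    sel <- rowSums(dv^2) <= d2max
    if (!any(sel)) next
    s <- colSums(dv[sel, , drop = FALSE])
    u <- unit3(s)
    if (!anyNA(u)) {
      r[i, ] <- u
      defined[i] <- TRUE
    }
  }
  list(r = r, defined = defined)
}

#' Default exposure-angle cutoffs (degrees)
#' @export
pseudo_cutoffs <- function() c(DON = 100, ACC = 100, DAC = 120, ARO = 100)

#' Filter pseudocenters by surface exposure
#'
#' Directional centers are kept when the angle between their interaction
#' direction v and exposure vector r is within the per-kind cutoff
#' (DON/ACC/ARO 100 degrees, DAC 120 degrees). ARO directions are ring
#' normals with ambiguous sign and are compared axially (the smaller of the
#' angles to +v and -v). Aliphatic centers are exempt from filtering;
#' directional centers with undefined exposure (no surface within `d_max`)
#' are dropped.
#'
#' @param centers A `pseudocenters` data frame.
#' @param mesh A `surface_mesh`.
#' @param cutoffs Named cutoff vector, see [pseudo_cutoffs()].
#' @param d_max Exposure neighbourhood radius (Å).
#' @return The retained subset of `centers` (with an `angle` column, NA for
#'   ALI).
#' @export
filter_pseudocenters <- function(centers, mesh, cutoffs = pseudo_cutoffs(),
                                 d_max = 3.0) {
  if (!nrow(centers)) return(centers)
  exp <- exposure_vector(centers, mesh, d_max)
  v <- as.matrix(centers[, c("vx", "vy", "vz"), drop = FALSE])
  cosang <- rowSums(v * exp$r)
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  aro <- centers$kind == "ARO"
  ang[aro] <- pmin(ang[aro], 180 - ang[aro])
  keep <- rep(FALSE, nrow(centers))
  ali <- centers$kind == "ALI"
  keep[ali] <- TRUE
  dir <- !ali
  keep[dir] <- exp$defined[dir] & !is.na(ang[dir]) &
    ang[dir] <= cutoffs[centers$kind[dir]]
  out <- centers[keep, , drop = FALSE]
  out$angle <- ifelse(ali[keep], NA_real_, ang[keep])
  out
}

#' Nearest-pseudocenter channel assignment
#'
#' Each vertex takes the channels of its single nearest filtered
#' pseudocenter within `radius`; DAC sets both the DON and ACC bits.
#' Vertices with no center within range are NULL (all-zero row),
#' representing the open mouth of the pocket.
#'
#' @param mesh A `surface_mesh`.
#' @param centers Filtered `pseudocenters`.
#' @param radius Assignment radius in Å (default 3).
#' @return n x 4 binary matrix with columns DON, ACC, ALI, ARO.
#' @export
assign_pseudo_channels <- function(mesh, centers, radius = 3.0) {
  n <- nrow(mesh$vertices)
  out <- matrix(0L, n, 4, dimnames = list(NULL, c("DON", "ACC", "ALI", "ARO")))
  if (!nrow(centers)) return(out)
  p <- as.matrix(centers[, c("x", "y", "z"), drop = FALSE])
  vtx <- mesh$vertices
  d2 <- outer(rowSums(vtx^2), rowSums(p^2), `+`) - 2 * vtx %*% t(p)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first")
  ok <- d2[cbind(seq_len(n), nearest)] <= radius^2
  kind <- centers$kind[nearest]
  out[ok & kind == "DON", "DON"] <- 1L
  out[ok & kind == "ACC", "ACC"] <- 1L
  out[ok & kind == "DAC", c("DON", "ACC")] <- 1L
  out[ok & kind == "ALI", "ALI"] <- 1L
  out[ok & kind == "ARO", "ARO"] <- 1L
  out
}

#' Distance-weighted vertex hydrophobicity
#'
#' Atoms are binarized by partial charge magnitude: nonpolar atoms
#' (|q| <= 0.25 e) score -1, polar atoms (|q| > 0.25 e) score +1. Each
#' vertex averages the scores of atoms within `radius`, weighted by inverse
#' distance (floored at 0.5 Å); vertices with no atom in range score 0.
#'
#' @param mesh A `surface_mesh`.
#' @param atoms An [atom_set()] carrying partial charges (ligand rows
#'   ignored).
#' @param radius Inclusion radius in Å (default 4.5).
#' @param polar_cut Charge-magnitude threshold separating polar from
#'   nonpolar atoms (default 0.25 e).
#' @return Numeric vector in `[-1, 1]`, one value per vertex.
#' @export
assign_hydrophobicity <- function(mesh, atoms, radius = 4.5,
                                  polar_cut = 0.25) {
  prot <- atoms[!atoms$is_ligand, , drop = FALSE]
  h <- ifelse(abs(prot$charge) > polar_cut, 1, -1)
  xyz <- atom_coords(prot)
  vtx <- mesh$vertices
  d2 <- outer(rowSums(vtx^2), rowSums(xyz^2), `+`) - 2 * vtx %*% t(xyz)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  w <- 1 / pmax(d, 0.5)
  w[d > radius] <- 0
  num <- as.vector(w %*% h)
  den <- rowSums(w)
  ifelse(den > 0, num / den, 0)
}

#' Vertex electrostatic potential, capped and normalized
#'
#' The potential is evaluated at each vertex either by trilinear
#' interpolation of an external scalar grid (see [read_opendx()]) or with
#' the built-in screened-Coulomb model from per-atom partial charges,
#' phi(x) = sum_i q_i exp(-kappa d_i) / (eps_r d_i) in kT/e. Values are
#' capped to +/-`cap` and scaled to `[-1, 1]`.
#'
#' @param mesh A `surface_mesh`.
#' @param source Either a `dx_grid` (external potential) or an
#'   [atom_set()] with charges (built-in model).
#' @param cap Potential cap (default 30, kT/e).
#' @param kappa Inverse screening length, 1/Å (default 0.1).
#' @param eps_r Relative dielectric (default 4).
#' @return Numeric vector in `[-1, 1]`, one value per vertex.
#' @export
assign_electrostatics <- function(mesh, source, cap = 30, kappa = 0.1,
                                  eps_r = 4) {
  vtx <- mesh$vertices
  if (inherits(source, "dx_grid")) {
    lo <- c(source$xs[1], source$ys[1], source$zs[1])
    hi <- c(source$xs[length(source$xs)], source$ys[length(source$ys)],
            source$zs[length(source$zs)])
    below <- apply(sweep(vtx, 2, lo) < -1e-9, 2, any)
    above <- apply(sweep(vtx, 2, hi) > 1e-9, 2, any)
    if (any(below | above)) {
      stop("potential grid does not cover the mesh bounding box on axis ",
        paste(c("x", "y", "z")[below | above], collapse = ","))
    }
    phi <- trilinear(source$values, source$xs, source$ys, source$zs, vtx)
  } else if (inherits(source, "atom_set")) {
    phi <- coulomb_potential(vtx, source, kappa = kappa, eps_r = eps_r)
  } else {
    stop("source must be a dx_grid or an atom_set")
  }
  pmin(pmax(phi / cap, -1), 1)
}

# kT/e at 298 K: Coulomb constant 332.0636 kcal mol^-1 A e^-2 over
# kT = 0.593 kcal/mol
COULOMB_KT <- 332.0636 / 0.593

coulomb_potential <- function(points, atoms, kappa = 0.1, eps_r = 4) {
  prot <- atoms[!atoms$is_ligand, , drop = FALSE]
  q <- prot$charge
  if (!any(q != 0)) return(numeric(nrow(points)))
  xyz <- atom_coords(prot)
  d2 <- outer(rowSums(points^2), rowSums(xyz^2), `+`) - 2 * points %*% t(xyz)
  d2[d2 < 0] <- 0
  d <- pmax(sqrt(d2), 0.5)
  as.vector((exp(-kappa * d) / d) %*% q) * COULOMB_KT / eps_r
}

#' Read a scalar field in OpenDX format
#'
#' Parses the OpenDX dialect written by Poisson-Boltzmann solvers
#' (`gridpositions counts`, `origin`, three `delta` rows, data block).
#'
#' @param file Path to the .dx file.
#' @return A `dx_grid`: list with axis coordinate vectors `xs`, `ys`, `zs`
#'   and `values` (3D array, x fastest... stored x-major internally).
#' @export
read_opendx <- function(file) {
  lines <- readLines(file)
  cnt <- grep("gridpositions", lines, value = TRUE)[1]
  if (is.na(cnt)) stop("not an OpenDX gridpositions file: ", file)
  counts <- as.integer(rev(rev(strsplit(trimws(cnt), "\\s+")[[1]])[1:3]))
  org <- as.numeric(strsplit(trimws(sub("origin", "",
    grep("^origin", lines, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- t(vapply(grep("^delta", lines, value = TRUE)[1:3], function(l) {
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(deltas[row(deltas) != col(deltas)]) > 1e-9)) {
    stop("only axis-aligned OpenDX grids are supported")
  }
  d3 <- grep("class array", lines)
  data_start <- d3[length(d3)] + 1L
  end <- grep("^(attribute|object \"|component)", lines)
  end <- end[end >= data_start]
  data_end <- if (length(end)) min(end) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[data_start:data_end]), "\\s+")))
  vals <- vals[!is.na(vals)]
  nx <- counts[1]; ny <- counts[2]; nz <- counts[3]
  if (length(vals) != nx * ny * nz) {
    stop("OpenDX data length ", length(vals), " != ", nx * ny * nz)
  }
  # dx data order: z fastest; convert to x-fastest array
  arr <- aperm(array(vals, c(nz, ny, nx)), c(3, 2, 1))
  structure(list(
    xs = org[1] + (seq_len(nx) - 1) * deltas[1, 1],
    ys = org[2] + (seq_len(ny) - 1) * deltas[2, 2],
    zs = org[3] + (seq_len(nz) - 1) * deltas[3, 3],
    values = arr), class = "dx_grid")
}

#' Compute the full vertex property table
#'
#' Convenience wrapper running pseudocenter construction, exposure
#' filtering, channel assignment, hydrophobicity and electrostatics for a
#' mesh against its source structure.
#'
#' @param mesh A `surface_mesh`.
#' @param atoms The source [atom_set()].
#' @param potential Optional `dx_grid`; defaults to the built-in Coulomb
#'   model from `atoms` charges.
#' @param cutoffs Exposure cutoffs, see [pseudo_cutoffs()].
#' @return A `vertex_properties` list: `pseudo` (n x 4 binary),
#'   `hydrophobicity`, `charge` (both n, in `[-1, 1]`), plus the filtered
#'   `centers`.
#' @export
compute_vertex_properties <- function(mesh, atoms, potential = NULL,
                                      cutoffs = pseudo_cutoffs()) {
  centers <- build_pseudocenters(atoms)
  centers <- filter_pseudocenters(centers, mesh, cutoffs)
  structure(list(
    pseudo = assign_pseudo_channels(mesh, centers),
    hydrophobicity = assign_hydrophobicity(mesh, atoms),
    charge = assign_electrostatics(mesh,
      if (is.null(potential)) atoms else potential),
    centers = centers), class = "vertex_properties")
}

#' Write vertex properties as a TSV sidecar
#' @param props A `vertex_properties` object.
#' @param file Output path.
#' @export
write_vertex_properties <- function(props, file) {
  df <- data.frame(vertex = seq_along(props$hydrophobicity),
    DON = props$pseudo[, 1], ACC = props$pseudo[, 2],
    ALI = props$pseudo[, 3], ARO = props$pseudo[, 4],
    hydrophobicity = props$hydrophobicity, charge = props$charge)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a vertex property sidecar written by [write_vertex_properties()]
#' @param file Path to the TSV.
#' @return A `vertex_properties` list (without `centers`).
#' @export
read_vertex_properties <- function(file) {
  df <- utils::read.delim(file)
  structure(list(
    pseudo = as.matrix(df[, c("DON", "ACC", "ALI", "ARO")]),
    hydrophobicity = df$hydrophobicity,
    charge = df$charge, centers = NULL), class = "vertex_properties")
}
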