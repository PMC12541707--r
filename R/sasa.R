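# Shrake-Rupley solvent-accessible surface area and radius of gyration.
#
# SASA uses a deterministic golden-spiral quadrature on each expanded
# sphere (radius + probe); a point is accessible when outside every other
# atom's expanded sphere. Deterministic point placement makes results
# exactly reproducible.

# n approximately evenly spread unit vectors (Fibonacci / golden spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-molecule and total SASA for a subset of molecules, with
#' every atom in the snapshot acting as potential occluder.
#'
#' @param snap A [snapshot()].
#' @param subset Molecule ids to measure; defaults to all molecules.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Quadrature points per atom (default 960; must be >= 100).
#' @return List with `per_molecule` (named numeric, Angstrom^2), `total`,
#'   and `per_atom` (numeric vector aligned with the measured atoms).
#' @export
sasa <- function(snap, subset = NULL, probe_radius = 1.4, n_points = 960) {
  stopifnot(n_points >= 100)
  if (is.null(subset)) subset <- snap$molecules$mol_id
  if (length(subset) == 0) stop("empty molecule subset")
  if (!all(subset %in% snap$molecules$mol_id)) stop("unknown molecule id in subset")
  pts <- golden_spiral_points(n_points)
  all_atoms <- snap$atoms
  xyz_all <- coords(all_atoms)
  r_all <- all_atoms$radius + probe_radius
  sel <- all_atoms$mol_id %in% subset
  idx <- which(sel)
  area <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ri <- r_all[i]
    surf <- sweep(pts * ri, 2, xyz_all[i, ], "+")
    # occluders: atoms whose expanded sphere can reach this atom's surface
    d2 <- rowSums(sweep(xyz_all, 2, xyz_all[i, ])^2)
    occ <- which(d2 < (ri + r_all)^2 & seq_along(d2) != i)
    if (length(occ) == 0) {
      acc <- n_points
    } else {
      inside <- rep(FALSE, n_points)
      for (j in occ) {
        dj2 <- rowSums(sweep(surf, 2, xyz_all[j, ])^2)
        inside <- inside | dj2 < r_all[j]^2
        if (all(inside)) break
      }
      acc <- sum(!inside)
    }
    area[k] <- 4 * pi * ri^2 * acc / n_points
  }
  per_mol <- tapply(area, all_atoms$mol_id[idx], sum)
  per_mol <- stats::setNames(as.numeric(per_mol), names(per_mol))
  list(per_molecule = per_mol[as.character(subset)], total = sum(area),
       per_atom = area)
}

#' Burial fraction of a molecule
#'
#' SASA of the molecule in the full system divided by its SASA in
#' isolation; 1 means fully exposed, 0 fully occluded.
#'
#' @param mol_id Molecule id.
#' @param snap A [snapshot()].
#' @param probe_radius Probe radius in Angstrom.
#' @param n_points Quadrature points per atom.
#' @return Ratio in `[0, 1]`.
#' @export
burial_fraction <- function(mol_id, snap, probe_radius = 1.4, n_points = 960) {
  in_system <- sasa(snap, subset = mol_id, probe_radius = probe_radius,
                    n_points = n_points)$total
  atoms <- mol_atoms(snap, mol_id)
  iso <- snapshot(atoms, snap$molecules[snap$molecules$mol_id == mol_id, , drop = FALSE])
  alone <- sasa(iso, subset = mol_id, probe_radius = probe_radius,
                n_points = n_points)$total
  if (alone <= 0) stop("degenerate geometry: isolated SASA of molecule ",
                       mol_id, " is zero")
  in_system / alone
}

#' Radius of gyration
#'
#' Mass-unweighted Rg about the centroid of the given atoms (all atoms
#' weighted equally); set `weights` for a weighted variant.
#'
#' @param atoms Atom data.frame (e.g. `snapshot$atoms` or a subset).
#' @param weights Optional per-atom weights.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(atoms, weights = NULL) {
  xyz <- coords(atoms)
  if (nrow(xyz) == 0) stop("no atoms")
  w <- if (is.null(weights)) rep(1, nrow(xyz)) else weights
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}
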