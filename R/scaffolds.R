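# Assembly builders.
#
# Peptides use a reduced representation: backbone N, CA, C, O per residue
# plus one typed side-chain pseudo-atom, laid out as an idealized extended
# beta-strand (3.5 A rise per residue; amide N and carbonyl O offset
# +/-0.9 A across the hydrogen-bond axis so that an antiparallel partner
# at the standard 4.8 A inter-strand spacing forms N...O contacts of
# 3.0 A). The ordered-assembly (IPS) builder stacks pocket units - one
# drug enclosed by two antiparallel peptide pairs on facing layers - and
# places Zn2+ at coordination distance from His imidazoles with NO3-
# completing neutrality.

.RISE <- 3.5        # A per residue along the strand axis
.NO_OFF <- 0.9      # N/O offset across the hydrogen-bond axis
.FLIP_SHIFT <- 3 * .RISE  # x shift aligning an antiparallel partner's H-bonds

# idealized extended strand for one peptide, N-terminus at x ~ 0,
# strand axis +x, side chains alternating +/- z
peptide_atoms <- function(pep) {
  aa <- amino_acid_table()
  rows <- list()
  for (i in 0:3) {
    code <- pep$residues[i + 1]
    x0 <- .RISE * i
    side <- if (i %% 2 == 0) 1 else -1
    rec <- aa[code, ]
    rows[[length(rows) + 1]] <- data.frame(
      name = c("N", "CA", "C", "O", rec$sc_name),
      element = c("N", "C", "C", "O", rec$sc_element),
      resid = i + 1L, rescode = code,
      x = c(x0 - 1.2, x0, x0 + 1.2, x0 + 1.2, x0),
      y = c(.NO_OFF, 0, -0.3, -.NO_OFF, 0),
      z = c(0, 0.3 * side, 0, 0, 1.5 * side),
      radius = c(element_radius(c("N", "C", "C", "O")),
                 element_radius(rec$sc_element)),
      hydrophobic = c(FALSE, FALSE, FALSE, FALSE, rec$sc_hydrophobic),
      donor = c(TRUE, FALSE, FALSE, FALSE, rec$sc_donor),
      acceptor = c(FALSE, FALSE, FALSE, TRUE, rec$sc_acceptor),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, rec$sc_aromatic),
      metal = FALSE,
      charged = c(FALSE, FALSE, FALSE, FALSE, rec$sc_fcharge != 0),
      fcharge = c(0, 0, 0, 0, rec$sc_fcharge),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (pep$termini$c_terminus == "carboxylate") {
    atoms <- rbind(atoms, data.frame(
      name = "OXT", element = "O", resid = 4L, rescode = pep$residues[4],
      x = .RISE * 3 + 2.2, y = -0.3, z = 0, radius = element_radius("O"),
      hydrophobic = FALSE, donor = FALSE, acceptor = TRUE, aromatic = FALSE,
      metal = FALSE, charged = TRUE, fcharge = -1, stringsAsFactors = FALSE))
  }
  atoms
}

transform_atoms <- function(atoms, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- sweep(coords(atoms) %*% t(rotation), 2, translation, "+")
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# antiparallel partner: 180 degrees about the hydrogen-bond (y) normal,
# so the partner's carbonyl oxygens point back toward the first strand
rot_y180 <- diag(c(-1, 1, -1))

# axis-angle rotation matrix
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  u <- stats::runif(3)
  axis <- c(cos(2 * pi * u[2]) * sqrt(u[1]), sin(2 * pi * u[2]) * sqrt(u[1]),
            sqrt(1 - u[1]))
  rotation_matrix(axis, 2 * pi * u[3])
}

# place a drug's atoms so its reference frame lands on the given frame,
# optionally pre-rotated (pose) about its own frame
place_drug_atoms <- function(drug, origin, axes = diag(3), pose = diag(3)) {
  a <- drug_atoms(drug)
  rp <- drug$reference_pose
  local <- sweep(coords(a), 2, rp$origin) %*% rp$axes  # to local frame
  xyz <- sweep(local %*% t(pose) %*% t(axes), 2, origin, "+")
  a[, c("x", "y", "z")] <- xyz
  a
}

#' Build an idealized ordered assembly (IPS)
#'
#' Stacks `n_pocket_units` pocket units into a continuous antiparallel
#' beta-sheet arrangement: each unit holds one drug centered between two
#' layers, each layer an antiparallel pair of peptides at the given
#' inter-strand spacing. The drug contacts the side chains of residues 2
#' and 4 of the front pair and residues 1 and 3 of the back pair. Zn2+
#' ions are placed at coordination distance (2.1 A) from His imidazole
#' nitrogens and NO3- ions complete charge neutrality. The construction
#' is fully deterministic.
#'
#' @param pep A [peptide()].
#' @param drug A [drug_spec()].
#' @param n_pocket_units Number of stacked pocket units (default 1).
#' @param inter_strand Inter-strand spacing in Angstrom (default 4.8).
#' @param layer_sep Separation between front and back layers (default 10).
#' @param min_zn Minimum Zn2+ count passed to [solve_neutrality()]
#'   (default: one per pocket unit).
#' @return A [snapshot()].
#' @export
build_ips <- function(pep, drug, n_pocket_units = 1L, inter_strand = 4.8,
                      layer_sep = 10, min_zn = n_pocket_units) {
  stopifnot(n_pocket_units >= 1)
  sol <- solve_neutrality(4L * n_pocket_units, pep, n_pocket_units, drug,
                          min_zn = min_zn)
  snap <- empty_snapshot()
  label <- format(pep)
  tmpl <- peptide_atoms(pep)
  his_sc <- which(tmpl$resid == 4L & !tmpl$name %in% c("N", "CA", "C", "O", "OXT"))
  zn_sites <- list()
  for (u in seq_len(n_pocket_units) - 1L) {
    y0 <- u * 2 * inter_strand * 2  # unit pitch: two strands + one gap
    for (layer in c(1, -1)) {
      zoff <- layer * layer_sep / 2
      a1 <- transform_atoms(tmpl, translation = c(0, y0, zoff))
      a2 <- transform_atoms(tmpl, rot_y180, c(.FLIP_SHIFT, y0 + inter_strand, zoff))
      snap <- add_molecule(snap, "peptide", label, a1)
      snap <- add_molecule(snap, "peptide", label, a2)
      # His side chain of each layer's first strand: a Zn coordination site
      # extended along the side-chain direction (away from the backbone)
      sc <- a1[his_sc, c("x", "y", "z")]
      ca_z <- a1$z[a1$resid == 4L & a1$name == "CA"]
      zn_sites[[length(zn_sites) + 1]] <-
        c(sc$x, sc$y, sc$z + 2.1 * sign(sc$z - ca_z))
    }
    dctr <- c(.FLIP_SHIFT / 2, y0 + inter_strand / 2, 0)
    snap <- add_molecule(snap, "drug", drug$name, place_drug_atoms(drug, dctr))
  }
  for (k in seq_len(sol$n_zn)) {
    site <- zn_sites[[(k - 1L) %% length(zn_sites) + 1L]]
    off <- c(0, 3.0 * ((k - 1L) %/% length(zn_sites)), 0)
    snap <- add_molecule(snap, "zn", "ZN", zn_atoms(site + off))
  }
  for (k in seq_len(sol$n_no3)) {
    site <- zn_sites[[(k - 1L) %% length(zn_sites) + 1L]]
    pos <- site + c(4.0 + 4.0 * ((k - 1L) %/% length(zn_sites)), 0,
                    -sign(site[3]) * 1.0)
    snap <- add_molecule(snap, "no3", "NO3", no3_atoms(pos))
  }
  validate_snapshot(snap)
  snap
}

#' Rigid-body superposition of a drug onto a reference frame
#'
#' Least-squares (Kabsch) fit of the drug's reference-pose anchor points
#' (origin plus the three axis tips) onto the reference, then applies the
#' fitted transform to all atoms.
#'
#' @param drug A [drug_spec()].
#' @param reference Either another `drug_spec` (its reference pose is the
#'   target) or a list with `origin` (length 3) and `axes` (3x3 orthonormal
#'   columns).
#' @return List with `atoms` (placed atom table), `rmsd` (over anchor
#'   points), `rotation` and `translation`.
#' @export
superpose_drug <- function(drug, reference) {
  ref <- if (inherits(reference, "drug_spec")) reference$reference_pose else reference
  rp <- drug$reference_pose
  P <- rbind(rp$origin, sweep(t(rp$axes) * 2, 2, rp$origin, "+"))
  Q <- rbind(ref$origin, sweep(t(ref$axes) * 2, 2, ref$origin, "+"))
  fit <- kabsch_fit(P, Q)
  a <- drug_atoms(drug)
  xyz <- sweep(coords(a) %*% t(fit$rotation), 2, fit$translation, "+")
  a[, c("x", "y", "z")] <- xyz
  list(atoms = a, rmsd = fit$rmsd, rotation = fit$rotation,
       translation = fit$translation)
}

#' Kabsch rigid-body fit
#'
#' Optimal rotation + translation minimizing the RMSD of point set `P`
#' onto `Q` (rows are points).
#'
#' @param P,Q Numeric matrices of matching dimension (n x 3, n >= 3).
#' @return List with `rotation`, `translation`, `rmsd`.
#' @export
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) stop("degenerate (collinear) anchor geometry")
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t_, "+")
  list(rotation = R, translation = t_,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

# minimum intermolecular atom distance between atom table A and B
min_pair_distance <- function(A, B) {
  xa <- coords(A); xb <- coords(B)
  D2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(D2)))
}

# TRUE when some intermolecular pair overlaps below factor * (r_i + r_j)
has_overlap <- function(A, B, factor = 0.7) {
  xa <- coords(A); xb <- coords(B)
  D2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  lim <- (factor * outer(A$radius, B$radius, "+"))^2
  any(D2 < lim - 1e-9)
}

#' Build a perturbed, compacted (SES-like) assembly
#'
#' Scales all inter-molecule centroid distances toward the system
#' centroid by `compaction` - clamped to the tightest sterically
#' feasible value, so ordered assemblies that are already near contact
#' compact only as far as the 0.7 x radius-sum overlap limit allows -
#' then applies a seeded random rigid-body jitter per molecule
#' (translation bounded by `perturbation` Angstrom, rotation angle
#' scaled with it). A jitter draw creating an overlap is re-drawn; after
#' `max_retries` draws the molecule keeps its unjittered (always
#' feasible) position.
#'
#' @param ips A [snapshot()] (typically from [build_ips()]).
#' @param perturbation Maximum per-molecule displacement in Angstrom (>= 0).
#' @param compaction Requested centroid-distance scale factor in (0, 1].
#' @param seed Integer seed.
#' @param max_retries Per-molecule jitter retry budget (default 50).
#' @return A [snapshot()]; the effective compaction used is attached as
#'   attribute `"compaction"`.
#' @export
build_ses_like <- function(ips, perturbation, compaction = 1, seed = 1L,
                           max_retries = 50L) {
  stopifnot(perturbation >= 0, compaction > 0, compaction <= 1)
  set.seed(as.integer(seed))
  sys_ctr <- colMeans(coords(ips$atoms))
  ids <- ips$molecules$mol_id
  tables <- lapply(ids, function(id) mol_atoms(ips, id))
  ctrs <- lapply(tables, function(a) colMeans(coords(a)))
  scale_to <- function(cf) {
    lapply(seq_along(tables), function(i) {
      a <- tables[[i]]
      shift <- (cf - 1) * (ctrs[[i]] - sys_ctr)
      a[, c("x", "y", "z")] <- sweep(coords(a), 2, shift, "+")
      a
    })
  }
  any_clash <- function(tabs) {
    n <- length(tabs)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (has_overlap(tabs[[i]], tabs[[j]])) return(TRUE)
    FALSE
  }
  # clamp the compaction to steric feasibility (bisection; gaps shrink
  # monotonically as the scale factor decreases)
  c_eff <- compaction
  if (compaction < 1 && any_clash(scale_to(compaction))) {
    lo <- compaction; hi <- 1
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      if (any_clash(scale_to(mid))) lo <- mid else hi <- mid
    }
    c_eff <- hi
  }
  tabs <- scale_to(c_eff)
  if (perturbation > 0) {
    for (i in seq_along(tabs)) {
      a <- tabs[[i]]
      ctr <- colMeans(coords(a))
      for (try in seq_len(max_retries)) {
        ang <- stats::runif(1, 0, perturbation * 0.1)
        R <- rotation_matrix(stats::rnorm(3), ang)
        u <- stats::rnorm(3)
        shift <- stats::runif(1, 0, perturbation) * u / sqrt(sum(u^2))
        cand <- a
        cand[, c("x", "y", "z")] <- sweep(sweep(coords(a), 2, ctr) %*% t(R),
                                          2, ctr + shift, "+")
        clash <- any(vapply(seq_along(tabs)[-i], function(j)
          has_overlap(cand, tabs[[j]]), logical(1)))
        if (!clash) { tabs[[i]] <- cand; break }
      }
    }
  }
  out <- ips
  for (i in seq_along(ids))
    out$atoms[out$atoms$mol_id == ids[i], c("x", "y", "z")] <-
      tabs[[i]][, c("x", "y", "z")]
  attr(out, "compaction") <- c_eff
  out
}

# molecule atom-table factory for one composition, in manifest order
composition_molecules <- function(comp) {
  mols <- list()
  for (i in seq_len(comp$n_peptides))
    mols[[length(mols) + 1]] <- list(kind = "peptide", label = format(comp$peptide),
                                     atoms = peptide_atoms(comp$peptide))
  for (i in seq_len(comp$n_drugs))
    mols[[length(mols) + 1]] <- list(kind = "drug", label = comp$drug$name,
                                     atoms = drug_atoms(comp$drug))
  for (i in seq_len(comp$n_zn))
    mols[[length(mols) + 1]] <- list(kind = "zn", label = "ZN", atoms = zn_atoms())
  for (i in seq_len(comp$n_no3))
    mols[[length(mols) + 1]] <- list(kind = "no3", label = "NO3", atoms = no3_atoms())
  mols
}

#' Random-arrangement co-assembly starting snapshot
#'
#' Places all components of a charge-neutral composition (optionally
#' multiplied) at seeded random positions and orientations in a cubic
#' box, enforcing a minimum inter-molecule atom distance. This emulates
#' the random starting states of early-stage co-assembly runs at the
#' designed component ratio.
#'
#' @param comp A [system_composition()].
#' @param n_copies Integer multiplier on all counts (default 1).
#' @param box Box edge in Angstrom, or `NULL` to derive it from a target
#'   number density of 0.001 molecules per cubic Angstrom.
#' @param min_separation Minimum inter-molecule atom distance (default 3).
#' @param seed Integer seed.
#' @param max_retries Per-molecule placement retries (default 200).
#' @return A [snapshot()].
#' @export
generate_random_snapshot <- function(comp, n_copies = 1L, box = NULL,
                                     min_separation = 3, seed = 1L,
                                     max_retries = 200L) {
  stopifnot(inherits(comp, "system_composition"), n_copies >= 1)
  set.seed(as.integer(seed))
  mols <- rep(composition_molecules(comp), n_copies)
  n <- length(mols)
  rho <- vapply(mols, function(m) {
    xyz <- coords(m$atoms); ctr <- colMeans(xyz)
    sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  }, numeric(1))
  max_rho <- max(rho)
  # default box: target number density 5e-4 / A^3, but never so small that
  # the largest molecule has no room to move
  if (is.null(box)) box <- max((n / 5e-4)^(1 / 3),
                               3.5 * max_rho + 2 * min_separation)
  # coarse feasibility guard; tight-but-possible packings are left to the
  # retry loop
  if (4 * n * min_separation^3 > box^3 || box < 2 * max_rho + min_separation)
    stop("box too small for ", n, " molecules at min_separation ", min_separation)
  snap <- empty_snapshot()
  placed <- list()
  for (mi in seq_along(mols)) {
    m <- mols[[mi]]
    ctr0 <- colMeans(coords(m$atoms))
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      R <- random_rotation()
      pos <- stats::runif(3, rho[mi], box - rho[mi])
      cand <- m$atoms
      cand[, c("x", "y", "z")] <- sweep(sweep(coords(m$atoms), 2, ctr0) %*% t(R),
                                        2, pos, "+")
      far <- all(vapply(placed, function(p) min_pair_distance(cand, p) >=
                          min_separation, logical(1)))
      if (far) { ok <- TRUE; break }
    }
    if (!ok) stop("packing failure after ", max_retries,
                  " retries (", length(placed), "/", n, " molecules placed; ",
                  "box ", round(box, 1), " A)")
    placed[[length(placed) + 1]] <- cand
    snap <- add_molecule(snap, m$kind, m$label, cand)
  }
  validate_snapshot(snap)
  snap
}

#' Plant spatially separated clusters with known ground truth
#'
#' Builds a snapshot whose partition into connected aggregates is known
#' by construction: each planned cluster is a chain of molecules placed
#' so consecutive members are within `contact` Angstrom, and clusters are
#' separated by at least `spacing` Angstrom. Useful as a fixture for
#' cluster-detection tests: the truth is recovered exactly whenever
#' `contact < cutoff < spacing`.
#'
#' @param plan List of per-cluster counts; each element a list/vector with
#'   `peptide`, `drug`, `zn`, `no3` entries (missing = 0). Use counts of 1
#'   for singletons.
#' @param pep A [peptide()] used for all peptide members.
#' @param drug A [drug_spec()] used for all drug members.
#' @param spacing Minimum gap between clusters (default 20).
#' @param contact Target intra-chain contact distance (default 3).
#' @param seed Integer seed (molecule orientations).
#' @return List with `snapshot` and `truth` (list of molecule-id vectors,
#'   one per planned cluster).
#' @export
plant_clusters <- function(plan, pep = peptide("FFWH"), drug = drug_spec("toy"),
                           spacing = 20, contact = 3, seed = 1L) {
  set.seed(as.integer(seed))
  snap <- empty_snapshot()
  truth <- list()
  if (length(plan) == 0) return(list(snapshot = snap, truth = truth))
  x_base <- 0
  for (ci in seq_along(plan)) {
    p <- as.list(plan[[ci]])
    for (f in c("peptide", "drug", "zn", "no3")) if (is.null(p[[f]])) p[[f]] <- 0L
    mols <- list()
    for (i in seq_len(p$peptide)) mols[[length(mols) + 1]] <-
        list(kind = "peptide", label = format(pep), atoms = peptide_atoms(pep))
    for (i in seq_len(p$drug)) mols[[length(mols) + 1]] <-
        list(kind = "drug", label = drug$name, atoms = drug_atoms(drug))
    for (i in seq_len(p$zn)) mols[[length(mols) + 1]] <-
        list(kind = "zn", label = "ZN", atoms = zn_atoms())
    for (i in seq_len(p$no3)) mols[[length(mols) + 1]] <-
        list(kind = "no3", label = "NO3", atoms = no3_atoms())
    if (length(mols) == 0) next
    ids <- integer(0)
    prev <- NULL
    for (m in mols) {
      a <- m$atoms
      ctr <- colMeans(coords(a))
      a[, c("x", "y", "z")] <- sweep(coords(a), 2, ctr) %*% t(random_rotation())
      if (is.null(prev)) {
        a[, "x"] <- a[, "x"] + x_base - min(a$x)
      } else {
        # slide along +x from beyond the previous molecule until the chain
        # contact distance is reached
        shift <- max(prev$x) - min(a$x) + contact + 3
        a[, "x"] <- a[, "x"] + shift
        while (min_pair_distance(a, prev) > contact) a[, "x"] <- a[, "x"] - 0.25
      }
      prev <- a
      snap <- add_molecule(snap, m$kind, m$label, a)
      ids <- c(ids, max(snap$molecules$mol_id))
    }
    truth[[ci]] <- ids
    x_base <- max(snap$atoms$x) + spacing
  }
  validate_snapshot(snap)
  list(snapshot = snap, truth = truth)
}
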