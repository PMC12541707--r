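# Empirical pairwise association scoring.
#
# The scorer follows the published Vinardo parameterization: a single
# attractive gaussian and a quadratic repulsion on the atom surface
# distance, a linear-switch hydrophobic term, and a linear-switch
# non-directional hydrogen-bond term, all truncated at a hard cutoff.
# Zn2+ coordination is scored as a separable gaussian distance well
# between the metal and eligible partners (His deprotonated imidazole N,
# anionic oxygens) - a deliberate simplification of directional
# metal-docking terms. Energies are reported in kcal/mol.

#' Scoring parameters
#'
#' Defaults follow the published Vinardo weights (gauss -0.045 with width
#' 0.8 A; repulsion 0.8; hydrophobic -0.035 switching off over 0..2.5 A of
#' surface distance; hydrogen bond -0.6 switching off over -0.6..0 A) with
#' an 8 A hard cutoff on the center distance, plus a Zn coordination well
#' (ideal 2.1 A, tolerance 0.4 A).
#'
#' @param gauss_weight,gauss_width Attractive gaussian term.
#' @param repulsion_weight Quadratic penalty for surface overlap (d < 0).
#' @param hydrophobic_weight,hydrophobic_on,hydrophobic_off Linear switch for
#'   hydrophobic-hydrophobic pairs.
#' @param hbond_weight,hbond_on,hbond_off Linear switch for donor-acceptor
#'   pairs.
#' @param zn_weight,zn_ideal,zn_tolerance Gaussian well on the Zn-partner
#'   center distance.
#' @param cutoff Hard cutoff on atom center distance in Angstrom.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(gauss_weight = -0.045, gauss_width = 0.8,
                           repulsion_weight = 0.8,
                           hydrophobic_weight = -0.035, hydrophobic_on = 0,
                           hydrophobic_off = 2.5,
                           hbond_weight = -0.6, hbond_on = -0.6, hbond_off = 0,
                           zn_weight = -2.0, zn_ideal = 2.1, zn_tolerance = 0.4,
                           cutoff = 8) {
  stopifnot(gauss_width > 0, zn_tolerance > 0,
            hydrophobic_on < hydrophobic_off, hbond_on < hbond_off,
            cutoff >= hydrophobic_off)
  structure(list(gauss_weight = gauss_weight, gauss_width = gauss_width,
                 repulsion_weight = repulsion_weight,
                 hydrophobic_weight = hydrophobic_weight,
                 hydrophobic_on = hydrophobic_on, hydrophobic_off = hydrophobic_off,
                 hbond_weight = hbond_weight, hbond_on = hbond_on,
                 hbond_off = hbond_off,
                 zn_weight = zn_weight, zn_ideal = zn_ideal,
                 zn_tolerance = zn_tolerance, cutoff = cutoff),
            class = "scoring_params")
}

# linear switch: 1 for d <= on, 0 for d >= off
.switch_fn <- function(d, on, off) pmin(1, pmax(0, (off - d) / (off - on)))

# atoms eligible to coordinate Zn2+: His deprotonated imidazole N or an
# anionic oxygen (carboxylate terminus, drug carboxylate/sulfonate)
.zn_eligible <- function(atoms) {
  (atoms$element == "N" & !is.na(atoms$rescode) & atoms$rescode == "H" &
     atoms$name == "NE2") |
    (atoms$element == "O" & atoms$fcharge < 0)
}

# term-wise energies between every atom of A and every atom of B.
# Returns a list of n_A x n_B matrices (gauss, repulsion, hydrophobic,
# hbond, zn), all zeroed beyond the center-distance cutoff.
.pair_terms <- function(A, B, params) {
  xa <- coords(A); xb <- coords(B)
  D2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  D <- sqrt(pmax(D2, 0))
  within_cut <- D <= params$cutoff
  ds <- D - outer(A$radius, B$radius, "+")
  gauss <- params$gauss_weight * exp(-(ds / params$gauss_width)^2)
  rep_ <- params$repulsion_weight * ds^2 * (ds < 0)
  hyd <- params$hydrophobic_weight *
    outer(A$hydrophobic, B$hydrophobic, "&") *
    .switch_fn(ds, params$hydrophobic_on, params$hydrophobic_off)
  hb_pair <- outer(A$donor, B$acceptor, "&") | outer(A$acceptor, B$donor, "&")
  hb <- params$hbond_weight * hb_pair * .switch_fn(ds, params$hbond_on, params$hbond_off)
  zn_pair <- outer(A$metal, .zn_eligible(B), "&") | outer(.zn_eligible(A), B$metal, "&")
  zn <- params$zn_weight * zn_pair *
    exp(-(D - params$zn_ideal)^2 / (2 * params$zn_tolerance^2))
  lapply(list(gauss = gauss, repulsion = rep_, hydrophobic = hyd,
              hbond = hb, zn = zn),
         function(m) m * within_cut)
}

#' Pairwise interaction energy between two atoms
#'
#' Evaluates the empirical pair potential on the surface distance
#' `d = |pos_a - pos_b| - r_a - r_b`: attractive gaussian plus overlap
#' repulsion, a hydrophobic switch term when both atoms are hydrophobic,
#' a hydrogen-bond switch term for donor-acceptor pairs, and the Zn
#' coordination well for metal-partner pairs. Exactly zero beyond the
#' center-distance cutoff.
#'
#' @param a,b Single-row atom records (as in `snapshot$atoms`).
#' @param params A [scoring_params()].
#' @param breakdown If `TRUE`, return the named per-term vector.
#' @return Energy in kcal/mol (or named vector of terms).
#' @export
pair_term_energy <- function(a, b, params = scoring_params(), breakdown = FALSE) {
  tl <- .pair_terms(a, b, params)
  terms <- vapply(tl, function(m) m[1, 1], numeric(1))
  if (breakdown) terms else sum(terms)
}

#' Association energy of one molecule with the rest of the system
#'
#' Sums the empirical pair potential over every atom pair joining the
#' molecule with every other molecule in the snapshot. This is the
#' quantity the design loop minimizes when averaged over drug copies.
#'
#' @param mol_id Molecule id present in the snapshot.
#' @param snap A [snapshot()].
#' @param params A [scoring_params()].
#' @return An object of class `association_energy`: list with
#'   `molecule_id`, `energy` (kcal/mol) and the per-term `terms` breakdown
#'   (which sums to `energy`).
#' @export
association_energy <- function(mol_id, snap, params = scoring_params()) {
  A <- mol_atoms(snap, mol_id)
  B <- snap$atoms[snap$atoms$mol_id != mol_id, , drop = FALSE]
  terms <- c(gauss = 0, repulsion = 0, hydrophobic = 0, hbond = 0, zn = 0)
  if (nrow(B)) {
    # prefilter partner atoms by a bounding box to keep the matrices small
    xa <- coords(A)
    lo <- apply(xa, 2, min) - params$cutoff
    hi <- apply(xa, 2, max) + params$cutoff
    keep <- B$x >= lo[1] & B$x <= hi[1] & B$y >= lo[2] & B$y <= hi[2] &
      B$z >= lo[3] & B$z <= hi[3]
    B <- B[keep, , drop = FALSE]
    if (nrow(B)) {
      tl <- .pair_terms(A, B, params)
      terms <- vapply(tl, sum, numeric(1))
    }
  }
  structure(list(molecule_id = mol_id, energy = sum(terms), terms = terms),
            class = "association_energy")
}

#' @export
print.association_energy <- function(x, ...) {
  cat("<association_energy> molecule ", x$molecule_id, ": ",
      format(x$energy, digits = 6), " kcal/mol\n", sep = "")
  print(round(x$terms, 4))
  invisible(x)
}

#' Mean association energy over all drug molecules
#'
#' The design-evaluation objective: the arithmetic mean of
#' [association_energy()] over every drug copy in the snapshot.
#'
#' @param snap A [snapshot()] containing at least one drug molecule.
#' @param params A [scoring_params()].
#' @return Mean energy in kcal/mol.
#' @export
mean_drug_association_energy <- function(snap, params = scoring_params()) {
  ids <- mol_ids_of_kind(snap, "drug")
  if (length(ids) == 0) stop("no drug molecules in snapshot")
  mean(vapply(ids, function(id) association_energy(id, snap, params)$energy,
              numeric(1)))
}

#' Zinc coordination census
#'
#' For each Zn2+ in the snapshot, lists the coordinating partners within
#' the cutoff - histidine deprotonated imidazole nitrogens, carboxylate /
#' anionic oxygens on peptides, and anionic drug atoms - with their
#' distances, and reports the percentage of Zn2+ coordinated to at least
#' one histidine nitrogen.
#'
#' @param snap A [snapshot()].
#' @param cutoff Coordination distance cutoff in Angstrom (default 2.5).
#' @return An object of class `zn_census`: list with `per_zn` (one
#'   data.frame of partners per Zn) and `percent_his_coordinated`
#'   (`NA` when the snapshot contains no Zn).
#' @export
zn_coordination_census <- function(snap, cutoff = 2.5) {
  zn_ids <- mol_ids_of_kind(snap, "zn")
  others <- snap$atoms
  kind_of <- stats::setNames(snap$molecules$kind, snap$molecules$mol_id)
  per_zn <- list()
  his_flag <- logical(length(zn_ids))
  for (i in seq_along(zn_ids)) {
    zn <- mol_atoms(snap, zn_ids[i])
    cand <- others[others$mol_id != zn_ids[i], , drop = FALSE]
    elig <- .zn_eligible(cand)
    cand <- cand[elig, , drop = FALSE]
    if (nrow(cand)) {
      d <- sqrt((cand$x - zn$x)^2 + (cand$y - zn$y)^2 + (cand$z - zn$z)^2)
      sel <- d <= cutoff
      cand <- cand[sel, , drop = FALSE]; d <- d[sel]
    } else d <- numeric()
    category <- character(nrow(cand))
    if (nrow(cand)) {
      mk <- kind_of[as.character(cand$mol_id)]
      category <- ifelse(!is.na(cand$rescode) & cand$rescode == "H" &
                           cand$name == "NE2", "his_n",
                  ifelse(mk == "drug", "drug_anion", "anionic_o"))
    }
    per_zn[[i]] <- data.frame(zn_mol_id = rep(zn_ids[i], nrow(cand)),
                              partner_mol_id = cand$mol_id,
                              partner_atom = cand$name,
                              category = category, distance = d,
                              stringsAsFactors = FALSE)
    his_flag[i] <- any(category == "his_n")
  }
  pct <- if (length(zn_ids)) 100 * mean(his_flag) else NA_real_
  structure(list(per_zn = per_zn, percent_his_coordinated = pct,
                 cutoff = cutoff), class = "zn_census")
}

#' @export
print.zn_census <- function(x, ...) {
  n <- length(x$per_zn)
  cat("<zn_census> ", n, " Zn2+; His-coordinated: ",
      if (is.na(x$percent_his_coordinated)) "n/a"
      else paste0(format(x$percent_his_coordinated, digits = 4), "%"),
      " (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}
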