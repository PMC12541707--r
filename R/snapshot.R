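# Snapshot container: one labelled multi-molecule coordinate frame.
#
# A snapshot holds a flat typed atom table plus a molecule table mapping
# molecule ids to kinds (peptide / drug / zn / no3) and labels (sequence
# string or drug name). All coordinates are in Angstrom.

.atom_cols <- c("atom_id", "mol_id", "name", "element", "resid", "rescode",
                "x", "y", "z", "radius", "hydrophobic", "donor", "acceptor",
                "aromatic", "metal", "charged", "fcharge")

#' Construct a snapshot
#'
#' Low-level constructor; most users build snapshots with [build_ips()],
#' [generate_random_snapshot()], [plant_clusters()] or [read_snapshot()].
#'
#' @param atoms data.frame with columns atom_id, mol_id, name, element,
#'   resid, rescode, x, y, z, radius and logical typing flags
#'   (hydrophobic, donor, acceptor, aromatic, metal, charged) plus numeric
#'   fcharge.
#' @param molecules data.frame with columns mol_id, kind
#'   (peptide/drug/zn/no3) and label.
#' @return An object of class `snapshot`.
#' @export
snapshot <- function(atoms, molecules) {
  missing <- setdiff(.atom_cols, names(atoms))
  if (length(missing)) stop("atom table missing column(s): ", paste(missing, collapse = ", "))
  snap <- structure(list(atoms = atoms[, .atom_cols],
                         molecules = molecules[, c("mol_id", "kind", "label")]),
                    class = "snapshot")
  validate_snapshot(snap)
  snap
}

empty_snapshot <- function() {
  atoms <- data.frame(atom_id = integer(), mol_id = integer(), name = character(),
                      element = character(), resid = integer(), rescode = character(),
                      x = numeric(), y = numeric(), z = numeric(), radius = numeric(),
                      hydrophobic = logical(), donor = logical(), acceptor = logical(),
                      aromatic = logical(), metal = logical(), charged = logical(),
                      fcharge = numeric(), stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 molecules = data.frame(mol_id = integer(), kind = character(),
                                        label = character(), stringsAsFactors = FALSE)),
            class = "snapshot")
}

#' Validate snapshot invariants
#'
#' Checks unique atom ids, molecule table consistency, finite coordinates,
#' positive radii, exactly one metal atom per zn molecule and four atoms
#' per nitrate.
#'
#' @param snap A `snapshot`.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_snapshot <- function(snap) {
  stopifnot(inherits(snap, "snapshot"))
  a <- snap$atoms; m <- snap$molecules
  if (anyDuplicated(a$atom_id)) stop("duplicate atom ids")
  if (anyDuplicated(m$mol_id)) stop("duplicate molecule ids")
  if (!all(a$mol_id %in% m$mol_id)) stop("atoms reference unknown molecule ids")
  if (!all(m$kind %in% c("peptide", "drug", "zn", "no3")))
    stop("unknown molecule kind(s): ", paste(setdiff(m$kind, c("peptide", "drug", "zn", "no3")), collapse = ", "))
  if (nrow(a)) {
    stopifnot(all(is.finite(as.matrix(a[, c("x", "y", "z")]))), all(a$radius > 0))
  }
  for (id in m$mol_id[m$kind == "zn"]) {
    sub <- a[a$mol_id == id, ]
    if (nrow(sub) != 1L || !sub$metal) stop("zn molecule ", id, " must be a single metal atom")
  }
  for (id in m$mol_id[m$kind == "no3"]) {
    if (sum(a$mol_id == id) != 4L) stop("no3 molecule ", id, " must have 4 atoms")
  }
  invisible(TRUE)
}

#' @export
print.snapshot <- function(x, ...) {
  k <- table(factor(x$molecules$kind, levels = c("peptide", "drug", "zn", "no3")))
  cat("<snapshot> ", nrow(x$molecules), " molecules (",
      k[["peptide"]], " peptide, ", k[["drug"]], " drug, ",
      k[["zn"]], " Zn2+, ", k[["no3"]], " NO3-), ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

# append one molecule; returns updated snapshot
add_molecule <- function(snap, kind, label, atoms) {
  mol_id <- if (nrow(snap$molecules)) max(snap$molecules$mol_id) + 1L else 1L
  base <- if (nrow(snap$atoms)) max(snap$atoms$atom_id) else 0L
  atoms$mol_id <- mol_id
  atoms$atom_id <- base + seq_len(nrow(atoms))
  if (is.null(atoms$resid)) atoms$resid <- NA_integer_
  if (is.null(atoms$rescode)) atoms$rescode <- NA_character_
  snap$atoms <- rbind(snap$atoms, atoms[, .atom_cols])
  snap$molecules <- rbind(snap$molecules,
                          data.frame(mol_id = mol_id, kind = kind, label = label,
                                     stringsAsFactors = FALSE))
  snap
}

mol_atoms <- function(snap, mol_id) {
  a <- snap$atoms[snap$atoms$mol_id == mol_id, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown molecule id: ", mol_id)
  a
}

mol_ids_of_kind <- function(snap, kind) snap$molecules$mol_id[snap$molecules$kind == kind]

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Rigid-body transform of a whole snapshot
#'
#' @param snap A `snapshot`.
#' @param rotation 3x3 rotation matrix (applied about the origin).
#' @param translation Length-3 numeric shift in Angstrom.
#' @return The transformed snapshot.
#' @export
transform_snapshot <- function(snap, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(snap$atoms) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  snap$atoms[, c("x", "y", "z")] <- xyz
  snap
}

# ion atom tables ------------------------------------------------------------

zn_atoms <- function(center = c(0, 0, 0)) {
  data.frame(name = "ZN", element = "ZN", resid = NA_integer_, rescode = NA_character_,
             x = center[1], y = center[2], z = center[3],
             radius = element_radius("ZN"), hydrophobic = FALSE, donor = FALSE,
             acceptor = FALSE, aromatic = FALSE, metal = TRUE, charged = TRUE,
             fcharge = 2, stringsAsFactors = FALSE)
}

no3_atoms <- function(center = c(0, 0, 0)) {
  # trigonal planar nitrate, N-O 1.25 A; the -1 charge spread over the oxygens
  ang <- c(0, 2, 4) * pi / 3
  data.frame(name = c("N", "O1", "O2", "O3"), element = c("N", "O", "O", "O"),
             resid = NA_integer_, rescode = NA_character_,
             x = center[1] + c(0, 1.25 * cos(ang)),
             y = center[2] + c(0, 1.25 * sin(ang)),
             z = center[3],
             radius = element_radius(c("N", "O", "O", "O")),
             hydrophobic = FALSE, donor = FALSE,
             acceptor = c(FALSE, TRUE, TRUE, TRUE), aromatic = FALSE,
             metal = FALSE, charged = TRUE,
             fcharge = c(0, -1 / 3, -1 / 3, -1 / 3), stringsAsFactors = FALSE)
}

drug_atoms <- function(drug) {
  a <- drug$atoms
  a$resid <- NA_integer_; a$rescode <- NA_character_
  a
}
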