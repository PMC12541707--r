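# Built-in drug specifications.
#
# Each drug carries a reduced (toy) heavy-atom geometry with per-atom
# interaction typing, a fixed net charge, and a reference pose used when
# superposing the drug into a binding pocket. Net charges (EPI/DOX +1,
# MTX -2, MIT/5FU/CPT/CP 0) are an assumption: they are the unique
# assignment consistent with the designed peptide:drug:Zn ratios and the
# peptide termini chemistry.

#' Van der Waals radii used by the scorer and SASA
#'
#' @param element Character vector of element symbols.
#' @return Numeric radii in Angstrom.
#' @export
element_radius <- function(element) {
  # heavy-atom radii follow the XS typing of empirical docking scorers;
  # Zn2+ uses its bare-cation ionic radius
  tab <- c(C = 1.9, N = 1.8, O = 1.7, S = 2.0, P = 2.1, F = 1.5,
           CL = 1.8, BR = 2.0, I = 2.2, ZN = 0.74)
  r <- tab[toupper(element)]
  if (anyNA(r)) stop("no radius for element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

.atoms_from_list <- function(lst) {
  df <- do.call(rbind, lapply(lst, function(a) {
    data.frame(name = a$name, element = toupper(a$element),
               x = a$x, y = a$y, z = a$z, radius = a$radius,
               hydrophobic = isTRUE(a$hydrophobic), donor = isTRUE(a$donor),
               acceptor = isTRUE(a$acceptor), aromatic = isTRUE(a$aromatic),
               metal = isTRUE(a$metal), charged = isTRUE(a$charged),
               fcharge = as.numeric(a$fcharge), stringsAsFactors = FALSE)
  }))
  stopifnot(all(df$radius > 0), all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
  df
}

drug_table <- function() {
  if (!is.null(.nanopep_cache$drugs)) return(.nanopep_cache$drugs)
  path <- system.file("extdata", "drugs.json", package = "nanopep")
  raw <- jsonlite::read_json(path)
  specs <- lapply(names(raw$drugs), function(nm) {
    d <- raw$drugs[[nm]]
    axes <- do.call(cbind, lapply(d$reference_pose$axes, unlist))
    new_drug_spec(nm, as.integer(d$net_charge), .atoms_from_list(d$atoms),
                  list(origin = unlist(d$reference_pose$origin), axes = axes))
  })
  names(specs) <- names(raw$drugs)
  .nanopep_cache$drugs <- specs
  specs
}

new_drug_spec <- function(name, net_charge, atoms, reference_pose) {
  stopifnot(nrow(atoms) > 0)
  structure(list(name = name, net_charge = net_charge, atoms = atoms,
                 reference_pose = reference_pose), class = "drug_spec")
}

#' Built-in drug specification
#'
#' @param name One of `"EPI"`, `"DOX"`, `"MTX"`, `"MIT"`, `"5FU"`, `"CPT"`,
#'   `"CP"`, `"OrangeG"` (pose template), or `"toy"` (4-atom test molecule).
#' @return An object of class `drug_spec` with fields `name`, `net_charge`
#'   (elementary units), `atoms` (typed heavy-atom data.frame), and
#'   `reference_pose` (origin + orthonormal axes).
#' @examples
#' drug_spec("MTX")$net_charge  # -2
#' @export
drug_spec <- function(name) {
  tab <- drug_table()
  if (!name %in% names(tab))
    stop("unknown drug: ", name, " (have: ", paste(names(tab), collapse = ", "), ")")
  tab[[name]]
}

#' @export
print.drug_spec <- function(x, ...) {
  cat("<drug_spec> ", x$name, ": ", nrow(x$atoms), " heavy atoms, net charge ",
      x$net_charge, "e\n", sep = "")
  invisible(x)
}

#' Load a drug specification from a PDB file plus typing sidecar
#'
#' Reads HETATM coordinates with [bio3d::read.pdb()] and merges a JSON
#' sidecar giving the net charge and per-atom typing flags keyed by atom
#' name. Atoms missing from the sidecar default to untyped with
#' element-based radii.
#'
#' @param pdb_path Path to a PDB file whose HETATM records describe the drug.
#' @param sidecar_path Path to a JSON file with fields `name`, `net_charge`,
#'   and `atoms` (a map atom name -> typing flags/fcharge).
#' @return A `drug_spec`.
#' @export
read_drug_spec <- function(pdb_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path)
  pdb <- bio3d::read.pdb(pdb_path)
  het <- pdb$atom[pdb$atom$type == "HETATM", , drop = FALSE]
  if (nrow(het) == 0) stop("no HETATM records in ", pdb_path)
  elem <- toupper(ifelse(is.na(het$elesy) | het$elesy == "",
                         substr(trimws(het$elety), 1, 1), het$elesy))
  atoms <- data.frame(name = trimws(het$elety), element = elem,
                      x = het$x, y = het$y, z = het$z,
                      radius = element_radius(elem),
                      hydrophobic = FALSE, donor = FALSE, acceptor = FALSE,
                      aromatic = FALSE, metal = FALSE, charged = FALSE,
                      fcharge = 0, stringsAsFactors = FALSE)
  for (nm in names(side$atoms)) {
    i <- which(atoms$name == nm)
    if (length(i) == 0) stop("sidecar types unknown atom: ", nm)
    fl <- side$atoms[[nm]]
    for (f in c("hydrophobic", "donor", "acceptor", "aromatic", "metal"))
      if (!is.null(fl[[f]])) atoms[i, f] <- isTRUE(fl[[f]])
    if (!is.null(fl$fcharge)) {
      atoms$fcharge[i] <- as.numeric(fl$fcharge)
      atoms$charged[i] <- atoms$fcharge[i] != 0
    }
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  ev <- eigen(crossprod(sweep(xyz, 2, ctr)) / nrow(xyz), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  new_drug_spec(side$name, as.integer(side$net_charge), atoms,
                list(origin = ctr, axes = ev))
}
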