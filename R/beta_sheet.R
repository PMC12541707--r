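# Geometric beta-sheet assignment.
#
# A purpose-built geometric criterion standing in for extended/beta-bridge
# secondary-structure assignment, which is ill-defined for four-residue
# peptides in standard assigners: a peptide is strand-flagged when it
# shares at least `min_hbonds` inter-peptide backbone hydrogen bonds
# (N...O distance criterion; reduced peptides carry no amide hydrogens,
# so the donor-H angle test is skipped) with some neighbor whose strand
# axis is within `axis_tol` degrees of parallel or antiparallel.

#' Beta-sheet assignment criteria
#'
#' @param hbond_dist Maximum N...O distance, Angstrom (default 3.5).
#' @param angle_min Minimum N-H...O angle in degrees, applied only when
#'   amide hydrogens are present (default 140).
#' @param axis_tol Maximum deviation of strand axes from parallel or
#'   antiparallel, degrees (default 30).
#' @param min_hbonds Minimum inter-peptide backbone hydrogen bonds with
#'   a single neighbor (default 2).
#' @return List of criteria.
#' @export
beta_criteria <- function(hbond_dist = 3.5, angle_min = 140, axis_tol = 30,
                          min_hbonds = 2L) {
  list(hbond_dist = hbond_dist, angle_min = angle_min, axis_tol = axis_tol,
       min_hbonds = min_hbonds)
}

#' Assign beta-sheet-like configurations
#'
#' Flags each peptide in the snapshot as strand / not-strand under the
#' geometric criteria and reports the percent of peptides in
#' beta-sheet-like configurations. Rigid-body motion of the whole
#' snapshot leaves the assignment unchanged.
#'
#' @param snap A [snapshot()]; every peptide must carry backbone
#'   N, CA, C, O atoms.
#' @param criteria A [beta_criteria()] list.
#' @return An object of class `beta_assignment`: `per_peptide`
#'   data.frame (`mol_id`, `strand`) and `percent` (`NA` if the snapshot
#'   has no peptides).
#' @export
assign_beta_sheet <- function(snap, criteria = beta_criteria()) {
  pep_ids <- mol_ids_of_kind(snap, "peptide")
  if (length(pep_ids) == 0)
    return(structure(list(per_peptide = data.frame(mol_id = integer(),
                                                   strand = logical()),
                          percent = NA_real_), class = "beta_assignment"))
  bb <- lapply(pep_ids, function(id) {
    a <- mol_atoms(snap, id)
    N <- a[a$name == "N", , drop = FALSE]
    CA <- a[a$name == "CA", , drop = FALSE]
    O <- a[a$name == "O", , drop = FALSE]
    C <- a[a$name == "C", , drop = FALSE]
    if (nrow(N) < 4 || nrow(CA) < 4 || nrow(C) < 4 || nrow(O) < 4)
      stop("peptide molecule ", id, " is missing backbone N/CA/C/O atoms")
    H <- a[a$name == "H", , drop = FALSE]
    axis <- as.numeric(coords(CA)[which.max(CA$resid), ] -
                         coords(CA)[which.min(CA$resid), ])
    list(N = coords(N), O = coords(O), H = if (nrow(H)) coords(H) else NULL,
         axis = axis / sqrt(sum(axis^2)))
  })
  names(bb) <- pep_ids
  cos_tol <- cos(criteria$axis_tol * pi / 180)
  n_hb <- function(i, j) {
    # N(i)...O(j) plus N(j)...O(i) within the distance criterion
    cnt <- 0L
    for (pair in list(c(i, j), c(j, i))) {
      D2 <- outer(rowSums(bb[[pair[1]]]$N^2), rowSums(bb[[pair[2]]]$O^2), "+") -
        2 * tcrossprod(bb[[pair[1]]]$N, bb[[pair[2]]]$O)
      cnt <- cnt + sum(D2 <= criteria$hbond_dist^2)
    }
    cnt
  }
  k <- length(pep_ids)
  strand <- logical(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (abs(sum(bb[[i]]$axis * bb[[j]]$axis)) < cos_tol) next
      if (n_hb(i, j) >= criteria$min_hbonds) { strand[i] <- TRUE; break }
    }
  }
  structure(list(per_peptide = data.frame(mol_id = pep_ids, strand = strand),
                 percent = 100 * mean(strand)),
            class = "beta_assignment")
}

#' @export
print.beta_assignment <- function(x, ...) {
  cat("<beta_assignment> ", nrow(x$per_peptide), " peptides, ",
      if (is.na(x$percent)) "n/a" else paste0(format(x$percent, digits = 4), "%"),
      " in beta-sheet-like configurations\n", sep = "")
  invisible(x)
}

#' Beta-sheet percent along a trajectory
#'
#' @param trajectory List of [snapshot()]s in frame order.
#' @param criteria A [beta_criteria()] list.
#' @return Numeric vector: percent of peptides in beta-sheet-like
#'   configurations per frame.
#' @export
beta_sheet_series <- function(trajectory, criteria = beta_criteria()) {
  vapply(trajectory, function(s) assign_beta_sheet(s, criteria)$percent,
         numeric(1))
}
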