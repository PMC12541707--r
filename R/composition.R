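# Charge-neutral system compositions.
#
# Every modeled co-assembly is built charge-neutral: peptide charge comes
# from the C-terminus and side chains, drugs carry fixed formal charges,
# and Zn2+ (+2) / NO3- (-1) counts absorb the remainder. The designed
# systems use 4 peptides : 2 drugs with Zn counts of 1 (EPI, DOX, MIT,
# 5FU, CPT, CP) or 2 (MTX).

#' Solve for the neutralizing ion counts
#'
#' Finds the smallest `n_zn >= min_zn` and smallest `n_no3 >= 0` such that
#' `n_peptides * q_pep + n_drugs * q_drug + 2 * n_zn - n_no3 == 0`.
#' Because each added Zn2+ can always be offset by two NO3-, the minimal
#' feasible `n_zn` is `max(min_zn, ceiling(-q_rest / 2))` where `q_rest`
#' is the peptide-plus-drug charge, and `n_no3` follows by arithmetic.
#'
#' @param n_peptides,n_drugs Non-negative counts.
#' @param pep A [peptide()].
#' @param drug A [drug_spec()].
#' @param min_zn Minimum number of Zn2+ ions; defaults to 1 because every
#'   designed system retains Zn2+ for His coordination and fluorescence.
#' @return A list with integer fields `n_zn` and `n_no3`.
#' @examples
#' # designed 4:2:1 (EPI, carboxylate termini) and 4:2:2 (MTX, amidated)
#' solve_neutrality(4, peptide("FFWH", termini_spec("carboxylate")), 2, drug_spec("EPI"))
#' solve_neutrality(4, peptide("FFWH"), 2, drug_spec("MTX"))
#' @export
solve_neutrality <- function(n_peptides, pep, n_drugs, drug, min_zn = 1L) {
  stopifnot(n_peptides >= 0, n_drugs >= 0, min_zn >= 0)
  q_rest <- n_peptides * peptide_net_charge(pep) + n_drugs * drug$net_charge
  n_zn <- max(as.integer(min_zn), as.integer(ceiling(-q_rest / 2)))
  n_no3 <- q_rest + 2L * n_zn
  if (n_zn < 0 || n_no3 < 0)
    stop("infeasible composition: no nonnegative ion counts neutralize charge ", q_rest)
  list(n_zn = as.integer(n_zn), n_no3 = as.integer(n_no3))
}

#' Charge-neutral system composition
#'
#' Bundles component counts with the peptide and drug identities; ion
#' counts are taken from [solve_neutrality()] unless given explicitly.
#'
#' @param n_peptides,n_drugs Counts.
#' @param pep A [peptide()].
#' @param drug A [drug_spec()], or `NULL` for drug-free systems.
#' @param min_zn Passed to [solve_neutrality()].
#' @param n_zn,n_no3 Optional explicit ion counts (checked for neutrality).
#' @return An object of class `system_composition`.
#' @export
system_composition <- function(n_peptides, pep, n_drugs = 0L, drug = NULL,
                               min_zn = 1L, n_zn = NULL, n_no3 = NULL) {
  if (n_drugs > 0 && is.null(drug)) stop("drug spec required when n_drugs > 0")
  q_drug <- if (is.null(drug)) 0L else drug$net_charge
  if (is.null(n_zn) || is.null(n_no3)) {
    dd <- if (is.null(drug)) drug_spec("toy") else drug
    sol <- solve_neutrality(n_peptides, pep, if (is.null(drug)) 0L else n_drugs,
                            dd, min_zn = min_zn)
    n_zn <- sol$n_zn; n_no3 <- sol$n_no3
  }
  total <- n_peptides * peptide_net_charge(pep) + n_drugs * q_drug + 2L * n_zn - n_no3
  if (total != 0L) stop("composition is not charge neutral (total ", total, "e)")
  structure(list(n_peptides = as.integer(n_peptides), n_drugs = as.integer(n_drugs),
                 n_zn = as.integer(n_zn), n_no3 = as.integer(n_no3),
                 peptide = pep, drug = drug),
            class = "system_composition")
}

#' @export
print.system_composition <- function(x, ...) {
  dn <- if (is.null(x$drug)) "none" else x$drug$name
  cat("<system_composition> ", x$n_peptides, " x ", format(x$peptide),
      " : ", x$n_drugs, " x ", dn, " : ", x$n_zn, " Zn2+ : ", x$n_no3,
      " NO3-\n", sep = "")
  invisible(x)
}
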