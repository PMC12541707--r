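# Residue tables and peptide sequence objects.
#
# The designable unit throughout the package is a four-residue peptide with
# histidine fixed at position 4 (Zn2+ coordination), an acetylated N-terminus
# and either an amidated (neutral) or carboxylate (-1) C-terminus.

.nanopep_cache <- new.env(parent = emptyenv())

#' Built-in amino-acid table
#'
#' Returns the packaged residue table: one row per canonical amino acid with
#' its net side-chain charge at pH 7 (D/E -1, K/R +1, H 0) and the named
#' per-residue scales used by [aggregation_propensity()] (Kyte-Doolittle
#' hydrophobicity, Chou-Fasman beta-sheet propensity, and a 0/1 aromaticity
#' indicator). Side-chain columns describe the reduced one-pseudo-atom
#' representation used by the scaffold builders.
#'
#' @return A data.frame with one row per residue, rownames = one-letter codes.
#' @export
amino_acid_table <- function() {
  if (!is.null(.nanopep_cache$aa)) return(.nanopep_cache$aa)
  path <- system.file("extdata", "amino_acids.json", package = "nanopep")
  raw <- jsonlite::read_json(path)
  rows <- lapply(raw$residues, function(r) {
    data.frame(
      code = r$code,
      net_side_chain_charge = as.integer(r$net_side_chain_charge),
      hydrophobicity = r$scales$hydrophobicity,
      beta_propensity = r$scales$beta_propensity,
      aromaticity = r$scales$aromaticity,
      sc_element = r$side_chain$element,
      sc_name = r$side_chain$name,
      sc_hydrophobic = isTRUE(r$side_chain$hydrophobic),
      sc_donor = isTRUE(r$side_chain$donor),
      sc_acceptor = isTRUE(r$side_chain$acceptor),
      sc_aromatic = isTRUE(r$side_chain$aromatic),
      sc_fcharge = as.numeric(r$side_chain$fcharge),
      stringsAsFactors = FALSE
    )
  })
  aa <- do.call(rbind, rows)
  stopifnot(nrow(aa) == 20L, !anyDuplicated(aa$code),
            all(is.finite(aa$hydrophobicity)), all(is.finite(aa$beta_propensity)))
  rownames(aa) <- aa$code
  .nanopep_cache$aa <- aa
  aa
}

#' Named residue scale
#'
#' @param name One of `"hydrophobicity"`, `"beta_propensity"`, `"aromaticity"`.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
residue_scale <- function(name) {
  aa <- amino_acid_table()
  if (!name %in% c("hydrophobicity", "beta_propensity", "aromaticity"))
    stop("unknown residue scale: ", name)
  stats::setNames(aa[[name]], aa$code)
}

#' Peptide termini specification
#'
#' The N-terminus is always acetylated (neutral); the C-terminus is either a
#' carboxylate (charge -1) or amidated (neutral).
#'
#' @param c_terminus `"carboxylate"` or `"amidated"`.
#' @return An object of class `termini_spec`.
#' @export
termini_spec <- function(c_terminus = c("amidated", "carboxylate")) {
  c_terminus <- match.arg(c_terminus)
  structure(list(n_terminus = "acetylated", c_terminus = c_terminus),
            class = "termini_spec")
}

termini_charge <- function(termini) {
  stopifnot(inherits(termini, "termini_spec"))
  if (termini$c_terminus == "carboxylate") -1L else 0L
}

#' Four-residue peptide sequence
#'
#' Constructs a designable peptide: exactly four canonical residues with
#' histidine fixed at position 4 (1-based), plus a termini specification.
#'
#' @param seq A 4-character string (e.g. `"FFWH"`) or character vector of 4
#'   one-letter codes; position 4 must be `"H"`.
#' @param termini A [termini_spec()]; default amidated.
#' @return An object of class `peptide`.
#' @examples
#' peptide("FFWH", termini_spec("carboxylate"))
#' @export
peptide <- function(seq, termini = termini_spec()) {
  if (is.character(seq) && length(seq) == 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(as.character(seq))
  aa <- amino_acid_table()
  if (length(seq) != 4L)
    stop("a designable peptide has exactly 4 residues, got ", length(seq))
  if (!all(seq %in% aa$code))
    stop("non-canonical residue code(s): ", paste(setdiff(seq, aa$code), collapse = ", "))
  if (seq[4L] != "H")
    stop("position 4 must be histidine (Zn2+ coordination site), got ", seq[4L])
  stopifnot(inherits(termini, "termini_spec"))
  structure(list(residues = seq, termini = termini), class = "peptide")
}

#' @export
format.peptide <- function(x, ...) {
  ct <- if (x$termini$c_terminus == "carboxylate") "COO-" else "CONH2"
  paste0("Ac-", paste(x$residues, collapse = ""), "-", ct)
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", format(x), "  net charge ", peptide_net_charge(x), "e\n", sep = "")
  invisible(x)
}

#' @export
as.character.peptide <- function(x, ...) paste(x$residues, collapse = "")

#' Net charge of a peptide
#'
#' Sum of side-chain charges at pH 7 (His neutral) plus the C-terminus
#' contribution (-1 for carboxylate, 0 for amidated; the acetylated
#' N-terminus is neutral).
#'
#' @param pep A [peptide()].
#' @return Integer charge in elementary units.
#' @examples
#' peptide_net_charge(peptide("FFWH"))                         # 0
#' peptide_net_charge(peptide("FFWH", termini_spec("carboxylate"))) # -1
#' @export
peptide_net_charge <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  aa <- amino_acid_table()
  sum(aa[pep$residues, "net_side_chain_charge"]) + termini_charge(pep$termini)
}
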