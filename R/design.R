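# Evolution-guided "lock and design" sequence optimization.
#
# Each iteration proposes a single mutation at positions 1-3 (position 4
# stays histidine), drawn from substitution probabilities derived from a
# standard substitution matrix, and evaluates the mean drug association
# free energy of the threaded design. The proposal is accepted - the
# design re-locked - only on strict improvement; the locked design seeds
# the next iteration. Runs per drug are combined by consensus: sequences
# reached in every drug's runs, ranked by the mean energy gap to each
# drug's best design (the consensus energy penalty).

#' Substitution-based mutation model
#'
#' Conditional substitution probabilities P(b | a) derived from a
#' log-odds substitution matrix via a temperature softmax:
#' `P(b | a) proportional to exp(s(a, b) / temperature)`. The packaged
#' default matrix is BLOSUM62; any 20 x 20 score matrix with one-letter
#' row/column names can be supplied instead.
#'
#' @param scores Optional substitution score matrix; default the packaged
#'   BLOSUM62 table.
#' @param temperature Positive scalar; larger values flatten the
#'   distribution (default 1).
#' @return An object of class `evolution_model` with the row-stochastic
#'   `prob` matrix.
#' @export
evolution_model <- function(scores = NULL, temperature = 1) {
  stopifnot(temperature > 0)
  if (is.null(scores)) {
    path <- system.file("extdata", "blosum62.csv", package = "nanopep")
    scores <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  }
  stopifnot(nrow(scores) == 20, ncol(scores) == 20,
            identical(rownames(scores), colnames(scores)))
  w <- exp(scores / temperature)
  prob <- w / rowSums(w)
  stopifnot(all(abs(rowSums(prob) - 1) < 1e-9), all(prob >= 0))
  structure(list(prob = prob, temperature = temperature),
            class = "evolution_model")
}

#' @export
print.evolution_model <- function(x, ...) {
  cat("<evolution_model> 20x20 substitution probabilities, temperature ",
      x$temperature, "\n", sep = "")
  invisible(x)
}

#' Propose a single mutation
#'
#' Draws a position uniformly from {1, 2, 3} (position 4 is never
#' mutated) and a replacement residue from the model row of the current
#' residue, with self-substitution excluded and the row renormalized.
#' Uses the R RNG; seed at the call site for reproducibility.
#'
#' @param pep A [peptide()].
#' @param model An [evolution_model()].
#' @param position Optional fixed position in {1, 2, 3}; requesting
#'   position 4 is an error.
#' @return List with `position` and `residue`.
#' @export
propose_mutation <- function(pep, model, position = NULL) {
  if (is.null(position)) {
    position <- sample.int(3L, 1L)
  } else if (!position %in% 1:3) {
    stop("only positions 1-3 are mutable (histidine is fixed at position 4)")
  }
  cur <- pep$residues[position]
  row <- model$prob[cur, ]
  row[cur] <- 0
  row <- row / sum(row)
  residue <- sample(names(row), 1L, prob = row)
  list(position = as.integer(position), residue = residue)
}

apply_mutation <- function(pep, mut) {
  res <- pep$residues
  res[mut$position] <- mut$residue
  peptide(res, pep$termini)
}

#' Deterministic drug pose set
#'
#' Rotations applied to each drug about its own frame when evaluating a
#' design: the identity plus `n - 1` rotations alternating between the
#' z and x axes at evenly spaced angles.
#'
#' @param n Number of poses (default 4).
#' @return List of 3x3 rotation matrices.
#' @export
drug_pose_set <- function(n = 4L) {
  stopifnot(n >= 1)
  poses <- list(diag(3))
  if (n > 1) {
    ang <- 2 * pi * seq_len(n - 1) / n
    for (i in seq_len(n - 1)) {
      axis <- if (i %% 2 == 1) c(0, 0, 1) else c(1, 0, 0)
      poses[[i + 1]] <- rotation_matrix(axis, ang[i])
    }
  }
  poses
}

# re-type the side-chain pseudo-atoms of every peptide in a snapshot to a
# new sequence (positions 1-3; geometry kept)
thread_peptides <- function(snap, pep) {
  aa <- amino_acid_table()
  label <- format(pep)
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (id in mol_ids_of_kind(snap, "peptide")) {
    sel <- snap$atoms$mol_id == id & !snap$atoms$name %in% backbone &
      !is.na(snap$atoms$resid) & snap$atoms$resid %in% 1:3
    idx <- which(sel)
    res <- snap$atoms$resid[idx]
    rec <- aa[pep$residues[res], ]
    snap$atoms$name[idx] <- rec$sc_name
    snap$atoms$element[idx] <- rec$sc_element
    snap$atoms$rescode[idx] <- rec$code
    snap$atoms$radius[idx] <- element_radius(rec$sc_element)
    snap$atoms$hydrophobic[idx] <- rec$sc_hydrophobic
    snap$atoms$donor[idx] <- rec$sc_donor
    snap$atoms$acceptor[idx] <- rec$sc_acceptor
    snap$atoms$aromatic[idx] <- rec$sc_aromatic
    snap$atoms$charged[idx] <- rec$sc_fcharge != 0
    snap$atoms$fcharge[idx] <- rec$sc_fcharge
    # rescode of position 1-3 backbone atoms
    bb <- which(snap$atoms$mol_id == id & snap$atoms$name %in% backbone &
                  !is.na(snap$atoms$resid) & snap$atoms$resid %in% 1:3)
    snap$atoms$rescode[bb] <- pep$residues[snap$atoms$resid[bb]]
    snap$molecules$label[snap$molecules$mol_id == id] <- label
  }
  snap
}

# rotate every drug molecule about its centroid
apply_drug_pose <- function(snap, pose) {
  for (id in mol_ids_of_kind(snap, "drug")) {
    sel <- snap$atoms$mol_id == id
    xyz <- coords(snap$atoms[sel, , drop = FALSE])
    ctr <- colMeans(xyz)
    snap$atoms[sel, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(pose),
                                               2, ctr, "+")
  }
  snap
}

#' Evaluate a candidate design
#'
#' Threads the sequence onto every scaffold (side-chain identity swap at
#' positions 1-3), evaluates the mean drug association free energy for
#' every (scaffold, pose) combination, and returns the minimum - the
#' best binding mode found for this sequence.
#'
#' @param pep A [peptide()].
#' @param drug A [drug_spec()] (must match the drug molecules in the
#'   scaffolds).
#' @param scaffolds Nonempty list of scaffold [snapshot()]s (IPS and/or
#'   SES-like variants) containing drug molecules.
#' @param params A [scoring_params()].
#' @param poses Nonempty list of drug pose rotations (see
#'   [drug_pose_set()]).
#' @return Minimum mean drug association energy in kcal/mol.
#' @export
evaluate_design <- function(pep, drug, scaffolds, params = scoring_params(),
                            poses = list(diag(3))) {
  if (length(scaffolds) == 0) stop("scaffold set is empty")
  if (length(poses) == 0) stop("pose set is empty")
  best <- Inf
  for (sc in scaffolds) {
    if (!any(sc$molecules$kind == "drug"))
      stop("scaffold has no drug molecules")
    threaded <- thread_peptides(sc, pep)
    for (pose in poses) {
      posed <- apply_drug_pose(threaded, pose)
      e <- mean_drug_association_energy(posed, params)
      if (e < best) best <- e
    }
  }
  best
}

#' Run the iterative lock-and-design loop
#'
#' Starting from a locked sequence, each iteration proposes one mutation
#' of the locked design, evaluates it, and re-locks only on strict
#' improvement of the objective. The loop stops at the iteration budget
#' or after `stall` consecutive rejections. All evaluated sequences are
#' recorded with their best energy.
#'
#' @param drug A [drug_spec()] (identifies the run; passed to the
#'   evaluator).
#' @param start Starting [peptide()] (the scaffold sequence, e.g. LVFH).
#' @param model An [evolution_model()].
#' @param scaffolds List of scaffold snapshots (ignored when `evaluate`
#'   is supplied).
#' @param params A [scoring_params()].
#' @param budget Maximum number of iterations (>= 1).
#' @param stall Stop after this many consecutive rejections (default 200).
#' @param seed Integer seed; identical (inputs, seed) give bitwise
#'   identical histories.
#' @param poses Drug pose set for [evaluate_design()].
#' @param evaluate Optional custom objective `function(pep) -> energy`;
#'   defaults to [evaluate_design()] on the given scaffolds.
#' @return An object of class `design_run`.
#' @export
lock_and_design <- function(drug, start, model = evolution_model(),
                            scaffolds = NULL, params = scoring_params(),
                            budget = 500L, stall = 200L, seed = 1L,
                            poses = list(diag(3)), evaluate = NULL) {
  stopifnot(budget >= 1)
  if (is.null(evaluate)) {
    if (is.null(scaffolds)) stop("either scaffolds or an evaluate function is required")
    force(scaffolds)
    evaluate <- function(pep) evaluate_design(pep, drug, scaffolds, params, poses)
  }
  set.seed(as.integer(seed))
  locked <- start
  locked_e <- evaluate(start)
  n <- budget + 1L
  hist_seq <- character(n); hist_e <- numeric(n); hist_acc <- logical(n)
  hist_seq[1] <- as.character(start); hist_e[1] <- locked_e; hist_acc[1] <- TRUE
  visited <- new.env(parent = emptyenv())
  assign(as.character(start), locked_e, envir = visited)
  rejections <- 0L
  used <- 1L
  for (it in seq_len(budget)) {
    mut <- propose_mutation(locked, model)
    cand <- apply_mutation(locked, mut)
    key <- as.character(cand)
    e <- evaluate(cand)
    # keep the best energy seen per sequence (poses may differ on revisit)
    if (!exists(key, envir = visited) || e < get(key, envir = visited))
      assign(key, e, envir = visited)
    accepted <- e < locked_e
    used <- used + 1L
    hist_seq[used] <- key; hist_e[used] <- e; hist_acc[used] <- accepted
    if (accepted) {
      locked <- cand; locked_e <- e; rejections <- 0L
    } else {
      rejections <- rejections + 1L
      if (rejections >= stall) break
    }
  }
  history <- data.frame(iteration = 0:(used - 1L),
                        sequence = hist_seq[seq_len(used)],
                        energy = hist_e[seq_len(used)],
                        accepted = hist_acc[seq_len(used)],
                        stringsAsFactors = FALSE)
  vseq <- ls(visited)
  structure(list(drug = drug$name, start = start, seed = as.integer(seed),
                 budget = as.integer(budget), stall = as.integer(stall),
                 locked = locked, locked_energy = locked_e,
                 history = history,
                 visited = data.frame(sequence = vseq,
                                      energy = vapply(vseq, get, numeric(1),
                                                      envir = visited),
                                      stringsAsFactors = FALSE,
                                      row.names = NULL)),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat("<design_run> drug ", x$drug, ", seed ", x$seed, ": ",
      nrow(x$history) - 1L, " iterations, ", sum(x$history$accepted) - 1L,
      " improvements\n  locked: ", format(x$locked), " at ",
      format(x$locked_energy, digits = 6), " kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
summary.design_run <- function(object, ...) {
  acc <- object$history[object$history$accepted, ]
  cat("Lock-and-design run for drug ", object$drug, "\n", sep = "")
  cat("  start:  ", format(object$start), " (",
      format(object$history$energy[1], digits = 6), " kcal/mol)\n", sep = "")
  cat("  locked: ", format(object$locked), " (",
      format(object$locked_energy, digits = 6), " kcal/mol)\n", sep = "")
  cat("  ", nrow(object$history) - 1L, " proposals, ", nrow(acc) - 1L,
      " accepted, ", nrow(object$visited), " distinct sequences\n", sep = "")
  invisible(object)
}

#' @export
coef.design_run <- function(object, ...) {
  stats::setNames(object$locked$residues, paste0("pos", 1:4))
}

#' @export
plot.design_run <- function(x, ...) {
  h <- x$history
  locked_trace <- cummin(ifelse(h$accepted, h$energy, Inf))
  graphics::plot(h$iteration, h$energy, pch = 20, col = "grey60",
                 xlab = "iteration", ylab = "mean drug association energy (kcal/mol)",
                 main = paste("lock & design:", x$drug), ...)
  graphics::lines(h$iteration, locked_trace, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("proposal", "locked"), pch = c(20, NA),
                   lty = c(NA, 1), col = c("grey60", "firebrick"), bty = "n")
  invisible(x)
}

#' Consensus sequences across drugs
#'
#' Sequences (residue identity at positions 1-4; termini ignored) that
#' appear in every drug's run collection, either among accepted (locked)
#' designs or among all visited sequences.
#'
#' @param runs Named list: one entry per drug, each a list of
#'   [lock_and_design()] results (a bare `design_run` is promoted).
#' @param criterion `"accepted"` (default) or `"visited"`.
#' @return Character vector of consensus sequences (sorted).
#' @export
find_consensus <- function(runs, criterion = c("accepted", "visited")) {
  criterion <- match.arg(criterion)
  if (length(runs) < 2) stop("consensus needs runs for at least 2 drugs")
  sets <- lapply(runs, function(rl) {
    if (inherits(rl, "design_run")) rl <- list(rl)
    if (length(rl) == 0) stop("empty run collection")
    unique(unlist(lapply(rl, function(r) {
      if (criterion == "accepted") unique(r$history$sequence[r$history$accepted])
      else r$visited$sequence
    })))
  })
  sort(Reduce(intersect, sets))
}

#' Peptide-by-drug best-energy table
#'
#' Builds the energy matrix `E(peptide, drug)` from run collections: the
#' best (lowest) energy recorded for each sequence in each drug's runs,
#' restricted to the given peptides (default: the consensus set over all
#' visited sequences).
#'
#' @param runs As in [find_consensus()].
#' @param peptides Character vector of sequences (rows); default
#'   `find_consensus(runs, "visited")`.
#' @return An object of class `consensus_table` wrapping the energy
#'   matrix (rows = peptides, columns = drugs).
#' @export
consensus_table <- function(runs, peptides = NULL) {
  if (is.null(peptides)) peptides <- find_consensus(runs, "visited")
  if (length(peptides) == 0) stop("no consensus peptides")
  E <- matrix(NA_real_, length(peptides), length(runs),
              dimnames = list(peptides, names(runs)))
  for (d in seq_along(runs)) {
    rl <- runs[[d]]
    if (inherits(rl, "design_run")) rl <- list(rl)
    for (r in rl) {
      v <- r$visited
      hit <- v$sequence %in% peptides
      for (i in which(hit)) {
        p <- v$sequence[i]
        if (is.na(E[p, d]) || v$energy[i] < E[p, d]) E[p, d] <- v$energy[i]
      }
    }
  }
  structure(list(energy = E), class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("<consensus_table> ", nrow(x$energy), " peptides x ", ncol(x$energy),
      " drugs (kcal/mol)\n", sep = "")
  print(utils::head(x$energy, 10))
  if (nrow(x$energy) > 10) cat("...\n")
  invisible(x)
}

#' Consensus energy penalty
#'
#' For each peptide, the mean over drugs of its energy gap to the best
#' peptide for that drug:
#' `penalty(p) = (1/D) * sum_d [E(p, d) - min_q E(q, d)]`.
#' The penalty is >= 0, equals 0 only for a peptide that is best for
#' every drug, and is invariant to per-drug additive shifts of the
#' energy matrix.
#'
#' @param table A [consensus_table()] (or bare matrix) with no missing
#'   cells.
#' @return Named numeric vector sorted ascending by penalty, ties broken
#'   lexicographically by sequence.
#' @export
consensus_energy_penalty <- function(table) {
  E <- if (inherits(table, "consensus_table")) table$energy else as.matrix(table)
  if (anyNA(E)) stop("energy table has missing cells for: ",
                     paste(rownames(E)[apply(is.na(E), 1, any)], collapse = ", "))
  gaps <- sweep(E, 2, apply(E, 2, min))
  penalty <- rowMeans(gaps)
  penalty[order(penalty, names(penalty))]
}

#' Aggregation propensity of a sequence
#'
#' Sum of a named per-residue scale over all four positions; higher
#' means more aggregation-prone under the chosen scale. The default
#' scale is the packaged beta-sheet propensity.
#'
#' @param pep A [peptide()] or 4-character sequence string.
#' @param scale Scale name (see [residue_scale()]) or a named numeric
#'   vector over the 20 residues.
#' @return Numeric score (arbitrary units).
#' @export
aggregation_propensity <- function(pep, scale = "beta_propensity") {
  res <- if (inherits(pep, "peptide")) pep$residues else strsplit(toupper(pep), "")[[1]]
  sc <- if (is.character(scale) && length(scale) == 1) residue_scale(scale) else scale
  if (!all(res %in% names(sc))) stop("scale undefined for residue(s): ",
                                     paste(setdiff(res, names(sc)), collapse = ", "))
  sum(sc[res])
}

#' Select top designs by energy penalty and aggregation propensity
#'
#' Returns the `k_energy` lowest-penalty peptides, then the
#' `k_propensity` most aggregation-prone among the remainder, each row
#' tagged with its selection criterion. Ties break lexicographically.
#'
#' @param penalties Named penalty vector (see
#'   [consensus_energy_penalty()]).
#' @param propensities Named propensity vector over the same peptides.
#' @param k_energy,k_propensity Selection counts.
#' @return data.frame with columns `sequence`, `criterion`, `penalty`,
#'   `propensity`.
#' @export
select_top_designs <- function(penalties, propensities, k_energy,
                               k_propensity = 0L) {
  pool <- names(penalties)
  if (!setequal(pool, names(propensities)))
    stop("penalties and propensities must cover the same peptide set")
  if (k_energy + k_propensity > length(pool))
    stop("k_energy + k_propensity exceeds the pool size (", length(pool), ")")
  propensities <- propensities[pool]
  by_energy <- pool[order(penalties, pool)][seq_len(k_energy)]
  rest <- setdiff(pool, by_energy)
  by_prop <- rest[order(-propensities[rest], rest)][seq_len(k_propensity)]
  sel <- c(by_energy, by_prop)
  data.frame(sequence = sel,
             criterion = rep(c("energy", "propensity"),
                             c(length(by_energy), length(by_prop))),
             penalty = as.numeric(penalties[sel]),
             propensity = as.numeric(propensities[sel]),
             stringsAsFactors = FALSE)
}
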