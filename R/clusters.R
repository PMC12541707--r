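# Multicomponent cluster detection and co-assembly statistics.
#
# Two molecules are connected when their minimum heavy-atom distance is
# at or below the contact cutoff; clusters are the connected components
# of that graph. Detection uses a spatial cell grid (cell edge = cutoff)
# so only atom pairs in adjacent cells are examined - exactly equivalent
# to the naive all-pairs definition.

#' Detect multicomponent clusters
#'
#' @param snap A [snapshot()].
#' @param cutoff Contact cutoff on the minimum inter-molecular atom
#'   distance, Angstrom (default 4.5).
#' @return An object of class `cluster_set`: `clusters` is a list of
#'   components of size >= 2 (each with `members`, `size`, `composition`
#'   counts per kind, `rg`), `singletons` the remaining molecule ids,
#'   `totals` the per-kind molecule counts of the snapshot.
#' @export
detect_clusters <- function(snap, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  m <- snap$molecules
  n <- nrow(m)
  parent <- seq_len(n)                      # union-find over molecule index
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  a <- snap$atoms
  if (nrow(a) > 1 && n > 1) {
    mol_index <- match(a$mol_id, m$mol_id)
    cell <- floor(coords(a) / cutoff)
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    cell_map <- split(seq_len(nrow(a)), key)
    cells <- unique(cell)
    cell_key_of_atom <- key
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    cut2 <- cutoff^2
    for (ci in seq_len(nrow(cells))) {
      base <- cells[ci, ]
      here <- cell_map[[paste(base[1], base[2], base[3])]]
      neigh <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nb <- cell_map[[paste(base[1] + offs[k, 1], base[2] + offs[k, 2],
                              base[3] + offs[k, 3])]]
        if (!is.null(nb)) neigh <- c(neigh, nb)
      }
      if (length(neigh) == 0) next
      xa <- coords(a)[here, , drop = FALSE]
      xb <- coords(a)[neigh, , drop = FALSE]
      D2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
      hit <- which(D2 <= cut2, arr.ind = TRUE)
      if (nrow(hit)) {
        mi <- mol_index[here[hit[, 1]]]
        mj <- mol_index[neigh[hit[, 2]]]
        keep <- mi != mj
        for (p in which(keep)) union_(mi[p], mj[p])
      }
    }
  }
  comp_id <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp_id)
  clusters <- list()
  singletons <- integer(0)
  singleton_kinds <- character(0)
  for (g in groups) {
    ids <- sort(m$mol_id[g])
    if (length(ids) == 1L) {
      singletons <- c(singletons, ids)
      singleton_kinds <- c(singleton_kinds, m$kind[g])
      next
    }
    kinds <- m$kind[g]
    comp <- vapply(c("peptide", "drug", "zn", "no3"),
                   function(k) sum(kinds == k), integer(1))
    clusters[[length(clusters) + 1]] <- list(
      members = ids, size = length(ids), composition = comp,
      rg = radius_of_gyration(a[a$mol_id %in% ids, , drop = FALSE]))
  }
  ord <- order(-vapply(clusters, `[[`, integer(1), "size"),
               vapply(clusters, function(cl) cl$members[1], integer(1)))
  totals <- vapply(c("peptide", "drug", "zn", "no3"),
                   function(k) sum(m$kind == k), integer(1))
  sord <- order(singletons)
  structure(list(clusters = clusters[ord], singletons = singletons[sord],
                 singleton_kinds = singleton_kinds[sord],
                 totals = totals, cutoff = cutoff), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, `[[`, integer(1), "size")
  cat("<cluster_set> ", length(x$clusters), " clusters (sizes: ",
      paste(sizes, collapse = ", "), "), ", length(x$singletons),
      " singletons; cutoff ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Per-frame cluster size statistics for a trajectory
#'
#' @param trajectory List of [snapshot()]s in frame order.
#' @param cutoff Contact cutoff, Angstrom.
#' @return List with `histograms` (one data.frame of size/count per
#'   frame, singletons counted as size 1) and `largest` (largest cluster
#'   size per frame).
#' @export
cluster_size_series <- function(trajectory, cutoff = 4.5) {
  stopifnot(length(trajectory) >= 1)
  histograms <- vector("list", length(trajectory))
  largest <- integer(length(trajectory))
  for (f in seq_along(trajectory)) {
    cs <- detect_clusters(trajectory[[f]], cutoff)
    sizes <- c(vapply(cs$clusters, `[[`, integer(1), "size"),
               rep(1L, length(cs$singletons)))
    tab <- table(sizes)
    histograms[[f]] <- data.frame(size = as.integer(names(tab)),
                                  count = as.integer(tab))
    largest[f] <- if (length(sizes)) max(sizes) else 0L
  }
  list(histograms = histograms, largest = largest)
}

#' Encapsulation profile versus cluster size
#'
#' For every cluster size present (singletons = size 1), the percent of
#' all molecules of each kind residing in clusters of exactly that size
#' (`per_bin`) and in clusters of at least that size (`cumulative`).
#' The cumulative percent at threshold 1 is 100 by definition.
#'
#' @param cs A [detect_clusters()] result.
#' @param totals Optional named per-kind totals; defaults to the
#'   snapshot totals recorded in `cs` (an error if smaller than the
#'   in-cluster sums).
#' @return An object of class `encapsulation_profile` with `per_bin` and
#'   `cumulative` data.frames (size x kind, percent).
#' @export
encapsulation_profile <- function(cs, totals = NULL) {
  kinds <- c("peptide", "drug", "zn", "no3")
  if (is.null(totals)) totals <- cs$totals
  totals <- totals[kinds]
  sizes <- c(vapply(cs$clusters, `[[`, integer(1), "size"),
             rep(1L, length(cs$singletons)))
  # counts per (size, kind), singletons included as size-1 clusters
  uniq <- sort(unique(sizes))
  per <- matrix(0, length(uniq), length(kinds), dimnames = list(uniq, kinds))
  for (cl in cs$clusters) per[as.character(cl$size), ] <-
    per[as.character(cl$size), ] + cl$composition[kinds]
  for (k in cs$singleton_kinds) per["1", k] <- per["1", k] + 1
  got <- colSums(per)
  if (any(got > totals + 1e-9))
    stop("totals inconsistent with cluster membership for: ",
         paste(kinds[got > totals], collapse = ", "))
  pct_mat <- function(mat) {
    for (k in kinds) mat[, k] <- if (totals[[k]] > 0) 100 * mat[, k] / totals[[k]] else NA_real_
    mat
  }
  per_bin <- data.frame(size = uniq, pct_mat(per), row.names = NULL)
  cum <- apply(per[rev(seq_len(nrow(per))), , drop = FALSE], 2, cumsum)
  cum <- matrix(cum, ncol = length(kinds), dimnames = list(rev(uniq), kinds))
  cum <- cum[rev(seq_len(nrow(cum))), , drop = FALSE]
  cumulative <- data.frame(size = uniq, pct_mat(cum), row.names = NULL)
  structure(list(per_bin = per_bin, cumulative = cumulative),
            class = "encapsulation_profile")
}

#' Normalized peptide:drug:Zn composition ratio of a cluster
#'
#' Counts scaled so the peptide count maps to 4 (the designed base);
#' with zero peptides the raw counts are returned unnormalized.
#'
#' @param cluster One element of `detect_clusters(...)$clusters`, or a
#'   named count vector.
#' @return Named numeric vector `c(peptide, drug, zn)`.
#' @export
composition_ratio <- function(cluster) {
  cnt <- if (is.list(cluster) && !is.null(cluster$composition))
    cluster$composition else unlist(cluster)
  cnt <- cnt[c("peptide", "drug", "zn")]
  if (sum(cnt) == 0) stop("empty cluster")
  if (cnt[["peptide"]] == 0) return(cnt)
  cnt / cnt[["peptide"]] * 4
}

#' Drug mediation probabilities
#'
#' A drug mediates a peptide pair when it has at least one heavy-atom
#' contact (<= cutoff) with each of two distinct peptides; the
#' three-body variant additionally requires a Zn2+ contact. Reports the
#' fraction of all drugs that mediate, overall and by the size of the
#' cluster the drug belongs to (size 1 = unclustered).
#'
#' @param cs A [detect_clusters()] result for `snap` (used for cluster
#'   sizes).
#' @param snap The [snapshot()].
#' @param cutoff Contact cutoff, Angstrom (defaults to the detection
#'   cutoff).
#' @return An object of class `mediation_stats` with `p_two_peptides`,
#'   `p_two_peptides_zn`, and a `by_size` data.frame.
#' @export
mediation_stats <- function(cs, snap, cutoff = cs$cutoff) {
  stopifnot(cutoff > 0)
  drug_ids <- mol_ids_of_kind(snap, "drug")
  size_of <- rep(1L, nrow(snap$molecules))
  names(size_of) <- snap$molecules$mol_id
  for (cl in cs$clusters) size_of[as.character(cl$members)] <- cl$size
  med2 <- med3 <- logical(length(drug_ids))
  pep_ids <- mol_ids_of_kind(snap, "peptide")
  zn_ids <- mol_ids_of_kind(snap, "zn")
  for (i in seq_along(drug_ids)) {
    A <- mol_atoms(snap, drug_ids[i])
    pep_contacts <- sum(vapply(pep_ids, function(p)
      min_pair_distance(A, mol_atoms(snap, p)) <= cutoff, logical(1)))
    zn_contact <- any(vapply(zn_ids, function(z)
      min_pair_distance(A, mol_atoms(snap, z)) <= cutoff, logical(1)))
    med2[i] <- pep_contacts >= 2
    med3[i] <- med2[i] && zn_contact
  }
  if (length(drug_ids)) {
    sz <- size_of[as.character(drug_ids)]
    by_size <- do.call(rbind, lapply(sort(unique(sz)), function(s) {
      sel <- sz == s
      data.frame(size = s, n_drugs = sum(sel),
                 p_two_peptides = mean(med2[sel]),
                 p_two_peptides_zn = mean(med3[sel]))
    }))
  } else by_size <- data.frame(size = integer(), n_drugs = integer(),
                               p_two_peptides = numeric(),
                               p_two_peptides_zn = numeric())
  structure(list(p_two_peptides = if (length(drug_ids)) mean(med2) else NA_real_,
                 p_two_peptides_zn = if (length(drug_ids)) mean(med3) else NA_real_,
                 by_size = by_size, cutoff = cutoff),
            class = "mediation_stats")
}

#' @export
print.mediation_stats <- function(x, ...) {
  cat("<mediation_stats> P(drug bridges 2 peptides) = ",
      format(x$p_two_peptides, digits = 4),
      "; P(2 peptides + Zn) = ", format(x$p_two_peptides_zn, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Most representative cluster of a trajectory
#'
#' The largest cluster in the final frame; ties are broken by the lowest
#' mean per-molecule association energy.
#'
#' @param trajectory List of [snapshot()]s in frame order.
#' @param cutoff Contact cutoff, Angstrom.
#' @param params A [scoring_params()] (used only for tie-breaking).
#' @return List with `frame` (index), `cluster`.
#' @export
select_representative_cluster <- function(trajectory, cutoff = 4.5,
                                          params = scoring_params()) {
  stopifnot(length(trajectory) >= 1)
  f <- length(trajectory)
  snap <- trajectory[[f]]
  cs <- detect_clusters(snap, cutoff)
  if (length(cs$clusters) == 0)
    stop("no clusters of size >= 2 in the final frame")
  sizes <- vapply(cs$clusters, `[[`, integer(1), "size")
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    e <- vapply(best, function(i) {
      mean(vapply(cs$clusters[[i]]$members, function(id)
        association_energy(id, snap, params)$energy, numeric(1)))
    }, numeric(1))
    best <- best[which.min(e)]
  }
  list(frame = f, cluster = cs$clusters[[best[1]]])
}

#' Association energy versus burial for cluster members
#'
#' For every member molecule: the burial fraction (system SASA over
#' isolated SASA) and the association energy with the rest of the
#' system, split by kind for plotting drugs and peptides separately.
#'
#' @param cluster A cluster (element of `detect_clusters(...)$clusters`)
#'   or vector of molecule ids.
#' @param snap The [snapshot()].
#' @param params A [scoring_params()].
#' @param probe_radius SASA probe radius, Angstrom.
#' @param n_points SASA quadrature points per atom.
#' @return data.frame with `mol_id`, `kind`, `burial`, `energy`.
#' @export
energy_burial_profile <- function(cluster, snap, params = scoring_params(),
                                  probe_radius = 1.4, n_points = 960) {
  ids <- if (is.list(cluster)) cluster$members else cluster
  kind_of <- stats::setNames(snap$molecules$kind, snap$molecules$mol_id)
  data.frame(
    mol_id = ids,
    kind = unname(kind_of[as.character(ids)]),
    burial = vapply(ids, burial_fraction, numeric(1), snap = snap,
                    probe_radius = probe_radius, n_points = n_points),
    energy = vapply(ids, function(id)
      association_energy(id, snap, params)$energy, numeric(1)),
    stringsAsFactors = FALSE)
}
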