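# Shared fixtures and independent oracles. Oracles are deliberately
# naive re-implementations (full double loops, Monte-Carlo quadrature)
# kept separate from the package's production code paths.

# -- tiny atom/snapshot builders --------------------------------------------

mk_atom <- function(x, y, z, element = "C", radius = NULL, name = "X",
                    hydrophobic = FALSE, donor = FALSE, acceptor = FALSE,
                    aromatic = FALSE, metal = FALSE, fcharge = 0,
                    resid = NA_integer_, rescode = NA_character_) {
  data.frame(name = name, element = element, resid = resid, rescode = rescode,
             x = x, y = y, z = z,
             radius = if (is.null(radius)) nanopep::element_radius(element) else radius,
             hydrophobic = hydrophobic, donor = donor, acceptor = acceptor,
             aromatic = aromatic, metal = metal, charged = fcharge != 0,
             fcharge = fcharge, stringsAsFactors = FALSE)
}

# snapshot from a list of per-molecule atom tables
mk_snapshot <- function(mol_atoms, kinds = NULL, labels = NULL) {
  n <- length(mol_atoms)
  if (is.null(kinds)) kinds <- rep("drug", n)
  if (is.null(labels)) labels <- rep("toy", n)
  snap <- nanopep:::empty_snapshot()
  for (i in seq_len(n))
    snap <- nanopep:::add_molecule(snap, kinds[i], labels[i], mol_atoms[[i]])
  snap
}

# a modest random co-assembly snapshot for oracle comparisons
random_fixture <- function(seed, n_copies = 2, min_separation = 3,
                           drug = "toy") {
  comp <- system_composition(4L, peptide("FFWH"), 2L, drug_spec(drug))
  generate_random_snapshot(comp, n_copies = n_copies,
                           min_separation = min_separation, seed = seed)
}

# -- cluster partition oracle: naive BFS over full distance matrices --------

oracle_clusters <- function(snap, cutoff) {
  ids <- snap$molecules$mol_id
  n <- length(ids)
  tabs <- lapply(ids, function(id) snap$atoms[snap$atoms$mol_id == id, ])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    xa <- as.matrix(tabs[[i]][, c("x", "y", "z")])
    xb <- as.matrix(tabs[[j]][, c("x", "y", "z")])
    dmin <- Inf
    for (p in seq_len(nrow(xa))) {
      d <- sqrt(colSums((t(xb) - xa[p, ])^2))
      dmin <- min(dmin, min(d))
    }
    adj[i, j] <- adj[j, i] <- dmin <= cutoff
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- sort(ids[members])
  }
  comps
}

# canonical form of a partition for comparison (sorted list of sorted sets)
canon_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# cluster_set -> full partition including singletons
partition_of <- function(cs) {
  canon_partition(c(lapply(cs$clusters, `[[`, "members"),
                    as.list(cs$singletons)))
}

# -- pair-energy oracle: scalar double loop over atom pairs -----------------

oracle_pair_energy <- function(A, B, params) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + pair_term_energy(A[i, ], B[j, ], params)
  tot
}

oracle_association <- function(mol_id, snap, params) {
  A <- snap$atoms[snap$atoms$mol_id == mol_id, ]
  other_ids <- setdiff(snap$molecules$mol_id, mol_id)
  sum(vapply(other_ids, function(id)
    oracle_pair_energy(A, snap$atoms[snap$atoms$mol_id == id, ], params),
    numeric(1)))
}

# sum over unordered intermolecular atom-pair terms
oracle_unordered_pair_sum <- function(snap, params) {
  ids <- snap$molecules$mol_id
  tot <- 0
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    A <- snap$atoms[snap$atoms$mol_id == ids[i], ]
    B <- snap$atoms[snap$atoms$mol_id == ids[j], ]
    tl <- nanopep:::.pair_terms(A, B, params)
    tot <- tot + sum(vapply(tl, sum, numeric(1)))
  }
  tot
}

# -- Monte-Carlo SASA oracle for a single atom in context -------------------

mc_sasa_atom <- function(i, atoms, probe, n_mc = 1e6, seed = 42) {
  set.seed(seed)
  r <- atoms$radius + probe
  u <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * r[i], 2, as.numeric(atoms[i, c("x", "y", "z")]), "+")
  inside <- rep(FALSE, n_mc)
  for (j in seq_len(nrow(atoms))) {
    if (j == i) next
    d2 <- rowSums(sweep(pts, 2, as.numeric(atoms[j, c("x", "y", "z")]))^2)
    inside <- inside | d2 < r[j]^2
  }
  4 * pi * r[i]^2 * mean(!inside)
}

# -- separable synthetic design objective -----------------------------------

# graded aromatic ladder with unique optimum WWW at positions 1-3
separable_scorer <- function() {
  bonus <- stats::setNames(rep(0, 20),
                           rownames(nanopep::evolution_model()$prob))
  bonus[c("F", "Y", "W")] <- c(-1, -2, -3)
  function(pep) sum(bonus[pep$residues[1:3]])
}

# minimal design_run stand-in for consensus set arithmetic
fake_run <- function(accepted, visited = accepted,
                     energies = seq_along(visited)) {
  structure(list(history = data.frame(iteration = seq_along(accepted) - 1L,
                                      sequence = accepted,
                                      energy = seq_along(accepted),
                                      accepted = TRUE,
                                      stringsAsFactors = FALSE),
                 visited = data.frame(sequence = visited, energy = energies,
                                      stringsAsFactors = FALSE)),
            class = "design_run")
}
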