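# Multicomponent cluster detection and derived statistics.

test_that("connectivity follows the minimum heavy-atom distance exactly", {
  a <- mk_atom(0, 0, 0); b <- mk_atom(0, 4.0, 0)
  snap <- mk_snapshot(list(a, b))
  cs <- detect_clusters(snap, cutoff = 4.5)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$size, 2)
  cs2 <- detect_clusters(snap, cutoff = 3.5)
  expect_length(cs2$clusters, 0)
  expect_equal(cs2$singletons, c(1L, 2L))
})

test_that("grid-accelerated detection equals the naive BFS oracle", {
  for (seed in 41:45) {
    snap <- random_fixture(seed = seed, n_copies = 2, min_separation = 3)
    for (cutoff in c(3.5, 4.5, 6)) {
      cs <- detect_clusters(snap, cutoff)
      expect_identical(partition_of(cs),
                       canon_partition(oracle_clusters(snap, cutoff)))
    }
  }
})

test_that("detection is invariant to molecule relabeling", {
  snap <- random_fixture(seed = 46, n_copies = 2)
  perm <- sample(nrow(snap$molecules))
  relabeled <- snap
  map <- stats::setNames(snap$molecules$mol_id[perm], snap$molecules$mol_id)
  relabeled$atoms$mol_id <- unname(map[as.character(snap$atoms$mol_id)])
  relabeled$molecules$mol_id <- unname(map[as.character(snap$molecules$mol_id)])
  cs <- detect_clusters(snap, 4.5)
  cs2 <- detect_clusters(relabeled, 4.5)
  mapped <- canon_partition(lapply(partition_of(cs),
                                   function(s) unname(map[as.character(s)])))
  expect_identical(mapped, partition_of(cs2))
})

test_that("clusters refine monotonically with the cutoff", {
  snap <- random_fixture(seed = 47, n_copies = 2)
  cuts <- c(3, 4.5, 6, 8)
  parts <- lapply(cuts, function(ct) partition_of(detect_clusters(snap, ct)))
  # each partition at a smaller cutoff refines the next: every set is a
  # subset of some set at the larger cutoff
  for (i in seq_along(cuts)[-length(cuts)]) {
    for (s in parts[[i]]) {
      expect_true(any(vapply(parts[[i + 1]],
                             function(t) all(s %in% t), logical(1))))
    }
  }
})

test_that("per-kind counts are conserved across clusters and singletons", {
  for (seed in c(48, 49)) {
    snap <- random_fixture(seed = seed, n_copies = 2)
    cs <- detect_clusters(snap, 4.5)
    kinds <- c("peptide", "drug", "zn", "no3")
    in_clusters <- Reduce(`+`, lapply(cs$clusters, `[[`, "composition"),
                          stats::setNames(rep(0L, 4), kinds))
    sing <- vapply(kinds, function(k) sum(cs$singleton_kinds == k), integer(1))
    expect_equal(in_clusters[kinds] + sing, cs$totals[kinds])
  }
})

test_that("size series track merges and conserve molecule counts", {
  a <- mk_atom(0, 0, 0); b <- mk_atom(0, 20, 0); c_ <- mk_atom(0, 3, 0)
  frame1 <- mk_snapshot(list(a, b))
  frame2 <- mk_snapshot(list(a, nanopep:::transform_atoms(b, translation = c(0, -17, 0))))
  ser <- cluster_size_series(list(frame1, frame1), 4.5)
  expect_identical(ser$histograms[[1]], ser$histograms[[2]])
  ser2 <- cluster_size_series(list(frame1, frame2), 4.5)
  expect_lt(ser2$largest[1], ser2$largest[2])
  snap <- random_fixture(seed = 50, n_copies = 2)
  h <- cluster_size_series(list(snap), 4.5)$histograms[[1]]
  expect_equal(sum(h$size * h$count), nrow(snap$molecules))
})

test_that("encapsulation profiles count per-bin and cumulative percentages", {
  # hand-built partition: 6 of 8 drugs in clusters (sizes 4 and 2), 2 free
  mols <- lapply(seq_len(8), function(i) mk_atom(10 * i, 0, 0))
  mols[[2]]$y <- 0; # cluster A: drugs 1-4 chained at 3 A spacing
  for (i in 2:4) mols[[i]][, c("x", "y", "z")] <- c(3 * (i - 1), 0, 0)
  for (i in 5:6) mols[[i]][, c("x", "y", "z")] <- c(100 + 3 * (i - 5), 0, 0)
  for (i in 7:8) mols[[i]][, c("x", "y", "z")] <- c(200 + 50 * i, 0, 0)
  snap <- mk_snapshot(mols)
  cs <- detect_clusters(snap, 4.5)
  prof <- encapsulation_profile(cs)
  expect_equal(prof$per_bin$drug[prof$per_bin$size == 4], 50)
  expect_equal(prof$per_bin$drug[prof$per_bin$size == 2], 25)
  # cumulative at threshold 1 is 100% by definition
  expect_equal(prof$cumulative$drug[prof$cumulative$size == 1], 100)
  expect_equal(prof$cumulative$drug[prof$cumulative$size == 2], 75)
  # all molecules monomeric: 0% for every bin >= 2
  lonely <- mk_snapshot(lapply(1:4, function(i) mk_atom(100 * i, 0, 0)))
  prof2 <- encapsulation_profile(detect_clusters(lonely, 4.5))
  expect_true(all(prof2$per_bin$size == 1))
  expect_equal(prof2$cumulative$drug[1], 100)
  # a single all-inclusive cluster holds 100% at its size
  pl <- plant_clusters(list(c(peptide = 2, drug = 2, zn = 1)))
  prof3 <- encapsulation_profile(detect_clusters(pl$snapshot, 4.5))
  expect_equal(prof3$per_bin$drug[prof3$per_bin$size == 5], 100)
  # inconsistent totals are rejected
  cs_bad <- detect_clusters(pl$snapshot, 4.5)
  expect_error(encapsulation_profile(cs_bad,
                                     totals = c(peptide = 1, drug = 1, zn = 1, no3 = 0)),
               "inconsistent")
})

test_that("composition ratios normalize against four peptides", {
  expect_equal(composition_ratio(c(peptide = 8, drug = 4, zn = 2)),
               c(peptide = 4, drug = 2, zn = 1))
  expect_equal(composition_ratio(c(peptide = 4, drug = 2, zn = 2)),
               c(peptide = 4, drug = 2, zn = 2))
  expect_equal(composition_ratio(c(peptide = 0, drug = 3, zn = 1)),
               c(peptide = 0, drug = 3, zn = 1))
  pl <- plant_clusters(list(c(peptide = 8, drug = 4, zn = 2)))
  cs <- detect_clusters(pl$snapshot, 4.5)
  expect_equal(composition_ratio(cs$clusters[[1]]),
               c(peptide = 4, drug = 2, zn = 1))
})

test_that("mediation statistics match definitions and the triple oracle", {
  pepA <- nanopep:::peptide_atoms(peptide("FFWH"))
  pepB <- nanopep:::transform_atoms(pepA, translation = c(0, 8, 0))
  drug_mid <- nanopep:::transform_atoms(nanopep:::drug_atoms(drug_spec("toy")),
                                        translation = c(5, 4, 0))
  snap <- mk_snapshot(list(pepA, pepB, drug_mid),
                      kinds = c("peptide", "peptide", "drug"),
                      labels = c("p", "p", "toy"))
  cs <- detect_clusters(snap, 4.5)
  ms <- mediation_stats(cs, snap, 4.5)
  expect_equal(ms$p_two_peptides, 1)      # bridges both peptides
  expect_equal(ms$p_two_peptides_zn, 0)   # no Zn anywhere
  # no drug-peptide contacts: both probabilities zero
  lonely <- mk_snapshot(list(pepA, nanopep:::transform_atoms(drug_mid,
                                                             translation = c(100, 0, 0))),
                        kinds = c("peptide", "drug"), labels = c("p", "toy"))
  ms0 <- mediation_stats(detect_clusters(lonely, 4.5), lonely, 4.5)
  expect_equal(ms0$p_two_peptides, 0)
  expect_equal(ms0$p_two_peptides_zn, 0)
  # random fixture versus brute-force triple enumeration
  for (seed in c(51, 52)) {
    fx <- random_fixture(seed = seed, n_copies = 2)
    csx <- detect_clusters(fx, 4.5)
    msx <- mediation_stats(csx, fx, 4.5)
    drug_ids <- fx$molecules$mol_id[fx$molecules$kind == "drug"]
    pep_ids <- fx$molecules$mol_id[fx$molecules$kind == "peptide"]
    zn_ids <- fx$molecules$mol_id[fx$molecules$kind == "zn"]
    tab <- function(id) fx$atoms[fx$atoms$mol_id == id, ]
    touch <- function(i, j) nanopep:::min_pair_distance(tab(i), tab(j)) <= 4.5
    m2 <- m3 <- logical(length(drug_ids))
    for (k in seq_along(drug_ids)) {
      for (p1 in seq_along(pep_ids)) for (p2 in seq_along(pep_ids)) {
        if (p1 >= p2) next
        if (touch(drug_ids[k], pep_ids[p1]) && touch(drug_ids[k], pep_ids[p2])) {
          m2[k] <- TRUE
          for (z in zn_ids) if (touch(drug_ids[k], z)) m3[k] <- TRUE
        }
      }
    }
    expect_equal(msx$p_two_peptides, mean(m2))
    expect_equal(msx$p_two_peptides_zn, mean(m3))
  }
})

test_that("representative clusters come from the final frame with energy ties", {
  pl1 <- plant_clusters(list(c(drug = 2)), spacing = 30, seed = 1)
  pl2 <- plant_clusters(list(c(drug = 2), c(drug = 3)), spacing = 30, seed = 1)
  rep_ <- select_representative_cluster(list(pl1$snapshot, pl2$snapshot), 4.5)
  expect_equal(rep_$frame, 2)
  expect_equal(rep_$cluster$size, 3)
  one <- select_representative_cluster(list(pl1$snapshot), 4.5)
  expect_equal(one$frame, 1)
  # tie between equal sizes: the tighter (lower-energy) pair wins
  tight <- list(mk_atom(0, 0, 0, hydrophobic = TRUE),
                mk_atom(4.0, 0, 0, hydrophobic = TRUE),
                mk_atom(100, 0, 0, hydrophobic = TRUE),
                mk_atom(104.4, 0, 0, hydrophobic = TRUE))
  snap <- mk_snapshot(tight)
  sel <- select_representative_cluster(list(snap), 4.5)
  expect_equal(sel$cluster$members, c(1L, 2L))
  dispersed <- mk_snapshot(list(mk_atom(0, 0, 0), mk_atom(100, 0, 0)))
  expect_error(select_representative_cluster(list(dispersed), 4.5), "no clusters")
})

test_that("energy-burial profiles pair exposure with association energy", {
  lone <- mk_snapshot(list(mk_atom(0, 0, 0)))
  prof <- energy_burial_profile(1L, lone)
  expect_equal(prof$burial, 1.0)
  expect_equal(prof$energy, 0.0)
  # chain of seven identical molecules: interior members are more buried
  # and lower-energy than the ends
  chain <- mk_snapshot(lapply(1:7, function(i)
    nanopep:::transform_atoms(nanopep:::drug_atoms(drug_spec("toy")),
                              translation = c(6 * i, 0, 0))))
  cs <- detect_clusters(chain, 4.5)
  prof2 <- energy_burial_profile(cs$clusters[[1]], chain, n_points = 240)
  mid <- prof2[prof2$mol_id == 4, ]
  end <- prof2[prof2$mol_id == 1, ]
  expect_lt(mid$burial, end$burial)
  expect_lt(mid$energy, end$energy)
  expect_lt(mid$energy, 0)
  # deeper burial (lower SASA ratio) pairs with lower energy along the
  # constructed gradient
  expect_lt(cor(1 - prof2$burial, prof2$energy, method = "spearman"), 0)
})
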