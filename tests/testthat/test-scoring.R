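# Empirical pair potential, association energies, and the Zn census.

test_that("pair term energy matches the closed functional form", {
  params <- scoring_params()
  a <- mk_atom(0, 0, 0)
  # surface contact (d = 0), untyped pair: gauss weight * exp(0), no repulsion
  b <- mk_atom(a$radius + 1.9, 0, 0)
  expect_equal(pair_term_energy(a, b, params), params$gauss_weight)
  # beyond the hard cutoff: exactly zero
  far <- mk_atom(params$cutoff + 0.01, 0, 0)
  expect_identical(pair_term_energy(a, far, params), 0)
  # one gaussian width of surface separation, hydrophobic pair: closed form
  a2 <- mk_atom(0, 0, 0, hydrophobic = TRUE)
  b2 <- mk_atom(2 * 1.9 + params$gauss_width, 0, 0, hydrophobic = TRUE)
  d <- params$gauss_width
  expected <- params$gauss_weight * exp(-1) +
    params$hydrophobic_weight * (params$hydrophobic_off - d) /
      (params$hydrophobic_off - params$hydrophobic_on)
  expect_equal(pair_term_energy(a2, b2, params), expected)
  # overlapping donor/acceptor pair: repulsion + saturated hydrogen bond
  a3 <- mk_atom(0, 0, 0, element = "N", donor = TRUE)
  b3 <- mk_atom(2.5, 0, 0, element = "O", acceptor = TRUE)
  ds <- 2.5 - element_radius("N") - element_radius("O")  # -1.0: overlap
  expected3 <- params$gauss_weight * exp(-(ds / params$gauss_width)^2) +
    params$repulsion_weight * ds^2 + params$hbond_weight
  expect_equal(pair_term_energy(a3, b3, params), expected3)
  # breakdown sums to the total
  br <- pair_term_energy(a3, b3, params, breakdown = TRUE)
  expect_equal(sum(br), pair_term_energy(a3, b3, params))
})

test_that("association energy is zero beyond range and symmetric for twins", {
  params <- scoring_params()
  m1 <- mk_atom(0, 0, 0); m2 <- mk_atom(50, 0, 0)
  snap <- mk_snapshot(list(m1, m2))
  expect_identical(association_energy(1L, snap, params)$energy, 0)
  twin <- mk_snapshot(list(mk_atom(0, 0, 0, hydrophobic = TRUE),
                           mk_atom(4.5, 0, 0, hydrophobic = TRUE)))
  e1 <- association_energy(1L, twin, params)
  e2 <- association_energy(2L, twin, params)
  expect_equal(e1$energy, e2$energy)
  expect_equal(e1$energy, sum(e1$terms))
  expect_error(association_energy(99L, twin, params), "unknown molecule")
})

test_that("association energy equals the brute-force atom-pair oracle", {
  params <- scoring_params()
  snap <- random_fixture(seed = 11, n_copies = 1)
  for (id in snap$molecules$mol_id[c(1, 5, 7)]) {
    expect_equal(association_energy(id, snap, params)$energy,
                 oracle_association(id, snap, params), tolerance = 1e-10)
  }
})

test_that("mean drug association energy averages per-drug energies", {
  params <- scoring_params()
  snap <- random_fixture(seed = 12, n_copies = 1)
  drug_ids <- snap$molecules$mol_id[snap$molecules$kind == "drug"]
  manual <- mean(vapply(drug_ids, function(id)
    association_energy(id, snap, params)$energy, numeric(1)))
  expect_equal(mean_drug_association_energy(snap, params), manual)
  no_drugs <- mk_snapshot(list(nanopep:::zn_atoms()), kinds = "zn", labels = "ZN")
  expect_error(mean_drug_association_energy(no_drugs, params), "no drug")
})

test_that("energy additivity: molecule sums double-count unordered pairs", {
  params <- scoring_params()
  for (seed in c(21, 22)) {
    snap <- random_fixture(seed = seed, n_copies = 1)
    per_mol <- sum(vapply(snap$molecules$mol_id, function(id)
      association_energy(id, snap, params)$energy, numeric(1)))
    pairs <- oracle_unordered_pair_sum(snap, params)
    expect_equal(per_mol, 2 * pairs, tolerance = 1e-9)
  }
})

test_that("energies are invariant under rigid-body motion", {
  params <- scoring_params()
  snap <- random_fixture(seed = 13, n_copies = 1)
  R <- nanopep:::rotation_matrix(c(1, 2, 3), 1.1)
  moved <- transform_snapshot(snap, R, c(12, -7, 3))
  for (id in snap$molecules$mol_id[c(2, 6)])
    expect_equal(association_energy(id, moved, params)$energy,
                 association_energy(id, snap, params)$energy,
                 tolerance = 1e-6)
})

test_that("energies converge once the cutoff covers all interactions", {
  snap <- random_fixture(seed = 14, n_copies = 1)
  span <- max(dist(as.matrix(snap$atoms[, c("x", "y", "z")])))
  e_big <- mean_drug_association_energy(snap, scoring_params(cutoff = span + 1))
  e_bigger <- mean_drug_association_energy(snap, scoring_params(cutoff = span + 20))
  expect_equal(e_big, e_bigger, tolerance = 1e-12)
})

test_that("zinc census classifies His, carboxylate, and drug partners", {
  # Zn 2.2 A from a His imidazole nitrogen: coordinated
  his <- mk_atom(0, 0, 0, element = "N", name = "NE2", acceptor = TRUE,
                 resid = 4L, rescode = "H")
  zn1 <- nanopep:::zn_atoms(c(2.2, 0, 0))
  snap <- mk_snapshot(list(his, zn1), kinds = c("peptide", "zn"),
                      labels = c("pep", "ZN"))
  cen <- zn_coordination_census(snap, cutoff = 2.5)
  expect_equal(cen$percent_his_coordinated, 100)
  expect_equal(cen$per_zn[[1]]$category, "his_n")
  # isolated Zn: nothing within range
  snap2 <- mk_snapshot(list(his, nanopep:::zn_atoms(c(15, 0, 0))),
                       kinds = c("peptide", "zn"), labels = c("pep", "ZN"))
  expect_equal(zn_coordination_census(snap2, 2.5)$percent_his_coordinated, 0)
  # 2 His-bound + 1 carboxylate-bound -> 66.7%
  oxt <- mk_atom(30, 0, 0, element = "O", name = "OXT", acceptor = TRUE,
                 fcharge = -1, resid = 4L, rescode = "H")
  snap3 <- mk_snapshot(list(his, mk_atom(10, 0, 0, element = "N", name = "NE2",
                                         resid = 4L, rescode = "H"),
                            oxt,
                            nanopep:::zn_atoms(c(2.2, 0, 0)),
                            nanopep:::zn_atoms(c(10, 2.2, 0)),
                            nanopep:::zn_atoms(c(32.2, 0, 0))),
                       kinds = c("peptide", "peptide", "peptide", "zn", "zn", "zn"),
                       labels = c("p", "p", "p", "ZN", "ZN", "ZN"))
  cen3 <- zn_coordination_census(snap3, 2.5)
  expect_equal(cen3$percent_his_coordinated, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(cen3$per_zn[[3]]$category, "anionic_o")
  # no Zn at all: percent is not applicable
  expect_true(is.na(zn_coordination_census(mk_snapshot(list(his)),
                                           2.5)$percent_his_coordinated))
})
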