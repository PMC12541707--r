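# The evolution-guided lock-and-design loop and consensus ranking.

test_that("the mutation model is row-stochastic and temperature-sensitive", {
  m <- evolution_model()
  expect_equal(rowSums(m$prob), stats::setNames(rep(1, 20), rownames(m$prob)),
               tolerance = 1e-12)
  expect_true(all(m$prob > 0))
  flat <- evolution_model(temperature = 100)
  # high temperature flattens towards uniform
  expect_lt(max(flat$prob) - min(flat$prob), max(m$prob) - min(m$prob))
  expect_error(evolution_model(temperature = 0))
})

test_that("mutation proposals respect the contract", {
  pep <- peptide("FFWH")
  # degenerate model: all mass on W
  sc <- matrix(-100, 20, 20, dimnames = dimnames(evolution_model()$prob))
  sc[, "W"] <- 100
  degen <- evolution_model(sc)
  set.seed(1)
  # from a non-W residue the degenerate row always proposes W
  for (i in 1:20) expect_equal(propose_mutation(pep, degen, position = 1)$residue, "W")
  # position 4 is never proposed, and never allowed explicitly
  set.seed(2)
  pos <- replicate(300, propose_mutation(pep, evolution_model())$position)
  expect_setequal(unique(pos), 1:3)
  expect_error(propose_mutation(pep, evolution_model(), position = 4),
               "histidine is fixed")
  # determinism under a fixed seed
  set.seed(7); p1 <- propose_mutation(pep, evolution_model())
  set.seed(7); p2 <- propose_mutation(pep, evolution_model())
  expect_identical(p1, p2)
})

test_that("proposal frequencies recover the model row within 3-sigma bands", {
  model <- evolution_model()
  pep <- peptide("LVFH")
  n <- 30000
  set.seed(3)
  draws <- replicate(n, {
    mut <- propose_mutation(pep, model, position = 1)
    mut$residue
  })
  row <- model$prob["L", ]
  row["L"] <- 0; row <- row / sum(row)
  freq <- table(factor(draws, levels = names(row))) / n
  for (res in names(row)) {
    se <- sqrt(row[[res]] * (1 - row[[res]]) / n)
    expect_lt(abs(freq[[res]] - row[[res]]), 3 * se + 1e-12)
  }
})

test_that("evaluate_design minimizes over scaffolds and poses", {
  pep <- peptide("FFWH")
  drug <- drug_spec("CPT")
  near <- build_ips(pep, drug)
  # single scaffold, single pose: equals the direct objective
  expect_equal(evaluate_design(pep, drug, list(near)),
               mean_drug_association_energy(near))
  # duplicated pose leaves the minimum unchanged
  expect_equal(evaluate_design(pep, drug, list(near),
                               poses = list(diag(3), diag(3))),
               evaluate_design(pep, drug, list(near)))
  # a scaffold whose drug is out of range scores 0; the minimum picks the
  # bound scaffold
  far <- near
  dsel <- far$atoms$mol_id %in% nanopep:::mol_ids_of_kind(far, "drug")
  far$atoms[dsel, "x"] <- far$atoms[dsel, "x"] + 500
  expect_equal(evaluate_design(pep, drug, list(far)), 0)
  expect_equal(evaluate_design(pep, drug, list(near, far)),
               evaluate_design(pep, drug, list(near)))
  expect_error(evaluate_design(pep, drug, list()), "empty")
  # threading changes the label and side-chain typing but not the geometry
  threaded <- nanopep:::thread_peptides(near, peptide("WWWH"))
  expect_equal(threaded$molecules$label[1], "Ac-WWWH-CONH2")
  expect_equal(threaded$atoms[, c("x", "y", "z")], near$atoms[, c("x", "y", "z")])
})

test_that("a worsening proposal at budget 1 leaves the start locked", {
  always_worse <- local({
    first <- TRUE
    function(pep) {
      if (first) { first <<- FALSE; return(-10) }
      0
    }
  })
  run <- lock_and_design(drug_spec("toy"), peptide("LVFH"), budget = 1,
                         seed = 1, evaluate = always_worse)
  expect_identical(as.character(run$locked), "LVFH")
  expect_equal(run$locked_energy, -10)
  expect_false(run$history$accepted[2])
})

test_that("locked energies are monotone and histories reproducible", {
  scorer <- separable_scorer()
  for (seed in 1:5) {
    run <- lock_and_design(drug_spec("toy"), peptide("LVFH"), budget = 300,
                           seed = seed, evaluate = scorer)
    locked_trace <- run$history$energy[run$history$accepted]
    expect_false(is.unsorted(rev(locked_trace), strictly = FALSE))
    expect_equal(run$locked_energy, min(locked_trace))
  }
  r1 <- lock_and_design(drug_spec("toy"), peptide("LVFH"), budget = 200,
                        seed = 42, evaluate = scorer)
  r2 <- lock_and_design(drug_spec("toy"), peptide("LVFH"), budget = 200,
                        seed = 42, evaluate = scorer)
  expect_identical(r1$history, r2$history)
  expect_identical(coef(r1), coef(r2))
})

test_that("the loop concentrates on a planted separable optimum", {
  scorer <- separable_scorer()
  hits <- 0
  for (seed in 1:20) {
    run <- lock_and_design(drug_spec("toy"), peptide("LVFH"), budget = 500,
                           stall = 500, seed = seed, evaluate = scorer)
    hits <- hits + (as.character(run$locked) == "WWWH")
  }
  expect_gte(hits, 19)
})

test_that("consensus is the exact intersection of per-drug design sets", {
  runs <- list(EPI = fake_run(c("LVFH", "FVFH", "FWFH")),
               MTX = fake_run(c("LVFH", "FWFH", "WWFH")),
               CPT = list(fake_run(c("FWFH", "QQQH")),
                          fake_run(c("LVFH"))))
  expect_identical(find_consensus(runs), c("FWFH", "LVFH"))
  # disjoint accepted sets -> empty consensus
  expect_length(find_consensus(list(a = fake_run("AAAH"), b = fake_run("WWWH"))), 0)
  expect_error(find_consensus(list(a = fake_run("AAAH"))), "at least 2")
  expect_error(find_consensus(list(a = list(), b = fake_run("AAAH"))), "empty")
})

test_that("consensus penalty has a zero floor, shift invariance, and exact toys", {
  E <- rbind(AAWH = c(-10, -5), FFWH = c(-12, -4), WWWH = c(-11, -6))
  colnames(E) <- c("EPI", "MTX")
  pen <- consensus_energy_penalty(E)
  # hand enumeration: col minima -12, -6
  expect_equal(pen[["FFWH"]], mean(c(0, 2)))
  expect_equal(pen[["AAWH"]], mean(c(2, 1)))
  expect_equal(pen[["WWWH"]], mean(c(1, 0)))
  expect_identical(names(pen)[1], "WWWH")  # lowest penalty first
  expect_true(all(pen >= 0))
  # a peptide best for every drug sits exactly at zero
  E2 <- rbind(BEST = c(-9, -9), OTHR = c(-8, -7))
  expect_equal(consensus_energy_penalty(E2)[["BEST"]], 0)
  # adding a constant to one drug's column changes nothing
  E3 <- E; E3[, 1] <- E3[, 1] + 7.5
  expect_equal(consensus_energy_penalty(E3), pen)
  E4 <- E; E4[2, 2] <- NA
  expect_error(consensus_energy_penalty(E4), "missing")
})

test_that("consensus tables assemble best energies from real runs", {
  scorer <- separable_scorer()
  runs <- lapply(c(EPI = "EPI", MTX = "MTX"), function(dn)
    lock_and_design(drug_spec(dn), peptide("LVFH"), budget = 300, stall = 300,
                    seed = 11, evaluate = scorer))
  cons <- find_consensus(runs, "visited")
  expect_true(length(cons) > 0)
  tab <- consensus_table(runs)
  expect_identical(rownames(tab$energy), cons)
  # every reported consensus peptide appears in each drug's records
  for (p in cons) for (r in runs)
    expect_true(p %in% r$visited$sequence)
  pen <- consensus_energy_penalty(tab)
  expect_true(all(pen >= 0))
})

test_that("aggregation propensity is a position-independent scale sum", {
  zero <- stats::setNames(rep(0, 20), amino_acid_table()$code)
  expect_equal(aggregation_propensity(peptide("FFWH"), zero), 0)
  toy <- zero; toy[c("F", "W")] <- c(1, 2)
  expect_equal(aggregation_propensity(peptide("FFWH"), toy), 4)
  expect_equal(aggregation_propensity(peptide("FWFH"), toy),
               aggregation_propensity(peptide("WFFH"), toy))
  expect_equal(aggregation_propensity("WWWH"),
               3 * residue_scale("beta_propensity")[["W"]] +
                 residue_scale("beta_propensity")[["H"]])
  expect_error(aggregation_propensity(peptide("FFWH"), "no_such_scale"),
               "unknown residue scale")
})

test_that("top-design selection tags energy and propensity picks", {
  pen <- c(AAWH = 0.1, BBWH = 0.5, CCWH = 0.2, DDWH = 0.9, EEWH = 0.9)
  names(pen) <- c("AAWH", "FFWH", "CWWH", "DWWH", "EWWH")
  prop <- c(AAWH = 1, FFWH = 9, CWWH = 2, DWWH = 8, EWWH = 3)
  sel <- select_top_designs(pen, prop, k_energy = 2, k_propensity = 2)
  expect_equal(sel$sequence[1:2], c("AAWH", "CWWH"))
  expect_equal(sel$criterion, c("energy", "energy", "propensity", "propensity"))
  expect_equal(sel$sequence[3:4], c("FFWH", "DWWH"))
  # whole pool by energy
  all_e <- select_top_designs(pen, prop, k_energy = 5)
  expect_true(all(all_e$criterion == "energy"))
  # deterministic lexicographic tie-break on equal penalties
  expect_equal(select_top_designs(pen, prop, 4)$sequence[4], "DWWH")
  expect_error(select_top_designs(pen, prop, 6), "exceeds")
})
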