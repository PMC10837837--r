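# Secondary structure, interaction detection, densities, stratified
# composition and stability aggregation.

test_that("ideal conformations are assigned their classes", {
  helix <- assign_secondary_structure(build_peptide(strrep("A", 30), "helix"))
  expect_gte(sum(helix$ss == "H"), 26)
  expect_equal(helix$ss[1], "C")  # terminus lacks phi

  strand <- assign_secondary_structure(build_peptide(strrep("A", 12), "strand"))
  expect_gte(sum(strand$ss == "E"), 8)

  tri <- assign_secondary_structure(build_peptide("AAA", "helix"))
  expect_equal(tri$ss, c("C", "C", "C"))
})

test_that("chain breaks split runs", {
  pep <- build_peptide(strrep("A", 8), "helix")
  # move the last 4 residues far away: no run of >= 4 helix candidates remains
  sel <- pep$residue_index > 4
  pep$x[sel] <- pep$x[sel] + 50
  ss <- assign_secondary_structure(pep)
  expect_true(all(ss$ss == "C"))
})

test_that("contact fixtures at and around each criterion behave per truth", {
  bounds <- list(hydrophobic = 5.0, ionic = 6.0, aromatic_sulfur = 5.3,
                 cation_pi = 6.0, disulfide = 2.2)
  for (ty in names(bounds)) {
    for (d in bounds[[ty]] + c(-0.01, 0, 0.01)) {
      fx <- make_contact_fixture(ty, d)
      det <- suppressMessages(detect_interactions(fx$atoms))
      hit <- any(det$type == ty & det$res_i == 1 & det$res_j == 5)
      expect_identical(hit, fx$expected)
    }
  }
  # the aromatic-aromatic window has two boundaries
  for (d in c(4.49, 4.5, 4.51, 6.99, 7.0, 7.01, 7.1)) {
    fx <- make_contact_fixture("aromatic_aromatic", d)
    det <- suppressMessages(detect_interactions(fx$atoms))
    hit <- any(det$type == "aromatic_aromatic")
    expect_identical(hit, fx$expected)
  }
})

test_that("detection equals the brute-force oracle on random clusters", {
  withr::local_seed(16)
  for (i in 1:20) {
    atoms <- random_residue_cluster(sample(4:8, 1))
    got <- suppressMessages(detect_interactions(atoms))
    want <- oracle_contacts(atoms)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$type, want$type)
    expect_equal(got$res_i, want$res_i)
    expect_equal(got$res_j, want$res_j)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
})

test_that("detection is independent of atom row order", {
  withr::local_seed(17)
  atoms <- random_residue_cluster(6)
  ref <- suppressMessages(detect_interactions(atoms))
  shuf <- suppressMessages(detect_interactions(atoms[sample(nrow(atoms)), ]))
  expect_equal(ref, shuf)
})

test_that("interaction densities are counts per residue", {
  contacts <- tibble::tibble(type = rep("ionic", 9), res_i = 1:9,
                             res_j = 11:19, distance = 4)
  d <- interaction_density(contacts, 100)
  expect_equal(d$density[d$type == "ionic"], 0.09)
  expect_equal(sum(d$density[d$type != "ionic"]), 0)
  empty <- interaction_density(contacts[0, ], 50)
  expect_equal(sum(empty$density), 0)
})

test_that("stratified composition normalises within strata", {
  res <- tibble::tibble(
    residue_index = 1:40,
    residue_type = rep(c("ASP", "LEU", "LYS", "GLY"), 10),
    region = rep(c("surface", "core"), each = 20),
    ss = rep(c("H", "C"), 20))
  sc <- stratified_composition(res, min_support = 5)
  pop <- sc$strata[sc$strata$n > 0, ]
  for (k in seq_len(nrow(pop))) expect_equal(sum(pop$f[[k]]), 1)
  expect_equal(sum(sc$ss_fractions), 1)
  expect_true(all(sc$strata$low_support == (sc$strata$n < 5)))

  # an all-surface-helix structure populates only that stratum
  res2 <- tibble::tibble(residue_index = 1:10, residue_type = "ALA",
                         region = "surface", ss = "H")
  sc2 <- stratified_composition(res2, min_support = 5)
  expect_equal(sc2$strata$n[sc2$strata$region == "surface" & sc2$strata$ss == "H"], 10)
  expect_equal(sum(sc2$strata$n), 10)
})

test_that("stability aggregation means scores and reports clade changes", {
  sc <- tibble::tibble(protein_id = "p1", residue_index = 1:2,
                       S = c(-0.1, -0.06))
  expect_equal(aggregate_stability(sc)$mean_S, -0.08)
  expect_warning(empty <- aggregate_stability(sc[0, ]), "empty")
  expect_equal(nrow(empty), 0)

  # clade change -0.090 -> -0.085 is about +5.6% (less stable)
  scores <- tibble::tibble(
    protein_id = c("a1", "a2", "b1", "b2"),
    residue_index = 1, S = c(-0.090, -0.090, -0.085, -0.085))
  clades <- tibble::tibble(protein_id = c("a1", "a2", "b1", "b2"),
                           clade = c("ref", "ref", "tgt", "tgt"))
  out <- aggregate_stability(scores, clades, reference = "ref")
  expect_equal(out$pct_change_vs_reference[out$clade == "tgt"],
               100 * (-0.085 - -0.090) / 0.090, tolerance = 1e-9)
  expect_equal(round(out$pct_change_vs_reference[out$clade == "tgt"], 1), 5.6)
})

test_that("stability tables are matched against the structure", {
  res <- tibble::tibble(residue_index = 1:5, residue_type = "ALA", sasa = 1)
  sc <- tibble::tibble(protein_id = "p", residue_index = c(1, 2, 99), S = -0.1)
  expect_warning(kept <- match_stability(sc, res), "absent")
  expect_equal(nrow(kept), 2)
})

test_that("structure_features bundles residues, contacts and densities", {
  fx <- make_contact_fixture("ionic", 4.0)
  sf <- suppressMessages(structure_features(fx$atoms, "prot1"))
  expect_equal(unique(sf$residues$protein_id), "prot1")
  expect_true("ionic" %in% sf$contacts$type)
  expect_equal(sf$densities$density[sf$densities$type == "ionic"], 1 / 5)
})
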