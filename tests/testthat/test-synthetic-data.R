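# The synthetic-data generators: determinism, planted-value recovery, and
# format validity of everything they emit.

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_sim_config()
  expect_identical(make_clade_genomes(cfg, seed = 9),
                   make_clade_genomes(cfg, seed = 9))
  expect_false(identical(make_clade_genomes(cfg, seed = 9)$genomes[[1]],
                         make_clade_genomes(cfg, seed = 10)$genomes[[1]]))
  pcfg <- protein_sim_config(n_families = 3, members_per_clade = 2)
  expect_identical(make_protein_families(pcfg, seed = 9),
                   make_protein_families(pcfg, seed = 9))
  expect_identical(build_peptide("ARND", "helix"), build_peptide("ARND", "helix"))
  fx <- make_core_surface_fixture(3, 12)
  expect_identical(fx, make_core_surface_fixture(3, 12))
})

test_that("synthetic genomes realise their planted composition", {
  gs <- make_clade_genomes(small_sim_config(), seed = 31)
  for (iso in names(gs$genomes)[c(1, 3, 5, 7)]) {
    g <- gs$genomes[[iso]]
    tr <- gs$truth$isolates[[iso]]
    expect_lt(abs(gc_content(g$sequence) - tr$gc), 0.01)
    a <- gs$annotations[[iso]]
    expect_equal(sum(a$feature_type == "sRNA"), tr$n_srna)
    expect_equal(sum(a$feature_type == "insertion_sequence"), tr$n_is)
    expect_equal(sum(a$feature_type == "CRISPR"), tr$n_crispr)
    expect_equal(sum(a$feature_type == "operon"), tr$n_operon)
    # CDS have valid start and stop codons after strand resolution
    cds <- extract_feature_seq(a, g, "CDS")$sequence
    expect_true(all(substr(cds, 1, 3) == "ATG"))
    expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                      c("TAA", "TAG", "TGA")))
  }
  # infeasible packing errors out
  tiny <- genome_sim_config(n_isolates = 1, genome_length = 5000)
  expect_error(make_clade_genomes(tiny, seed = 1), "packing")
})

test_that("planted metadata means are exact per clade", {
  gs <- make_clade_genomes(small_sim_config(), seed = 32)
  hs <- habitat_summary(gs$metadata)
  planted <- gs$truth$clades
  for (k in seq_len(nrow(planted))) {
    row <- hs$subclades[hs$subclades$clade == planted$clade[k], ]
    expect_equal(row$mean_MAT, planted$mat[k], tolerance = 1e-9)
  }
  expect_lt(hs$major_clades$mean_salinity[hs$major_clades$clade == "I"], 1)
  expect_gt(hs$major_clades$mean_salinity[hs$major_clades$clade == "II"], 5)
})

test_that("generated genome sets survive a write/read round-trip", {
  cfg <- small_sim_config(n_isolates = 1)
  gs <- make_clade_genomes(cfg, seed = 33)
  iso <- names(gs$genomes)[1]
  dir <- withr::local_tempdir()
  ff <- file.path(dir, "g.fasta"); gf <- file.path(dir, "g.gff3")
  mf <- file.path(dir, "meta.tsv")
  write_fasta(dplyr::rename(gs$genomes[[iso]], id = contig_id), ff)
  write_gff3(gs$annotations[[iso]], gf)
  write_metadata(gs$metadata, mf)
  expect_no_warning({
    genome <- dplyr::rename(read_fasta(ff), contig_id = id)
    ann <- read_gff3(gf, genome)
    md <- read_metadata(mf)
  })
  expect_equal(genome$sequence, gs$genomes[[iso]]$sequence)
  expect_equal(nrow(ann), nrow(gs$annotations[[iso]]))
  expect_equal(md$isolate_id, gs$metadata$isolate_id)
})

test_that("planted family identity lands in the coincidence-corrected band", {
  cfg <- protein_sim_config(n_families = 3, members_per_clade = 3,
                            identity_sd = 0)
  sim <- make_protein_families(cfg, seed = 34)
  for (f in unique(sim$proteins$family_id)) {
    fam <- sim$proteins[sim$proteins$family_id == f, ][1:6, ]
    mpi <- mean_pairwise_identity(fam)
    expect_gt(mpi$mean_identity, 74)
    expect_lt(mpi$mean_identity, 86)
  }
})

test_that("zero shift vectors give only sampling-noise differences", {
  cfg <- protein_sim_config(
    shifts = list(Ia = NULL, Ib = NULL, IIa = NULL, IIb = NULL))
  sim <- make_protein_families(cfg, seed = 35)
  sf <- stratum_frequencies(sim, "surface")
  sch <- clade_scheme(dplyr::distinct(sim$proteins, isolate_id, clade))
  rep <- run_contrasts(sf, sch, test = "ks")
  # the 3% null bound applies above the integer-rounding granularity: for
  # the rarest residues (expected surface count < 3 per protein) the
  # relative noise floor is wider, so a 2.5-sigma bound is used there
  base <- aa_background_vec()
  common <- names(base)[base >= 0.02]
  expect_true(all(abs(rep$d[rep$feature %in% common]) < 3))
  expect_true(all(abs(rep$d) < 8))
})

test_that("surface-restricted shifts appear in the surface stratum only", {
  sim <- make_protein_families(seed = 36)
  sch <- clade_scheme(dplyr::distinct(sim$proteins, isolate_id, clade))
  surf <- run_contrasts(stratum_frequencies(sim, "surface"), sch, test = "ks")
  core <- run_contrasts(stratum_frequencies(sim, "core"), sch, test = "ks")
  d_surf <- surf$d[surf$label == "halophilic" & surf$feature == "D"]
  d_core <- core$d[core$label == "halophilic" & core$feature == "D"]
  expect_gte(d_surf, 8); expect_lte(d_surf, 12)
  expect_lt(abs(d_core), 3)
})

test_that("contact fixtures place the defining distance exactly", {
  for (ty in c("disulfide", "ionic", "aromatic_aromatic", "hydrophobic",
               "cation_pi", "aromatic_sulfur")) {
    fx <- make_contact_fixture(ty, 4.2)
    det <- suppressMessages(detect_interactions(fx$atoms))
    row <- det[det$type == ty & det$res_i == 1 & det$res_j == 5, ]
    if (fx$expected) expect_equal(row$distance, 4.2, tolerance = 1e-9)
  }
  expect_error(make_contact_fixture("nonsense", 3), "unknown interaction")
  expect_error(make_core_surface_fixture(0, 5), "at least one")
})
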