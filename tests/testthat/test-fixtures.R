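test_that("the ideal bundle is the scoring null reference", {
  b <- ideal_bundle()
  expect_length(b$helices, 7)
  expect_equal(tilt_penalty(b), 0)
  expect_lt(elevation_penalty(b), 1e-6)
  expect_equal(sum(find_pockets(b, min_volume = 20)$buried), 0)
  # no inter-helix clash below 3 A
  for (k in 1:6) {
    expect_gte(min_pair_distance(helix_coords(b$helices[[k]]),
                                 helix_coords(b$helices[[k + 1]])), 3.0)
  }
  # antiparallel alternation
  axes <- lapply(b$helices, helix_axis)
  for (k in 1:6) expect_lt(sum(axes[[k]] * axes[[k + 1]]), 0)
  # generation is deterministic
  expect_identical(coords_of(make_ideal_bundle()), coords_of(b))
})

test_that("minimal and infeasible fixture specs behave as specified", {
  b2 <- make_ideal_bundle(fixture_spec(n_helices = 2, helix_length = 10))
  expect_length(b2$helices, 2)
  expect_error(make_ideal_bundle(fixture_spec(ring_radius = 3)),
               "infeasible ring radius")
  expect_error(fixture_spec(helix_length = 3))
})

test_that("decoy sets grade disorder with amplitude", {
  b <- small_bundle()
  ds <- make_decoy_set(b, levels = c(0.25, 0.5, 1), n_per_level = 6, seed = 3)
  expect_length(ds$decoys, 18)
  rmsds <- vapply(ds$decoys, function(d) bundle_ca_rmsd(b, d), numeric(1))
  means <- tapply(rmsds, ds$level, mean)
  expect_true(all(diff(means) > 0))  # strictly increasing with level
  # reproducible from the seed
  ds2 <- make_decoy_set(b, levels = c(0.25, 0.5, 1), n_per_level = 6, seed = 3)
  expect_identical(coords_of(ds$decoys[[7]]), coords_of(ds2$decoys[[7]]))
  # amplitude-zero level: identical copies
  ds0 <- make_decoy_set(b, levels = 0, n_per_level = 2, seed = 1)
  expect_identical(coords_of(ds0$decoys[[1]]), coords_of(b))
})

test_that("toy ligand fixtures have the stated chemistry", {
  cat0 <- make_ligand_fixture("toy_cation")
  expect_equal(sum(cat0$atoms$element != "H"), 1)
  expect_equal(sum(cat0$atoms$charge), 1, tolerance = 1e-9)
  expect_length(cat0$rotatable, 0)
  cate <- make_ligand_fixture("toy_catechol_amine")
  expect_equal(sum(cate$atoms$aromatic), 6)
  expect_gt(length(cate$rotatable), 0)
  expect_equal(sum(cate$atoms$charge), 1, tolerance = 1e-9)
  # two aromatic hydroxyls and a protonated amine
  adj <- helixpack:::lig_adjacency(cate)
  oh <- sum(cate$atoms$element == "O" &
            vapply(adj, function(nb) any(cate$atoms$element[nb] == "H"),
                   logical(1)))
  expect_equal(oh, 2)
  expect_error(make_ligand_fixture("nonexistent"), "unknown ligand fixture")
})

test_that("R-NPA fixture: protonation, catechol, 8 A span", {
  npa <- make_ligand_fixture("R-NPA")
  adj <- helixpack:::lig_adjacency(npa)
  n_idx <- which(npa$atoms$element == "N")
  expect_length(n_idx, 1)
  # protonated tertiary amine: N carries a hydrogen and the +1 charge
  expect_true(any(npa$atoms$element[adj[[n_idx]]] == "H"))
  expect_equal(sum(npa$atoms$charge), 1, tolerance = 0.05)
  d <- catechol_amine_distances(npa)
  expect_length(d, 2)
  # the longer catechol-O..N distance across the rigid aporphine core: 8 A
  expect_equal(round(max(d)), 8)
  # stable across embedding seeds (lowest-energy-of-10 conformer selection)
  npa2 <- make_ligand_fixture("R-NPA", seed = 7)
  expect_equal(round(max(catechol_amine_distances(npa2))), 8)
})

test_that("pocket fixture places the key residues around the pocket", {
  pf <- pocket_fixture()
  at <- bundle_atoms(pf$bundle)
  expect_equal(unique(at$resname[at$resid == pf$target$asp_resid]), "ASP")
  expect_equal(unique(at$resname[at$resid %in% pf$target$ser_resids]), "SER")
  expect_equal(unique(at$resname[at$resid %in% pf$target$phe_resids]), "PHE")
  # aspartate-to-serine anchor distance falls inside the 12 +/- 2 window
  od <- as.matrix(at[at$resid == pf$target$asp_resid &
                     at$atom %in% c("OD1", "OD2"), c("x", "y", "z")])
  og <- as.matrix(at[at$resid %in% pf$target$ser_resids & at$atom == "OG",
                     c("x", "y", "z")])
  d <- sqrt(sum((colMeans(od) - colMeans(og))^2))
  expect_gt(d, 10); expect_lt(d, 14)
})
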