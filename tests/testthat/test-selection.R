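test_that("docking a toy cation finds the aspartate (grid-search oracle)", {
  pf <- pocket_fixture()
  cat0 <- make_ligand_fixture("toy_cation")
  poses <- dock_ligand(pf$bundle, cat0, seed = 5, n_starts = 8, steps = 800)
  expect_gt(length(poses), 0)
  # identical seed: identical stack
  poses2 <- dock_ligand(pf$bundle, cat0, seed = 5, n_starts = 8, steps = 800)
  expect_identical(lapply(poses, function(p) ligand_coords(p$ligand)),
                   lapply(poses2, function(p) ligand_coords(p$ligand)))
  # n_poses = 1 returns only the single lowest-energy pose
  p1 <- dock_ligand(pf$bundle, cat0, seed = 5, n_starts = 8, steps = 800,
                    n_poses = 1)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$energy, poses[[1]]$energy)
  # oracle: exhaustive grid search of the cation position over the box;
  # the MC best pose must land near the grid optimum (which sits by the Asp)
  at <- bundle_atoms(pf$bundle)
  od <- as.matrix(at[at$resid == pf$target$asp_resid &
                     at$atom %in% c("OD1", "OD2"), c("x", "y", "z")])
  best_n <- ligand_coords(poses[[1]]$ligand)[1, ]
  d_asp <- min(sqrt(rowSums(sweep(od, 2, best_n)^2)))
  expect_lt(d_asp, 5)
})

test_that("pose evaluation applies boundary semantics exactly", {
  pf <- pocket_fixture()
  lig <- posed_toy_ligand(pf$bundle, pf$target)
  rec0 <- evaluate_pose(list(ligand = lig, energy = -1), pf$bundle, pf$target)
  # thresholds set exactly AT the measured energies: still accepted
  # ("-0.2 kcal/mol or lower" includes equality)
  stopifnot(rec0$hbond_asp < 0)  # fixture sanity
  tg <- pf$target
  tg$criteria <- acceptance_criteria(
    hbond_asp_max = rec0$hbond_asp,
    hbond_ser_max = min(rec0$hbond_ser, -1e-6),
    aromatic_vdw_max = min(rec0$aromatic_vdw, -1e-6))
  rec1 <- evaluate_pose(list(ligand = lig, energy = -1), pf$bundle, tg)
  if (rec0$hbond_ser < 0 && rec0$aromatic_vdw < 0) {
    expect_true(rec1$accepted)
    # any criterion made infinitesimally stricter: rejected (monotonicity)
    tg2 <- tg
    tg2$criteria$hbond_asp_max <- rec0$hbond_asp - 1e-9
    rec2 <- evaluate_pose(list(ligand = lig, energy = -1), pf$bundle, tg2)
    expect_false(rec2$accepted)
    expect_true("aspartate hydrogen bond" %in% rec2$reasons)
  }
  # a ligand with no aromatic atoms is rejected with an explicit reason
  cat0 <- make_ligand_fixture("toy_cation")
  cat0$atoms[, c("x", "y", "z")] <-
    ligand_coords(cat0) + matrix(pf$bundle$bundle_center, 5, 3, byrow = TRUE)
  rec3 <- evaluate_pose(list(ligand = cat0, energy = 0), pf$bundle, pf$target)
  expect_false(rec3$accepted)
  expect_true("ligand has no aromatic atoms" %in% rec3$reasons)
})

test_that("best_accepted_pose: none, single, tie-break", {
  mk <- function(acc, e) list(accepted = acc, energy = e, compound = "x")
  expect_null(best_accepted_pose(list(mk(FALSE, -5), mk(FALSE, -9))))
  one <- list(mk(FALSE, -9), mk(TRUE, -3))
  expect_equal(best_accepted_pose(one)$energy, -3)
  tie <- list(mk(TRUE, -5), mk(TRUE, -5), mk(TRUE, -2))
  best <- best_accepted_pose(tie)
  expect_equal(best$energy, -5)
  expect_identical(best, tie[[1]])  # lower pose index wins the tie
})

test_that("rank_models matches the enumeration oracle", {
  # synthetic 3-model x 5-compound accept pattern with an enantiomer pair
  tab <- expand.grid(model = c("m1", "m2", "m3"),
                     compound = c("a1", "a2R", "a2S", "b1", "i1"),
                     stringsAsFactors = FALSE)
  tab$agonist <- tab$compound != "i1"
  tab$group <- sub("[RS]$", "", tab$compound)
  tab$accepted <- FALSE
  # m1 accepts both enantiomers of a2 (counts once) and i1
  tab$accepted[tab$model == "m1" & tab$compound %in% c("a2R", "a2S", "i1")] <- TRUE
  # m2 accepts a1, a2R, b1 (3 unique agonists)
  tab$accepted[tab$model == "m2" & tab$compound %in% c("a1", "a2R", "b1")] <- TRUE
  # m3 accepts nothing
  rk <- rank_models(tab, model_scores = c(m1 = 5, m2 = 9, m3 = 1))
  expect_equal(rk$model, c("m2", "m1", "m3"))
  expect_equal(rk$n_agonists, c(3L, 1L, 0L))
  expect_equal(rk$rank, 1:3)
  # permutation invariance of the input rows
  set.seed(1)
  rk2 <- rank_models(tab[sample(nrow(tab)), ],
                     model_scores = c(m1 = 5, m2 = 9, m3 = 1))
  expect_identical(rk, rk2)
  # ties broken by total score (ascending)
  tab2 <- tab
  tab2$accepted[tab2$model == "m3" & tab2$compound == "a1"] <- TRUE
  tab2$accepted[tab2$model == "m1"] <- FALSE
  tab2$accepted[tab2$model == "m1" & tab2$compound == "a1"] <- TRUE
  rk3 <- rank_models(tab2, model_scores = c(m1 = 5, m2 = 9, m3 = 1))
  expect_equal(rk3$model, c("m2", "m3", "m1"))  # m3 (1) before m1 (5)
})

test_that("superposition RMSD: identity, rigid motion, quaternion oracle", {
  b <- small_bundle()
  at <- bundle_atoms(b)
  expect_equal(superpose_and_rmsd(at, at, fit = "ca"), 0, tolerance = 1e-9)
  # rigidly moved copy: zero after superposition
  at2 <- at
  X <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation_about_axis(c(2, 1, 5), 63))
  at2[, c("x", "y", "z")] <- sweep(X, 2, c(10, -4, 2), `+`)
  expect_lt(superpose_and_rmsd(at, at2, fit = "ca"), 1e-9)
  # conformers: equals the independent quaternion oracle
  b3 <- randomize_bundle(b, perturb_amplitudes(2, 10, 10), seed = 2)
  at3 <- bundle_atoms(b3)
  ca_r <- as.matrix(at[at$atom == "CA", c("x", "y", "z")])
  ca_m <- as.matrix(at3[at3$atom == "CA", c("x", "y", "z")])
  expect_equal(superpose_and_rmsd(at, at3, fit = "ca"),
               oracle_quaternion_rmsd(ca_m, ca_r), tolerance = 1e-8)
  # symmetry
  expect_equal(superpose_and_rmsd(at, at3), superpose_and_rmsd(at3, at),
               tolerance = 1e-9)
  # fit and report sets may differ
  r <- superpose_and_rmsd(at, at3, fit = "ca", report = "heavy")
  expect_gt(r, 0)
  # atom mismatch errors name the missing atoms
  at4 <- at3[at3$resid != min(at3$resid), ]
  expect_error(superpose_and_rmsd(at, at4, fit = "ca"), "missing from model")
})

test_that("binding-site box transfer is robust to a displaced helix", {
  b <- small_bundle()
  at <- bundle_atoms(b)
  # centre the box on TM3 so it actually contains atoms
  box <- list(center = helix_center(b$helices[[3]]), size = 10)
  core <- all_ca_resids(b)[!(all_ca_resids(b) %in% b$helices[[1]]$atoms$resid)]
  # reference vs itself: identical selection
  sel <- binding_site_box_transfer(at, box, list(at), core)[[1]]
  inside <- abs(at$x - box$center[1]) <= 5 & abs(at$y - box$center[2]) <= 5 &
            abs(at$z - box$center[3]) <= 5
  expect_identical(sel, which(inside))
  # displacing TM1 (outside the core) does not change the selection of the
  # remaining atoms: superposition uses only conserved-core Calphas
  v <- get_rigid_variables(b, 1); v[["r"]] <- v[["r"]] + 8
  b_shift <- set_rigid_variables(b, 1, v)
  sel2 <- binding_site_box_transfer(bundle_atoms(b_shift), box,
                                    list(bundle_atoms(b_shift)), core)[[1]]
  h1 <- which(bundle_atoms(b)$helix == 1)
  expect_identical(setdiff(sel, h1), setdiff(sel2, h1))
  # empty box: empty selection with a warning
  far_box <- list(center = b$bundle_center + c(500, 0, 0), size = 10)
  expect_warning(
    empty_sel <- binding_site_box_transfer(at, far_box, list(at), core)[[1]],
    "empty")
  expect_length(empty_sel, 0)
})

test_that("APF grids localize the expected chemistry", {
  # single protonated amine: charge and donor channels peak at the nitrogen
  cat0 <- make_ligand_fixture("toy_cation")
  apf <- apf_grid(list(cat0), spacing = 0.5)
  n_pos <- ligand_coords(cat0)[1, ]
  peak_of <- function(ch) {
    idx <- which(apf$grids[[ch]] == max(apf$grids[[ch]]), arr.ind = TRUE)[1, ]
    apf$origin + (idx - 1) * apf$spacing
  }
  expect_lt(sqrt(sum((peak_of("charge") - n_pos)^2)), 1.0)
  expect_lt(sqrt(sum((peak_of("donor") - n_pos)^2)), 1.0)
  # catechol fixture: donor field maximum within 1 A of a hydroxyl hydrogen
  cate <- make_ligand_fixture("toy_catechol_amine")
  # strip the amine so the hydroxyls dominate the donor channel
  keep <- !(cate$atoms$atom %in% c("N1", "HN1", "HN2", "HN3", "C7", "C8"))
  sub <- cate
  old_idx <- which(keep)
  sub$atoms <- cate$atoms[keep, ]
  remap <- match(seq_len(nrow(cate$atoms)), old_idx)
  bmask <- cate$bonds[, 1] %in% old_idx & cate$bonds[, 2] %in% old_idx
  sub$bonds <- cbind(remap[cate$bonds[bmask, 1]], remap[cate$bonds[bmask, 2]],
                     cate$bonds[bmask, 3])
  sub <- new_ligand("catechol", sub$atoms, sub$bonds)
  apf2 <- apf_grid(list(sub), spacing = 0.4)
  idx <- which(apf2$grids$donor == max(apf2$grids$donor), arr.ind = TRUE)[1, ]
  peak <- apf2$origin + (idx - 1) * apf2$spacing
  hpos <- ligand_coords(sub)[sub$atoms$atom %in% c("HO3", "HO4"), ]
  expect_lt(min(sqrt(rowSums(sweep(hpos, 2, peak)^2))), 1.0)
  # oracle: channel value at a probe point equals the direct kernel sum
  probe <- n_pos + c(0.7, -0.3, 0.2)
  props <- helixpack:::apf_atom_properties(cat0)
  want <- sum(props$charge * exp(-rowSums(sweep(ligand_coords(cat0), 2,
                                                probe)^2) / 2))
  got <- helixpack:::cpp_interp3(as.numeric(apf$grids$charge), apf$origin,
                                 apf$spacing, apf$dims,
                                 matrix(probe, 1, 3), 0)
  expect_equal(got, want, tolerance = 0.05)
  # ensemble scaling: channels average over poses; empty ensemble errors
  apf3 <- apf_grid(list(cat0, cat0))
  expect_equal(max(abs(apf3$grids$charge - apf$grids$charge)), 0,
               tolerance = 1e-12)
  expect_error(apf_grid(list()), "empty")
  # non-negative channels for non-negative properties
  expect_gte(min(apf$grids$donor), 0)
  expect_gte(min(apf$grids$size), 0)
})
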