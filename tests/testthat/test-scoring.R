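test_that("molecular volume matches the analytic sphere oracle", {
  sphere <- data.frame(resid = 1L, resname = "ALA", atom = "X",
                       element = "C", x = 0, y = 0, z = 0, charge = 0)
  va <- molecular_volume_area(sphere, probe = 0, spacing = 0.15)
  r <- helixpack:::element_lj("C")$radius
  expect_equal(unname(va["volume"]), 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_equal(unname(va["area"]), 4 * pi * r^2, tolerance = 0.02)
  # moving helices apart increases the accessible area
  b <- small_bundle()
  b2 <- b
  for (h in seq_along(b2$helices)) {
    v <- get_rigid_variables(b2, h); v[["r"]] <- v[["r"]] + 10
    b2 <- set_rigid_variables(b2, h, v)
  }
  a1 <- molecular_volume_area(b, spacing = 0.8)["area"]
  a2 <- molecular_volume_area(b2, spacing = 0.8)["area"]
  expect_gt(a2, a1)
})

test_that("pocket finder: compact fixture clean, missing helix leaves a hole", {
  b <- ideal_bundle()
  pk <- find_pockets(b, min_volume = 20)
  expect_equal(sum(pk$buried), 0)
  # remove a middle helix: a large pocket appears at its former site
  b_open <- new_bundle_state(b$helices[-4])
  pk2 <- find_pockets(b_open, min_volume = 20)
  expect_gt(nrow(pk2), 0)
  expect_gt(max(pk2$volume), 50)
  # empty structure: empty result
  empty <- data.frame(resid = integer(0), resname = character(0),
                      atom = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = numeric(0))
  expect_equal(nrow(find_pockets(empty)), 0)
})

test_that("helix-center distance score is exact analytic geometry", {
  # hexagonal ring of radius 10 plus one central helix: 6 * 10 + 0 = 60
  spec <- fixture_spec(n_helices = 6, ring_radius = 10, helix_length = 14)
  b6 <- make_ideal_bundle(spec)
  center_h <- helixpack:::canonical_helix(rep("ALA", 14))
  center_h$resid <- center_h$resid + 200
  helices <- c(b6$helices, list(helixpack:::new_helix_segment(7, center_h)))
  b7 <- new_bundle_state(helices)
  expect_equal(helix_center_distance_score(b7), 60, tolerance = 1e-6)
  # sliding one helix along its own axis adds its center displacement
  v <- get_rigid_variables(b7, 1)
  v[["z"]] <- v[["z"]] + 5
  b8 <- set_rigid_variables(b7, 1, v)
  # oracle: recompute from the definition
  want <- sum(sqrt(rowSums(sweep(b8$helix_centers, 2, b8$bundle_center)^2)))
  expect_equal(helix_center_distance_score(b8), want, tolerance = 1e-9)
  expect_gt(helix_center_distance_score(b8), helix_center_distance_score(b7))
})

test_that("hydrophilic exposure: poly-Ala zero, Lys orientation, mid-third", {
  expect_equal(unname(hydrophilic_exposure(ideal_bundle())), c(0, 0))
  # Lys at mid-height facing the lipid exposes more than Lys facing the core
  L <- 20; mid <- 10
  seqs <- replicate(7, rep("ALA", L), simplify = FALSE)
  seqs[[1]][mid] <- "LYS"
  ring_az <- 0
  spin_in <- helixpack:::inward_spin(seqs[[1]], mid, "NZ", ring_az, FALSE)
  b_in <- make_ideal_bundle(fixture_spec(sequence = seqs, ring_radius = 12,
                                         spin = c(spin_in, rep(0, 6))))
  b_out <- make_ideal_bundle(fixture_spec(sequence = seqs, ring_radius = 12,
                                          spin = c(spin_in + 180, rep(0, 6))))
  e_in <- hydrophilic_exposure(b_in)["all"]
  e_out <- hydrophilic_exposure(b_out)["all"]
  expect_gt(e_out, e_in)
  # the same Lys at the helix top (outside the mid-third) contributes zero
  seqs_top <- replicate(7, rep("ALA", L), simplify = FALSE)
  seqs_top[[1]][L - 1] <- "LYS"
  b_top <- make_ideal_bundle(fixture_spec(sequence = seqs_top,
                                          ring_radius = 12))
  expect_equal(unname(hydrophilic_exposure(b_top)), c(0, 0))
})

test_that("tilt penalty: zero below 50 degrees, proportional beyond", {
  b <- ideal_bundle()
  expect_equal(tilt_penalty(b), 0)
  # tilt one helix to ~65 degrees; penalty = sum max(0, tilt_i - 50) with
  # tilts recomputed by an independent per-segment oracle
  v <- get_rigid_variables(b, 3)
  v[["tilt"]] <- v[["tilt"]] + 65
  b2 <- set_rigid_variables(b, 3, v)
  got <- tilt_penalty(b2)
  ax <- b2$bundle_axis
  oracle <- 0
  for (h in b2$helices) {
    for (seg in helix_axis_segments(h)) {
      a <- acos(min(1, abs(sum(seg$axis * ax)))) * 180 / pi
      oracle <- oracle + max(0, a - 50)
    }
  }
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_gt(got, 5)  # the 65-degree helix is penalized
  # helices moderately tilted (<= 50 deg) are not penalized
  v <- get_rigid_variables(b, 3)
  v[["tilt"]] <- v[["tilt"]] + 30
  expect_equal(tilt_penalty(set_rigid_variables(b, 3, v)), 0)
})

test_that("elevation penalty is analytic and frame invariant", {
  b <- ideal_bundle()
  expect_lt(elevation_penalty(b), 1e-6)
  v <- get_rigid_variables(b, 2); v[["z"]] <- v[["z"]] + 4
  b2 <- set_rigid_variables(b, 2, v)
  # after recentring: |4*6/7| + 6*|4/7|
  expect_equal(elevation_penalty(b2), 4 * 6 / 7 + 6 * 4 / 7, tolerance = 1e-6)
})

test_that("loop-span penalty follows the 3.2 A per residue rule", {
  b <- ideal_bundle()
  # generous loops: no penalty
  expect_equal(loop_span_penalty(b, loop_lengths = rep(20, 6)), 0)
  # oracle: junction distances vs 3.2 * n
  d <- vapply(1:6, function(j) {
    a <- b$helices[[j]]$atoms; bb <- b$helices[[j + 1]]$atoms
    ca1 <- as.numeric(a[a$resid == max(a$resid) & a$atom == "CA",
                        c("x", "y", "z")])
    ca2 <- as.numeric(bb[bb$resid == min(bb$resid) & bb$atom == "CA",
                         c("x", "y", "z")])
    sqrt(sum((ca1 - ca2)^2))
  }, numeric(1))
  nl <- rep(2, 6)
  want <- sum(pmax(0, d - 3.2 * nl)^2)
  expect_equal(loop_span_penalty(b, loop_lengths = nl), want,
               tolerance = 1e-9)
  # termini 15 A apart with a 10-residue loop (max 32 A): no penalty;
  # 36 A apart with the same loop: (36-32)^2 = 16 (pure formula check)
  expect_equal(max(0, 15 - 3.2 * 10)^2, 0)
  expect_equal(max(0, 36 - 3.2 * 10)^2, 16)
  # a zero-residue loop penalizes any separation
  expect_gt(loop_span_penalty(b, loop_lengths = c(0, rep(20, 5))), 0)
  expect_warning(loop_span_penalty(b, loop_lengths = c(NA, rep(20, 5))),
                 "junction 1")
})

test_that("ligand score responds to the key interactions", {
  pf <- pocket_fixture()
  lig_in <- posed_toy_ligand(pf$bundle, pf$target)
  lig_far <- lig_in
  lig_far$atoms[, c("x", "y", "z")] <- ligand_coords(lig_in) + c(50, 0, 0)
  anchors <- list(list(
    a = list(kind = "protein", resid = pf$target$asp_resid,
             atoms = c("OD1", "OD2")),
    b = list(kind = "ligand", atoms = "N1"), target = 3, halfwidth = 1, k = 1))
  rs <- restraint_set(anchors = anchors)
  st_in <- complex_state(pf$bundle, lig_in, rs)
  st_far <- complex_state(pf$bundle, lig_far, rs)
  ls_in <- ligand_score(st_in, pf$target)
  ls_far <- ligand_score(st_far, pf$target)
  # far ligand: no hbond/vdW contact, large positive restraint energy
  expect_equal(unname(ls_far$terms["ser_hbond"]), 0)
  expect_equal(unname(ls_far$terms["asp_hbond"]), 0)
  expect_equal(unname(ls_far$terms["aromatic_vdw"]), 0, tolerance = 1e-3)
  expect_gt(unname(ls_far$terms["restraint"]), 100)
  # posed ligand scores better (lower) than the same pose rotated away
  expect_lt(ls_in$score, ls_far$score)
  expect_lt(ls_in$terms[["asp_hbond"]] + ls_in$terms[["asp_elec"]], 0)
  # zero weights: zero score
  tg0 <- pf$target
  tg0$ligand_weights[] <- 0
  expect_equal(ligand_score(st_in, tg0)$score, 0)
  # named residue absent: error
  tg_bad <- pf$target; tg_bad$asp_resid <- 9999
  expect_error(ligand_score(st_in, tg_bad), "9999")
})

test_that("total score is a weighted sum, linear in the weights", {
  b <- small_bundle()
  rep <- score_report(complex_state(b))
  expect_equal(rep$total_score,
               rep$packing_score + rep$orientation_score + rep$ligand_score,
               tolerance = 1e-9)
  w <- c(packing = 2, orientation = 0.5, ligand = 3)
  rep2 <- total_score(rep, w)
  expect_equal(rep2$total_score,
               2 * rep$packing_score + 0.5 * rep$orientation_score +
               3 * rep$ligand_score, tolerance = 1e-9)
  # homogeneity
  rep3 <- total_score(rep, 2 * w)
  expect_equal(rep3$total_score, 2 * rep2$total_score, tolerance = 1e-9)
  expect_equal(total_score(rep, c(packing = 0, orientation = 0,
                                  ligand = 0))$total_score, 0)
})

test_that("key-interaction filter demands the salt bridge and aromatics", {
  pf <- pocket_fixture()
  lig_far <- make_ligand_fixture("toy_catechol_amine")
  lig_far$atoms[, c("x", "y", "z")] <-
    ligand_coords(lig_far) + matrix(c(60, 0, 0), nrow(lig_far$atoms), 3,
                                    byrow = TRUE)
  st <- complex_state(pf$bundle, lig_far)
  res <- key_interaction_filter(st, pf$target)
  expect_false(res$pass)
  expect_true(any(grepl("salt-bridge", res$reasons)))
})
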