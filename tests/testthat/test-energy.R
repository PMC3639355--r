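# The surrogate force-field terms, each against an independent oracle or a
# hand calculation.

two_atom_sys <- function(r, element = "C", q = c(0, 0)) {
  atoms <- data.frame(resid = 1:2, resname = "XXX", atom = c("A1", "A2"),
                      element = element, x = c(0, r), y = 0, z = 0,
                      charge = q)
  sys <- list(atoms = data.frame(atom = atoms$atom, resname = atoms$resname,
                                 resid = atoms$resid, element = atoms$element,
                                 charge = q, group = 1L),
              coords = as.matrix(atoms[, c("x", "y", "z")]),
              excl = matrix(integer(0), 0, 2),
              eps = helixpack:::element_lj(atoms$element)$eps,
              sig = helixpack:::element_lj(atoms$element)$sig,
              q = q, donors = matrix(integer(0), 0, 2),
              acceptors = integer(0), aromatic = integer(0),
              groups = list(`1` = 1:2), n_prot = 2L, ligand_idx = integer(0))
  sys
}

test_that("vdW energy: LJ minimum, stage-1 cap, soft-to-hard monotonicity", {
  eps_c <- helixpack:::element_lj("C")$eps
  sig_c <- helixpack:::element_lj("C")$sig
  sys <- two_atom_sys(sig_c * 2^(1 / 6))
  expect_equal(vdw_energy(sys, energy_params(lambda = 0)), -eps_c,
               tolerance = 1e-12)
  # heavily clashing pair at stage-1 softness: at most the 2.0 kcal/mol cap
  for (r in c(0.5, 1.0, 1.5, 2.0)) {
    sysc <- two_atom_sys(r)
    e <- vdw_energy(sysc, energy_params(lambda = 1, vdw_cap = 2))
    expect_lte(e, 2.0 + 1e-12)
    expect_gt(e, 0)
  }
  # for a clashing pair the energy is monotone non-decreasing as lambda -> 0
  sysc <- two_atom_sys(2.0)
  es <- vapply(c(1, 0.5, 0.25, 0.1, 0),
               function(l) vdw_energy(sysc, energy_params(lambda = l)),
               numeric(1))
  expect_true(all(diff(es) >= -1e-12))
})

test_that("engine equals the brute-force double-loop oracle", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 10
    coords <- matrix(runif(3 * n, 0, 8), ncol = 3)
    el <- sample(c("C", "N", "O"), n, replace = TRUE)
    q <- round(runif(n, -0.5, 0.5), 2)
    lj <- helixpack:::element_lj(el)
    excl <- matrix(c(0L, 1L, 2L, 3L), 2, 2, byrow = TRUE)
    sys <- list(atoms = data.frame(atom = paste0("X", 1:n), resname = "XXX",
                                   resid = 1:n, element = el, charge = q,
                                   group = 1L),
                coords = coords, excl = excl, eps = lj$eps, sig = lj$sig,
                q = q, donors = matrix(integer(0), 0, 2),
                acceptors = integer(0), aromatic = integer(0),
                groups = list(`1` = 1:n), n_prot = n, ligand_idx = integer(0))
    for (lambda in c(0, 0.6, 1)) {
      want <- oracle_nb(coords, lj$eps, lj$sig, q, excl, lambda, 2)
      expect_equal(vdw_energy(sys, energy_params(lambda = lambda)),
                   want[["vdw"]], tolerance = 1e-10)
      expect_equal(electrostatic_energy(sys, energy_params(lambda = lambda)),
                   want[["elec"]], tolerance = 1e-10)
    }
  }
})

test_that("electrostatics follow the distance-dependent dielectric", {
  # +1/-1 at 4 A under eps(r) = 4r: 332.06 q1 q2 / (4 r^2) = -5.188...
  sys <- two_atom_sys(4, q = c(1, -1))
  expect_equal(electrostatic_energy(sys), -332.06 / (4 * 16),
               tolerance = 1e-12)
  # neutral atoms contribute nothing
  expect_equal(electrostatic_energy(two_atom_sys(4)), 0)
  # doubling the distance scales the energy by 1/4 (1/r^2 law)
  e4 <- electrostatic_energy(two_atom_sys(4, q = c(1, -1)))
  e8 <- electrostatic_energy(two_atom_sys(8, q = c(1, -1)))
  expect_equal(e8, e4 / 4, tolerance = 1e-12)
  # constant-dielectric alternative: 332.06/(4 r)
  e <- electrostatic_energy(two_atom_sys(4, q = c(1, -1)),
                            energy_params(dielectric = "constant"))
  expect_equal(e, -332.06 / 16, tolerance = 1e-12)
})

test_that("hydrogen-bond term: ideal geometry, angular cutoff, formula", {
  p <- energy_params(hbond_well = 2)
  # ideal: H..A 1.9 A, D-H..A 180 degrees
  D <- c(0, 0, 0); H <- c(1, 0, 0); A <- c(2.9, 0, 0)
  expect_equal(hbond_energy(D, H, A, p), -2, tolerance = 1e-12)
  # 90 degrees: zero
  A90 <- c(1, 1.9, 0)
  expect_equal(hbond_energy(D, H, A90, p), 0)
  # 2.8 A at 160 degrees against an independent reimplementation:
  # rotate the D->H direction by 20 degrees and extend 2.8 A from H
  dirDH <- (H - D) / sqrt(sum((H - D)^2))
  rot <- rotation_about_axis(c(0, 0, 1), 180 - 160)
  A160 <- H + 2.8 * as.numeric(rot %*% dirDH)
  expect_equal(bond_angle(D, H, A160), 160, tolerance = 1e-9)
  fr <- (3.2 - 2.8) / (3.2 - 2.5)
  want <- -2 * fr * cos(160 * pi / 180)^2
  expect_equal(hbond_energy(D, H, A160, p), want, tolerance = 1e-12)
  # hbond energies are never positive
  set.seed(8)
  for (i in 1:50) {
    A <- H + runif(3, -3, 3)
    expect_lte(hbond_energy(D, H, A, p), 0)
  }
})

test_that("tether energy: definition, reference zero, switch-off", {
  b <- small_bundle()
  te <- tethers_from_bundle(b, all_ca_resids(b), k = 1)
  rs <- restraint_set(tethers = te)
  st <- complex_state(b, restraints = rs)
  expect_equal(tether_energy(st$sys, rs, 1, st$coords), 0)
  # single tether displaced 2 A with k = 1, scale 1: 4 kcal/mol
  te1 <- te[1, , drop = FALSE]
  te1$x <- te1$x + 2
  rs1 <- restraint_set(tethers = te1)
  expect_equal(tether_energy(st$sys, rs1, 1, st$coords), 4, tolerance = 1e-12)
  # scale 0 turns tethers off entirely
  expect_equal(tether_energy(st$sys, rs1, 0, st$coords), 0)
})

test_that("flat-bottom anchors: printed windows, boundary, C1 continuity", {
  # both printed windows: 9.5 +/- 1.5 and 12 +/- 2
  for (w in list(c(9.5, 1.5), c(12, 2))) {
    expect_equal(flat_bottom(w[1], w[1], w[2]), 0)
    expect_equal(flat_bottom(w[1] - w[2] + 0.01, w[1], w[2]), 0)
    expect_equal(flat_bottom(w[1] + w[2] - 0.01, w[1], w[2]), 0)
    expect_gt(flat_bottom(w[1] + w[2] + 0.1, w[1], w[2]), 0)
    # C1 continuity at both edges: finite-difference slope tends to zero
    for (edge in c(w[1] - w[2], w[1] + w[2])) {
      h <- 1e-6
      slope <- (flat_bottom(edge + h, w[1], w[2]) -
                flat_bottom(edge - h, w[1], w[2])) / (2 * h)
      expect_lt(abs(slope), 1e-4)
    }
  }
  # distance 15, target 12, halfwidth 2, k 1: (15-14)^2 = 1
  expect_equal(flat_bottom(15, 12, 2, 1), 1)
  # D2-style anchor at 11 A inside [10, 14]: zero
  expect_equal(flat_bottom(11, 12, 2, 1), 0)
  # beta1AR-style anchor exactly at target: zero
  expect_equal(flat_bottom(9.5, 9.5, 1.5, 1), 0)
})

test_that("total energy equals the sum of independently computed terms", {
  pf <- pocket_fixture()
  lig <- posed_toy_ligand(pf$bundle, pf$target)
  anchors <- list(list(
    a = list(kind = "protein", resid = pf$target$asp_resid,
             atoms = c("OD1", "OD2")),
    b = list(kind = "ligand", atoms = "N1"), target = 3, halfwidth = 1,
    k = 1))
  rs <- restraint_set(tethers = tethers_from_bundle(pf$bundle,
                                                    all_ca_resids(pf$bundle)),
                      anchors = anchors)
  st <- complex_state(pf$bundle, lig, rs)
  stage <- stage_config(1)
  e <- total_energy(st, stage)
  expect_equal(e$total, sum(e$terms), tolerance = 1e-9)
  p1 <- st$params; p1$lambda <- stage$lambda
  expect_equal(unname(e$terms["vdw"]), vdw_energy(st$sys, p1, st$coords),
               tolerance = 1e-12)
  expect_equal(unname(e$terms["elec"]),
               electrostatic_energy(st$sys, p1, st$coords), tolerance = 1e-12)
  expect_equal(unname(e$terms["tether"]),
               tether_energy(st$sys, rs, stage$tether_scale, st$coords),
               tolerance = 1e-12)
  expect_equal(unname(e$terms["anchor"]),
               anchor_restraint_energy(st$sys, rs, st$coords),
               tolerance = 1e-12)
  # restraint terms are non-negative
  expect_gte(e$terms[["tether"]], 0)
  expect_gte(e$terms[["anchor"]], 0)
  # adding a displaced tether strictly increases the total
  te2 <- rs$tethers
  te2$z[1] <- te2$z[1] + 3
  st2 <- complex_state(pf$bundle, lig, restraint_set(tethers = te2,
                                                     anchors = anchors))
  expect_gt(total_energy(st2, stage)$total, e$total)
})
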