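# Shared fixtures and independent oracles. Expensive fixtures are built once
# per test run and memoised here.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

ideal_bundle <- function() memo("ideal", make_ideal_bundle())
pocket_fixture <- function() memo("pocket", make_pocket_bundle())

# small bundle for fast MC tests
small_bundle <- function() memo("small",
  make_ideal_bundle(fixture_spec(helix_length = 14)))

all_ca_resids <- function(bundle) {
  at <- bundle_atoms(bundle)
  at$resid[at$atom == "CA"]
}

coords_of <- function(bundle) as.matrix(bundle_atoms(bundle)[, c("x", "y", "z")])

## independent brute-force nonbonded oracle (plain R double loop, no cutoff)
oracle_nb <- function(coords, eps, sig, q, excl, lambda, cap) {
  n <- nrow(coords)
  exmat <- matrix(FALSE, n, n)
  if (nrow(excl)) {
    exmat[excl + 1L] <- TRUE
    exmat[excl[, 2:1, drop = FALSE] + 1L] <- TRUE
  }
  vdw <- 0; elec <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (exmat[i, j]) next
    r2 <- sum((coords[i, ] - coords[j, ])^2)
    e <- sqrt(eps[i] * eps[j]); s <- 0.5 * (sig[i] + sig[j])
    s6 <- (s * s / r2)^3
    elj <- 4 * e * (s6 * s6 - s6)
    if (elj > 0 && lambda > 0) elj <- elj / (1 + lambda * elj / cap)
    vdw <- vdw + elj
    elec <- elec + 332.06 * q[i] * q[j] / (4 * r2)
  }
  c(vdw = vdw, elec = elec)
}

## independent quaternion-based superposition (Horn's method) oracle
oracle_quaternion_rmsd <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  S <- crossprod(P, Q)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lmax) / nrow(P)
  sqrt(max(0, msd))
}

## analytically kinked helix: two straight ideal segments joined at an angle
kinked_helix_atoms <- function(n1 = 10, n2 = 10, kink_deg = 30) {
  a <- build_peptide(rep("ALA", n1 + n2),
                     phi = c(rep(-57, n1), rep(-57, n2)),
                     psi = c(rep(-47, n1 - 1), -47 + kink_deg, rep(-47, n2)))
  a
}

random_vars <- function() {
  c(r = runif(1, 2, 15), azimuth = runif(1, -179, 179),
    z = runif(1, -5, 5), tilt = runif(1, 0.5, 170),
    tilt_azimuth = runif(1, -179, 179), spin = runif(1, -179, 179))
}

expect_vars_equal <- function(got, want, tol = 1e-6) {
  # angles compared modulo 360
  expect_lt(abs(got[["r"]] - want[["r"]]), tol)
  expect_lt(abs(got[["z"]] - want[["z"]]), tol)
  for (k in c("azimuth", "tilt", "tilt_azimuth", "spin")) {
    d <- (got[[k]] - want[[k]]) %% 360
    expect_lt(min(d, 360 - d), tol)
  }
}

## a ligand pose forming a salt bridge to the Asp, a hydrogen bond to a Ser
## and an aromatic contact with the pocket Phe, built by construction:
## amine N on the Asp->Ser axis 2.9 A from the carboxylate, catechol axis
## pointing at the serine, spin chosen to bring the ring near the Phe
posed_toy_ligand <- function(bundle, target) {
  lig <- make_ligand_fixture("toy_catechol_amine")
  at <- bundle_atoms(bundle)
  od <- as.matrix(at[at$resid == target$asp_resid &
                     at$atom %in% c("OD1", "OD2"), c("x", "y", "z")])
  og_all <- as.matrix(at[at$resid %in% target$ser_resids &
                         at$atom == "OG", c("x", "y", "z")])
  ser_hg <- as.matrix(at[at$resid %in% target$ser_resids &
                         at$atom == "HG", c("x", "y", "z")])
  phe <- as.matrix(at[at$resid == target$phe_filter &
                      at$atom %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                      c("x", "y", "z")])
  odc <- colMeans(od)
  ogm <- colMeans(og_all)
  dirv <- (ogm - odc) / sqrt(sum((ogm - odc)^2))
  n_target <- odc + 2.9 * dirv
  X <- ligand_coords(lig)
  ni <- which(lig$atoms$atom == "N1")
  oi <- which(lig$atoms$atom == "O3")
  v1 <- X[oi, ] - X[ni, ]; v1 <- v1 / sqrt(sum(v1^2))
  ax <- c(v1[2] * dirv[3] - v1[3] * dirv[2],
          v1[3] * dirv[1] - v1[1] * dirv[3],
          v1[1] * dirv[2] - v1[2] * dirv[1])
  ang <- acos(max(-1, min(1, sum(v1 * dirv)))) * 180 / pi
  X <- sweep(X, 2, X[ni, ])
  if (sqrt(sum(ax^2)) > 1e-8) X <- t(rotation_about_axis(ax, ang) %*% t(X))
  X <- sweep(X, 2, n_target, `+`)
  ring_idx <- which(lig$atoms$aromatic)
  hs <- which(lig$atoms$atom %in% c("HO3", "HO4"))
  os <- which(lig$atoms$atom %in% c("O3", "O4"))
  best <- NULL
  for (spin in seq(0, 350, by = 10)) {
    R <- rotation_about_axis(dirv, spin)
    Xs <- t(R %*% t(sweep(X, 2, n_target)))
    Xs <- sweep(Xs, 2, n_target, `+`)
    d_ring <- min_pair_distance(Xs[ring_idx, , drop = FALSE], phe)
    ## best achievable serine hydrogen bond in either direction
    e_ser <- 0
    for (s in seq_len(nrow(og_all))) {
      for (o in os)
        e_ser <- min(e_ser, hbond_energy(og_all[s, ], ser_hg[s, ], Xs[o, ]))
    }
    for (h in seq_along(hs)) {
      for (s in seq_len(nrow(og_all)))
        e_ser <- min(e_ser, hbond_energy(Xs[os[h], ], Xs[hs[h], ], og_all[s, ]))
    }
    score <- e_ser + max(0, d_ring - 4.0)
    if (is.null(best) || score < best$score)
      best <- list(score = score, X = Xs)
  }
  lig$atoms[, c("x", "y", "z")] <- best$X
  lig
}
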