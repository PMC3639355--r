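## Synthetic fixtures: idealized 7TM-like bundles and graded decoy sets.
## These are first-class generators (deterministic per seed), used both by
## the test suite and as null references for the scoring terms.

#' Fixture specification for an idealized helix bundle
#'
#' @param n_helices number of helices (default 7).
#' @param helix_length residues per helix (default 20).
#' @param ring_radius radius of the ring of helix axes in Angstrom. The
#'   default 11.5 A gives nearest-neighbour axis separations of ~10 A,
#'   typical of 7TM bundles.
#' @param sequence either a single three-letter residue name used for every
#'   position (default "ALA") or a list of per-helix character vectors of
#'   length `helix_length`.
#' @param spin optional numeric vector of per-helix spin angles (degrees)
#'   about each helix axis; default 0.
#' @param loop_gap residue-numbering gap between consecutive helix spans
#'   (emulates excised loops; default 10).
#' @param seed integer seed recorded in the spec (generation is
#'   deterministic; the seed matters only for downstream decoys).
#' @return object of class FixtureSpec.
#' @export
fixture_spec <- function(n_helices = 7, helix_length = 20, ring_radius = 11.5,
                         sequence = "ALA", spin = 0, loop_gap = 10, seed = 1) {
  stopifnot(n_helices >= 2, helix_length >= 6, ring_radius > 0)
  structure(list(n_helices = n_helices, helix_length = helix_length,
                 ring_radius = ring_radius, sequence = sequence,
                 spin = rep_len(spin, n_helices), loop_gap = loop_gap,
                 seed = seed),
            class = "FixtureSpec")
}

## A canonical ideal helix: built with (phi, psi) = (-57, -47), CA-centred at
## the origin, principal axis along +z.
canonical_helix <- function(sequence, chi = NULL) {
  atoms <- build_peptide(sequence, chi = chi)
  X <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- X[atoms$atom == "CA", , drop = FALSE]
  m <- colMeans(ca)
  u <- principal_axis(ca)
  seedv <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(seedv - sum(seedv * u) * u)
  e2 <- cross3(u, e1)
  M <- cbind(e1, e2, u)
  atoms[, c("x", "y", "z")] <- sweep(X, 2, m) %*% M
  atoms
}

#' Build an idealized antiparallel helix bundle
#'
#' Ideal alpha-helices (phi = -57, psi = -47) are placed on a ring with axes
#' parallel to z, alternating up/down orientation as in a 7TM topology.
#' Residue numbering leaves a `loop_gap` between spans.
#'
#' @param spec a [fixture_spec()].
#' @param chi optional list (per helix) of per-residue side-chain torsion
#'   overrides passed to [build_peptide()].
#' @return a BundleState.
#' @export
make_ideal_bundle <- function(spec = fixture_spec(), chi = NULL) {
  n <- spec$n_helices
  L <- spec$helix_length
  seqs <- if (is.list(spec$sequence)) spec$sequence
          else replicate(n, rep(spec$sequence, L), simplify = FALSE)
  helices <- vector("list", n)
  offset <- 0L
  for (k in seq_len(n)) {
    atoms <- canonical_helix(seqs[[k]], chi = chi[[k]])
    X <- as.matrix(atoms[, c("x", "y", "z")])
    if (spec$spin[k] != 0) X <- X %*% t(rot_z(spec$spin[k]))
    if (k %% 2 == 0) X <- X %*% t(rot_x(180))  # antiparallel alternation
    az <- 360 * (k - 1) / n
    pos <- spec$ring_radius * c(cos(az * pi / 180), sin(az * pi / 180), 0)
    atoms[, c("x", "y", "z")] <- sweep(X, 2, pos, `+`)
    atoms$resid <- atoms$resid + offset
    helices[[k]] <- new_helix_segment(k, atoms)
    offset <- offset + L + spec$loop_gap
  }
  ## steric feasibility of the ring radius
  for (k in seq_len(n - 1)) {
    a <- as.matrix(helices[[k]]$atoms[, c("x", "y", "z")])
    b <- as.matrix(helices[[k + 1]]$atoms[, c("x", "y", "z")])
    if (min_pair_distance(a, b) < 3.0)
      stop("infeasible ring radius: inter-helix contact below 3.0 A")
  }
  bundle <- new_bundle_state(helices)
  bundle$spec <- spec
  bundle
}

#' Residue spans of a bundle (for extract_helices round trips)
#' @param bundle a BundleState.
#' @export
bundle_spans <- function(bundle) lapply(bundle$helices, function(h) h$span)

## spin angle that points the side chain of local residue `p` toward the
## bundle center for a helix placed at ring azimuth `ring_az`
inward_spin <- function(seq_vec, p, tip_atom, ring_az, flipped) {
  atoms <- canonical_helix(seq_vec)
  tip <- atoms[atoms$resid == p & atoms$atom == tip_atom, ]
  if (!nrow(tip)) stop("tip atom not found for spin calculation")
  az_tip <- atan2(tip$y[1], tip$x[1]) * 180 / pi
  target <- ring_az + 180
  if (flipped) -(target) - az_tip else target - az_tip
}

#' Idealized 7TM bundle with a monoaminergic-like binding pocket
#'
#' A poly-Ala bundle in which TM3 carries an aspartate, TM5 two serines
#' (i, i+4) and TM6 two consecutive phenylalanines, each spun so the side
#' chain faces the bundle interior -- the synthetic stand-in for the
#' D3.32 / S5.42+S5.46 / F6.51+F6.52 motif of aminergic receptors.
#'
#' @param spec a [fixture_spec()] (sequence field ignored).
#' @return list with `bundle` (BundleState), `target` (a [target_spec()]
#'   naming the pocket residues) and `key_resids`.
#' @export
make_pocket_bundle <- function(spec = fixture_spec(ring_radius = 12.5)) {
  n <- spec$n_helices
  L <- spec$helix_length
  stopifnot(n >= 6, L >= 14)
  mid <- ceiling(L / 2)
  span_start <- function(k) (k - 1) * (L + spec$loop_gap) + 1
  seqs <- replicate(n, rep("ALA", L), simplify = FALSE)
  seqs[[3]][mid] <- "ASP"
  seqs[[5]][c(mid - 2, mid + 2)] <- "SER"
  seqs[[6]][c(mid, mid + 1)] <- "PHE"
  ring_az <- function(k) 360 * (k - 1) / n
  spins <- rep(0, n)
  spins[3] <- inward_spin(seqs[[3]], mid, "CG", ring_az(3), FALSE)
  spins[5] <- inward_spin(seqs[[5]], mid - 2, "OG", ring_az(5), FALSE)
  spins[6] <- inward_spin(seqs[[6]], mid, "CG", ring_az(6), TRUE)
  sp <- fixture_spec(n_helices = n, helix_length = L,
                     ring_radius = spec$ring_radius, sequence = seqs,
                     spin = spins, loop_gap = spec$loop_gap,
                     seed = spec$seed)
  bundle <- make_ideal_bundle(sp)
  key <- list(asp = span_start(3) + mid - 1,
              ser = span_start(5) + c(mid - 3, mid + 1),
              phe = span_start(6) + c(mid - 1, mid))
  ## filter on the Phe whose ring faces the pocket (the first of the pair)
  target <- target_spec(ser_resids = key$ser, asp_resid = key$asp,
                        phe_resids = key$phe, phe_filter = key$phe[1],
                        anchor_target = 12, anchor_halfwidth = 2)
  list(bundle = bundle, target = target, key_resids = key)
}

#' Graded decoy set
#'
#' Applies [randomize_bundle()] at each amplitude level (fractions of the
#' given base amplitudes), producing labelled decoys for scoring calibration.
#'
#' @param bundle a BundleState.
#' @param levels numeric vector of amplitude fractions (default
#'   c(0.25, 0.5, 1)).
#' @param n_per_level decoys per level (default 20).
#' @param base a [perturb_amplitudes()] giving the 100% level.
#' @param seed integer seed.
#' @return list with elements `decoys` (list of BundleState), `level`
#'   (numeric vector) and `seeds` (integer vector).
#' @export
make_decoy_set <- function(bundle, levels = c(0.25, 0.5, 1), n_per_level = 20,
                           base = perturb_amplitudes(), seed = 1) {
  decoys <- list(); lev <- numeric(0); seeds <- integer(0)
  k <- 0L
  for (f in levels) {
    amp <- perturb_amplitudes(max_translation = f * base$max_translation,
                              max_tilt = f * base$max_tilt,
                              max_spin = f * base$max_spin,
                              ligand_min_distance = base$ligand_min_distance)
    for (i in seq_len(n_per_level)) {
      k <- k + 1L
      s <- seed * 10000L + k
      decoys[[k]] <- randomize_bundle(bundle, amp, seed = s)
      lev[k] <- f; seeds[k] <- s
    }
  }
  list(decoys = decoys, level = lev, seeds = seeds)
}

#' Ca RMSD between two conformations of the same bundle (no superposition)
#' @param a,b BundleStates with identical helix definitions.
#' @export
bundle_ca_rmsd <- function(a, b) {
  A <- do.call(rbind, lapply(a$helices, helix_ca_coords))
  B <- do.call(rbind, lapply(b$helices, helix_ca_coords))
  rmsd_coords(A, B)
}
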