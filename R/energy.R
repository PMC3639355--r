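## Surrogate force field: Lennard-Jones 6-12 with per-element parameters and
## soft-core interpolation, Coulomb term with a distance-dependent dielectric
## eps(r) = 4r, a 10-12-like hydrogen-bond well, harmonic Calpha tethers and
## flat-bottom anchor restraints. This replaces the proprietary
## internal-coordinate force field the method was originally run with; the
## staging/restraint/scoring logic, not the energy magnitudes, is the point.

ELEMENT_LJ <- data.frame(
  element = c("C", "N", "O", "S", "H"),
  eps = c(0.066, 0.170, 0.210, 0.250, 0.015),
  sig = c(3.50, 3.25, 2.96, 3.55, 2.42),
  radius = c(1.70, 1.55, 1.52, 1.80, 1.10),
  stringsAsFactors = FALSE)

#' Energy parameters for the surrogate force field
#'
#' @param lambda soft-core softness in [0, 1]; 1 = fully soft (stage-1
#'   repulsion capped at `vdw_cap` per pair), 0 = plain Lennard-Jones.
#' @param vdw_cap maximal per-pair repulsive vdW energy at lambda = 1,
#'   kcal/mol (default 2.0, the stage-1 limit).
#' @param dielectric "distance" for eps(r) = 4r (default) or "constant" for
#'   eps = 4.
#' @param hbond_well hydrogen-bond well depth, kcal/mol (default 2.0).
#' @param hbond_full H..acceptor range treated as full-strength upper edge
#'   (default 2.5 A); the well fades linearly to zero at `hbond_fade`
#'   (default 3.2 A).
#' @return object of class EnergyParams.
#' @export
energy_params <- function(lambda = 0, vdw_cap = 2.0, dielectric = "distance",
                          hbond_well = 2.0, hbond_full = 2.5,
                          hbond_fade = 3.2) {
  stopifnot(lambda >= 0, lambda <= 1, vdw_cap > 0,
            dielectric %in% c("distance", "constant"))
  structure(list(lambda = lambda, vdw_cap = vdw_cap, dielectric = dielectric,
                 hbond_well = hbond_well, hbond_full = hbond_full,
                 hbond_fade = hbond_fade),
            class = "EnergyParams")
}

element_lj <- function(element) {
  i <- match(element, ELEMENT_LJ$element)
  i[is.na(i)] <- 1  # default to carbon for exotic elements
  ELEMENT_LJ[i, c("eps", "sig", "radius")]
}

## 1-2/1-3/1-4 exclusion pairs (0-based) from a bond list over n atoms
exclusions_from_bonds <- function(bonds, n) {
  if (!nrow(bonds)) return(matrix(integer(0), 0, 2))
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- new.env()
  addp <- function(i, j) {
    if (i == j) return()
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    assign(key, c(min(i, j), max(i, j)), envir = out)
  }
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    for (j in n1) {
      addp(i, j)
      for (k in adj[[j]]) {
        addp(i, k)
        for (l in adj[[k]]) addp(i, l)
      }
    }
  }
  m <- do.call(rbind, as.list(out))
  if (is.null(m)) return(matrix(integer(0), 0, 2))
  m - 1L  # 0-based
}

#' Assemble a protein/ligand complex into an energy system
#'
#' Flattens a bundle plus optional ligand into coordinate/parameter arrays,
#' builds the bonded-exclusion list, and perceives hydrogen-bond donors
#' (heavy atom + bound H), acceptors and aromatic atoms.
#'
#' @param bundle a BundleState.
#' @param ligand optional Ligand.
#' @return list used by the energy and scoring routines.
#' @export
complex_system <- function(bundle, ligand = NULL) {
  prot <- bundle_atoms(bundle)
  n_prot <- nrow(prot)
  tables <- list(data.frame(atom = prot$atom, resname = prot$resname,
                            resid = prot$resid, element = prot$element,
                            charge = prot$charge, group = prot$helix,
                            stringsAsFactors = FALSE))
  coords <- as.matrix(prot[, c("x", "y", "z")])
  bonds <- list()
  off <- 0L
  for (h in bundle$helices) {
    b <- peptide_bond_list(h$atoms)
    if (nrow(b)) bonds[[length(bonds) + 1]] <- b + off
    off <- off + nrow(h$atoms)
  }
  aromatic <- prot$resname == "PHE" &
    prot$atom %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  if (!is.null(ligand)) {
    la <- ligand$atoms
    tables[[2]] <- data.frame(atom = la$atom, resname = "LIG",
                              resid = max(prot$resid) + 1L,
                              element = la$element, charge = la$charge,
                              group = 0L, stringsAsFactors = FALSE)
    coords <- rbind(coords, as.matrix(la[, c("x", "y", "z")]))
    if (nrow(ligand$bonds))
      bonds[[length(bonds) + 1]] <- ligand$bonds[, 1:2, drop = FALSE] + n_prot
    aromatic <- c(aromatic, ligand$atoms$aromatic)
  }
  atoms <- do.call(rbind, tables)
  n <- nrow(atoms)
  bondmat <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), 0, 2)
  excl <- exclusions_from_bonds(bondmat, n)
  lj <- element_lj(atoms$element)
  ## hydrogen-bond perception from the bond graph
  adj <- vector("list", n)
  if (nrow(bondmat)) for (k in seq_len(nrow(bondmat))) {
    i <- bondmat[k, 1]; j <- bondmat[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  donors <- list()
  for (i in which(atoms$element == "H")) {
    heavy <- adj[[i]]
    heavy <- heavy[atoms$element[heavy] %in% c("N", "O")]
    if (length(heavy)) donors[[length(donors) + 1]] <- c(heavy[1], i)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else matrix(integer(0), 0, 2)
  has_h <- rep(FALSE, n)
  if (nrow(donors)) has_h[donors[, 1]] <- TRUE
  heavy_deg <- vapply(seq_len(n), function(i)
    sum(atoms$element[adj[[i]]] != "H"), integer(1))
  acceptors <- which(atoms$element == "O" |
                     (atoms$element == "N" & !has_h & heavy_deg <= 2 &
                      atoms$charge <= 0))
  groups <- split(seq_len(n), atoms$group)
  list(atoms = atoms, coords = coords, bonds = bondmat, excl = excl,
       eps = lj$eps, sig = lj$sig, radius = lj$radius, q = atoms$charge,
       donors = donors, acceptors = acceptors, aromatic = which(aromatic),
       groups = groups, n_prot = n_prot,
       ligand_idx = if (is.null(ligand)) integer(0) else (n_prot + 1):n)
}

#' van der Waals energy of a system
#'
#' Pairwise Lennard-Jones 6-12 (Lorentz-Berthelot combining) with 1-2/1-3/1-4
#' exclusions and soft-core interpolation E/(1 + lambda E / cap) of the
#' repulsive branch.
#'
#' @param sys a [complex_system()].
#' @param params an [energy_params()].
#' @param coords optional coordinate override (n-by-3).
#' @param sel_a,sel_b optional 1-based atom index sets; with both given, only
#'   cross interactions are summed.
#' @return energy in kcal/mol.
#' @export
vdw_energy <- function(sys, params = energy_params(), coords = NULL,
                       sel_a = NULL, sel_b = NULL) {
  nb_energy(sys, params, coords, sel_a, sel_b)[["vdw"]]
}

#' Electrostatic energy of a system
#'
#' Coulomb sum, conversion 332.06 kcal A/(mol e^2), with the distance-
#' dependent dielectric eps(r) = 4r (so E ~ q1 q2 / (4 r^2)) or constant 4.
#'
#' @inheritParams vdw_energy
#' @return energy in kcal/mol.
#' @export
electrostatic_energy <- function(sys, params = energy_params(), coords = NULL,
                                 sel_a = NULL, sel_b = NULL) {
  nb_energy(sys, params, coords, sel_a, sel_b)[["elec"]]
}

nb_energy <- function(sys, params, coords = NULL, sel_a = NULL, sel_b = NULL) {
  x <- coords %||% sys$coords
  if (any(!is.finite(x))) stop("non-finite coordinates")
  sa <- if (is.null(sel_a)) seq_len(nrow(x)) else sel_a
  sb <- if (is.null(sel_b)) integer(0) else sel_b
  cpp_nb_energy(x, sys$eps, sys$sig, sys$q, sys$excl,
                as.integer(sa - 1L), as.integer(sb - 1L),
                params$lambda, params$vdw_cap,
                if (params$dielectric == "distance") 0L else 1L)
}

#' Hydrogen-bond energy of a single donor/acceptor geometry
#'
#' Well depth times a distance switch on the H..acceptor separation (full
#' below `hbond_full`, fading to zero at `hbond_fade`) times an angular
#' factor cos^2 of the donor-H..acceptor angle for angles beyond 90 degrees.
#' Always <= 0.
#'
#' @param donor length-3 coordinate of the donor heavy atom.
#' @param hydrogen length-3 coordinate of the donor hydrogen.
#' @param acceptor length-3 coordinate of the acceptor atom.
#' @param params an [energy_params()].
#' @return energy in kcal/mol (<= 0).
#' @export
hbond_energy <- function(donor, hydrogen, acceptor, params = energy_params()) {
  r <- vnorm(acceptor - hydrogen)
  fr <- if (r <= params$hbond_full) 1
        else if (r >= params$hbond_fade) 0
        else (params$hbond_fade - r) / (params$hbond_fade - params$hbond_full)
  if (fr == 0) return(0)
  theta <- bond_angle(donor, hydrogen, acceptor)
  if (theta <= 90) return(0)
  -params$hbond_well * fr * cos(theta * pi / 180)^2
}

## All donor->acceptor hydrogen bonds between two atom sets (or within one)
system_hbond_energy <- function(sys, params = energy_params(), coords = NULL,
                                sel_a = NULL, sel_b = NULL) {
  x <- coords %||% sys$coords
  if (!nrow(sys$donors) || !length(sys$acceptors)) return(0)
  total <- 0
  pairs_in <- function(didx, aidx) {
    e <- 0
    for (k in didx) {
      d <- sys$donors[k, 1]; h <- sys$donors[k, 2]
      for (a in aidx) {
        if (a == d) next
        if (vnorm(x[a, ] - x[h, ]) < params$hbond_fade)
          e <- e + hbond_energy(x[d, ], x[h, ], x[a, ], params)
      }
    }
    e
  }
  if (is.null(sel_a)) {
    total <- pairs_in(seq_len(nrow(sys$donors)), sys$acceptors)
  } else {
    sb <- sel_b %||% setdiff(seq_len(nrow(x)), sel_a)
    da <- which(sys$donors[, 1] %in% sel_a)
    db <- which(sys$donors[, 1] %in% sb)
    total <- pairs_in(da, intersect(sys$acceptors, sb)) +
             pairs_in(db, intersect(sys$acceptors, sel_a))
  }
  total
}

#' Tether and anchor restraints
#'
#' Tethers are harmonic distance restraints from model Calpha atoms to fixed
#' reference points with target 0 A (conserved residues keep the homology
#' model's position). Anchors are flat-bottom quadratic distance restraints
#' between two atoms or atom-set centroids.
#'
#' @param tethers data.frame with columns resid, x, y, z, k (kcal/mol/A^2).
#' @param anchors list of anchors, each
#'   `list(a = endpoint, b = endpoint, target, halfwidth, k)` where an
#'   endpoint is `list(kind = "protein", resid, atoms)` or
#'   `list(kind = "ligand", atoms)` (atom names; centroid used).
#' @return object of class RestraintSet.
#' @export
restraint_set <- function(tethers = NULL, anchors = list()) {
  if (is.null(tethers))
    tethers <- data.frame(resid = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), k = numeric(0))
  for (a in anchors) stopifnot(a$halfwidth > 0, a$k >= 0)
  structure(list(tethers = tethers, anchors = anchors), class = "RestraintSet")
}

#' Tethers for conserved residues of a bundle
#'
#' Builds a [restraint_set()] tether table pinning the Calpha atoms of the
#' given residues at their current positions.
#'
#' @param bundle a BundleState (the reference/homology model).
#' @param resids integer residue numbers to tether.
#' @param k force constant kcal/mol/A^2 (default 1).
#' @export
tethers_from_bundle <- function(bundle, resids, k = 1) {
  at <- bundle_atoms(bundle)
  ca <- at[at$atom == "CA" & at$resid %in% resids, ]
  missing <- setdiff(resids, ca$resid)
  if (length(missing))
    stop("tether residue(s) not in bundle: ", paste(missing, collapse = ", "))
  data.frame(resid = ca$resid, x = ca$x, y = ca$y, z = ca$z, k = k)
}

#' Tether restraint energy
#'
#' Sum of k * scale * d^2 over tethers, d being the displacement of each
#' tethered Calpha from its reference point (target 0 A).
#'
#' @param sys a [complex_system()].
#' @param restraints a [restraint_set()].
#' @param scale stage-dependent strength scale (0 switches tethers off).
#' @param coords optional coordinate override.
#' @return energy in kcal/mol (>= 0).
#' @export
tether_energy <- function(sys, restraints, scale = 1, coords = NULL) {
  te <- restraints$tethers
  if (!nrow(te) || scale == 0) return(0)
  x <- coords %||% sys$coords
  idx <- match(paste(te$resid, "CA"), paste(sys$atoms$resid, sys$atoms$atom))
  if (anyNA(idx)) stop("tethered residue(s) missing from system")
  d2 <- rowSums((x[idx, , drop = FALSE] - as.matrix(te[, c("x", "y", "z")]))^2)
  sum(te$k * scale * d2)
}

resolve_endpoint <- function(sys, ep, coords) {
  if (ep$kind == "protein") {
    sel <- which(sys$atoms$resid == ep$resid & sys$atoms$atom %in% ep$atoms)
    if (!length(sel))
      stop("anchor endpoint not found: residue ", ep$resid, " atoms ",
           paste(ep$atoms, collapse = "/"))
  } else {
    sel <- sys$ligand_idx[match(ep$atoms, sys$atoms$atom[sys$ligand_idx])]
    if (anyNA(sel))
      stop("anchor endpoint not found on ligand: ",
           paste(ep$atoms, collapse = "/"))
  }
  colMeans(coords[sel, , drop = FALSE])
}

#' Flat-bottom anchor restraint energy
#'
#' Zero inside [target - halfwidth, target + halfwidth], k * excess^2
#' outside (C1-continuous at the boundaries).
#'
#' @inheritParams tether_energy
#' @return energy in kcal/mol (>= 0).
#' @export
anchor_restraint_energy <- function(sys, restraints, coords = NULL) {
  if (!length(restraints$anchors)) return(0)
  x <- coords %||% sys$coords
  total <- 0
  for (a in restraints$anchors) {
    pa <- resolve_endpoint(sys, a$a, x)
    pb <- resolve_endpoint(sys, a$b, x)
    total <- total + flat_bottom(vnorm(pa - pb), a$target, a$halfwidth, a$k)
  }
  total
}

#' Flat-bottom quadratic penalty
#' @param d observed distance; @param target,halfwidth window; @param k force
#'   constant.
#' @export
flat_bottom <- function(d, target, halfwidth, k = 1) {
  excess <- abs(d - target) - halfwidth
  if (excess <= 0) 0 else k * excess^2
}

## Ligand torsion strain: 3-fold cosine over rotatable bonds
ligand_torsion_energy <- function(sys, ligand, coords = NULL, v3 = 0.3) {
  if (is.null(ligand) || !length(ligand$rotatable)) return(0)
  x <- coords %||% sys$coords
  off <- sys$n_prot
  e <- 0
  for (rb in ligand$rotatable) {
    phi <- dihedral(x[off + rb$path[1], ], x[off + rb$path[2], ],
                    x[off + rb$path[3], ], x[off + rb$path[4], ])
    e <- e + 0.5 * v3 * (1 + cos(3 * phi * pi / 180))
  }
  e
}

#' Total energy with per-term breakdown
#'
#' @param state a ComplexState (see [complex_state()]).
#' @param stage a [stage_config()] supplying the vdW softness lambda and the
#'   tether scale; defaults to stage 1 settings.
#' @return list with `total` and a named `terms` vector (vdw, elec, hbond,
#'   torsion, tether, anchor).
#' @export
total_energy <- function(state, stage = stage_config(1)) {
  params <- state$params
  params$lambda <- stage$lambda
  nb <- nb_energy(state$sys, params, state$coords)
  terms <- c(
    vdw = nb[["vdw"]],
    elec = nb[["elec"]],
    hbond = system_hbond_energy(state$sys, params, state$coords),
    torsion = ligand_torsion_energy(state$sys, state$ligand, state$coords),
    tether = tether_energy(state$sys, state$restraints, stage$tether_scale,
                           state$coords),
    anchor = anchor_restraint_energy(state$sys, state$restraints, state$coords))
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad)) stop("non-finite energy term(s): ", paste(bad, collapse = ", "))
  list(total = sum(terms), terms = terms)
}

#' Bundle + ligand + restraints as an optimizable state
#'
#' @param bundle a BundleState.
#' @param ligand optional Ligand.
#' @param restraints a [restraint_set()].
#' @param params an [energy_params()].
#' @return object of class ComplexState with the assembled energy system and
#'   a live coordinate matrix.
#' @export
complex_state <- function(bundle, ligand = NULL, restraints = restraint_set(),
                          params = energy_params()) {
  sys <- complex_system(bundle, ligand)
  structure(list(bundle = bundle, ligand = ligand, restraints = restraints,
                 params = params, sys = sys, coords = sys$coords),
            class = "ComplexState")
}

#' Write a ComplexState's current coordinates back into bundle and ligand
#' @param state a ComplexState.
#' @return the state with `bundle` and `ligand` coordinate tables updated.
#' @export
sync_state <- function(state) {
  off <- 0L
  for (i in seq_along(state$bundle$helices)) {
    ni <- nrow(state$bundle$helices[[i]]$atoms)
    state$bundle$helices[[i]]$atoms[, c("x", "y", "z")] <-
      state$coords[(off + 1):(off + ni), , drop = FALSE]
    off <- off + ni
  }
  state$bundle <- recompute_derived(state$bundle)
  ## refresh rigid variables from coordinates
  for (i in seq_along(state$bundle$helices)) {
    pl <- placement_from_coords(state$bundle$helices[[i]],
                                state$bundle$local[[i]], state$bundle$frame)
    state$bundle$rigid_vars[i, ] <- vars_from_placement(pl$p, pl$R)
  }
  if (!is.null(state$ligand)) {
    state$ligand$atoms[, c("x", "y", "z")] <-
      state$coords[state$sys$ligand_idx, , drop = FALSE]
  }
  state
}

#' Minimal heavy-atom distance between two coordinate sets
#' @param a,b n-by-3 matrices.
#' @export
min_pair_distance <- function(a, b) cpp_min_pair_distance(a, b)
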