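## Model selection by ligand docking performance: grid-map Monte Carlo
## docking, pose evaluation against hydrogen-bond and aromatic-contact
## criteria, ranking of receptor models by unique accepted agonists, RMSD
## analytics and atom-property-field summaries of accepted pose ensembles.

#' Docking-pose acceptance criteria
#'
#' A pose is accepted only if the hydrogen bond from the protonated amine to
#' the TM3 aspartate is -0.2 kcal/mol or lower, a hydrogen bond from any
#' ligand atom to at least one TM5 serine is -0.2 kcal/mol or lower, and the
#' aromatic vdW energy against the TM6 phenylalanine is -0.3 kcal/mol or
#' lower.
#'
#' @param hbond_asp_max,hbond_ser_max,aromatic_vdw_max thresholds in
#'   kcal/mol (all <= 0).
#' @return object of class AcceptanceCriteria.
#' @export
acceptance_criteria <- function(hbond_asp_max = -0.2, hbond_ser_max = -0.2,
                                aromatic_vdw_max = -0.3) {
  stopifnot(hbond_asp_max <= 0, hbond_ser_max <= 0, aromatic_vdw_max <= 0)
  structure(list(hbond_asp_max = hbond_asp_max,
                 hbond_ser_max = hbond_ser_max,
                 aromatic_vdw_max = aromatic_vdw_max),
            class = "AcceptanceCriteria")
}

## heavy-atom RMSD between two conformers of the same ligand
pose_rmsd <- function(a, b) {
  ha <- a$atoms$element != "H"
  rmsd_coords(ligand_coords(a)[ha, , drop = FALSE],
              ligand_coords(b)[ha, , drop = FALSE])
}

#' Dock a ligand to a receptor model on interaction grid maps
#'
#' Precomputes van der Waals, electrostatic, hydrogen-bonding and
#' hydrophobic potential maps (0.5 A spacing) over the binding-site box,
#' then runs restarted torsion + rigid-body Monte Carlo of the ligand
#' against the maps. Distinct low-energy conformations (heavy-atom RMSD
#' deduplication at 1 A) are returned.
#'
#' @param bundle receptor BundleState.
#' @param compound a Ligand.
#' @param box list(center = c(x, y, z), size = edge length in Angstrom)
#'   defining the binding-site box (default 10 A cube at the bundle center).
#' @param seed integer seed.
#' @param n_poses maximal number of stored poses (default 32).
#' @param n_starts Monte Carlo restarts (default 12).
#' @param steps proposals per restart (default 1500).
#' @return list of pose records `list(ligand, energy)`, energy-sorted; empty
#'   (with a warning) if the ligand never fit the box.
#' @export
dock_ligand <- function(bundle, compound, box = NULL, seed = 1,
                        n_poses = 32, n_starts = 12, steps = 1500) {
  box <- box %||% list(center = bundle$bundle_center, size = 10)
  prot <- bundle_atoms(bundle)
  coords <- as.matrix(prot[, c("x", "y", "z")])
  lj <- element_lj(prot$element)
  ## map region: box + margin so the ligand can settle at the box edge
  margin <- 4
  spacing <- 0.5
  origin <- box$center - box$size / 2 - margin
  dims <- as.integer(rep(ceiling((box$size + 2 * margin) / spacing), 3)) + 1L
  polar <- prot$element %in% c("N", "O")
  apolar <- prot$element == "C" & !(prot$atom %in% c("C", "CA"))
  maps <- cpp_grid_maps(coords, lj$eps, lj$sig, prot$charge, polar, apolar,
                        origin, spacing, dims, 2.0)
  heavy <- compound$atoms$element != "H"
  qa <- compound$atoms$charge
  adj <- lig_adjacency(compound)
  lig_polar <- compound$atoms$element %in% c("N", "O")
  lig_apolar <- compound$atoms$element == "C" &
    !vapply(adj, function(nb) any(compound$atoms$element[nb] %in% c("N", "O")),
            logical(1))
  map_energy <- function(X) {
    ev <- cpp_interp3(maps$vdw, origin, spacing, dims, X[heavy, , drop = FALSE], 50)
    ee <- cpp_interp3(maps$elec, origin, spacing, dims, X, 0) * qa
    eh <- cpp_interp3(maps$hbond, origin, spacing, dims,
                      X[lig_polar, , drop = FALSE], 0)
    ep <- cpp_interp3(maps$hydrophobic, origin, spacing, dims,
                      X[lig_apolar, , drop = FALSE], 0)
    ## keep the ligand centroid inside the nominal box
    cen <- colMeans(X[heavy, , drop = FALSE])
    wall <- sum(pmax(0, abs(cen - box$center) - box$size / 2)^2) * 10
    sum(ev) + sum(ee) + sum(eh) + sum(ep) + wall
  }
  poses <- list()
  with_seed(seed, {
    for (start in seq_len(n_starts)) {
      lig <- compound
      if (length(lig$rotatable))
        for (k in seq_along(lig$rotatable))
          lig <- set_ligand_torsion(lig, k, stats::runif(1, -180, 180))
      X <- ligand_coords(lig)
      cen <- colMeans(X[heavy, , drop = FALSE])
      X <- t(rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360)) %*%
             t(sweep(X, 2, cen)))
      X <- sweep(X, 2, box$center + stats::runif(3, -box$size / 4, box$size / 4),
                 `+`)
      lig$atoms[, c("x", "y", "z")] <- X
      e_cur <- map_energy(X)
      best <- list(X = X, e = e_cur)
      for (stp in seq_len(steps)) {
        temp <- 600 * (300 / 600)^((stp - 1) / max(1, steps - 1))
        Xp <- ligand_coords(lig)
        if (length(lig$rotatable) && stats::runif(1) < 0.4) {
          k <- sample.int(length(lig$rotatable), 1)
          rb <- lig$rotatable[[k]]
          ang <- stats::rnorm(1, 0, 30)
          R <- rotation_about_axis(Xp[rb$path[3], ] - Xp[rb$path[2], ], ang)
          piv <- Xp[rb$path[3], ]
          Xp[rb$moved, ] <- t(R %*% t(sweep(Xp[rb$moved, , drop = FALSE], 2, piv))) +
            matrix(piv, length(rb$moved), 3, byrow = TRUE)
        } else {
          cen <- colMeans(Xp[heavy, , drop = FALSE])
          R <- rotation_about_axis(stats::rnorm(3), stats::rnorm(1, 0, 10))
          Xp <- t(R %*% t(sweep(Xp, 2, cen))) +
            matrix(cen + stats::rnorm(3, 0, 0.5), nrow(Xp), 3, byrow = TRUE)
        }
        e_new <- map_energy(Xp)
        de <- e_new - e_cur
        if (de <= 0 || stats::runif(1) < exp(-de / (BOLTZ * temp))) {
          lig$atoms[, c("x", "y", "z")] <- Xp
          e_cur <- e_new
          if (e_cur < best$e) best <- list(X = Xp, e = e_cur)
        }
      }
      lig$atoms[, c("x", "y", "z")] <- best$X
      poses[[length(poses) + 1]] <- list(ligand = lig, energy = best$e)
    }
  })
  poses <- poses[order(vapply(poses, `[[`, numeric(1), "energy"))]
  ## deduplicate at 1 A heavy-atom RMSD
  kept <- list()
  for (p in poses) {
    dup <- any(vapply(kept, function(k) pose_rmsd(k$ligand, p$ligand) < 1,
                      logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- p
    if (length(kept) >= n_poses) break
  }
  if (!length(kept)) warning("no docking poses generated for ", compound$name)
  kept
}

#' Evaluate a docked pose against the acceptance criteria
#'
#' Computes the three key interaction energies (amine-to-aspartate hydrogen
#' bond, best ligand-to-serine hydrogen bond, aromatic vdW against the
#' filter phenylalanine) and applies the thresholds. Every pose of a stack
#' is evaluated; no docking-energy pre-threshold is applied.
#'
#' @param pose a pose record from [dock_ligand()] (`list(ligand, energy)`).
#' @param bundle receptor BundleState.
#' @param target a [target_spec()] (whose `criteria` supply thresholds).
#' @return a PoseRecord: compound, energy, hbond_asp, hbond_ser,
#'   aromatic_vdw, accepted, reasons.
#' @export
evaluate_pose <- function(pose, bundle, target) {
  crit <- target$criteria
  st <- complex_state(bundle, pose$ligand)
  sys <- st$sys
  x <- st$coords
  params <- st$params
  asp_o <- residue_atom_idx(sys, target$asp_resid, c("OD1", "OD2"))
  lig_n_don <- which(sys$donors[, 1] %in% sys$ligand_idx &
                     sys$atoms$element[sys$donors[, 1]] == "N")
  hb_asp <- 0
  for (k in lig_n_don) {
    d <- sys$donors[k, 1]; h <- sys$donors[k, 2]
    for (a in asp_o)
      hb_asp <- hb_asp + hbond_energy(x[d, ], x[h, ], x[a, ], params)
  }
  hb_ser <- min(vapply(target$ser_resids, function(r) {
    system_hbond_energy(sys, params, x, sel_a = sys$ligand_idx,
                        sel_b = residue_atom_idx(sys, r))
  }, numeric(1)))
  lig_arom <- intersect(sys$ligand_idx, sys$aromatic)
  phe_atoms <- intersect(residue_atom_idx(sys, target$phe_filter),
                         sys$aromatic)
  reasons <- character(0)
  if (length(lig_arom)) {
    arom <- vdw_energy(sys, energy_params(lambda = 0), x, lig_arom, phe_atoms)
  } else {
    arom <- NA_real_
    reasons <- c(reasons, "ligand has no aromatic atoms")
  }
  if (hb_asp > crit$hbond_asp_max)
    reasons <- c(reasons, "aspartate hydrogen bond")
  if (hb_ser > crit$hbond_ser_max)
    reasons <- c(reasons, "serine hydrogen bond")
  if (!is.na(arom) && arom > crit$aromatic_vdw_max)
    reasons <- c(reasons, "aromatic vdW")
  structure(list(compound = pose$ligand$name, ligand = pose$ligand,
                 energy = pose$energy, hbond_asp = hb_asp,
                 hbond_ser = hb_ser, aromatic_vdw = arom,
                 accepted = length(reasons) == 0, reasons = reasons),
            class = "PoseRecord")
}

#' Lowest-energy accepted pose of an evaluated stack
#'
#' @param records list of PoseRecords.
#' @return the accepted PoseRecord with the lowest docking energy (ties
#'   broken by position in the stack), or NULL if none is accepted.
#' @export
best_accepted_pose <- function(records) {
  acc <- which(vapply(records, `[[`, logical(1), "accepted"))
  if (!length(acc)) return(NULL)
  e <- vapply(records[acc], `[[`, numeric(1), "energy")
  records[[acc[which.min(e)]]]
}

#' Rank receptor models by unique accepted agonists
#'
#' For each model, the number of unique agonist compounds (enantiomer pairs
#' counted once) with at least one accepted docking pose is summed and used
#' to rank the models (descending); ties are broken by the model's total
#' score (ascending).
#'
#' @param accept_table data.frame with columns model, compound, agonist
#'   (logical), group (enantiomer group id; compounds sharing a group count
#'   once) and accepted (logical).
#' @param model_scores optional named numeric of total scores per model for
#'   tie-breaking.
#' @return data.frame model / n_agonists / rank, ordered by rank.
#' @export
rank_models <- function(accept_table, model_scores = NULL) {
  stopifnot(all(c("model", "compound", "agonist", "group", "accepted")
                %in% names(accept_table)))
  models <- sort(unique(accept_table$model))
  n_ag <- vapply(models, function(m) {
    sub <- accept_table[accept_table$model == m & accept_table$agonist &
                        accept_table$accepted, , drop = FALSE]
    length(unique(sub$group))
  }, integer(1))
  scores <- if (is.null(model_scores)) rep(0, length(models))
            else model_scores[as.character(models)]
  ord <- order(-n_ag, scores, models)
  out <- data.frame(model = models[ord], n_agonists = n_ag[ord],
                    total_score = scores[ord])
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## resolve a selection scheme to (key, coords) for matched superposition
resolve_selection <- function(atoms, scheme, ligand_resname = "LIG") {
  if (is.data.frame(scheme)) {
    key <- paste(scheme$resid, scheme$atom)
    idx <- match(key, paste(atoms$resid, atoms$atom))
    if (anyNA(idx))
      stop("selection atoms not found: ",
           paste(key[is.na(idx)], collapse = ", "))
    return(idx)
  }
  switch(scheme,
    ca = which(atoms$atom == "CA"),
    heavy = which(atoms$element != "H"),
    ligand = which(atoms$resname == ligand_resname & atoms$element != "H"),
    stop("unknown selection scheme: ", scheme))
}

#' Superpose two structures and report an RMSD
#'
#' Least-squares (Kabsch) superposition on the fit selection, RMSD reported
#' on the report selection (which may differ, e.g. fit on binding-site
#' residues, report on ligand heavy atoms). Atoms are matched by
#' (resid, atom name); a mismatch is an error listing the unmatched atoms.
#'
#' @param ref,model atom data.frames (resid, atom, element, x, y, z, and
#'   resname for the "ligand" scheme).
#' @param fit selection for superposition: "ca", "heavy", "ligand" or a
#'   data.frame(resid, atom).
#' @param report selection for the RMSD (default: same as fit).
#' @return RMSD in Angstrom.
#' @export
superpose_and_rmsd <- function(ref, model, fit = "ca", report = fit) {
  i_fit_r <- resolve_selection(ref, fit)
  key_fit <- paste(ref$resid[i_fit_r], ref$atom[i_fit_r])
  i_fit_m <- match(key_fit, paste(model$resid, model$atom))
  if (anyNA(i_fit_m))
    stop("fit atoms missing from model: ",
         paste(key_fit[is.na(i_fit_m)], collapse = ", "))
  Pr <- as.matrix(ref[i_fit_r, c("x", "y", "z")])
  Pm <- as.matrix(model[i_fit_m, c("x", "y", "z")])
  kb <- kabsch(Pm, Pr)
  i_rep_r <- resolve_selection(ref, report)
  key_rep <- paste(ref$resid[i_rep_r], ref$atom[i_rep_r])
  i_rep_m <- match(key_rep, paste(model$resid, model$atom))
  if (anyNA(i_rep_m))
    stop("report atoms missing from model: ",
         paste(key_rep[is.na(i_rep_m)], collapse = ", "))
  Rm <- kb$transform(as.matrix(model[i_rep_m, c("x", "y", "z")]))
  rmsd_coords(as.matrix(ref[i_rep_r, c("x", "y", "z")]), Rm)
}

#' Binding-site residues around a ligand
#'
#' Residues with any heavy atom within `cutoff` (default 5 A) of any ligand
#' heavy atom.
#'
#' @param atoms protein atom data.frame.
#' @param ligand a Ligand.
#' @param cutoff Angstrom (default 5).
#' @return integer residue numbers.
#' @export
binding_site_residues <- function(atoms, ligand, cutoff = 5) {
  L <- ligand_coords(ligand)[ligand$atoms$element != "H", , drop = FALSE]
  heavy <- atoms$element != "H"
  P <- as.matrix(atoms[heavy, c("x", "y", "z")])
  keep <- vapply(seq_len(nrow(P)), function(i) {
    dx <- L[, 1] - P[i, 1]; dy <- L[, 2] - P[i, 2]; dz <- L[, 3] - P[i, 3]
    min(dx * dx + dy * dy + dz * dz) <= cutoff^2
  }, logical(1))
  sort(unique(atoms$resid[heavy][keep]))
}

#' Transfer a binding-site box selection across receptor models
#'
#' The box is defined once on the reference model; every other model is
#' first superposed on the reference using the sequence-conserved core
#' Calpha atoms (so single deviant helices do not skew the alignment), then
#' its atoms falling inside the box are selected.
#'
#' @param ref reference atom data.frame.
#' @param box list(center, size) in the reference frame (10 A cube typical).
#' @param models list of atom data.frames.
#' @param core_resids residue numbers of the conserved core used for the
#'   superposition.
#' @return list of integer atom-index vectors, one per model (empty with a
#'   warning where nothing falls in the box).
#' @export
binding_site_box_transfer <- function(ref, box, models, core_resids) {
  fit <- data.frame(resid = core_resids, atom = "CA")
  lapply(models, function(m) {
    i_fit_r <- resolve_selection(ref, fit)
    i_fit_m <- match(paste(core_resids, "CA"), paste(m$resid, m$atom))
    if (anyNA(i_fit_m)) stop("core Calpha atoms missing from model")
    kb <- kabsch(as.matrix(m[i_fit_m, c("x", "y", "z")]),
                 as.matrix(ref[i_fit_r, c("x", "y", "z")]))
    Xm <- kb$transform(as.matrix(m[, c("x", "y", "z")]))
    inside <- abs(Xm[, 1] - box$center[1]) <= box$size / 2 &
              abs(Xm[, 2] - box$center[2]) <= box$size / 2 &
              abs(Xm[, 3] - box$center[3]) <= box$size / 2
    if (!any(inside)) warning("empty binding-site box selection")
    which(inside)
  })
}

## ---- atom property fields ---------------------------------------------------

PAULING_EN <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, H = 2.20,
                F = 3.98, CL = 3.16, BR = 2.96, P = 2.19)

## per-atom values of the seven APF channels
apf_atom_properties <- function(lig) {
  el <- lig$atoms$element
  adj <- lig_adjacency(lig)
  has_h <- vapply(adj, function(nb) any(el[nb] == "H"), logical(1))
  bonded_no <- vapply(adj, function(nb) any(el[nb] %in% c("N", "O")),
                      logical(1))
  sp2 <- lig$atoms$aromatic
  if (nrow(lig$bonds)) {
    dbl <- lig$bonds[lig$bonds[, 3] %in% c(2, 3), 1:2, drop = FALSE]
    sp2[unique(as.vector(dbl))] <- TRUE
  }
  acceptor <- (el == "O") | (el == "N" & !has_h & lig$atoms$charge <= 0)
  ## donor density lives on the polar hydrogens (the donated proton)
  donor <- el == "H" &
    vapply(adj, function(nb) any(el[nb] %in% c("N", "O")), logical(1))
  data.frame(
    hydrophobicity = as.numeric(el == "C" & !bonded_no),
    acceptor = as.numeric(acceptor),
    donor = as.numeric(donor),
    charge = lig$atoms$charge,
    sp2 = as.numeric(sp2 & el != "H"),
    size = as.numeric(el != "H") * element_lj(el)$radius,
    electronegativity = as.numeric(el != "H") *
      unname(PAULING_EN[el] %||% 2.5) )
}

#' Atom property fields of an accepted pose ensemble
#'
#' Seven per-atom properties (hydrophobicity, hydrogen-bond acceptor and
#' donor, charge, sp2 hybridization, size, electronegativity) are splatted
#' onto a common grid with a Gaussian kernel and averaged over the ensemble.
#'
#' @param poses non-empty list of Ligands (accepted docked conformers).
#' @param spacing grid spacing (default 0.5 A).
#' @param half_width Gaussian kernel half-width sigma (default 1.0 A).
#' @param margin grid margin beyond the pose bounding box (default 3 A).
#' @return object of class APFGrid: list of 7 named 3D arrays plus origin
#'   and spacing.
#' @export
apf_grid <- function(poses, spacing = 0.5, half_width = 1.0, margin = 3) {
  if (!length(poses)) stop("empty pose ensemble")
  if (inherits(poses, "Ligand")) poses <- list(poses)
  allx <- do.call(rbind, lapply(poses, ligand_coords))
  origin <- apply(allx, 2, min) - margin
  upper <- apply(allx, 2, max) + margin
  dims <- as.integer(ceiling((upper - origin) / spacing)) + 1L
  gx <- origin[1] + (0:(dims[1] - 1)) * spacing
  gy <- origin[2] + (0:(dims[2] - 1)) * spacing
  gz <- origin[3] + (0:(dims[3] - 1)) * spacing
  channels <- c("hydrophobicity", "acceptor", "donor", "charge", "sp2",
                "size", "electronegativity")
  grids <- lapply(channels, function(ch) array(0, dims))
  names(grids) <- channels
  inv2s2 <- 1 / (2 * half_width^2)
  for (lig in poses) {
    props <- apf_atom_properties(lig)
    X <- ligand_coords(lig)
    for (a in seq_len(nrow(X))) {
      wx <- exp(-(gx - X[a, 1])^2 * inv2s2)
      wy <- exp(-(gy - X[a, 2])^2 * inv2s2)
      wz <- exp(-(gz - X[a, 3])^2 * inv2s2)
      kern <- outer(outer(wx, wy), wz)
      for (ch in channels) {
        v <- props[[ch]][a]
        if (v != 0) grids[[ch]] <- grids[[ch]] + v * kern
      }
    }
  }
  for (ch in channels) grids[[ch]] <- grids[[ch]] / length(poses)
  structure(list(grids = grids, origin = origin, spacing = spacing,
                 dims = dims, n_poses = length(poses)),
            class = "APFGrid")
}

#' Write one APF channel as an OpenDX volumetric file
#'
#' @param apf an APFGrid.
#' @param channel channel name.
#' @param path output path.
#' @export
write_dx <- function(apf, channel, path) {
  g <- apf$grids[[channel]]
  if (is.null(g)) stop("unknown APF channel: ", channel)
  d <- apf$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", apf$origin[1], apf$origin[2], apf$origin[3]),
    sprintf("delta %.4f 0 0", apf$spacing),
    sprintf("delta 0 %.4f 0", apf$spacing),
    sprintf("delta 0 0 %.4f", apf$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## dx layout: z varies fastest
  vals <- as.vector(aperm(g, c(3, 2, 1)))
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1,
                   function(r) paste(format(r[!is.na(r)], digits = 6),
                                     collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
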