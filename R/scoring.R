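## Complex-model scoring: protein packing terms (volume, area, buried
## pockets, helix-center distances), protein orientation terms (hydrophilic
## exposure, tilt, elevation, loop spans, anchor distances), and the
## target-specific ligand score, weighted into a total score.

#' Scoring configuration
#'
#' @param probe solvent probe radius, Angstrom (default 1.4).
#' @param vol_spacing grid spacing for volume/area (default 0.5 A).
#' @param pocket_spacing grid spacing for pocket detection (default 0.8 A).
#' @param pocket_min_volume report pockets above this volume (default
#'   20 A^3).
#' @param k_tilt,k_elev,k_loop penalty constants per degree / Angstrom /
#'   Angstrom^2 (default 1).
#' @param tilt_threshold tilt beyond which segments are penalized, degrees
#'   (default 50).
#' @param exposure_fraction exposure threshold relative to the Gly-X-Gly
#'   reference (default 0.25).
#' @param loop_lengths optional numeric vector of loop residue counts per
#'   helix junction (for the loop-span term).
#' @param top_weights length-3 named vector weighting packing, orientation
#'   and ligand sub-scores in the total (default all 1; lower total is
#'   better).
#' @return object of class ScoreConfig.
#' @export
score_config <- function(probe = 1.4, vol_spacing = 0.5, pocket_spacing = 0.8,
                         pocket_min_volume = 20, k_tilt = 1, k_elev = 1,
                         k_loop = 1, tilt_threshold = 50,
                         exposure_fraction = 0.25, loop_lengths = NULL,
                         top_weights = c(packing = 1, orientation = 1,
                                         ligand = 1)) {
  structure(list(probe = probe, vol_spacing = vol_spacing,
                 pocket_spacing = pocket_spacing,
                 pocket_min_volume = pocket_min_volume, k_tilt = k_tilt,
                 k_elev = k_elev, k_loop = k_loop,
                 tilt_threshold = tilt_threshold,
                 exposure_fraction = exposure_fraction,
                 loop_lengths = loop_lengths, top_weights = top_weights),
            class = "ScoreConfig")
}

default_score_config <- function() score_config()

as_protein_atoms <- function(obj) {
  if (inherits(obj, "BundleState")) return(bundle_atoms(obj))
  if (inherits(obj, "ComplexState")) {
    st <- sync_state(obj)
    return(bundle_atoms(st$bundle))
  }
  obj
}

as_bundle <- function(obj) {
  if (inherits(obj, "BundleState")) return(obj)
  if (inherits(obj, "ComplexState")) return(sync_state(obj)$bundle)
  stop("expected a BundleState or ComplexState")
}

## Shared voxel analysis: vdW occupancy, solvent cover (bulk probe-accessible
## region dilated by the probe), and the pocket mask between them.
grid_analysis <- function(coords, radii, spacing, probe, margin = 2) {
  pad <- max(radii) + probe + margin
  origin <- apply(coords, 2, min) - pad
  upper <- apply(coords, 2, max) + pad
  dims <- as.integer(ceiling((upper - origin) / spacing)) + 1L
  occA <- cpp_occupancy(coords, radii, origin, spacing, dims, 0)
  occB <- cpp_occupancy(coords, radii, origin, spacing, dims, probe)
  freeB <- as.integer(occB == 0L)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ## all voxels on the box faces seed the bulk solvent
  face <- function(i, j, k) (k * ny + j) * nx + i  # 0-based
  ij <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  ik <- expand.grid(i = 0:(nx - 1), k = 0:(nz - 1))
  jk <- expand.grid(j = 0:(ny - 1), k = 0:(nz - 1))
  seeds <- unique(c(face(ij$i, ij$j, 0), face(ij$i, ij$j, nz - 1),
                    face(ik$i, 0, ik$k), face(ik$i, ny - 1, ik$k),
                    face(0, jk$j, jk$k), face(nx - 1, jk$j, jk$k)))
  outside <- cpp_flood_fill(freeB, dims, as.integer(seeds))
  ## solvent cover = outside region plus the probe-radius dilation of its
  ## boundary layer (dilating interior bulk voxels is redundant)
  out_arr <- array(outside == 1L, dims)
  shift <- function(a, d, n) {
    out <- array(FALSE, dim(a))
    idx_src <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    idx_dst <- idx_src
    if (n > 0) { idx_dst[[d]] <- (1 + n):dims[d]; idx_src[[d]] <- 1:(dims[d] - n) }
    else { idx_dst[[d]] <- 1:(dims[d] + n); idx_src[[d]] <- (1 - n):dims[d] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  interior_nb <- shift(out_arr, 1, 1) & shift(out_arr, 1, -1) &
                 shift(out_arr, 2, 1) & shift(out_arr, 2, -1) &
                 shift(out_arr, 3, 1) & shift(out_arr, 3, -1)
  boundary <- out_arr & !interior_nb
  b_idx <- which(boundary) - 1L
  ks <- b_idx %/% (nx * ny)
  js <- (b_idx %/% nx) %% ny
  is <- b_idx %% nx
  centers <- cbind(origin[1] + is * spacing, origin[2] + js * spacing,
                   origin[3] + ks * spacing)
  solvent <- if (nrow(centers))
    cpp_occupancy(centers, rep(0, nrow(centers)), origin, spacing, dims, probe)
  else rep(0L, prod(dims))
  solvent <- as.integer(solvent == 1L | outside == 1L)
  pocket_mask <- as.integer(occA == 0L & solvent == 0L)
  list(origin = origin, spacing = spacing, dims = dims, occA = occA,
       solvent = solvent, pocket_mask = pocket_mask)
}

#' Molecular volume and solvent-accessible area
#'
#' Solvent-excluded volume (voxel count of space not covered by bulk
#' solvent, i.e. vdW volume plus probe-inaccessible interstices) and
#' Shrake-Rupley solvent-accessible surface area.
#'
#' @param obj BundleState, ComplexState or atom data.frame.
#' @param probe probe radius (default 1.4 A; 0 gives the bare vdW surface).
#' @param spacing volume grid spacing (default 0.5 A).
#' @return named numeric c(volume =, area =) in A^3 / A^2.
#' @export
molecular_volume_area <- function(obj, probe = 1.4, spacing = 0.5) {
  atoms <- as_protein_atoms(obj)
  if (!nrow(atoms)) return(c(volume = 0, area = 0))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- element_lj(atoms$element)$radius
  ga <- grid_analysis(coords, radii, spacing, probe)
  vol <- sum(ga$occA == 1L | ga$pocket_mask == 1L) * spacing^3
  area <- sum(cpp_sasa(coords, radii, probe, 240L))
  c(volume = vol, area = area)
}

#' Detect pockets and cavities on a voxel grid
#'
#' Empty voxels not covered by bulk solvent are clustered (6-connectivity);
#' clusters with no contact with the solvent region are buried cavities,
#' the rest are surface concavities.
#'
#' @param obj BundleState, ComplexState or atom data.frame.
#' @param spacing grid spacing (default 0.8 A).
#' @param probe probe radius (default 1.4 A).
#' @param min_volume only report pockets above this volume (default 0 A^3).
#' @return data.frame with columns volume (A^3) and buried (logical), sorted
#'   by decreasing volume.
#' @export
find_pockets <- function(obj, spacing = 0.8, probe = 1.4, min_volume = 0) {
  atoms <- as_protein_atoms(obj)
  if (!nrow(atoms))
    return(data.frame(volume = numeric(0), buried = logical(0)))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- element_lj(atoms$element)$radius
  ga <- grid_analysis(coords, radii, spacing, probe)
  lab <- cpp_label_components(ga$pocket_mask, ga$dims)
  nlab <- max(lab)
  if (nlab == 0)
    return(data.frame(volume = numeric(0), buried = logical(0)))
  touches <- cpp_touches(lab, ga$solvent, ga$dims, nlab)
  vol <- tabulate(lab[lab > 0], nbins = nlab) * spacing^3
  out <- data.frame(volume = vol, buried = touches == 0L)
  out <- out[out$volume >= min_volume, , drop = FALSE]
  out[order(-out$volume), , drop = FALSE]
}

#' Sum of helix-center distances from the bundle center
#' @param obj BundleState or ComplexState.
#' @return Angstrom.
#' @export
helix_center_distance_score <- function(obj) {
  bundle <- as_bundle(obj)
  sum(sqrt(rowSums(sweep(bundle$helix_centers, 2,
                         bundle$bundle_center)^2)))
}

## polar side-chain atom names per residue type (charged/polar groups)
POLAR_SIDECHAIN <- list(SER = c("OG", "HG"), ASP = c("OD1", "OD2"),
                        LYS = c("NZ"))

gxg_reference_env <- new.env(parent = emptyenv())

## Standard exposed side-chain area of residue type X in an extended
## Gly-X-Gly tripeptide (computed once per type and cached).
gxg_reference_area <- function(resname, probe = 1.4) {
  key <- paste0(resname, "_", probe)
  if (!is.null(gxg_reference_env[[key]])) return(gxg_reference_env[[key]])
  polar <- POLAR_SIDECHAIN[[resname]]
  if (is.null(polar)) stop("no Gly-X-Gly reference for residue ", resname)
  tri <- build_peptide(c("GLY", resname, "GLY"), phi = -120, psi = 120)
  coords <- as.matrix(tri[, c("x", "y", "z")])
  radii <- element_lj(tri$element)$radius
  a <- cpp_sasa(coords, radii, probe, 480L)
  ref <- sum(a[tri$resid == 2 & tri$atom %in% polar])
  gxg_reference_env[[key]] <- ref
  ref
}

#' Hydrophilic (lipid-facing) exposure of the membrane-embedded mid-third
#'
#' Solvent-accessible area of charged/polar side-chain groups of residues
#' whose Calpha lies in the mid-third of the bundle along its axis. Term
#' `exposed25` sums groups exposed at least 25% relative to their standard
#' Gly-X-Gly area; term `all` sums every polar group's exposure.
#'
#' @param obj BundleState or ComplexState.
#' @param config a [score_config()].
#' @return named numeric c(exposed25 =, all =) in A^2.
#' @export
hydrophilic_exposure <- function(obj, config = score_config()) {
  bundle <- as_bundle(obj)
  atoms <- bundle_atoms(bundle)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- element_lj(atoms$element)$radius
  fr <- membrane_frame(bundle)
  proj <- as.numeric(sweep(coords, 2, fr$point) %*% fr$normal)
  ca <- atoms$atom == "CA"
  zr <- range(proj[ca])
  third <- c(zr[1] + diff(zr) / 3, zr[1] + 2 * diff(zr) / 3)
  ca_proj <- proj[ca]; ca_res <- atoms$resid[ca]
  mid_res <- ca_res[ca_proj >= third[1] & ca_proj <= third[2]]
  sasa <- cpp_sasa(coords, radii, config$probe, 240L)
  e25 <- 0; eall <- 0
  for (r in unique(atoms$resid)) {
    rn <- atoms$resname[atoms$resid == r][1]
    polar <- POLAR_SIDECHAIN[[rn]]
    if (is.null(polar) || !(r %in% mid_res)) next
    expo <- sum(sasa[atoms$resid == r & atoms$atom %in% polar])
    ref <- gxg_reference_area(rn, config$probe)
    eall <- eall + expo
    if (expo >= config$exposure_fraction * ref) e25 <- e25 + expo
  }
  c(exposed25 = e25, all = eall)
}

#' Tilt penalty of helix segments
#'
#' Helices are split at kinks ([helix_axis_segments()]); each segment tilted
#' more than the threshold relative to the bundle axis contributes
#' k_tilt * (tilt - threshold).
#'
#' @param obj BundleState or ComplexState.
#' @param config a [score_config()].
#' @return penalty (>= 0).
#' @export
tilt_penalty <- function(obj, config = score_config()) {
  bundle <- as_bundle(obj)
  ax <- bundle$bundle_axis
  total <- 0
  for (h in bundle$helices) {
    for (seg in helix_axis_segments(h)) {
      ang <- acos(max(-1, min(1, abs(sum(seg$axis * ax))))) * 180 / pi
      total <- total + config$k_tilt * max(0, ang - config$tilt_threshold)
    }
  }
  total
}

#' Elevation penalty
#'
#' Sum of absolute helix-center offsets from the membrane mid-plane times
#' k_elev (near zero for accurately placed helices).
#'
#' @inheritParams tilt_penalty
#' @return penalty (>= 0).
#' @export
elevation_penalty <- function(obj, config = score_config()) {
  bundle <- as_bundle(obj)
  config$k_elev * sum(abs(helix_elevations(bundle)))
}

#' Loop-span penalty
#'
#' Loops are absent from the models; helix-termini separations are instead
#' scored against the maximal span of the excised loop, estimated at 3.2 A
#' per loop residue: penalty k_loop * max(0, d - 3.2 n)^2 per junction.
#'
#' @param obj BundleState or ComplexState.
#' @param loop_lengths numeric vector of loop residue counts per junction
#'   (length n_helices - 1); NA junctions are skipped with a warning.
#' @param config a [score_config()].
#' @param per_residue maximal span per loop residue (default 3.2 A).
#' @return penalty (>= 0).
#' @export
loop_span_penalty <- function(obj, loop_lengths = NULL,
                              config = score_config(), per_residue = 3.2) {
  bundle <- as_bundle(obj)
  loop_lengths <- loop_lengths %||% config$loop_lengths
  n <- length(bundle$helices)
  if (is.null(loop_lengths)) return(0)
  total <- 0
  for (j in seq_len(n - 1)) {
    nl <- if (j <= length(loop_lengths)) loop_lengths[j] else NA
    if (is.na(nl)) {
      warning("no loop length for junction ", j, "; skipped")
      next
    }
    a <- bundle$helices[[j]]$atoms
    b <- bundle$helices[[j + 1]]$atoms
    ca_end <- as.numeric(a[a$resid == bundle$helices[[j]]$span[2] &
                           a$atom == "CA", c("x", "y", "z")])
    ca_start <- as.numeric(b[b$resid == bundle$helices[[j + 1]]$span[1] &
                             b$atom == "CA", c("x", "y", "z")])
    d <- vnorm(ca_end - ca_start)
    total <- total + config$k_loop * max(0, d - per_residue * nl)^2
  }
  total
}

#' Target specification for ligand scoring and pose filtering
#'
#' Names the binding-site residues whose interactions define the
#' target-specific ligand score: the TM5 serines (hydrogen bonds to the
#' ligand), the TM3 aspartate (salt bridge to the protonated amine), and the
#' TM6 phenylalanines (aromatic contact), plus the flat-bottom anchor
#' restraint window and the pose acceptance criteria.
#'
#' @param ser_resids residue numbers of the serines.
#' @param asp_resid residue number of the aspartate.
#' @param phe_resids residue numbers of the phenylalanines (score term).
#' @param phe_filter residue whose aromatic vdW contact is required by the
#'   key-interaction filter (default: last of phe_resids).
#' @param anchor_target,anchor_halfwidth flat-bottom window for the
#'   aspartate-to-serine-midpoint distance (e.g. 12 +/- 2 A).
#' @param criteria an [acceptance_criteria()].
#' @param ligand_weights named weights of the four ligand score terms.
#' @param loop_lengths optional loop residue counts per junction.
#' @return object of class TargetSpec.
#' @export
target_spec <- function(ser_resids, asp_resid, phe_resids,
                        phe_filter = NULL, anchor_target = 12,
                        anchor_halfwidth = 2,
                        criteria = acceptance_criteria(),
                        ligand_weights = c(ser_hbond = 1, asp = 1,
                                           restraint = 1, aromatic_vdw = 1),
                        loop_lengths = NULL) {
  structure(list(ser_resids = ser_resids, asp_resid = asp_resid,
                 phe_resids = phe_resids,
                 phe_filter = phe_filter %||% phe_resids[length(phe_resids)],
                 anchor_target = anchor_target,
                 anchor_halfwidth = anchor_halfwidth, criteria = criteria,
                 ligand_weights = ligand_weights,
                 loop_lengths = loop_lengths),
            class = "TargetSpec")
}

residue_atom_idx <- function(sys, resid, atoms = NULL) {
  sel <- which(sys$atoms$resid == resid & sys$atoms$group != 0)
  if (!length(sel)) stop("residue ", resid, " not present in model")
  if (!is.null(atoms)) sel <- sel[sys$atoms$atom[sel] %in% atoms]
  sel
}

## ligand score terms against a target spec (kcal/mol each)
ligand_score_terms <- function(state, target) {
  sys <- state$sys
  if (!length(sys$ligand_idx)) stop("state has no ligand")
  lig <- sys$ligand_idx
  params <- state$params
  x <- state$coords
  ser_h <- sum(vapply(target$ser_resids, function(r) {
    system_hbond_energy(sys, params, x, sel_a = lig,
                        sel_b = residue_atom_idx(sys, r))
  }, numeric(1)))
  asp_side <- residue_atom_idx(sys, target$asp_resid,
                               c("CB", "CG", "OD1", "OD2"))
  nb <- nb_energy(sys, params, x, sel_a = lig, sel_b = asp_side)
  asp_h <- system_hbond_energy(sys, params, x, sel_a = lig, sel_b = asp_side)
  restr <- anchor_restraint_energy(sys, state$restraints, x)
  lig_arom <- intersect(lig, sys$aromatic)
  phe_atoms <- unlist(lapply(target$phe_resids, function(r)
    intersect(residue_atom_idx(sys, r), sys$aromatic)))
  arom <- if (length(lig_arom) && length(phe_atoms))
    vdw_energy(sys, energy_params(lambda = 0), x, lig_arom, phe_atoms)
  else 0
  c(ser_hbond = ser_h, asp_elec = nb[["elec"]], asp_hbond = asp_h,
    restraint = restr, aromatic_vdw = arom)
}

#' Target-specific ligand score
#'
#' Weighted sum of (1) hydrogen-bond energy between ligand and the TM5
#' serines, (2) electrostatic plus hydrogen-bond energy between ligand and
#' the TM3 aspartate side chain, (3) the flat-bottom anchor restraint
#' energies, and (4) the aromatic-atom vdW energy against the TM6
#' phenylalanines.
#'
#' @param state a ComplexState with a ligand.
#' @param target a [target_spec()].
#' @return list with `score` and the `terms` vector.
#' @export
ligand_score <- function(state, target) {
  terms <- ligand_score_terms(state, target)
  w <- target$ligand_weights
  score <- w[["ser_hbond"]] * terms[["ser_hbond"]] +
    w[["asp"]] * (terms[["asp_elec"]] + terms[["asp_hbond"]]) +
    w[["restraint"]] * terms[["restraint"]] +
    w[["aromatic_vdw"]] * terms[["aromatic_vdw"]]
  list(score = score, terms = terms)
}

#' Key-interaction filter for complex models
#'
#' A model passes only if the protonated-amine/aspartate salt bridge is
#' stabilized by a qualifying hydrogen bond and the aromatic-aromatic vdW
#' contact energy is at or below the threshold (-0.3 kcal/mol: weaker
#' contacts are discarded).
#'
#' @param state a ComplexState with a ligand.
#' @param target a [target_spec()].
#' @return list with `pass` (logical) and `reasons` (character, empty when
#'   passing).
#' @export
key_interaction_filter <- function(state, target) {
  sys <- state$sys
  crit <- target$criteria
  x <- state$coords
  reasons <- character(0)
  ## salt-bridge hydrogen bond: ligand amine N-H donors to Asp carboxylate O
  asp_o <- residue_atom_idx(sys, target$asp_resid, c("OD1", "OD2"))
  lig_don <- which(sys$donors[, 1] %in% sys$ligand_idx &
                   sys$atoms$element[sys$donors[, 1]] == "N" &
                   !(sys$donors[, 1] %in%
                     sys$ligand_idx[sys$atoms$element[sys$ligand_idx] != "N"]))
  hb <- 0
  for (k in lig_don) {
    d <- sys$donors[k, 1]; h <- sys$donors[k, 2]
    for (a in asp_o)
      hb <- hb + hbond_energy(x[d, ], x[h, ], x[a, ], state$params)
  }
  if (!length(lig_don) || hb > crit$hbond_asp_max)
    reasons <- c(reasons, "salt-bridge lacks qualifying hydrogen bond")
  lig_arom <- intersect(sys$ligand_idx, sys$aromatic)
  phe_atoms <- intersect(residue_atom_idx(sys, target$phe_filter),
                         sys$aromatic)
  if (!length(lig_arom)) {
    reasons <- c(reasons, "ligand has no aromatic atoms")
  } else {
    av <- vdw_energy(sys, energy_params(lambda = 0), x, lig_arom, phe_atoms)
    if (av > crit$aromatic_vdw_max)
      reasons <- c(reasons, "aromatic vdW contact too weak")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Score report for a complex model
#'
#' Computes every packing, orientation and (when a target and ligand are
#' present) ligand term, then the three weighted sub-scores and the weighted
#' total (lower is better).
#'
#' @param state a ComplexState (or BundleState for protein-only terms).
#' @param config a [score_config()].
#' @param target optional [target_spec()].
#' @return object of class ScoreReport: `packing`, `orientation`, `ligand`
#'   term vectors plus packing_score, orientation_score, ligand_score,
#'   total_score.
#' @export
score_report <- function(state, config = score_config(), target = NULL) {
  if (inherits(state, "BundleState")) state <- complex_state(state)
  state <- sync_state(state)
  va <- molecular_volume_area(state, config$probe, config$vol_spacing)
  pk <- find_pockets(state, config$pocket_spacing, config$probe,
                     config$pocket_min_volume)
  buried <- pk[pk$buried, , drop = FALSE]
  packing <- c(volume = unname(va["volume"]), area = unname(va["area"]),
               n_buried_pockets = nrow(buried),
               buried_pocket_volume = sum(buried$volume),
               helix_center_distance = helix_center_distance_score(state))
  he <- hydrophilic_exposure(state, config)
  orientation <- c(
    hydrophilic_exposed25 = unname(he["exposed25"]),
    hydrophilic_all = unname(he["all"]),
    tilt = tilt_penalty(state, config),
    elevation = elevation_penalty(state, config),
    loop_span = loop_span_penalty(state,
      config$loop_lengths %||% target$loop_lengths, config),
    anchor = anchor_restraint_energy(state$sys, state$restraints,
                                     state$coords))
  lig_terms <- NULL
  lscore <- 0
  if (!is.null(target) && length(state$sys$ligand_idx)) {
    ls <- ligand_score(state, target)
    lig_terms <- ls$terms
    lscore <- ls$score
  }
  rep <- structure(list(packing = packing, orientation = orientation,
                        ligand = lig_terms,
                        packing_score = sum(packing),
                        orientation_score = sum(orientation),
                        ligand_score = lscore),
                   class = "ScoreReport")
  total_score(rep, config$top_weights)
}

#' Weighted total score
#'
#' @param report a ScoreReport.
#' @param weights named length-3 vector (packing, orientation, ligand).
#' @return the report with `total_score` set to the weighted sum of the
#'   three sub-scores.
#' @export
total_score <- function(report, weights = c(packing = 1, orientation = 1,
                                            ligand = 1)) {
  report$total_score <- weights[["packing"]] * report$packing_score +
    weights[["orientation"]] * report$orientation_score +
    weights[["ligand"]] * report$ligand_score
  report$weights <- weights
  report
}

#' @export
print.ScoreReport <- function(x, ...) {
  cat("ScoreReport  total:", signif(x$total_score, 5), "\n")
  cat("  packing    (", signif(x$packing_score, 5), "):",
      paste(names(x$packing), signif(x$packing, 4), collapse = ", "), "\n")
  cat("  orientation(", signif(x$orientation_score, 5), "):",
      paste(names(x$orientation), signif(x$orientation, 4), collapse = ", "), "\n")
  if (!is.null(x$ligand))
    cat("  ligand     (", signif(x$ligand_score, 5), "):",
        paste(names(x$ligand), signif(x$ligand, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Score an ensemble of models with z-score normalized terms
#'
#' The per-term weights are not prescribed by the method; the default is to
#' express each packing/orientation term as a z-score over the ensemble
#' (scale 1/sd across models) and sum, keeping ligand terms in kcal/mol.
#'
#' @param states list of ComplexStates.
#' @param config a [score_config()].
#' @param target optional [target_spec()].
#' @return list of ScoreReports (z-normalized sub-scores and totals).
#' @export
score_ensemble <- function(states, config = score_config(), target = NULL) {
  reports <- lapply(states, score_report, config = config, target = target)
  if (length(reports) < 2) return(reports)
  zsum <- function(mat) {
    mu <- colMeans(mat)
    sdev <- apply(mat, 2, stats::sd)
    sdev[sdev < 1e-9] <- 1
    rowSums(scale(mat, center = mu, scale = sdev))
  }
  pmat <- do.call(rbind, lapply(reports, `[[`, "packing"))
  omat <- do.call(rbind, lapply(reports, `[[`, "orientation"))
  pz <- zsum(pmat); oz <- zsum(omat)
  for (i in seq_along(reports)) {
    reports[[i]]$packing_score <- pz[i]
    reports[[i]]$orientation_score <- oz[i]
    reports[[i]] <- total_score(reports[[i]], config$top_weights)
  }
  reports
}
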