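## Four-stage Monte Carlo geometry optimization. Stage 1 treats helices and
## ligand as rigid bodies under full tethers and soft vdW; later stages free
## ligand torsions, then side chains, then the backbone, while tethers soften
## and vdW hardens. Models are score-filtered after stages 1 and 3.

BOLTZ <- 0.0019872041  # kcal/mol/K

#' Configuration of one optimization stage
#'
#' @param stage_id integer 1-4.
#' @param free_classes character vector of freed degree-of-freedom classes,
#'   subset of "helix", "ligand_rigid", "ligand_torsion",
#'   "sidechain_pocket", "sidechain_all", "backbone". Defaults grow
#'   monotonically over stages 1-4.
#' @param lambda vdW soft-core softness for the stage (1 soft, 0 hard);
#'   default schedule 1, 0.5, 0.25, 0.
#' @param tether_scale tether strength scale; a length-2 vector ramps
#'   linearly across the stage. Stage 4 defaults to c(0.25, 0): tethers are
#'   softened and completely off by the end.
#' @param steps Monte Carlo proposals (desk-scale defaults 2000, 5000,
#'   10000, 20000).
#' @param t_start,t_end geometric cooling schedule in K (default 600 to 300).
#' @param filter_after whether a score checkpoint follows the stage
#'   (stages 1 and 3).
#' @return object of class StageConfig.
#' @export
stage_config <- function(stage_id,
                         free_classes = NULL, lambda = NULL,
                         tether_scale = NULL, steps = NULL,
                         t_start = 600, t_end = 300,
                         filter_after = NULL) {
  stopifnot(stage_id %in% 1:4)
  defaults <- list(
    list(classes = c("helix", "ligand_rigid"),
         lambda = 1, tether = 1, steps = 2000, filter = TRUE),
    list(classes = c("helix", "ligand_rigid", "ligand_torsion",
                     "sidechain_pocket"),
         lambda = 0.5, tether = 1, steps = 5000, filter = FALSE),
    list(classes = c("helix", "ligand_rigid", "ligand_torsion",
                     "sidechain_pocket", "sidechain_all"),
         lambda = 0.25, tether = 0.5, steps = 10000, filter = TRUE),
    list(classes = c("helix", "ligand_rigid", "ligand_torsion",
                     "sidechain_pocket", "sidechain_all", "backbone"),
         lambda = 0, tether = c(0.25, 0), steps = 20000, filter = FALSE))
  d <- defaults[[stage_id]]
  ts <- tether_scale %||% d$tether
  if (length(ts) == 1) ts <- c(ts, ts)
  structure(list(stage_id = stage_id,
                 free_classes = free_classes %||% d$classes,
                 lambda = lambda %||% d$lambda,
                 tether_scale = ts[1], tether_ramp = ts,
                 steps = steps %||% d$steps,
                 t_start = t_start, t_end = t_end,
                 filter_after = filter_after %||% d$filter),
            class = "StageConfig")
}

#' Relative move-selection frequencies
#'
#' Ligand variables are sampled twice as often as binding-pocket variables,
#' five times more often than helix positional variables, and 50 times more
#' often than the remaining protein residues (encoded as weights
#' 100:50:20:2).
#'
#' @param ligand,binding_pocket,helix_positional,remaining_protein relative
#'   weights.
#' @return object of class SamplingWeights.
#' @export
sampling_weights <- function(ligand = 100, binding_pocket = 50,
                             helix_positional = 20, remaining_protein = 2) {
  structure(list(ligand = ligand, binding_pocket = binding_pocket,
                 helix_positional = helix_positional,
                 remaining_protein = remaining_protein),
            class = "SamplingWeights")
}

#' Residues of the ligand binding pocket
#'
#' Residues with any heavy atom within `cutoff` of any ligand heavy atom
#' (re-computed regularly during optimization as the complex changes).
#'
#' @param state a ComplexState with a ligand.
#' @param cutoff distance in Angstrom (default 7).
#' @return integer vector of residue numbers (possibly empty).
#' @export
binding_pocket_residues <- function(state, cutoff = 7) {
  if (is.null(state$ligand) || cutoff <= 0) return(integer(0))
  sys <- state$sys
  x <- state$coords
  lig_heavy <- sys$ligand_idx[sys$atoms$element[sys$ligand_idx] != "H"]
  if (!length(lig_heavy)) return(integer(0))
  prot <- setdiff(seq_len(nrow(x)), sys$ligand_idx)
  prot_heavy <- prot[sys$atoms$element[prot] != "H"]
  if (!length(prot_heavy)) return(integer(0))
  L <- x[lig_heavy, , drop = FALSE]
  keep <- vapply(prot_heavy, function(i) {
    dx <- L[, 1] - x[i, 1]; dy <- L[, 2] - x[i, 2]; dz <- L[, 3] - x[i, 3]
    min(dx * dx + dy * dy + dz * dz) <= cutoff^2
  }, logical(1))
  sort(unique(sys$atoms$resid[prot_heavy[keep]]))
}

#' Empirical move-class selection frequencies
#'
#' Draws move classes exactly as the optimizer does (weighted sampling over
#' the classes available in the stage) and tabulates them; used to verify
#' the 100:50:20:2 sampling ratios.
#'
#' @param stage a [stage_config()].
#' @param weights a [sampling_weights()].
#' @param n number of draws.
#' @param has_ligand whether a ligand is present (default TRUE).
#' @param seed integer seed or NULL.
#' @return named table of counts.
#' @export
move_class_frequencies <- function(stage, weights, n, has_ligand = TRUE,
                                   seed = NULL) {
  classes <- available_classes(stage, has_ligand)
  wmap <- c(ligand = weights$ligand, binding_pocket = weights$binding_pocket,
            helix_positional = weights$helix_positional,
            remaining_protein = weights$remaining_protein)
  with_seed(seed, {
    draws <- sample(classes, n, replace = TRUE, prob = wmap[classes])
    table(factor(draws, levels = classes))
  })
}

## ---- move proposal machinery ----------------------------------------------

## Precompute movable torsion definitions (axis atom indices + moved atom
## indices, system numbering) for side chains and backbone.
torsion_catalog <- function(sys) {
  at <- sys$atoms
  side <- list()
  for (r in unique(at$resid[at$group != 0])) {
    rn <- at$resname[at$resid == r][1]
    axes <- SIDECHAIN_CHI_AXES[[rn]] %||% list()
    if (!length(axes)) next
    for (ci in seq_along(axes)) {
      ax <- axes[[ci]]
      i2 <- which(at$resid == r & at$atom == ax[2])
      i3 <- which(at$resid == r & at$atom == ax[3])
      moved_names <- sidechain_downstream(rn, ci)
      mv <- which(at$resid == r & at$atom %in% moved_names)
      if (length(i2) == 1 && length(i3) == 1 && length(mv))
        side[[length(side) + 1]] <- list(resid = r, axis = c(i2, i3), moved = mv)
    }
  }
  ## backbone phi/psi within each helix: moved = all chain atoms C-terminal
  ## of the rotation axis inside the same helix
  backbone <- list()
  for (g in names(sys$groups)) {
    if (g == "0") next
    idx <- sys$groups[[g]]
    resids <- sort(unique(at$resid[idx]))
    for (r in resids[-c(1, length(resids))]) {  # keep helix ends anchored
      iN <- idx[at$resid[idx] == r & at$atom[idx] == "N"]
      iCA <- idx[at$resid[idx] == r & at$atom[idx] == "CA"]
      iC <- idx[at$resid[idx] == r & at$atom[idx] == "C"]
      after <- idx[at$resid[idx] > r]
      sc <- idx[at$resid[idx] == r &
                !(at$atom[idx] %in% c("N", "CA", "C", "O"))]
      iO <- idx[at$resid[idx] == r & at$atom[idx] == "O"]
      if (length(iN) && length(iCA))
        backbone[[length(backbone) + 1]] <- list(
          resid = r, axis = c(iN, iCA), moved = c(sc, iC, iO, after))
      if (length(iCA) && length(iC))
        backbone[[length(backbone) + 1]] <- list(
          resid = r, axis = c(iCA, iC), moved = c(iO, after))
    }
  }
  list(side = side, backbone = backbone)
}

rigid_move_coords <- function(x, idx, trans_sd, rot_sd) {
  sel <- x[idx, , drop = FALSE]
  cen <- colMeans(sel)
  R <- rotation_about_axis(stats::rnorm(3), stats::rnorm(1, 0, rot_sd))
  t <- stats::rnorm(3, 0, trans_sd / sqrt(3))
  x[idx, ] <- t(R %*% t(sweep(sel, 2, cen))) +
    matrix(cen + t, length(idx), 3, byrow = TRUE)
  x
}

torsion_move_coords <- function(x, tors, sd_deg) {
  ang <- stats::rnorm(1, 0, sd_deg)
  axis <- x[tors$axis[2], ] - x[tors$axis[1], ]
  pivot <- x[tors$axis[2], ]
  R <- rotation_about_axis(axis, ang)
  x[tors$moved, ] <- t(R %*% t(sweep(x[tors$moved, , drop = FALSE], 2, pivot))) +
    matrix(pivot, length(tors$moved), 3, byrow = TRUE)
  x
}

## stage-dependent available move classes for the weighted draw
available_classes <- function(stage, has_ligand) {
  cls <- character(0)
  if (has_ligand &&
      any(c("ligand_rigid", "ligand_torsion") %in% stage$free_classes))
    cls <- c(cls, "ligand")
  if (any(c("sidechain_pocket", "sidechain_all") %in% stage$free_classes))
    cls <- c(cls, "binding_pocket")
  if ("helix" %in% stage$free_classes)
    cls <- c(cls, "helix_positional")
  if (any(c("sidechain_all", "backbone") %in% stage$free_classes))
    cls <- c(cls, "remaining_protein")
  cls
}


#' Monte Carlo geometry optimization of one stage
#'
#' Metropolis sampling over the stage's free variable classes. Move classes
#' are drawn according to the sampling weights; the binding pocket is
#' re-defined every `redefine_every` accepted moves; the best-energy state
#' encountered is returned.
#'
#' @param state a ComplexState.
#' @param stage a [stage_config()].
#' @param weights a [sampling_weights()].
#' @param seed integer seed or NULL.
#' @param redefine_every accepted moves between pocket redefinitions
#'   (default 250).
#' @param trace_every record the energy every this many proposals
#'   (default 50).
#' @return list with `state` (best-energy ComplexState, synchronized),
#'   `trace` (data.frame step/energy/temperature/accepted) and
#'   `acceptance_rate`.
#' @export
mc_optimize <- function(state, stage, weights = sampling_weights(),
                        seed = NULL, redefine_every = 250, trace_every = 50) {
  with_seed(seed, {
    sys <- state$sys
    params <- state$params
    params$lambda <- stage$lambda
    coords <- state$coords
    cat_tors <- torsion_catalog(sys)
    has_lig <- length(sys$ligand_idx) > 0
    classes <- available_classes(stage, has_lig)
    if (stage$steps <= 0 || !length(classes)) {
      return(list(state = state, trace = data.frame(), acceptance_rate = NA))
    }
    wmap <- c(ligand = weights$ligand, binding_pocket = weights$binding_pocket,
              helix_positional = weights$helix_positional,
              remaining_protein = weights$remaining_protein)
    pocket <- binding_pocket_residues(state)
    helix_groups <- sys$groups[names(sys$groups) != "0"]
    emode <- if (params$dielectric == "distance") 0L else 1L
    n_atoms <- nrow(coords)
    all_idx0 <- as.integer(seq_len(n_atoms) - 1L)
    ## tether bookkeeping precomputed once: atom row -> tether row
    te <- state$restraints$tethers
    tt_idx <- if (nrow(te))
      match(paste(te$resid, "CA"), paste(sys$atoms$resid, sys$atoms$atom))
    else integer(0)
    if (anyNA(tt_idx)) stop("tethered residue(s) missing from system")
    tt_ref <- as.matrix(te[, c("x", "y", "z")])
    tt_k <- te$k
    atom_tether_row <- rep(NA_integer_, n_atoms)
    if (length(tt_idx)) atom_tether_row[tt_idx] <- seq_along(tt_idx)
    tether_fast <- function(x, scale, rows = seq_along(tt_idx)) {
      if (!length(rows) || scale == 0) return(0)
      sum(tt_k[rows] * scale *
          rowSums((x[tt_idx[rows], , drop = FALSE] -
                   tt_ref[rows, , drop = FALSE])^2))
    }
    has_hb <- nrow(sys$donors) > 0 && length(sys$acceptors) > 0
    full_energy <- function(x, tscale) {
      nb <- cpp_nb_energy(x, sys$eps, sys$sig, sys$q, sys$excl,
                          all_idx0, integer(0),
                          params$lambda, params$vdw_cap, emode)
      nb[["vdw"]] + nb[["elec"]] +
        (if (has_hb) system_hbond_energy(sys, params, x) else 0) +
        tether_fast(x, tscale) +
        anchor_restraint_energy(sys, state$restraints, x) +
        ligand_torsion_energy(sys, state$ligand, x)
    }
    moved_part <- function(x, moved, tscale) {
      rest <- setdiff(seq_len(n_atoms), moved)
      nb <- cpp_nb_energy(x, sys$eps, sys$sig, sys$q, sys$excl,
                          as.integer(moved - 1L), as.integer(rest - 1L),
                          params$lambda, params$vdw_cap, emode)
      hb <- if (has_hb)
        system_hbond_energy(sys, params, x, sel_a = moved, sel_b = rest)
      else 0
      rows <- atom_tether_row[moved]
      rows <- rows[!is.na(rows)]
      nb[["vdw"]] + nb[["elec"]] + hb + tether_fast(x, tscale, rows) +
        anchor_restraint_energy(sys, state$restraints, x) +
        ligand_torsion_energy(sys, state$ligand, x)
    }
    tscale_at <- function(step) {
      f <- if (stage$steps <= 1) 1 else (step - 1) / (stage$steps - 1)
      stage$tether_ramp[1] + f * (stage$tether_ramp[2] - stage$tether_ramp[1])
    }
    e_cur <- full_energy(coords, tscale_at(1))
    best <- list(coords = coords, energy = e_cur)
    n_acc <- 0L
    trace <- list()
    for (step in seq_len(stage$steps)) {
      temp <- stage$t_start * (stage$t_end / stage$t_start)^
        (if (stage$steps <= 1) 0 else (step - 1) / (stage$steps - 1))
      tsc <- tscale_at(step)
      cls <- sample(classes, 1, prob = wmap[classes])
      prop <- coords
      moved <- NULL
      if (cls == "ligand") {
        do_torsion <- "ligand_torsion" %in% stage$free_classes &&
          length(state$ligand$rotatable) && stats::runif(1) < 0.5
        if (do_torsion) {
          rb <- state$ligand$rotatable[[sample.int(length(state$ligand$rotatable), 1)]]
          tors <- list(axis = sys$n_prot + rb$bond, moved = sys$n_prot + rb$moved)
          prop <- torsion_move_coords(prop, tors, 15)
          moved <- tors$moved
        } else {
          prop <- rigid_move_coords(prop, sys$ligand_idx, 0.5, 3)
          moved <- sys$ligand_idx
        }
      } else if (cls == "binding_pocket") {
        cand <- Filter(function(t) t$resid %in% pocket, cat_tors$side)
        if (!length(cand)) next
        tors <- cand[[sample.int(length(cand), 1)]]
        prop <- torsion_move_coords(prop, tors, 15)
        moved <- tors$moved
      } else if (cls == "helix_positional") {
        hidx <- helix_groups[[sample.int(length(helix_groups), 1)]]
        prop <- rigid_move_coords(prop, hidx, 0.5, 3)
        moved <- hidx
      } else {  # remaining_protein
        cand <- Filter(function(t) !(t$resid %in% pocket), cat_tors$side)
        if ("backbone" %in% stage$free_classes)
          cand <- c(cand, cat_tors$backbone)
        if (!length(cand)) next
        tors <- cand[[sample.int(length(cand), 1)]]
        prop <- torsion_move_coords(prop, tors, 15)
        moved <- tors$moved
      }
      ## delta energy: only interactions involving moved atoms change
      e_old_part <- moved_part(coords, moved, tsc)
      e_new_part <- moved_part(prop, moved, tsc)
      de <- e_new_part - e_old_part
      if (de <= 0 || stats::runif(1) < exp(-de / (BOLTZ * temp))) {
        coords <- prop
        e_cur <- e_cur + de
        n_acc <- n_acc + 1L
        if (n_acc %% redefine_every == 0 && has_lig) {
          st_tmp <- state; st_tmp$coords <- coords
          pocket <- binding_pocket_residues(st_tmp)
        }
        if (e_cur < best$energy) best <- list(coords = coords, energy = e_cur)
      }
      if (step %% trace_every == 0 || step == stage$steps) {
        trace[[length(trace) + 1]] <-
          data.frame(step = step, energy = e_cur, temperature = temp,
                     accepted = n_acc)
      }
    }
    ## recompute exactly at the end-of-stage tether scale to kill drift
    best$energy <- full_energy(best$coords, stage$tether_ramp[2])
    state$coords <- best$coords
    state <- sync_state(state)
    list(state = state, energy = best$energy,
         trace = do.call(rbind, trace), acceptance_rate = n_acc / stage$steps)
  })
}

#' Filter models by score threshold or percentile
#'
#' @param models list of model records, each carrying `report$total_score`
#'   (or a numeric vector of scores).
#' @param score_key report field to filter on (default "total_score").
#' @param threshold keep models with score <= threshold.
#' @param percentile keep the best `percentile` % (0 keeps the single best
#'   model, 100 keeps all). Exactly one of threshold/percentile.
#' @return the surviving subset, deterministically ordered (ties by index).
#' @export
select_by_threshold <- function(models, score_key = "total_score",
                                threshold = NULL, percentile = NULL) {
  if (is.numeric(models)) {
    scores <- models
  } else {
    scores <- vapply(models, function(m) m$report[[score_key]], numeric(1))
  }
  n <- length(scores)
  if (!is.null(threshold)) {
    keep <- which(scores <= threshold)
  } else {
    stopifnot(!is.null(percentile), percentile >= 0, percentile <= 100)
    k <- max(1L, as.integer(ceiling(n * percentile / 100)))
    keep <- order(scores, seq_len(n))[seq_len(min(k, n))]
    keep <- sort(keep)
  }
  if (is.numeric(models)) keep else models[keep]
}

#' Run the full four-stage repacking protocol
#'
#' For each model seed: perturb the bundle and ligand, stage-1 optimize with
#' rigid helices and rigid ligand, score and filter (checkpoint 1), run
#' stages 2-3 with growing torsional freedom, score and filter
#' (checkpoint 2), then the final stage 4 with all torsions free and tethers
#' ramped off.
#'
#' @param bundle starting BundleState (the helical homology model).
#' @param ligand a Ligand, or NULL for apo repacking.
#' @param restraints a [restraint_set()] (tethers + ligand anchors).
#' @param stages list of four [stage_config()]s.
#' @param n_models number of stage-1 models to generate.
#' @param seed integer master seed.
#' @param weights a [sampling_weights()].
#' @param amplitudes a [perturb_amplitudes()].
#' @param checkpoint_percentiles best-% kept at the two checkpoints
#'   (default c(15, 25)).
#' @param score_config optional [score_config()] for the checkpoints.
#' @param target optional [target_spec()] for ligand-term scoring.
#' @return list with `models` (surviving model records: state, report, seed,
#'   id), `funnel` (named counts per phase) and `log`.
#' @export
run_protocol <- function(bundle, ligand, restraints,
                         stages = lapply(1:4, stage_config),
                         n_models = 10, seed = 1,
                         weights = sampling_weights(),
                         amplitudes = perturb_amplitudes(),
                         checkpoint_percentiles = c(15, 25),
                         score_config = NULL, target = NULL) {
  score_config <- score_config %||% default_score_config()
  model_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_models))
  models <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    s <- model_seeds[i]
    b <- randomize_bundle(bundle, amplitudes, seed = s)
    lig <- if (!is.null(ligand))
      place_ligand_random(b, ligand, amplitudes, seed = s + 1L) else NULL
    st <- complex_state(b, lig, restraints)
    opt <- mc_optimize(st, stages[[1]], weights, seed = s + 2L)
    models[[i]] <- list(id = i, seed = s, state = opt$state,
                        energy = opt$energy)
  }
  funnel <- c(stage1 = n_models)
  reports <- score_ensemble(lapply(models, `[[`, "state"), score_config,
                            target = target)
  for (i in seq_along(models)) models[[i]]$report <- reports[[i]]
  models <- select_by_threshold(models, percentile = checkpoint_percentiles[1])
  funnel["checkpoint1"] <- length(models)
  if (!length(models)) {
    warning("no models survived checkpoint 1")
    return(list(models = list(), funnel = funnel, seeds = model_seeds))
  }
  for (i in seq_along(models)) {
    st <- models[[i]]$state
    for (sg in 2:3) {
      opt <- mc_optimize(st, stages[[sg]], weights,
                         seed = models[[i]]$seed + sg + 10L)
      st <- opt$state
    }
    models[[i]]$state <- st
    models[[i]]$energy <- opt$energy
  }
  reports <- score_ensemble(lapply(models, `[[`, "state"), score_config,
                            target = target)
  for (i in seq_along(models)) models[[i]]$report <- reports[[i]]
  models <- select_by_threshold(models, percentile = checkpoint_percentiles[2])
  funnel["checkpoint2"] <- length(models)
  if (!length(models)) {
    warning("no models survived checkpoint 2")
    return(list(models = list(), funnel = funnel, seeds = model_seeds))
  }
  for (i in seq_along(models)) {
    opt <- mc_optimize(models[[i]]$state, stages[[4]], weights,
                       seed = models[[i]]$seed + 20L)
    models[[i]]$state <- opt$state
    models[[i]]$energy <- opt$energy
  }
  reports <- score_ensemble(lapply(models, `[[`, "state"), score_config,
                            target = target)
  for (i in seq_along(models)) models[[i]]$report <- reports[[i]]
  funnel["stage4"] <- length(models)
  list(models = models, funnel = funnel, seeds = model_seeds)
}
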