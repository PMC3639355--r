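## Ligand handling: a small-molecule container with a bond graph, perceived
## rotatable bonds and torsion manipulation; analytic toy fixtures and
## RDKit-backed real-ligand fixtures ((R)-NPA, (S)-cyanopindolol) built from
## packaged SMILES at run time.

PACKAGED_SMILES <- c(
  ## (R)-N-propylapomorphine, protonated tertiary amine, catechol
  "R-NPA" = "CCC[NH+]1CCc2cccc3c2[C@H]1Cc1ccc(O)c(O)c13",
  ## (S)-cyanopindolol, protonated secondary amine, indole-2-carbonitrile
  "S-cyanopindolol" = "CC(C)[NH2+]C[C@@H](O)COc1cccc2[nH]c(C#N)cc12"
)

#' Construct a Ligand
#'
#' @param name ligand name.
#' @param atoms data.frame with columns atom, element, x, y, z, charge,
#'   aromatic (logical).
#' @param bonds integer matrix with columns i, j (1-based) and order
#'   (aromatic = 4).
#' @return object of class Ligand with perceived rotatable bonds.
#' @export
new_ligand <- function(name, atoms, bonds) {
  stopifnot(all(c("atom", "element", "x", "y", "z", "charge", "aromatic")
                %in% names(atoms)))
  lig <- structure(list(name = name, atoms = atoms, bonds = bonds),
                   class = "Ligand")
  lig$rotatable <- perceive_rotatable(lig)
  lig
}

#' Coordinate matrix of a ligand
#' @param lig a Ligand.
#' @return n-by-3 matrix in Angstrom.
#' @export
ligand_coords <- function(lig) as.matrix(lig$atoms[, c("x", "y", "z")])

lig_adjacency <- function(lig) {
  n <- nrow(lig$atoms)
  adj <- vector("list", n)
  if (nrow(lig$bonds)) for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds[k, 1]; j <- lig$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

## connected component of `start` with the i-j bond removed
component_without_bond <- function(adj, start, i, j) {
  seen <- logical(length(adj))
  queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if ((v == i && w == j) || (v == j && w == i)) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

perceive_rotatable <- function(lig) {
  adj <- lig_adjacency(lig)
  el <- lig$atoms$element
  heavy_deg <- vapply(seq_along(adj), function(i)
    sum(el[adj[[i]]] != "H"), integer(1))
  out <- list()
  if (!nrow(lig$bonds)) return(out)
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds[k, 1]; j <- lig$bonds[k, 2]
    if (lig$bonds[k, 3] != 1) next                  # single bonds only
    if (el[i] == "H" || el[j] == "H") next
    if (heavy_deg[i] < 2 || heavy_deg[j] < 2) next  # no terminal twists
    comp_j <- component_without_bond(adj, j, i, j)
    if (i %in% comp_j) next                         # ring bond
    ## torsion path a-i-j-b with heavy reference atoms
    a <- setdiff(adj[[i]][el[adj[[i]]] != "H"], j)[1]
    b <- setdiff(adj[[j]][el[adj[[j]]] != "H"], i)[1]
    if (is.na(a) || is.na(b)) next
    moved <- setdiff(comp_j, j)
    out[[length(out) + 1]] <- list(bond = c(i, j), path = c(a, i, j, b),
                                   moved = moved)
  }
  out
}

#' Set one rotatable torsion of a ligand
#'
#' Rotates the distal side of rotatable bond `k` so that the torsion along
#' its reference path equals `angle` degrees.
#'
#' @param lig a Ligand.
#' @param k rotatable-bond index (see `lig$rotatable`).
#' @param angle target torsion, degrees.
#' @return the Ligand with updated coordinates.
#' @export
set_ligand_torsion <- function(lig, k, angle) {
  rb <- lig$rotatable[[k]]
  X <- ligand_coords(lig)
  cur <- dihedral(X[rb$path[1], ], X[rb$path[2], ], X[rb$path[3], ],
                  X[rb$path[4], ])
  delta <- angle - cur
  axis <- X[rb$path[3], ] - X[rb$path[2], ]
  R <- rotation_about_axis(axis, delta)
  pivot <- X[rb$path[3], ]
  X[rb$moved, ] <- t(R %*% t(sweep(X[rb$moved, , drop = FALSE], 2, pivot))) +
    matrix(pivot, length(rb$moved), 3, byrow = TRUE)
  lig$atoms[, c("x", "y", "z")] <- X
  lig
}

## ---- analytic toy fixtures -------------------------------------------------

toy_cation_ligand <- function() {
  ## ammonium-like single-heavy-atom cation
  r <- 1.03
  td <- acos(-1 / 3) * 180 / pi
  N <- c(0, 0, 0)
  H1 <- c(0, 0, r)
  H2 <- as.numeric(rot_y(td) %*% H1)
  H3 <- as.numeric(rot_z(120) %*% H2)
  H4 <- as.numeric(rot_z(240) %*% H2)
  atoms <- data.frame(
    atom = c("N1", "H1", "H2", "H3", "H4"),
    element = c("N", "H", "H", "H", "H"),
    x = c(N[1], H1[1], H2[1], H3[1], H4[1]),
    y = c(N[2], H1[2], H2[2], H3[2], H4[2]),
    z = c(N[3], H1[3], H2[3], H3[3], H4[3]),
    charge = c(0.0, 0.25, 0.25, 0.25, 0.25),
    aromatic = FALSE, stringsAsFactors = FALSE)
  bonds <- cbind(rep(1L, 4), 2:5, 1L)
  new_ligand("toy_cation", atoms, bonds)
}

toy_catechol_amine_ligand <- function() {
  ## dopamine-like: catechol ring + protonated ethylamine tail
  ring_az <- seq(0, 300, by = 60)
  C <- t(vapply(ring_az, function(a)
    1.39 * c(cos(a * pi / 180), sin(a * pi / 180), 0), numeric(3)))
  radial <- function(i, d) C[i, ] + d * unitv(C[i, ])
  O3 <- radial(3, 1.36); O4 <- radial(4, 1.36)
  HO3 <- place_atom(C[2, ], C[3, ], O3, 0.96, 109, 180)
  HO4 <- place_atom(C[5, ], C[4, ], O4, 0.96, 109, 180)
  C7 <- radial(1, 1.50)
  C8 <- place_atom(C[2, ], C[1, ], C7, 1.53, 111, 90)
  N <- place_atom(C[1, ], C7, C8, 1.49, 111, 180)
  HN <- lapply(c(60, 180, 300), function(t)
    place_atom(C7, C8, N, 1.03, 109.5, t))
  xyz <- rbind(C, O3, O4, HO3, HO4, C7, C8, N, HN[[1]], HN[[2]], HN[[3]])
  atoms <- data.frame(
    atom = c(paste0("C", 1:6), "O3", "O4", "HO3", "HO4", "C7", "C8", "N1",
             "HN1", "HN2", "HN3"),
    element = c(rep("C", 6), "O", "O", "H", "H", "C", "C", "N",
                "H", "H", "H"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = c(0, 0, 0.10, 0.10, 0, 0, -0.40, -0.40, 0.30, 0.30,
               0, 0.10, 0.00, 0.30, 0.30, 0.30),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 10)), stringsAsFactors = FALSE)
  bonds <- rbind(
    cbind(1:6, c(2:6, 1), 4L),            # aromatic ring
    c(3, 7, 1L), c(4, 8, 1L),             # C-OH
    c(7, 9, 1L), c(8, 10, 1L),            # O-H
    c(1, 11, 1L), c(11, 12, 1L), c(12, 13, 1L),  # chain
    cbind(13, 14:16, 1L))                 # N-H
  new_ligand("toy_catechol_amine", atoms, bonds)
}

embed_from_smiles <- function(name, smiles, seed = 42, n_confs = 10) {
  script <- system.file("python", "embed_smiles.py", package = "helixpack")
  if (script == "") stop("embed_smiles.py not found in package")
  req <- jsonlite::toJSON(list(smiles = smiles, seed = seed,
                               n_confs = n_confs), auto_unbox = TRUE)
  out <- tryCatch(
    system2("python", script, input = as.character(req), stdout = TRUE,
            stderr = FALSE),
    warning = function(w) stop("python/RDKit embedding failed for ", name),
    error = function(e) stop("python/RDKit embedding unavailable for ", name))
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyMatrix = TRUE)
  coords <- res$coords
  if (!is.matrix(coords)) coords <- do.call(rbind, coords)
  atoms <- data.frame(
    atom = paste0(res$elements, seq_along(res$elements)),
    element = res$elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = res$charges, aromatic = res$aromatic, stringsAsFactors = FALSE)
  bonds <- res$bonds
  if (!is.matrix(bonds)) bonds <- do.call(rbind, bonds)
  storage.mode(bonds) <- "integer"
  bonds[, 1:2] <- bonds[, 1:2] + 1L
  new_ligand(name, atoms, bonds)
}

#' Ligand fixtures
#'
#' Deterministic ligand conformers: analytic toys (`toy_cation`, a
#' tetrahedral ammonium cation; `toy_catechol_amine`, a dopamine-like
#' catechol with a protonated ethylamine tail) and packaged-SMILES fixtures
#' (`R-NPA`, `S-cyanopindolol`) embedded at run time with RDKit (lowest
#' MMFF energy of `n_confs` embeddings at a fixed seed). Basic nitrogens are
#' protonated in the packaged SMILES.
#'
#' @param name one of "toy_cation", "toy_catechol_amine", "R-NPA",
#'   "S-cyanopindolol".
#' @param seed embedding seed for the SMILES-based fixtures (default 42;
#'   fixed so conformers are stable across runs).
#' @param n_confs embeddings to generate before picking the lowest-energy
#'   one (default 10).
#' @return a Ligand.
#' @export
make_ligand_fixture <- function(name, seed = 42, n_confs = 10) {
  switch(name,
    toy_cation = toy_cation_ligand(),
    toy_catechol_amine = toy_catechol_amine_ligand(),
    `R-NPA` = embed_from_smiles(name, PACKAGED_SMILES[["R-NPA"]], seed, n_confs),
    `S-cyanopindolol` = embed_from_smiles(name,
      PACKAGED_SMILES[["S-cyanopindolol"]], seed, n_confs),
    stop("unknown ligand fixture: ", name))
}

#' Catechol-oxygen to basic-nitrogen distances of a ligand
#'
#' Finds hydroxyl oxygens on aromatic carbons (catechol oxygens) and the
#' protonated (H-bearing, positively charged or quaternary-protonated)
#' nitrogen, and returns the O..N distances.
#'
#' @param lig a Ligand.
#' @return numeric vector of distances (Angstrom).
#' @export
catechol_amine_distances <- function(lig) {
  adj <- lig_adjacency(lig)
  el <- lig$atoms$element
  X <- ligand_coords(lig)
  is_oh <- vapply(seq_len(nrow(lig$atoms)), function(i) {
    el[i] == "O" && any(el[adj[[i]]] == "H") &&
      any(lig$atoms$aromatic[adj[[i]]])
  }, logical(1))
  is_basic_n <- vapply(seq_len(nrow(lig$atoms)), function(i) {
    el[i] == "N" && any(el[adj[[i]]] == "H") && !lig$atoms$aromatic[i]
  }, logical(1))
  if (!any(is_oh) || !any(is_basic_n))
    stop("ligand has no catechol O / basic N pair")
  n_idx <- which(is_basic_n)[1]
  vapply(which(is_oh), function(o) vnorm(X[o, ] - X[n_idx, ]), numeric(1))
}

## ---- minimal SDF (V2000) I/O ----------------------------------------------

#' Write ligand conformers as a multi-record SDF file
#' @param ligs a Ligand or list of Ligands.
#' @param path output path.
#' @export
write_sdf <- function(ligs, path) {
  if (inherits(ligs, "Ligand")) ligs <- list(ligs)
  con <- file(path, "w")
  on.exit(close(con))
  for (lig in ligs) {
    n <- nrow(lig$atoms); m <- nrow(lig$bonds)
    writeLines(c(lig$name, "  helixpack", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       lig$atoms$x, lig$atoms$y, lig$atoms$z,
                       lig$atoms$element), con)
    if (m) writeLines(sprintf("%3d%3d%3d  0  0  0  0", lig$bonds[, 1],
                              lig$bonds[, 2], pmin(lig$bonds[, 3], 3)), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
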