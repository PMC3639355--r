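## Bundle model: a 7TM helix bundle represented as rigid helical segments,
## each placed by six virtual variables (radial distance, azimuth, axial
## offset, tilt, tilt azimuth, spin) relative to a fixed bundle frame, layered
## over immutable intra-helix internal coordinates.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

helix_ca_coords <- function(helix) {
  a <- helix$atoms
  as.matrix(a[a$atom == "CA", c("x", "y", "z")])
}

#' Coordinate matrix of a helix segment
#' @param helix a HelixSegment.
#' @return n-by-3 matrix in Angstrom.
#' @export
helix_coords <- function(helix) as.matrix(helix$atoms[, c("x", "y", "z")])

#' Geometric center of a helix (mean of CA positions)
#' @param helix a HelixSegment.
#' @export
helix_center <- function(helix) colMeans(helix_ca_coords(helix))

#' Axis of a helix (first principal component of CA positions, N to C)
#' @param helix a HelixSegment.
#' @export
helix_axis <- function(helix) principal_axis(helix_ca_coords(helix))

new_helix_segment <- function(helix_id, atoms) {
  resids <- sort(unique(atoms$resid))
  if (length(resids) < 6) stop("helix ", helix_id, " has fewer than 6 residues")
  if (!all(diff(resids) == 1))
    stop("helix ", helix_id, " residue numbering is not contiguous")
  for (r in resids) {
    present <- atoms$atom[atoms$resid == r]
    miss <- setdiff(BACKBONE_ATOMS, present)
    if (length(miss))
      stop("residue ", r, " (helix ", helix_id, ") missing backbone atom(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(helix_id = helix_id, atoms = atoms,
                 span = c(resids[1], resids[length(resids)])),
            class = "HelixSegment")
}

n_residues <- function(helix) as.integer(helix$span[2] - helix$span[1] + 1)

## Orthonormal bundle frame: column 3 = axis; columns 1-2 by Gram-Schmidt
## from the global x (or y) axis.
make_frame <- function(origin, axis) {
  z <- unitv(axis)
  seedv <- if (abs(sum(z * c(1, 0, 0))) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- unitv(seedv - sum(seedv * z) * z)
  y <- cross3(z, x)
  list(origin = as.numeric(origin), axes = cbind(x, y, z))
}

## Body-local coordinates of a helix: origin at the CA mean, axes from the
## helix principal axis and the first-CA radial direction. Fixed thereafter;
## every later placement is a rigid motion of these coordinates.
helix_local_coords <- function(helix) {
  X <- helix_coords(helix)
  ca <- helix_ca_coords(helix)
  m <- colMeans(ca)
  u <- principal_axis(ca)
  radial <- ca[1, ] - m
  e1 <- radial - sum(radial * u) * u
  if (vnorm(e1) < 1e-9) e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(e1 - sum(e1 * u) * u)
  e2 <- cross3(u, e1)
  M <- cbind(e1, e2, u)
  sweep(X, 2, m) %*% M
}

## vars = (r, azimuth, z, tilt, tilt_azimuth, spin); angles in degrees
place_rotation <- function(vars) {
  rot_zyz(vars[5], vars[4], vars[6] - vars[5])
}

wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

vars_from_placement <- function(p, R) {
  e <- euler_zyz(R)
  c(r = vnorm(p[1:2]),
    azimuth = if (vnorm(p[1:2]) < 1e-12) 0 else atan2(p[2], p[1]) * 180 / pi,
    z = p[3],
    tilt = unname(e["beta"]),
    tilt_azimuth = wrap180(unname(e["alpha"])),
    spin = wrap180(unname(e["gamma"] + e["alpha"])))
}

## Recover (position, rotation) of a helix in the bundle frame from its
## current coordinates and its body-local template.
placement_from_coords <- function(helix, local, frame) {
  X <- helix_coords(helix)
  m <- colMeans(helix_ca_coords(helix))
  B <- frame$axes
  R_global <- kabsch(local, sweep(X, 2, m))$R
  list(p = as.numeric(t(B) %*% (m - frame$origin)), R = t(B) %*% R_global)
}

#' Rigid-body virtual variables of one helix
#'
#' Returns the six placement variables (radial distance r and azimuth in the
#' membrane plane, axial offset z, tilt and tilt azimuth of the helix axis
#' relative to the bundle axis, and spin about the helix axis) of a helix in
#' the bundle frame. Distances in Angstrom, angles in degrees.
#'
#' @param bundle a BundleState.
#' @param helix_id integer 1..n.
#' @export
get_rigid_variables <- function(bundle, helix_id) {
  bundle$rigid_vars[helix_id, ]
}

recompute_derived <- function(bundle) {
  centers <- t(vapply(bundle$helices, helix_center, numeric(3)))
  w <- vapply(bundle$helices, n_residues, integer(1))
  bundle$helix_centers <- centers
  bundle$bundle_center <- colSums(centers * w) / sum(w)
  bundle$bundle_axis <- bundle_axis(bundle)
  bundle
}

#' Construct a BundleState from helix segments
#'
#' Computes the residue-count-weighted bundle center, the clustered weighted
#' bundle axis, fixes the bundle frame, and initializes per-helix rigid
#' variables from the coordinates.
#'
#' @param helices list of HelixSegment objects.
#' @return a BundleState.
#' @export
new_bundle_state <- function(helices) {
  if (length(helices) < 2) stop("a bundle needs at least 2 helices")
  bundle <- structure(list(helices = helices), class = "BundleState")
  centers <- t(vapply(helices, helix_center, numeric(3)))
  w <- vapply(helices, n_residues, integer(1))
  center0 <- colSums(centers * w) / sum(w)
  bundle$helix_centers <- centers
  bundle$bundle_center <- center0
  axis0 <- bundle_axis(bundle)
  bundle$frame <- make_frame(center0, axis0)
  bundle$local <- lapply(helices, helix_local_coords)
  rv <- t(vapply(seq_along(helices), function(i) {
    pl <- placement_from_coords(helices[[i]], bundle$local[[i]], bundle$frame)
    vars_from_placement(pl$p, pl$R)
  }, numeric(6)))
  colnames(rv) <- c("r", "azimuth", "z", "tilt", "tilt_azimuth", "spin")
  bundle$rigid_vars <- rv
  recompute_derived(bundle)
}

#' Extract helical segments from an atomic structure
#'
#' Pulls the residue spans out of a structure table (e.g. from
#' [read_pdb()]), discards everything outside the spans (loops, termini),
#' and initializes a BundleState with rigid variables derived from the
#' coordinates.
#'
#' @param structure data.frame of atoms (resid, resname, atom, element,
#'   x, y, z).
#' @param ranges list of length-2 integer vectors `c(first, last)`, one per
#'   helix, in helix order.
#' @return a BundleState.
#' @export
extract_helices <- function(structure, ranges) {
  helices <- lapply(seq_along(ranges), function(i) {
    rg <- ranges[[i]]
    sel <- structure$resid >= rg[1] & structure$resid <= rg[2]
    atoms <- structure[sel, , drop = FALSE]
    found <- unique(atoms$resid)
    missing <- setdiff(seq(rg[1], rg[2]), found)
    if (length(missing))
      stop("helix ", i, ": residue(s) ", paste(missing, collapse = ", "),
           " absent from structure")
    rownames(atoms) <- NULL
    if (is.null(atoms$charge))
      atoms$charge <- mapply(protein_charge, atoms$resname, atoms$atom)
    new_helix_segment(i, atoms)
  })
  new_bundle_state(helices)
}

#' Rigidly re-place one helix from its virtual variables
#'
#' Rebuilds the helix coordinates from the six placement variables; all
#' intra-helix internal coordinates are untouched (the body template is
#' immutable).
#'
#' @param bundle a BundleState.
#' @param helix_id integer.
#' @param vars numeric length-6 (r, azimuth, z, tilt, tilt_azimuth, spin).
#' @return updated BundleState.
#' @export
set_rigid_variables <- function(bundle, helix_id, vars) {
  vars <- as.numeric(vars)
  if (length(vars) != 6 || any(!is.finite(vars)))
    stop("vars must be 6 finite numbers")
  if (helix_id < 1 || helix_id > length(bundle$helices))
    stop("invalid helix_id: ", helix_id)
  B <- bundle$frame$axes
  p <- c(vars[1] * cos(vars[2] * pi / 180),
         vars[1] * sin(vars[2] * pi / 180), vars[3])
  R <- place_rotation(vars)
  L <- bundle$local[[helix_id]]
  X <- t(B %*% R %*% t(L)) +
    matrix(bundle$frame$origin + as.numeric(B %*% p),
           nrow(L), 3, byrow = TRUE)
  bundle$helices[[helix_id]]$atoms[, c("x", "y", "z")] <- X
  rv <- vars_from_placement(p, R)
  bundle$rigid_vars[helix_id, ] <- rv
  recompute_derived(bundle)
}

#' Apply an incremental rigid motion to a helix
#'
#' Composes a rotation (3x3, acting about the helix center) and a translation
#' (global frame, Angstrom) onto the current placement, then refreshes the
#' stored virtual variables from the resulting coordinates.
#'
#' @param bundle a BundleState.
#' @param helix_id integer.
#' @param R 3x3 rotation matrix (global frame), default identity.
#' @param t numeric length-3 translation, default zero.
#' @return updated BundleState.
#' @export
move_helix <- function(bundle, helix_id, R = diag(3), t = c(0, 0, 0)) {
  helix <- bundle$helices[[helix_id]]
  X <- helix_coords(helix)
  m <- colMeans(helix_ca_coords(helix))
  Xn <- t(R %*% t(sweep(X, 2, m))) +
    matrix(m + t, nrow(X), 3, byrow = TRUE)
  bundle$helices[[helix_id]]$atoms[, c("x", "y", "z")] <- Xn
  pl <- placement_from_coords(bundle$helices[[helix_id]],
                              bundle$local[[helix_id]], bundle$frame)
  bundle$rigid_vars[helix_id, ] <- vars_from_placement(pl$p, pl$R)
  recompute_derived(bundle)
}

## Ideal alpha-helix O(i)..O(i+4) carbonyl distance (Angstrom), measured on
## the ideal-geometry builder; kinks are detected as excess over this.
IDEAL_O_O4_DIST <- 6.35

#' Split a helix into straight segments at kinks
#'
#' Successive carbonyl-oxygen i to i+4 distances are compared with the ideal
#' alpha-helix value; where the deviation exceeds `tol` the helix is split.
#' Every returned segment has >= 4 residues; each segment's axis is the first
#' principal component of its backbone atoms.
#'
#' @param helix a HelixSegment.
#' @param tol kink tolerance in Angstrom (default 1.0).
#' @param ideal ideal O..O(i+4) distance (default 6.17 A).
#' @return list of `list(resids, axis)`.
#' @export
helix_axis_segments <- function(helix, tol = 1.0, ideal = IDEAL_O_O4_DIST) {
  a <- helix$atoms
  resids <- seq(helix$span[1], helix$span[2])
  n <- length(resids)
  ocoord <- t(vapply(resids, function(r) {
    as.numeric(a[a$resid == r & a$atom == "O", c("x", "y", "z")])
  }, numeric(3)))
  seg_axis <- function(rr) {
    bb <- a[a$resid %in% rr & a$atom %in% BACKBONE_ATOMS, c("x", "y", "z")]
    principal_axis(as.matrix(bb))
  }
  if (n < 8) return(list(list(resids = resids, axis = seg_axis(resids))))
  d <- vapply(seq_len(n - 4), function(i) vnorm(ocoord[i + 4, ] - ocoord[i, ]),
              numeric(1))
  kinked <- which(abs(d - ideal) > tol)
  if (!length(kinked)) return(list(list(resids = resids, axis = seg_axis(resids))))
  ## merge consecutive flagged windows; cut at the center of each run
  runs <- split(kinked, cumsum(c(1, diff(kinked) != 1)))
  cuts <- vapply(runs, function(k) as.integer(round(mean(k))) + 2L, integer(1))
  bounds <- c(0L, sort(unique(cuts)), n)
  segs <- list()
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1]
    if (hi - lo + 1 < 4) {  # too short: merge into previous segment
      if (length(segs)) {
        segs[[length(segs)]]$resids <- c(segs[[length(segs)]]$resids, resids[lo:hi])
        segs[[length(segs)]]$axis <- seg_axis(segs[[length(segs)]]$resids)
      } else {
        segs[[1]] <- list(resids = resids[lo:hi], axis = NULL)
      }
      next
    }
    segs[[length(segs) + 1]] <- list(resids = resids[lo:hi],
                                     axis = seg_axis(resids[lo:hi]))
  }
  for (i in seq_along(segs))
    if (is.null(segs[[i]]$axis)) segs[[i]]$axis <- seg_axis(segs[[i]]$resids)
  segs
}

#' Overall bundle axis
#'
#' Helix axis vectors are sign-aligned (antiparallel helices flipped),
#' single-link clustered at a 30 degree cutoff, and up to floor(0.10 * N)
#' vectors outside the main cluster are excluded; the remainder are summed
#' with residue-count weights and normalized.
#'
#' @param bundle a BundleState.
#' @param cluster_cutoff angular cutoff in degrees (default 30).
#' @return unit length-3 vector.
#' @export
bundle_axis <- function(bundle, cluster_cutoff = 30) {
  vs <- lapply(bundle$helices, helix_axis)
  w <- vapply(bundle$helices, n_residues, integer(1))
  if (any(vapply(vs, vnorm, numeric(1)) < 1e-9))
    stop("degenerate (zero) helix axis vector")
  N <- length(vs)
  ref <- vs[[1]]
  vs <- lapply(vs, function(v) if (sum(v * ref) < 0) -v else v)
  V <- do.call(rbind, vs)
  ## single-link clustering on angular distance
  ang <- function(i, j) {
    acos(max(-1, min(1, sum(V[i, ] * V[j, ])))) * 180 / pi
  }
  cl <- seq_len(N)
  repeat {
    merged <- FALSE
    for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
      if (cl[i] != cl[j] && ang(i, j) <= cluster_cutoff) {
        cl[cl == cl[j]] <- cl[i]; merged <- TRUE
      }
    }
    if (!merged) break
  }
  sizes <- table(cl)
  main <- as.integer(names(sizes)[which.max(sizes)])
  outliers <- which(cl != main)
  k <- floor(0.10 * N)
  keep <- seq_len(N)
  if (length(outliers) && k > 0) {
    mean_main <- unitv(colSums(V[cl == main, , drop = FALSE] *
                               w[cl == main]))
    dev <- vapply(outliers, function(i)
      acos(max(-1, min(1, sum(V[i, ] * mean_main)))) * 180 / pi, numeric(1))
    drop_idx <- outliers[order(-dev)][seq_len(min(k, length(outliers)))]
    keep <- setdiff(keep, drop_idx)
  }
  unitv(colSums(V[keep, , drop = FALSE] * w[keep]))
}

#' Membrane frame of a bundle
#'
#' The membrane mid-plane passes through the bundle center with the bundle
#' axis as its normal.
#'
#' @param bundle a BundleState.
#' @return list with `point` and `normal`.
#' @export
membrane_frame <- function(bundle) {
  list(point = bundle$bundle_center, normal = bundle$bundle_axis)
}

#' Signed helix-center elevations from the membrane mid-plane
#' @param bundle a BundleState.
#' @return numeric vector, one value per helix (Angstrom).
#' @export
helix_elevations <- function(bundle) {
  fr <- membrane_frame(bundle)
  as.numeric((bundle$helix_centers -
              matrix(fr$point, nrow(bundle$helix_centers), 3, byrow = TRUE)) %*%
             fr$normal)
}

#' Flatten a bundle into a single atom table
#' @param bundle a BundleState.
#' @return data.frame of all helix atoms with a `helix` column.
#' @export
bundle_atoms <- function(bundle) {
  do.call(rbind, lapply(bundle$helices, function(h) {
    cbind(h$atoms, helix = h$helix_id)
  }))
}

#' @export
print.BundleState <- function(x, ...) {
  cat("BundleState:", length(x$helices), "helices,",
      sum(vapply(x$helices, function(h) nrow(h$atoms), integer(1))), "atoms\n")
  spans <- vapply(x$helices, function(h) paste(h$span, collapse = "-"), "")
  cat("  spans:", paste(spans, collapse = ", "), "\n")
  invisible(x)
}
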