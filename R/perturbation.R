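## Stochastic expansion of conformational space: randomized rigid helix
## displacement and randomized ligand placement. All operations take an
## explicit seed and are bit-reproducible.

#' Perturbation amplitudes
#'
#' Defaults follow the stated randomization scheme: each helix is moved
#' 0-5 Angstrom radially outward in the membrane plane, tilted within
#' +/- 20 degrees about its center, spun within +/- 30 degrees about its own
#' axis, and the ligand is placed at least 5 Angstrom from the bundle.
#'
#' @param max_translation maximal outward translation, Angstrom (default 5).
#' @param max_tilt maximal tilt magnitude, degrees (default 20).
#' @param max_spin maximal axial spin magnitude, degrees (default 30).
#' @param ligand_min_distance minimal ligand-bundle heavy-atom distance,
#'   Angstrom (default 5).
#' @return object of class PerturbAmplitudes.
#' @export
perturb_amplitudes <- function(max_translation = 5, max_tilt = 20,
                               max_spin = 30, ligand_min_distance = 5) {
  vals <- c(max_translation, max_tilt, max_spin, ligand_min_distance)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("perturbation amplitudes must be finite and >= 0")
  structure(list(max_translation = max_translation, max_tilt = max_tilt,
                 max_spin = max_spin,
                 ligand_min_distance = ligand_min_distance),
            class = "PerturbAmplitudes")
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## unit vector perpendicular to u at azimuth a (degrees) in u's normal plane
perp_at_azimuth <- function(u, a) {
  seedv <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(seedv - sum(seedv * u) * u)
  e2 <- cross3(u, e1)
  cos(a * pi / 180) * e1 + sin(a * pi / 180) * e2
}

#' Randomly displace every helix of a bundle
#'
#' Each helix is independently translated radially outward from the bundle
#' center in the membrane plane by U(0, max_translation), tilted about its
#' own center by U(-max_tilt, +max_tilt) in a uniformly random tilt plane,
#' and spun about its own axis by U(-max_spin, +max_spin).
#'
#' @param bundle a BundleState.
#' @param amplitudes a [perturb_amplitudes()].
#' @param seed integer seed (reproducible) or NULL to use the current RNG
#'   stream.
#' @return perturbed BundleState.
#' @export
randomize_bundle <- function(bundle, amplitudes = perturb_amplitudes(),
                             seed = NULL) {
  with_seed(seed, {
    B <- bundle$frame$axes
    zhat <- B[, 3]
    for (i in seq_along(bundle$helices)) {
      m <- helix_center(bundle$helices[[i]])
      u <- helix_axis(bundle$helices[[i]])
      ## outward radial direction in the membrane plane
      rad <- m - bundle$frame$origin
      rad <- rad - sum(rad * zhat) * zhat
      outward <- if (vnorm(rad) < 1e-9) perp_at_azimuth(zhat, stats::runif(1, 0, 360))
                 else unitv(rad)
      dr <- stats::runif(1, 0, amplitudes$max_translation)
      tilt <- stats::runif(1, -amplitudes$max_tilt, amplitudes$max_tilt)
      tilt_az <- stats::runif(1, 0, 360)
      spin <- stats::runif(1, -amplitudes$max_spin, amplitudes$max_spin)
      R <- rotation_about_axis(perp_at_azimuth(u, tilt_az), tilt) %*%
           rotation_about_axis(u, spin)
      bundle <- move_helix(bundle, i, R = R, t = dr * outward)
    }
    bundle
  })
}

#' Randomize ligand placement outside the bundle
#'
#' Randomizes the ligand's internal torsions and orientation, then places it
#' along a random direction from the bundle center so that the minimal
#' ligand-bundle heavy-atom distance is at least
#' `amplitudes$ligand_min_distance` (and within 3 A beyond it, to remain
#' reachable by the optimizer).
#'
#' @param bundle a BundleState.
#' @param ligand a Ligand (see [make_ligand_fixture()]).
#' @param amplitudes a [perturb_amplitudes()].
#' @param seed integer seed or NULL.
#' @param max_attempts placement attempts before erroring (default 1000).
#' @return the Ligand with new coordinates.
#' @export
place_ligand_random <- function(bundle, ligand,
                                amplitudes = perturb_amplitudes(),
                                seed = NULL, max_attempts = 1000) {
  with_seed(seed, {
    prot <- as.matrix(bundle_atoms(bundle)[, c("x", "y", "z")])
    dmin <- amplitudes$ligand_min_distance
    for (attempt in seq_len(max_attempts)) {
      lig <- ligand
      ## torsion randomization
      if (length(lig$rotatable)) {
        for (k in seq_along(lig$rotatable)) {
          lig <- set_ligand_torsion(lig, k, stats::runif(1, -180, 180))
        }
      }
      ## uniform random orientation about the ligand centroid
      ax <- stats::rnorm(3)
      ang <- stats::runif(1, 0, 360)
      X <- ligand_coords(lig)
      cen <- colMeans(X)
      X <- t(rotation_about_axis(ax, ang) %*% t(sweep(X, 2, cen))) +
        matrix(cen, nrow(X), 3, byrow = TRUE)
      ## random approach direction; slide along it to land in
      ## [dmin, dmin + 3] of closest approach
      dirv <- unitv(stats::rnorm(3))
      target <- dmin + stats::runif(1, 0, 3)
      cen0 <- bundle$bundle_center
      X <- sweep(X, 2, cen0 - colMeans(X), `+`)
      heavy <- lig$atoms$element != "H"
      gap <- function(shift) {
        min_pair_distance(X[heavy, , drop = FALSE] +
                          matrix(shift * dirv, sum(heavy), 3, byrow = TRUE),
                          prot[bundle_atoms(bundle)$element != "H", , drop = FALSE])
      }
      lo <- 0; hi <- 100
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (gap(mid) < target) lo <- mid else hi <- mid
      }
      shift <- hi
      g <- gap(shift)
      if (g >= dmin) {
        lig$atoms[, c("x", "y", "z")] <-
          X + matrix(shift * dirv, nrow(X), 3, byrow = TRUE)
        return(lig)
      }
    }
    stop("could not place ligand >= ", dmin, " A from the bundle in ",
         max_attempts, " attempts")
  })
}
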