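test_that("extract_helices performs identity extraction on the fixture", {
  b <- ideal_bundle()
  at <- bundle_atoms(b)
  # add decoy loop atoms outside the spans; they must be discarded
  loops <- data.frame(resid = c(21L, 25L), resname = "GLY",
                      atom = c("CA", "CA"), element = "C",
                      x = 0, y = 0, z = 50, charge = 0, helix = NA)
  structure <- rbind(at, loops)
  b2 <- extract_helices(structure, bundle_spans(b))
  expect_length(b2$helices, 7)
  expect_equal(coords_of(b2), coords_of(b), tolerance = 1e-12)
  expect_false(any(bundle_atoms(b2)$resid %in% c(21, 25)))
})

test_that("beta1AR-style spans yield the printed segment lengths", {
  # helical regions W40-S68, L75-V103, G110-A142, R155-I177, R205-E233,
  # H286-V314, D322-Y343 applied to a renumbered fixture
  spans <- list(c(40, 68), c(75, 103), c(110, 142), c(155, 177),
                c(205, 233), c(286, 314), c(322, 343))
  lens <- vapply(spans, function(s) as.integer(s[2] - s[1] + 1), integer(1))
  expect_equal(lens, c(29L, 29L, 33L, 23L, 29L, 29L, 22L))
  spec <- fixture_spec(helix_length = max(lens))
  b <- make_ideal_bundle(spec)
  # renumber each helix to start at the span start, trim to span length
  structure <- do.call(rbind, lapply(1:7, function(k) {
    a <- b$helices[[k]]$atoms
    a$resid <- a$resid - min(a$resid) + spans[[k]][1]
    a[a$resid <= spans[[k]][2], ]
  }))
  b2 <- extract_helices(structure, spans)
  got <- vapply(b2$helices, function(h) h$span[2] - h$span[1] + 1, numeric(1))
  expect_equal(got, as.numeric(lens))
})

test_that("extract_helices errors identify missing residues and atoms", {
  b <- ideal_bundle()
  at <- bundle_atoms(b)
  expect_error(extract_helices(at, list(c(1, 25), c(31, 50), c(61, 80),
                                        c(91, 110), c(121, 140), c(151, 170),
                                        c(181, 200))),
               "2[1-5]")
  # missing backbone atom
  at2 <- at[!(at$resid == 5 & at$atom == "O"), ]
  expect_error(extract_helices(at2, bundle_spans(b)), "residue 5")
})

test_that("set_rigid_variables: identity, involution and translation oracle", {
  b <- ideal_bundle()
  v <- get_rigid_variables(b, 4)
  expect_equal(coords_of(set_rigid_variables(b, 4, v)), coords_of(b),
               tolerance = 1e-9)
  # pure axial spin by 180 twice returns the original coordinates
  v2 <- v; v2[["spin"]] <- v[["spin"]] + 180
  b2 <- set_rigid_variables(b, 4, v2)
  v3 <- get_rigid_variables(b2, 4); v3[["spin"]] <- v3[["spin"]] + 180
  b3 <- set_rigid_variables(b2, 4, v3)
  expect_equal(coords_of(b3), coords_of(b), tolerance = 1e-6)
  # in-plane translation against an explicit rotation-matrix oracle
  v4 <- v
  v4[["r"]] <- v[["r"]] + 3  # radially outward by 3 A
  b4 <- set_rigid_variables(b, 4, v4)
  old_c <- helix_center(b$helices[[4]])
  new_c <- helix_center(b4$helices[[4]])
  expect_equal(sqrt(sum((new_c - old_c)^2)), 3, tolerance = 1e-9)
  # internal structure untouched: zero RMSD after re-superposition
  kb <- kabsch(helix_coords(b4$helices[[4]]), helix_coords(b$helices[[4]]))
  expect_lt(kb$rmsd, 1e-9)
  expect_error(set_rigid_variables(b, 4, c(1, NA, 0, 0, 0, 0)), "finite")
  expect_error(set_rigid_variables(b, 99, rep(0, 6)), "helix_id")
})

test_that("rigid moves preserve all intra-helix distances", {
  b <- ideal_bundle()
  X0 <- helix_coords(b$helices[[2]])
  D0 <- as.matrix(dist(X0))
  set.seed(4)
  for (i in 1:5) {
    b2 <- set_rigid_variables(b, 2, random_vars())
    D1 <- as.matrix(dist(helix_coords(b2$helices[[2]])))
    expect_lt(max(abs(D1 - D0)), 1e-9)
  }
})

test_that("rigid-variable round trip holds for random variable sets", {
  b <- ideal_bundle()
  set.seed(5)
  for (i in 1:200) {
    v <- random_vars()
    b2 <- set_rigid_variables(b, 3, v)
    expect_vars_equal(get_rigid_variables(b2, 3), v, tol = 1e-6)
  }
})

test_that("helix_axis_segments splits at kinks and respects minimum size", {
  # straight ideal helix: one segment, axis within 2 degrees of construction
  h <- ideal_bundle()$helices[[1]]
  segs <- helix_axis_segments(h)
  expect_length(segs, 1)
  ang <- acos(abs(sum(segs[[1]]$axis * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  # kinked helix built analytically: split into two segments at the kink
  ka <- kinked_helix_atoms(10, 10, 30)
  hk <- helixpack:::new_helix_segment(1, ka)
  segs <- helix_axis_segments(hk)
  expect_length(segs, 2)
  split_at <- max(segs[[1]]$resids)
  expect_true(abs(split_at - 10) <= 2)
  # inter-segment angle close to the constructed kink
  a12 <- acos(abs(sum(segs[[1]]$axis * segs[[2]]$axis))) * 180 / pi
  expect_gt(a12, 15)
  # 6-residue helix returns a single segment
  h6 <- helixpack:::new_helix_segment(1, build_peptide(rep("ALA", 6)))
  expect_length(helix_axis_segments(h6), 1)
})

test_that("bundle_axis: weighted mean and outlier exclusion", {
  b <- ideal_bundle()
  expect_equal(abs(sum(bundle_axis(b) * c(0, 0, 1))), 1, tolerance = 1e-6)
  # one of 7 tilted by 40 degrees: floor(0.7) = 0 exclusions, axis equals the
  # residue-weighted mean of all sign-aligned axes (closed-form oracle)
  v <- get_rigid_variables(b, 2)
  v[["tilt"]] <- v[["tilt"]] - 40
  b2 <- set_rigid_variables(b, 2, v)
  axes <- lapply(b2$helices, helix_axis)
  ref <- axes[[1]]
  axes <- lapply(axes, function(a) if (sum(a * ref) < 0) -a else a)
  w <- vapply(b2$helices, function(h) nrow(h$atoms[h$atoms$atom == "CA", ]),
              numeric(1))
  oracle <- colSums(do.call(rbind, axes) * w)
  oracle <- oracle / sqrt(sum(oracle^2))
  expect_equal(abs(sum(bundle_axis(b2) * oracle)), 1, tolerance = 1e-9)
  # 10-helix synthetic bundle with one near-orthogonal outlier: excluded
  b10 <- make_ideal_bundle(fixture_spec(n_helices = 10, ring_radius = 16))
  v <- get_rigid_variables(b10, 5)
  v[["tilt"]] <- v[["tilt"]] + 80
  b10 <- set_rigid_variables(b10, 5, v)
  ax <- bundle_axis(b10)
  # brute-force oracle: weighted mean of the 9 non-outliers
  axes <- lapply(b10$helices[-5], helix_axis)
  ref <- axes[[1]]
  axes <- lapply(axes, function(a) if (sum(a * ref) < 0) -a else a)
  w <- rep(20, 9)
  oracle <- colSums(do.call(rbind, axes) * w)
  oracle <- oracle / sqrt(sum(oracle^2))
  expect_equal(abs(sum(ax * oracle)), 1, tolerance = 1e-9)
})

test_that("membrane frame and elevations behave analytically", {
  b <- ideal_bundle()
  expect_lt(max(abs(helix_elevations(b))), 1e-6)
  # one helix shifted +4 A along the axis; with 7 equal-weight helices the
  # mid-plane recentres so the shifted helix sits at 4*6/7 and the others at
  # -4/7 (analytic recomputation)
  v <- get_rigid_variables(b, 6)
  v[["z"]] <- v[["z"]] + 4
  b2 <- set_rigid_variables(b, 6, v)
  el <- helix_elevations(b2)
  expect_equal(el[6], 4 * 6 / 7, tolerance = 1e-6)
  expect_equal(el[-6], rep(-4 / 7, 6), tolerance = 1e-6)
  # residue-weighted elevations always sum to zero by construction
  w <- vapply(b2$helices, function(h) h$span[2] - h$span[1] + 1, numeric(1))
  expect_lt(abs(sum(w * el)), 1e-9)
  # frame invariance: rigid global transform leaves elevations unchanged
  at <- bundle_atoms(b2)
  R <- rotation_about_axis(c(1, 1, 0), 35)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at[, c("x", "y", "z")] <- sweep(xyz, 2, c(3, -7, 11), `+`)
  b3 <- extract_helices(at, bundle_spans(b2))
  expect_equal(sort(helix_elevations(b3)), sort(el), tolerance = 1e-6)
})
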