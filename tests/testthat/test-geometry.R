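test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(1)
  x <- matrix(stats::rnorm(15), 5, 3)
  id <- kabsch_superpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  R <- idpkit:::.rotation_about(c(0, 0, 1), 37)
  y <- sweep(x %*% t(R), 2, c(1, 2, 3), "+")
  expect_equal(kabsch_superpose(y, x)$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(kabsch_superpose(y, x)$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD is symmetric, rigid-invariant, and matches the
           quaternion oracle on random pairs", {
  set.seed(7)
  for (k in 1:100) {
    a <- matrix(stats::rnorm(15, sd = 3), 5, 3)
    b <- matrix(stats::rnorm(15, sd = 3), 5, 3)
    r1 <- kabsch_superpose(a, b)$rmsd
    expect_equal(r1, quaternion_rmsd(a, b), tolerance = 1e-9)
    expect_equal(r1, kabsch_superpose(b, a)$rmsd, tolerance = 1e-9)
    expect_equal(kabsch_superpose(random_rigid_transform(a), b)$rmsd, r1,
                 tolerance = 1e-9)
  }
})

test_that("rmsd_series is zero on copies and analytic in no-fit mode", {
  p <- helix16()
  x <- get_frame(p, 1)
  tr <- new_trajectory(p$topology, list(x, x, x))
  rs <- rmsd_series(tr, selection = "backbone")
  expect_equal(rs$rmsd, c(0, 0, 0), tolerance = 1e-9)
  # single atom displaced by d among N atoms, no superposition: d / sqrt(N)
  sel <- select_atoms(p, "calpha")
  x2 <- x
  x2[sel[1], ] <- x2[sel[1], ] + c(3, 0, 0)
  tr2 <- new_trajectory(p$topology, list(x, x2))
  rs2 <- rmsd_series(tr2, reference = 1, selection = sel, fit = FALSE)
  expect_equal(rs2$rmsd[2], 3 / sqrt(length(sel)), tolerance = 1e-12)
})

test_that("RMSF is zero for static trajectories and exact for oscillations", {
  p <- helix16()
  x <- get_frame(p, 1)
  static <- new_trajectory(p$topology, list(x, x, x, x))
  expect_equal(max(rmsf(static)$atom), 0, tolerance = 1e-9)
  # one atom oscillating +/- d along x in a pre-aligned frame set: RMSF = d
  d <- 0.8
  xp <- x; xm <- x
  xp[1, 1] <- xp[1, 1] + d
  xm[1, 1] <- xm[1, 1] - d
  osc <- new_trajectory(p$topology, list(xp, xm, xp, xm))
  r <- rmsf(osc, align = FALSE)
  expect_equal(r$atom[1], d, tolerance = 1e-12)
  expect_equal(max(r$atom[-1]), 0, tolerance = 1e-12)
})

test_that("mean RMSF grows monotonically with ensemble noise", {
  seq8 <- "ADGSVEKF"
  means <- sapply(c(0.05, 0.15, 0.3), function(ns) {
    ce <- compose_ensemble(ensemble_spec(seq8, 20, c(beta = 1),
                                         noise_sigma = ns, seed = 5))
    rmsf(ce$trajectory)$stats["mean"]
  })
  expect_true(all(diff(means) > 0))
})

test_that("gyration tensor satisfies its invariants", {
  expect_equal(gyration(matrix(c(1, 2, 3), 1, 3),
                        mass_weighted = FALSE)$rg, 0)
  # two equal masses 2 A apart: rg 1, anisotropy 0 (collinear)
  two <- gyration(rbind(c(0, 0, 0), c(2, 0, 0)), mass_weighted = FALSE)
  expect_equal(two$rg, 1, tolerance = 1e-12)
  expect_equal(two$anisotropy, 0, tolerance = 1e-12)
  expect_equal(two$kappa2, 1, tolerance = 1e-12)
  # regular tetrahedron: fully symmetric, anisotropy 1
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  g <- gyration(tet, mass_weighted = FALSE)
  expect_equal(g$anisotropy, 1, tolerance = 1e-12)
  expect_equal(g$kappa2, 0, tolerance = 1e-12)
  # planar symmetric ring: eigenvalues (x, x, 0) -> anisotropy 0.5
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(cos(th), sin(th), 0)
  expect_equal(gyration(ring, mass_weighted = FALSE)$anisotropy, 0.5,
               tolerance = 1e-12)
})

test_that("trace identity, rigid invariance and linear scaling hold", {
  p <- helix16()
  set.seed(3)
  x <- get_frame(p, 1)
  g <- gyration(p)
  expect_equal(sum(g$eigenvalues), g$rg^2, tolerance = 1e-9)
  gr <- gyration(random_rigid_transform(x), topology = p$topology)
  expect_equal(gr$rg, g$rg, tolerance = 1e-9)
  expect_equal(gr$eigenvalues, g$eigenvalues, tolerance = 1e-9)
  g2 <- gyration(x * 2, topology = p$topology)
  expect_equal(g2$rg, 2 * g$rg, tolerance = 1e-9)
  expect_true(g$anisotropy >= 0 && g$anisotropy <= 1)
})

test_that("shape_series summarizes per-frame descriptors", {
  p <- extended16()
  x <- get_frame(p, 1)
  tr <- new_trajectory(p$topology, list(x, x * 1.05))
  sh <- shape_series(tr)
  expect_equal(nrow(sh$per_frame), 2)
  expect_equal(sh$summary$rg[["min"]], sh$per_frame$rg[1], tolerance = 1e-9)
  expect_true(sh$prolate)  # an extended chain is rod-like
  expect_lt(sh$per_frame$anisotropy[1], 0.05)
})

test_that("dihedral sign convention and mirror behaviour are correct", {
  p1 <- c(0, 0, 0); p2 <- c(1, 0, 0); p3 <- c(1, 1, 0); p4 <- c(1, 1, 1)
  expect_equal(dihedral_points(p1, p2, p3, p4), -90, tolerance = 1e-12)
  # invariant under rigid transforms, sign-flipped under mirror reflection
  set.seed(11)
  pts <- rbind(p1, p2, p3, p4)
  tp <- random_rigid_transform(pts)
  expect_equal(dihedral_points(tp[1, ], tp[2, ], tp[3, ], tp[4, ]), -90,
               tolerance = 1e-9)
  mir <- pts %*% diag(c(1, 1, -1))
  expect_equal(dihedral_points(mir[1, ], mir[2, ], mir[3, ], mir[4, ]), 90,
               tolerance = 1e-12)
})

test_that("extended build gives (180, 180) dihedrals", {
  dh <- dihedrals(extended16())
  expect_equal(abs(dh$phi[1, -1]), rep(180, 15), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(abs(dh$psi[1, -16]), rep(180, 15), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("ring geometry measures centroid separation and interplanar angle", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring1 <- cbind(cos(th), sin(th), 0)
  ring2 <- sweep(ring1, 2, c(0, 0, 3.5), "+")
  xyz <- rbind(ring1, ring2)
  g <- ring_geometry(xyz, 1:6, 7:12)
  expect_equal(g$centroid_distance, 3.5, tolerance = 1e-12)
  expect_equal(g$interplanar_angle, 0, tolerance = 1e-9)
  perp <- cbind(cos(th), 0, sin(th))   # shares the centroid, perpendicular
  g2 <- ring_geometry(rbind(ring1, perp), 1:6, 7:12)
  expect_equal(g2$centroid_distance, 0, tolerance = 1e-12)
  expect_equal(g2$interplanar_angle, 90, tolerance = 1e-9)
})

test_that("harmonic metal-site energies follow k (x - x0)^2", {
  par <- metal_site_parameters()
  at_min <- harmonic_energy(par,
                            bonds = data.frame(label = par$bonds$label,
                                               r = par$bonds$r0),
                            angles = data.frame(label = par$angles$label,
                                                theta = par$angles$theta0))
  expect_equal(at_min$total, 0, tolerance = 1e-12)
  # Pt-N_His at 2.15 A with (r0 = 2.05, k = 127): 127 * 0.1^2 = 1.27
  e <- harmonic_energy(par, bonds = data.frame(label = "Pt-NHis", r = 2.15))
  expect_equal(unname(e$bond["Pt-NHis"]), 1.27, tolerance = 1e-9)
  expect_true(all(harmonic_energy(par,
    bonds = data.frame(label = par$bonds$label,
                       r = par$bonds$r0 + 0.07))$bond > 0))
  expect_error(harmonic_energy(par, bonds = data.frame(label = "Pt-X", r = 2)),
               "no bond parameters")
})
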