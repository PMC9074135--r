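test_that("measured backbone dihedrals reproduce the request exactly", {
  set.seed(42)
  n <- 6
  for (rep in 1:5) {
    pp <- cbind(stats::runif(n, -179, 180), stats::runif(n, -179, 180))
    p <- build_peptide("ADGSVE", pp)
    dh <- dihedrals(p)
    expect_equal(dh$phi[1, 2:n], pp[2:n, 1], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(dh$psi[1, 1:(n - 1)], pp[1:(n - 1), 2], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("all built residues are L-amino acids", {
  p <- build_peptide(abeta_sequences()$abeta42, c(-70, 140))
  at <- p$topology$atoms
  x <- get_frame(p, 1)
  pos <- function(r, nm) x[which(at$resid == r & at$name == nm)[1], ]
  for (r in unique(at$resid)) {
    if (!"CB" %in% at$name[at$resid == r]) next  # glycine
    improper <- dihedral_points(pos(r, "C"), pos(r, "N"),
                                pos(r, "CA"), pos(r, "CB"))
    expect_gt(improper, 0)  # D-residues would give the mirror (negative) value
    expect_equal(improper, 120, tolerance = 1)
  }
})

test_that("unknown residue letters are rejected", {
  expect_error(build_peptide("AXZ", c(180, 180)), "sequence error")
  expect_error(build_peptide("", c(180, 180)), "sequence error")
})

test_that("idealized phenanthroline is planar C12N2 with three rings", {
  ph <- build_phenanthroline()
  at <- ph$topology$atoms
  expect_equal(n_atoms(ph), 14)
  expect_equal(sum(at$element == "C"), 12)
  expect_equal(sum(at$element == "N"), 2)
  xyz <- get_frame(ph, 1)
  pf <- idpkit:::.plane_fit(xyz)
  expect_lt(max(abs(sweep(xyz, 2, pf$centroid) %*% pf$normal)), 1e-6)
  rings <- ligand_rings(ph$topology)
  expect_length(rings, 3)
  for (r in rings) expect_length(r, 6)
  # aromatic bond lengths within the standard range
  d <- as.matrix(dist(xyz))
  bonds <- d[d > 0 & d < 1.75]
  expect_true(all(bonds > 1.35 & bonds < 1.45))
})

test_that("Pt(phen) fragment places Pt at the Pt-N equilibrium distance", {
  ph <- build_phenanthroline(include_pt = TRUE)
  expect_equal(n_atoms(ph), 15)
  at <- ph$topology$atoms
  xyz <- get_frame(ph, 1)
  pt <- which(at$element == "PT")
  nn <- which(at$element == "N")
  dd <- sqrt(rowSums(sweep(xyz[nn, , drop = FALSE], 2, xyz[pt, ])^2))
  expect_equal(dd, c(2.06, 2.06), tolerance = 1e-9)
})

test_that("ligand stacking poses reproduce the requested geometry", {
  p <- extended16()
  for (req in list(c(3.5, 0), c(4.0, 90), c(3.55, 0.18), c(3.81, 12.7))) {
    st <- pose_ligand_stack(p, "ring(TYR10)", req[1], req[2])
    ri <- select_atoms(st, "ring(TYR10)")
    lr <- ligand_rings(st$topology, get_frame(st, 1))
    g <- ring_geometry(get_frame(st, 1), ri,
                       idpkit:::.ligand_central_ring(lr))
    expect_equal(g$centroid_distance, req[1], tolerance = 1e-3)
    expect_equal(g$interplanar_angle, req[2], tolerance = 1e-3)
  }
  expect_error(pose_ligand_stack(p, "ring(TYR10)", -1), "positive")
})

test_that("alpha-helical build forms i+4 -> i backbone hydrogen bonds", {
  p <- helix16()
  x <- get_frame(p, 1)
  at <- p$topology$atoms
  pos <- function(r, nm) x[which(at$resid == r & at$name == nm)[1], ]
  for (i in 1:12) {
    dON <- sqrt(sum((pos(i, "O") - pos(i + 4, "N"))^2))
    expect_lt(dON, 3.5)
    expect_lt(ks_hbond_energy(p, i + 4, i), -0.5)
  }
  # the classic 2.8-3.2 A O...N window holds at the ideal helix geometry
  ph <- build_peptide(abeta_sequences()$abeta16, c(-57, -47))
  xh <- get_frame(ph, 1)
  ath <- ph$topology$atoms
  posh <- function(r, nm) xh[which(ath$resid == r & ath$name == nm)[1], ]
  dON <- sapply(1:12, function(i) sqrt(sum((posh(i, "O") - posh(i + 4, "N"))^2)))
  expect_true(all(dON > 2.8 & dON < 3.2))
})

test_that("extended build spans ~3.6 A per residue", {
  p <- extended16()
  ca <- select_atoms(p, "calpha")
  x <- get_frame(p, 1)[ca, ]
  span <- sqrt(sum((x[16, ] - x[1, ])^2))
  expect_gt(span / 15, 3.5)
  expect_lt(span / 15, 3.8)
})

test_that("beta-sheet builder produces strand geometry in both senses", {
  sa <- fixture("sheet_anti", function() build_beta_sheet(sense = "antiparallel"))
  sp <- fixture("sheet_par", function() build_beta_sheet(sense = "parallel"))
  la <- assign_dssp(sa)
  lp <- assign_dssp(sp)
  expect_gte(sum(la[1, ] == "E"), 6)
  expect_gte(sum(lp[1, ] == "E"), 6)
})
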