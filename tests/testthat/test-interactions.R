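test_that("helical backbone is dominated by i+4 -> i hydrogen bonds", {
  hb <- hydrogen_bonds(helix16(), dist_cutoff = 3.5)
  cl <- classify_hbonds(hb$records)
  expect_gte(cl[["i+4->i"]], 10)
  expect_equal(unname(cl[["i+3->i"]] + cl[["i+5->i"]]), 0)
  # every interior residue accepts from its i+4 partner
  recs <- hb$records[hb$records$backbone_backbone &
                       hb$records$sequence_offset == 4, ]
  expect_true(all(1:12 %in% recs$acceptor_res))
})

test_that("3,10 build is dominated by i+3 -> i bonds", {
  p3 <- build_peptide(abeta_sequences()$abeta16, "three10")
  cl <- classify_hbonds(hydrogen_bonds(p3, dist_cutoff = 3.5)$records)
  expect_gt(cl[["i+3->i"]], cl[["i+4->i"]])
  expect_gte(cl[["i+3->i"]], 10)
})

test_that("distance cutoff excludes long contacts and is monotone", {
  p <- helix16()
  n30 <- sum(classify_hbonds(hydrogen_bonds(p, 3.0)$records))
  n35 <- sum(classify_hbonds(hydrogen_bonds(p, 3.5)$records))
  n25 <- sum(classify_hbonds(hydrogen_bonds(p, 2.5)$records))
  expect_true(n25 <= n30 && n30 <= n35)
  # a 3.5 A donor-acceptor pair is absent at the default 3.0 A cutoff
  expect_equal(sum(hydrogen_bonds(p, 3.0)$records$distance > 3.0), 0)
})

test_that("per-frame counts are constant over duplicated static frames", {
  p <- helix16()
  x <- get_frame(p, 1)
  tr <- new_trajectory(p$topology, rep(list(x), 10))
  hb <- hydrogen_bonds(tr, dist_cutoff = 3.5)
  expect_equal(hb$counts$stats[["sd"]], 0)
  expect_equal(hb$counts$stats[["min"]], hb$counts$stats[["max"]])
})

test_that("side-chain donors route to the side-chain category", {
  ce <- compose_ensemble(ensemble_spec(abeta_sequences()$abeta16, 4, c(coil = 1),
    seed = 3, injections = list(list(type = "hbond", donor_res = 14,
      donor_atom = "ND1", acceptor_res = 11, acceptor_atom = "O",
      distance = 2.9, occupancy = 1))))
  hb <- hydrogen_bonds(ce$trajectory)
  rec <- hb$records[hb$records$donor_res == 14 & hb$records$acceptor_res == 11, ]
  expect_true(nrow(rec) >= 4)
  expect_false(any(rec$backbone_backbone))
  expect_gte(classify_hbonds(hb$records)[["side-chain"]], 4)
})

test_that("hbond occupancy is the fraction of bonded frames", {
  rec <- data.frame(frame = 1:34, donor = 1, acceptor = 2, donor_res = 14,
                    acceptor_res = 11, distance = 2.9, angle = 170,
                    backbone_backbone = FALSE, sequence_offset = 3,
                    key = "HIS14:ND1-GLU11:O")
  occ <- hbond_occupancy(rec, 100)
  expect_equal(occ$occupancy, 0.34)
  expect_equal(nrow(hbond_occupancy(NULL, 10)), 0)
  expect_equal(nrow(hbond_occupancy(rec, 100, min_occupancy = 0.5)), 0)
})

test_that("salt bridges respect the 3.2 A O-N contact definition", {
  # constructive fixture: Glu carboxylate vs Lys ammonium (a single N-zeta,
  # so the realized O-N distance is exactly the requested one)
  base <- build_peptide("EAK", c(180, 180))
  at <- base$topology$atoms
  x <- get_frame(base, 1)
  o_idx <- which(at$resid == 1 & at$name %in% c("OE1", "OE2"))
  nz <- which(at$resid == 3 & at$name == "NZ")
  place <- function(target) {
    xx <- x
    mob <- which(at$resid == 3 & !at$name %in% c("N", "CA", "C", "O", "OXT"))
    dm <- sqrt(colSums((t(xx[o_idx, ]) - xx[nz, ])^2))
    k <- o_idx[which.min(dm)]
    u <- idpkit:::.unit(xx[nz, ] - xx[k, ])
    shift <- (xx[k, ] + target * u) - xx[nz, ]
    xx[mob, ] <- sweep(xx[mob, , drop = FALSE], 2, shift, "+")
    # the other carboxylate O must not slip under the target distance
    stopifnot(min(sqrt(colSums((t(xx[o_idx, ]) - xx[nz, ])^2))) >=
                target - 1e-9)
    xx
  }
  tr <- new_trajectory(base$topology, list(place(3.0), place(3.3)))
  sb <- salt_bridges(tr, include_termini = FALSE)
  row <- sb[sb$key == "Glu1-Lys3", ]
  expect_equal(row$occupancy, 0.5)  # frame at 3.0 counted, frame at 3.3 not
  expect_equal(row$mean_min_dist, 3.15, tolerance = 1e-6)
})

test_that("salt-bridge detection is invariant under rigid transforms", {
  set.seed(5)
  ce <- compose_ensemble(ensemble_spec(abeta_sequences()$abeta16, 4, c(coil = 1),
    seed = 8, injections = list(list(type = "salt_bridge", acidic_res = 3,
      basic_res = 5, distance = 3.0, occupancy = 0.5))))
  tr <- ce$trajectory
  moved <- tr
  for (f in seq_len(n_frames(tr))) {
    moved$coords[, , f] <- random_rigid_transform(tr$coords[, , f])
  }
  expect_equal(salt_bridges(moved)$occupancy, salt_bridges(tr)$occupancy)
})

test_that("a topology without charged residues warns and returns empty", {
  p <- build_peptide("AGSAG", c(180, 180))
  expect_warning(sb <- salt_bridges(p, include_termini = FALSE), "no charged")
  expect_equal(nrow(sb), 0)
})

test_that("ligand contact fractions follow the 5 A criterion", {
  p <- extended16()
  near <- pose_ligand_stack(p, "ring(TYR10)", 4.0, 0)
  expect_equal(ligand_contacts(near, 10)$contact_fraction, 1)
  far <- pose_ligand_stack(p, "ring(TYR10)", 25, 0)
  expect_equal(ligand_contacts(far, 10)$contact_fraction, 0)
  expect_error(ligand_contacts(p, 10), "no ligand")
})

test_that("stacking search recovers poses and identifies the closest frame", {
  p <- extended16()
  st <- pose_ligand_stack(p, "ring(TYR10)", 3.5, 0)
  res <- stacking_search(st)
  expect_equal(res$closest$ring, "Tyr10")
  expect_equal(res$closest$centroid_distance, 3.5, tolerance = 1e-3)
  expect_equal(res$closest$interplanar_angle, 0, tolerance = 1e-3)
  # one injected close-stack frame among distant frames is the argmin
  ce <- compose_ensemble(ensemble_spec(abeta_sequences()$abeta16, 10, c(coil = 1),
    seed = 6, injections = list(list(type = "stack", ring = "ring(TYR10)",
      distance = 3.5, angle = 0, occupancy = 0.1))))
  res2 <- stacking_search(ce$trajectory)
  injected <- which(ce$truth$stack_ringTYR10)
  expect_equal(res2$closest$closest_frame, injected)
  expect_equal(res2$occupancy, 0.1)
})

test_that("contact maps average hand-computable distances", {
  p <- build_peptide("GG", c(180, 180))
  ca <- select_atoms(p, "calpha")
  mk <- function(d) {
    x <- get_frame(p, 1)
    x[ca[2], ] <- x[ca[1], ] + c(d, 0, 0)
    x
  }
  tr <- new_trajectory(p$topology, list(mk(6), mk(8)))
  cm <- contact_map(tr)
  expect_equal(cm[1, 2], 7)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), c(0, 0))
})

test_that("per-frame contact maps satisfy the triangle inequality", {
  ce <- compose_ensemble(ensemble_spec("ADGSVEKF", 1, c(coil = 1), seed = 4))
  cm <- contact_map(ce$trajectory)
  n <- nrow(cm)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    expect_lte(cm[i, k], cm[i, j] + cm[j, k] + 1e-9)
  }
})
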