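test_that("single ATOM line parses to a one-atom, one-frame trajectory", {
  txt <- paste0("ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
                "  1.00  0.00           C")
  tr <- read_pdb_models(txt)
  expect_equal(n_frames(tr), 1)
  expect_equal(n_atoms(tr), 1)
  expect_equal(as.vector(get_frame(tr, 1)), c(1, 2, 3))
  expect_false(tr$topology$atoms$is_ligand)
})

test_that("MODEL/ENDMDL blocks become frames and HETATM flags ligands", {
  block <- c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
             "HETATM    2  N1  PHN L   2       1.400   0.000   0.000")
  txt <- c(rbind(sprintf("MODEL %8d", 1:3),
                 matrix(rep(block, 3), nrow = 2), "ENDMDL"))
  tr <- read_pdb_models(paste(txt, collapse = "\n"))
  expect_equal(n_frames(tr), 3)
  expect_equal(tr$topology$atoms$is_ligand, c(FALSE, TRUE))
  expect_equal(tr$topology$atoms$element, c("C", "N"))
})

test_that("malformed records and inconsistent models raise informative errors", {
  expect_error(read_pdb_models("ATOM      1  CA  ALA A   1     bad"),
               "line 1")
  bad <- paste(
    "MODEL 1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000",
    "ENDMDL", "MODEL 2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
    "ENDMDL", sep = "\n")
  expect_error(read_pdb_models(bad), "model 2")
})

test_that("write/read round-trip preserves coordinates, names and indices", {
  p <- helix16()
  xyz <- get_frame(p, 1)
  tr <- new_trajectory(p$topology, list(xyz, xyz + 0.5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(tr, f)
  lines <- readLines(f)
  expect_length(grep("^MODEL", lines), 2)
  expect_length(grep("^ENDMDL", lines), 2)
  expect_true(grep("^MODEL +1$", lines) < grep("^MODEL +2$", lines))
  rt <- read_pdb_models(f)
  expect_equal(rt$coords, round(tr$coords, 3), tolerance = 1e-9)
  expect_equal(rt$topology$atoms$name, tr$topology$atoms$name)
  expect_equal(rt$topology$atoms$resid, tr$topology$atoms$resid)
  expect_equal(rt$topology$atoms$resname, tr$topology$atoms$resname)
  # second round trip is the identity on the already-written file
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(rt, f2)
  expect_equal(read_pdb_models(f2)$coords, rt$coords)
})

test_that("parser agrees with bio3d on a multi-model file", {
  skip_if_not_installed("bio3d")
  p <- helix16()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_models(p, f)
  b <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(b$atom), n_atoms(p))
  expect_equal(matrix(b$xyz[1, ], ncol = 3, byrow = TRUE),
               round(get_frame(p, 1), 3), ignore_attr = TRUE)
  expect_equal(b$atom$resno, p$topology$atoms$resid)
})

test_that("coordinates beyond the fixed-column field width are rejected", {
  p <- build_peptide("AG", c(180, 180))
  x <- get_frame(p, 1)
  x[1, 1] <- 123456.0
  tr <- new_trajectory(p$topology, x)
  expect_error(write_pdb_models(tr, withr::local_tempfile()), "field width")
})

test_that("selection grammar resolves backbone, calpha, ranges and rings", {
  p <- extended16()
  expect_length(select_atoms(p, "calpha"), 16)
  expect_length(select_atoms(p, "backbone"), 64)
  at <- p$topology$atoms
  ring <- select_atoms(p, "ring(TYR10)")
  expect_setequal(at$name[ring], c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
  expect_true(all(at$resid[ring] == 10))
  his <- select_atoms(p, "ring(HIS6)")
  expect_length(his, 5)
  expect_length(select_atoms(p, "resid 3-5"), sum(at$resid %in% 3:5))
  expect_setequal(at$name[select_atoms(p, "name CA CB")],
                  c("CA", "CB"))
  expect_error(select_atoms(p, "ring(GLY9)"), "selection error")
  expect_error(select_atoms(p, "resname XYZ"), "selection error")
})

test_that("selection is idempotent and backbone/sidechain partition peptide", {
  p <- helix16()
  bb <- select_atoms(p, "backbone")
  expect_identical(bb, sort(unique(bb)))
  pep <- select_atoms(p, "peptide")
  sc <- setdiff(pep, bb)
  expect_identical(sort(c(bb, sc)), pep)
})

test_that("canonical amyloid-beta sequences are exposed", {
  s <- abeta_sequences()
  expect_equal(s$abeta16, "DAEFRHDSGYEVHHQK")
  expect_equal(nchar(s$abeta42), 42)
  expect_equal(substr(s$abeta16, 6, 6), "H")     # His6, the Pt-binding site
  expect_equal(substr(s$abeta16, 16, 16), "K")   # Lys16
  expect_equal(substr(s$abeta42, 42, 42), "A")   # Ala42
  expect_equal(substr(s$abeta42, 1, 16), s$abeta16)  # Abeta16 prefix of 42
})
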