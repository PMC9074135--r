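# Residue chemistry tables used by the builder, the selection grammar and the
# interaction detectors. All geometry is idealized (Engh & Huber-like bond
# lengths/angles); side chains use one fixed extended rotamer per residue type.

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, PT = 195.084
)

.aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.aa_one <- structure(names(.aa_three), names = unname(.aa_three))

#' Infer the element symbol of a PDB atom
#'
#' Strips digits and primes from an atom name and maps the leading letters to
#' an element. Two-letter elements recognised here are limited to what this
#' package's systems contain (Pt); everything else resolves by first letter.
#'
#' @param name atom-name string (e.g. `"CA"`, `"OD1"`, `"NZ"`, `"PT"`).
#' @return element symbol string.
#' @keywords internal
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (nm == "") stop("cannot infer element from atom name '", name, "'")
  if (nm %in% c("PT")) return("PT")
  first <- substr(nm, 1, 1)
  if (!first %in% names(.element_masses)) {
    stop("unknown element for atom name '", name, "'")
  }
  first
}

.element_mass <- function(element) {
  m <- .element_masses[element]
  if (any(is.na(m))) {
    stop("no mass for element(s): ", paste(element[is.na(m)], collapse = ", "))
  }
  unname(m)
}

# Side-chain internal-coordinate templates. Each row places one atom by the
# natural-extension (NeRF) construction: bond |new-c|, angle (b,c,new),
# torsion (a,b,c,new), references resolved within the residue (backbone
# N/CA/C included). CB uses the improper torsion C-N-CA-CB = +120 deg, which
# fixes L-chirality. Aromatic rings are closed exactly by the polygon
# constructor (.ring_specs), not by chained NeRF placements.
.cb_row <- function() {
  data.frame(name = "CB", a = "C", b = "N", c = "CA",
             bond = 1.530, angle = 110.4, torsion = 120, stringsAsFactors = FALSE)
}

.sc_row <- function(name, a, b, c, bond, angle, torsion) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             torsion = torsion, stringsAsFactors = FALSE)
}

.sidechain_templates <- list(
  GLY = NULL,
  ALA = .cb_row(),
  SER = rbind(.cb_row(), .sc_row("OG",  "N",  "CA", "CB", 1.417, 110.8, 180)),
  CYS = rbind(.cb_row(), .sc_row("SG",  "N",  "CA", "CB", 1.808, 114.4, 180)),
  THR = rbind(.cb_row(),
              .sc_row("OG1", "N",  "CA", "CB", 1.433, 109.6, 180),
              .sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, -60)),
  VAL = rbind(.cb_row(),
              .sc_row("CG1", "N",  "CA", "CB", 1.521, 110.5, 180),
              .sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, -60)),
  LEU = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.530, 116.3, 180),
              .sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
              .sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ILE = rbind(.cb_row(),
              .sc_row("CG1", "N",  "CA", "CB", 1.530, 110.4, 180),
              .sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, -60),
              .sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 180),
              .sc_row("SD",  "CA", "CB", "CG", 1.803, 112.7, 180),
              .sc_row("CE",  "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.495, 104.5, 30),
              .sc_row("CD",  "CA", "CB", "CG", 1.507, 106.1, -30)),
  ASP = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.516, 112.6, 180),
              .sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
              .sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.516, 112.6, 180),
              .sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
              .sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.530, 114.1, 180),
              .sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
              .sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
              .sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.530, 114.1, 180),
              .sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
              .sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
              .sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.530, 114.1, 180),
              .sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
              .sc_row("CE",  "CB", "CG", "CD", 1.520, 111.3, 180),
              .sc_row("NZ",  "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.530, 114.1, 180),
              .sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
              .sc_row("NE",  "CB", "CG", "CD", 1.461, 112.0, 180),
              .sc_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, 180),
              .sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
              .sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  HIS = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.497, 113.8, 180)),
  PHE = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.502, 113.8, 180)),
  TYR = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.512, 113.8, 180)),
  TRP = rbind(.cb_row(),
              .sc_row("CG",  "N",  "CA", "CB", 1.498, 113.8, 180))
)

# Planar-ring closures: attached at `attach`, plane tilted by chi2 = 90 deg
# about the CB-CG axis (the common perpendicular aromatic rotamer). `names`
# walk the ring from the attachment vertex; TRP's benzo ring is fused on the
# CE2-CD2 edge afterwards.
.ring_specs <- list(
  HIS = list(attach = "CG", prev = "CB", ref = "CA", n = 5, bond = 1.37,
             chi = 90, names = c("ND1", "CE1", "NE2", "CD2")),
  PHE = list(attach = "CG", prev = "CB", ref = "CA", n = 6, bond = 1.39,
             chi = 90, names = c("CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(attach = "CG", prev = "CB", ref = "CA", n = 6, bond = 1.39,
             chi = 90, names = c("CD1", "CE1", "CZ", "CE2", "CD2"),
             para_sub = list(name = "OH", bond = 1.376, at = "CZ")),
  TRP = list(attach = "CG", prev = "CB", ref = "CA", n = 5, bond = 1.37,
             chi = 90, names = c("CD1", "NE1", "CE2", "CD2"),
             fused = list(edge = c("CE2", "CD2"), bond = 1.40,
                          names = c("CZ2", "CH2", "CZ3", "CE3")))
)

# Aromatic ring membership for the ring() selection and stacking analysis.
.residue_ring_atoms <- list(
  TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
  HIS = c("CG", "ND1", "CE1", "NE2", "CD2"),
  TRP = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
)

# Charged-group atom names for salt-bridge detection (physiological pH;
# His neutral / metal-coordinated).
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_atoms  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

# Side-chain hydrogen-bond donors (heavy donor -> reconstructable H count)
# and acceptors, by residue type.
.sc_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", TRP = "NE1",
  SER = "OG", THR = "OG1", TYR = "OH"
)
.sc_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)
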