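# Internal-coordinate construction of idealized peptide and ligand
# conformers. Backbones are grown by natural-extension (NeRF) placement from
# standard bond lengths/angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom,
# omega = 180); side chains use fixed extended rotamers; aromatic rings are
# closed exactly as planar regular polygons.

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle defined by three points
#' @param p1,p2,p3 numeric xyz vectors; the angle is at `p2`.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_points <- function(p1, p2, p3) {
  u <- .unit(p1 - p2); v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Torsion angle defined by four points
#'
#' IUPAC sign convention: looking along `p2 -> p3`, a positive angle is a
#' clockwise rotation of `p3 -> p4` relative to `p1 -> p2`.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return dihedral in degrees in `(-180, 180]`.
#' @export
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2 * b2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Returns the position `d` such that `|d - c| = bond`,
#' `angle(b, c, d) = angle` and `dihedral(a, b, c, d) = torsion`.
#'
#' @param a,b,c xyz positions of the three reference atoms.
#' @param bond bond length (Angstrom), `angle`/`torsion` in degrees.
#' @param angle,torsion internal coordinates in degrees.
#' @return xyz position of the new atom.
#' @export
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  ab <- a - b
  u <- ab - sum(ab * bc) * bc        # in-plane reference: torsion 0 is cis to a
  u <- .unit(u)
  q <- .cross3(bc, u)
  d <- -cos(ang) * bc + sin(ang) * (cos(tor) * u - sin(tor) * q)
  c + bond * d
}

# Backbone ideal internal coordinates (Angstrom / degrees).
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, c_oxt = 1.249,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, ang_ca_c_oxt = 117.0, omega = 180
)

#' Backbone dihedral templates for named conformer classes
#'
#' Basin centres used by the synthetic-ensemble generator: right-handed
#' alpha-helix (-60, -40), 3,10-helix (-49, -26), beta-strand (-150, 160),
#' polyproline-II (-75, 150), fully extended (180, 180). `coil` is a
#' per-residue random mixture handled by [compose_ensemble()].
#'
#' @return named list of `c(phi, psi)` pairs in degrees.
#' @export
conformer_templates <- function() {
  list(alpha = c(-60, -40), three10 = c(-49, -26), beta = c(-150, 160),
       ppii = c(-75, 150), extended = c(180, 180))
}

.resolve_phi_psi <- function(phi_psi, n) {
  if (is.character(phi_psi) && length(phi_psi) == 1) {
    tpl <- conformer_templates()[[phi_psi]]
    if (is.null(tpl)) stop("unknown conformer template '", phi_psi, "'")
    phi_psi <- tpl
  }
  if (is.numeric(phi_psi) && length(phi_psi) == 2) {
    phi_psi <- matrix(rep(phi_psi, each = n), ncol = 2)
  }
  phi_psi <- as.matrix(phi_psi)
  if (nrow(phi_psi) != n || ncol(phi_psi) != 2) {
    stop("phi_psi must be one (phi, psi) pair or an n_residue x 2 matrix")
  }
  phi_psi
}

# Close a planar regular ring attached at `attach`; returns the n-1 remaining
# vertices walking the ring from the attachment vertex.
.close_ring <- function(attach, prev, ref, n, bond, chi) {
  w <- .unit(attach - prev)
  r0 <- ref - prev
  v0 <- .unit(r0 - sum(r0 * w) * w)
  ch <- chi * pi / 180
  v <- cos(ch) * v0 + sin(ch) * .cross3(w, v0)
  rc <- bond / (2 * sin(pi / n))
  center <- attach + rc * w
  th <- pi + seq_len(n - 1) * 2 * pi / n
  verts <- t(vapply(th, function(t) center + rc * (cos(t) * w + sin(t) * v),
                    numeric(3)))
  list(verts = verts, center = center, normal = .cross3(w, v))
}

# Fuse a near-regular 6-ring onto an existing edge (TRP benzo ring).
.fuse_ring6 <- function(e1, e2, center5, bond) {
  mid <- (e1 + e2) / 2
  dir <- .unit(mid - center5)
  half <- sqrt(sum((e1 - e2)^2)) / 2
  apoth <- sqrt(bond^2 - half^2)
  c6 <- mid + apoth * dir
  nrm <- .unit(.cross3(e1 - c6, e2 - c6))
  u <- .unit(e1 - c6)
  v <- .cross3(nrm, u)
  a2 <- atan2(sum((e2 - c6) * v), sum((e2 - c6) * u))   # angle of e2; e1 at 0
  s <- if (a2 > 0) -1 else 1                             # walk away from e2
  span <- 2 * pi - abs(a2)
  th <- s * seq_len(4) * span / 5
  t(vapply(th, function(t) c6 + bond * (cos(t) * u + sin(t) * v), numeric(3)))
}

#' Build an idealized all-heavy-atom peptide at prescribed backbone dihedrals
#'
#' Grows the backbone by NeRF placement so that the measured phi/psi of the
#' built frame equal the request (to numerical precision); phi of residue 1
#' is undefined (no preceding carbonyl) and is ignored. Side chains use one
#' fixed extended rotamer per residue type; all residues are built as
#' L-amino acids. The C-terminal carboxylate gains an OXT atom.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi_psi a single `c(phi, psi)` pair (recycled), an n x 2 matrix of
#'   per-residue dihedrals in degrees, or a template name from
#'   [conformer_templates()].
#' @param oxt add the C-terminal carboxylate OXT atom (default TRUE).
#' @param chain chain identifier.
#' @return a single-frame [new_trajectory()] object.
#' @export
build_peptide <- function(sequence, phi_psi = c(180, 180), oxt = TRUE,
                          chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop("sequence error: empty sequence")
  bad <- setdiff(letters1, names(.aa_three))
  if (length(bad)) {
    stop("sequence error: unknown residue letter(s) ",
         paste(unique(bad), collapse = ", "))
  }
  n <- length(letters1)
  pp <- .resolve_phi_psi(phi_psi, n)
  res3 <- unname(.aa_three[letters1])

  name <- character(0); elem <- character(0); resid <- integer(0)
  resname <- character(0)
  xyz <- matrix(numeric(0), ncol = 3)
  add_atom <- function(nm, rid, rn, pos) {
    name <<- c(name, nm); resid <<- c(resid, rid); resname <<- c(resname, rn)
    elem <<- c(elem, guess_element(nm))
    xyz <<- rbind(xyz, pos)
  }
  pos_of <- function(rid, nm) {
    i <- which(resid == rid & name == nm)
    if (!length(i)) stop("builder: missing reference atom ", nm,
                         " in residue ", rid)
    xyz[i[1], ]
  }

  prev <- NULL  # list(N, CA, C) of previous residue
  for (i in seq_len(n)) {
    rn <- res3[i]
    if (is.null(prev)) {
      N <- c(0, 0, 0)
      CA <- c(.bb$n_ca, 0, 0)
      ang <- .bb$ang_n_ca_c * pi / 180
      C <- CA + .bb$ca_c * c(-cos(ang), sin(ang), 0)
    } else {
      N <- nerf_place(prev$N, prev$CA, prev$C, .bb$c_n, .bb$ang_ca_c_n,
                      pp[i - 1, 2])
      CA <- nerf_place(prev$CA, prev$C, N, .bb$n_ca, .bb$ang_c_n_ca, .bb$omega)
      C <- nerf_place(prev$C, N, CA, .bb$ca_c, .bb$ang_n_ca_c, pp[i, 1])
    }
    psi_i <- pp[i, 2]
    O <- nerf_place(N, CA, C, .bb$c_o, .bb$ang_ca_c_o,
                    ((psi_i + 180 + 180) %% 360) - 180)
    add_atom("N", i, rn, N); add_atom("CA", i, rn, CA)
    add_atom("C", i, rn, C); add_atom("O", i, rn, O)

    tpl <- .sidechain_templates[[rn]]
    if (!is.null(tpl)) {
      for (k in seq_len(nrow(tpl))) {
        row <- tpl[k, ]
        pos <- nerf_place(pos_of(i, row$a), pos_of(i, row$b), pos_of(i, row$c),
                          row$bond, row$angle, row$torsion)
        add_atom(row$name, i, rn, pos)
      }
    }
    rs <- .ring_specs[[rn]]
    if (!is.null(rs)) {
      cl <- .close_ring(pos_of(i, rs$attach), pos_of(i, rs$prev),
                        pos_of(i, rs$ref), rs$n, rs$bond, rs$chi)
      for (k in seq_along(rs$names)) add_atom(rs$names[k], i, rn, cl$verts[k, ])
      if (!is.null(rs$para_sub)) {
        p <- pos_of(i, rs$para_sub$at)
        add_atom(rs$para_sub$name, i, rn,
                 p + rs$para_sub$bond * .unit(p - cl$center))
      }
      if (!is.null(rs$fused)) {
        e1 <- pos_of(i, rs$fused$edge[1]); e2 <- pos_of(i, rs$fused$edge[2])
        fv <- .fuse_ring6(e1, e2, cl$center, rs$fused$bond)
        for (k in seq_along(rs$fused$names)) {
          add_atom(rs$fused$names[k], i, rn, fv[k, ])
        }
      }
    }
    if (i == n && oxt) {
      OXT <- nerf_place(N, CA, C, .bb$c_oxt, .bb$ang_ca_c_oxt,
                        ((psi_i + 180) %% 360) - 180)
      add_atom("OXT", i, rn, OXT)
    }
    prev <- list(N = N, CA = CA, C = C)
  }

  atoms <- data.frame(serial = seq_along(name), name = name, element = elem,
                      resid = resid, resname = resname, chain = chain,
                      mass = .element_mass(elem), is_ligand = FALSE,
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms)
  attr(top, "ref_coords") <- xyz
  new_trajectory(top, xyz)
}

#' Build an idealized planar phenanthroline ligand (optionally with Pt)
#'
#' Constructs 1,10-phenanthroline (12 C + 2 N heavy atoms) as three fused
#' regular six-membered rings on a planar hexagon lattice with aromatic bond
#' length 1.40 Angstrom; the chelating nitrogens are the bay positions of
#' the two outer rings. With `include_pt = TRUE` a platinum atom is added
#' in-plane on the bay bisector at the Pt-N_phen equilibrium distance of
#' 2.06 Angstrom, giving the Pt(phen) fragment as present in the simulated
#' complex.
#'
#' @param include_pt add the coordinated Pt atom (default FALSE).
#' @param bond aromatic C-C bond length in Angstrom.
#' @return a single-frame [new_trajectory()]; the ligand residue is named
#'   `PHN` (Pt atom, if any, residue `PT`), all atoms flagged `is_ligand`.
#' @export
build_phenanthroline <- function(include_pt = FALSE, bond = 1.40) {
  hexv <- function(center) {
    t(vapply(0:5, function(k) center + bond * c(cos(k * pi / 3),
                                                sin(k * pi / 3), 0),
             numeric(3)))
  }
  d <- bond * sqrt(3)
  centers <- list(c(0, 0, 0),
                  d * c(cos(pi / 6), sin(pi / 6), 0),
                  d * c(cos(5 * pi / 6), sin(5 * pi / 6), 0))
  pts <- do.call(rbind, lapply(centers, hexv))
  key <- apply(round(pts, 6), 1, paste, collapse = ",")
  pts <- pts[!duplicated(key), , drop = FALSE]

  near <- function(p, q, tol = 1e-6) sqrt(sum((p - q)^2)) < tol
  in_ring <- function(p, center) sqrt(sum((p - center)^2)) < bond + 1e-6
  inmid <- apply(pts, 1, in_ring, center = centers[[1]])
  outB <- which(!inmid & apply(pts, 1, in_ring, center = centers[[2]]))
  outC <- which(!inmid & apply(pts, 1, in_ring, center = centers[[3]]))
  # chelating N = the mutually closest pair of outer-ring-only vertices
  best <- c(NA, NA); bestd <- Inf
  for (i in outB) for (j in outC) {
    dd <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (dd < bestd) { bestd <- dd; best <- c(i, j) }
  }
  is_n <- seq_len(nrow(pts)) %in% best
  elem <- ifelse(is_n, "N", "C")
  nm <- character(nrow(pts)); nm[is_n] <- paste0("N", 1:2)
  nm[!is_n] <- paste0("C", seq_len(sum(!is_n)))

  xyz <- pts
  resid <- rep(1L, nrow(pts))
  resname <- rep("PHN", nrow(pts))
  if (include_pt) {
    mid <- (pts[best[1], ] + pts[best[2], ]) / 2
    axis <- .unit(mid)                     # bay bisector through the origin
    half <- bestd / 2
    pt_pos <- mid + axis * sqrt(2.06^2 - half^2)
    xyz <- rbind(xyz, pt_pos)
    nm <- c(nm, "PT"); elem <- c(elem, "PT")
    resid <- c(resid, 2L); resname <- c(resname, "PT")
  }
  atoms <- data.frame(serial = seq_along(nm), name = nm, element = elem,
                      resid = resid, resname = resname, chain = "L",
                      mass = .element_mass(elem), is_ligand = TRUE,
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms)
  attr(top, "ref_coords") <- xyz
  new_trajectory(top, xyz)
}

#' Concatenate two structures into one topology
#'
#' Appends the atoms of `b` after those of `a` (residue indices of `b`
#' shifted past `a`'s) and binds their coordinates frame-wise. If one input
#' has a single frame it is recycled to match the other.
#'
#' @param a,b `idp_trajectory` objects.
#' @return an `idp_trajectory`.
#' @export
combine_structures <- function(a, b) {
  nfa <- n_frames(a); nfb <- n_frames(b)
  nf <- max(nfa, nfb)
  if (!(nfa %in% c(1, nf)) || !(nfb %in% c(1, nf))) {
    stop("frame counts are incompatible: ", nfa, " vs ", nfb)
  }
  at_a <- a$topology$atoms; at_b <- b$topology$atoms
  at_b$resid <- at_b$resid + max(at_a$resid)
  at_b$serial <- at_b$serial + max(at_a$serial)
  atoms <- rbind(at_a, at_b)
  top <- new_topology(atoms, termini = a$topology$termini)
  ra <- attr(a$topology, "ref_coords"); rb <- attr(b$topology, "ref_coords")
  if (!is.null(ra) && !is.null(rb)) attr(top, "ref_coords") <- rbind(ra, rb)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- rbind(get_frame(a, min(f, nfa)), get_frame(b, min(f, nfb)))
  }
  new_trajectory(top, coords)
}

# Least-squares plane through points: returns centroid and unit normal.
.plane_fit <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  sv <- svd(x)
  list(centroid = ctr, normal = sv$v[, 3])
}

.rotation_about <- function(axis, angle_deg) {
  a <- .unit(axis); th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation taking unit vector u onto unit vector v.
.rotation_between <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    perp <- if (abs(u[1]) < 0.9) .unit(.cross3(u, c(1, 0, 0)))
            else .unit(.cross3(u, c(0, 1, 0)))
    return(.rotation_about(perp, 180))
  }
  axis <- .cross3(u, v)
  .rotation_about(axis, acos(c_) * 180 / pi)
}

#' Pose a ligand in a stacking geometry over a peptide aromatic ring
#'
#' Places the ligand so that its central-ring centroid sits at
#' `centroid_distance` along the normal of the selected peptide ring, with
#' the ligand plane tilted by `interplanar_angle` relative to the ring
#' plane. The constructed geometry reproduces the request exactly (up to
#' numerical precision) when re-measured with [ring_geometry()].
#'
#' @param peptide a single-frame peptide `idp_trajectory`.
#' @param ring_selection a `ring(...)` selection string or integer atom
#'   indices of a planar ring.
#' @param centroid_distance target centroid-centroid separation (Angstrom).
#' @param interplanar_angle target angle between ring planes (degrees).
#' @param ligand ligand structure (default [build_phenanthroline()]).
#' @return combined single-frame `idp_trajectory` (peptide atoms first).
#' @export
pose_ligand_stack <- function(peptide, ring_selection, centroid_distance,
                              interplanar_angle = 0,
                              ligand = build_phenanthroline()) {
  if (centroid_distance <= 0) stop("centroid_distance must be positive")
  ring <- if (is.character(ring_selection)) {
    select_atoms(peptide, ring_selection)
  } else as.integer(ring_selection)
  if (length(ring) < 3) stop("geometry error: ring needs >= 3 atoms")
  pxyz <- get_frame(peptide, 1)
  rxyz <- pxyz[ring, , drop = FALSE]
  pf <- .plane_fit(rxyz)
  rms_out <- sqrt(mean((sweep(rxyz, 2, pf$centroid) %*% pf$normal)^2))
  if (rms_out > 0.15) stop("geometry error: ring selection is not planar")

  lrings <- ligand_rings(ligand$topology)
  lxyz <- get_frame(ligand, 1)
  central <- .ligand_central_ring(lrings)
  lf <- .plane_fit(lxyz[central, , drop = FALSE])

  # orient ligand normal at the requested tilt from the peptide-ring normal
  inplane <- if (abs(pf$normal[1]) < 0.9) {
    .unit(.cross3(pf$normal, c(1, 0, 0)))
  } else .unit(.cross3(pf$normal, c(0, 1, 0)))
  target_normal <- .rotation_about(inplane, interplanar_angle) %*% pf$normal
  R <- .rotation_between(lf$normal, as.vector(target_normal))
  target_centroid <- pf$centroid + centroid_distance * pf$normal
  new_l <- sweep(sweep(lxyz, 2, lf$centroid) %*% t(R), 2, target_centroid, "+")
  lig2 <- new_trajectory(ligand$topology, new_l)
  combine_structures(peptide, lig2)
}

# The central ring of a fused three-ring system shares atoms with both others.
.ligand_central_ring <- function(rings) {
  if (length(rings) == 1) return(rings[[1]])
  shared <- vapply(seq_along(rings), function(i) {
    sum(vapply(seq_along(rings), function(j) {
      if (i == j) 0L else length(intersect(rings[[i]], rings[[j]]))
    }, 0L))
  }, 0L)
  rings[[which.max(shared)]]
}

#' Build an idealized two-stranded beta-sheet
#'
#' Builds two strands at beta dihedrals (-140, 135) and rigidly docks the
#' second against the first (180-degree flip about the strand axis for the
#' antiparallel sense, pure translation for parallel), optimizing the
#' inter-strand offset on a deterministic grid plus local refinement so that
#' the Kabsch-Sander backbone hydrogen-bond pattern of the chosen sheet
#' sense forms. The two strands carry distinct chain identifiers; the
#' inter-strand peptide "bond" is a chain break.
#'
#' @param seq1,seq2 one-letter sequences of the two strands.
#' @param sense `"antiparallel"` or `"parallel"`.
#' @return a single-frame `idp_trajectory` containing both strands.
#' @export
build_beta_sheet <- function(seq1 = "AAAAAAAA", seq2 = seq1,
                             sense = c("antiparallel", "parallel")) {
  sense <- match.arg(sense)
  s1 <- build_peptide(seq1, c(-140, 135), chain = "A")
  s2 <- build_peptide(seq2, c(-140, 135), chain = "B")
  # canonical strand frame: C-alpha axis along x, backbone plane normal
  # along z, C-alpha centroid at the origin
  orient <- function(s) {
    x <- get_frame(s, 1)
    ca <- select_atoms(s, "calpha")
    bbi <- select_atoms(s, "backbone")
    x <- x %*% t(.rotation_between(x[ca[length(ca)], ] - x[ca[1], ],
                                   c(1, 0, 0)))
    x <- x %*% t(.rotation_between(.plane_fit(x[bbi, ])$normal, c(0, 0, 1)))
    sweep(x, 2, colMeans(x[ca, , drop = FALSE]))
  }
  x1 <- orient(s1)
  x2 <- orient(s2)
  if (sense == "antiparallel") {
    x2 <- x2 %*% t(.rotation_about(c(0, 0, 1), 180))
  }

  n1 <- nchar(seq1)
  cand_top <- combine_structures(s1, s2)$topology
  score <- function(off) {
    xx <- sweep(x2, 2, off, "+")
    dmin <- min(sqrt(pmax(outer(rowSums(x1^2), rowSums(xx^2), "+") -
                            2 * x1 %*% t(xx), 0)))
    if (dmin < 1.5) return(1000 - 100 * dmin)   # steric clash guard
    e <- .ks_bond_matrix(cand_top, rbind(x1, xx))
    inter <- rbind(e$energy[seq_len(n1), -seq_len(n1), drop = FALSE],
                   t(e$energy[-seq_len(n1), seq_len(n1), drop = FALSE]))
    nb <- sum(inter < .KS_CUTOFF)
    -10 * nb + sum(pmax(pmin(inter, 0), -3))
  }
  best <- NULL; bestv <- Inf
  for (dy in c(seq(-5.4, -4.2, by = 0.3), seq(4.2, 5.4, by = 0.3))) {
    for (dx in seq(-4, 4, by = 0.5)) {
      for (dz in c(-0.5, 0, 0.5)) {
        v <- score(c(dx, dy, dz))
        if (v < bestv) { bestv <- v; best <- c(dx, dy, dz) }
      }
    }
  }
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  par <- if (opt$value < bestv) opt$par else best
  x2 <- sweep(x2, 2, par, "+")
  combine_structures(new_trajectory(s1$topology, x1),
                     new_trajectory(s2$topology, x2))
}
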