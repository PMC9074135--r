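# Non-covalent interaction detection: hydrogen bonds (geometric criterion,
# with helix-type classification), salt bridges, peptide-ligand contacts,
# aromatic stacking and C-alpha contact maps.
#
# Inputs may be heavy-atom only: polar hydrogens are reconstructed from
# standard geometry where their position is determined (amide, guanidinium,
# ammonium, imidazole/indole NH); rotatable hydroxyl hydrogens (Ser/Thr/Tyr)
# are underdetermined and are treated as pointing at the candidate acceptor,
# making hydroxyl donors effectively distance-only.

# Three staggered hydrogens of an sp3 -NH3 group around `center`, with the
# heavy neighbour `anchor` on the fourth tetrahedral position and `ref`
# fixing the rotational phase.
.sp3_hydrogens <- function(center, anchor, ref) {
  u <- .unit(anchor - center)            # towards the heavy neighbour
  p0 <- ref - center
  p <- p0 - sum(p0 * u) * u
  p <- if (sqrt(sum(p * p)) < 1e-8) {
    .unit(.cross3(u, c(0.12, 0.57, 0.81)))
  } else .unit(p)
  q <- .cross3(u, p)
  cosb <- -1 / 3                          # cos(109.47): H at tetrahedral angle
  sinb <- sqrt(1 - cosb^2)
  t(vapply(c(pi / 3, pi, 5 * pi / 3), function(th) {
    center + 1.01 * (cosb * u + sinb * (cos(th) * p + sin(th) * q))
  }, numeric(3)))
}

# One H on the external bisector of two in-plane neighbours.
.bisector_hydrogen <- function(center, nb1, nb2, blen = 1.01) {
  d <- .unit(.unit(center - nb1) + .unit(center - nb2))
  matrix(center + blen * d, 1, 3)
}

# Two H of a planar -NH2 at +/-120 degrees from the N-C bond, in the plane
# defined by (plane_ref, C, N).
.nh2_hydrogens <- function(center, cpos, plane_ref) {
  nrm <- .unit(.cross3(cpos - center, plane_ref - center))
  u <- .unit(cpos - center)
  rot <- function(ang) {
    R <- .rotation_about(nrm, ang)
    center + 1.01 * as.vector(R %*% u)
  }
  rbind(rot(120), rot(-120))
}

# Enumerate donors of a topology: data.frame with the heavy-donor atom index,
# residue, backbone flag and H-placement rule.
.donor_table <- function(top) {
  at <- top$atoms
  pep <- !at$is_ligand
  out <- list()
  add <- function(idx, rule, backbone) {
    out[[length(out) + 1L]] <<- data.frame(idx = idx, rule = rule,
                                           backbone = backbone,
                                           stringsAsFactors = FALSE)
  }
  resids <- unique(at$resid[pep])
  first_res <- min(resids)
  for (r in resids) {
    rn <- at$resname[pep & at$resid == r][1]
    ni <- which(pep & at$resid == r & at$name == "N")
    if (length(ni)) {
      if (r == first_res && !identical(top$termini$nter_amine, FALSE)) {
        add(ni[1], "nterm", TRUE)
      } else if (rn != "PRO") {
        add(ni[1], "amide", TRUE)
      }
    }
    for (dn in .sc_donors[[rn]]) {
      di <- which(pep & at$resid == r & at$name == dn)
      if (!length(di)) next
      rule <- switch(dn,
                     NZ = "nh3",
                     NE = "arg_ne", NH1 = "nh2_arg", NH2 = "nh2_arg",
                     ND1 = "ring_nh", NE2 = if (rn == "HIS") "ring_nh"
                                            else "nh2_amide",
                     ND2 = "nh2_amide", NE1 = "ring_nh",
                     OG = "hydroxyl", OG1 = "hydroxyl", OH = "hydroxyl")
      add(di[1], rule, FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

.acceptor_table <- function(top) {
  at <- top$atoms
  pep <- !at$is_ligand
  out <- integer(0); backbone <- logical(0)
  for (i in which(pep)) {
    nm <- at$name[i]; rn <- at$resname[i]
    if (nm %in% c("O", "OXT")) {
      out <- c(out, i); backbone <- c(backbone, TRUE)
    } else if (nm %in% .sc_acceptors[[rn]]) {
      out <- c(out, i); backbone <- c(backbone, FALSE)
    }
  }
  data.frame(idx = out, backbone = backbone)
}

# Hydrogen positions for one donor in one frame; may return multiple rows.
# For "hydroxyl" returns NULL (angle handled as satisfied by construction).
.place_donor_h <- function(rule, idx, top, xyz, bb, linked) {
  at <- top$atoms
  r <- at$resid[idx]
  pos <- function(nm) {
    i <- which(!at$is_ligand & at$resid == r & at$name == nm)
    if (!length(i)) return(NULL)
    xyz[i[1], ]
  }
  ctr <- xyz[idx, ]
  switch(rule,
    amide = {
      ri <- match(r, bb$resids)
      if (ri == 1 || !linked[ri - 1]) return(NULL)
      cprev <- xyz[bb$C[ri - 1], ]; ca <- pos("CA")
      matrix(ctr + 1.01 * .unit(.unit(ctr - cprev) + .unit(ctr - ca)), 1, 3)
    },
    nterm = .sp3_hydrogens(ctr, pos("CA"), if (!is.null(pos("C"))) pos("C")
                           else ctr + c(0, 0, 1)),
    nh3 = .sp3_hydrogens(ctr, pos("CE"), pos("CD")),
    arg_ne = .bisector_hydrogen(ctr, pos("CD"), pos("CZ")),
    nh2_arg = .nh2_hydrogens(ctr, pos("CZ"), pos("NE")),
    nh2_amide = {
      cpos <- if (!is.null(pos("CD"))) pos("CD") else pos("CG")
      opos <- if (!is.null(pos("OE1"))) pos("OE1") else pos("OD1")
      .nh2_hydrogens(ctr, cpos, opos)
    },
    ring_nh = {
      rn <- at$resname[idx]; nm <- at$name[idx]
      nbs <- switch(paste(rn, nm),
                    "HIS ND1" = c("CG", "CE1"), "HIS NE2" = c("CE1", "CD2"),
                    "TRP NE1" = c("CD1", "CE2"))
      .bisector_hydrogen(ctr, pos(nbs[1]), pos(nbs[2]))
    },
    hydroxyl = NULL
  )
}

#' Detect hydrogen bonds with a geometric criterion
#'
#' A bond is recorded when the heavy donor-acceptor distance is at most
#' `dist_cutoff` and the donor-H...acceptor angle is at least `angle_cutoff`
#' (hydroxyl donors: distance criterion only, their H being rotatable).
#' Donors are peptide N/O bearing (reconstructable) hydrogens; acceptors are
#' backbone and side-chain N/O with lone pairs. The donor's own residue and
#' the covalently preceding backbone carbonyl are excluded.
#'
#' @param traj an `idp_trajectory`.
#' @param dist_cutoff heavy donor-acceptor cutoff in Angstrom (default 3.0).
#' @param angle_cutoff donor-H-acceptor angle cutoff in degrees (default 135).
#' @return list with `records` (one row per bond per frame: frame, donor /
#'   acceptor atom indices and residues, distance, angle, backbone_backbone,
#'   sequence_offset = donor minus acceptor residue, key) and `counts`
#'   (per-frame bond count with mean/sd/min/max stats).
#' @export
hydrogen_bonds <- function(traj, dist_cutoff = 3.0, angle_cutoff = 135) {
  top <- traj$topology
  at <- top$atoms
  don <- .donor_table(top)
  acc <- .acceptor_table(top)
  bb <- .backbone_index(top)
  nf <- n_frames(traj)
  recs <- list()
  counts <- integer(nf)
  if (is.null(don) || !nrow(acc)) {
    return(list(records = NULL,
                counts = list(per_frame = counts,
                              stats = c(mean = 0, sd = 0, min = 0, max = 0))))
  }
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    linked <- .chain_links(bb, xyz)
    dmat <- sqrt(pmax(outer(rowSums(xyz[don$idx, , drop = FALSE]^2),
                            rowSums(xyz[acc$idx, , drop = FALSE]^2), "+") -
                        2 * xyz[don$idx, , drop = FALSE] %*%
                          t(xyz[acc$idx, , drop = FALSE]), 0))
    hits <- which(dmat <= dist_cutoff, arr.ind = TRUE)
    nfound <- 0L
    for (k in seq_len(nrow(hits))) {
      di <- hits[k, 1]; ai <- hits[k, 2]
      didx <- don$idx[di]; aidx <- acc$idx[ai]
      dres <- at$resid[didx]; ares <- at$resid[aidx]
      if (dres == ares) next
      # exclude the donor's covalent carbonyl partner O(i-1)
      if (don$backbone[di] && acc$backbone[ai] && ares == dres - 1 &&
          at$name[aidx] == "O") next
      H <- .place_donor_h(don$rule[di], didx, top, xyz, bb, linked)
      if (is.null(H) && don$rule[di] != "hydroxyl") next
      ang <- if (is.null(H)) 180 else {
        max(vapply(seq_len(nrow(H)), function(h) {
          angle_points(xyz[didx, ], H[h, ], xyz[aidx, ])
        }, numeric(1)))
      }
      if (ang < angle_cutoff) next
      nfound <- nfound + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        frame = f, donor = didx, acceptor = aidx,
        donor_res = dres, acceptor_res = ares,
        distance = dmat[di, ai], angle = ang,
        backbone_backbone = don$backbone[di] && acc$backbone[ai],
        sequence_offset = dres - ares,
        key = paste0(at$resname[didx], dres, ":", at$name[didx], "-",
                     at$resname[aidx], ares, ":", at$name[aidx]),
        stringsAsFactors = FALSE)
    }
    counts[f] <- nfound
  }
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  list(records = records,
       counts = list(per_frame = counts,
                     stats = c(mean = mean(counts), sd = stats::sd(counts),
                               min = min(counts), max = max(counts))))
}

#' Classify hydrogen bonds by backbone sequence offset
#'
#' Backbone-backbone bonds are binned by donor-minus-acceptor residue offset:
#' `i+3 -> i` (3,10-helix like), `i+4 -> i` (alpha-helix), `i+5 -> i`
#' (pi-helix), other backbone, and side-chain (any bond involving a
#' side-chain donor or acceptor).
#'
#' @param records the `records` data.frame from [hydrogen_bonds()].
#' @return named integer vector of record counts per category.
#' @export
classify_hbonds <- function(records) {
  cats <- c("i+3->i" = 0L, "i+4->i" = 0L, "i+5->i" = 0L,
            "other backbone" = 0L, "side-chain" = 0L)
  if (is.null(records) || !nrow(records)) return(cats)
  bbrec <- records$backbone_backbone
  off <- records$sequence_offset
  cats["i+3->i"] <- sum(bbrec & off == 3)
  cats["i+4->i"] <- sum(bbrec & off == 4)
  cats["i+5->i"] <- sum(bbrec & off == 5)
  cats["other backbone"] <- sum(bbrec & !off %in% 3:5)
  cats["side-chain"] <- sum(!bbrec)
  cats
}

#' Hydrogen-bond occupancy table
#'
#' Fraction of frames in which each donor-acceptor pair is bonded, with mean
#' and standard deviation of the bonded distance.
#'
#' @param records the `records` data.frame from [hydrogen_bonds()].
#' @param n_frames total number of frames analysed.
#' @param min_occupancy report only pairs at or above this fraction
#'   (default 0; the conventional reporting threshold is 0.10).
#' @return data.frame with `key`, `occupancy`, `mean_dist`, `sd_dist`,
#'   sorted by decreasing occupancy.
#' @export
hbond_occupancy <- function(records, n_frames, min_occupancy = 0) {
  empty <- data.frame(key = character(0), occupancy = numeric(0),
                      mean_dist = numeric(0), sd_dist = numeric(0))
  if (is.null(records) || !nrow(records)) return(empty)
  sp <- split(records, records$key)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(key = d$key[1],
               occupancy = length(unique(d$frame)) / n_frames,
               mean_dist = mean(d$distance),
               sd_dist = if (nrow(d) > 1) stats::sd(d$distance) else 0,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$occupancy), , drop = FALSE]
}

.title_case_res <- function(resname, resid) {
  paste0(substr(resname, 1, 1), tolower(substr(resname, 2, 3)), resid)
}

#' Salt-bridge occupancy over acidic-basic residue pairs
#'
#' A pair is counted in a frame when any qualifying O-N distance is below
#' `cutoff` (default 3.2 Angstrom). Acidic oxygens: Asp OD1/OD2, Glu
#' OE1/OE2, plus the C-terminal carboxylate O/OXT; basic nitrogens: Lys NZ,
#' Arg NE/NH1/NH2, plus the N-terminal amine. His is treated as neutral.
#'
#' @param traj an `idp_trajectory`.
#' @param cutoff O-N contact distance in Angstrom (default 3.2).
#' @param include_termini include the terminal charged groups (default TRUE).
#' @return data.frame per pair: `key` (e.g. `"Glu3-Arg5"`), `occupancy`,
#'   `mean_min_dist`, `sd_min_dist`; empty (with a warning) when no charged
#'   residues exist.
#' @export
salt_bridges <- function(traj, cutoff = 3.2, include_termini = TRUE) {
  top <- traj$topology
  at <- top$atoms
  pep <- !at$is_ligand
  resids <- unique(at$resid[pep])
  groups_a <- list(); groups_b <- list()
  for (r in resids) {
    rn <- at$resname[pep & at$resid == r][1]
    aa <- .acidic_atoms[[rn]]
    if (!is.null(aa)) {
      idx <- which(pep & at$resid == r & at$name %in% aa)
      if (length(idx)) groups_a[[.title_case_res(rn, r)]] <- idx
    }
    ba <- .basic_atoms[[rn]]
    if (!is.null(ba)) {
      idx <- which(pep & at$resid == r & at$name %in% ba)
      if (length(idx)) groups_b[[.title_case_res(rn, r)]] <- idx
    }
  }
  if (include_termini && !identical(top$termini$cter_carboxylate, FALSE)) {
    r <- max(resids)
    rn <- at$resname[pep & at$resid == r][1]
    idx <- which(pep & at$resid == r & at$name %in% c("O", "OXT"))
    key <- paste0(.title_case_res(rn, r), "(C-term)")
    if (length(idx)) groups_a[[key]] <- idx
  }
  if (include_termini && !identical(top$termini$nter_amine, FALSE)) {
    r <- min(resids)
    rn <- at$resname[pep & at$resid == r][1]
    idx <- which(pep & at$resid == r & at$name == "N")
    key <- paste0(.title_case_res(rn, r), "(N-term)")
    if (length(idx)) groups_b[[key]] <- idx
  }
  empty <- data.frame(key = character(0), occupancy = numeric(0),
                      mean_min_dist = numeric(0), sd_min_dist = numeric(0))
  if (!length(groups_a) || !length(groups_b)) {
    warning("no charged residue pairs in topology")
    return(empty)
  }
  nf <- n_frames(traj)
  out <- list()
  for (ka in names(groups_a)) {
    for (kb in names(groups_b)) {
      ia <- groups_a[[ka]]; ib <- groups_b[[kb]]
      mind <- vapply(seq_len(nf), function(f) {
        xa <- matrix(traj$coords[ia, , f], ncol = 3)
        xb <- matrix(traj$coords[ib, , f], ncol = 3)
        min(sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                        2 * xa %*% t(xb), 0)))
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        key = paste0(ka, "-", kb), occupancy = mean(mind < cutoff),
        mean_min_dist = mean(mind),
        sd_min_dist = if (nf > 1) stats::sd(mind) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-out$occupancy), , drop = FALSE]
}

#' Peptide-ligand proximity of one residue
#'
#' Two distance definitions are computed per frame: (a) the minimum over the
#' residue's C-alpha/C-beta/C-gamma atoms to any ligand carbon (the
#' monitoring series reported as mean +/- SD), and (b) the minimum over all
#' heavy-atom pairs, from which the fraction of frames with any contact
#' below `contact_cutoff` is taken.
#'
#' @param traj an `idp_trajectory` whose topology contains a ligand.
#' @param residue 1-based peptide residue index.
#' @param contact_cutoff contact distance in Angstrom (default 5).
#' @return list with `series` (per-frame C-alpha/beta/gamma-to-ligand-carbon
#'   minimum), `mean`, `sd`, `min_heavy` (per-frame any-heavy-atom minimum)
#'   and `contact_fraction`.
#' @export
ligand_contacts <- function(traj, residue, contact_cutoff = 5) {
  at <- traj$topology$atoms
  lig_c <- which(at$is_ligand & at$element == "C")
  lig_heavy <- which(at$is_ligand & at$element != "PT" & at$element != "H")
  if (!length(lig_heavy)) stop("topology contains no ligand")
  res_sel <- which(!at$is_ligand & at$resid == residue)
  if (!length(res_sel)) stop("residue ", residue, " not in topology")
  abg <- res_sel[at$name[res_sel] %in% c("CA", "CB") |
                   startsWith(at$name[res_sel], "CG")]
  nf <- n_frames(traj)
  mind <- function(ia, ib, f) {
    xa <- matrix(traj$coords[ia, , f], ncol = 3)
    xb <- matrix(traj$coords[ib, , f], ncol = 3)
    min(sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                    2 * xa %*% t(xb), 0)))
  }
  series <- vapply(seq_len(nf), function(f) mind(abg, lig_c, f), numeric(1))
  min_heavy <- vapply(seq_len(nf), function(f) mind(res_sel, lig_heavy, f),
                      numeric(1))
  list(series = series, mean = mean(series), sd = stats::sd(series),
       min_heavy = min_heavy,
       contact_fraction = mean(min_heavy < contact_cutoff))
}

#' Search aromatic stacking between peptide rings and the ligand
#'
#' For every frame, the minimum ring-centroid distance over all peptide-ring
#' x ligand-ring combinations is recorded; the global-minimum frame's
#' geometry (centroid distance, interplanar angle) is reported per peptide
#' ring and overall. A frame counts as "stacked" for the occupancy when some
#' ring pair has centroid distance at most `dist_cutoff` and interplanar
#' angle at most `angle_cutoff`.
#'
#' @param traj an `idp_trajectory` with a ligand.
#' @param peptide_rings optional named list of atom-index vectors; defaults
#'   to the rings of all aromatic residues (Tyr/Phe/His/Trp).
#' @param lig_rings optional list of ligand-ring index vectors; defaults to
#'   [ligand_rings()] of the topology.
#' @param dist_cutoff,angle_cutoff stacking occupancy criteria
#'   (default 4.5 Angstrom, 30 degrees).
#' @return list with `per_ring` (data.frame: ring, closest frame, centroid
#'   distance, interplanar angle, stack occupancy), `closest` (the global
#'   minimum-distance record) and `occupancy` (fraction of frames stacked on
#'   any ring).
#' @export
stacking_search <- function(traj, peptide_rings = NULL, lig_rings = NULL,
                            dist_cutoff = 4.5, angle_cutoff = 30) {
  top <- traj$topology
  at <- top$atoms
  if (is.null(peptide_rings)) {
    peptide_rings <- list()
    pep <- !at$is_ligand
    for (r in unique(at$resid[pep])) {
      rn <- at$resname[pep & at$resid == r][1]
      if (!is.null(.residue_ring_atoms[[rn]])) {
        key <- .title_case_res(rn, r)
        idx <- which(pep & at$resid == r &
                       at$name %in% .residue_ring_atoms[[rn]])
        if (length(idx) >= 5) peptide_rings[[key]] <- idx
      }
    }
  }
  if (!length(peptide_rings)) stop("no aromatic peptide rings found")
  if (is.null(lig_rings)) {
    lig_rings <- ligand_rings(top, xyz = get_frame(traj, 1))
  }
  nf <- n_frames(traj)
  per <- list()
  any_stack <- rep(FALSE, nf)
  global <- NULL
  for (key in names(peptide_rings)) {
    pr <- peptide_rings[[key]]
    best <- list(d = Inf, frame = NA, ang = NA)
    occ <- 0L
    for (f in seq_len(nf)) {
      xyz <- traj$coords[, , f]
      stacked <- FALSE
      for (lr in lig_rings) {
        g <- ring_geometry(xyz, pr, lr)
        if (g$centroid_distance < best$d) {
          best <- list(d = g$centroid_distance, frame = f,
                       ang = g$interplanar_angle)
        }
        if (g$centroid_distance <= dist_cutoff &&
            g$interplanar_angle <= angle_cutoff) stacked <- TRUE
      }
      if (stacked) { occ <- occ + 1L; any_stack[f] <- TRUE }
    }
    per[[length(per) + 1L]] <- data.frame(
      ring = key, closest_frame = best$frame, centroid_distance = best$d,
      interplanar_angle = best$ang, stack_occupancy = occ / nf,
      stringsAsFactors = FALSE)
    if (is.null(global) || best$d < global$centroid_distance) {
      global <- data.frame(ring = key, closest_frame = best$frame,
                           centroid_distance = best$d,
                           interplanar_angle = best$ang,
                           stringsAsFactors = FALSE)
    }
  }
  list(per_ring = do.call(rbind, per), closest = global,
       occupancy = mean(any_stack))
}

#' Mean C-alpha contact map
#'
#' Mean over frames of all pairwise C-alpha distances; symmetric with a zero
#' diagonal.
#'
#' @param traj an `idp_trajectory`.
#' @return n_res x n_res matrix (Angstrom) with residue labels.
#' @export
contact_map <- function(traj) {
  ca <- select_atoms(traj, "calpha")
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  n <- length(ca)
  acc <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[ca, , f], ncol = 3)
    acc <- acc + as.matrix(stats::dist(x))
  }
  m <- acc / nf
  lab <- paste0(at$resname[ca], at$resid[ca])
  dimnames(m) <- list(lab, lab)
  m
}
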