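# From-scratch Kabsch-Sander secondary-structure assignment.
#
# Backbone amide hydrogens are reconstructed geometrically (1.01 Angstrom
# along the direction opposing the bisector of N's bonds to C(i-1) and CA),
# the electrostatic H-bond energy is
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol,
# and a bond exists when E < -0.5 kcal/mol. Chain breaks (peptide C-N
# distance > 2.5 Angstrom) interrupt donors, turns and bends.

.KS_Q <- 0.084 * 332
.KS_CUTOFF <- -0.5

# Per-residue backbone bookkeeping for a topology.
.backbone_index <- function(top) {
  at <- top$atoms
  pep <- which(!at$is_ligand)
  resids <- unique(at$resid[pep])
  pick <- function(r, nm) {
    i <- pep[at$resid[pep] == r & at$name[pep] == nm]
    if (length(i)) i[1] else NA_integer_
  }
  list(resids = resids,
       N = vapply(resids, pick, 1L, nm = "N"),
       CA = vapply(resids, pick, 1L, nm = "CA"),
       C = vapply(resids, pick, 1L, nm = "C"),
       O = vapply(resids, pick, 1L, nm = "O"),
       resname = vapply(resids, function(r) {
         at$resname[pep[at$resid[pep] == r][1]]
       }, ""))
}

.chain_links <- function(bb, xyz) {
  n <- length(bb$resids)
  linked <- rep(FALSE, max(n - 1, 0))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!is.na(bb$C[i]) && !is.na(bb$N[i + 1])) {
        linked[i] <- sqrt(sum((xyz[bb$C[i], ] - xyz[bb$N[i + 1], ])^2)) < 2.5
      }
    }
  }
  linked
}

# Amide H for donor residue i (NA row when the donor is excluded:
# chain start, chain break, or proline).
.amide_h <- function(bb, xyz, linked) {
  n <- length(bb$resids)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1 || !linked[i - 1]) next
    if (bb$resname[i] == "PRO") next
    if (anyNA(c(bb$N[i], bb$CA[i], bb$C[i - 1]))) next
    N <- xyz[bb$N[i], ]
    d <- .unit(.unit(N - xyz[bb$C[i - 1], ]) + .unit(N - xyz[bb$CA[i], ]))
    H[i, ] <- N + 1.01 * d
  }
  H
}

# Full donor x acceptor Kabsch-Sander energy matrix for one frame.
# energy[i, j]: N-H of residue i donating to C=O of residue j.
.ks_bond_matrix <- function(top, xyz) {
  bb <- .backbone_index(top)
  n <- length(bb$resids)
  linked <- .chain_links(bb, xyz)
  H <- .amide_h(bb, xyz, linked)
  E <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (anyNA(H[i, ])) next
    Ni <- xyz[bb$N[i], ]; Hi <- H[i, ]
    for (j in seq_len(n)) {
      if (j == i || j == i - 1) next       # own and covalently-linked carbonyl
      if (anyNA(c(bb$C[j], bb$O[j]))) next
      Cj <- xyz[bb$C[j], ]; Oj <- xyz[bb$O[j], ]
      rON <- sqrt(sum((Oj - Ni)^2)); rCH <- sqrt(sum((Cj - Hi)^2))
      rOH <- sqrt(sum((Oj - Hi)^2)); rCN <- sqrt(sum((Cj - Ni)^2))
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- .KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  list(energy = E, hbond = E < .KS_CUTOFF, bb = bb, linked = linked)
}

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' Electrostatic energy of the backbone N-H (donor) to C=O (acceptor)
#' interaction; a hydrogen bond is assigned when the energy is below
#' -0.5 kcal/mol. The amide hydrogen is reconstructed geometrically when
#' absent; chain-start and proline donors are excluded (energy `NA`).
#'
#' @param traj an `idp_trajectory`.
#' @param donor_residue,acceptor_residue 1-based residue indices.
#' @param frame frame number (default 1).
#' @return energy in kcal/mol (`NA` for excluded donors).
#' @export
ks_hbond_energy <- function(traj, donor_residue, acceptor_residue, frame = 1) {
  xyz <- get_frame(traj, frame)
  bm <- .ks_bond_matrix(traj$topology, xyz)
  i <- match(donor_residue, bm$bb$resids)
  j <- match(acceptor_residue, bm$bb$resids)
  if (is.na(i) || is.na(j)) stop("residue index not in topology")
  H <- .amide_h(bm$bb, xyz, bm$linked)
  if (anyNA(H[i, ])) return(NA_real_)
  bm$energy[i, j]
}

#' Eight-state secondary-structure assignment (Kabsch-Sander)
#'
#' Assigns one of H (alpha-helix), G (3,10-helix), I (pi-helix), E (strand),
#' B (isolated bridge), T (turn), S (bend), C (coil) to every residue of
#' every frame. n-turns (n = 3, 4, 5) come from i+n -> i backbone hydrogen
#' bonds; two consecutive n-turns make a minimal helix; parallel and
#' antiparallel bridges follow the classic patterns, ladders of >= 2
#' consecutive bridges become E and isolated bridges B; T marks unlabelled
#' turn interiors, S bends (C-alpha direction change > 70 degrees).
#' Overlap priority: H > E/B > G > I > T > S.
#'
#' @param traj an `idp_trajectory` with backbone atoms.
#' @return character matrix (n_frames x n_residues) of labels, with
#'   attributes `parallel` and `antiparallel`: integer matrices counting
#'   per-frame bridge participations of each residue by sheet sense.
#' @export
assign_dssp <- function(traj) {
  bb <- .backbone_index(traj$topology)
  n <- length(bb$resids)
  nf <- n_frames(traj)
  labels <- matrix("C", nf, n)
  colnames(labels) <- bb$resids
  par_m <- matrix(0L, nf, n)
  anti_m <- matrix(0L, nf, n)
  if (n < 5) {
    warning("fewer than 5 residues: all residues labelled C")
    return(structure(labels, parallel = par_m, antiparallel = anti_m))
  }
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    bm <- .ks_bond_matrix(traj$topology, xyz)
    hb <- bm$hbond
    linked <- bm$linked
    span_ok <- function(i, j) all(linked[seq(min(i, j), max(i, j) - 1)])

    turns <- list()
    for (nn in 3:5) {
      tn <- rep(FALSE, n)
      for (i in seq_len(n - nn)) {
        if (hb[i + nn, i] && span_ok(i, i + nn)) tn[i] <- TRUE
      }
      turns[[as.character(nn)]] <- tn
    }

    helix_flag <- function(nn) {
      tn <- turns[[as.character(nn)]]
      fl <- rep(FALSE, n)
      for (i in 2:n) {
        if (i <= length(tn) && i >= 2 && tn[i] && tn[i - 1]) {
          fl[i:min(n, i + nn - 1)] <- TRUE
        }
      }
      fl
    }
    isH <- helix_flag(4)
    isG <- helix_flag(3)
    isI <- helix_flag(5)

    # bridges
    bridge_par <- matrix(FALSE, n, n)
    bridge_anti <- matrix(FALSE, n, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3) next
        # hb[d, a]: NH of d donates to CO of a. In Kabsch-Sander notation
        # Hbond(a, d) = CO(a) <- NH(d), so patterns transpose accordingly.
        p <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
        a <- (hb[j, i] && hb[i, j]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
        if (p) bridge_par[i, j] <- TRUE
        if (a) bridge_anti[i, j] <- TRUE
      }
    }
    in_ladder <- rep(FALSE, n)
    in_bridge <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (bridge_par[i, j]) {
          par_m[f, i] <- par_m[f, i] + 1L
          ext <- (i > 2 && j > 2 && bridge_par[i - 1, j - 1]) ||
            (i < n - 1 && j < n - 1 && bridge_par[i + 1, j + 1])
          if (ext) in_ladder[i] <- TRUE else in_bridge[i] <- TRUE
        }
        if (bridge_anti[i, j]) {
          anti_m[f, i] <- anti_m[f, i] + 1L
          ext <- (i > 2 && j < n - 1 && bridge_anti[i - 1, j + 1]) ||
            (i < n - 1 && j > 2 && bridge_anti[i + 1, j - 1])
          if (ext) in_ladder[i] <- TRUE else in_bridge[i] <- TRUE
        }
      }
    }

    isT <- rep(FALSE, n)
    for (nn in 3:5) {
      tn <- turns[[as.character(nn)]]
      for (i in which(tn)) {
        if (nn >= 2) isT[(i + 1):(i + nn - 1)] <- TRUE
      }
    }
    isS <- rep(FALSE, n)
    for (i in 3:(n - 2)) {
      if (!all(linked[(i - 2):(i + 1)])) next
      u <- xyz[bb$CA[i], ] - xyz[bb$CA[i - 2], ]
      v <- xyz[bb$CA[i + 2], ] - xyz[bb$CA[i], ]
      kap <- acos(max(-1, min(1, sum(.unit(u) * .unit(v))))) * 180 / pi
      if (kap > 70) isS[i] <- TRUE
    }

    lab <- rep("C", n)
    lab[isS] <- "S"
    lab[isT] <- "T"
    lab[isI] <- "I"
    lab[isG] <- "G"
    lab[in_bridge] <- "B"
    lab[in_ladder] <- "E"
    lab[isH] <- "H"
    labels[f, ] <- lab
  }
  structure(labels, parallel = par_m, antiparallel = anti_m)
}

#' Summaries of a secondary-structure label matrix
#'
#' Per-residue percentage of each 8-state label over frames, plus the
#' grouped system-level percentages: helix = H + G + I, sheet = E + B,
#' other = T + S + C (frame x residue averages).
#'
#' @param labels matrix from [assign_dssp()].
#' @return list with `per_residue` (residues x labels, percent) and
#'   `grouped` (`helix`, `sheet`, `other`, percent).
#' @export
ss_summary <- function(labels) {
  if (!length(labels)) stop("empty label matrix")
  states <- c("H", "G", "I", "E", "B", "T", "S", "C")
  nres <- ncol(labels)
  per <- matrix(0, nres, length(states),
                dimnames = list(colnames(labels), states))
  for (s in states) per[, s] <- 100 * colMeans(labels == s)
  all_pct <- vapply(states, function(s) 100 * mean(labels == s), numeric(1))
  grouped <- c(helix = sum(all_pct[c("H", "G", "I")]),
               sheet = sum(all_pct[c("E", "B")]),
               other = sum(all_pct[c("T", "S", "C")]))
  list(per_residue = per, grouped = grouped)
}

#' Parallel/antiparallel attribution of strand residues
#'
#' Uses the bridge bookkeeping recorded by [assign_dssp()] to attribute each
#' residue's strand participation to parallel or antiparallel ladders.
#'
#' @param labels matrix from [assign_dssp()] (with bridge attributes).
#' @return data.frame per residue: fraction of frames with parallel /
#'   antiparallel bridge participation.
#' @export
sheet_sense <- function(labels) {
  par_m <- attr(labels, "parallel")
  anti_m <- attr(labels, "antiparallel")
  if (is.null(par_m) || is.null(anti_m)) {
    stop("labels must come from assign_dssp() (bridge bookkeeping missing)")
  }
  data.frame(residue = colnames(labels),
             parallel = colMeans(par_m > 0),
             antiparallel = colMeans(anti_m > 0))
}
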