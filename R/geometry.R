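# Superposition, deviation/fluctuation statistics, gyration-tensor shape
# descriptors, backbone dihedrals, ring geometry and harmonic metal-site
# energy terms.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation/translation of `mobile` onto `reference`,
#' reflections excluded (det = +1), with optional per-point weights.
#'
#' @param mobile,reference m x 3 coordinate matrices (equal m >= 3).
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with `rotation` (3 x 3, proper), `translation` (length-3;
#'   the transform is `x %*% t(R) + translation`), and `rmsd` (Angstrom,
#'   weighted) after applying the transform.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-size m x 3 matrices")
  }
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else as.numeric(weights)
  if (length(w) != nrow(mobile) || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.vector(cr - cm %*% t(R)), rmsd = rmsd)
}

.resolve_selection <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(n_atoms(traj)))
  if (is.character(selection)) return(select_atoms(traj, selection))
  as.integer(selection)
}

#' Per-frame RMSD against a fixed reference
#'
#' Best-fit (Kabsch) RMSD of each frame over a selection, against a fixed
#' reference structure (typically the energy-minimised starting point or the
#' first frame). With `fit = FALSE` the raw (no superposition) RMSD is
#' returned instead.
#'
#' @param traj an `idp_trajectory`.
#' @param reference reference coordinates: an n_atoms x 3 matrix for the full
#'   topology, or a frame number into `traj` (default 1).
#' @param selection selection string or atom indices (default `"backbone"`).
#' @param fit superpose before measuring (default TRUE).
#' @return list with `rmsd` (per-frame, Angstrom) and `stats`
#'   (mean, sd, min, max).
#' @export
rmsd_series <- function(traj, reference = 1, selection = "backbone",
                        fit = TRUE) {
  sel <- .resolve_selection(traj, selection)
  if (!length(sel)) stop("empty selection")
  ref <- if (is.matrix(reference)) reference else get_frame(traj, reference)
  if (nrow(ref) != n_atoms(traj)) {
    stop("reference must have the trajectory's atom count")
  }
  refs <- ref[sel, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- matrix(traj$coords[sel, , f], ncol = 3)
    if (fit) {
      kabsch_superpose(x, refs)$rmsd
    } else {
      sqrt(mean(rowSums((x - refs)^2)))
    }
  }, numeric(1))
  list(rmsd = vals,
       stats = c(mean = mean(vals), sd = stats::sd(vals),
                 min = min(vals), max = max(vals)))
}

#' Root-mean-square fluctuation per atom and per residue
#'
#' With `align = TRUE` all frames are iteratively superposed onto the mean
#' structure of the selection (two passes), then
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`. The per-residue value is the
#' RMSF of that residue's C-alpha.
#'
#' @param traj an `idp_trajectory` with >= 2 frames.
#' @param selection atoms over which to align and report (default all atoms).
#' @param align superpose frames onto the running mean first (default TRUE).
#' @return list with `atom` (per selected atom, Angstrom), `residue` (named
#'   per-residue C-alpha RMSF), and `stats` (mean/sd/min/max over residues,
#'   falling back to atoms when the selection holds no C-alpha).
#' @export
rmsf <- function(traj, selection = NULL, align = TRUE) {
  if (n_frames(traj) < 2) stop("RMSF needs at least two frames")
  sel <- .resolve_selection(traj, selection)
  nf <- n_frames(traj)
  X <- lapply(seq_len(nf), function(f) matrix(traj$coords[sel, , f], ncol = 3))
  if (align) {
    ref <- X[[1]]
    for (pass in 1:2) {
      X <- lapply(X, function(x) {
        k <- kabsch_superpose(x, ref)
        x %*% t(k$rotation) + matrix(k$translation, nrow(x), 3, byrow = TRUE)
      })
      ref <- Reduce(`+`, X) / nf
    }
  }
  mean_x <- Reduce(`+`, X) / nf
  msd <- Reduce(`+`, lapply(X, function(x) rowSums((x - mean_x)^2))) / nf
  atom_rmsf <- sqrt(msd)
  at <- traj$topology$atoms[sel, , drop = FALSE]
  is_ca <- at$name == "CA" & !at$is_ligand
  res <- NULL
  if (any(is_ca)) {
    res <- atom_rmsf[is_ca]
    names(res) <- paste0(at$resname[is_ca], at$resid[is_ca])
  }
  base <- if (!is.null(res)) res else atom_rmsf
  list(atom = atom_rmsf, residue = res,
       stats = c(mean = mean(base), sd = stats::sd(base),
                 min = min(base), max = max(base)))
}

#' Radius of gyration and gyration-tensor shape descriptors
#'
#' `Rg^2 = sum_i w_i |x_i - xbar|^2 / sum_i w_i` with the gyration tensor
#' `S = sum_i w_i (x_i - xbar)(x_i - xbar)^T / sum_i w_i`; eigenvalues are
#' sorted descending and satisfy `lambda1 + lambda2 + lambda3 = Rg^2`.
#' The anisotropy descriptor follows the convention in which 0 is an ideal
#' linear chain and 1 a fully symmetric distribution:
#' `(lambda2 + lambda3) / (2 lambda1)`. The conventional relative shape
#' anisotropy `kappa^2` (1 for a line, 0 for spherical symmetry) is also
#' returned for reference, along with the asphericity
#' `lambda1 - (lambda2 + lambda3)/2`.
#'
#' @param x an n x 3 coordinate matrix, or an `idp_trajectory` (frame 1).
#' @param selection selection applied when `x` is a trajectory/topology.
#' @param mass_weighted weight by atomic mass (default TRUE).
#' @param topology required when `x` is a bare matrix and
#'   `mass_weighted = TRUE`: an `idp_topology` supplying masses.
#' @param frame frame number when `x` is a trajectory.
#' @return list with `rg`, `eigenvalues` (descending, Angstrom^2),
#'   `anisotropy`, `kappa2`, `asphericity`.
#' @export
gyration <- function(x, selection = NULL, mass_weighted = TRUE,
                     topology = NULL, frame = 1) {
  if (inherits(x, "idp_trajectory")) {
    sel <- .resolve_selection(x, selection)
    topology <- x$topology
    xyz <- matrix(x$coords[sel, , frame], ncol = 3)
    w <- if (mass_weighted) topology$atoms$mass[sel] else rep(1, length(sel))
  } else {
    xyz <- as.matrix(x)
    if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
    w <- if (mass_weighted) {
      if (is.null(topology)) stop("mass weighting needs a topology")
      sel <- if (is.null(selection)) seq_len(nrow(topology$atoms)) else selection
      topology$atoms$mass[sel]
    } else rep(1, nrow(xyz))
  }
  if (nrow(xyz) < 1) stop("empty selection")
  w <- w / sum(w)
  ctr <- colSums(xyz * w)
  Xc <- sweep(xyz, 2, ctr)
  S <- t(Xc * w) %*% Xc
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  rg2 <- sum(ev)
  l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
  aniso <- if (l1 > 0) (l2 + l3) / (2 * l1) else 1
  kappa2 <- if (rg2 > 0) {
    1.5 * (l1^2 + l2^2 + l3^2) / rg2^2 - 0.5
  } else 0
  list(rg = sqrt(rg2), eigenvalues = ev, anisotropy = aniso,
       kappa2 = kappa2, asphericity = l1 - (l2 + l3) / 2)
}

#' Per-frame shape descriptors and ensemble summary
#'
#' @param traj an `idp_trajectory`.
#' @param selection selection string or atom indices (default all atoms).
#' @param mass_weighted weight by atomic mass (default TRUE).
#' @return list with `per_frame` (data.frame: rg, lambda1..3, anisotropy,
#'   kappa2, asphericity per frame), `summary` (mean/sd/min/max of rg and
#'   anisotropy), and `prolate` (TRUE when on average lambda1 dominates two
#'   comparable smaller eigenvalues).
#' @export
shape_series <- function(traj, selection = NULL, mass_weighted = TRUE) {
  sel <- .resolve_selection(traj, selection)
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    g <- gyration(traj, selection = sel, mass_weighted = mass_weighted,
                  frame = f)
    data.frame(frame = f, rg = g$rg, lambda1 = g$eigenvalues[1],
               lambda2 = g$eigenvalues[2], lambda3 = g$eigenvalues[3],
               anisotropy = g$anisotropy, kappa2 = g$kappa2,
               asphericity = g$asphericity)
  })
  pf <- do.call(rbind, rows)
  summ <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        min = min(v), max = max(v))
  l <- colMeans(pf[, c("lambda1", "lambda2", "lambda3")])
  prolate <- l[1] > 2 * l[2]     # one long axis, two comparatively small
  list(per_frame = pf,
       summary = list(rg = summ(pf$rg), anisotropy = summ(pf$anisotropy)),
       prolate = unname(prolate))
}

#' Backbone phi/psi dihedrals for every frame
#'
#' `phi(i) = C(i-1)-N(i)-CA(i)-C(i)`, `psi(i) = N(i)-CA(i)-C(i)-N(i+1)`
#' (IUPAC sign convention); undefined at chain termini and across chain
#' breaks (peptide C-N distance > 2.5 Angstrom), where `NA` is reported.
#'
#' @param traj an `idp_trajectory`.
#' @return list with `phi` and `psi`: n_frames x n_residue matrices
#'   (degrees, `(-180, 180]`, `NA` where undefined).
#' @export
dihedrals <- function(traj) {
  at <- traj$topology$atoms
  pep <- which(!at$is_ligand)
  resids <- unique(at$resid[pep])
  nres <- length(resids)
  idx_of <- function(r, nm) {
    i <- pep[at$resid[pep] == r & at$name[pep] == nm]
    if (length(i)) i[1] else NA_integer_
  }
  Ni <- vapply(resids, idx_of, 1L, nm = "N")
  CAi <- vapply(resids, idx_of, 1L, nm = "CA")
  Ci <- vapply(resids, idx_of, 1L, nm = "C")
  nf <- n_frames(traj)
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  colnames(phi) <- colnames(psi) <- resids
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    linked <- rep(FALSE, nres)
    if (nres > 1) {
      for (i in seq_len(nres - 1)) {
        if (!is.na(Ci[i]) && !is.na(Ni[i + 1])) {
          linked[i] <- sqrt(sum((x[Ci[i], ] - x[Ni[i + 1], ])^2)) < 2.5
        }
      }
    }
    for (i in seq_len(nres)) {
      if (i > 1 && linked[i - 1] &&
          !anyNA(c(Ci[i - 1], Ni[i], CAi[i], Ci[i]))) {
        phi[f, i] <- dihedral_points(x[Ci[i - 1], ], x[Ni[i], ],
                                     x[CAi[i], ], x[Ci[i], ])
      }
      if (i < nres && linked[i] &&
          !anyNA(c(Ni[i], CAi[i], Ci[i], Ni[i + 1]))) {
        psi[f, i] <- dihedral_points(x[Ni[i], ], x[CAi[i], ],
                                     x[Ci[i], ], x[Ni[i + 1], ])
      }
    }
  }
  list(phi = phi, psi = psi)
}

#' Centroid distance and interplanar angle of two rings
#'
#' Centroids are unweighted means; plane normals come from a least-squares
#' plane fit (SVD); the angle is folded to `[0, 90]` degrees.
#'
#' @param xyz n x 3 coordinates (a frame).
#' @param ring_a,ring_b integer atom indices of the two rings (>= 3 each).
#' @return list with `centroid_distance` (Angstrom) and
#'   `interplanar_angle` (degrees).
#' @export
ring_geometry <- function(xyz, ring_a, ring_b) {
  if (length(ring_a) < 3 || length(ring_b) < 3) {
    stop("each ring needs at least 3 atoms")
  }
  fa <- .plane_fit(xyz[ring_a, , drop = FALSE])
  fb <- .plane_fit(xyz[ring_b, , drop = FALSE])
  d <- sqrt(sum((fa$centroid - fb$centroid)^2))
  cosang <- abs(sum(fa$normal * fb$normal))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  list(centroid_distance = d, interplanar_angle = ang)
}

#' Default Pt(phen)-His metal-site harmonic parameters
#'
#' Bonded parameters of the Pt coordination sphere as `[r0, k]` /
#' `[theta0, k]` pairs: Pt-N_phen (2.06 Angstrom, 107 kcal/mol/A^2),
#' Pt-N_His (2.05, 127); angles N_phen-Pt-N_phen (81 deg, 169),
#' N_His-Pt-N_His (89, 150), cis N_phen-Pt-N_His (95, 158),
#' trans N_phen-Pt-N_His (176, 167). Angle force constants are interpreted
#' per rad^2 (see [harmonic_energy()]). Non-bonded Pt parameters:
#' charge +0.027 e, epsilon 0.0031 kcal/mol, sigma 1.266 Angstrom.
#'
#' @return list with `bonds`, `angles` (data.frames) and `nonbonded`.
#' @export
metal_site_parameters <- function() {
  list(
    bonds = data.frame(
      label = c("Pt-Nphen", "Pt-NHis"),
      r0 = c(2.06, 2.05), k = c(107, 127), stringsAsFactors = FALSE),
    angles = data.frame(
      label = c("Nphen-Pt-Nphen", "NHis-Pt-NHis", "cis-Nphen-Pt-NHis",
                "trans-Nphen-Pt-NHis"),
      theta0 = c(81, 89, 95, 176), k = c(169, 150, 158, 167),
      stringsAsFactors = FALSE),
    nonbonded = c(charge = 0.027, epsilon = 0.0031, sigma = 1.266)
  )
}

#' Harmonic bond/angle energies of measured metal-site geometry
#'
#' `E_bond = k (r - r0)^2`; `E_angle = k (theta - theta0)^2` with the angular
#' displacement in radians by default (`angle_units = "rad"`), matching the
#' magnitude of the printed force constants.
#'
#' @param params parameter list as from [metal_site_parameters()].
#' @param bonds data.frame with columns `label`, `r` (measured, Angstrom).
#' @param angles data.frame with columns `label`, `theta` (measured, deg).
#' @param angle_units `"rad"` (default) or `"deg"`: unit of the angular
#'   displacement implied by the angle force constants.
#' @return list with per-term energies (kcal/mol) and `total`.
#' @export
harmonic_energy <- function(params = metal_site_parameters(), bonds = NULL,
                            angles = NULL, angle_units = c("rad", "deg")) {
  angle_units <- match.arg(angle_units)
  eb <- numeric(0)
  if (!is.null(bonds) && nrow(bonds)) {
    m <- match(bonds$label, params$bonds$label)
    if (anyNA(m)) stop("no bond parameters for: ",
                       paste(bonds$label[is.na(m)], collapse = ", "))
    eb <- params$bonds$k[m] * (bonds$r - params$bonds$r0[m])^2
    names(eb) <- bonds$label
  }
  ea <- numeric(0)
  if (!is.null(angles) && nrow(angles)) {
    m <- match(angles$label, params$angles$label)
    if (anyNA(m)) stop("no angle parameters for: ",
                       paste(angles$label[is.na(m)], collapse = ", "))
    dth <- angles$theta - params$angles$theta0[m]
    if (angle_units == "rad") dth <- dth * pi / 180
    ea <- params$angles$k[m] * dth^2
    names(ea) <- angles$label
  }
  list(bond = eb, angle = ea, total = sum(eb) + sum(ea))
}
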