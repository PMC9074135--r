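# Labelled synthetic peptide ensembles with known ground truth: conformer
# classes drawn from named dihedral templates, optional Gaussian coordinate
# noise, and injected interactions (salt bridges, hydrogen bonds, ligand
# stacking poses) realized at exact occupancies. Stands in for REMD sampling
# so that every downstream detector can be validated against known truth.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Specification of a synthetic labelled ensemble
#'
#' @param sequence one-letter peptide sequence.
#' @param n_frames number of frames to generate.
#' @param class_fractions named fractions over conformer classes (names from
#'   [conformer_templates()] plus `"coil"`); must sum to 1.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom (>= 0).
#' @param seed integer RNG seed; identical specs and seeds give identical
#'   ensembles.
#' @param injections list of injected interactions, each a list with a
#'   `type` of:
#'   \itemize{
#'     \item `"salt_bridge"`: fields `acidic_res`, `basic_res`, `distance`
#'       (Angstrom, default 3.0), `occupancy`;
#'     \item `"hbond"`: fields `donor_res`, `donor_atom`, `acceptor_res`,
#'       `acceptor_atom` (default `"O"`), `distance` (default 2.9),
#'       `occupancy`;
#'     \item `"stack"`: fields `ring` (a `ring(...)` selection), `distance`
#'       (default 3.5), `angle` (degrees, default 0), `occupancy`.
#'   }
#' @param with_ligand include a phenanthroline ligand even without stacking
#'   injections (default: only when a stack injection is present).
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(sequence, n_frames, class_fractions,
                          noise_sigma = 0, seed = 1L, injections = list(),
                          with_ligand = NULL) {
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1")
  }
  known <- c(names(conformer_templates()), "coil")
  bad <- setdiff(names(class_fractions), known)
  if (length(bad)) stop("unknown conformer class(es): ",
                        paste(bad, collapse = ", "))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  for (inj in injections) {
    if (is.null(inj$type) ||
        !inj$type %in% c("salt_bridge", "hbond", "stack")) {
      stop("spec error: injection type must be salt_bridge, hbond or stack")
    }
    if (is.null(inj$occupancy) || inj$occupancy < 0 || inj$occupancy > 1) {
      stop("spec error: injection occupancy must be in [0, 1]")
    }
  }
  if (is.null(with_ligand)) {
    with_ligand <- any(vapply(injections, function(i) i$type == "stack",
                              logical(1)))
  }
  structure(list(sequence = sequence, n_frames = as.integer(n_frames),
                 class_fractions = class_fractions,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 injections = injections, with_ligand = with_ligand),
            class = "ensemble_spec")
}

# Largest-remainder apportionment of n frames over the class fractions.
.class_counts <- function(fractions, n) {
  base <- floor(fractions * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

.coil_phi_psi <- function(n_res) {
  basins <- rbind(c(-150, 160), c(-75, 150), c(180, 180))
  pick <- sample.int(3, n_res, replace = TRUE)
  pp <- basins[pick, , drop = FALSE] +
    matrix(stats::runif(2 * n_res, -20, 20), ncol = 2)
  ((pp + 180) %% 360) - 180
}

# Ligand pose helper shared with pose_ligand_stack: returns new ligand xyz.
.pose_ligand_xyz <- function(pep_xyz, ring_idx, lig_xyz, central_ring_local,
                             dist, angle) {
  pf <- .plane_fit(pep_xyz[ring_idx, , drop = FALSE])
  lf <- .plane_fit(lig_xyz[central_ring_local, , drop = FALSE])
  inplane <- if (abs(pf$normal[1]) < 0.9) {
    .unit(.cross3(pf$normal, c(1, 0, 0)))
  } else .unit(.cross3(pf$normal, c(0, 1, 0)))
  target_normal <- .rotation_about(inplane, angle) %*% pf$normal
  R <- .rotation_between(lf$normal, as.vector(target_normal))
  target_centroid <- pf$centroid + dist * pf$normal
  sweep(sweep(lig_xyz, 2, lf$centroid) %*% t(R), 2, target_centroid, "+")
}

# Atom indices (within the combined topology) of a residue's side chain
# beyond CB -- the rigid unit moved by contact injections.
.sidechain_tail <- function(top, resid, from = c("CG")) {
  at <- top$atoms
  idx <- which(!at$is_ligand & at$resid == resid &
                 !at$name %in% c("N", "CA", "C", "O", "OXT", "CB"))
  if (!length(idx)) stop("spec error: residue ", resid, " has no side-chain ",
                         "tail to reposition")
  idx
}

.injection_atoms <- function(top, inj) {
  at <- top$atoms
  if (inj$type == "salt_bridge") {
    rn_a <- at$resname[!at$is_ligand & at$resid == inj$acidic_res][1]
    rn_b <- at$resname[!at$is_ligand & at$resid == inj$basic_res][1]
    o_names <- .acidic_atoms[[rn_a]]
    n_names <- .basic_atoms[[rn_b]]
    if (is.null(o_names) || is.null(n_names)) {
      stop("spec error: salt-bridge injection needs Asp/Glu + Lys/Arg, got ",
           rn_a, "-", rn_b)
    }
    list(o = which(!at$is_ligand & at$resid == inj$acidic_res &
                     at$name %in% o_names),
         n = which(!at$is_ligand & at$resid == inj$basic_res &
                     at$name %in% n_names),
         mobile = .sidechain_tail(top, inj$basic_res),
         key = paste0("salt_", inj$acidic_res, "_", inj$basic_res))
  } else if (inj$type == "hbond") {
    d <- which(!at$is_ligand & at$resid == inj$donor_res &
                 at$name == inj$donor_atom)
    acc_nm <- if (is.null(inj$acceptor_atom)) "O" else inj$acceptor_atom
    a <- which(!at$is_ligand & at$resid == inj$acceptor_res &
                 at$name == acc_nm)
    if (!length(d) || !length(a)) {
      stop("spec error: hbond injection atoms not found in topology")
    }
    list(d = d[1], a = a[1], mobile = .sidechain_tail(top, inj$donor_res),
         key = paste0("hbond_", inj$donor_res, inj$donor_atom, "_",
                      inj$acceptor_res, acc_nm))
  } else {
    list(key = paste0("stack_", gsub("[^A-Za-z0-9]", "", inj$ring)))
  }
}

# Apply one injection to (or push it away from) the coordinates of a frame.
.apply_injection <- function(xyz, top, inj, ia, lig_local, engage) {
  if (inj$type == "salt_bridge") {
    dist <- if (is.null(inj$distance)) 3.0 else inj$distance
    xo <- xyz[ia$o, , drop = FALSE]
    xn <- xyz[ia$n, , drop = FALSE]
    dm <- sqrt(pmax(outer(rowSums(xo^2), rowSums(xn^2), "+") -
                      2 * xo %*% t(xn), 0))
    best <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    opos <- xo[best[1], ]; npos <- xn[best[2], ]
    u <- .unit(npos - opos)
    target <- if (engage) dist else 6.0
    if (!engage && min(dm) >= 3.4) return(xyz)
    shift <- (opos + target * u) - npos
    xyz[ia$mobile, ] <- sweep(xyz[ia$mobile, , drop = FALSE], 2, shift, "+")
  } else if (inj$type == "hbond") {
    dist <- if (is.null(inj$distance)) 2.9 else inj$distance
    bb <- .backbone_index(top)
    linked <- .chain_links(bb, xyz)
    don <- .donor_table(top)
    di <- which(don$idx == ia$d)
    H <- .place_donor_h(don$rule[di], ia$d, top, xyz, bb, linked)
    dpos <- xyz[ia$d, ]
    apos <- xyz[ia$a, ]
    if (engage) {
      h <- if (is.null(H)) .unit(apos - dpos) else .unit(H[1, ] - dpos)
      shift <- (apos - dist * h) - dpos
      xyz[ia$mobile, ] <- sweep(xyz[ia$mobile, , drop = FALSE], 2, shift, "+")
    } else if (sqrt(sum((apos - dpos)^2)) < 3.4) {
      u <- .unit(dpos - apos)
      shift <- (apos + 6.0 * u) - dpos
      xyz[ia$mobile, ] <- sweep(xyz[ia$mobile, , drop = FALSE], 2, shift, "+")
    }
  } else {  # stack
    ring_idx <- select_atoms(structure(top, class = "idp_topology"), inj$ring)
    dist <- if (is.null(inj$distance)) 3.5 else inj$distance
    ang <- if (is.null(inj$angle)) 0 else inj$angle
    lig_rows <- lig_local$rows
    if (engage) {
      xyz[lig_rows, ] <- .pose_ligand_xyz(xyz, ring_idx,
                                          xyz[lig_rows, , drop = FALSE],
                                          lig_local$central, dist, ang)
    } else {
      pf <- .plane_fit(xyz[ring_idx, , drop = FALSE])
      xyz[lig_rows, ] <- .pose_ligand_xyz(xyz, ring_idx,
                                          xyz[lig_rows, , drop = FALSE],
                                          lig_local$central, 30, 0)
    }
  }
  xyz
}

#' Compose a labelled synthetic ensemble
#'
#' Generates `n_frames` conformers of the spec's sequence: each frame's
#' backbone comes from a conformer class drawn by the class fractions
#' (deterministic largest-remainder counts, seeded shuffle); `coil` frames
#' get independent per-residue dihedrals from the beta/PPII/extended basins
#' with +/-20 degree jitter. Injected interactions are realized in exactly
#' `round(occupancy * n_frames)` frames (seeded choice) by rigidly
#' repositioning the relevant side chain or ligand; i.i.d. Gaussian noise is
#' added afterwards and injected frames are then re-posed on the noisy
#' coordinates, so the injection criterion holds exactly at any noise level
#' and the realized occupancy is exact.
#'
#' @param spec an [ensemble_spec()].
#' @return list with `trajectory` (an `idp_trajectory`) and `truth`
#'   (data.frame: frame, class, plus one logical column per injection key).
#' @export
compose_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_frames
  .with_seed(spec$seed, {
    counts <- .class_counts(spec$class_fractions, n)
    classes <- rep(names(counts), counts)[sample.int(n)]

    tmpl_frames <- list()
    for (cls in setdiff(unique(classes), "coil")) {
      tmpl_frames[[cls]] <- build_peptide(spec$sequence, cls)
    }
    base <- if (length(tmpl_frames)) {
      tmpl_frames[[1]]
    } else build_peptide(spec$sequence, c(180, 180))
    top_pep <- base$topology
    n_res <- nchar(spec$sequence)

    lig <- NULL; lig_local <- NULL
    if (spec$with_ligand) {
      lig <- build_phenanthroline()
      combo <- combine_structures(base, lig)
      top <- combo$topology
      lig_rows <- which(top$atoms$is_ligand)
      rings_local <- lapply(ligand_rings(lig$topology), identity)
      lig_local <- list(rows = lig_rows,
                        central = .ligand_central_ring(rings_local))
    } else {
      top <- top_pep
    }
    na <- nrow(top$atoms)

    inj_atoms <- lapply(spec$injections, function(i) .injection_atoms(top, i))
    inj_frames <- lapply(spec$injections, function(i) {
      k <- round(i$occupancy * n)
      sort(sample.int(n)[seq_len(k)])
    })

    make_frame <- function(cls) {
      pep <- if (cls == "coil") {
        build_peptide(spec$sequence, .coil_phi_psi(n_res))
      } else tmpl_frames[[cls]]
      x <- get_frame(pep, 1)
      if (!is.null(lig)) {
        lx <- get_frame(lig, 1)
        # park the ligand well away from the peptide by default
        off <- colMeans(x) + c(30, 0, 0) - colMeans(lx)
        x <- rbind(x, sweep(lx, 2, off, "+"))
      }
      x
    }

    coords <- array(NA_real_, dim = c(na, 3, n))
    truth <- data.frame(frame = seq_len(n), class = classes,
                        stringsAsFactors = FALSE)
    for (ii in seq_along(spec$injections)) {
      truth[[inj_atoms[[ii]]$key]] <- seq_len(n) %in% inj_frames[[ii]]
    }

    for (f in seq_len(n)) {
      x <- make_frame(classes[f])
      for (ii in seq_along(spec$injections)) {
        x <- .apply_injection(x, top, spec$injections[[ii]], inj_atoms[[ii]],
                              lig_local, engage = f %in% inj_frames[[ii]])
      }
      if (spec$noise_sigma > 0) {
        x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sigma),
                        nrow(x), 3)
        # re-pose so injected criteria survive the noise exactly
        for (ii in seq_along(spec$injections)) {
          x <- .apply_injection(x, top, spec$injections[[ii]],
                                inj_atoms[[ii]], lig_local,
                                engage = f %in% inj_frames[[ii]])
        }
      }
      coords[, , f] <- x
    }
    list(trajectory = new_trajectory(top, coords), truth = truth)
  })
}
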