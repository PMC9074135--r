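# Molecular data model and multi-model PDB I/O.
#
# A topology is the per-atom metadata shared by all frames; a trajectory
# holds the topology plus an n_atoms x 3 x n_frames coordinate array in
# Angstrom. Residues are numbered 1-based in file order (Asp1...Ala42
# convention); ligand fragments (HETATM) are flagged per atom.

#' Construct a topology
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (1-based residue index), `resname` (3-letter code), `chain`,
#'   `mass` (amu), `is_ligand` (logical).
#' @param termini list with logical flags `nter_amine`, `cter_carboxylate`.
#' @return an object of class `idp_topology`.
#' @export
new_topology <- function(atoms,
                         termini = list(nter_amine = TRUE,
                                        cter_carboxylate = TRUE)) {
  required <- c("serial", "name", "element", "resid", "resname", "chain",
                "mass", "is_ligand")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("topology atoms missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (is.unsorted(atoms$resid)) {
    stop("residue indices must be non-decreasing in atom order")
  }
  pep <- !atoms$is_ligand
  seq1 <- character(0)
  if (any(pep)) {
    res <- unique(atoms$resid[pep])
    rn <- vapply(res, function(r) atoms$resname[pep & atoms$resid == r][1], "")
    seq1 <- unname(ifelse(rn %in% names(.aa_one), .aa_one[rn], "X"))
  }
  structure(list(atoms = atoms,
                 sequence = paste(seq1, collapse = ""),
                 termini = termini),
            class = "idp_topology")
}

#' Construct a trajectory
#'
#' @param topology an `idp_topology`.
#' @param coords either an n_atoms x 3 matrix (single frame), a list of such
#'   matrices, or an n_atoms x 3 x n_frames array.
#' @param frame_index integer frame labels (default 1..n).
#' @param temperature,time optional per-frame metadata (K, ps).
#' @return an object of class `idp_trajectory`.
#' @export
new_trajectory <- function(topology, coords, frame_index = NULL,
                           temperature = NULL, time = NULL) {
  stopifnot(inherits(topology, "idp_topology"))
  na <- nrow(topology$atoms)
  if (is.matrix(coords)) coords <- list(coords)
  if (is.list(coords)) {
    arr <- array(NA_real_, dim = c(na, 3, length(coords)))
    for (i in seq_along(coords)) {
      m <- coords[[i]]
      if (!is.matrix(m) || nrow(m) != na || ncol(m) != 3) {
        stop("frame ", i, ": coordinate matrix must be ", na, " x 3")
      }
      arr[, , i] <- m
    }
    coords <- arr
  }
  if (length(dim(coords)) != 3 || dim(coords)[1] != na || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[3] < 1) stop("a trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("coordinates must all be finite")
  nf <- dim(coords)[3]
  if (is.null(frame_index)) frame_index <- seq_len(nf)
  structure(list(topology = topology, coords = coords,
                 frame_index = as.integer(frame_index),
                 temperature = temperature, time = time),
            class = "idp_trajectory")
}

#' @export
print.idp_topology <- function(x, ...) {
  cat("<idp_topology> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$resid[!x$atoms$is_ligand])), " peptide residues",
      if (any(x$atoms$is_ligand)) " + ligand", "\n", sep = "")
  if (nzchar(x$sequence)) cat("  sequence: ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' @export
print.idp_trajectory <- function(x, ...) {
  cat("<idp_trajectory> ", n_frames(x), " frame(s) of ",
      n_atoms(x), " atoms\n", sep = "")
  print(x$topology)
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `idp_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame's coordinates
#' @param traj an `idp_trajectory`.
#' @param i frame number (1-based position, not MODEL label).
#' @return n_atoms x 3 matrix (Angstrom).
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

#' Subset a trajectory to selected frames
#' @param traj an `idp_trajectory`.
#' @param frames integer vector of frame positions.
#' @return an `idp_trajectory`.
#' @export
subset_frames <- function(traj, frames) {
  new_trajectory(traj$topology, traj$coords[, , frames, drop = FALSE],
                 frame_index = traj$frame_index[frames],
                 temperature = traj$temperature[frames],
                 time = traj$time[frames])
}

# ---------------------------------------------------------------------------
# PDB reading

.parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": fewer than 54 columns")
  }
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (any(is.na(xyz))) {
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": unreadable coordinates")
  }
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  resid <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (is.na(resid)) {
    stop("malformed ATOM/HETATM record at line ", lineno,
         ": unreadable residue number")
  }
  elem <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (elem == "" || !toupper(elem) %in% names(.element_masses)) {
    elem <- guess_element(name)
  } else {
    elem <- toupper(elem)
  }
  list(record = substr(line, 1, 6), serial = serial, name = name,
       resname = trimws(substr(line, 18, 20)),
       chain = substr(line, 22, 22), resid = resid, xyz = xyz, element = elem)
}

#' Read a (multi-model) PDB trajectory
#'
#' Fixed-column parsing of ATOM/HETATM records; MODEL/ENDMDL blocks become
#' frames (a file without MODEL records yields a single frame). HETATM
#' fragments are flagged `is_ligand`; missing element columns are inferred
#' from the atom name. Residues are renumbered 1-based in order of first
#' appearance so downstream reporting matches the Asp1...Ala42 convention.
#'
#' @param source path to a PDB file, or a character vector of PDB text
#'   (single string with newlines, or one line per element).
#' @return an `idp_trajectory`.
#' @export
read_pdb_models <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec6 <- substr(lines, 1, 6)
  is_atom <- rec6 %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 4) == "ATOM" & !rec6 %in% "ATOM  "
  is_model <- substr(lines, 1, 5) == "MODEL"
  is_end <- substr(lines, 1, 6) == "ENDMDL"

  frames <- list()
  meta <- NULL
  cur <- list()
  in_model <- FALSE
  seen_model <- any(is_model)
  flush <- function(cur) {
    if (!length(cur)) return(NULL)
    cur
  }
  for (k in seq_along(lines)) {
    if (is_model[k]) {
      if (length(cur)) frames[[length(frames) + 1L]] <- cur
      cur <- list()
      in_model <- TRUE
    } else if (is_end[k]) {
      frames[[length(frames) + 1L]] <- cur
      cur <- list()
      in_model <- FALSE
    } else if (is_atom[k]) {
      cur[[length(cur) + 1L]] <- .parse_pdb_atom_line(lines[k], k)
    }
  }
  if (length(cur)) frames[[length(frames) + 1L]] <- cur
  frames <- Filter(length, frames)
  if (!length(frames)) stop("no ATOM/HETATM records found")

  first <- frames[[1]]
  na <- length(first)
  serial <- vapply(first, `[[`, 1L, "serial")
  if (any(is.na(serial))) serial <- seq_len(na)
  name <- vapply(first, `[[`, "", "name")
  resname <- vapply(first, `[[`, "", "resname")
  chain <- vapply(first, `[[`, "", "chain")
  raw_resid <- vapply(first, `[[`, 1L, "resid")
  is_lig <- vapply(first, `[[`, "", "record") == "HETATM" &
    !resname %in% names(.aa_one)
  elem <- vapply(first, `[[`, "", "element")
  # renumber residues 1-based in order of first appearance (chain-aware key)
  key <- paste(chain, raw_resid, resname)
  resid <- as.integer(factor(key, levels = unique(key)))
  atoms <- data.frame(serial = serial, name = name, element = elem,
                      resid = resid, resname = resname, chain = chain,
                      mass = .element_mass(elem), is_ligand = is_lig,
                      stringsAsFactors = FALSE)
  top <- new_topology(atoms)

  coords <- array(NA_real_, dim = c(na, 3, length(frames)))
  for (f in seq_along(frames)) {
    if (length(frames[[f]]) != na) {
      stop("model ", f, " has ", length(frames[[f]]), " atoms; expected ", na)
    }
    for (a in seq_len(na)) coords[a, , f] <- frames[[f]][[a]]$xyz
  }
  new_trajectory(top, coords)
}

# ---------------------------------------------------------------------------
# PDB writing

.format_pdb_atom <- function(record, serial, name, resname, chain, resid, xyz,
                             element) {
  if (any(abs(xyz) >= 10000) || any(xyz <= -1000)) {
    stop("coordinate ", paste(sprintf("%.3f", xyz), collapse = ", "),
         " exceeds PDB fixed-column field width")
  }
  nm <- if (nchar(name) < 4 && nchar(element) == 1) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, substr(nm, 1, 4), resname,
          substr(chain, 1, 1), resid %% 10000L, xyz[1], xyz[2], xyz[3],
          1.00, 0.00, substr(element, 1, 2))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame (numbered from 1), coordinates at
#' 3-decimal precision, element column populated, ligand atoms as HETATM.
#'
#' @param traj an `idp_trajectory`.
#' @param dest output file path.
#' @return `dest`, invisibly.
#' @export
write_pdb_models <- function(traj, dest) {
  at <- traj$topology$atoms
  rec <- ifelse(at$is_ligand, "HETATM", "ATOM")
  chain <- ifelse(at$chain == "" | is.na(at$chain), "A", at$chain)
  out <- character(0)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- get_frame(traj, f)
    body <- vapply(seq_len(nrow(at)), function(a) {
      .format_pdb_atom(rec[a], at$serial[a], at$name[a], at$resname[a],
                       chain[a], at$resid[a], xyz[a, ], at$element[a])
    }, "")
    out <- c(out, sprintf("MODEL     %4d", f), body, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, dest)
  invisible(dest)
}

# ---------------------------------------------------------------------------
# Atom selection

.backbone_names <- c("N", "CA", "C", "O")

.parse_ranges <- function(tokens) {
  out <- integer(0)
  for (tk in tokens) {
    if (grepl("^[0-9]+-[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", tk)) {
      out <- c(out, as.integer(tk))
    } else {
      stop("selection error: bad residue range token '", tk, "'")
    }
  }
  out
}

#' Select atoms from a topology
#'
#' A small selection grammar:
#' \itemize{
#'   \item `"backbone"` -- peptide N, CA, C, O;
#'   \item `"calpha"` -- peptide CA atoms;
#'   \item `"peptide"`, `"ligand"`, `"all"`, `"heavy"`;
#'   \item `"resid 3-5 9"` -- residue index ranges;
#'   \item `"resname HIS TYR"` -- residue names;
#'   \item `"name CA CB"` -- atom names;
#'   \item `"ring(TYR10)"` / `"ring(HIS14)"` -- the aromatic ring atoms of one
#'     residue (phenol ring for Tyr, imidazole for His, phenyl for Phe);
#'   \item `"ring(PHN)"` -- the ligand's three fused six-membered rings,
#'     returned as a list of three index vectors.
#' }
#'
#' @param top an `idp_topology` (or `idp_trajectory`, whose topology is used).
#' @param expr selection-expression string.
#' @return sorted integer vector of atom indices (1-based row positions);
#'   for `ring(PHN)`, a list of three such vectors.
#' @export
select_atoms <- function(top, expr) {
  if (inherits(top, "idp_trajectory")) top <- top$topology
  stopifnot(inherits(top, "idp_topology"))
  at <- top$atoms
  expr <- trimws(expr)
  pep <- !at$is_ligand

  if (grepl("^ring\\(.+\\)$", expr)) {
    inner <- toupper(sub("^ring\\((.+)\\)$", "\\1", expr))
    if (inner %in% c("PHN", "PHEN", "LIGAND")) {
      return(ligand_rings(top))
    }
    m <- regmatches(inner, regexec("^([A-Z]{3})([0-9]+)$", inner))[[1]]
    if (length(m) != 3) stop("selection error: cannot parse '", expr, "'")
    resname <- m[2]; resid <- as.integer(m[3])
    ring_names <- .residue_ring_atoms[[resname]]
    if (is.null(ring_names)) {
      stop("selection error: residue type ", resname, " has no aromatic ring")
    }
    idx <- which(pep & at$resid == resid & at$resname == resname &
                   at$name %in% ring_names)
    if (length(idx) != length(ring_names)) {
      stop("selection error: ring atoms of ", resname, resid,
           " not found in topology")
    }
    return(sort(idx))
  }

  tokens <- strsplit(expr, "[[:space:]]+")[[1]]
  head <- tolower(tokens[1])
  idx <- switch(
    head,
    backbone = which(pep & at$name %in% .backbone_names),
    calpha = which(pep & at$name == "CA"),
    peptide = which(pep),
    ligand = which(at$is_ligand),
    all = seq_len(nrow(at)),
    heavy = which(at$element != "H"),
    resid = which(pep & at$resid %in% .parse_ranges(tokens[-1])),
    resname = {
      rn <- toupper(tokens[-1])
      bad <- setdiff(rn, unique(at$resname))
      if (length(bad)) stop("selection error: unknown residue name ",
                            paste(bad, collapse = ", "))
      which(at$resname %in% rn)
    },
    name = {
      nm <- toupper(tokens[-1])
      bad <- setdiff(nm, unique(at$name))
      if (length(bad)) stop("selection error: unknown atom name ",
                            paste(bad, collapse = ", "))
      which(at$name %in% nm)
    },
    stop("selection error: unknown selection '", expr, "'")
  )
  if (!length(idx)) stop("selection error: '", expr, "' matches no atoms")
  sort(unique(idx))
}

#' Enumerate six-membered rings of the ligand
#'
#' Detects rings from the ligand's bond graph (heavy-atom distance < 1.75
#' Angstrom in the reference geometry), so it works for HETATM fragments with
#' arbitrary atom naming. Uses the idealized builder geometry when the
#' topology came from [build_phenanthroline()], otherwise requires a frame.
#'
#' @param top an `idp_topology`.
#' @param xyz optional n_atoms x 3 coordinates used to infer bonds; defaults
#'   to the reference coordinates stored by the builder.
#' @return list of integer vectors, one per six-membered ring.
#' @export
ligand_rings <- function(top, xyz = NULL) {
  if (is.null(xyz)) xyz <- attr(top, "ref_coords")
  if (is.null(xyz)) stop("ligand_rings needs coordinates (xyz)")
  lig <- which(top$atoms$is_ligand & top$atoms$element != "PT")
  if (!length(lig)) stop("topology contains no ligand atoms")
  sub <- xyz[lig, , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  adj <- d > 0 & d < 1.75
  n <- length(lig)
  rings <- list()
  # enumerate 6-cycles by DFS with canonical de-duplication (n <= ~30)
  paths <- function(path) {
    last <- path[length(path)]
    for (nb in which(adj[last, ])) {
      if (length(path) == 6 && nb == path[1]) {
        cyc <- sort(path)
        key <- paste(cyc, collapse = ",")
        if (is.null(rings[[key]])) rings[[key]] <<- path
      } else if (!(nb %in% path) && length(path) < 6 && nb > path[1]) {
        paths(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) paths(s)
  lapply(unname(rings), function(p) sort(lig[p]))
}

#' Canonical amyloid-beta sequences
#'
#' @return named list with one-letter sequences for `abeta16` (the N-terminal
#'   metal-binding fragment) and `abeta42` (the full-length peptide).
#' @export
abeta_sequences <- function() {
  list(abeta16 = "DAEFRHDSGYEVHHQK",
       abeta42 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")
}
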