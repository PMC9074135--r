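# Conformational-ensemble analysis: pairwise best-fit backbone RMSD,
# density-based (DBSCAN) clustering with medoid representatives, and
# Ramachandran histograms with named-region fractions.

#' Pairwise best-fit RMSD matrix over frames
#'
#' Every frame pair is superposed independently (Kabsch) on the selection
#' before the RMSD is taken, the metric used for conformational clustering.
#'
#' @param traj an `idp_trajectory` with >= 2 frames.
#' @param selection selection string or atom indices (default `"backbone"`).
#' @return symmetric n_frames x n_frames matrix (Angstrom, zero diagonal).
#' @export
pairwise_rmsd <- function(traj, selection = "backbone") {
  nf <- n_frames(traj)
  if (nf < 2) stop("pairwise RMSD needs at least two frames")
  sel <- .resolve_selection(traj, selection)
  X <- lapply(seq_len(nf), function(f) matrix(traj$coords[sel, , f], ncol = 3))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      r <- kabsch_superpose(X[[i]], X[[j]])$rmsd
      m[i, j] <- r; m[j, i] <- r
    }
  }
  m
}

#' Density-based clustering (DBSCAN) of a precomputed distance matrix
#'
#' Classic DBSCAN on a distance matrix: points with at least `min_points`
#' neighbours within `eps` (the point itself included) are core points;
#' clusters are grown by density reachability in scan order; border points
#' join the first cluster that reaches them; everything else is noise
#' (label 0). Deterministic given the row order.
#'
#' @param dmat symmetric distance matrix (e.g. from [pairwise_rmsd()]).
#' @param eps neighbourhood radius, in the units of `dmat`
#'   (default 0.8 Angstrom of backbone RMSD).
#' @param min_points minimum neighbourhood size for a core point (default 5).
#' @return list with `labels` (0 = noise), `populations` (named member
#'   counts), `fractions` (populations / n), `n_noise`, and `medoids`
#'   (per-cluster medoid index, from [cluster_representative()]).
#' @export
dbscan_rmsd <- function(dmat, eps = 0.8, min_points = 5) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n == 0 || ncol(dmat) != n) stop("dmat must be a square distance matrix")
  nb <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_points
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  res <- list(labels = labels)
  ids <- setdiff(sort(unique(labels)), 0L)
  pops <- vapply(ids, function(k) sum(labels == k), 1L)
  names(pops) <- ids
  res$populations <- pops
  res$fractions <- pops / n
  res$n_noise <- sum(labels == 0L)
  res$medoids <- cluster_representative(res, dmat)
  res
}

#' Medoid representative of each cluster
#'
#' The medoid is the member minimizing the summed intra-cluster distance;
#' ties break to the lowest frame index.
#'
#' @param result clustering result with a `labels` vector (0 = noise).
#' @param dmat the distance matrix the clustering was run on.
#' @return named integer vector: medoid frame index per cluster id.
#' @export
cluster_representative <- function(result, dmat) {
  dmat <- as.matrix(dmat)
  labels <- result$labels
  ids <- setdiff(sort(unique(labels)), 0L)
  out <- vapply(ids, function(k) {
    members <- which(labels == k)
    sums <- rowSums(dmat[members, members, drop = FALSE])
    members[which.min(sums)]
  }, 1L)
  names(out) <- ids
  out
}

.rama_regions <- data.frame(
  region = c("alphaR", "ppii", "beta", "gammap", "alphaL"),
  phi = c(-60, -75, -150, -80, 60),
  psi = c(-40, 150, 160, 80, 40)
)

.circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Ramachandran histogram and named-region fractions
#'
#' Bins all defined (phi, psi) pairs on a fixed grid and assigns each pair
#' to the nearest named basin centre within a 30-degree Chebyshev radius
#' (circular): alphaR (-60, -40), PPII (-75, 150), beta (-150, 160),
#' gamma-prime (-80, 80), alphaL (+60, +40); pairs outside every basin
#' count as `other`.
#'
#' @param dih dihedral table from [dihedrals()].
#' @param bin bin width in degrees (default 5; must divide 360).
#' @return list with `counts` (phi x psi matrix, bin mid-point labels),
#'   `n` (total pairs binned) and `fractions` (named region fractions,
#'   summing to 1 with `other`).
#' @export
ramachandran <- function(dih, bin = 5) {
  if (360 %% bin != 0) stop("bin width must divide 360")
  phi <- as.vector(dih$phi); psi <- as.vector(dih$psi)
  ok <- !is.na(phi) & !is.na(psi)
  phi <- phi[ok]; psi <- psi[ok]
  if (!length(phi)) stop("no defined (phi, psi) pairs")
  edges <- seq(-180, 180, by = bin)
  bi <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                              1), length(edges) - 1)
  counts <- matrix(0L, length(edges) - 1, length(edges) - 1)
  mids <- edges[-length(edges)] + bin / 2
  dimnames(counts) <- list(phi = mids, psi = mids)
  ij <- cbind(bi(phi), bi(psi))
  for (k in seq_len(nrow(ij))) {
    counts[ij[k, 1], ij[k, 2]] <- counts[ij[k, 1], ij[k, 2]] + 1L
  }
  cheb <- sapply(seq_len(nrow(.rama_regions)), function(r) {
    pmax(.circ_diff(phi, .rama_regions$phi[r]),
         .circ_diff(psi, .rama_regions$psi[r]))
  })
  cheb <- matrix(cheb, ncol = nrow(.rama_regions))
  nearest <- apply(cheb, 1, which.min)
  within <- cheb[cbind(seq_along(nearest), nearest)] <= 30
  region <- ifelse(within, .rama_regions$region[nearest], "other")
  frac <- vapply(c(.rama_regions$region, "other"),
                 function(r) mean(region == r), numeric(1))
  list(counts = counts, n = length(phi), fractions = frac)
}
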