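# Independent oracles and shared fixtures for the test suite.

# Quaternion (Horn) RMSD oracle: optimal superposition RMSD via the largest
# eigenvalue of the 4x4 key matrix. Independent of the SVD/Kabsch path.
quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lmax) / n
  sqrt(max(msd, 0))
}

# Brute-force DBSCAN oracle: core set from distance-matrix row counts,
# clusters as connected components of the core-core graph (matrix-power
# reachability), border points attached to their first core neighbour.
dbscan_bruteforce <- function(dmat, eps, min_points) {
  n <- nrow(dmat)
  within <- dmat <= eps
  core <- rowSums(within) >= min_points
  labels <- rep(0L, n)
  cl <- 0L
  remaining <- which(core)
  while (length(remaining)) {
    cl <- cl + 1L
    comp <- remaining[1]
    repeat {
      grown <- which(core & colSums(within[comp, , drop = FALSE]) > 0)
      grown <- union(comp, grown)
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    labels[comp] <- cl
    remaining <- setdiff(remaining, comp)
  }
  for (i in which(!core)) {
    nb <- which(within[i, ] & core)
    if (length(nb)) labels[i] <- labels[nb[1]]
  }
  labels
}

# Partition comparison up to relabelling: map each label of `a` to the label
# of `b` at its first occurrence and compare.
same_partition <- function(a, b) {
  canon <- function(x) {
    out <- integer(length(x))
    seen <- integer(0)
    for (i in seq_along(x)) {
      if (x[i] == 0L) { out[i] <- 0L; next }
      k <- match(x[i], seen)
      if (is.na(k)) { seen <- c(seen, x[i]); k <- length(seen) }
      out[i] <- k
    }
    out
  }
  identical(canon(a), canon(b))
}

random_rigid_transform <- function(xyz) {
  ax <- stats::rnorm(3)
  R <- idpkit:::.rotation_about(ax, stats::runif(1, 0, 360))
  sweep(xyz %*% t(R), 2, stats::rnorm(3, 0, 5), "+")
}

# Cached builder fixtures (built once per test run).
.fx <- new.env()
fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}
helix16 <- function() fixture("helix16", function() {
  build_peptide(abeta_sequences()$abeta16, c(-60, -40))
})
extended16 <- function() fixture("extended16", function() {
  build_peptide(abeta_sequences()$abeta16, c(180, 180))
})
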