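test_that("pairwise RMSD vanishes for duplicated or rigidly moved frames", {
  set.seed(2)
  p <- helix16()
  x <- get_frame(p, 1)
  tr <- new_trajectory(p$topology,
                       list(x, x, random_rigid_transform(x)))
  m <- pairwise_rmsd(tr)
  expect_equal(max(m), 0, tolerance = 1e-9)
  expect_equal(m, t(m))
})

test_that("pairwise RMSD equals brute-force per-pair superposition", {
  ce <- compose_ensemble(ensemble_spec("ADGSVEKF", 10, c(coil = 1),
                                       noise_sigma = 0.2, seed = 13))
  tr <- ce$trajectory
  sel <- select_atoms(tr, "backbone")
  m <- pairwise_rmsd(tr)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(m[i, j],
                 kabsch_superpose(matrix(tr$coords[sel, , i], ncol = 3),
                                  matrix(tr$coords[sel, , j], ncol = 3))$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("DBSCAN handles the trivial regimes", {
  d_all_close <- matrix(0.1, 10, 10); diag(d_all_close) <- 0
  cl <- dbscan_rmsd(d_all_close, eps = 0.8, min_points = 5)
  expect_equal(unname(cl$populations), 10)
  expect_equal(cl$n_noise, 0)
  d_far <- matrix(10, 8, 8); diag(d_far) <- 0
  cl2 <- dbscan_rmsd(d_far, eps = 0.8, min_points = 5)
  expect_equal(length(cl2$populations), 0)
  expect_equal(cl2$n_noise, 8)
})

test_that("DBSCAN matches an independent reference implementation", {
  set.seed(17)
  for (rep in 1:5) {
    # 50-frame two-blob synthetic RMSD-like matrix with stragglers
    pts <- rbind(matrix(stats::rnorm(40, 0, 0.25), 20, 2),
                 matrix(stats::rnorm(44, 3, 0.25), 22, 2),
                 matrix(stats::runif(16, -8, 8), 8, 2))
    dm <- as.matrix(stats::dist(pts))
    mine <- dbscan_rmsd(dm, eps = 0.8, min_points = 5)
    ref <- dbscan_bruteforce(dm, eps = 0.8, min_points = 5)
    expect_true(same_partition(mine$labels, ref))
    expect_identical(which(mine$labels == 0L), which(ref == 0L))
  }
})

test_that("DBSCAN labels are permutation-invariant up to relabelling", {
  set.seed(23)
  pts <- rbind(matrix(stats::rnorm(30, 0, 0.3), 15, 2),
               matrix(stats::rnorm(30, 4, 0.3), 15, 2))
  dm <- as.matrix(stats::dist(pts))
  base <- dbscan_rmsd(dm, eps = 0.9, min_points = 4)
  perm <- sample(nrow(dm))
  permuted <- dbscan_rmsd(dm[perm, perm], eps = 0.9, min_points = 4)
  back <- integer(length(perm)); back[perm] <- permuted$labels
  expect_true(same_partition(base$labels, back))
})

test_that("growing eps never shrinks the largest cluster", {
  set.seed(31)
  pts <- matrix(stats::rnorm(60, 0, 1.2), 30, 2)
  dm <- as.matrix(stats::dist(pts))
  largest <- sapply(c(0.4, 0.8, 1.2, 1.6, 2.4), function(e) {
    cl <- dbscan_rmsd(dm, eps = e, min_points = 4)
    if (length(cl$populations)) max(cl$populations) else 0
  })
  expect_true(all(diff(largest) >= 0))
})

test_that("medoids minimize summed intra-cluster distance", {
  # hand case: distances (1,2)=1, (1,3)=1, (2,3)=2 -> medoid is member 1
  d <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3)
  res <- list(labels = c(1L, 1L, 1L))
  expect_equal(unname(cluster_representative(res, d)), 1L)
  # identical frames tie-break to the lowest index; singletons map to self
  d0 <- matrix(0, 4, 4)
  expect_equal(unname(cluster_representative(list(labels = rep(1L, 4)), d0)), 1L)
  expect_equal(unname(cluster_representative(list(labels = c(0L, 1L, 0L)), d0)),
               2L)
  # exhaustive minimality on a random cluster
  set.seed(5)
  dd <- as.matrix(stats::dist(matrix(stats::rnorm(40), 20, 2)))
  med <- cluster_representative(list(labels = rep(1L, 20)), dd)
  expect_equal(unname(med), unname(which.min(rowSums(dd))))
})

test_that("Ramachandran regions capture the named basins", {
  mk <- function(phi, psi) list(phi = matrix(phi, 4, 8),
                                psi = matrix(psi, 4, 8))
  expect_equal(ramachandran(mk(-60, -40))$fractions[["alphaR"]], 1)
  expect_equal(ramachandran(mk(-75, 150))$fractions[["ppii"]], 1)
  expect_equal(ramachandran(mk(-80, 80))$fractions[["gammap"]], 1)
  expect_equal(ramachandran(mk(60, 40))$fractions[["alphaL"]], 1)
  mixed <- list(phi = cbind(matrix(-60, 4, 4), matrix(-150, 4, 4)),
                psi = cbind(matrix(-40, 4, 4), matrix(160, 4, 4)))
  fr <- ramachandran(mixed)$fractions
  expect_equal(fr[["alphaR"]], 0.5)
  expect_equal(fr[["beta"]], 0.5)
})

test_that("histogram totals are conserved across bin widths", {
  dh <- dihedrals(compose_ensemble(ensemble_spec("ADGSVEKF", 6, c(coil = 1),
                                                 seed = 19))$trajectory)
  n_defined <- sum(!is.na(dh$phi) & !is.na(dh$psi))
  for (bin in c(5, 10, 30)) {
    ra <- ramachandran(dh, bin = bin)
    expect_equal(sum(ra$counts), n_defined)
    expect_equal(sum(ra$fractions), 1, tolerance = 1e-12)
  }
})
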