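test_that("superposition RMSD removes rigid motion exactly", {
  set.seed(2)
  A <- matrix(stats::rnorm(30), 10, 3)
  frames <- list(A, A)
  expect_equal(pairwise_rmsd(frames)[1, 2], 0)
  # arbitrary rotation + translation: RMSD 0 within 1e-6 A
  th <- 0.7; ph <- 1.2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  B <- A %*% (Rz %*% Rx) + matrix(c(1, -2, 0.5), 10, 3, byrow = TRUE)
  expect_lt(pairwise_rmsd(list(A, B))[1, 2], 1e-6)
})

test_that("closed-form superposition agrees with a rotation-grid oracle", {
  set.seed(4)
  A <- matrix(stats::rnorm(12, 0, 0.5), 4, 3)
  B <- A
  B[2, ] <- B[2, ] + c(0.1, 0, 0)              # +1 A on one bead (in nm)
  got <- pairwise_rmsd(list(A, B))[1, 2]
  oracle <- 10 * grid_rmsd(A, B)
  # the optimal rotation can only beat the search; they agree after refinement
  expect_lte(got, oracle + 1e-6)
  expect_equal(got, oracle, tolerance = 1e-4)
  # perturbing one of 4 beads by 1 A costs at most 1/2 A RMSD before fitting
  expect_lte(got, sqrt(1 / 4) + 1e-9)
})

test_that("superposition cross-checks against bio3d", {
  skip_if_not_installed("bio3d")
  set.seed(6)
  A <- matrix(stats::rnorm(45), 15, 3)
  B <- A + matrix(stats::rnorm(45, 0, 0.1), 15, 3)
  got <- pairwise_rmsd(list(A, B))[1, 2]
  want <- bio3d::rmsd(10 * as.vector(t(A)), 10 * as.vector(t(B)),
                      fit = TRUE)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("single linkage reproduces the textbook cases", {
  # all pairs at 5 A with a 4 A cutoff: singletons
  n <- 10
  D <- matrix(5, n, n); diag(D) <- 0
  cl <- single_linkage(D, 4)
  expect_equal(cl$sizes, rep(1, n))
  expect_length(cl$medoids, n)
  # chain of structures 3.9 A apart, ends 20 A apart: one cluster (chaining)
  n <- 8
  D <- abs(outer(1:n, 1:n, "-")) * 3.9
  D[D > 0 & D < 3.9] <- 3.9
  cl2 <- single_linkage(D, 4)
  expect_equal(cl2$sizes, n)
  expect_gt(max(D), 20)
  # exactly at the cutoff is NOT joined (strict inequality)
  D3 <- matrix(4, 3, 3); diag(D3) <- 0
  expect_equal(single_linkage(D3, 4)$sizes, c(1, 1, 1))
})

test_that("clusters equal the exhaustive connected-components oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    P <- matrix(stats::rnorm(n * 2, 0, 6), n, 2)
    D <- as.matrix(stats::dist(P))
    cl <- single_linkage(D, 4)
    want <- bfs_components(D, 4)
    # same partition up to relabelling
    expect_equal(length(unique(want)), length(cl$sizes))
    tab <- table(cl$membership, want)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("cluster ids are canonical: size order, stable under permutation", {
  fix <- make_cluster_fixture(c(8, 3, 1), spread = 2, separation = 12,
                              seed = 41)
  D <- pairwise_rmsd(fix$frames)
  cl <- single_linkage(D, 4)
  expect_equal(cl$sizes, c(8, 3, 1))
  expect_equal(cl$membership, fix$labels)
  # permute the frames: memberships map through the permutation
  perm <- sample(length(fix$frames))
  Dp <- D[perm, perm]
  clp <- single_linkage(Dp, 4)
  expect_equal(clp$sizes, cl$sizes)
  same_before <- outer(cl$membership[perm], cl$membership[perm], "==")
  same_after <- outer(clp$membership, clp$membership, "==")
  expect_identical(same_before, same_after)
  # raising the cutoff never increases the cluster count
  counts <- vapply(c(1, 2, 4, 8, 16, 30), function(ct)
    length(single_linkage(D, ct)$sizes), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("medoids minimise the mean intra-cluster distance", {
  # 1D points: 0, 1, 2.5 in one chained cluster; medoid is the middle one
  D <- as.matrix(stats::dist(c(0, 1.9, 3.8)))
  cl <- single_linkage(D, 2)
  expect_equal(cl$sizes, 3)
  expect_equal(cl$medoids, 2L)
})
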