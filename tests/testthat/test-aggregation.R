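# Hand-built micro-trajectories where every distance is known by
# construction.
micro_traj <- function(frames, seqs, box = NA_real_) {
  sys <- toy_system(seqs)
  topo <- build_topology(sys)
  new_trajectory(frames, seq_along(frames), box = box, topology = topo)
}

test_that("distance maps take the smallest bead pair and average frames", {
  # two single-residue chains: glycine has no side chain, so CA-CA only
  sys <- toy_system(list("G", "G"))
  topo <- build_topology(sys)
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  tr <- new_trajectory(list(f1), 1, topology = topo)
  M <- min_distance_map(tr)
  expect_equal(M[1, 2], 1.0)
  expect_equal(diag(M), c(0, 0))
  # with side chains, the smallest of the four bead-pair distances wins
  sys2 <- toy_system(list("Q", "Q"))
  topo2 <- build_topology(sys2)
  f2 <- rbind(c(0, 0, 0), c(0, 0, 0.3),     # chain 1: CA, SC
              c(1, 0, 0), c(0.8, 0, 0.3))   # chain 2: CA, SC
  tr2 <- new_trajectory(list(f2), 1, topology = topo2)
  M2 <- min_distance_map(tr2)
  expect_equal(M2[1, 2], 0.8)                  # SC1-SC2 is the closest pair
  expect_error(min_distance_map(new_trajectory(list(), numeric(0),
                                               topology = topo2)),
               "empty")
})

test_that("distance maps match brute-force recomputation on random frames", {
  set.seed(9)
  seqs <- list("QAG", "LP")
  sys <- toy_system(seqs)
  topo <- build_topology(sys)
  frames <- lapply(1:2, function(i)
    matrix(stats::runif(nrow(topo$beads) * 3, 0, 3), ncol = 3))
  tr <- new_trajectory(frames, 1:2, box = 4, topology = topo)
  M <- min_distance_map(tr)
  # independent recomputation, bead by bead
  R <- nrow(sys$table)
  want <- matrix(0, R, R)
  for (f in frames) {
    for (i in seq_len(R)) for (j in seq_len(R)) {
      if (i == j) next
      bi <- which(topo$beads$res == i); bj <- which(topo$beads$res == j)
      dmin <- Inf
      for (a in bi) for (b in bj) {
        d <- f[b, ] - f[a, ]; d <- d - 4 * round(d / 4)
        dmin <- min(dmin, sqrt(sum(d * d)))
      }
      want[i, j] <- want[i, j] + dmin / length(frames)
    }
  }
  diag(want) <- 0
  expect_equal(unclass(M), want, ignore_attr = TRUE)
  expect_equal(unclass(M), t(unclass(M)))    # symmetry
})

test_that("cross-beta maps obey the strict 0.4 nm rule and frame averaging", {
  sys <- build_system(build_construct(23), build_construct(23))
  # planted contact below the cutoff in ~half the frames
  planted <- plant_segment_pair(sys, 1, "polyQ", 2, "polyQ",
                                contact = 0.35, frac = 0.5, length = 10)
  fix <- make_planted_trajectory(sys, n_frames = 300, planted = planted,
                                 seed = 13, noise_sd = 0.003)
  tr <- fix$trajectory
  ann <- beta_annotations(tr)
  cb <- cross_beta_map(tr, ann)
  on_frac <- mean(fix$truth$on[, 1])
  al <- fix$truth$aligned
  # every interior-aligned pair carries exactly one contact per "on" frame
  interior <- al[al$interior, ]
  expect_equal(unname(cb[cbind(interior$ra, interior$rb)]),
               rep(on_frac, nrow(interior)))
  # and no contact appears off the planted alignment
  mask <- matrix(FALSE, nrow(cb), ncol(cb))
  mask[cbind(al$ra, al$rb)] <- TRUE
  mask[cbind(al$rb, al$ra)] <- TRUE
  expect_equal(sum(cb[!mask]), 0)
  # intra-chain block is zero by construction
  ch <- sys$table$chain
  expect_true(all(cb[ch == 1, ch == 1] == 0))
  expect_true(all(cb[ch == 2, ch == 2] == 0))
  # same geometry beyond the cutoff: all-zero map
  fix45 <- make_planted_trajectory(sys, n_frames = 40,
                                   planted = plant_segment_pair(
                                     sys, 1, "polyQ", 2, "polyQ",
                                     contact = 0.45, frac = 1, length = 10),
                                   seed = 13, noise_sd = 0.003)
  ann45 <- beta_annotations(fix45$trajectory)
  expect_true(any(ann45))                      # still beta-paired...
  expect_equal(sum(cross_beta_map(fix45$trajectory, ann45)), 0)  # ...no contacts
  # no beta anywhere -> all zero regardless of proximity
  cb0 <- cross_beta_map(tr, ann & FALSE)
  expect_equal(sum(cb0), 0)
  expect_error(cross_beta_map(tr, ann[1:3, ]), "frame counts")
})

test_that("precursor calls recover planted region pairs with no false pairs", {
  sys <- build_system(build_construct(23), build_construct(74))
  planted <- plant_segment_pair(sys, 1, "R17", 2, "polyQ", contact = 0.35)
  fix <- make_planted_trajectory(sys, n_frames = 30, planted = planted,
                                 seed = 17)
  tr <- fix$trajectory
  ann <- beta_annotations(tr)
  pc <- call_precursors(tr$frames[[1]], ann[1, ], tr$topology, tr$box)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$region_a, "1:R17")
  expect_equal(pc$region_b, "2:polyQ")
  smry <- precursor_summary(tr, ann)
  expect_equal(nrow(smry), 1)
  expect_equal(smry$fraction, 1)
})

test_that("a monomeric hairpin is not an aggregate precursor", {
  sys <- build_system(build_construct(23))
  # intra-chain pairing: polyQ start against polyQ end (gap >= 3)
  planted <- data.frame(chain_a = 1, start_a = 18, chain_b = 1, start_b = 31,
                        length = 8, contact = 0.35, frac = 1)
  fix <- make_planted_trajectory(sys, n_frames = 10, planted = planted,
                                 seed = 19)
  ann <- beta_annotations(fix$trajectory)
  expect_true(any(ann))                        # the hairpin is beta...
  smry <- precursor_summary(fix$trajectory, ann)
  expect_equal(nrow(smry), 0)                  # ...but not inter-chain
})

test_that("ternary fixture: R12 of one 23Q chain with the 74Q polyQ", {
  sys <- build_system(build_construct(23), build_construct(23),
                      build_construct(74))
  planted <- plant_segment_pair(sys, 1, "R12", 3, "polyQ", contact = 0.35)
  fix <- make_planted_trajectory(sys, n_frames = 10, planted = planted,
                                 seed = 23)
  ann <- beta_annotations(fix$trajectory)
  smry <- precursor_summary(fix$trajectory, ann)
  expect_equal(nrow(smry), 1)
  expect_equal(smry$region_a, "1:R12")
  expect_equal(smry$region_b, "3:polyQ")
})

test_that("region block summaries reduce maps correctly", {
  sys <- build_system(build_construct(23), build_construct(23))
  R <- sys$total_length
  uniform <- matrix(2.5, R, R)
  attr(uniform, "system") <- sys
  bs <- region_block_summary(uniform)
  expect_true(all(abs(bs - 2.5) < 1e-12))
  single <- matrix(0, R, R); single[1, 100] <- 1
  attr(single, "system") <- sys
  bs1 <- region_block_summary(single)
  expect_equal(sum(bs1 > 0), 1)
  # random map equals brute-force block averaging
  set.seed(3)
  M <- matrix(stats::runif(R * R), R, R)
  attr(M, "system") <- sys
  bs2 <- region_block_summary(M)
  labs <- region_labels(sys)
  i <- which(labs == "1:polyQ"); j <- which(labs == "2:R17")
  expect_equal(bs2["1:polyQ", "2:R17"], mean(M[i, j]))
})
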