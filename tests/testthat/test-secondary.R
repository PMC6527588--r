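# Geometry builders local to these tests: ideal CG sheet and helix fixtures.
ideal_sheet_system <- function(len = 12) {
  toy_system(list(strrep("Q", len), strrep("Q", len)))
}

# Two antiparallel zig-zag strands 0.48 nm apart (the classic CG sheet).
ideal_sheet_frame <- function(topo, len = 12, sep = 0.48) {
  a <- 0.36; b <- sqrt(0.38^2 - a^2) / 2
  X <- matrix(0, nrow(topo$beads), 3)
  for (ch in 1:2) {
    res <- topo$system$table$global_index[topo$system$table$chain == ch]
    m <- seq_along(res) - 1
    ca <- cbind(m * a, (ch - 1) * sep, 5 + b * (-1)^m)
    X[topo$ca_of[res], ] <- ca
    sc <- ca; sc[, 3] <- sc[, 3] + 0.3 * (-1)^ch
    X[topo$sc_of[res], ] <- sc
  }
  X
}

helix_frame <- function(topo) {
  tabs <- topo$system$table
  X <- matrix(0, nrow(topo$beads), 3)
  for (ch in unique(tabs$chain)) {
    res <- tabs$global_index[tabs$chain == ch]
    th <- seq_along(res) * 100 * pi / 180
    ca <- cbind(0.245 * cos(th) + 3 * ch, 0.245 * sin(th), 0.06 * seq_along(res))
    X[topo$ca_of[res], ] <- ca
    sc <- ca; sc[, 1] <- sc[, 1] + 0.3
    X[topo$sc_of[res], ] <- sc
  }
  X
}

test_that("an ideal two-strand sheet is beta at all interior residues", {
  sys <- ideal_sheet_system(12)
  topo <- build_topology(sys)
  X <- ideal_sheet_frame(topo, 12)
  beta <- assign_beta(X, topo)
  # interior: dihedral quadruple must fit, so residues 2..L-2 per chain
  for (ch in 1:2) {
    idx <- sys$table$global_index[sys$table$chain == ch]
    expect_true(all(beta[idx[2:10]]))
    expect_false(any(beta[idx[c(1, 11, 12)]]))
  }
})

test_that("helical geometry yields zero beta and short chains are skipped", {
  sys <- toy_system(list("QQQQQQQQ", "QQQQQQQQ"))
  topo <- build_topology(sys)
  expect_false(any(assign_beta(helix_frame(topo), topo)))
  sys3 <- toy_system(list("QQL"))
  topo3 <- build_topology(sys3)
  X3 <- matrix(stats::rnorm(nrow(topo3$beads) * 3), ncol = 3)
  expect_false(any(assign_beta(X3, topo3)))
})

test_that("strand separation beyond the pairing cutoff kills the label", {
  sys <- ideal_sheet_system(12)
  topo <- build_topology(sys)
  X_far <- ideal_sheet_frame(topo, 12, sep = 0.60)   # > 0.55 nm
  expect_false(any(assign_beta(X_far, topo)))
  X_near <- ideal_sheet_frame(topo, 12, sep = 0.54)
  expect_true(any(assign_beta(X_near, topo)))
})

test_that("binomial error bars match the closed form", {
  expect_equal(binom_halfwidth(0.5, 4000), 1.96 * sqrt(0.25 / 4000))
  expect_equal(signif(binom_halfwidth(0.5, 4000), 2), 0.015)
  expect_equal(binom_halfwidth(0, 4000), 0)
  expect_equal(binom_halfwidth(0.2, 4000), 1.96 * sqrt(0.16 / 4000))
  expect_equal(round(binom_halfwidth(0.2, 4000), 4), 0.0124)
  expect_error(binom_halfwidth(0.5, 0), "positive")
  # the half-width is maximal at p = 0.5 for fixed N
  p <- seq(0, 1, by = 0.01)
  expect_equal(p[which.max(binom_halfwidth(p, 4000))], 0.5)
})

test_that("beta profiles count frames and propagate errors", {
  ann <- rbind(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE),
               c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
  prof <- beta_profile(ann)
  expect_equal(prof$p, c(1, 0, 0.5))
  expect_equal(prof$dp, binom_halfwidth(c(1, 0, 0.5), 4))
  expect_equal(attr(prof, "n_frames"), 4)
  expect_error(beta_profile(matrix(logical(0), 0, 3)), "at least one")
})

test_that("planted beta frequencies are recovered within the error bars", {
  sys <- build_system(build_construct(23), build_construct(23))
  planted <- plant_segment_pair(sys, 1, "polyQ", 2, "polyQ",
                                contact = 0.45, frac = 0.6)
  fix <- make_planted_trajectory(sys, n_frames = 150, planted = planted,
                                 seed = 5)
  ann <- beta_annotations(fix$trajectory)
  prof <- beta_profile(ann, sys)
  truth <- fix$truth$beta_freq
  sel <- !is.na(truth)
  ok <- abs(prof$p[sel] - truth[sel]) <= pmax(prof$dp[sel], 1e-9)
  expect_gte(mean(ok), 0.95)
})
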