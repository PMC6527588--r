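test_that("bead topology counts and bonds match the two-bead scheme", {
  sys <- toy_system(list("QAGPL"))           # one glycine -> one missing SC
  topo <- build_topology(sys)
  expect_equal(nrow(topo$beads), 2 * 5 - 1)
  expect_equal(sum(topo$beads$kind == "SC"), 4)
  # bonded pairs listed exactly once, no self-bonds
  keys <- paste(pmin(topo$bonds$i, topo$bonds$j),
                pmax(topo$bonds$i, topo$bonds$j))
  expect_false(any(duplicated(keys)))
  expect_true(all(topo$bonds$i != topo$bonds$j))
  # CA-CA bonds: 4; pseudo-bonds: 3; CA-SC: 4
  expect_equal(sum(topo$bonds$kind == "ca_ca"), 4)
  expect_equal(sum(topo$bonds$kind == "ca_ca2"), 3)
  expect_equal(sum(topo$bonds$kind == "ca_sc"), 4)
})

test_that("pair potentials are symmetric with the declared structure", {
  sys <- build_system(build_construct(23), build_construct(23))
  topo <- build_topology(sys)
  tabs <- interaction_tables(topo)
  ff <- topo$ff
  # adjacent CA beads: infinite bond well with the configured window
  ca1 <- topo$ca_of[1]; ca2 <- topo$ca_of[2]
  p <- pair_potential(topo, tabs, ca1, ca2)
  expect_true(p$bonded)
  expect_equal(p$radii, ff$bond_ca_ca)
  expect_identical(pair_potential(topo, tabs, ca2, ca1), p)  # symmetry
  # Q side chains on different chains: attractive well present
  q1 <- topo$sc_of[which(sys$table$aa == "Q" & sys$table$chain == 1)[1]]
  q2 <- topo$sc_of[which(sys$table$aa == "Q" & sys$table$chain == 2)[1]]
  pq <- pair_potential(topo, tabs, q1, q2)
  expect_false(pq$bonded)
  expect_true(any(pq$energies < 0))
  # beyond the outermost shell the energy is zero
  expect_equal(pq$energies[length(pq$energies)], 0)
  expect_error(pair_potential(topo, tabs, 0, 1), "range")
})

test_that("Q-Q attraction dominates proline contacts", {
  ff <- default_forcefield()
  expect_gt(ff$class_eps["Q", "Q"], ff$class_eps["P", "Q"])
  expect_gt(ff$hb_eps, max(ff$class_eps["P", ]))
})

test_that("system energy matches a brute-force double loop", {
  st <- toy_mixed_state(seed = 5)
  got <- system_energy(st, parts = TRUE)
  want <- brute_energy(st)
  expect_equal(got$potential, want$potential)
  expect_equal(got$kinetic, want$kinetic)
  # trivial cases: far apart at rest -> 0; one pair in a well at rest -> -eps
  types <- list(list(radii = c(0.35, 0.62), energies = c(Inf, -1, 0),
                     bonded = FALSE))
  itab <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  far <- make_raw_state(rbind(c(1, 1, 1), c(3, 3, 3)),
                        matrix(0, 2, 3), 50, types, itab)
  expect_equal(system_energy(far), 0)
  near <- make_raw_state(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                         matrix(0, 2, 3), 50, types, itab)
  expect_equal(system_energy(near), -1)
  overlapping <- make_raw_state(rbind(c(1, 1, 1), c(1.2, 1, 1)),
                                matrix(0, 2, 3), 50, types, itab)
  expect_error(system_energy(overlapping), "inconsistent state")
})

test_that("energy is invariant under rigid translation and periodic shifts", {
  st <- toy_mixed_state(seed = 7)
  e0 <- system_energy(st)
  st_shift <- st
  st_shift$x <- sweep(st$x, 2, c(0.13, -0.4, 0.77), "+")
  expect_equal(system_energy(st_shift), e0)
  st_img <- st
  st_img$x[3, ] <- st$x[3, ] + c(st$box, -2 * st$box, st$box)
  expect_equal(system_energy(st_img), e0)
})

test_that("force-field files round-trip", {
  ff <- default_forcefield()
  ff$class_eps["Q", "Q"] <- 1.25
  ff$hb_eps <- 0.55
  path <- withr::local_tempfile(fileext = ".ff")
  write_forcefield(ff, path)
  ff2 <- read_forcefield(path)
  expect_equal(ff2$class_eps, ff$class_eps)
  expect_equal(ff2$hb_eps, ff$hb_eps)
  expect_equal(ff2$bond_ca_ca, ff$bond_ca_ca)
  expect_equal(forcefield_hash(ff2), forcefield_hash(ff))
  expect_false(forcefield_hash(ff2) == forcefield_hash(default_forcefield()))
})

test_that("amino-acid classes cover the alphabet and reject junk", {
  expect_equal(aa_class(c("Q", "P", "G", "L", "S")),
               c("Q", "P", "G", "H", "O"))
  expect_error(aa_class("Z"), "unknown")
})
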