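# Stability toys: two parallel QQQQQ chains 0.5 nm apart (side chains carry
# only attractive contacts across the interface; backbone is untouched by
# mutation). A repack shell of 0.3 nm restricts annealing to the mutated
# side chain itself, which makes ablation properties exact.
ablate_fixture <- function() toy_structure(list("QQQQQ", "QQQQQ"))

test_that("the dG surrogate is finite on valid geometry and tracks contacts", {
  st <- ablate_fixture()
  e <- structure_energy(st)
  expect_true(is.finite(e))
  expect_lt(e, 0)                              # attractive interface
})

test_that("identity substitutions give exactly zero", {
  st <- ablate_fixture()
  res <- ddg_scan(st, positions = 3, substitutions = "Q", iterations = 3,
                  seed = 1)
  expect_equal(res$ddg, 0)
  expect_equal(res$sd, 0)
  expect_equal(res$flag, "identity")
})

test_that("glycine ablation of an attractive side chain destabilizes", {
  st <- ablate_fixture()
  params <- repack_params(shell = 0.3, n_steps = 150)
  res <- ddg_scan(st, positions = 3, substitutions = "G", iterations = 6,
                  seed = 7, params = params)
  expect_equal(res$flag, "ok")
  expect_gte(res$ddg, 0)
  # direct check: removing only-attractive wells cannot lower the energy
  mut <- mutate_structure(st, 3, "G")
  expect_gte(structure_energy(mut), structure_energy(st) - 1e-12)
})

test_that("proline substitutions are flagged as omitted", {
  st <- ablate_fixture()
  res <- ddg_scan(st, positions = 2, substitutions = c("P", "A"),
                  iterations = 2, seed = 3,
                  params = repack_params(n_steps = 60))
  pr <- res[res$sub == "P", ]
  expect_equal(pr$flag, "proline-omitted")
  expect_true(is.na(pr$ddg))
  expect_equal(res$flag[res$sub == "A"], "ok")
})

test_that("repacking is deterministic given the seed", {
  st <- ablate_fixture()
  r1 <- repack(st, 3, seed = 42)
  r2 <- repack(st, 3, seed = 42)
  expect_identical(r1$dG, r2$dG)
  expect_identical(r1$x, r2$x)
  expect_error(repack(st, 99, seed = 1), "range")
  expect_error(ddg_scan(st, positions = integer(0)), "empty")
})

test_that("classification follows the sign convention", {
  fake <- structure(data.frame(position = 1:3, wt = "Q", sub = c("A", "L", "S"),
                               ddg = c(5, -5, 0.1), sd = c(1, 1, 1),
                               n_iter = 10, flag = "ok"),
                    class = c("pqd_ddg", "data.frame"))
  expect_equal(classify_ddg(fake),
               c("destabilizing", "stabilizing", "neutral"))
  expect_equal(classify_ddg(fake, tau = 0.01),
               c("destabilizing", "stabilizing", "destabilizing"))
})

test_that("scan means tighten as 1/sqrt(iterations)", {
  st <- ablate_fixture()
  params <- repack_params(shell = 0.45, n_steps = 60)
  reps <- 14
  ks <- c(4, 16, 64)
  sds <- vapply(ks, function(k) {
    means <- vapply(seq_len(reps), function(r) {
      res <- ddg_scan(st, positions = 3, substitutions = "A",
                      iterations = k, seed = 1000 * r + k, params = params)
      res$ddg
    }, numeric(1))
    stats::sd(means)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  ratio <- sds[1] / sds[3]                     # expect ~ sqrt(64/4) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("mutation rebuilds the topology consistently", {
  st <- ablate_fixture()
  mutL <- mutate_structure(st, 3, "L")
  expect_equal(mutL$topology$beads$class[mutL$topology$beads$res == 3 &
                                         mutL$topology$beads$kind == "SC"], "H")
  mutG <- mutate_structure(st, 3, "G")
  expect_equal(nrow(mutG$topology$beads), nrow(st$topology$beads) - 1)
  # glycine -> leucine recreates a side chain near its CA
  back <- mutate_structure(mutG, 3, "L", seed = 5)
  expect_equal(nrow(back$topology$beads), nrow(st$topology$beads))
  ca <- back$topology$ca_of[3]; sc <- back$topology$sc_of[3]
  d <- sqrt(sum((back$x[sc, ] - back$x[ca, ])^2))
  ff <- default_forcefield()
  expect_gte(d, ff$bond_ca_sc[1] - 1e-9)
  expect_lte(d, ff$bond_ca_sc[2] + 1e-9)
})
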