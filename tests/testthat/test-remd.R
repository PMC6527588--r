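test_that("temperature ladders are linear with exact endpoints", {
  lad <- make_ladder(0.5, 0.72, 20)
  expect_length(lad$temperatures, 20)
  expect_equal(lad$temperatures[1], 0.5)
  expect_equal(lad$temperatures[20], 0.72)
  expect_equal(unique(round(diff(lad$temperatures), 12)),
               round(0.22 / 19, 12))
  expect_equal(make_ladder(0.5, 0.72, 2)$temperatures, c(0.5, 0.72))
  expect_error(make_ladder(0.72, 0.5, 20), "t_min")
  expect_error(make_ladder(0.5, 0.72, 1), "at least 2")
})

test_that("swap acceptance probability follows the Metropolis rule", {
  expect_equal(swap_accept_prob(0.5, 0.6, 3, 3), 1)       # equal energies
  # the cold replica holding the higher energy always swaps
  expect_equal(swap_accept_prob(0.5, 0.6, 2, -1), 1)
  # the cold replica already lower in energy swaps with the Boltzmann factor
  expect_equal(swap_accept_prob(0.5, 0.6, -1, 2),
               exp((1 / 0.5 - 1 / 0.6) * (-1 - 2)))
  expect_lt(swap_accept_prob(0.5, 0.6, -1, 2), 1)
})

test_that("empirical swap decisions match the formula within binomial error", {
  set.seed(21)
  for (case in list(c(0.5, 0.55, 1.2, 0.3), c(0.6, 0.72, 0.4, 0.9))) {
    p <- swap_accept_prob(case[1], case[2], case[3], case[4])
    n <- 4000
    acc <- sum(replicate(n, attempt_swap(case[1], case[2], case[3], case[4])))
    ci <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(acc / n - p), max(ci, 0.02))
  }
})

test_that("two-level toy occupancies match the analytic Boltzmann oracle", {
  toy <- make_two_level_toy(0.5, make_ladder(0.5, 0.72, 5))
  res <- remd_toy(toy, n_cycles = 6000, seed = 3)
  expect_equal(res$occupancy, res$expected, tolerance = 0.03)
  # occupancy increases with temperature
  expect_true(all(diff(res$occupancy) > -0.02))
  # per-(state pair) acceptance matches the Metropolis value
  temps <- res$temps
  for (k in seq_len(length(temps) - 1)) {
    for (cell in 1:4) {
      att <- res$accept_by_state$attempts[k, cell]
      if (att < 200) next
      si <- (cell - 1) %/% 2; sj <- (cell - 1) %% 2
      p <- swap_accept_prob(temps[k], temps[k + 1], si * toy$dE, sj * toy$dE)
      emp <- res$accept_by_state$accepts[k, cell] / att
      expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / att) + 0.01)
    }
  }
})

test_that("run_remd conserves the temperature multiset and labels output", {
  sys <- toy_system(list("QQLQQ", "QQLQQ"))
  lad <- make_ladder(0.5, 0.72, 3, exchange_interval = 10)
  res <- run_remd(sys, lad, t_total = 60, dt_sample = 5, thermostat = 1,
                  seed = 5, box_edge = 8, spacing = 0.8)
  # at every swap step the replicas hold exactly the ladder temperatures
  for (r in seq_len(nrow(res$replica_temps)))
    expect_setequal(res$replica_temps[r, ], 1:3)
  expect_equal(res$acceptance$t_low, lad$temperatures[1:2])
  for (k in 1:3) {
    tr <- res$trajectories[[k]]
    expect_equal(tr$temperature, lad$temperatures[k])
    expect_true(all(diff(tr$times) > 0))
  }
  # one replica reduces to a plain advance (no swap partners)
  lad1 <- structure(list(temperatures = 0.6, exchange_interval = 10),
                    class = "pqd_ladder")
  res1 <- run_remd(sys, lad1, t_total = 30, dt_sample = 5, thermostat = 1,
                   seed = 5, box_edge = 8, spacing = 0.8)
  expect_equal(nrow(res1$acceptance), 0)
  expect_length(res1$trajectories[[1]], 6)
  expect_error(run_remd(sys, lad, t_total = 5), "exchange interval")
})

test_that("remd runs are reproducible for a fixed seed", {
  sys <- toy_system(list("QLQ", "QLQ"))
  lad <- make_ladder(0.5, 0.7, 2, exchange_interval = 10)
  r1 <- run_remd(sys, lad, t_total = 40, dt_sample = 10, thermostat = 1,
                 seed = 11, box_edge = 6, spacing = 0.8)
  r2 <- run_remd(sys, lad, t_total = 40, dt_sample = 10, thermostat = 1,
                 seed = 11, box_edge = 6, spacing = 0.8)
  expect_identical(r1$replica_temps, r2$replica_temps)
  expect_identical(r1$trajectories[[1]]$frames, r2$trajectories[[1]]$frames)
})

test_that("burn-in marking discards the unequilibrated head", {
  # a decaying series stabilises: the running-mean rule cuts the transient
  e <- c(seq(100, 0, length.out = 50), stats::rnorm(150, 0, 1))
  k <- burnin_index(e, window = 20, tol = 0.5)
  expect_gt(k, 10)
  expect_lt(k, 120)
  # fallback: first half discarded
  expect_equal(burnin_index(stats::rnorm(40)), 21L)
  expect_equal(burnin_index(numeric(0)), 1L)
})
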